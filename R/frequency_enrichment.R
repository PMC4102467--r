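#' Configuration for frequency-enrichment analysis
#'
#' @param tail_fraction Fraction of the ratio-ranked list considered as each
#'   tail (default 0.025, the top/bottom 2.5%).
#' @param enrich_ratio_min Minimum panel:reference frequency ratio for a
#'   top-tail variant to be called enriched (default 10).
#' @param deplete_ratio_max Maximum ratio for a bottom-tail variant to be
#'   called depleted (default 0.1).
#' @param window_size Odd sliding-window width, in variants, for the
#'   functional-fraction profile (default 2001).
#' @return A list of class `enrichment_config`.
#' @export
enrichment_config <- function(tail_fraction = 0.025, enrich_ratio_min = 10,
                              deplete_ratio_max = 0.1, window_size = 2001) {
  stopifnot(tail_fraction > 0, tail_fraction < 0.5,
            window_size >= 3, window_size %% 2 == 1)
  structure(
    list(tail_fraction = tail_fraction, enrich_ratio_min = enrich_ratio_min,
         deplete_ratio_max = deplete_ratio_max, window_size = window_size),
    class = "enrichment_config"
  )
}

#' Mean panel allelic frequency of each variant
#'
#' The panel frequency of a variant is the mean of its per-line allelic
#' fractions (percent conversion / 100) over the panel; lines without the
#' variant contribute 0.
#'
#' @param catalog A variant table.
#' @param lines Optional character vector of cell line columns to average
#'   over (default: all cell line columns of `catalog`).
#' @return Numeric vector of frequencies in \[0,1\], one per row.
#' @export
panel_variant_frequency <- function(catalog, lines = NULL) {
  if (is.null(lines)) lines <- cell_line_columns(catalog)
  if (length(lines) == 0) abort("empty cell line panel")
  pc <- as.matrix(catalog[, lines, drop = FALSE])
  rowMeans(pc) / 100
}

#' Build panel-vs-reference frequency comparisons
#'
#' Restricts to variants present in the reference (ESP5400-style frequency
#' known and > 0; ratio is undefined otherwise — reference-absent variants
#' belong to the homozygous-deleterious catalog instead) and computes the
#' panel:reference frequency ratio. The 1000 Genomes column is carried but
#' not used as the denominator: the reference must be exome data on the same
#' footing as the panel.
#'
#' @param catalog A variant table.
#' @param criteria A [functional_criteria()] object, used to label each
#'   comparison with its function-affecting category.
#' @return Tibble with `variant_id`, `gene`, `panel_freq`, `ref_freq`,
#'   `ratio`, and `functional` (logical: category != none).
#' @export
frequency_comparisons <- function(catalog, criteria = functional_criteria()) {
  category <- assess_protein_function_effect(catalog, criteria)
  keep <- !is.na(catalog$freq_esp5400) & catalog$freq_esp5400 > 0
  tibble(
    variant_id = catalog$variant_id[keep],
    gene = catalog$gene[keep],
    panel_freq = panel_variant_frequency(catalog)[keep],
    ref_freq = catalog$freq_esp5400[keep],
    ratio = panel_variant_frequency(catalog)[keep] / catalog$freq_esp5400[keep],
    functional = category[keep] != "none"
  )
}

#' Classify variants as enriched, depleted, or neither
#'
#' Variants are ranked by the panel:reference ratio. Enriched variants are
#' those in the top `tail_fraction` of the ranking whose ratio is at least
#' `enrich_ratio_min`; when the tail cutoff falls inside a group of equal
#' ratios, the whole tied group is included. Depleted variants satisfy the
#' symmetric rule at the bottom tail with ratio at most `deplete_ratio_max`.
#' Tie comparison uses a 1e-12 relative tolerance on the ratio.
#'
#' @param comparisons A tibble from [frequency_comparisons()] (any tibble
#'   with a `ratio` column works).
#' @param config An [enrichment_config()].
#' @return `comparisons` sorted by descending ratio, with `rank` and
#'   `enrichment_class` (factor: enriched/depleted/neither) columns added.
#' @export
classify_enrichment <- function(comparisons, config = enrichment_config()) {
  stopifnot(all(is.finite(comparisons$ratio)))
  x <- comparisons[order(-comparisons$ratio), , drop = FALSE]
  n <- nrow(x)
  x$rank <- seq_len(n)
  cls <- rep("neither", n)
  k <- floor(config$tail_fraction * n)
  tied <- function(r, r0) abs(r - r0) <= 1e-12 * pmax(1, abs(r0))
  if (k >= 1) {
    r_cut <- x$ratio[k]
    enr <- (x$rank <= k & x$ratio >= config$enrich_ratio_min)
    if (r_cut >= config$enrich_ratio_min) enr <- enr | tied(x$ratio, r_cut)
    cls[enr] <- "enriched"
    r_cut_lo <- x$ratio[n - k + 1]
    dep <- (x$rank > n - k & x$ratio <= config$deplete_ratio_max)
    if (r_cut_lo <= config$deplete_ratio_max) dep <- dep | tied(x$ratio, r_cut_lo)
    cls[dep & cls != "enriched"] <- "depleted"
  }
  x$enrichment_class <- factor(cls, levels = c("enriched", "depleted", "neither"))
  x
}

#' Sliding-window fraction of function-affecting variants along the ranking
#'
#' With the comparisons sorted by descending ratio, computes for every full
#' window of `window_size` consecutive variants the percentage that are
#' function-affecting. Used to profile how functional relevance changes with
#' panel enrichment.
#'
#' @param comparisons A tibble with `ratio` and logical `functional` columns.
#' @param window_size Odd window width; must not exceed the number of rows.
#' @return Tibble with one row per window: `center_rank`, `center_ratio`,
#'   `percent_functional`.
#' @export
sliding_window_functional_fraction <- function(comparisons, window_size) {
  stopifnot(window_size >= 3, window_size %% 2 == 1)
  n <- nrow(comparisons)
  if (n < window_size) {
    abort(sprintf(
      "list of %d comparisons is shorter than the window (%d); use a smaller window",
      n, window_size))
  }
  x <- comparisons[order(-comparisons$ratio), , drop = FALSE]
  f <- as.numeric(x$functional)
  cs <- cumsum(c(0, f))
  counts <- cs[(window_size + 1):(n + 1)] - cs[1:(n - window_size + 1)]
  half <- (window_size - 1) / 2
  centers <- (1 + half):(n - half)
  tibble(
    center_rank = centers,
    center_ratio = x$ratio[centers],
    percent_functional = 100 * counts / window_size
  )
}
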