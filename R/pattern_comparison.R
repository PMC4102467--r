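#' Correlate a per-line pattern against every drug's activity profile
#'
#' Computes, for each drug row, the Pearson correlation between an arbitrary
#' per-cell-line pattern (e.g. the Totals row of a variant summation) and
#' the drug's z-scores, using pairwise-complete observations, with a
#' two-tailed t-based p-value at n - 2 df. Positive correlations mean the
#' drug works better in lines carrying the pattern; negative, worse. Drugs
#' with fewer than 3 paired observations are dropped. Rows are sorted by
#' decreasing |r|, ties broken by NSC id.
#'
#' @param pattern Named numeric vector (names are cell lines).
#' @param drugs A drug tibble with z-score cell line columns.
#' @param alpha Significance threshold for the `significant` flag
#'   (default 0.05).
#' @return Tibble with `nsc`, `name`, `moa`, `r`, `p`, `n`, `significant`.
#' @export
correlate_pattern <- function(pattern, drugs, alpha = 0.05) {
  cells <- intersect(names(pattern), cell_line_columns(drugs))
  if (length(cells) < 3) abort("pattern and drug matrix share fewer than 3 cell lines")
  if (stats::var(pattern[cells], na.rm = TRUE) == 0) {
    abort("pattern is constant across cell lines; correlation is undefined")
  }
  rows <- lapply(seq_len(nrow(drugs)), function(d) {
    z <- as.numeric(drugs[d, cells])
    ok <- !is.na(z) & !is.na(pattern[cells])
    if (sum(ok) < 3) return(NULL)
    if (stats::var(z[ok]) == 0) return(NULL)
    ct <- cor.test(pattern[cells][ok], z[ok], method = "pearson")
    tibble(
      nsc = as.character(drugs$nsc[d]),
      name = drugs$name[d],
      moa = drugs$moa[d],
      r = unname(ct$estimate),
      p = ct$p.value,
      n = as.integer(sum(ok))
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(nsc = character(), name = character(), moa = character(),
                  r = numeric(), p = numeric(), n = integer(),
                  significant = logical()))
  }
  out$significant <- out$p < alpha
  out[order(-abs(out$r), out$nsc), , drop = FALSE]
}

#' Enrichment of pathway-targeting drugs among significant correlations
#'
#' Two-tailed Fisher exact test on the 2x2 table crossing significance of
#' the pattern correlation with whether a drug targets the pathway of
#' interest, over a universe of drugs with known mechanism of action.
#'
#' @param significant Character vector of significant drug ids (subset of
#'   `universe`).
#' @param pathway_targeting Character vector of pathway-targeting drug ids
#'   (subset of `universe`).
#' @param universe Character vector of all drugs considered.
#' @return Two-tailed p-value.
#' @export
pathway_target_enrichment <- function(significant, pathway_targeting, universe) {
  if (length(universe) == 0) abort("drug universe is empty")
  significant <- intersect(significant, universe)
  pathway_targeting <- intersect(pathway_targeting, universe)
  a <- length(intersect(significant, pathway_targeting))
  b <- length(significant) - a
  c_ <- length(pathway_targeting) - a
  d <- length(universe) - a - b - c_
  fisher_exact_2x2(a, b, c_, d)
}
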