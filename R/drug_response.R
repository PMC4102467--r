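#' Transform GI50 measurements to per-drug activity z-scores
#'
#' Each drug row of molar GI50 values is converted to activity scores as
#' -log10(GI50) (so larger means more potent), then standardized over the
#' observed cells of that row using the population standard deviation
#' (divisor n). Missing cells stay missing; observed cells of every retained
#' row have mean 0 and SD 1. Rows with fewer than two observed cells or zero
#' variance are excluded and reported via the `"excluded"` attribute rather
#' than propagating NaN.
#'
#' @param gi50 Numeric matrix (drugs x cell lines) of positive molar GI50
#'   values, or a drug tibble whose cell line columns hold GI50s.
#' @param already_log Set `TRUE` if the input is already on the -log10 scale.
#' @return Object of the same shape with z-scores in the cell line cells and
#'   an `"excluded"` attribute: a tibble of dropped rows and reasons.
#' @export
gi50_to_zscores <- function(gi50, already_log = FALSE) {
  if (is.data.frame(gi50)) {
    cells <- cell_line_columns(gi50)
    m <- as.matrix(gi50[, cells, drop = FALSE])
    rownames(m) <- if ("nsc" %in% names(gi50)) as.character(gi50$nsc) else NULL
    z <- gi50_to_zscores(m, already_log = already_log)
    keep <- !(seq_len(nrow(gi50)) %in% attr(z, "excluded")$row)
    out <- gi50[keep, , drop = FALSE]
    out[, cells] <- as_tibble(as.data.frame(z))
    attr(out, "excluded") <- attr(z, "excluded")
    return(out)
  }
  stopifnot(is.matrix(gi50))
  if (!already_log && any(gi50 <= 0, na.rm = TRUE)) {
    abort("GI50 values must be positive molar concentrations")
  }
  act <- if (already_log) gi50 else -log10(gi50)
  n_obs <- rowSums(!is.na(act))
  mu <- rowMeans(act, na.rm = TRUE)
  dev <- act - mu
  sdev <- sqrt(rowSums(dev^2, na.rm = TRUE) / n_obs) # population SD
  reason <- rep(NA_character_, nrow(act))
  reason[n_obs == 0] <- "all missing"
  reason[n_obs == 1] <- "single observation"
  reason[n_obs >= 2 & sdev == 0] <- "zero variance"
  excluded <- tibble(
    row = which(!is.na(reason)),
    nsc = if (is.null(rownames(act))) NA_character_ else rownames(act)[!is.na(reason)],
    reason = reason[!is.na(reason)]
  )
  keep <- is.na(reason)
  z <- dev[keep, , drop = FALSE] / sdev[keep]
  attr(z, "excluded") <- excluded
  z
}

#' Categorize a z-score as resistant, no response, or sensitive
#'
#' A line is resistant to a drug at z <= -0.5, sensitive at z >= 0.5, and
#' shows no response in between; the boundary values belong to the outer
#' classes. Missing z stays `NA` — an unmeasured cell is excluded from
#' counts, it is not "no response".
#'
#' @param z Numeric vector of z-scores.
#' @return Factor with levels `resistant`, `none`, `sensitive` (`NA` kept).
#' @export
categorize_response <- function(z) {
  out <- rep(NA_character_, length(z))
  out[!is.na(z) & z <= -0.5] <- "resistant"
  out[!is.na(z) & z > -0.5 & z < 0.5] <- "none"
  out[!is.na(z) & z >= 0.5] <- "sensitive"
  factor(out, levels = c("resistant", "none", "sensitive"))
}

#' Per-line resistance:sensitivity response profiles
#'
#' For each cell line, counts the drugs to which it is sensitive (z >= 0.5)
#' or resistant (z <= -0.5), and forms the resistance:sensitivity ratio and
#' its -log10. Lines with zero sensitive calls have an undefined ratio
#' (`NA`). The drug set can be restricted (e.g. to FDA-approved drugs) and
#' tissues excluded (e.g. the generally drug-sensitive leukemias).
#'
#' @param drugs A drug tibble with z-score cell line columns.
#' @param subset Optional logical or integer vector selecting drug rows, or a
#'   character vector of `status` values to keep (e.g. `"fda_approved"`).
#' @param exclude_tissues Optional character vector of tissue prefixes to
#'   drop (e.g. `"LE"`).
#' @return Tibble with `cell_line`, `tissue`, `n_sensitive`, `n_resistant`,
#'   `ratio` (resistant/sensitive) and `neg_log10_ratio`.
#' @export
resistance_sensitivity_profile <- function(drugs, subset = NULL,
                                           exclude_tissues = NULL) {
  if (nrow(drugs) == 0) abort("empty drug matrix")
  if (!is.null(subset)) {
    if (is.character(subset)) subset <- drugs$status %in% subset
    drugs <- drugs[subset, , drop = FALSE]
  }
  cells <- cell_line_columns(drugs)
  tissue <- sub(":.*$", "", cells)
  if (!is.null(exclude_tissues)) {
    keep <- !(tissue %in% exclude_tissues)
    cells <- cells[keep]
    tissue <- tissue[keep]
  }
  z <- as.matrix(drugs[, cells, drop = FALSE])
  n_sens <- colSums(z >= 0.5, na.rm = TRUE)
  n_res <- colSums(z <= -0.5, na.rm = TRUE)
  ratio <- unname(ifelse(n_sens > 0, n_res / n_sens, NA_real_))
  tibble(
    cell_line = cells,
    tissue = tissue,
    n_sensitive = as.integer(n_sens),
    n_resistant = as.integer(n_res),
    ratio = ratio,
    neg_log10_ratio = -log10(ratio)
  )
}

#' Correlate two per-line resistance:sensitivity profiles
#'
#' Pearson correlation (with a two-tailed t-based p at n-2 df) between the
#' -log10 resistance:sensitivity ratios of two profiles, e.g. all compounds
#' versus the FDA-approved subset. Pairs with an undefined ratio in either
#' profile are dropped.
#'
#' @param all_profile,subset_profile Profile tibbles from
#'   [resistance_sensitivity_profile()], or named numeric vectors of ratios.
#' @return List with `r`, `p`, and `n` (paired lines used).
#' @export
compare_ratio_profiles <- function(all_profile, subset_profile) {
  as_named <- function(p) {
    if (is.data.frame(p)) stats::setNames(p$ratio, p$cell_line) else p
  }
  a <- as_named(all_profile)
  b <- as_named(subset_profile)
  shared <- intersect(names(a), names(b))
  x <- -log10(a[shared])
  y <- -log10(b[shared])
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) abort("fewer than 3 paired observed ratios")
  ct <- cor.test(x[ok], y[ok], method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' Plot per-line resistance:sensitivity profiles
#'
#' Horizontal bar chart of -log10 resistance:sensitivity ratios per cell
#' line, colored by tissue of origin.
#'
#' @param profile A tibble from [resistance_sensitivity_profile()].
#' @return A ggplot object.
#' @export
plot_response_profiles <- function(profile) {
  profile <- profile[!is.na(profile$ratio), , drop = FALSE]
  ggplot2::ggplot(
    profile,
    ggplot2::aes(x = .data$neg_log10_ratio,
                 y = stats::reorder(.data$cell_line, .data$neg_log10_ratio),
                 fill = .data$tissue)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "-log10(resistance : sensitivity)", y = NULL,
                  fill = "Tissue") +
    ggplot2::theme_minimal()
}
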