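# Independent oracles used to cross-check the package implementations.
# These deliberately avoid the code paths they verify.

# MCC as the Pearson correlation of the two binary vectors a contingency
# table expands to (carrier indicator vs responder indicator).
oracle_mcc_pearson <- function(tp, fp, fn, tn) {
  carrier <- c(rep(1, tp + fp), rep(0, fn + tn))
  responder <- c(rep(1, tp), rep(0, fp), rep(1, fn), rep(0, tn))
  if (stats::sd(carrier) == 0 || stats::sd(responder) == 0) return(0)
  stats::cor(carrier, responder)
}

# Two-tailed Fisher exact p by explicit hypergeometric enumeration over the
# table's margins, summing the probabilities of all tables at most as
# probable as the observed one (with the conventional 1e-7 relative slack
# for floating-point ties).
oracle_fisher_p <- function(a, b, c, d) {
  m1 <- a + b   # first-margin total
  m2 <- a + c   # second-margin total
  N <- a + b + c + d
  if (N == 0) return(1)
  support <- max(0, m1 + m2 - N):min(m1, m2)
  logp <- lchoose(m1, support) + lchoose(N - m1, m2 - support) - lchoose(N, m2)
  p <- exp(logp)
  p_obs <- p[support == a]
  sum(p[p <= p_obs * (1 + 1e-7)])
}

# Brute-force best-MCC subset search: enumerate every non-empty subset of
# size <= max_size, score its carrier union with the Pearson oracle.
oracle_best_subset_mcc <- function(carrier_mat, resp, max_size = 5) {
  nv <- nrow(carrier_mat)
  best <- -Inf
  for (k in seq_len(min(max_size, nv))) {
    for (s in utils::combn(nv, k, simplify = FALSE)) {
      u <- colSums(carrier_mat[s, , drop = FALSE]) > 0
      tp <- sum(u & resp); fp <- sum(u & !resp)
      fn <- sum(!u & resp); tn <- sum(!u & !resp)
      best <- max(best, oracle_mcc_pearson(tp, fp, fn, tn))
    }
  }
  best
}

# Two-tailed t-tail probability by numerical quadrature of the t density.
oracle_t_two_tail <- function(tstat, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  2 * stats::integrate(dens, abs(tstat), Inf, rel.tol = 1e-10)$value
}

# --- fixture builders -------------------------------------------------------

toy_cell_lines <- function(n = 4) {
  prefixes <- c("BR", "CO", "ME", "LC", "OV", "RE", "LE", "CNS", "PR")
  sprintf("%s:T%02d", rep_len(prefixes, n), seq_len(n))
}

# One variant row in the canonical table dialect. `percents` is a named
# vector over the panel; unnamed lines default to 0.
toy_variant <- function(cell_lines, gene = "G1",
                        variant_id = "chr1:1000_A_T",
                        change_type = "missense", aa_impact = "A1T",
                        dbsnp_id = NA_character_, sift = NA_real_,
                        polyphen2 = NA_real_, freq_1000g = 0,
                        freq_esp5400 = 0, in_segdup = FALSE, multimap = FALSE,
                        percents = numeric(0)) {
  pc <- stats::setNames(rep(0, length(cell_lines)), cell_lines)
  pc[names(percents)] <- percents
  dplyr::bind_cols(
    tibble::tibble(
      gene = gene, variant_id = variant_id, change_type = change_type,
      aa_impact = aa_impact, dbsnp_id = dbsnp_id, sift = sift,
      polyphen2 = polyphen2, freq_1000g = freq_1000g,
      freq_esp5400 = freq_esp5400, in_segdup = in_segdup, multimap = multimap
    ),
    tibble::as_tibble(as.list(pc))
  )
}

toy_drug <- function(cell_lines, nsc = "1", name = "drug", moa = "YK",
                     status = "fda_approved", z = numeric(0)) {
  row <- stats::setNames(rep(NA_real_, length(cell_lines)), cell_lines)
  row[names(z)] <- z
  dplyr::bind_cols(
    tibble::tibble(nsc = nsc, name = name, moa = moa, status = status),
    tibble::as_tibble(as.list(row))
  )
}
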