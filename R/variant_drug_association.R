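#' Matthews correlation coefficient from a 2x2 contingency table
#'
#' MCC of the binary classification implied by a table of true/false
#' positives and negatives:
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' Here TP counts cell lines that carry the variant(s) and respond to the
#' drug, FP carriers that do not respond, FN responders without the
#' variant(s), and TN lines with neither. When any marginal factor is zero
#' the coefficient is defined as 0. Equivalent to the Pearson correlation of
#' the two implied 0/1 vectors.
#'
#' @param tp,fp,fn,tn Non-negative counts; vectors recycle.
#' @return Numeric vector of MCC values in \[-1, 1\].
#' @examples
#' matthews_correlation(9, 1, 0, 49) # 0.939...
#' @export
matthews_correlation <- function(tp, fp, fn, tn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  # clamp away sub-ulp overshoot so perfect tables give exactly +-1
  pmin(1, pmax(-1, ifelse(den == 0, 0, num / den)))
}

#' Significance of an observed MCC
#'
#' Two-tailed p-value from the Pearson-style t transform
#' `t = mcc * sqrt(n - 2) / sqrt(1 - mcc^2)` referred to a t distribution
#' with n - 2 degrees of freedom. At the screen's gate of MCC 0.596 with n =
#' 35 evaluable lines this gives p = 1.6e-4, consistent with the p <= 2e-4
#' calibration the gate is quoted at. `|mcc| = 1` returns the smallest
#' representable positive value.
#'
#' @param mcc MCC value(s) in \[-1, 1\].
#' @param n Number of evaluable cell lines (>= 3).
#' @return Two-tailed p-value(s).
#' @export
mcc_significance <- function(mcc, n) {
  stopifnot(all(n >= 3), all(abs(mcc) <= 1 + 1e-9))
  mcc <- pmin(1, pmax(-1, mcc))
  p <- rep(.Machine$double.xmin, length(mcc))
  ok <- abs(mcc) < 1
  tstat <- mcc[ok] * sqrt(n - 2) / sqrt(1 - mcc[ok]^2)
  p[ok] <- 2 * pt(-abs(tstat), df = n - 2)
  p
}

#' Screen configuration for the variant-subset vs drug-response search
#'
#' @param max_subset_size Largest variant combination searched (default 5).
#' @param max_carriers_per_variant Single variants carried by more lines than
#'   this are ineligible (default 12, i.e. "fewer than 13 lines").
#' @param min_consistent_cells Minimum true positives for a reported pair
#'   (default 3).
#' @param mcc_min MCC gate (default 0.596, calibrated to p <= 2e-4 at n=35).
#' @param precision_min Precision gate for the winning subset (default 0.70).
#' @param gene_precision_min Gate on the precision of the union of all the
#'   gene's eligible variants against the same responders (default 0.50).
#' @param shift_sd Response binarization threshold in SD units (default 0.5).
#' @param reference_n Evaluable-line count at which `mcc_min` was calibrated.
#' @param exhaustive_max_variants Genes with more eligible variants than this
#'   fall back to greedy forward selection (default 25).
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(max_subset_size = 5, max_carriers_per_variant = 12,
                          min_consistent_cells = 3, mcc_min = 0.596,
                          precision_min = 0.70, gene_precision_min = 0.50,
                          shift_sd = 0.5, reference_n = 35,
                          exhaustive_max_variants = 25) {
  stopifnot(max_subset_size >= 1, max_carriers_per_variant >= 1,
            mcc_min >= -1, mcc_min <= 1, precision_min >= 0, precision_min <= 1,
            gene_precision_min >= 0, gene_precision_min <= 1, shift_sd >= 0)
  structure(
    list(max_subset_size = max_subset_size,
         max_carriers_per_variant = max_carriers_per_variant,
         min_consistent_cells = min_consistent_cells, mcc_min = mcc_min,
         precision_min = precision_min, gene_precision_min = gene_precision_min,
         shift_sd = shift_sd, reference_n = reference_n,
         exhaustive_max_variants = exhaustive_max_variants),
    class = "screen_config"
  )
}

#' Binarize a drug's z-score row into responders and evaluable lines
#'
#' A line responds in the sensitivity direction when its z-score is at least
#' `+shift_sd`, and in the resistance direction when it is at most
#' `-shift_sd` (shifted from the panel mean by 0.5 SD under the default).
#' Lines with an observed z-score form the evaluable set; missing cells are
#' excluded from both sets.
#'
#' @param z_row Named numeric vector of z-scores (names are cell lines).
#' @param direction `"sensitivity"` or `"resistance"`.
#' @param shift_sd Threshold in SD units (default 0.5).
#' @return List with character vectors `responders` and `evaluable`.
#' @export
binarize_drug_response <- function(z_row, direction = c("sensitivity", "resistance"),
                                   shift_sd = 0.5) {
  direction <- match.arg(direction)
  evaluable <- names(z_row)[!is.na(z_row)]
  z <- z_row[evaluable]
  responders <- if (direction == "sensitivity") {
    evaluable[z >= shift_sd]
  } else {
    evaluable[z <= -shift_sd]
  }
  list(responders = responders, evaluable = evaluable)
}

#' Eligible variants of a gene for the association screen
#'
#' Keeps amino-acid-changing variants carried by at most
#' `max_carriers_per_variant` lines (carrier = percent conversion > 0; a
#' heterozygous call counts as carrying), not in segmental duplications, and
#' not multi-mapping. Variants are kept regardless of presence or absence in
#' the reference populations: the screen aims at both disease-associated and
#' germline influences.
#'
#' @param gene_records Variant-table rows for one gene.
#' @param config A [screen_config()].
#' @return The eligible subset of `gene_records`.
#' @export
eligible_variants <- function(gene_records, config = screen_config()) {
  if (nrow(gene_records) == 0) return(gene_records)
  stopifnot(length(unique(gene_records$gene)) <= 1)
  cells <- cell_line_columns(gene_records)
  carriers <- rowSums(as.matrix(gene_records[, cells, drop = FALSE]) > 0)
  keep <- is_amino_acid_changing(gene_records$change_type) &
    carriers <= config$max_carriers_per_variant &
    !gene_records$in_segdup & !gene_records$multimap
  gene_records[keep, , drop = FALSE]
}

# Logical carrier matrix (variants x lines), restricted to the given lines.
carrier_matrix <- function(gene_records, lines) {
  m <- as.matrix(gene_records[, lines, drop = FALSE]) > 0
  rownames(m) <- gene_records$variant_id
  m
}

# All non-empty variant index subsets of size <= max_size, as a list.
enumerate_subsets <- function(n_variants, max_size) {
  unlist(lapply(seq_len(min(max_size, n_variants)), function(k) {
    combn(n_variants, k, simplify = FALSE)
  }), recursive = FALSE)
}

# Contingency stats for a set of carrier-union indicator rows vs responders.
# U: logical matrix (subsets x lines); resp: logical vector over same lines.
subset_stats <- function(U, resp) {
  n <- length(resp)
  tp <- as.vector(U %*% resp)
  carriers <- rowSums(U)
  fp <- carriers - tp
  fn <- sum(resp) - tp
  tn <- n - carriers - fn
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       mcc = matthews_correlation(tp, fp, fn, tn),
       precision = ifelse(carriers > 0, tp / carriers, NA_real_))
}

assemble_result <- function(gene, subset_ids, st, i, n_eval, gene_precision,
                            search) {
  tibble(
    gene = gene,
    variants = paste(sort(subset_ids), collapse = ","),
    n_variants = length(subset_ids),
    tp = as.integer(st$tp[i]), fp = as.integer(st$fp[i]),
    fn = as.integer(st$fn[i]), tn = as.integer(st$tn[i]),
    mcc = st$mcc[i],
    precision = st$precision[i],
    recall = ifelse(st$tp[i] + st$fn[i] > 0, st$tp[i] / (st$tp[i] + st$fn[i]),
                    NA_real_),
    p = mcc_significance(st$mcc[i], n_eval),
    n_evaluable = as.integer(n_eval),
    gene_overall_precision = gene_precision,
    search = search
  )
}

# Pick the best subset index: max MCC, then fewer variants, then higher
# precision, then lexicographically smallest sorted variant-id string.
pick_best <- function(st, subsets, variant_ids) {
  sizes <- lengths(subsets)
  keys <- vapply(subsets, function(s) paste(sort(variant_ids[s]), collapse = ","), "")
  ord <- order(-st$mcc, sizes, -st$precision, keys)
  ord[1]
}

#' Best variant combination of a gene for one drug response
#'
#' Searches non-empty subsets of the gene's eligible variants (subset carrier
#' set = union of member carriers, on evaluable lines only) for the one whose
#' carrier/responder contingency table maximizes the MCC. Ties break toward
#' fewer variants, then higher precision, then lexicographic variant ids.
#' Exhaustive over all subsets of size up to `max_subset_size` when the gene
#' has at most `exhaustive_max_variants` eligible variants; beyond that, a
#' greedy forward selection (adding the variant that most increases the MCC)
#' is used and flagged in the `search` column.
#'
#' When `require_thresholds` is `TRUE` the result is reported only if it
#' passes all screen gates: `mcc >= mcc_min`, `precision >= precision_min`,
#' `gene_overall_precision >= gene_precision_min` (precision of the union of
#' all the gene's eligible variants against the same responders), and
#' `tp >= min_consistent_cells`.
#'
#' @param variants Eligible variant rows for one gene (see
#'   [eligible_variants()]).
#' @param responders Character vector of responding cell lines.
#' @param evaluable Character vector of evaluable cell lines.
#' @param config A [screen_config()].
#' @param require_thresholds Apply the reporting gates (default `TRUE`).
#' @return A one-row tibble, or `NULL` when nothing passes (or no variants).
#' @export
best_variant_combination <- function(variants, responders, evaluable,
                                     config = screen_config(),
                                     require_thresholds = TRUE) {
  if (nrow(variants) == 0 || length(evaluable) == 0) return(NULL)
  cm <- carrier_matrix(variants, evaluable)
  resp <- evaluable %in% responders
  nv <- nrow(cm)
  gene_precision <- {
    union_all <- colSums(cm) > 0
    if (sum(union_all) > 0) sum(union_all & resp) / sum(union_all) else NA_real_
  }
  if (nv <= config$exhaustive_max_variants) {
    subsets <- enumerate_subsets(nv, config$max_subset_size)
    U <- do.call(rbind, lapply(subsets, function(s) {
      colSums(cm[s, , drop = FALSE]) > 0
    }))
    st <- subset_stats(U, resp)
    best <- pick_best(st, subsets, rownames(cm))
    search <- "exhaustive"
    subset_ids <- rownames(cm)[subsets[[best]]]
    res <- assemble_result(variants$gene[1], subset_ids, st, best,
                           length(evaluable), gene_precision, search)
  } else {
    chosen <- integer(0)
    best_mcc <- -Inf
    repeat {
      if (length(chosen) >= config$max_subset_size) break
      cand <- setdiff(seq_len(nv), chosen)
      U <- do.call(rbind, lapply(cand, function(j) {
        colSums(cm[c(chosen, j), , drop = FALSE]) > 0
      }))
      st <- subset_stats(U, resp)
      j <- which.max(st$mcc)
      if (st$mcc[j] <= best_mcc) break
      best_mcc <- st$mcc[j]
      chosen <- c(chosen, cand[j])
    }
    U <- matrix(colSums(cm[chosen, , drop = FALSE]) > 0, nrow = 1)
    st <- subset_stats(U, resp)
    res <- assemble_result(variants$gene[1], rownames(cm)[chosen], st, 1,
                           length(evaluable), gene_precision, "greedy")
  }
  if (require_thresholds) {
    ok <- !is.na(res$mcc) && res$mcc >= config$mcc_min &&
      !is.na(res$precision) && res$precision >= config$precision_min &&
      !is.na(res$gene_overall_precision) &&
      res$gene_overall_precision >= config$gene_precision_min &&
      res$tp >= config$min_consistent_cells
    if (!ok) return(NULL)
  }
  res
}

#' Screen every gene x drug x direction for variant-response associations
#'
#' Runs [best_variant_combination()] for each gene of the catalog against
#' each drug of the activity matrix, in both the sensitivity and resistance
#' directions, and collects the pairs passing all gates. No multiple-testing
#' correction is applied beyond the fixed MCC/p gate; all passing results are
#' reported.
#'
#' @param catalog A variant table.
#' @param drugs A drug tibble with z-score cell line columns.
#' @param config A [screen_config()].
#' @return A list with tibbles `sensitivity` and `resistance`, each one row
#'   per reported gene-drug pair with the contingency counts, `mcc`,
#'   `precision`, `recall`, `p`, and the winning variant ids.
#' @export
association_screen <- function(catalog, drugs, config = screen_config()) {
  cat_cells <- cell_line_columns(catalog)
  drug_cells <- cell_line_columns(drugs)
  shared <- intersect(cat_cells, drug_cells)
  if (nrow(catalog) > 0 && nrow(drugs) > 0 && length(shared) == 0) {
    abort("variant catalog and drug matrix share no cell lines")
  }
  empty <- function() {
    res <- best_template()
    res[0, ]
  }
  out <- list(sensitivity = list(), resistance = list())
  if (nrow(drugs) == 0 || nrow(catalog) == 0) {
    return(list(sensitivity = empty(), resistance = empty()))
  }
  zmat <- as.matrix(drugs[, shared, drop = FALSE])
  rownames(zmat) <- as.character(drugs$nsc)
  genes <- unique(catalog$gene)
  for (g in genes) {
    gene_records <- catalog[catalog$gene == g, , drop = FALSE]
    ev <- eligible_variants(gene_records, config)
    if (nrow(ev) == 0) next
    nv <- nrow(ev)
    exhaustive <- nv <= config$exhaustive_max_variants
    cm_full <- carrier_matrix(ev, shared)
    U_full <- subsets_full <- NULL
    if (exhaustive) {
      subsets_full <- enumerate_subsets(nv, config$max_subset_size)
      U_full <- do.call(rbind, lapply(subsets_full, function(s) {
        colSums(cm_full[s, , drop = FALSE]) > 0
      }))
    }
    for (d in seq_len(nrow(drugs))) {
      z_row <- zmat[d, ]
      observed <- !is.na(z_row)
      if (!any(observed)) next
      complete <- all(observed)
      for (direction in c("sensitivity", "resistance")) {
        resp <- if (direction == "sensitivity") {
          z_row[observed] >= config$shift_sd
        } else {
          z_row[observed] <= -config$shift_sd
        }
        if (exhaustive && complete) {
          # fast path: reuse the gene's precomputed subset-union matrix and
          # only assemble a result when the best subset can pass the gate
          st <- subset_stats(U_full, resp)
          if (max(st$mcc) < config$mcc_min) next
          best <- pick_best(st, subsets_full, rownames(cm_full))
          union_all <- colSums(cm_full) > 0
          gene_precision <- if (sum(union_all) > 0) {
            sum(union_all & resp) / sum(union_all)
          } else NA_real_
          res <- assemble_result(g, rownames(cm_full)[subsets_full[[best]]],
                                 st, best, sum(observed), gene_precision,
                                 "exhaustive")
          ok <- res$mcc >= config$mcc_min &&
            !is.na(res$precision) && res$precision >= config$precision_min &&
            !is.na(res$gene_overall_precision) &&
            res$gene_overall_precision >= config$gene_precision_min &&
            res$tp >= config$min_consistent_cells
          if (!ok) next
        } else {
          evaluable <- shared[observed]
          res <- best_variant_combination(ev, evaluable[resp], evaluable, config)
          if (is.null(res)) next
        }
        res$nsc <- as.character(drugs$nsc[d])
        res$name <- drugs$name[d]
        res$moa <- drugs$moa[d]
        res$status <- drugs$status[d]
        res$direction <- direction
        out[[direction]] <- c(out[[direction]], list(res))
      }
    }
  }
  finish <- function(rows) {
    if (length(rows) == 0) return(empty())
    x <- dplyr::bind_rows(rows)
    x[, names(best_template())]
  }
  list(sensitivity = finish(out$sensitivity), resistance = finish(out$resistance))
}

best_template <- function() {
  tibble(
    gene = character(), nsc = character(), name = character(),
    moa = character(), status = character(), direction = character(),
    tp = integer(), fp = integer(), fn = integer(), tn = integer(),
    mcc = numeric(), precision = numeric(), recall = numeric(), p = numeric(),
    n_evaluable = integer(), gene_overall_precision = numeric(),
    n_variants = integer(), variants = character(), search = character()
  )
}

#' Partition winning variants by presence in the reference populations
#'
#' Labels every variant appearing in a reported winning combination as
#' present or absent in the non-cancerous reference populations (absent =
#' frequency missing or exactly 0 in both the 1000 Genomes and ESP5400
#' columns), totals them over the report rows significant at each p-value
#' threshold, and returns the proportions (which sum to 1 at each threshold
#' with any counts).
#'
#' @param report A report tibble (e.g. the row-bound output of
#'   [association_screen()]).
#' @param catalog The variant table the screen ran on.
#' @param p_thresholds Numeric thresholds (default `c(0.05, 2e-4, 1e-6, 1e-8)`).
#' @return Tibble with one row per threshold: `p_threshold`, `n_absent`,
#'   `n_present`, `prop_absent`, `prop_present`.
#' @export
provenance_partition <- function(report, catalog,
                                 p_thresholds = c(0.05, 2e-4, 1e-6, 1e-8)) {
  absent_lookup <- stats::setNames(
    (is.na(catalog$freq_1000g) | catalog$freq_1000g == 0) &
      (is.na(catalog$freq_esp5400) | catalog$freq_esp5400 == 0),
    catalog$variant_id
  )
  rows <- lapply(p_thresholds, function(th) {
    sig <- report[!is.na(report$p) & report$p < th, , drop = FALSE]
    vids <- unlist(strsplit(sig$variants, ",", fixed = TRUE))
    n_abs <- sum(absent_lookup[vids])
    n_pres <- length(vids) - n_abs
    tot <- length(vids)
    tibble(
      p_threshold = th, n_absent = n_abs, n_present = n_pres,
      prop_absent = if (tot > 0) n_abs / tot else NA_real_,
      prop_present = if (tot > 0) n_pres / tot else NA_real_
    )
  })
  dplyr::bind_rows(rows)
}
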