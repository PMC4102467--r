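#' Declare a planted variant-drug effect
#'
#' @param gene Gene symbol (must exist in the simulated catalog).
#' @param nsc Drug id (must exist in the simulated drug table).
#' @param direction `"sensitivity"` or `"resistance"`.
#' @param effect_sd Size of the shift applied to carriers' activity scores,
#'   in units of the background noise SD.
#' @param n_carriers Number of carrier lines for the planted gene (its
#'   variants' carriers are resampled so their union has exactly this size).
#' @return A list describing the planted pair.
#' @export
planted_pair <- function(gene, nsc, direction = c("sensitivity", "resistance"),
                         effect_sd = 2, n_carriers = 8) {
  direction <- match.arg(direction)
  stopifnot(effect_sd >= 0, n_carriers >= 1)
  list(gene = gene, nsc = as.character(nsc), direction = direction,
       effect_sd = effect_sd, n_carriers = n_carriers)
}

#' Simulation settings for a synthetic 60-line panel
#'
#' Defaults emulate the shape of the 60-cell-line panel: 60 lines spread over
#' the 9 tissue-of-origin codes, sparse variants whose percent conversions
#' sit at the heterozygous (50) and homozygous (100) levels, and per-drug
#' activity z-scores with unit background noise. Desk-scale defaults of 20
#' genes x 3 variants and 10 drugs keep a full screen fast while exercising
#' every code path.
#'
#' @param n_cell_lines Panel size (default 60).
#' @param tissue_prefixes Tissue codes cycled over the lines.
#' @param n_genes,n_variants_per_gene Catalog dimensions.
#' @param carrier_rate Per-line carrier probability of each variant (every
#'   variant is guaranteed at least one carrier — an observed variant exists
#'   somewhere).
#' @param het_fraction Probability that a carrier call is heterozygous
#'   (percent 50) rather than homozygous (percent 100).
#' @param n_drugs Number of compounds.
#' @param planted_pairs List of [planted_pair()] effects.
#' @param noise_sd Background SD of the raw activity scores (default 1).
#' @param missing_rate Fraction of activity cells set missing (default 0,
#'   assay dropouts can be emulated by raising it).
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_cell_lines = 60, tissue_prefixes = PANEL_TISSUES,
                              n_genes = 20, n_variants_per_gene = 3,
                              carrier_rate = 0.08, het_fraction = 0.5,
                              n_drugs = 10, planted_pairs = list(),
                              noise_sd = 1, missing_rate = 0, seed = 1) {
  stopifnot(carrier_rate >= 0, carrier_rate <= 1, het_fraction >= 0,
            het_fraction <= 1, noise_sd >= 0, missing_rate >= 0,
            missing_rate < 1, n_cell_lines >= 1)
  structure(
    list(n_cell_lines = n_cell_lines, tissue_prefixes = tissue_prefixes,
         n_genes = n_genes, n_variants_per_gene = n_variants_per_gene,
         carrier_rate = carrier_rate, het_fraction = het_fraction,
         n_drugs = n_drugs, planted_pairs = planted_pairs,
         noise_sd = noise_sd, missing_rate = missing_rate,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

sim_cell_lines <- function(config) {
  tissues <- rep_len(config$tissue_prefixes, config$n_cell_lines)
  sprintf("%s:CL%02d", tissues, seq_len(config$n_cell_lines))
}

sim_aa_impact <- function(change_type, i) {
  pos <- 50 + (i * 37) %% 900
  switch(change_type,
    missense = sprintf("A%dT", pos),
    premature_stop = sprintf("Q%dX", pos),
    frameshift = sprintf("G%dfs", pos),
    nonframeshift_indel = sprintf("%d_%ddel", pos, pos + 1),
    read_through = sprintf("X%dW", pos),
    splicesense = "-",
    silent = sprintf("L%dL", pos),
    "-"
  )
}

#' Simulate a panel: variant catalog, drug activity matrix, ground truth
#'
#' Deterministic for a given seed. Variants get carriers by per-line
#' Bernoulli draws (forced non-empty), percent conversions at the het/hom
#' levels, change types covering every functional category, SIFT/PolyPhen-2
#' scores for score-bearing types, and reference-population frequencies that
#' are mostly absent with a present minority. Drug rows are unit-normal
#' noise; each planted pair resamples its gene's carriers to the requested
#' count and shifts those carriers' raw scores by `effect_sd` (up for
#' sensitivity, down for resistance) before the row is standardized to mean
#' 0, population SD 1 over observed cells.
#'
#' @param config A [simulation_config()].
#' @return List with `catalog` (variant tibble), `drugs` (drug tibble with
#'   z-score columns), and `truth` (planted pairs with realized carrier and
#'   responder sets, plus per-variant carrier sets).
#' @export
simulate_panel <- function(config = simulation_config()) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  cells <- sim_cell_lines(config)
  n <- config$n_cell_lines
  genes <- sprintf("G%03d", seq_len(config$n_genes))
  nv <- config$n_genes * config$n_variants_per_gene

  type_probs <- c(missense = 0.45, silent = 0.15, splicesense = 0.08,
                  frameshift = 0.08, premature_stop = 0.08,
                  read_through = 0.05, nonframeshift_indel = 0.06,
                  other = 0.05)
  change_type <- sample(names(type_probs), nv, replace = TRUE, prob = type_probs)

  chrom <- as.character(sample(1:22, nv, replace = TRUE))
  pos <- sample.int(2e8, nv)
  nts <- c("A", "C", "G", "T")
  ref <- sample(nts, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nts, r), 1), "")
  variant_id <- sprintf("chr%s:%d_%s_%s", chrom, pos, ref, alt)

  scored <- change_type %in% c("missense", "premature_stop", "read_through")
  sift <- ifelse(scored, round(runif(nv), 2), NA_real_)
  damaging <- scored & runif(nv) < 0.3
  sift[damaging] <- round(runif(sum(damaging), 0, 0.049), 3)
  polyphen2 <- ifelse(scored, round(runif(nv), 3), NA_real_)

  present <- runif(nv) < 0.3
  freq_esp5400 <- ifelse(present, runif(nv, 5e-4, 0.05), 0)
  freq_1000g <- ifelse(present & runif(nv) < 0.8, runif(nv, 5e-4, 0.05), 0)

  carriers <- matrix(runif(nv * n) < config$carrier_rate, nrow = nv)
  none <- rowSums(carriers) == 0
  carriers[cbind(which(none), sample.int(n, sum(none), replace = TRUE))] <- TRUE
  het <- matrix(runif(nv * n) < config$het_fraction, nrow = nv)
  percents <- carriers * ifelse(het, 50, 100)
  colnames(percents) <- cells

  catalog <- tibble(
    gene = rep(genes, each = config$n_variants_per_gene),
    variant_id = variant_id,
    change_type = change_type,
    aa_impact = vapply(seq_len(nv), function(i) sim_aa_impact(change_type[i], i), ""),
    dbsnp_id = ifelse(present, sprintf("rs%07d", sample.int(9999999, nv)), NA_character_),
    sift = sift,
    polyphen2 = polyphen2,
    freq_1000g = freq_1000g,
    freq_esp5400 = freq_esp5400,
    in_segdup = runif(nv) < 0.02,
    multimap = runif(nv) < 0.02
  )
  catalog <- dplyr::bind_cols(catalog, as_tibble(as.data.frame(percents)))

  nsc <- as.character(100000 + seq_len(config$n_drugs))
  moa_codes <- c("A7", "Ds", "YK", "DNMT", "Tu", "Ho", "STK", "Db", "PKC", "Apo")
  drugs_meta <- tibble(
    nsc = nsc,
    name = sprintf("compound-%03d", seq_len(config$n_drugs)),
    moa = sample(moa_codes, config$n_drugs, replace = TRUE),
    status = sample(c("fda_approved", "clinical_trial", "other"),
                    config$n_drugs, replace = TRUE, prob = c(0.2, 0.1, 0.7))
  )
  raw <- matrix(rnorm(config$n_drugs * n, sd = config$noise_sd),
                nrow = config$n_drugs, dimnames = list(nsc, cells))

  planted_rows <- list()
  for (pp in config$planted_pairs) {
    if (!pp$gene %in% genes) abort(sprintf("planted gene '%s' not in panel", pp$gene))
    if (!pp$nsc %in% nsc) abort(sprintf("planted drug '%s' not in panel", pp$nsc))
    gi <- which(catalog$gene == pp$gene)
    planted_carriers <- sample(cells, pp$n_carriers)
    assignment <- sample(seq_along(gi), pp$n_carriers, replace = TRUE)
    catalog[gi, cells] <- 0
    for (k in seq_len(pp$n_carriers)) {
      catalog[gi[assignment[k]], planted_carriers[k]] <-
        ifelse(runif(1) < config$het_fraction, 50, 100)
    }
    # keep the planted gene's variants eligible for the screen
    catalog$change_type[gi] <- "missense"
    catalog$aa_impact[gi] <- vapply(gi, function(i) sim_aa_impact("missense", i), "")
    catalog$in_segdup[gi] <- FALSE
    catalog$multimap[gi] <- FALSE
    shift <- if (pp$direction == "sensitivity") pp$effect_sd else -pp$effect_sd
    raw[pp$nsc, planted_carriers] <- raw[pp$nsc, planted_carriers] + shift
    planted_rows <- c(planted_rows, list(
      tibble(gene = pp$gene, nsc = pp$nsc, direction = pp$direction,
             effect_sd = pp$effect_sd, carriers = list(sort(planted_carriers)))
    ))
  }

  if (config$missing_rate > 0) {
    raw[runif(length(raw)) < config$missing_rate] <- NA
  }
  z <- gi50_to_zscores(raw, already_log = TRUE)
  drugs_meta <- drugs_meta[!(seq_len(nrow(drugs_meta)) %in% attr(z, "excluded")$row), ]
  drugs <- dplyr::bind_cols(drugs_meta, as_tibble(as.data.frame(z)))

  planted <- if (length(planted_rows) > 0) dplyr::bind_rows(planted_rows) else
    tibble(gene = character(), nsc = character(), direction = character(),
           effect_sd = numeric(), carriers = list())
  responder_sets <- lapply(seq_len(nrow(planted)), function(i) {
    zr <- stats::setNames(as.numeric(drugs[drugs$nsc == planted$nsc[i], cells]), cells)
    binarize_drug_response(zr, planted$direction[i])$responders
  })
  carrier_sets <- lapply(seq_len(nrow(catalog)), function(i) {
    cells[as.numeric(catalog[i, cells]) > 0]
  })
  names(carrier_sets) <- catalog$variant_id

  list(
    catalog = catalog,
    drugs = drugs,
    truth = list(planted = planted, responder_sets = responder_sets,
                 carrier_sets = carrier_sets)
  )
}

#' Simulate reference-population frequencies for a catalog
#'
#' Overwrites the ESP5400-style reference frequency column so that the
#' panel:reference ratio of each variant follows a chosen design: background
#' variants get log-normal ratios around 1, planted enriched variants ratios
#' in `enrich_ratio_range` (>= 10), planted depleted variants ratios in
#' `deplete_ratio_range` (<= 0.1). Requires the realized catalog, so the
#' reference frequencies are exactly consistent with the panel frequencies
#' computed from the percent-conversion matrix.
#'
#' @param catalog A variant table (e.g. from [simulate_panel()]).
#' @param n_enriched,n_depleted Number of planted enriched/depleted variants.
#' @param enrich_ratio_range,deplete_ratio_range Ratio ranges for planted
#'   variants.
#' @param background_sdlog SD of the background log-ratio (default 0.5).
#' @param seed Integer seed.
#' @return List with `catalog` (frequencies filled in) and `truth` (tibble of
#'   `variant_id`, `label` in enriched/depleted/background, `ratio`).
#' @export
simulate_reference_frequencies <- function(catalog, n_enriched = 0, n_depleted = 0,
                                           enrich_ratio_range = c(10, 500),
                                           deplete_ratio_range = c(0.01, 0.1),
                                           background_sdlog = 0.5, seed = 1) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  nv <- nrow(catalog)
  stopifnot(n_enriched + n_depleted <= nv)
  pf <- panel_variant_frequency(catalog)
  if (any(pf == 0)) abort("catalog contains variants with no carriers; ratios undefined")
  label <- rep("background", nv)
  special <- sample.int(nv, n_enriched + n_depleted)
  label[special[seq_len(n_enriched)]] <- "enriched"
  label[special[seq_len(n_depleted) + n_enriched]] <- "depleted"
  ratio <- rlnorm(nv, meanlog = 0, sdlog = background_sdlog)
  ratio[label == "enriched"] <- runif(n_enriched, enrich_ratio_range[1], enrich_ratio_range[2])
  ratio[label == "depleted"] <- runif(n_depleted, deplete_ratio_range[1], deplete_ratio_range[2])
  catalog$freq_esp5400 <- pmin(pf / ratio, 1)
  ratio <- pf / catalog$freq_esp5400 # exact realized ratio after the cap
  list(
    catalog = catalog,
    truth = tibble(variant_id = catalog$variant_id, label = label, ratio = ratio)
  )
}
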