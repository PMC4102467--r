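test_that("MCC reproduces published-style worked tables and degenerate cases", {
  expect_equal(round(matthews_correlation(9, 1, 0, 49), 2), 0.94)
  expect_equal(round(matthews_correlation(3, 0, 1, 45), 2), 0.86)
  expect_equal(matthews_correlation(5, 0, 0, 5), 1)
  # any zero marginal factor yields 0 by contract
  expect_equal(matthews_correlation(0, 0, 3, 5), 0)
  expect_equal(matthews_correlation(2, 3, 0, 0), 0)
  expect_equal(matthews_correlation(0, 0, 0, 0), 0)
})

test_that("MCC equals the binary-vector Pearson correlation (oracle property)", {
  set.seed(31)
  for (i in 1:200) {
    counts <- stats::rmultinom(1, sample(4:80, 1), prob = runif(4, 0.05, 1))
    got <- matthews_correlation(counts[1], counts[2], counts[3], counts[4])
    want <- oracle_mcc_pearson(counts[1], counts[2], counts[3], counts[4])
    expect_equal(got, want, tolerance = 1e-12)
    expect_true(got >= -1 && got <= 1)
  }
})

test_that("MCC symmetries: class swap preserves, prediction flip negates", {
  set.seed(32)
  for (i in 1:50) {
    t <- sample(0:20, 4, replace = TRUE)
    expect_equal(matthews_correlation(t[1], t[2], t[3], t[4]),
                 matthews_correlation(t[4], t[3], t[2], t[1]))
    expect_equal(matthews_correlation(t[1], t[2], t[3], t[4]),
                 -matthews_correlation(t[2], t[1], t[4], t[3]))
  }
})

test_that("MCC significance uses the t transform at n-2 df", {
  expect_lte(mcc_significance(0.596, 35), 2e-4)
  expect_equal(mcc_significance(0, 40), 1)
  # quadrature oracle for the two-tailed t tail
  t_stat <- 0.5 * sqrt(18) / sqrt(1 - 0.25)
  expect_equal(mcc_significance(0.5, 20), oracle_t_two_tail(t_stat, 18),
               tolerance = 1e-9)
  expect_equal(mcc_significance(1, 35), .Machine$double.xmin)
  expect_equal(mcc_significance(-1, 35), .Machine$double.xmin)
})

test_that("drug response binarizes by direction with missing cells excluded", {
  z <- stats::setNames(c(0.6, -0.6, 0.0, NA), sprintf("BR:L%d", 1:4))
  sens <- binarize_drug_response(z, "sensitivity")
  expect_equal(sens$responders, "BR:L1")
  expect_setequal(sens$evaluable, sprintf("BR:L%d", 1:3))
  res <- binarize_drug_response(z, "resistance")
  expect_equal(res$responders, "BR:L2")
  # boundary values respond
  zb <- stats::setNames(c(0.5, -0.5), c("BR:A", "BR:B"))
  expect_equal(binarize_drug_response(zb, "sensitivity")$responders, "BR:A")
  expect_equal(binarize_drug_response(zb, "resistance")$responders, "BR:B")
  allna <- stats::setNames(rep(NA_real_, 3), sprintf("BR:L%d", 1:3))
  expect_length(binarize_drug_response(allna, "sensitivity")$evaluable, 0)
})

test_that("variant eligibility enforces carrier cap, type, and mapping flags", {
  cells <- sprintf("BR:L%02d", 1:20)
  thirteen <- stats::setNames(rep(50, 13), cells[1:13])
  cat <- dplyr::bind_rows(
    toy_variant(cells, variant_id = "chr1:1_A_T", percents = c("BR:L01" = 50)),
    toy_variant(cells, variant_id = "chr1:2_A_T", percents = thirteen),
    toy_variant(cells, variant_id = "chr1:3_A_T", change_type = "silent",
                percents = c("BR:L01" = 50)),
    toy_variant(cells, variant_id = "chr1:4_A_T", in_segdup = TRUE,
                percents = c("BR:L01" = 50)),
    toy_variant(cells, variant_id = "chr1:5_A_T", multimap = TRUE,
                percents = c("BR:L01" = 50)),
    # presence in the reference population does NOT disqualify
    toy_variant(cells, variant_id = "chr1:6_A_T", freq_esp5400 = 0.02,
                percents = c("BR:L02" = 100))
  )
  ev <- eligible_variants(cat)
  expect_setequal(ev$variant_id, c("chr1:1_A_T", "chr1:6_A_T"))
  # exactly 12 carriers is still eligible ("<13 cell lines")
  twelve <- toy_variant(cells, variant_id = "chr1:7_A_T",
                        percents = stats::setNames(rep(50, 12), cells[1:12]))
  expect_equal(nrow(eligible_variants(twelve)), 1)
})

test_that("single-variant combination reproduces the 9/1/0/49 vemurafenib-style table", {
  cells <- sprintf("BR:L%02d", 1:59)
  carriers <- cells[1:10]
  v <- toy_variant(cells, gene = "BRAF", variant_id = "chr7:140453136_A_T",
                   percents = stats::setNames(rep(c(100, 50), 5), carriers))
  responders <- carriers[1:9] # 9 of 10 carriers respond; no one else does
  res <- best_variant_combination(v, responders, cells)
  expect_equal(c(res$tp, res$fp, res$fn, res$tn), c(9L, 1L, 0L, 49L))
  expect_equal(round(res$mcc, 2), 0.94)
  expect_equal(res$precision, 0.9)
  expect_equal(res$recall, 1)
  expect_lt(res$p, 2e-4)
})

test_that("subset search matches brute-force enumeration and breaks ties sanely", {
  cells <- sprintf("BR:L%02d", 1:30)
  # optimal pair strictly better than any single variant
  v1 <- toy_variant(cells, gene = "G", variant_id = "chr1:1_A_T",
                    percents = stats::setNames(rep(50, 4), cells[1:4]))
  v2 <- toy_variant(cells, gene = "G", variant_id = "chr1:2_A_T",
                    percents = stats::setNames(rep(50, 4), cells[5:8]))
  v3 <- toy_variant(cells, gene = "G", variant_id = "chr1:3_A_T",
                    percents = stats::setNames(rep(50, 3), cells[20:22]))
  gene <- dplyr::bind_rows(v1, v2, v3)
  responders <- cells[1:8]
  res <- best_variant_combination(gene, responders, cells)
  expect_equal(res$variants, "chr1:1_A_T,chr1:2_A_T")
  expect_equal(res$mcc, 1)
  cm <- as.matrix(gene[, cells]) > 0
  expect_equal(res$mcc,
               oracle_best_subset_mcc(cm, cells %in% responders),
               tolerance = 1e-12)

  # duplicate carrier sets: ties resolve to fewer variants, then smaller id
  dup <- dplyr::bind_rows(v1, toy_variant(cells, gene = "G",
    variant_id = "chr1:0_A_T",
    percents = stats::setNames(rep(50, 4), cells[1:4])))
  res2 <- best_variant_combination(dup, cells[1:4], cells,
                                   require_thresholds = FALSE)
  expect_equal(res2$n_variants, 1L)
  expect_equal(res2$variants, "chr1:0_A_T")

  # nothing passes the gates -> no report
  weak <- best_variant_combination(v3, responders, cells)
  expect_null(weak)
})

test_that("greedy forward selection never beats exhaustive search", {
  set.seed(33)
  cells <- sprintf("BR:L%02d", 1:40)
  for (i in 1:25) {
    nv <- sample(4:8, 1)
    cm <- matrix(runif(nv * 40) < 0.12, nrow = nv)
    gene <- dplyr::bind_rows(lapply(seq_len(nv), function(j) {
      toy_variant(cells, gene = "G", variant_id = sprintf("chr1:%d_A_T", j),
                  percents = stats::setNames(rep(50, sum(cm[j, ])),
                                             cells[cm[j, ]]))
    }))
    responders <- sample(cells, 8)
    ex <- best_variant_combination(gene, responders, cells,
                                   require_thresholds = FALSE)
    gr <- best_variant_combination(gene, responders, cells,
                                   screen_config(exhaustive_max_variants = 0),
                                   require_thresholds = FALSE)
    expect_equal(gr$search, "greedy")
    expect_lte(gr$mcc, ex$mcc + 1e-12)
  }
})

test_that("the screen recovers strongly planted pairs and nothing else", {
  cfg <- simulation_config(
    planted_pairs = list(
      planted_pair("G003", "100002", "sensitivity", effect_sd = 4, n_carriers = 8),
      planted_pair("G010", "100007", "resistance", effect_sd = 4, n_carriers = 8)
    ),
    seed = 99
  )
  sim <- simulate_panel(cfg)
  rep <- association_screen(sim$catalog, sim$drugs)
  sens <- rep$sensitivity
  res <- rep$resistance
  expect_true(any(sens$gene == "G003" & sens$nsc == "100002"))
  expect_true(any(res$gene == "G010" & res$nsc == "100007"))
  all_pairs <- dplyr::bind_rows(sens, res)
  expect_true(all(paste(all_pairs$gene, all_pairs$nsc) %in%
                    c("G003 100002", "G010 100007")))
  expect_true(all(all_pairs$mcc >= 0.596 & all_pairs$precision >= 0.70 &
                    all_pairs$tp >= 3))
  # report is shaped like the published pairing table
  expect_true(all(c("gene", "nsc", "name", "moa", "status", "direction",
                    "tp", "fp", "fn", "tn", "mcc", "precision", "recall",
                    "p", "variants") %in% names(sens)))

  empty <- association_screen(sim$catalog, sim$drugs[0, ])
  expect_equal(nrow(empty$sensitivity), 0)
  expect_equal(nrow(empty$resistance), 0)

  disjoint <- sim$drugs
  names(disjoint) <- sub("^[A-Z]+:", "XX:", names(disjoint))
  expect_error(association_screen(sim$catalog, disjoint), "share no cell lines")
})

test_that("provenance partition totals winning variants by reference presence", {
  cells <- toy_cell_lines(2)
  cat <- dplyr::bind_rows(
    toy_variant(cells, variant_id = "chr1:1_A_T", freq_esp5400 = 0),   # absent
    toy_variant(cells, variant_id = "chr1:2_A_T", freq_esp5400 = 0.02), # present
    toy_variant(cells, variant_id = "chr1:3_A_T", freq_1000g = NA_real_,
                freq_esp5400 = NA_real_)                                # absent
  )
  report <- tibble::tibble(
    variants = c("chr1:1_A_T,chr1:3_A_T", "chr1:2_A_T", "chr1:1_A_T"),
    p = c(1e-9, 1e-5, 0.01)
  )
  part <- provenance_partition(report, cat)
  expect_equal(nrow(part), 4)
  # p<0.05: variants 1,3,2,1 -> 3 absent, 1 present
  expect_equal(part$n_absent[part$p_threshold == 0.05], 3)
  expect_equal(part$prop_absent[part$p_threshold == 0.05], 0.75)
  expect_equal(part$prop_absent + part$prop_present, rep(1, 4))
  # all-absent report at the strictest threshold
  expect_equal(part$prop_absent[part$p_threshold == 1e-8], 1)
  empty <- provenance_partition(report[0, ], cat)
  expect_true(all(is.na(empty$prop_absent)))
})
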