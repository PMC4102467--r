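test_that("amino-acid-changing classification covers every change type", {
  expect_true(all(is_amino_acid_changing(
    c("missense", "splicesense", "frameshift", "read_through",
      "nonframeshift_indel", "premature_stop"))))
  expect_false(any(is_amino_acid_changing(c("silent", "other"))))
})

test_that("protein-function categories follow type priority and score rules", {
  cells <- toy_cell_lines(2)
  cat <- dplyr::bind_rows(
    # V600E-like: SIFT branch fires although PolyPhen is below threshold
    toy_variant(cells, sift = 0.00, polyphen2 = 0.796),
    # S204R-like: SIFT damaging, PolyPhen clearly benign
    toy_variant(cells, sift = 0.00, polyphen2 = 0.023),
    # both scores fail
    toy_variant(cells, sift = 0.5, polyphen2 = 0.5),
    # PolyPhen branch alone
    toy_variant(cells, sift = 0.9, polyphen2 = 0.97),
    # premature stop is categorical regardless of scores
    toy_variant(cells, change_type = "premature_stop", sift = 0.35,
                polyphen2 = 0.735),
    toy_variant(cells, change_type = "splicesense"),
    toy_variant(cells, change_type = "frameshift"),
    # unknown scores never satisfy a score criterion
    toy_variant(cells, sift = NA_real_, polyphen2 = NA_real_),
    toy_variant(cells, change_type = "silent", sift = 0.0, polyphen2 = 0.99)
  )
  got <- assess_protein_function_effect(cat)
  expect_equal(as.character(got),
               c("sift_polyphen", "sift_polyphen", "none", "sift_polyphen",
                 "premature_stop", "splicesense", "frameshift", "none", "none"))
})

test_that("every record maps to exactly one category (partition property)", {
  sim <- simulate_panel(simulation_config(n_genes = 40, seed = 7))
  got <- assess_protein_function_effect(sim$catalog)
  expect_false(anyNA(got))
  expect_setequal(levels(got),
                  c("splicesense", "frameshift", "premature_stop",
                    "sift_polyphen", "none"))
  # all four function-affecting categories are represented in a 120-variant draw
  expect_true(all(c("splicesense", "frameshift", "premature_stop",
                    "sift_polyphen") %in% as.character(got)))
})

test_that("tightening score thresholds never grows the sift_polyphen set", {
  sim <- simulate_panel(simulation_config(n_genes = 40, seed = 8))
  base <- assess_protein_function_effect(sim$catalog,
                                         functional_criteria(0.05, 0.85))
  for (crit in list(functional_criteria(0.01, 0.85),
                    functional_criteria(0.05, 0.95),
                    functional_criteria(0.01, 0.99))) {
    tight <- assess_protein_function_effect(sim$catalog, crit)
    expect_true(all(which(tight == "sift_polyphen") %in%
                      which(base == "sift_polyphen")))
  }
})

test_that("homozygous-deleterious filter applies all four rules", {
  cells <- toy_cell_lines(3)
  cat <- dplyr::bind_rows(
    # 1: passes all four rules via SIFT
    toy_variant(cells, gene = "A", variant_id = "chr1:1_A_T", sift = 0.01,
                percents = c("BR:T01" = 100)),
    # 2: passes via frameshift
    toy_variant(cells, gene = "B", variant_id = "chr1:2_*_-AC",
                change_type = "frameshift", percents = c("CO:T02" = 95)),
    # 3: heterozygous only -> fails homozygosity
    toy_variant(cells, gene = "C", variant_id = "chr1:3_A_T", sift = 0.01,
                percents = c("BR:T01" = 50)),
    # 4: present in the reference -> fails absence
    toy_variant(cells, gene = "D", variant_id = "chr1:4_A_T", sift = 0.01,
                freq_esp5400 = 0.01, percents = c("BR:T01" = 100)),
    # 5: silent -> fails amino-acid change
    toy_variant(cells, gene = "E", variant_id = "chr1:5_A_T",
                change_type = "silent", percents = c("BR:T01" = 100)),
    # 6: missense with benign scores -> category none
    toy_variant(cells, gene = "F", variant_id = "chr1:6_A_T", sift = 0.4,
                polyphen2 = 0.2, percents = c("BR:T01" = 100))
  )
  res <- filter_homozygous_deleterious(cat)
  expect_equal(res$records$gene, c("A", "B"))
  expect_equal(as.character(res$records$category),
               c("sift_polyphen", "frameshift"))
  expect_equal(res$category_counts[["sift_polyphen"]], 1L)
  expect_equal(res$category_counts[["frameshift"]], 1L)
  expect_equal(res$n_genes, 2L)
  # the filtered subset is always a subset of the amino-acid-changing records
  expect_true(all(is_amino_acid_changing(res$records$change_type)))

  empty <- filter_homozygous_deleterious(cat[0, ])
  expect_equal(nrow(empty$records), 0)
  expect_equal(sum(empty$category_counts), 0L)
  expect_equal(empty$n_genes, 0L)
})

test_that("a missing frequency counts as absent but a nonzero one does not", {
  cells <- toy_cell_lines(2)
  na_freq <- toy_variant(cells, sift = 0.01, freq_1000g = NA_real_,
                         freq_esp5400 = NA_real_, percents = c("BR:T01" = 100))
  expect_equal(nrow(filter_homozygous_deleterious(na_freq)$records), 1)
  present <- toy_variant(cells, sift = 0.01, freq_esp5400 = 0.01,
                         percents = c("BR:T01" = 100))
  expect_equal(nrow(filter_homozygous_deleterious(present)$records), 0)
})

test_that("driver-gene enrichment matches exhaustive hypergeometric enumeration", {
  universe <- sprintf("g%02d", 1:20)
  drivers <- universe[1:10]
  # perfect overlap of selected and drivers
  p1 <- driver_gene_enrichment_test(drivers, drivers, universe)
  expect_equal(p1, oracle_fisher_p(10, 0, 0, 10), tolerance = 1e-12)
  # disjoint tiny sets
  p2 <- driver_gene_enrichment_test(universe[1:3], universe[11:14], universe)
  expect_equal(p2, oracle_fisher_p(0, 3, 4, 13), tolerance = 1e-12)
  # empty selection is never enriched
  expect_equal(driver_gene_enrichment_test(character(0), drivers, universe), 1)
  expect_error(driver_gene_enrichment_test(drivers, drivers, character(0)),
               "empty")
})
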