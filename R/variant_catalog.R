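#' Functional-effect classification criteria
#'
#' Thresholds used to decide whether a variant is likely to affect protein
#' function, and what counts as a homozygous call from percent conversion.
#' Defaults: missense variants are damaging when SIFT < 0.05 or PolyPhen-2
#' >= 0.85; a percent conversion >= 95 is treated as a homozygous call
#' (heterozygous variants sit near 50, homozygous near 100).
#'
#' @param sift_max Missense variants with SIFT strictly below this are
#'   score-damaging. In \[0,1\].
#' @param polyphen_min Missense variants with PolyPhen-2 at or above this are
#'   score-damaging. In \[0,1\].
#' @param homozygous_min_percent Percent-conversion threshold for calling a
#'   variant homozygous in a line.
#' @return A list of class `functional_criteria`.
#' @export
functional_criteria <- function(sift_max = 0.05, polyphen_min = 0.85,
                                homozygous_min_percent = 95) {
  stopifnot(sift_max >= 0, sift_max <= 1, polyphen_min >= 0, polyphen_min <= 1,
            homozygous_min_percent >= 0, homozygous_min_percent <= 100)
  structure(
    list(sift_max = sift_max, polyphen_min = polyphen_min,
         homozygous_min_percent = homozygous_min_percent),
    class = "functional_criteria"
  )
}

#' Is a variant amino-acid changing?
#'
#' Amino-acid-changing change types are missense, splicesense, frameshift,
#' read-through, non-frameshift insertion/deletion, and premature stop.
#' Silent and other changes are not.
#'
#' @param change_type Character vector of change types.
#' @return Logical vector.
#' @export
is_amino_acid_changing <- function(change_type) {
  change_type %in% AA_CHANGING_TYPES
}

#' Classify the protein-function effect of each variant
#'
#' Every variant maps to exactly one of five categories. Splicesense,
#' frameshift, and premature-stop changes are function-affecting by type,
#' regardless of scores. Any other amino-acid-changing variant (missense,
#' read-through, non-frameshift indel) is function-affecting through the
#' score branch (`sift_polyphen`) when SIFT < `sift_max` OR PolyPhen-2 >=
#' `polyphen_min`; unknown (`NA`) scores never satisfy a score criterion.
#' Everything else, including silent changes, is `none`. Priority when type
#' annotations would overlap: splicesense > frameshift > premature_stop >
#' sift_polyphen, so the category census never double-counts.
#'
#' @param catalog A variant table.
#' @param criteria A [functional_criteria()] object.
#' @return Factor with levels `splicesense, frameshift, premature_stop,
#'   sift_polyphen, none`, one per row of `catalog`.
#' @export
assess_protein_function_effect <- function(catalog, criteria = functional_criteria()) {
  ct <- catalog$change_type
  sift_hit <- !is.na(catalog$sift) & catalog$sift < criteria$sift_max
  pp_hit <- !is.na(catalog$polyphen2) & catalog$polyphen2 >= criteria$polyphen_min
  score_hit <- (sift_hit | pp_hit) & is_amino_acid_changing(ct)
  cat <- rep("none", length(ct))
  cat[score_hit] <- "sift_polyphen"
  cat[ct == "premature_stop"] <- "premature_stop"
  cat[ct == "frameshift"] <- "frameshift"
  cat[ct == "splicesense"] <- "splicesense"
  factor(cat, levels = FUNCTION_CATEGORIES)
}

#' Filter the catalog of homozygous deleterious variants
#'
#' Retains variants that are (i) homozygous in at least one panel line
#' (percent conversion at or above `criteria$homozygous_min_percent`, or an
#' explicit `zygosity == "hom"` column when present), (ii) absent from both
#' reference populations (frequency cell missing or exactly 0 in both the
#' 1000 Genomes and ESP5400 columns — exports encode absence both ways),
#' (iii) amino-acid changing, and (iv) in a function-affecting category.
#'
#' @param catalog A variant table.
#' @param criteria A [functional_criteria()] object.
#' @return A list: `records` (the filtered rows, with a `category` column),
#'   `category_counts` (named integer vector over the four function-affecting
#'   categories), and `n_genes` (number of unique genes in the subset).
#' @export
filter_homozygous_deleterious <- function(catalog, criteria = functional_criteria()) {
  if (nrow(catalog) == 0) {
    counts <- stats::setNames(integer(4), FUNCTION_CATEGORIES[1:4])
    return(list(records = catalog, category_counts = counts, n_genes = 0L))
  }
  cells <- cell_line_columns(catalog)
  pc <- as.matrix(catalog[, cells, drop = FALSE])
  homozygous <- apply(pc >= criteria$homozygous_min_percent, 1, any)
  if ("zygosity" %in% names(catalog)) {
    explicit <- !is.na(catalog$zygosity)
    homozygous[explicit] <- catalog$zygosity[explicit] == "hom"
  }
  absent <- (is.na(catalog$freq_1000g) | catalog$freq_1000g == 0) &
    (is.na(catalog$freq_esp5400) | catalog$freq_esp5400 == 0)
  aa <- is_amino_acid_changing(catalog$change_type)
  category <- assess_protein_function_effect(catalog, criteria)
  keep <- homozygous & absent & aa & category != "none"
  records <- catalog[keep, , drop = FALSE]
  records$category <- droplevels(category[keep])
  counts <- table(factor(category[keep], levels = FUNCTION_CATEGORIES[1:4]))
  list(
    records = records,
    category_counts = stats::setNames(as.integer(counts), names(counts)),
    n_genes = length(unique(records$gene))
  )
}

#' Test enrichment of a gene set for cancer-driver genes
#'
#' Two-tailed Fisher exact test on the 2x2 table crossing membership in the
#' selected set with membership in the driver set, over a common gene
#' universe.
#'
#' @param selected_genes Character vector, a subset of `universe`.
#' @param driver_genes Character vector, a subset of `universe`.
#' @param universe Character vector of all genes considered.
#' @return Two-tailed p-value.
#' @export
driver_gene_enrichment_test <- function(selected_genes, driver_genes, universe) {
  if (length(universe) == 0) abort("gene universe is empty")
  selected_genes <- intersect(selected_genes, universe)
  driver_genes <- intersect(driver_genes, universe)
  a <- length(intersect(selected_genes, driver_genes))
  b <- length(selected_genes) - a
  c_ <- length(driver_genes) - a
  d <- length(universe) - a - b - c_
  fisher_exact_2x2(a, b, c_, d)
}

#' Two-tailed Fisher exact p-value for a 2x2 table
#'
#' Conventional two-sided test: sums the probabilities of all tables with the
#' observed margins whose probability does not exceed the observed table's.
#'
#' @param a,b,c,d Cell counts (row-wise).
#' @return Two-tailed p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE),
              alternative = "two.sided")$p.value
}
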