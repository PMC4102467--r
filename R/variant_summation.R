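#' Combine a gene's variant percentages under independence
#'
#' Treats the per-variant percent conversions P1..Pn of one gene in one cell
#' line as independent event probabilities and returns the percent chance
#' that at least one variant is present:
#' `100 * (1 - prod(1 - Pi/100))`. The formula never exceeds 100, any
#' Pi = 100 (homozygous) forces 100, and an empty input gives 0. It is
#' permutation-invariant and monotone non-decreasing in each Pi.
#'
#' @param percents Numeric vector of percentages in \[0, 100\].
#' @return Combined percentage in \[0, 100\].
#' @examples
#' gene_variant_summary(c(36, 42)) # 62.88
#' @export
gene_variant_summary <- function(percents) {
  if (length(percents) == 0) return(0)
  if (any(is.na(percents)) || any(percents < 0 | percents > 100)) {
    abort("variant percentages must lie in [0, 100]")
  }
  100 * (1 - prod(1 - percents / 100))
}

#' Sum gene summaries into per-line multi-gene totals
#'
#' The variant burden of a gene set in a cell line is the plain sum of the
#' genes' combined percentages — deliberately uncapped, so it can exceed 100.
#'
#' @param profiles A list of gene profiles (elements with a `summary` named
#'   numeric vector over a shared panel), e.g. from a `summation_table`.
#' @return Named numeric vector of per-line totals.
#' @export
multi_gene_totals <- function(profiles) {
  if (length(profiles) == 0) return(numeric(0))
  panels <- lapply(profiles, function(p) names(p$summary))
  if (length(unique(vapply(panels, paste, "", collapse = "|"))) != 1) {
    abort("gene profiles do not share the same cell line panel")
  }
  Reduce(`+`, lapply(profiles, function(p) p$summary))
}

new_summation_table <- function(subset, cell_lines, profiles, totals) {
  structure(
    list(subset = subset, cell_lines = cell_lines, profiles = profiles,
         totals = totals),
    class = "summation_table"
  )
}

#' @export
print.summation_table <- function(x, ...) {
  cat(sprintf("<summation_table: %s; %d gene(s), %d cell line(s)>\n",
              x$subset, length(x$profiles), length(x$cell_lines)))
  invisible(x)
}

gene_profile <- function(gene, records, cell_lines) {
  if (nrow(records) == 0) {
    variants <- tibble(variant_id = character(), aa_impact = character(),
                       percents = list())
    summary <- stats::setNames(rep(0, length(cell_lines)), cell_lines)
  } else {
    pm <- as.matrix(records[, cell_lines, drop = FALSE])
    variants <- tibble(
      variant_id = records$variant_id,
      aa_impact = records$aa_impact,
      percents = lapply(seq_len(nrow(pm)), function(i) {
        stats::setNames(pm[i, ], cell_lines)
      })
    )
    summary <- apply(pm, 2, gene_variant_summary)
  }
  list(gene = gene, variants = variants, summary = summary)
}

#' Build the two variant-summation tables for a gene list
#'
#' For each queried gene, collects its variants and combines their per-line
#' percentages with [gene_variant_summary()]; per-line totals over the gene
#' list come from [multi_gene_totals()]. Two tables are returned, matching
#' the two sheets of the summation workbook: `all_aa` uses every
#' amino-acid-changing variant; `functional` restricts to variants in a
#' function-affecting category that are also absent from both reference
#' populations. Gene symbols not found in the catalog yield a warning and an
#' all-zero profile. Since the functional sheet uses a subset of each gene's
#' variants, its totals never exceed the all-variant totals in any line.
#'
#' @param genes Character vector of gene symbols (at most `max_genes`).
#' @param catalog A variant table.
#' @param criteria A [functional_criteria()] object for the functional sheet.
#' @param max_genes Query size cap (default 150).
#' @return A list with `summation_table` elements `all_aa` and `functional`.
#' @export
build_summation <- function(genes, catalog, criteria = functional_criteria(),
                            max_genes = 150) {
  if (length(genes) > max_genes) {
    abort(sprintf("%d genes requested; the query limit is %d genes",
                  length(genes), max_genes))
  }
  cells <- cell_line_columns(catalog)
  unknown <- setdiff(genes, catalog$gene)
  if (length(unknown) > 0) {
    warn(sprintf("gene symbol(s) not in catalog: %s",
                 paste(unknown, collapse = ", ")))
  }
  category <- assess_protein_function_effect(catalog, criteria)
  absent <- (is.na(catalog$freq_1000g) | catalog$freq_1000g == 0) &
    (is.na(catalog$freq_esp5400) | catalog$freq_esp5400 == 0)
  aa <- is_amino_acid_changing(catalog$change_type)
  build <- function(keep, subset) {
    profiles <- lapply(genes, function(g) {
      gene_profile(g, catalog[keep & catalog$gene == g, , drop = FALSE], cells)
    })
    names(profiles) <- genes
    totals <- if (length(profiles) == 0) {
      stats::setNames(rep(0, length(cells)), cells)
    } else {
      multi_gene_totals(profiles)
    }
    new_summation_table(subset, cells, profiles, totals)
  }
  list(
    all_aa = build(aa, "all_aa_changing"),
    functional = build(aa & category != "none" & absent,
                       "function_affecting_and_absent")
  )
}

#' Plot multi-gene variant-burden totals
#'
#' Horizontal bar chart of the per-line totals of a summation table, colored
#' by tissue of origin.
#'
#' @param st A `summation_table` from [build_summation()].
#' @return A ggplot object.
#' @export
plot_summation_totals <- function(st) {
  df <- tibble(
    cell_line = names(st$totals),
    tissue = sub(":.*$", "", names(st$totals)),
    total = unname(st$totals)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$total,
                                   y = stats::reorder(.data$cell_line, .data$total),
                                   fill = .data$tissue)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Summed variant percentage (Totals)", y = NULL,
                  fill = "Tissue") +
    ggplot2::theme_minimal()
}
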