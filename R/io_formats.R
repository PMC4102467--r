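#' Parse positional variant identifiers
#'
#' Variant loci are interchanged as strings of the form
#' `chr<label>:<position>_<ref>_<alt>`, e.g. `"chr17:7577610_T_C"` for a
#' substitution. Insertions and deletions carry `*` in the reference slot and
#' a signed payload in the alternate slot: `"chr13:48916816_*_-ACTT"` deletes
#' `ACTT`, a `+SEQ` payload inserts `SEQ`. Coordinates are 1-based and fully
#' closed; the identifier string itself is the interchange key, so
#' [format_variant_id()] regenerates the input exactly.
#'
#' @param ids Character vector of identifier strings.
#' @return A tibble with one row per identifier and columns `variant_id`,
#'   `chromosome`, `position`, `ref`, `alt`, and `type`
#'   (`"substitution"`, `"insertion"`, or `"deletion"`).
#' @examples
#' parse_variant_id(c("chr17:7577610_T_C", "chr13:48916816_*_-ACTT"))
#' @export
parse_variant_id <- function(ids) {
  stopifnot(is.character(ids))
  m <- regmatches(ids, regexec("^chr([0-9XYMT]+):([0-9]+)_([^_]+)_([^_]+)$", ids))
  bad <- lengths(m) == 0
  if (any(bad)) {
    abort(sprintf(
      "malformed variant identifier: '%s' (expected chr<label>:<position>_<ref>_<alt>)",
      ids[which(bad)[1]]
    ))
  }
  parts <- do.call(rbind, m)
  ref <- parts[, 4]
  alt <- parts[, 5]
  nuc <- "^[ACGTN]+$"
  type <- rep(NA_character_, length(ids))
  type[grepl(nuc, ref) & grepl(nuc, alt)] <- "substitution"
  type[ref == "*" & grepl("^\\+[ACGTN]+$", alt)] <- "insertion"
  type[ref == "*" & grepl("^-[ACGTN]+$", alt)] <- "deletion"
  if (anyNA(type)) {
    i <- which(is.na(type))[1]
    abort(sprintf(
      "malformed variant identifier '%s': allele pair '%s'/'%s' is neither a substitution nor a signed indel",
      ids[i], ref[i], alt[i]
    ))
  }
  tibble(
    variant_id = ids,
    chromosome = parts[, 2],
    position = as.integer(parts[, 3]),
    ref = ref,
    alt = alt,
    type = type
  )
}

#' Format variant loci back to identifier strings
#'
#' Inverse of [parse_variant_id()]: `format_variant_id(parse_variant_id(x))`
#' is identical to `x`.
#'
#' @param locus A tibble with columns `chromosome`, `position`, `ref`, `alt`
#'   (as returned by [parse_variant_id()]).
#' @return Character vector of identifier strings.
#' @export
format_variant_id <- function(locus) {
  sprintf("chr%s:%d_%s_%s", locus$chromosome, as.integer(locus$position),
          locus$ref, locus$alt)
}

#' Identify the per-cell-line columns of a panel table
#'
#' Cell line columns carry a tissue-of-origin prefix separated by a colon,
#' e.g. `BR:MCF7` or `ME:LOXIMVI`; every other column is metadata.
#'
#' @param x A variant or drug table (data frame).
#' @return Character vector of cell line column names, in table order.
#' @export
cell_line_columns <- function(x) {
  grep("^[A-Z]+:", names(x), value = TRUE)
}

variant_meta_cols <- c(
  "gene", "variant_id", "change_type", "aa_impact", "dbsnp_id",
  "sift", "polyphen2", "freq_1000g", "freq_esp5400", "in_segdup", "multimap"
)

drug_meta_cols <- c("nsc", "name", "moa", "status")

#' Read a variant annotation table
#'
#' Reads the canonical TSV dialect: one row per annotated variant with the
#' metadata columns `gene, variant_id, change_type, aa_impact, dbsnp_id,
#' sift, polyphen2, freq_1000g, freq_esp5400, in_segdup, multimap` followed
#' by one percent-conversion column per cell line (headers with tissue
#' prefixes such as `BR:MCF7`). Unknown extra columns are kept but ignored by
#' downstream analyses.
#'
#' Missing SIFT/PolyPhen-2/population-frequency cells are read as `NA`
#' ("unknown") and are never imputed to zero: a missing score must not count
#' as damaging or benign, and a missing reference frequency is distinct from
#' an observed frequency of 0. Missing percent-conversion cells, by contrast,
#' mean the variant was not observed in that line and become 0.
#'
#' @param path Path to a TSV file.
#' @return A tibble of variant records; identifiers are validated by parsing.
#' @export
read_variant_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                       progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(variant_meta_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("variant table is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  cells <- cell_line_columns(x)
  if (length(cells) == 0) {
    abort("variant table has no cell line columns (expected headers like 'BR:MCF7')")
  }
  for (cl in cells) {
    v <- as.numeric(x[[cl]])
    v[is.na(v)] <- 0
    bad <- which(v < 0 | v > 100)
    if (length(bad) > 0) {
      abort(sprintf("percent conversion outside [0,100] in column '%s', row %d",
                    cl, bad[1]))
    }
    x[[cl]] <- v
  }
  x$gene <- as.character(x$gene)
  x$variant_id <- as.character(x$variant_id)
  x$change_type <- as.character(x$change_type)
  x$aa_impact <- as.character(x$aa_impact)
  x$dbsnp_id <- as.character(x$dbsnp_id)
  for (nc in c("sift", "polyphen2", "freq_1000g", "freq_esp5400")) {
    x[[nc]] <- as.numeric(x[[nc]])
  }
  for (lc in c("in_segdup", "multimap")) {
    x[[lc]] <- as.logical(x[[lc]])
  }
  parse_variant_id(x$variant_id) # validates; parse errors propagate
  x
}

#' Write a variant annotation table
#'
#' @param x A variant table as returned by [read_variant_table()] or
#'   [simulate_panel()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Read a drug activity table
#'
#' Canonical TSV dialect: columns `nsc, name, moa, status` then one z-score
#' (or GI50) column per cell line. Missing activity cells stay `NA`
#' (assay dropouts), never zero.
#'
#' @param path Path to a TSV file.
#' @return A tibble of drug rows.
#' @export
read_drug_table <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_guess()),
                       progress = FALSE, show_col_types = FALSE)
  missing_cols <- setdiff(drug_meta_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(sprintf("drug table is missing mandatory column(s): %s",
                  paste(missing_cols, collapse = ", ")))
  }
  if (length(cell_line_columns(x)) == 0) {
    abort("drug table has no cell line columns (expected headers like 'BR:MCF7')")
  }
  x$nsc <- as.character(x$nsc)
  x
}

#' @rdname read_drug_table
#' @param x A drug table.
#' @param path Output TSV path.
#' @export
write_drug_table <- function(x, path) {
  readr::write_tsv(x, path, progress = FALSE)
  invisible(path)
}

#' Write a two-sheet variant summation workbook
#'
#' Writes the paired output of [build_summation()] as a plain-text workbook
#' with two named sheets: `"AA Change"` (all amino-acid-changing variants)
#' and `"Prot. Func. Affecting AA Change"` (the function-affecting subset
#' absent from the reference populations). Each sheet lists per-variant
#' percent-conversion rows, closes each gene with a `Summary` row (combined
#' percent, capped at 100 by the independence formula), and closes the sheet
#' with a `Totals` row equal to the column-wise sum of the Summary rows.
#' Percentages are displayed with one decimal.
#'
#' An empty gene set yields a valid workbook with headers only.
#'
#' @param tables A list with elements `all_aa` and `functional`, each a
#'   `summation_table` from [build_summation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summation_workbook <- function(tables, path) {
  stopifnot(is.list(tables), all(c("all_aa", "functional") %in% names(tables)))
  sheet_names <- c(all_aa = "AA Change",
                   functional = "Prot. Func. Affecting AA Change")
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(v) sprintf("%.1f", v)
  for (key in c("all_aa", "functional")) {
    st <- tables[[key]]
    writeLines(sprintf("# Sheet: %s", sheet_names[[key]]), con)
    header <- paste(c("gene", "row", "aa_impact", st$cell_lines), collapse = "\t")
    writeLines(header, con)
    for (prof in st$profiles) {
      if (nrow(prof$variants) > 0) {
        for (i in seq_len(nrow(prof$variants))) {
          writeLines(paste(c(prof$gene, prof$variants$variant_id[i],
                             prof$variants$aa_impact[i],
                             fmt(unlist(prof$variants$percents[i]))),
                           collapse = "\t"), con)
        }
      }
      writeLines(paste(c(prof$gene, "Summary", "", fmt(prof$summary)),
                       collapse = "\t"), con)
    }
    if (length(st$profiles) > 0) {
      writeLines(paste(c("", "Totals", "", fmt(st$totals)), collapse = "\t"), con)
    }
  }
  invisible(path)
}

#' Read a summation workbook written by [write_summation_workbook()]
#'
#' @param path Workbook path.
#' @return A list with elements `all_aa` and `functional`, each a
#'   `summation_table`.
#' @export
read_summation_workbook <- function(path) {
  lines <- readLines(path)
  sheet_starts <- grep("^# Sheet: ", lines)
  if (length(sheet_starts) != 2) {
    abort("summation workbook must contain exactly two sheets")
  }
  keys <- c("AA Change" = "all_aa", "Prot. Func. Affecting AA Change" = "functional")
  out <- list()
  bounds <- c(sheet_starts, length(lines) + 1)
  for (s in 1:2) {
    sheet_name <- sub("^# Sheet: ", "", lines[bounds[s]])
    body <- lines[(bounds[s] + 1):(bounds[s + 1] - 1)]
    header <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
    cell_lines <- header[-(1:3)]
    rows <- lapply(body[-1], function(l) strsplit(l, "\t", fixed = TRUE)[[1]])
    profiles <- list()
    cur_gene <- NULL
    cur_rows <- list()
    totals <- stats::setNames(rep(0, length(cell_lines)), cell_lines)
    for (r in rows) {
      vals <- as.numeric(r[-(1:3)])
      names(vals) <- cell_lines
      if (r[2] == "Totals") {
        totals <- vals
      } else if (r[2] == "Summary") {
        variants <- if (length(cur_rows) == 0) {
          tibble(variant_id = character(), aa_impact = character(),
                 percents = list())
        } else {
          tibble(
            variant_id = vapply(cur_rows, `[`, "", 2),
            aa_impact = vapply(cur_rows, `[`, "", 3),
            percents = lapply(cur_rows, function(cr) {
              stats::setNames(as.numeric(cr[-(1:3)]), cell_lines)
            })
          )
        }
        profiles[[r[1]]] <- list(gene = r[1], variants = variants, summary = vals)
        cur_rows <- list()
      } else {
        cur_rows <- c(cur_rows, list(r))
      }
    }
    out[[keys[[sheet_name]]]] <- new_summation_table(
      subset = if (keys[[sheet_name]] == "all_aa") "all_aa_changing"
               else "function_affecting_and_absent",
      cell_lines = cell_lines, profiles = profiles, totals = totals
    )
  }
  out
}
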