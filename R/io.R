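#' Write and read expression cohorts as tab-delimited text
#'
#' The expression matrix is written genes-in-rows with a `gene_id`
#' first column and sample ids as the header; sample metadata goes to a
#' companion TSV with columns `sample_id`, `condition`, `cancer_type`,
#' `dataset_id`. UTF-8, Unix newlines, no quoting. The reader validates
#' that every sample has metadata and reports offenders by id, and the
#' pair round-trips losslessly on its own output.
#'
#' @param cohort An [expr_cohort()].
#' @param path,meta_path Paths for the value matrix and the metadata
#'   table.
#' @return `write_expression()`: the paths, invisibly.
#'   `read_expression()`: an [expr_cohort()].
#' @export
write_expression <- function(cohort, path, meta_path) {
  stopifnot(inherits(cohort, "expr_cohort"))
  tab <- data.frame(gene_id = rownames(cohort$values),
                    cohort$values, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cohort$sample_meta, meta_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(values = path, meta = meta_path))
}

#' @rdname write_expression
#' @export
read_expression <- function(path, meta_path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1L] != "gene_id") {
    stopf("expression file '%s' must start with a 'gene_id' column", path)
  }
  values <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(values) <- tab$gene_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(values), meta$sample_id)
  if (length(missing)) {
    stopf("sample(s) missing metadata: %s", paste(missing, collapse = ", "))
  }
  meta <- meta[match(colnames(values), meta$sample_id), ]
  expr_cohort(values, meta)
}

#' Read and write gene-set collections in GMT format
#'
#' GMT lines are tab-separated: set name, description, then member
#' genes. Parse errors report the offending line number.
#'
#' @param path File path.
#' @param gene_sets Named list of character vectors; descriptions taken
#'   from a `descriptions` attribute when present.
#' @return `read_gmt()`: named list of character vectors with a
#'   `descriptions` attribute. `write_gmt()`: the path, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L) {
      stopf("malformed GMT line %d in '%s': need name, description, members",
            i, path)
    }
    sets[[parts[1L]]] <- parts[-(1:2)]
    descs <- c(descs, parts[2L])
  }
  attr(sets, "descriptions") <- descs
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(gene_sets, path) {
  descs <- attr(gene_sets, "descriptions")
  if (is.null(descs)) descs <- rep("na", length(gene_sets))
  lines <- vapply(seq_along(gene_sets), function(i) {
    paste(c(names(gene_sets)[i], descs[i], gene_sets[[i]]),
          collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Read a literature-evidence table
#'
#' Expects a TSV with columns `gene`, `cell_growth_plus_angiogenesis`,
#' `cell_growth_or_angiogenesis`, `cell_growth`, `angiogenesis`; a
#' `total_articles` column is recomputed if absent. Lines starting with
#' `#` are treated as comments.
#'
#' @param path File path.
#' @return A data frame usable by [rank_by_evidence()].
#' @export
read_evidence <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  count_cols <- c("cell_growth_plus_angiogenesis",
                  "cell_growth_or_angiogenesis",
                  "cell_growth", "angiogenesis")
  missing_cols <- setdiff(c("gene", count_cols), names(tab))
  if (length(missing_cols)) {
    stopf("evidence table '%s' lacks column(s): %s", path,
          paste(missing_cols, collapse = ", "))
  }
  for (col in count_cols) {
    if (!is.numeric(tab[[col]]) || any(tab[[col]] < 0)) {
      stopf("evidence column '%s' must hold non-negative counts", col)
    }
  }
  if (!"total_articles" %in% names(tab)) {
    tab$total_articles <- rowSums(tab[, count_cols])
  }
  tab
}

#' Write a table as TSV with a comment header
#'
#' Standard table writer for pipeline artifacts: optional `# key: value`
#' comment lines recording configuration, then a tab-delimited table;
#' fractions and other numerics are serialized with 6 decimal places.
#'
#' @param table A data frame.
#' @param path Output path.
#' @param comments Named character/numeric vector written as
#'   `# name: value` header lines.
#' @return The path, invisibly.
#' @export
write_tsv <- function(table, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comments)) {
    writeLines(sprintf("# %s: %s", names(comments),
                       vapply(comments, format, character(1L))), con)
  }
  tab <- as.data.frame(table)
  for (col in names(tab)) {
    if (is.numeric(tab[[col]]) && !is.integer(tab[[col]])) {
      tab[[col]] <- formatC(tab[[col]], digits = 6L, format = "f")
    }
  }
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a motif registry TSV
#'
#' Columns: `name`, `sequence`, optional `expansion` (concrete A/C/G/T
#' expansion for IUPAC-degenerate consensi) and `note`.
#'
#' @param path File path.
#' @return A registry data frame for [assemble_promoter()].
#' @export
read_motif_registry <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (!all(c("name", "sequence") %in% names(tab))) {
    stopf("motif registry '%s' needs 'name' and 'sequence' columns", path)
  }
  tab
}
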