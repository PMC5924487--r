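#' Construct an expression cohort object
#'
#' A light container for a log2 expression matrix (genes in rows,
#' samples in columns) plus per-sample metadata: condition
#' (`tumor`/`normal`), cancer type, and dataset (series) identifier.
#' The constructor validates the invariants every downstream operation
#' assumes: dimnames match the metadata, all values are finite, and
#' every dataset contains at least one sample in each arm.
#'
#' @param values Numeric matrix of log2 expression, genes x samples,
#'   with row and column names.
#' @param sample_meta Data frame with columns `sample_id`, `condition`
#'   (`"tumor"` or `"normal"`), `cancer_type`, `dataset_id`; one row per
#'   column of `values`, in the same order.
#' @return An object of class `expr_cohort`.
#' @export
expr_cohort <- function(values, sample_meta) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("'values' must be a numeric matrix (genes x samples)")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stopf("'values' must carry gene row names and sample column names")
  }
  if (!all(is.finite(values))) {
    stopf("'values' contains non-finite entries")
  }
  need <- c("sample_id", "condition", "cancer_type", "dataset_id")
  missing_cols <- setdiff(need, names(sample_meta))
  if (length(missing_cols)) {
    stopf("'sample_meta' lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  sample_meta <- as.data.frame(sample_meta)[, need]
  rownames(sample_meta) <- NULL
  for (col in need) sample_meta[[col]] <- as.character(sample_meta[[col]])
  if (nrow(sample_meta) != ncol(values) ||
      !identical(sample_meta$sample_id, colnames(values))) {
    stopf("'sample_meta$sample_id' must equal colnames(values) in order")
  }
  if (anyDuplicated(rownames(values))) stopf("duplicate gene ids")
  if (anyDuplicated(colnames(values))) stopf("duplicate sample ids")
  bad <- setdiff(unique(sample_meta$condition), c("tumor", "normal"))
  if (length(bad)) {
    stopf("unknown condition label(s): %s", paste(bad, collapse = ", "))
  }
  if (any(is.na(sample_meta))) stopf("'sample_meta' contains NA fields")
  arms <- table(sample_meta$dataset_id, sample_meta$condition)
  if (ncol(arms) < 2L || any(arms == 0L)) {
    off <- rownames(arms)[rowSums(arms == 0L) > 0L]
    if (ncol(arms) < 2L) off <- rownames(arms)
    stopf("dataset(s) missing a tumor or normal arm: %s",
          paste(off, collapse = ", "))
  }
  structure(
    list(values = values, sample_meta = sample_meta),
    class = "expr_cohort"
  )
}

#' @export
print.expr_cohort <- function(x, ...) {
  m <- x$sample_meta
  cat(sprintf(
    "expr_cohort: %d genes x %d samples (%d tumor / %d normal)\n",
    nrow(x$values), ncol(x$values),
    sum(m$condition == "tumor"), sum(m$condition == "normal")))
  cat(sprintf("  cancer types: %s\n",
              paste(unique(m$cancer_type), collapse = ", ")))
  cat(sprintf("  datasets: %d\n", length(unique(m$dataset_id))))
  invisible(x)
}

#' @export
dim.expr_cohort <- function(x) dim(x$values)

gene_ids <- function(cohort) rownames(cohort$values)

# Resolve user-supplied symbols against cohort genes, case-insensitively.
match_genes <- function(cohort, genes) {
  idx <- match(norm_symbols(genes), norm_symbols(gene_ids(cohort)))
  if (anyNA(idx)) {
    stopf("unknown gene(s): %s", paste(genes[is.na(idx)], collapse = ", "))
  }
  idx
}
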