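#' Selection configuration for the TF screening workflow
#'
#' @param fc_threshold Log2 fold-change cutoff (default 1, i.e. 2-fold).
#' @param strict If `TRUE`, the fold-change filter uses a strict `>`
#'   comparison instead of the default `>=`.
#' @param growth_term_id,angio_term_id Gene-set labels used for the GO
#'   membership filter.
#' @param overexpression_margin Log2 margin above the within-dataset
#'   normal mean for calling a tumor sample overexpressed (default 1,
#'   i.e. 2-fold).
#' @param dataset_aggregation How per-dataset fold changes combine into
#'   a per-cancer-type value: `"median"`, `"mean"`, or `"any-dataset"`
#'   (the maximum, so passing in at least one series suffices).
#' @param top_k Number of top-ranked TFs flagged for promoter design.
#' @param evidence_min_articles Article-count threshold for calling a
#'   TF well studied (default 100).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(fc_threshold = 1,
                             strict = FALSE,
                             growth_term_id = "GO:0016049",
                             angio_term_id = "GO:0001525",
                             overexpression_margin = 1,
                             dataset_aggregation = c("median", "mean",
                                                     "any-dataset"),
                             top_k = 3L,
                             evidence_min_articles = 100L) {
  structure(list(
    fc_threshold = check_number(fc_threshold, "fc_threshold", min = 0),
    strict = check_flag(strict, "strict"),
    growth_term_id = as.character(growth_term_id),
    angio_term_id = as.character(angio_term_id),
    overexpression_margin = check_number(overexpression_margin,
                                         "overexpression_margin"),
    dataset_aggregation = match.arg(dataset_aggregation),
    top_k = check_count(top_k, "top_k"),
    evidence_min_articles = check_count(evidence_min_articles,
                                        "evidence_min_articles", min = 0L)
  ), class = "selection_config")
}

#' Quantile-normalize an expression cohort
#'
#' Forces every sample (column) onto a common distribution: after
#' normalization all columns share the identical sorted value vector,
#' the per-rank across-sample mean. This is the normalization component
#' of RMA-style microarray preprocessing. Delegates to
#' [limma::normalizeQuantiles()]; gene and sample ordering and metadata
#' are preserved.
#'
#' @param cohort An [expr_cohort()].
#' @return An [expr_cohort()] with normalized values.
#' @export
quantile_normalize <- function(cohort) {
  stopifnot(inherits(cohort, "expr_cohort"))
  if (anyNA(cohort$values)) stopf("expression matrix contains missing values")
  norm <- limma::normalizeQuantiles(cohort$values)
  dimnames(norm) <- dimnames(cohort$values)
  expr_cohort(norm, cohort$sample_meta)
}

#' Tumor-vs-normal log2 fold changes for one cancer type
#'
#' For each dataset (series) of the cancer type, the per-gene fold
#' change is the mean log2 expression over tumor samples minus the mean
#' over normal samples; per-dataset values are then aggregated across
#' the cancer type's datasets by the chosen rule. Because both arms of
#' a dataset share its baseline offset, between-series batch shifts
#' cancel within datasets before aggregation.
#'
#' @param cohort An [expr_cohort()].
#' @param cancer_type Cancer-type label present in the cohort.
#' @param aggregation `"median"` (default), `"mean"`, or
#'   `"any-dataset"` (maximum over datasets).
#' @return A data frame of class `fold_change_table` with columns
#'   `gene`, `fc`, `n_tumor`, `n_normal` and attributes `cancer_type`,
#'   `aggregation` and `per_dataset` (the genes x datasets matrix of
#'   per-series fold changes).
#' @export
log2_fold_change <- function(cohort, cancer_type,
                             aggregation = c("median", "mean",
                                             "any-dataset")) {
  stopifnot(inherits(cohort, "expr_cohort"))
  aggregation <- match.arg(aggregation)
  meta <- cohort$sample_meta
  if (!cancer_type %in% meta$cancer_type) {
    stopf("cancer type '%s' not present in the cohort", cancer_type)
  }
  meta <- meta[meta$cancer_type == cancer_type, ]
  datasets <- unique(meta$dataset_id)
  per_ds <- matrix(NA_real_, nrow(cohort$values), length(datasets),
                   dimnames = list(gene_ids(cohort), datasets))
  n_tumor <- 0L
  n_normal <- 0L
  for (ds in datasets) {
    tum <- meta$sample_id[meta$dataset_id == ds & meta$condition == "tumor"]
    nor <- meta$sample_id[meta$dataset_id == ds & meta$condition == "normal"]
    if (length(tum) == 0L || length(nor) == 0L) {
      stopf("dataset '%s' lacks a %s arm", ds,
            if (length(tum) == 0L) "tumor" else "normal")
    }
    per_ds[, ds] <- rowMeans(cohort$values[, tum, drop = FALSE]) -
      rowMeans(cohort$values[, nor, drop = FALSE])
    n_tumor <- n_tumor + length(tum)
    n_normal <- n_normal + length(nor)
  }
  fc <- switch(aggregation,
               median = apply(per_ds, 1L, stats::median),
               mean = rowMeans(per_ds),
               `any-dataset` = apply(per_ds, 1L, max))
  out <- data.frame(gene = gene_ids(cohort), fc = unname(fc),
                    n_tumor = n_tumor, n_normal = n_normal,
                    stringsAsFactors = FALSE)
  structure(out, class = c("fold_change_table", "data.frame"),
            cancer_type = cancer_type, aggregation = aggregation,
            per_dataset = per_ds)
}

#' Apply the TF / GO / fold-change selection funnel
#'
#' Reproduces the candidate-selection funnel: a gene is selected iff it
#' is in the TF catalog, annotated to the growth or the angiogenesis
#' set, and its aggregated log2 fold change reaches the threshold in at
#' least one cancer type. Every intermediate flag is recorded, and the
#' funnel counts are attached as an attribute, including the number of
#' GO associations counted with multiplicity (a TF in both sets counts
#' twice) alongside the number of unique GO-annotated TFs.
#'
#' @param fc A `fold_change_table` or a list of them (one per cancer
#'   type, as returned by [log2_fold_change()]).
#' @param tf_catalog Character vector of TF symbols.
#' @param gene_sets Named list of gene sets containing the configured
#'   growth and angiogenesis term ids.
#' @param config A [selection_config()].
#' @return A data frame of class `candidate_table` with columns `gene`,
#'   `is_tf`, `go_growth`, `go_angio`, `fc_<type>` per cancer type,
#'   `max_fc`, `passes_fc`, `selected`; attribute `funnel` holds the
#'   stage counts.
#' @export
select_tfs <- function(fc, tf_catalog, gene_sets,
                       config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  if (inherits(fc, "fold_change_table")) fc <- list(fc)
  if (!length(fc) || !all(vapply(fc, inherits, logical(1L),
                                 "fold_change_table"))) {
    stopf("'fc' must be a fold_change_table or a list of them")
  }
  for (term in c(config$growth_term_id, config$angio_term_id)) {
    if (!term %in% names(gene_sets)) {
      stopf("gene-set collection lacks term '%s'", term)
    }
  }
  genes <- fc[[1L]]$gene
  for (tab in fc) {
    if (!identical(tab$gene, genes)) {
      stopf("fold-change tables disagree on gene ids")
    }
  }
  types <- vapply(fc, attr, character(1L), "cancer_type")
  fc_mat <- vapply(fc, function(tab) tab$fc, numeric(length(genes)))
  fc_mat <- matrix(fc_mat, ncol = length(fc),
                   dimnames = list(genes, types))

  key <- norm_symbols(genes)
  is_tf <- key %in% norm_symbols(tf_catalog)
  growth <- norm_symbols(gene_sets[[config$growth_term_id]])
  angio <- norm_symbols(gene_sets[[config$angio_term_id]])
  go_growth <- key %in% growth
  go_angio <- key %in% angio
  max_fc <- apply(fc_mat, 1L, max)
  passes_fc <- if (config$strict) max_fc > config$fc_threshold else
    max_fc >= config$fc_threshold
  selected <- is_tf & (go_growth | go_angio) & passes_fc

  out <- data.frame(gene = genes, is_tf = is_tf, go_growth = go_growth,
                    go_angio = go_angio, stringsAsFactors = FALSE)
  fc_cols <- as.data.frame(fc_mat)
  names(fc_cols) <- paste0("fc_", types)
  out <- cbind(out, fc_cols)
  out$max_fc <- unname(max_fc)
  out$passes_fc <- unname(passes_fc)
  out$selected <- unname(selected)
  rownames(out) <- NULL

  go_tf <- is_tf & (go_growth | go_angio)
  funnel <- list(
    n_genes = length(genes),
    n_tf = sum(is_tf),
    n_go_with_multiplicity = sum(is_tf & go_growth) + sum(is_tf & go_angio),
    n_go_unique = sum(go_tf),
    n_pass_fc = sum(go_tf & passes_fc),
    n_selected = sum(selected)
  )
  structure(out, class = c("candidate_table", "data.frame"),
            funnel = funnel, config = config)
}

#' Per-patient overexpression fraction of a gene in a cancer type
#'
#' A tumor sample overexpresses a gene when its log2 expression is at
#' least the same dataset's normal-arm mean plus `margin` (default 1,
#' i.e. 2-fold), mirroring the gene-level 2-fold criterion. The
#' fraction is the count of such tumor samples over all tumor samples
#' of the cancer type, pooled across its datasets.
#'
#' @param cohort An [expr_cohort()].
#' @param gene Gene symbol.
#' @param cancer_type Cancer-type label.
#' @param margin Log2 margin above the normal mean.
#' @return A fraction in `[0, 1]`.
#' @export
overexpression_fraction <- function(cohort, gene, cancer_type,
                                    margin = 1) {
  frac <- coexpression_fraction(cohort, gene, cancer_type,
                                min_genes = 1L, margin = margin)
  frac
}

#' Fraction of tumor samples co-overexpressing several genes
#'
#' Counts tumor samples of a cancer type that overexpress (per the
#' dataset-relative rule of [overexpression_fraction()]) at least
#' `min_genes` of the listed genes. Non-increasing in `min_genes`;
#' `min_genes = 0` vacuously returns 1.
#'
#' @param cohort An [expr_cohort()].
#' @param genes Character vector of gene symbols.
#' @param cancer_type Cancer-type label.
#' @param min_genes Minimum number of listed genes a sample must
#'   overexpress (0 to `length(genes)`).
#' @param margin Log2 margin above the normal mean.
#' @return A fraction in `[0, 1]`.
#' @export
coexpression_fraction <- function(cohort, genes, cancer_type,
                                  min_genes = length(genes),
                                  margin = 1) {
  stopifnot(inherits(cohort, "expr_cohort"))
  min_genes <- check_count(min_genes, "min_genes", min = 0L)
  if (!length(genes)) stopf("'genes' must name at least one gene")
  if (min_genes > length(genes)) {
    stopf("'min_genes' (%d) exceeds the number of genes (%d)",
          min_genes, length(genes))
  }
  gidx <- match_genes(cohort, genes)
  meta <- cohort$sample_meta
  if (!cancer_type %in% meta$cancer_type) {
    stopf("cancer type '%s' not present in the cohort", cancer_type)
  }
  meta <- meta[meta$cancer_type == cancer_type, ]
  hits <- integer(0)
  for (ds in unique(meta$dataset_id)) {
    tum <- meta$sample_id[meta$dataset_id == ds & meta$condition == "tumor"]
    nor <- meta$sample_id[meta$dataset_id == ds & meta$condition == "normal"]
    if (length(nor) == 0L) stopf("dataset '%s' has no normal samples", ds)
    cutoff <- rowMeans(cohort$values[gidx, nor, drop = FALSE]) + margin
    over <- cohort$values[gidx, tum, drop = FALSE] >= cutoff
    hits <- c(hits, colSums(matrix(over, nrow = length(gidx))))
  }
  if (length(hits) == 0L) stopf("no tumor samples in '%s'", cancer_type)
  mean(hits >= min_genes)
}

#' Hypergeometric gene-set enrichment
#'
#' Tests each gene set for over-representation in a query list: with a
#' universe of size N, a set of size K (after intersecting the set with
#' the universe), a query of size n and an observed overlap k, the
#' p-value is the hypergeometric upper tail P(X >= k). P-values are
#' adjusted across the tested sets by Benjamini-Hochberg, and results
#' are sorted by ascending p-value.
#'
#' @param query Character vector of query symbols (must lie in
#'   `universe`).
#' @param universe Character vector of background symbols.
#' @param gene_sets Named list of character vectors.
#' @return A data frame of class `enrichment_result` with columns
#'   `set_id`, `overlap`, `set_size`, `query_size`, `universe_size`,
#'   `p_value`, `adjusted_p`.
#' @export
enrich_gene_sets <- function(query, universe, gene_sets) {
  uni <- unique(norm_symbols(universe))
  qry <- unique(norm_symbols(query))
  outside <- setdiff(qry, uni)
  if (length(outside)) {
    stopf("query gene(s) outside the universe: %s",
          paste(outside, collapse = ", "))
  }
  if (!length(gene_sets) || is.null(names(gene_sets))) {
    stopf("'gene_sets' must be a non-empty named list")
  }
  res <- lapply(names(gene_sets), function(id) {
    set <- intersect(unique(norm_symbols(gene_sets[[id]])), uni)
    k <- length(intersect(set, qry))
    p <- stats::phyper(k - 1L, length(set), length(uni) - length(set),
                       length(qry), lower.tail = FALSE)
    data.frame(set_id = id, overlap = k, set_size = length(set),
               query_size = length(qry), universe_size = length(uni),
               p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
  res <- res[order(res$p_value, res$set_id), ]
  rownames(res) <- NULL
  structure(res, class = c("enrichment_result", "data.frame"),
            adjust_method = "BH")
}

#' Rank selected candidates by literature evidence
#'
#' Orders the selected candidates by descending total article count
#' (the sum of the four evidence categories), breaking ties
#' alphabetically by symbol; assigns ranks 1..n, flags the `top_k`
#' genes, and marks candidates whose total reaches
#' `evidence_min_articles` as well studied.
#'
#' @param candidates A `candidate_table` from [select_tfs()].
#' @param evidence An evidence table as produced by
#'   [generate_evidence_table()] or [read_evidence()]; every selected
#'   candidate must have a row.
#' @param config A [selection_config()].
#' @return The candidate table with added columns `total_articles`,
#'   `well_studied`, `rank` (NA for unselected genes) and `top_k`.
#' @export
rank_by_evidence <- function(candidates, evidence,
                             config = selection_config()) {
  stopifnot(inherits(config, "selection_config"))
  count_cols <- c("cell_growth_plus_angiogenesis",
                  "cell_growth_or_angiogenesis",
                  "cell_growth", "angiogenesis")
  missing_cols <- setdiff(c("gene", count_cols), names(evidence))
  if (length(missing_cols)) {
    stopf("evidence table lacks column(s): %s",
          paste(missing_cols, collapse = ", "))
  }
  idx <- match(norm_symbols(candidates$gene), norm_symbols(evidence$gene))
  sel <- candidates$selected
  no_row <- sel & is.na(idx)
  if (any(no_row)) {
    stopf("no evidence row for selected gene(s): %s",
          paste(candidates$gene[no_row], collapse = ", "))
  }
  total <- rowSums(evidence[idx, count_cols, drop = FALSE])
  candidates$total_articles <- ifelse(is.na(idx), NA_real_, total)
  candidates$well_studied <- !is.na(total) & sel &
    total >= config$evidence_min_articles

  candidates$rank <- NA_integer_
  if (any(sel)) {
    ord <- order(-candidates$total_articles[sel],
                 norm_symbols(candidates$gene[sel]))
    candidates$rank[which(sel)[ord]] <- seq_len(sum(sel))
  }
  candidates$top_k <- !is.na(candidates$rank) &
    candidates$rank <= config$top_k
  candidates
}

#' Top-ranked TF symbols from a ranked candidate table
#'
#' @param candidates A ranked `candidate_table` (after
#'   [rank_by_evidence()]).
#' @param k Number of top genes to return (default: all flagged
#'   `top_k`).
#' @return Character vector of gene symbols in rank order.
#' @export
top_tfs <- function(candidates, k = NULL) {
  if (!"rank" %in% names(candidates)) {
    stopf("'candidates' has no ranks; run rank_by_evidence() first")
  }
  ranked <- candidates[!is.na(candidates$rank), ]
  ranked <- ranked[order(ranked$rank), ]
  if (is.null(k)) ranked <- ranked[ranked$top_k, ] else
    ranked <- ranked[ranked$rank <= k, ]
  ranked$gene
}
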