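# Small in-code fixtures shared across test files.

# A compact but fully structured simulation configuration.
small_config <- function(...) {
  defaults <- list(n_genes = 60, n_tf = 12, n_cancer_types = 2,
                   n_datasets_per_type = 2, n_tumor_per_dataset = 8,
                   n_normal_per_dataset = 8, noise_sd = 0.4, seed = 11)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Build an expr_cohort with fully deterministic values from a matrix.
manual_cohort <- function(values, condition, cancer_type = "CT01",
                          dataset_id = "CT01_DS01") {
  n <- ncol(values)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("G%03d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("S%03d", seq_len(n))
  }
  expr_cohort(values, data.frame(
    sample_id = colnames(values),
    condition = rep_len(condition, n),
    cancer_type = rep_len(cancer_type, n),
    dataset_id = rep_len(dataset_id, n)))
}

# Fold-change tables for a one-dataset cohort built from tumor/normal
# value matrices laid side by side.
manual_fc <- function(tumor, normal, cancer_type = "CT01",
                      aggregation = "median") {
  values <- cbind(tumor, normal)
  colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  cohort <- manual_cohort(values,
                          rep(c("tumor", "normal"),
                              c(ncol(tumor), ncol(normal))),
                          cancer_type = cancer_type,
                          dataset_id = paste0(cancer_type, "_DS01"))
  log2_fold_change(cohort, cancer_type, aggregation)
}

# Exhaustive hypergeometric upper tail by enumerating every draw of
# size n from an N-element universe (independent oracle).
enum_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)
  overlaps <- apply(draws, 2L, function(d) sum(d %in% in_set))
  mean(overlaps >= k)
}
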