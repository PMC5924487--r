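#' Simulation configuration for synthetic tumor/normal cohorts
#'
#' Bundles every parameter of the synthetic-cohort generator: cohort
#' geometry (genes, transcription factors, cancer types, datasets per
#' type, samples per arm), the planted overexpression signal (which TF
#' genes carry it, its size in log2 units, and its penetrance across
#' tumor samples), and the noise model (per-gene baseline spread,
#' per-dataset batch offsets, residual noise), all on the log2 scale
#' typical of RMA-processed microarray data.
#'
#' @param n_genes Number of genes in the expression matrix.
#' @param n_tf Number of genes flagged as transcription factors (the TF
#'   catalog); must not exceed `n_genes`.
#' @param n_cancer_types Number of cancer types in the cohort.
#' @param n_datasets_per_type Number of independent datasets (series)
#'   per cancer type.
#' @param n_tumor_per_dataset,n_normal_per_dataset Samples per arm in
#'   each dataset.
#' @param planted_tfs Gene symbols carrying the planted tumor
#'   overexpression; always placed in the TF catalog.
#' @param planted_effect Mean tumor-minus-normal shift, in log2 units,
#'   added to carrier tumor samples of planted genes.
#' @param baseline_mean,baseline_sd Mean and spread of per-gene baseline
#'   expression (log2 units).
#' @param noise_sd Residual per-measurement noise (log2 units).
#' @param dataset_sd Spread of per-dataset baseline offsets (log2
#'   units), emulating between-series batch effects.
#' @param overexpress_penetrance Probability that a tumor sample carries
#'   the planted shift for a given planted gene, in `[0, 1]`.
#' @param seed Integer seed; all generators are pure functions of their
#'   configuration and seed.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [generate_cohort()], [tf_catalog()]
#' @export
sim_config <- function(n_genes = 1000L,
                       n_tf = 120L,
                       n_cancer_types = 8L,
                       n_datasets_per_type = 3L,
                       n_tumor_per_dataset = 20L,
                       n_normal_per_dataset = 20L,
                       planted_tfs = c("NFKB1", "CREB1", "HIF1A"),
                       planted_effect = 2,
                       baseline_mean = 7,
                       baseline_sd = 1.5,
                       noise_sd = 0.5,
                       dataset_sd = 0.25,
                       overexpress_penetrance = 0.8,
                       seed = 1L) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_tf = check_count(n_tf, "n_tf"),
    n_cancer_types = check_count(n_cancer_types, "n_cancer_types"),
    n_datasets_per_type = check_count(n_datasets_per_type,
                                      "n_datasets_per_type"),
    n_tumor_per_dataset = check_count(n_tumor_per_dataset,
                                      "n_tumor_per_dataset"),
    n_normal_per_dataset = check_count(n_normal_per_dataset,
                                       "n_normal_per_dataset"),
    planted_tfs = as.character(planted_tfs),
    planted_effect = check_number(planted_effect, "planted_effect"),
    baseline_mean = check_number(baseline_mean, "baseline_mean"),
    baseline_sd = check_number(baseline_sd, "baseline_sd", min = 0),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    dataset_sd = check_number(dataset_sd, "dataset_sd", min = 0),
    overexpress_penetrance = check_number(overexpress_penetrance,
                                          "overexpress_penetrance",
                                          min = 0, max = 1),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$n_tf > cfg$n_genes) {
    stopf("'n_tf' (%d) must not exceed 'n_genes' (%d)",
          cfg$n_tf, cfg$n_genes)
  }
  if (anyDuplicated(norm_symbols(cfg$planted_tfs))) {
    stopf("'planted_tfs' contains duplicate symbols")
  }
  if (length(cfg$planted_tfs) > cfg$n_tf) {
    stopf("'planted_tfs' has more genes (%d) than 'n_tf' (%d)",
          length(cfg$planted_tfs), cfg$n_tf)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  genes: %d (%d TFs; planted: %s)\n", x$n_genes, x$n_tf,
              paste(x$planted_tfs, collapse = ", ")))
  cat(sprintf("  cohorts: %d cancer types x %d datasets x (%dT/%dN)\n",
              x$n_cancer_types, x$n_datasets_per_type,
              x$n_tumor_per_dataset, x$n_normal_per_dataset))
  cat(sprintf(
    "  effect: %.2f log2, penetrance %.2f; noise_sd %.2f, dataset_sd %.2f\n",
    x$planted_effect, x$overexpress_penetrance, x$noise_sd, x$dataset_sd))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

#' Gene identifiers and TF catalog implied by a simulation configuration
#'
#' Gene symbols are deterministic in the configuration (not the seed):
#' the planted TFs come first under their given names, followed by
#' zero-padded synthetic symbols. The TF catalog is the first `n_tf`
#' genes, so it always contains every planted TF.
#'
#' @param config A [sim_config()] object.
#' @return `sim_gene_ids()`: character vector of `n_genes` symbols.
#' @export
sim_gene_ids <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_extra <- config$n_genes - length(config$planted_tfs)
  c(config$planted_tfs, sprintf("G%05d", seq_len(n_extra)))
}

#' @rdname sim_gene_ids
#' @return `tf_catalog()`: character vector of `n_tf` symbols.
#' @export
tf_catalog <- function(config) {
  sim_gene_ids(config)[seq_len(config$n_tf)]
}
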