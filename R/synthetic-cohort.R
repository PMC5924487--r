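#' Generate a synthetic multi-cancer tumor/normal expression cohort
#'
#' Simulates a log2 expression matrix with the structure the selection
#' pipeline assumes: several cancer types, each observed in several
#' independent datasets (series) with their own baseline offsets, and a
#' planted subset of TF genes overexpressed in tumor samples.
#'
#' The generative model, per gene g and sample s of dataset d:
#' \deqn{y_{gs} = \mu_g + \beta_d + \Delta \, Z_{gs} \, [s\ tumor,\ g\ planted]
#'   + \varepsilon_{gs}}
#' with per-gene baseline \eqn{\mu_g \sim N(\mu_0, \sigma_b^2)},
#' per-dataset offset \eqn{\beta_d \sim N(0, \sigma_d^2)}, planted
#' effect \eqn{\Delta} carried with probability equal to the penetrance
#' (independent Bernoulli \eqn{Z_{gs}} per tumor sample and planted
#' gene), and Gaussian noise \eqn{\varepsilon_{gs} \sim N(0,
#' \sigma^2)}. The expected tumor-minus-normal difference of a planted
#' gene in any dataset is therefore `planted_effect *
#' overexpress_penetrance`, and 0 for all other genes; dataset offsets
#' cancel within datasets.
#'
#' @param config A [sim_config()] object.
#' @return An [expr_cohort()] with `n_genes` rows and
#'   `n_cancer_types * n_datasets_per_type *
#'   (n_tumor_per_dataset + n_normal_per_dataset)` columns.
#' @examples
#' cfg <- sim_config(n_genes = 50, n_tf = 10, n_cancer_types = 2,
#'                   n_datasets_per_type = 2, n_tumor_per_dataset = 5,
#'                   n_normal_per_dataset = 5, seed = 7)
#' cohort <- generate_cohort(cfg)
#' dim(cohort)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  genes <- sim_gene_ids(config)
  planted_idx <- match(norm_symbols(config$planted_tfs),
                       norm_symbols(genes))

  with_seed(derive_seed(config$seed, 1L), {
    baseline <- rnorm(config$n_genes, config$baseline_mean,
                      config$baseline_sd)
    per_ds <- config$n_tumor_per_dataset + config$n_normal_per_dataset
    blocks <- list()
    meta <- list()
    k <- 0L
    for (ct in seq_len(config$n_cancer_types)) {
      ct_label <- sprintf("CT%02d", ct)
      for (ds in seq_len(config$n_datasets_per_type)) {
        k <- k + 1L
        ds_label <- sprintf("%s_DS%02d", ct_label, ds)
        offset <- rnorm(1L, 0, config$dataset_sd)
        cond <- rep(c("tumor", "normal"),
                    c(config$n_tumor_per_dataset,
                      config$n_normal_per_dataset))
        ids <- sprintf("%s_%s%02d", ds_label,
                       ifelse(cond == "tumor", "T", "N"),
                       c(seq_len(config$n_tumor_per_dataset),
                         seq_len(config$n_normal_per_dataset)))
        vals <- baseline + offset +
          matrix(rnorm(config$n_genes * per_ds, 0, config$noise_sd),
                 config$n_genes, per_ds)
        if (length(planted_idx) && config$planted_effect != 0) {
          tum <- which(cond == "tumor")
          carrier <- matrix(
            rbinom(length(planted_idx) * length(tum), 1L,
                   config$overexpress_penetrance),
            length(planted_idx), length(tum))
          vals[planted_idx, tum] <- vals[planted_idx, tum] +
            config$planted_effect * carrier
        }
        dimnames(vals) <- list(genes, ids)
        blocks[[k]] <- vals
        meta[[k]] <- data.frame(sample_id = ids, condition = cond,
                                cancer_type = ct_label,
                                dataset_id = ds_label,
                                stringsAsFactors = FALSE)
      }
    }
    expr_cohort(do.call(cbind, blocks), do.call(rbind, meta))
  })
}

#' Generate growth and angiogenesis gene sets over the TF catalog
#'
#' Builds a two-set collection emulating GO cell-growth (GO:0016049)
#' and angiogenesis (GO:0001525) annotation restricted to a TF catalog.
#' Set sizes are `round(fraction * n_tf)`; their overlap is
#' `round(overlap_fraction * min(size))` genes shared between the two.
#' Planted TFs are always placed in the growth set, so the planted
#' signal can pass the GO filter. Membership is drawn deterministically
#' from the configuration seed.
#'
#' @param config A [sim_config()] object.
#' @param growth_fraction,angio_fraction Fractions of the TF catalog
#'   annotated to each set. Defaults mirror 43/1624 and 68/1624.
#' @param overlap_fraction Fraction of the smaller set also in the
#'   larger (default 8/43).
#' @param growth_term_id,angio_term_id Labels used as set names.
#' @return A named list of two character vectors (a gene-set
#'   collection), with a `descriptions` attribute.
#' @export
generate_gene_sets <- function(config,
                               growth_fraction = 43 / 1624,
                               angio_fraction = 68 / 1624,
                               overlap_fraction = 8 / 43,
                               growth_term_id = "GO:0016049",
                               angio_term_id = "GO:0001525") {
  stopifnot(inherits(config, "sim_config"))
  check_number(growth_fraction, "growth_fraction", min = 0, max = 1)
  check_number(angio_fraction, "angio_fraction", min = 0, max = 1)
  check_number(overlap_fraction, "overlap_fraction", min = 0, max = 1)

  catalog <- tf_catalog(config)
  n_tf <- length(catalog)
  planted <- config$planted_tfs
  n_growth <- max(round(growth_fraction * n_tf), length(planted))
  n_angio <- round(angio_fraction * n_tf)
  n_overlap <- round(overlap_fraction * min(n_growth, n_angio))
  if (n_growth + n_angio - n_overlap > n_tf) {
    stopf("requested set sizes (%d + %d - %d) exceed the TF catalog (%d)",
          n_growth, n_angio, n_overlap, n_tf)
  }

  with_seed(derive_seed(config$seed, 2L), {
    pool <- setdiff(catalog, planted)
    growth <- c(planted,
                sample(pool, n_growth - length(planted)))
    shared <- if (n_overlap > 0L) sample(growth, n_overlap) else character()
    rest <- setdiff(catalog, growth)
    angio <- c(shared, sample(rest, n_angio - n_overlap))
    sets <- list(sort(growth), sort(angio))
    names(sets) <- c(growth_term_id, angio_term_id)
    attr(sets, "descriptions") <- c("cell growth", "angiogenesis")
    sets
  })
}

#' Generate a literature-evidence count table
#'
#' Emulates a PubMed evidence table: for each TF, non-negative article
#' counts in four categories (both keywords, either keyword, cell
#' growth alone, angiogenesis alone as search terms), with the
#' union-count identity `either = growth + angiogenesis - both`
#' maintained. Per-gene abundances are drawn from a heavy-tailed
#' log-normal so a few genes dominate, as in real citation counts.
#' Genes named in `top_genes` are guaranteed the largest totals
#' (emulating heavily published TFs).
#'
#' @param tfs Character vector of TF symbols (non-empty).
#' @param seed Integer seed.
#' @param top_genes Symbols forced to carry the maximal total counts.
#' @return Data frame with columns `gene`,
#'   `cell_growth_plus_angiogenesis`, `cell_growth_or_angiogenesis`,
#'   `cell_growth`, `angiogenesis`, `total_articles`.
#' @export
generate_evidence_table <- function(tfs, seed = 1L,
                                    top_genes = character()) {
  if (!is.character(tfs) || length(tfs) == 0L) {
    stopf("'tfs' must be a non-empty character vector of gene symbols")
  }
  seed <- check_count(seed, "seed", min = 0L)
  top_genes <- as.character(top_genes)
  missing <- setdiff(norm_symbols(top_genes), norm_symbols(tfs))
  if (length(missing)) {
    stopf("'top_genes' not in 'tfs': %s", paste(missing, collapse = ", "))
  }

  with_seed(seed, {
    n <- length(tfs)
    lam <- rlnorm(n, meanlog = log(15), sdlog = 1.4)
    is_top <- norm_symbols(tfs) %in% norm_symbols(top_genes)
    lam[is_top] <- lam[is_top] * 100
    growth <- rpois(n, lam)
    angio <- rpois(n, 0.6 * lam)
    both <- rbinom(n, pmin(growth, angio), 0.2)
    either <- growth + angio - both
    total <- both + either + growth + angio
    # guarantee designated top genes outrank every other gene
    if (any(is_top) && any(!is_top)) {
      floor_total <- max(total[!is_top]) + 1L
      short <- is_top & total < floor_total
      bump <- floor_total - total[short]
      growth[short] <- growth[short] + bump
      either[short] <- either[short] + bump
      total[short] <- total[short] + 2L * bump
    }
    data.frame(gene = tfs,
               cell_growth_plus_angiogenesis = both,
               cell_growth_or_angiogenesis = either,
               cell_growth = growth,
               angiogenesis = angio,
               total_articles = total,
               stringsAsFactors = FALSE)
  })
}

#' Generate a reporter-assay measurement
#'
#' Simulates the four total fluorescence intensities (TFI) entering the
#' ratiometric expression index: the TFBS-driven GFP construct and its
#' co-transfected AsRed2 control in the test well, and the ARE-driven
#' GFP construct and its AsRed2 control in the control well.
#'
#' Per-well transfection efficiencies multiply both channels of a well
#' and therefore cancel exactly in the within-well ratios, which is the
#' point of ratiometric normalization; the residual biological
#' variability is a single mean-one Gamma term with coefficient of
#' variation `noise_cv` on the responsive (TFBS) channel. The expression
#' index computed from the output consequently has expectation exactly
#' `true_index`, and equals it exactly when `noise_cv = 0`.
#'
#' @param true_index True expression index (> 0).
#' @param noise_cv Coefficient of variation of the index (>= 0).
#' @param seed Integer seed.
#' @param condition Label, `"activator"` or `"medium"`.
#' @return A `reporter_measurement` object (see [expression_index()]).
#' @export
generate_reporter_measurements <- function(true_index, noise_cv = 0.1,
                                           seed = 1L,
                                           condition = c("activator",
                                                         "medium")) {
  if (!is.numeric(true_index) || length(true_index) != 1L ||
      !is.finite(true_index) || true_index <= 0) {
    stopf("'true_index' must be a single positive number")
  }
  check_number(noise_cv, "noise_cv", min = 0)
  seed <- check_count(seed, "seed", min = 0L)
  condition <- match.arg(condition)

  with_seed(seed, {
    s_red <- 800
    s_are <- 500
    eff_test <- rlnorm(1L, 0, 0.2)
    eff_ctrl <- rlnorm(1L, 0, 0.2)
    m <- if (noise_cv > 0) {
      shape <- 1 / noise_cv^2
      rgamma(1L, shape = shape, scale = 1 / shape)
    } else 1
    reporter_measurement(
      tfi_tfbs = true_index * s_are * eff_test * m,
      tfi_asred2_test = s_red * eff_test,
      tfi_are = s_are * eff_ctrl,
      tfi_asred2_ctrl = s_red * eff_ctrl,
      condition = condition
    )
  })
}
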