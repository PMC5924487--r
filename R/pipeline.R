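#' Pipeline configuration
#'
#' Assembles the full run configuration from its parts, applying
#' defaults for anything not supplied. The single `seed` governs every
#' stochastic stage through independent derived substreams, so changing
#' one stage's behaviour does not shift another stage's draws.
#'
#' @param simulation A [sim_config()] or a named list of its arguments.
#' @param selection A [selection_config()] or a named list of its
#'   arguments.
#' @param design Named list: `registry` (motif registry data frame or
#'   TSV path), `order`, `copies`, `spacer`, `enzymes`.
#' @param scoring Named list: `enabled` flag, `true_index`, `noise_cv`
#'   for the simulated reporter readout.
#' @param seed Run seed (overrides the simulation seed when given).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = sim_config(),
                            selection = selection_config(),
                            design = list(),
                            scoring = list(),
                            seed = NULL) {
  if (!inherits(simulation, "sim_config")) {
    simulation <- do.call(sim_config, as.list(simulation))
  }
  if (!inherits(selection, "selection_config")) {
    selection <- do.call(selection_config, as.list(selection))
  }
  if (!is.null(seed)) simulation$seed <- check_count(seed, "seed",
                                                     min = 0L)
  design_defaults <- list(registry = default_motif_registry(),
                          order = c("NFKB", "CRE", "HRE"),
                          copies = 3L, spacer = "",
                          enzymes = default_enzymes())
  unknown <- setdiff(names(design), names(design_defaults))
  if (length(unknown)) {
    stopf("unknown design key(s): %s (valid: %s)",
          paste(unknown, collapse = ", "),
          paste(names(design_defaults), collapse = ", "))
  }
  design <- utils::modifyList(design_defaults, design)
  if (is.character(design$registry)) {
    design$registry <- read_motif_registry(design$registry)
  }
  scoring_defaults <- list(enabled = FALSE, true_index = 4,
                           noise_cv = 0.1)
  unknown <- setdiff(names(scoring), names(scoring_defaults))
  if (length(unknown)) {
    stopf("unknown scoring key(s): %s (valid: %s)",
          paste(unknown, collapse = ", "),
          paste(names(scoring_defaults), collapse = ", "))
  }
  scoring <- utils::modifyList(scoring_defaults, scoring)
  structure(list(simulation = simulation, selection = selection,
                 design = design, scoring = scoring),
            class = "pipeline_config")
}

config_sections <- c("simulation", "selection", "design", "scoring",
                     "seed")

#' Load and save pipeline configurations as YAML
#'
#' The file is a key-value document with optional sections
#' `simulation`, `selection`, `design`, `scoring` and a top-level
#' `seed`; absent keys take their defaults (an empty document yields
#' the full default configuration). Unknown section or parameter names
#' are configuration errors listing the valid keys; type mismatches
#' name the offending key. `save_config()` writes the effective
#' configuration so that a save/load round trip is the identity.
#'
#' @param path YAML file path.
#' @param config A `pipeline_config`.
#' @return `load_config()`: a `pipeline_config`. `save_config()`: the
#'   path, invisibly.
#' @export
load_config <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc)) doc <- list()
  if (!is.list(doc)) stopf("config '%s' must be a key-value document", path)
  unknown <- setdiff(names(doc), config_sections)
  if (length(unknown)) {
    stopf("unknown config key(s): %s (valid: %s)",
          paste(unknown, collapse = ", "),
          paste(config_sections, collapse = ", "))
  }
  check_section <- function(section, fun) {
    given <- doc[[section]]
    if (is.null(given)) return(list())
    valid <- names(formals(fun))
    unknown <- setdiff(names(given), valid)
    if (length(unknown)) {
      stopf("unknown %s key(s): %s (valid: %s)", section,
            paste(unknown, collapse = ", "), paste(valid, collapse = ", "))
    }
    given
  }
  sim_args <- check_section("simulation", sim_config)
  sel_args <- check_section("selection", selection_config)
  numeric_like <- function(args, fun, section) {
    for (nm in names(args)) {
      default <- formals(fun)[[nm]]
      if (is.numeric(default) && !is.numeric(args[[nm]])) {
        stopf("config key '%s' in section '%s' must be numeric, got '%s'",
              nm, section, paste(args[[nm]], collapse = ","))
      }
    }
  }
  numeric_like(sim_args, sim_config, "simulation")
  numeric_like(sel_args, selection_config, "selection")
  pipeline_config(
    simulation = do.call(sim_config, sim_args),
    selection = do.call(selection_config, sel_args),
    design = if (is.null(doc$design)) list() else doc$design,
    scoring = if (is.null(doc$scoring)) list() else doc$scoring,
    seed = doc$seed
  )
}

#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  doc <- list(
    simulation = unclass(config$simulation),
    selection = unclass(config$selection),
    design = list(order = config$design$order,
                  copies = config$design$copies,
                  spacer = config$design$spacer),
    scoring = config$scoring
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Run the full design pipeline
#'
#' Executes simulate, normalize, fold change, select, enrich, rank and
#' design in order (plus an optional reporter-scoring stage), writing
#' every intermediate table under `output_dir` together with a JSON
#' manifest recording the effective configuration, seed, package
#' version and the stage outputs. Identical configuration and seed
#' reproduce byte-identical artifacts. A stage failure aborts with the
#' stage name and cause, leaving earlier outputs in place alongside a
#' `FAILED` marker file.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if absent).
#' @return Invisibly, a list with the in-memory stage results:
#'   `cohort`, `normalized`, `fold_changes`, `candidates`,
#'   `enrichment`, `ranked`, `top_tfs`, `construct`, `primers`, and
#'   `score` when scoring is enabled.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  state <- new.env(parent = emptyenv())
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines(sprintf("stage '%s' failed: %s", name,
                         conditionMessage(e)),
                 file.path(output_dir, "FAILED"))
      stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    res
  }
  sim <- config$simulation
  sel <- config$selection

  cohort <- run_stage("simulate", generate_cohort(sim))
  p <- file.path(output_dir, "cohort.tsv")
  write_expression(cohort, p, file.path(output_dir, "cohort_meta.tsv"))
  outputs <- c(outputs, "cohort.tsv")

  normalized <- run_stage("normalize", quantile_normalize(cohort))
  p <- file.path(output_dir, "normalized.tsv")
  write_expression(normalized, p,
                   file.path(output_dir, "normalized_meta.tsv"))
  outputs <- c(outputs, "normalized.tsv")

  types <- unique(cohort$sample_meta$cancer_type)
  fold_changes <- run_stage("fold_change", lapply(types, function(ct) {
    log2_fold_change(normalized, ct, sel$dataset_aggregation)
  }))
  names(fold_changes) <- types
  fc_wide <- data.frame(gene = fold_changes[[1L]]$gene)
  for (ct in types) fc_wide[[paste0("fc_", ct)]] <- fold_changes[[ct]]$fc
  write_tsv(fc_wide, file.path(output_dir, "fold_changes.tsv"),
            comments = c(aggregation = sel$dataset_aggregation))
  outputs <- c(outputs, "fold_changes.tsv")

  catalog <- tf_catalog(sim)
  gene_sets <- run_stage("gene_sets", generate_gene_sets(
    sim, growth_term_id = sel$growth_term_id,
    angio_term_id = sel$angio_term_id))
  write_gmt(gene_sets, file.path(output_dir, "gene_sets.gmt"))

  candidates <- run_stage("select", select_tfs(fold_changes, catalog,
                                               gene_sets, sel))
  write_tsv(candidates, file.path(output_dir, "candidates.tsv"),
            comments = c(fc_threshold = sel$fc_threshold,
                         strict = sel$strict,
                         aggregation = sel$dataset_aggregation))
  outputs <- c(outputs, "candidates.tsv")

  enrichment <- run_stage("enrich", enrich_gene_sets(
    candidates$gene[candidates$selected], catalog, gene_sets))
  write_tsv(enrichment, file.path(output_dir, "enrichment.tsv"),
            comments = c(adjust_method = "BH"))
  outputs <- c(outputs, "enrichment.tsv")

  # planted TFs stand in for the heavily published genes of the field
  evidence <- run_stage("evidence", generate_evidence_table(
    catalog, seed = derive_seed(sim$seed, 3L),
    top_genes = sim$planted_tfs))
  ranked <- run_stage("rank", rank_by_evidence(candidates, evidence, sel))
  write_tsv(ranked, file.path(output_dir, "ranked_candidates.tsv"),
            comments = c(top_k = sel$top_k,
                         evidence_min_articles = sel$evidence_min_articles))
  outputs <- c(outputs, "ranked_candidates.tsv")

  construct <- run_stage("design", assemble_promoter(
    config$design$registry, config$design$order, config$design$copies,
    config$design$spacer))
  files <- write_construct(construct,
                           file.path(output_dir, "mini_promoter"))
  outputs <- c(outputs, basename(files[["fasta"]]))
  sites <- scan_restriction_sites(construct$sequence,
                                  config$design$enzymes)
  if (nrow(sites)) {
    write_tsv(sites, file.path(output_dir, "restriction_hits.tsv"))
  }

  result <- list(cohort = cohort, normalized = normalized,
                 fold_changes = fold_changes, candidates = candidates,
                 enrichment = enrichment, ranked = ranked,
                 top_tfs = top_tfs(ranked), construct = construct)

  if (isTRUE(config$scoring$enabled)) {
    m <- run_stage("score", generate_reporter_measurements(
      config$scoring$true_index, config$scoring$noise_cv,
      seed = derive_seed(sim$seed, 4L)))
    score <- data.frame(expression_index = expression_index(m))
    write_tsv(score, file.path(output_dir, "reporter_score.tsv"))
    outputs <- c(outputs, "reporter_score.tsv")
    result$score <- score
  }

  manifest <- list(
    package = "promoterforge",
    version = as.character(utils::packageVersion("promoterforge")),
    seed = sim$seed,
    stages = outputs,
    config = list(simulation = unclass(sim), selection = unclass(sel),
                  design = list(order = config$design$order,
                                copies = config$design$copies,
                                spacer = config$design$spacer),
                  scoring = config$scoring)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(result)
}
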