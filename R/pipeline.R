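#' Default pipeline configuration
#'
#' One flat list of every tunable in the study replica, with defaults equal
#' to the published analysis settings: raw p threshold 0.1, fold-change
#' threshold 1.5, fill 0.1, S/N 10, 2/3 batch detection, m/z tolerance 0.01,
#' RT tolerance 0.75 min, 13 replicate simulations, enrichment significance
#' at 0.01/0.05. Unknown keys passed in `...` are rejected.
#'
#' @param ... overrides of the default keys.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic scale
    n_strains = 4L, replicates_per_condition = 3L, n_batches = 2L,
    qc_interval = 5L, n_features = 120L, missing_rate = 0.05,
    n_internal_mets = 5L, n_regulator_genes = 4L,
    n_pathways = 5L, n_compounds = 30L,
    # thresholds (study defaults)
    p_threshold = 0.1, fc_threshold = 1.5,
    fill_threshold = 0.1, sn_threshold = 10, detection_fraction = 2 / 3,
    mz_tol = 0.01, rt_tol = 0.75, loess_span = 0.75,
    n_replicates = 13L, jitter_fraction = 0.05, alpha = 0.1,
    enrich_sig = c(0.01, 0.05), n_permutations = 1000L, lambda = 0.01,
    # dynamic FBA
    dt = 0.1, horizon = 30, glucose0 = 20, biomass0 = 0.05,
    # stage toggles
    run_synthetic = TRUE, run_fba = TRUE, run_preprocess = TRUE,
    run_stats = TRUE, run_enrichment = TRUE, run_validation = TRUE
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' Round-trips through [pipeline_config()] so unknown keys are rejected and
#' missing keys take their defaults.
#'
#' @param path YAML file path.
#' @param config a `pipeline_config` (for writing).
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Run the full study replica
#'
#' Executes, under one seed: synthetic input generation (toy model pair,
#' peak tables, knowledge graph) -> strain ranking by dynamic FBA ->
#' metabolomics preprocessing -> differential statistics and O-PLS-DA ->
#' diffusion enrichment -> flux-sum model validation. Each stage logs its
#' input/output sizes; tables are written as CSV/TSV under `out_dir` together
#' with a JSON manifest. Rerunning with the same config reproduces identical
#' outputs (manifest timestamp aside).
#'
#' @param config a `pipeline_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("diauxflux")),
                   seed = config$seed, stages = list())
  res <- list()
  log_stage <- function(stage, ...) {
    msg <- sprintf("[%s] %s", stage, paste(..., collapse = " "))
    message(msg)
    cat(msg, "\n", file = file.path(out_dir, "pipeline.log"), append = TRUE)
  }
  need <- function(stage, dep, val) {
    if (is.null(val)) stop("stage '", stage, "' requires output of stage '",
                           dep, "' which did not run", call. = FALSE)
    val
  }

  if (config$run_synthetic) {
    pair <- make_toy_model_pair(config$n_internal_mets,
                                config$n_regulator_genes, seed = config$seed)
    design <- sim_design(n_strains = config$n_strains,
                         replicates_per_condition = config$replicates_per_condition,
                         n_batches = config$n_batches,
                         qc_interval = config$qc_interval,
                         n_features = config$n_features,
                         missing_rate = config$missing_rate,
                         seed = config$seed)
    sim <- simulate_peak_table(design)
    kg <- make_knowledge_graph(config$n_pathways, config$n_compounds,
                               seed = config$seed)
    res$synthetic <- list(pair = pair, design = design, sim = sim, kg = kg)
    write_sbml_model(pair$model, file.path(out_dir, "model.xml"))
    write_regulatory_rules(pair$rules_m1, file.path(out_dir, "rules_m1.tsv"))
    write_regulatory_rules(pair$rules_m1smart,
                           file.path(out_dir, "rules_m1smart.tsv"))
    write_peak_table(sim$table, out_dir, "raw")
    write_knowledge_graph(kg$graph, file.path(out_dir, "kg_edges.tsv"),
                          file.path(out_dir, "kg_nodes.tsv"))
    manifest$stages$synthetic <- list(
      features = nrow(sim$table$intensity),
      samples = ncol(sim$table$intensity),
      reactions = ncol(pair$model$S),
      graph_nodes = igraph::vcount(kg$graph))
    log_stage("synthetic", "generated", manifest$stages$synthetic$features,
              "features,", manifest$stages$synthetic$samples, "samples")
  }

  if (config$run_fba) {
    pair <- need("fba", "synthetic", res$synthetic$pair)
    genes <- pair$truth$regulator_genes
    rank <- rank_strains(pair$model, pair$rules_m1, pair$rules_m1smart, genes,
                         glucose0 = config$glucose0, biomass0 = config$biomass0,
                         dt = config$dt, horizon = config$horizon)
    traj <- run_dfba(pair$model, pair$rules_m1smart,
                     glucose0 = config$glucose0, biomass0 = config$biomass0,
                     dt = config$dt, horizon = config$horizon)
    res$fba <- list(rank = rank, trajectory = traj)
    utils::write.csv(rank, file.path(out_dir, "strain_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(traj), file.path(out_dir, "dfba_wt.csv"),
                     row.names = FALSE)
    manifest$stages$fba <- list(strains_ranked = nrow(rank),
                                shift_time = attr(traj, "shift_time"))
    log_stage("fba", "ranked", nrow(rank), "strains; WT shift at",
              round(attr(traj, "shift_time"), 2), "h")
  }

  if (config$run_preprocess) {
    sim <- need("preprocess", "synthetic", res$synthetic$sim)
    prep <- preprocess_peaks(sim$table,
                             fill_threshold = config$fill_threshold,
                             sn_threshold = config$sn_threshold,
                             detection_fraction = config$detection_fraction,
                             loess_span = config$loess_span,
                             mz_tol = config$mz_tol, rt_tol = config$rt_tol)
    res$preprocess <- prep
    write_peak_table(prep$table, out_dir, "normalized")
    manifest$stages$preprocess <- list(
      features_in = nrow(sim$table$intensity),
      features_out = nrow(prep$table$intensity))
    log_stage("preprocess", manifest$stages$preprocess$features_in, "->",
              manifest$stages$preprocess$features_out, "features")
  }

  if (config$run_stats) {
    tab <- need("stats", "preprocess", res$preprocess$table)
    diff_phase <- fit_linear_model(tab, "phase",
                                   covariates = c("strain", "batch"),
                                   moderate = TRUE)
    sig <- volcano_classify(diff_phase, config$p_threshold, config$fc_threshold)
    study <- which(tab$samples$class == "sample")
    X <- t(log2_intensities(tab$intensity[, study, drop = FALSE]))
    opls <- fit_opls_da(X, tab$samples$phase[study], n_orthogonal = 1)
    prof <- correlation_profiles(tab)
    strains <- setdiff(unique(tab$samples$strain[study]), "WT")
    diff_strain <- list()
    for (s in strains) for (ph in c("pre", "post")) {
      diff_strain[[paste(s, ph, sep = ".")]] <-
        fit_linear_model(tab, "strain", strain = s, phase = ph,
                         covariates = "batch")
    }
    res$stats <- list(diff_phase = diff_phase, significant = sig,
                      opls = opls, profiles = prof, diff_strain = diff_strain)
    utils::write.csv(as.data.frame(diff_phase),
                     file.path(out_dir, "diff_phase.csv"), row.names = FALSE)
    manifest$stages$stats <- list(features_tested = nrow(diff_phase),
                                  significant = length(sig))
    log_stage("stats", length(sig), "of", nrow(diff_phase),
              "features significant (p <", config$p_threshold,
              ", FC >", config$fc_threshold, ")")
  }

  if (config$run_enrichment) {
    kg <- need("enrichment", "synthetic", res$synthetic$kg)
    diff_phase <- need("enrichment", "stats", res$stats$diff_phase)
    tab <- res$preprocess$table
    # dictionary: identified significant features map onto the planted
    # pathway's compounds (round-robin), exercising the mapping contract
    sig_id <- tab$features$identification[
      match(volcano_classify(diff_phase, config$p_threshold, 1),
            tab$features$feature_id)]
    sig_id <- sig_id[!is.na(sig_id) & nzchar(sig_id)]
    cps <- kg$truth$input_compounds
    dict <- if (length(sig_id)) {
      stats::setNames(cps[1 + (seq_along(sig_id) - 1) %% length(cps)], sig_id)
    } else stats::setNames(character(0), character(0))
    mp <- map_features_to_compounds(diff_phase, tab$features, dict,
                                    config$p_threshold)
    enr <- if (length(mp$compounds)) {
      pscore(kg$graph, mp$compounds, config$n_permutations,
             seed = config$seed, lambda = config$lambda)
    } else NULL
    res$enrichment <- list(mapping = mp, result = enr)
    if (!is.null(enr)) {
      utils::write.csv(as.data.frame(enr), file.path(out_dir, "enrichment.csv"),
                       row.names = FALSE)
    }
    manifest$stages$enrichment <- list(
      compounds_mapped = length(mp$compounds),
      unmatched = length(mp$unmatched),
      pathways_sig_0.05 = if (is.null(enr)) 0L else
        sum(enr$sig_0.05[enr$type == "pathway"]))
    log_stage("enrichment", length(mp$compounds), "compounds mapped;",
              manifest$stages$enrichment$pathways_sig_0.05,
              "pathway(s) enriched at 0.05")
  }

  if (config$run_validation) {
    pair <- need("validation", "synthetic", res$synthetic$pair)
    diff_strain <- need("validation", "stats", res$stats$diff_strain)
    tab <- res$preprocess$table
    # link the first identified features to model metabolites
    mets <- intersect(c("PYR", "ETH", "ATP", "NADH"), pair$model$metabolites)
    fid <- tab$features$feature_id[nzchar(tab$features$identification)]
    mm <- data.frame(metabolite = mets,
                     feature_id = fid[seq_along(mets)])
    # strain names in the peak table (KO1..) stand for the deletion strains,
    # assigned in ranking order: the top-discrepancy strains are profiled
    genes <- if (!is.null(res$fba$rank)) res$fba$rank$gene else
      pair$truth$regulator_genes
    kos <- paste0("KO", seq_along(genes))
    dr <- list()
    for (i in seq_along(genes)) for (ph in c("pre", "post")) {
      key_in <- paste(kos[i], ph, sep = ".")
      if (!is.null(diff_strain[[key_in]])) {
        dr[[paste(genes[i], ph, sep = ".")]] <- diff_strain[[key_in]]
      }
    }
    genes <- genes[paste(genes, "pre", sep = ".") %in% names(dr)]
    reports <- end_to_end_validation(
      pair$model, list(M1 = pair$rules_m1, M1Smart = pair$rules_m1smart),
      genes, dr, mm, alpha = config$alpha,
      n_replicates = config$n_replicates,
      jitter_fraction = config$jitter_fraction, seed = config$seed)
    tabv <- validation_table(reports)
    res$validation <- list(reports = reports, table = tabv)
    utils::write.csv(tabv, file.path(out_dir, "validation.csv"),
                     row.names = FALSE)
    manifest$stages$validation <- list(
      metabolites = length(unique(tabv$metabolite)),
      mean_balanced_accuracy = round(mean(tabv$balanced_accuracy), 4))
    log_stage("validation", "mean balanced accuracy",
              manifest$stages$validation$mean_balanced_accuracy)
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
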