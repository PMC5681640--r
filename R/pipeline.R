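#' Run the full synthetic study pipeline end to end
#'
#' Simulates a study, reconstructs subpathways, scores activity, ranks
#' subpathways by resampled survival screening, runs the hypergeometric
#' enrichment baseline, and evaluates the selected signature by K-means
#' risk grouping, log-rank testing and permutation calibration. All inputs
#' and results are written as TSV under `out_dir`, together with a JSON
#' manifest echoing every parameter, the seeds, and per-stage row counts.
#'
#' @param config A [simulation_config()]; its seed drives all randomness.
#' @param out_dir Output directory (created if needed).
#' @param params A [reconstruction_params()].
#' @param plan A [resample_plan()]; defaults to the config seed.
#' @param top_rank Dense-rank cutoff for signature selection.
#' @param n_perm Permutations for the empirical p-value.
#' @return (Invisibly) a list with all in-memory results and the manifest.
#' @export
run_spagm_pipeline <- function(config = simulation_config(), out_dir,
                               params = reconstruction_params(),
                               plan = NULL, top_rank = 25L, n_perm = 1000L) {
  if (is.null(plan)) plan <- resample_plan(seed = config$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", simulate_spagm_study(config, params))
  stage("write-inputs", {
    write_pathways(sim$pathways, file.path(out_dir, "pathways.tsv"))
    write_interactions(sim$interactions,
                       file.path(out_dir, "interactions.tsv"))
    write_expression(sim$gene_expr, file.path(out_dir, "gene_expr.tsv"))
    write_expression(sim$mirna_expr, file.path(out_dir, "mirna_expr.tsv"))
    write_clinical(sim$survival, file.path(out_dir, "clinical.tsv"))
    writeLines(paste(names(sim$condition), sim$condition, sep = "\t"),
               file.path(out_dir, "condition.tsv"))
    writeLines(sim$truth$effect_ids,
               file.path(out_dir, "truth_effect_subpathways.txt"))
  })
  stage("reconstruct", write_subpathways(
    sim$subpathways,
    sif_path = file.path(out_dir, "subpathways.sif"),
    gmt_path = file.path(out_dir, "subpathways.gmt")
  ))
  profile <- stage("score",
                   spa_scores(sim$gene_expr, sim$mirna_expr,
                              sim$subpathways))
  stage("score-write",
        write_profile(profile, file.path(out_dir, "spa_profile.tsv")))
  ranking <- stage("signature",
                   rank_subpathways(profile, sim$survival, plan))
  signature <- select_signature(ranking, top_rank = top_rank)
  stage("signature-write", {
    sel <- ranking
    sel$selected <- sel$subpathway_id %in% signature
    utils::write.table(sel, file.path(out_dir, "ranking.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  enrichment <- stage("enrich", {
    prog <- screen_prognostic_features(sim$gene_expr, sim$mirna_expr,
                                       sim$survival, alpha = plan$alpha)
    enrich_subpathways(sim$subpathways, prog,
                       universe = c(rownames(sim$gene_expr),
                                    rownames(sim$mirna_expr)))
  })
  stage("enrich-write",
        utils::write.table(enrichment, file.path(out_dir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE))
  evaluation <- stage("evaluate", {
    sig_profile <- profile[signature, , drop = FALSE]
    sig_profile <- activity_profile(sig_profile, level = "integrated")
    grouping <- kmeans_risk_groups(sig_profile, seed = config$seed)
    lr <- logrank_compare(grouping, sim$survival)
    perm <- permutation_pvalue(sig_profile, sim$survival, n_perm = n_perm,
                               seed = config$seed)
    utils::write.table(
      data.frame(sample_id = names(grouping$group),
                 risk_group = as.character(grouping$group)),
      file.path(out_dir, "risk_groups.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE
    )
    utils::write.table(lr$km, file.path(out_dir, "km_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(grouping = grouping, logrank = lr, permutation = perm)
  })
  manifest <- list(
    package_version = as.character(utils::packageVersion("spagm")),
    config = unclass(config),
    reconstruction_params = unclass(params),
    resample_plan = unclass(plan),
    top_rank = top_rank, n_perm = n_perm,
    counts = list(
      pathways = length(sim$pathways),
      interactions = nrow(sim$interactions),
      subpathways = length(sim$subpathways),
      samples = ncol(sim$gene_expr),
      scored_subpathways = sum(!apply(is.na(unclass(profile)), 1L, all)),
      signature_size = length(signature),
      enriched_significant = sum(enrichment$significant)
    ),
    results = list(
      logrank_p = evaluation$logrank$p_value,
      permutation_p = evaluation$permutation$p_empirical
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(sim = sim, profile = profile, ranking = ranking,
                 signature = signature, enrichment = enrichment,
                 evaluation = evaluation, manifest = manifest))
}
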