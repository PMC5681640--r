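# Heavy shared experiments, computed once per test run and reused by
# several acceptance checks (recovery and variant-comparison blocks both
# consume the same 20-seed resampling study).

.experiment_cache <- new.env(parent = emptyenv())

# For each seed: simulate the reference configuration, score the integrated,
# gene-only and miRNA-only profiles, and run the 200-replicate stratified
# screening for all three variants on identical splits. Returns, per seed,
# the count table (subpathways x variants) and the effect ids.
recovery_experiment <- function(seeds = 1:20, n_reps = 200L) {
  key <- paste0("recovery_", paste(range(seeds), collapse = "_"), "_", n_reps)
  if (!is.null(.experiment_cache[[key]])) return(.experiment_cache[[key]])
  res <- lapply(seeds, function(s) {
    sim <- simulate_spagm_study(simulation_config(seed = s))
    gn <- normalize_profile(score_matrix(sim$gene_expr, sim$subpathways,
                                         "gene"))
    mn <- normalize_profile(score_matrix(sim$mirna_expr, sim$subpathways,
                                         "mirna"))
    profiles <- list(integrated = unclass(gn) - unclass(mn),
                     gene_only = unclass(gn),
                     mirna_only = -unclass(mn))
    sv <- sim$survival
    plan <- resample_plan(n_reps = n_reps, seed = s)
    big <- do.call(rbind, profiles)[, sv$sample_id, drop = FALSE]
    n_spw <- nrow(gn)
    counts <- matrix(0L, n_spw, length(profiles),
                     dimnames = list(rownames(gn), names(profiles)))
    for (b in seq_len(n_reps)) {
      sp <- stratified_split(sv, plan, b)
      idx <- match(sp$train, sv$sample_id)
      p <- spagm:::cox_screen_pvalues(big[, idx, drop = FALSE],
                                      sv$time[idx], sv$event[idx])
      sig <- !is.na(p) & p < plan$alpha
      counts <- counts + matrix(sig, n_spw, length(profiles))
    }
    list(counts = counts, effect_ids = sim$truth$effect_ids)
  })
  .experiment_cache[[key]] <- res
  res
}
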