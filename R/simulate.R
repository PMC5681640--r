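#' Configuration of the synthetic study generator
#'
#' Defines a complete synthetic study: random pathway graphs, a verified
#' miRNA-target table, matched gene/miRNA expression matrices, condition
#' labels, and survival times whose hazard depends on injected subpathway
#' activity. Defaults describe the reference configuration used throughout
#' the package's own validation: roughly fifty reconstructed subpathways of
#' which five carry a survival effect, 300 tumour samples, coordinated
#' 1.5-SD member-gene up-shifts and member-miRNA down-shifts per unit of
#' latent activity, and a log-hazard slope of 1 on the mean latent
#' activity.
#'
#' @param n_pathways Number of pathway graphs.
#' @param genes_per_pathway Genes per pathway graph.
#' @param edge_density Probability of each extra gene-gene edge beyond the
#'   spanning-tree backbone that guarantees connectivity.
#' @param n_mirnas Number of miRNAs in the interaction table.
#' @param targets_per_mirna Verified targets sampled per miRNA.
#' @param n_samples Number of profiled samples.
#' @param n_effect_subpathways Number of subpathways given a latent activity
#'   that shifts expression and drives the hazard.
#' @param gene_shift,mirna_shift Log2-expression shift (in SD units of the
#'   baseline noise) per unit latent activity; genes move up, miRNAs down.
#' @param survival_beta Log-hazard slope on the mean latent activity.
#' @param censoring_rate Expected fraction of censored samples, in `[0, 1)`.
#' @param noise_sd SD of the baseline log2-expression noise.
#' @param background_genes,background_mirnas Measured features outside every
#'   pathway, padding the ranked feature space.
#' @param condition_frac Fraction of samples labelled `"normal"` (default 0:
#'   an all-tumour survival cohort).
#' @param condition_shift Mean latent-activity offset of tumour over normal
#'   samples (latent activity is re-standardized afterwards).
#' @param seed Master seed; all generator randomness derives from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_pathways = 50L, genes_per_pathway = 8L,
                              edge_density = 0.35, n_mirnas = 250L,
                              targets_per_mirna = 2L, n_samples = 300L,
                              n_effect_subpathways = 5L, gene_shift = 1.5,
                              mirna_shift = 1.5, survival_beta = 1.0,
                              censoring_rate = 0.3, noise_sd = 1.0,
                              background_genes = 8000L,
                              background_mirnas = 2000L,
                              condition_frac = 0, condition_shift = 0,
                              seed = 1L) {
  assert_scalar_count(n_pathways, "n_pathways")
  assert_scalar_count(genes_per_pathway, "genes_per_pathway", min = 2L)
  assert_scalar_count(n_mirnas, "n_mirnas")
  assert_scalar_count(targets_per_mirna, "targets_per_mirna")
  assert_scalar_count(n_samples, "n_samples", min = 2L)
  assert_scalar_count(n_effect_subpathways, "n_effect_subpathways", min = 0L)
  stopifnot(edge_density >= 0, edge_density <= 1,
            censoring_rate >= 0, censoring_rate < 1, noise_sd > 0,
            condition_frac >= 0, condition_frac < 1)
  structure(
    list(n_pathways = as.integer(n_pathways),
         genes_per_pathway = as.integer(genes_per_pathway),
         edge_density = edge_density, n_mirnas = as.integer(n_mirnas),
         targets_per_mirna = as.integer(targets_per_mirna),
         n_samples = as.integer(n_samples),
         n_effect_subpathways = as.integer(n_effect_subpathways),
         gene_shift = gene_shift, mirna_shift = mirna_shift,
         survival_beta = survival_beta, censoring_rate = censoring_rate,
         noise_sd = noise_sd,
         background_genes = as.integer(background_genes),
         background_mirnas = as.integer(background_mirnas),
         condition_frac = condition_frac, condition_shift = condition_shift,
         seed = as.integer(seed)),
    class = "simulation_config"
  )
}

#' Generate random connected pathway graphs
#'
#' Each pathway is a simple undirected graph on its own gene ids: a random
#' spanning tree guarantees connectivity, and every remaining node pair is
#' added independently with probability `edge_density`.
#'
#' @param config A [simulation_config()].
#' @return List of [pathway_graph()] objects, deterministic per seed.
#' @export
generate_pathways <- function(config) {
  with_local_seed(derive_seed(config$seed, 1L), {
    lapply(seq_len(config$n_pathways), function(p) {
      ng <- config$genes_per_pathway
      genes <- sprintf("p%02dg%03d", p, seq_len(ng))
      # random spanning tree: attach each node to a random earlier node
      tree <- cbind(genes[vapply(2:ng, function(i) sample.int(i - 1L, 1L),
                                 integer(1L))],
                    genes[2:ng])
      pairs <- utils::combn(ng, 2L)
      in_tree <- paste(pmin(tree[, 1L], tree[, 2L]),
                       pmax(tree[, 1L], tree[, 2L]))
      cand <- cbind(genes[pairs[1L, ]], genes[pairs[2L, ]])
      cand_key <- paste(pmin(cand[, 1L], cand[, 2L]),
                        pmax(cand[, 1L], cand[, 2L]))
      extra <- cand[!(cand_key %in% in_tree) &
                      stats::runif(ncol(pairs)) < config$edge_density, ,
                    drop = FALSE]
      pathway_graph(sprintf("path%02d", p), rbind(tree, extra),
                    nodes = genes,
                    name = sprintf("synthetic pathway %d", p))
    })
  })
}

#' Generate a verified miRNA-target interaction table
#'
#' Each miRNA is assigned to one pathway (miRNAs tend to regulate genes of
#' a common functional module) and receives `targets_per_mirna` distinct
#' target genes sampled from that pathway; every record is flagged as
#' low-throughput evidence.
#'
#' @param pathways List of [pathway_graph()] objects.
#' @param config A [simulation_config()].
#' @return A [mirna_target_table()].
#' @export
generate_interactions <- function(pathways, config) {
  sizes <- vapply(pathways, function(p) length(p$gene_nodes), integer(1L))
  if (config$targets_per_mirna > min(sizes)) {
    stop("'targets_per_mirna' exceeds the smallest pathway's gene count")
  }
  with_local_seed(derive_seed(config$seed, 2L), {
    recs <- lapply(seq_len(config$n_mirnas), function(i) {
      pw <- pathways[[sample.int(length(pathways), 1L)]]
      data.frame(mirna_id = sprintf("mir%03d", i),
                 gene_id = sample(pw$gene_nodes, config$targets_per_mirna),
                 stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, recs)
    mirna_target_table(tab$mirna_id, tab$gene_id, low_throughput = TRUE)
  })
}

#' Generate matched expression, condition labels and survival times
#'
#' Baseline log2 expression is Gaussian per feature. A single standardized
#' latent activity program per sample is shared by the effect subpathways:
#' it shifts their member genes up by `gene_shift` and their member miRNAs
#' down by `mirna_shift` per unit activity (in log2 space), the coordinated
#' regulation pattern the integrated score is designed to detect. Survival
#' is exponential with log-hazard `survival_beta` times the mean latent
#' activity over effect subpathways (the shared program itself), with
#' independent censoring at `censoring_rate`; times are in days (baseline
#' median 1,200, about 40 months), matching the day-scale early-death
#' exclusion applied by the clinical reader.
#'
#' @param subpathways List of [subpathway_graph()] objects.
#' @param config A [simulation_config()].
#' @param effect_ids Optional explicit effect subpathway ids; defaults to a
#'   seeded sample of `n_effect_subpathways` ids.
#' @param gene_universe,mirna_universe Optional measured feature ids; they
#'   default to the subpathway members plus the configured background
#'   features.
#' @return List: `gene_expr`, `mirna_expr`, `condition`, `survival`,
#'   `truth` (effect ids, latent matrix, beta, condition labels).
#' @export
generate_expression_and_survival <- function(subpathways, config,
                                             effect_ids = NULL,
                                             gene_universe = NULL,
                                             mirna_universe = NULL) {
  ids <- vapply(subpathways, `[[`, character(1L), "subpathway_id")
  k <- config$n_effect_subpathways
  if (is.null(effect_ids)) {
    if (k > length(ids)) {
      stop(sprintf("requested %d effect subpathways but only %d were reconstructed",
                   k, length(ids)))
    }
    # spread effects across parent pathways so injected units are as
    # independent as the topology allows
    parents <- vapply(subpathways, `[[`, character(1L), "parent_pathway_id")
    effect_ids <- with_local_seed(derive_seed(config$seed, 3L), {
      solo <- ids[parents %in% names(which(table(parents) == 1L))]
      pool <- if (length(solo) >= k) solo else ids[!duplicated(parents)]
      if (length(pool) >= k) sort(sample(pool, k)) else sort(sample(ids, k))
    })
  }
  stopifnot(all(effect_ids %in% ids))
  genes <- sort(unique(c(
    unlist(lapply(subpathways, `[[`, "gene_nodes")),
    gene_universe,
    if (config$background_genes > 0)
      sprintf("bgg%03d", seq_len(config$background_genes))
  )))
  mirnas <- sort(unique(c(
    unlist(lapply(subpathways, `[[`, "mirna_nodes")),
    mirna_universe,
    if (config$background_mirnas > 0)
      sprintf("bgm%03d", seq_len(config$background_mirnas))
  )))
  ns <- config$n_samples
  samples <- sprintf("s%03d", seq_len(ns))
  n_normal <- round(config$condition_frac * ns)
  condition <- stats::setNames(
    rep(c("tumor", "normal"), c(ns - n_normal, n_normal)), samples
  )
  with_local_seed(derive_seed(config$seed, 4L), {
    # one latent activity program per sample, shared by the effect
    # subpathways (a coordinated prognostic axis), standardized after any
    # tumour-vs-normal offset
    z <- stats::rnorm(ns)
    if (config$condition_shift != 0) {
      z <- z + config$condition_shift * (condition == "tumor")
    }
    z <- as.numeric(scale(z))
    names(z) <- samples
    log_g <- matrix(stats::rnorm(length(genes), 6, 1.5), length(genes), ns) +
      matrix(stats::rnorm(length(genes) * ns, 0, config$noise_sd),
             length(genes), ns)
    dimnames(log_g) <- list(genes, samples)
    log_m <- matrix(stats::rnorm(length(mirnas), 6, 1.5), length(mirnas), ns) +
      matrix(stats::rnorm(length(mirnas) * ns, 0, config$noise_sd),
             length(mirnas), ns)
    dimnames(log_m) <- list(mirnas, samples)
    for (e in seq_along(effect_ids)) {
      s <- subpathways[[match(effect_ids[e], ids)]]
      gm <- intersect(s$gene_nodes, genes)
      mm <- intersect(s$mirna_nodes, mirnas)
      if (length(gm) > 0L) {
        log_g[gm, ] <- log_g[gm, ] +
          config$gene_shift * matrix(z, length(gm), ns, byrow = TRUE)
      }
      if (length(mm) > 0L) {
        log_m[mm, ] <- log_m[mm, ] -
          config$mirna_shift * matrix(z, length(mm), ns, byrow = TRUE)
      }
    }
    # mean latent activity over effect subpathways; with a shared program
    # this is the program itself (zero when no effect is injected)
    lp <- if (length(effect_ids) > 0L) config$survival_beta * z else rep(0, ns)
    event_time <- stats::rexp(ns, rate = exp(lp) * log(2) / 1200)
    censored <- stats::rbinom(ns, 1L, config$censoring_rate) == 1L
    time <- ifelse(censored, event_time * stats::runif(ns), event_time)
    surv <- data.frame(
      sample_id = samples, time = time, event = as.integer(!censored),
      age_group = sample(c("young", "old"), ns, replace = TRUE),
      sex = sample(c("female", "male"), ns, replace = TRUE),
      stringsAsFactors = FALSE
    )
    truth <- list(effect_ids = effect_ids, latent = z,
                  beta = config$survival_beta, condition = condition)
    list(gene_expr = 2^log_g, mirna_expr = 2^log_m, condition = condition,
         survival = surv, truth = truth)
  })
}

#' Simulate a complete synthetic subpathway study
#'
#' Chains the generators with the reconstruction module: random pathways,
#' a verified interaction table, reconstructed subpathways, and matched
#' expression/condition/survival data with known effect subpathways.
#'
#' @param config A [simulation_config()].
#' @param params A [reconstruction_params()] used for reconstruction.
#' @return List: `pathways`, `interactions`, `subpathways`, `gene_expr`,
#'   `mirna_expr`, `condition`, `survival`, `truth`, `config`.
#' @export
simulate_spagm_study <- function(config = simulation_config(),
                                 params = reconstruction_params()) {
  pathways <- generate_pathways(config)
  interactions <- generate_interactions(pathways, config)
  subpathways <- reconstruct_subpathways(pathways, interactions, params)
  dat <- generate_expression_and_survival(subpathways, config)
  c(list(pathways = pathways, interactions = interactions,
         subpathways = subpathways, config = config), dat)
}
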