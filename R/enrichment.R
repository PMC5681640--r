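#' Upper-tail hypergeometric enrichment p-value
#'
#' Probability of observing at least `r` prognostic features inside a
#' subpathway of `t_sub` features, when `n` prognostic features are drawn
#' from a universe of `m` genes and miRNAs: `P(X >= r)` with
#' `X ~ Hypergeometric(m, t_sub, n)`.
#'
#' @param m Universe size (genes plus miRNAs).
#' @param t_sub Number of universe features in the subpathway.
#' @param n Number of prognostic features in the universe.
#' @param r Number of prognostic features inside the subpathway.
#' @return A probability in `[0, 1]`.
#' @examples
#' hypergeom_enrichment_p(m = 10, t_sub = 5, n = 4, r = 4)  # 5/210
#' @export
hypergeom_enrichment_p <- function(m, t_sub, n, r) {
  for (v in list(m = m, t_sub = t_sub, n = n, r = r)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 ||
        v != floor(v)) {
      stop("all counts must be single non-negative integers")
    }
  }
  if (t_sub > m || n > m || r > min(t_sub, n) || r < max(0, n - (m - t_sub))) {
    stop("infeasible counts: require t_sub <= m, n <= m, ",
         "max(0, n - (m - t_sub)) <= r <= min(t_sub, n)")
  }
  if (r == 0) return(1)
  stats::phyper(r - 1, t_sub, m - t_sub, n, lower.tail = FALSE)
}

#' Screen individual features for survival association
#'
#' Per-feature univariate proportional-hazards screen at level `alpha`;
#' features whose fit fails (constant expression, no events) are excluded.
#'
#' @param gene_expr,mirna_expr Expression matrices (either may be `NULL`).
#' @param survival Survival table covering the expression samples.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of prognostic feature ids.
#' @export
screen_prognostic_features <- function(gene_expr, mirna_expr, survival,
                                       alpha = 0.05) {
  assert_survival_table(survival)
  mats <- Filter(Negate(is.null), list(gene_expr, mirna_expr))
  if (length(mats) == 0L) stop("at least one expression matrix is required")
  hits <- character()
  for (mat in mats) {
    assert_expression_matrix(mat)
    if (!all(survival$sample_id %in% colnames(mat))) {
      stop("every survival sample must be present in the expression matrix")
    }
    x <- mat[, survival$sample_id, drop = FALSE]
    p <- cox_screen_pvalues(x, survival$time, survival$event)
    hits <- c(hits, rownames(x)[!is.na(p) & p < alpha])
  }
  unique(hits)
}

#' Hypergeometric enrichment of prognostic features over subpathways
#'
#' Genes and miRNAs are pooled into one urn. The universe defaults to the
#' supplied measured features; `universe_size` can override the urn size `m`
#' (e.g. to use whole-genome and miRNAome catalogue sizes) while overlaps
#' are still computed against `universe`. P-values are Benjamini-Hochberg
#' adjusted across all tested subpathways.
#'
#' @param subpathways List of [subpathway_graph()] objects.
#' @param prognostic_features Character vector of prognostic feature ids.
#' @param universe Character vector of all measured feature ids (genes and
#'   miRNAs).
#' @param universe_size Optional override of the urn size `m`.
#' @param alpha Adjusted-p significance level (default 0.05).
#' @return Data frame (`subpathway_id`, `r`, `t_sub`, `p_value`, `bh_p`,
#'   `significant`); subpathways with no universe overlap are skipped with
#'   a message.
#' @export
enrich_subpathways <- function(subpathways, prognostic_features, universe,
                               universe_size = NULL, alpha = 0.05) {
  universe <- unique(as.character(universe))
  prognostic <- intersect(unique(as.character(prognostic_features)), universe)
  m <- as.integer(universe_size %||% length(universe))
  n <- length(prognostic)
  if (n > m) stop("more prognostic features than the universe size")
  ids <- character(); rr <- integer(); tt <- integer(); pp <- numeric()
  for (s in subpathways) {
    feats <- intersect(c(s$gene_nodes, s$mirna_nodes), universe)
    t_sub <- length(feats)
    if (t_sub == 0L) {
      message(sprintf("subpathway %s has no overlap with the universe; skipped",
                      s$subpathway_id))
      next
    }
    r <- length(intersect(feats, prognostic))
    ids <- c(ids, s$subpathway_id)
    rr <- c(rr, r)
    tt <- c(tt, t_sub)
    pp <- c(pp, hypergeom_enrichment_p(m, t_sub, n, r))
  }
  bh <- stats::p.adjust(pp, method = "BH")
  data.frame(subpathway_id = ids, r = rr, t_sub = tt, p_value = pp,
             bh_p = bh, significant = bh < alpha, stringsAsFactors = FALSE)
}
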