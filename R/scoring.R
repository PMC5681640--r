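#' Exponential rank weights for one sample
#'
#' Features are ordered by ascending expression within the sample; each
#' feature with rank `r` out of `|N|` measured features receives the weight
#' `w = r * exp(r / |N|)`, so highly expressed features dominate. Ties take
#' the average rank, which keeps the weighting deterministic and invariant
#' to input order.
#'
#' @param values Non-negative numeric vector of one sample's expression,
#'   named by feature id.
#' @return List with `rank` (average ranks in `[1, |N|]`) and `weight`.
#' @examples
#' rank_weights(c(a = 5, b = 1, c = 3))
#' @export
rank_weights <- function(values) {
  n <- length(values)
  if (n == 0L) stop("empty feature space")
  r <- rank(values, ties.method = "average")
  w <- r * exp(r / n)
  list(rank = r, weight = w)
}

#' Subpathway activity component score for one sample
#'
#' The mean rank weight over member features minus the mean over the
#' complement (all other measured features). Positive scores mean the
#' members sit higher in the sample's expression ranking than the rest of
#' the measured feature space.
#'
#' @param weights A list as returned by [rank_weights()] (or a named numeric
#'   weight vector).
#' @param members Character vector of member feature ids.
#' @return A single score, or `NA` when no member is measured.
#' @export
spa_component_score <- function(weights, members) {
  w <- if (is.list(weights)) weights$weight else weights
  if (is.null(names(w))) stop("weights must be named by feature id")
  inside <- names(w) %in% members
  if (!any(inside)) return(NA_real_)
  if (all(inside)) {
    stop("member set covers every measured feature; complement is empty")
  }
  mean(w[inside]) - mean(w[!inside])
}

#' Activity profile container
#'
#' A subpathways x samples score matrix tagged with its level
#' (`gene_raw`, `mirna_raw`, `gene_norm`, `mirna_norm`, `integrated`,
#' `gene_only`, `mirna_only`) and the ids of constant rows zeroed during
#' normalization.
#'
#' @param scores Numeric matrix (subpathways x samples) with dimnames.
#' @param level Level tag.
#' @param constant_rows Ids of rows flagged constant.
#' @return An object of class `activity_profile`.
#' @export
activity_profile <- function(scores, level, constant_rows = character()) {
  stopifnot(is.matrix(scores))
  structure(scores, level = level, constant_rows = constant_rows,
            class = c("activity_profile", "matrix", "array"))
}

#' @export
print.activity_profile <- function(x, ...) {
  cat(sprintf("<activity_profile> level=%s: %d subpathways x %d samples (%d unscored rows)\n",
              attr(x, "level"), nrow(x), ncol(x),
              sum(apply(is.na(unclass(x)), 1L, all))))
  invisible(x)
}

profile_level <- function(x) attr(x, "level")

#' Raw component score matrix for a set of subpathways
#'
#' Applies [rank_weights()] and [spa_component_score()] per sample and
#' subpathway, at either the gene or the miRNA level. Member sets are
#' intersected with the measured features; a subpathway is scorable at the
#' gene level only when at least `min_cover` (default 3) member genes are
#' measured, and at the miRNA level when at least 1 member miRNA is
#' measured — mirroring the construction-time size filter. Unscorable
#' subpathways get rows of `NA`.
#'
#' @param expr Numeric feature x sample matrix (genes or miRNAs).
#' @param subpathways List of [subpathway_graph()] objects.
#' @param level `"gene"` or `"mirna"`; selects which member set is scored.
#' @param min_cover Minimum measured members required; defaults to 3 for
#'   genes and 1 for miRNAs.
#' @return An `activity_profile` with level `gene_raw` or `mirna_raw`.
#' @export
score_matrix <- function(expr, subpathways, level = c("gene", "mirna"),
                         min_cover = NULL) {
  level <- match.arg(level)
  assert_expression_matrix(expr)
  if (is.null(min_cover)) min_cover <- if (level == "gene") 3L else 1L
  n <- nrow(expr)
  rk <- apply(expr, 2L, rank, ties.method = "average")
  if (n == 1L) rk <- matrix(rk, nrow = 1L, dimnames = dimnames(expr))
  w <- rk * exp(rk / n)
  tot <- colSums(w)
  ids <- unname(vapply(subpathways, `[[`, character(1L), "subpathway_id"))
  scores <- matrix(NA_real_, nrow = length(subpathways), ncol = ncol(expr),
                   dimnames = list(ids, colnames(expr)))
  member_field <- if (level == "gene") "gene_nodes" else "mirna_nodes"
  for (i in seq_along(subpathways)) {
    memb <- intersect(subpathways[[i]][[member_field]], rownames(expr))
    m <- length(memb)
    if (m < min_cover) next
    if (m == n) {
      stop(sprintf("subpathway %s covers every measured feature; complement is empty",
                   ids[i]))
    }
    inside <- colSums(w[memb, , drop = FALSE])
    scores[i, ] <- inside / m - (tot - inside) / (n - m)
  }
  activity_profile(scores, level = paste0(level, "_raw"))
}

#' Z-normalize an activity profile across samples
#'
#' Each subpathway row is centred on its mean over samples and divided by
#' its standard deviation (denominator `n - 1` by default). Constant rows
#' map to all zeros and are recorded in the `constant_rows` attribute; rows
#' of `NA` (unscorable subpathways) propagate unchanged.
#'
#' @param profile A raw `activity_profile`.
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return A normalized `activity_profile` (`gene_norm` / `mirna_norm`).
#' @export
normalize_profile <- function(profile, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  x <- unclass(profile)
  attributes(x)[setdiff(names(attributes(x)), c("dim", "dimnames"))] <- NULL
  if (ncol(x) < 2L) stop("normalization requires >= 2 samples")
  mu <- rowMeans(x)
  cent <- x - mu
  ss <- rowSums(cent^2)
  denom <- sqrt(ss / (ncol(x) - (sd_type == "sample")))
  const <- is.finite(denom) & denom <= 1e-12 * (abs(mu) + 1)
  z <- cent / denom
  z[const, ] <- 0
  lvl <- sub("_raw$", "_norm", attr(profile, "level") %||% "raw")
  activity_profile(z, level = lvl,
                   constant_rows = rownames(x)[which(const)])
}

#' Integrate gene- and miRNA-level normalized profiles
#'
#' The integrated activity is the normalized gene score minus the normalized
#' miRNA score, reflecting the repressive role of miRNAs: high member-miRNA
#' expression lowers the inferred subpathway activity. Cells missing at
#' either level are missing in the result.
#'
#' @param gene_norm,mirna_norm Normalized `activity_profile`s with identical
#'   subpathway and sample orderings.
#' @return An `activity_profile` with level `integrated`.
#' @export
integrate_profiles <- function(gene_norm, mirna_norm) {
  if (!identical(dim(gene_norm), dim(mirna_norm)) ||
      !identical(dimnames(gene_norm), dimnames(mirna_norm))) {
    stop("gene and miRNA profiles must share subpathway and sample orderings")
  }
  out <- unclass(gene_norm) - unclass(mirna_norm)
  activity_profile(out, level = "integrated")
}

#' Compute subpathway activity scores
#'
#' End-to-end scoring: per-sample rank weighting, member-vs-complement
#' contrast at the gene and miRNA levels, z-normalization across samples,
#' and (for the integrated level) the gene-minus-miRNA combination. The
#' `gene_only` variant is the normalized gene score; the `mirna_only`
#' variant is the negated normalized miRNA score, so that for every variant
#' a larger score means larger inferred activity under miRNA repression.
#'
#' @param gene_expr Gene expression matrix (genes x samples).
#' @param mirna_expr miRNA expression matrix (miRNAs x samples); may be
#'   `NULL` for the `gene_only` variant.
#' @param subpathways List of [subpathway_graph()] objects.
#' @param level `"integrated"` (default), `"gene_only"` or `"mirna_only"`.
#' @param sd_type Standard-deviation convention for normalization.
#' @return An `activity_profile` (subpathways x samples).
#' @examples
#' sim <- simulate_spagm_study(simulation_config(n_pathways = 2,
#'   genes_per_pathway = 12, n_mirnas = 10, n_samples = 10,
#'   n_effect_subpathways = 1, seed = 7))
#' spa <- spa_scores(sim$gene_expr, sim$mirna_expr, sim$subpathways)
#' spa[1:3, 1:4]
#' @export
spa_scores <- function(gene_expr, mirna_expr, subpathways,
                       level = c("integrated", "gene_only", "mirna_only"),
                       sd_type = c("sample", "population")) {
  level <- match.arg(level)
  sd_type <- match.arg(sd_type)
  if (level != "mirna_only" && level != "gene_only") {
    check_matched_samples(gene_expr, mirna_expr)
  }
  if (level == "gene_only") {
    g <- normalize_profile(score_matrix(gene_expr, subpathways, "gene"),
                           sd_type)
    return(activity_profile(unclass(g), level = "gene_only",
                            constant_rows = attr(g, "constant_rows")))
  }
  if (level == "mirna_only") {
    m <- normalize_profile(score_matrix(mirna_expr, subpathways, "mirna"),
                           sd_type)
    return(activity_profile(-unclass(m), level = "mirna_only",
                            constant_rows = attr(m, "constant_rows")))
  }
  g <- normalize_profile(score_matrix(gene_expr, subpathways, "gene"),
                         sd_type)
  m <- normalize_profile(score_matrix(mirna_expr, subpathways, "mirna"),
                         sd_type)
  integrate_profiles(g, m)
}

check_matched_samples <- function(gene_expr, mirna_expr) {
  if (is.null(mirna_expr)) {
    stop("miRNA expression is required for this scoring level")
  }
  if (!identical(colnames(gene_expr), colnames(mirna_expr))) {
    stop("gene and miRNA matrices must share identical sample ids in matched order")
  }
  invisible(TRUE)
}
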