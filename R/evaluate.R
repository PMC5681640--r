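#' K-means risk grouping on a signature activity profile
#'
#' Samples are clustered (K = 2, Euclidean distance, multiple restarts)
#' using their signature subpathway activity vectors. The cluster with the
#' lower mean signature activity is labelled `"high"` risk, reflecting that
#' low subpathway activity marks the poor-prognosis group; the labelling is
#' therefore invariant to cluster index permutation.
#'
#' @param profile An `activity_profile` restricted to the signature
#'   subpathways (subpathways x samples). Missing cells are imputed to the
#'   subpathway row mean (reported via a message).
#' @param seed Seed for the k-means restarts.
#' @param nstart Number of random restarts (default 10; best inertia kept).
#' @return List of class `risk_grouping`: `group` (named factor
#'   `"low"`/`"high"`), `cluster_means`, `seed`.
#' @export
kmeans_risk_groups <- function(profile, seed = 1L, nstart = 10L) {
  x <- unclass(profile)
  keep <- !apply(is.na(x), 1L, all)
  x <- x[keep, , drop = FALSE]
  if (nrow(x) == 0L) stop("profile has no scorable subpathways")
  if (ncol(x) < 4L) stop("risk grouping requires >= 4 samples")
  n_miss <- sum(is.na(x))
  if (n_miss > 0L) {
    message(sprintf("imputing %d missing cells to subpathway row means", n_miss))
    mu <- rowMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- mu[idx[, 1L]]
  }
  pts <- t(x)
  if (nrow(unique(pts)) < 2L) {
    stop("all samples have identical signature activity; cannot form two groups")
  }
  km <- with_local_seed(seed,
                        stats::kmeans(pts, centers = 2L, nstart = nstart))
  means <- tapply(rowMeans(pts), km$cluster, mean)
  high_cluster <- as.integer(names(means)[which.min(means)])
  lab <- ifelse(km$cluster == high_cluster, "high", "low")
  structure(
    list(group = stats::setNames(factor(lab, levels = c("low", "high")),
                                 rownames(pts)),
         cluster_means = means, seed = seed),
    class = "risk_grouping"
  )
}

#' @export
print.risk_grouping <- function(x, ...) {
  cat(sprintf("<risk_grouping> %d high / %d low risk samples\n",
              sum(x$group == "high"), sum(x$group == "low")))
  invisible(x)
}

#' Log-rank comparison of risk groups
#'
#' Standard two-group log-rank test, with Kaplan-Meier survival estimates
#' per group (serializable for plotting) and the mean observed survival
#' time per group.
#'
#' @param groups A [kmeans_risk_groups()] result, or a named
#'   `"high"`/`"low"` vector per sample.
#' @param survival Survival table covering the grouped samples.
#' @return List of class `logrank_result`: `chi_square`, `p_value`, `km`
#'   (data frame `group`, `time`, `surv`, `n_risk`, `n_event`),
#'   `mean_survival` and `n_events` per group.
#' @export
logrank_compare <- function(groups, survival) {
  assert_survival_table(survival)
  g <- if (inherits(groups, "risk_grouping")) groups$group else groups
  if (is.null(names(g))) stop("'groups' must be named by sample id")
  g <- factor(as.character(g[survival$sample_id]), levels = c("low", "high"))
  if (anyNA(g)) stop("every survival sample must have a risk group")
  if (nlevels(droplevels(g)) < 2L) stop("log-rank comparison requires two groups")
  y <- survival::Surv(survival$time, survival$event)
  sd <- survival::survdiff(y ~ g)
  chisq <- unname(sd$chisq)
  fit <- survival::survfit(y ~ g)
  sm <- summary(fit)
  km <- data.frame(
    group = sub("^g=", "", as.character(sm$strata)),
    time = sm$time, surv = sm$surv, n_risk = sm$n.risk,
    n_event = sm$n.event, stringsAsFactors = FALSE
  )
  structure(
    list(chi_square = chisq,
         p_value = stats::pchisq(chisq, df = 1L, lower.tail = FALSE),
         km = km,
         mean_survival = tapply(survival$time, g, mean),
         n_events = tapply(survival$event, g, sum)),
    class = "logrank_result"
  )
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chi-square %.3f, p = %.3g\n",
              x$chi_square, x$p_value))
  invisible(x)
}

#' Permutation calibration of the grouping/log-rank p-value
#'
#' Permutes the (time, event) pairs jointly across samples `n_perm` times,
#' keeping the activity profile (and hence the K-means grouping) fixed, and
#' recomputes the log-rank p-value each time. The empirical p is the
#' fraction of permuted p-values strictly below the observed one, so a
#' strong association yields exactly 0.
#'
#' @param profile Signature `activity_profile`.
#' @param survival Survival table.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Seed for grouping restarts and permutations.
#' @return List: `p_empirical`, `observed_p`, `n_perm`.
#' @export
permutation_pvalue <- function(profile, survival, n_perm = 1000L, seed = 1L) {
  assert_survival_table(survival)
  grouping <- kmeans_risk_groups(profile, seed = seed)
  obs <- logrank_compare(grouping, survival)$p_value
  g <- factor(as.character(grouping$group[survival$sample_id]),
              levels = c("low", "high"))
  n <- nrow(survival)
  perm_p <- with_local_seed(derive_seed(seed, 97L), {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      y <- survival::Surv(survival$time[idx], survival$event[idx])
      sd <- survival::survdiff(y ~ g)
      stats::pchisq(unname(sd$chisq), df = 1L, lower.tail = FALSE)
    }, numeric(1L))
  })
  list(p_empirical = mean(perm_p < obs), observed_p = obs, n_perm = n_perm)
}

#' Tumor-versus-normal contrast of subpathway activities
#'
#' Two-sided Wilcoxon rank-sum test per subpathway between the two
#' conditions, with a three-state call at the 0.05 level: `tumor-high`,
#' `normal-high`, or `ns`. Direction is the sign of the tumor-minus-normal
#' median activity difference.
#'
#' @param profile An `activity_profile` (subpathways x samples).
#' @param condition Per-sample labels `"tumor"`/`"normal"`, named by sample
#'   id or aligned with the profile columns.
#' @return Data frame (`subpathway_id`, `direction`, `p_value`, `call`);
#'   subpathways with fewer than 2 scored samples in either condition are
#'   skipped.
#' @export
condition_contrast <- function(profile, condition) {
  x <- unclass(profile)
  if (!is.null(names(condition))) condition <- condition[colnames(x)]
  if (length(condition) != ncol(x)) {
    stop("'condition' must cover every profile sample")
  }
  condition <- factor(as.character(condition), levels = c("normal", "tumor"))
  if (any(table(condition) == 0L)) {
    stop("both conditions must be represented")
  }
  ids <- character(); dirs <- integer(); ps <- numeric()
  for (i in seq_len(nrow(x))) {
    xt <- x[i, condition == "tumor"]
    xn <- x[i, condition == "normal"]
    xt <- xt[!is.na(xt)]; xn <- xn[!is.na(xn)]
    if (length(xt) < 2L || length(xn) < 2L) next
    wt <- suppressWarnings(stats::wilcox.test(xt, xn,
                                              alternative = "two.sided"))
    ids <- c(ids, rownames(x)[i])
    dirs <- c(dirs, sign(stats::median(xt) - stats::median(xn)))
    ps <- c(ps, wt$p.value)
  }
  call <- ifelse(ps >= 0.05, "ns",
                 ifelse(dirs > 0, "tumor-high", "normal-high"))
  data.frame(subpathway_id = ids, direction = dirs, p_value = ps,
             call = call, stringsAsFactors = FALSE)
}
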