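#' Resampling plan for robust signature screening
#'
#' @param n_reps Number of resampling iterations (default 1000).
#' @param train_fraction Fraction of samples drawn (without replacement)
#'   into each training subset (default 0.8).
#' @param alpha Per-subpathway screening significance level (default 0.05).
#' @param seed Base seed; each replicate derives its own stream from
#'   (`seed`, replicate index).
#' @return A list of class `resample_plan`.
#' @export
resample_plan <- function(n_reps = 1000L, train_fraction = 0.8,
                          alpha = 0.05, seed = 1L) {
  assert_scalar_count(n_reps, "n_reps")
  if (!is.numeric(train_fraction) || train_fraction <= 0 ||
      train_fraction >= 1) {
    stop("'train_fraction' must be in (0, 1)")
  }
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("'alpha' must be in (0, 1)")
  }
  structure(
    list(n_reps = as.integer(n_reps), train_fraction = train_fraction,
         alpha = alpha, seed = as.integer(seed)),
    class = "resample_plan"
  )
}

#' Survival-stratified train/test split
#'
#' Samples are dichotomized at the cohort median observed survival time into
#' poor (time at or below the median) and good (above) strata; the training
#' fraction is drawn without replacement independently within each stratum
#' so the good/poor ratio of the cohort is preserved. Per-stratum sizes take
#' the floor of the fraction; any remainder needed to reach the overall
#' training size goes to the larger stratum. Reproducible from
#' (`plan$seed`, `rep_index`).
#'
#' @param survival Survival table (`sample_id`, `time`, `event`).
#' @param plan A [resample_plan()].
#' @param rep_index Replicate index (1-based).
#' @return List with `train` and `test` sample-id vectors.
#' @export
stratified_split <- function(survival, plan, rep_index = 1L) {
  assert_survival_table(survival)
  n <- nrow(survival)
  if (n < 10L) stop("stratified splitting requires >= 10 samples")
  med <- stats::median(survival$time)
  poor <- survival$sample_id[survival$time <= med]
  good <- survival$sample_id[survival$time > med]
  if (length(poor) < 2L || length(good) < 2L) {
    stop("a survival stratum has fewer than 2 samples")
  }
  target <- round(plan$train_fraction * n)
  n_poor <- floor(plan$train_fraction * length(poor))
  n_good <- floor(plan$train_fraction * length(good))
  extra <- target - n_poor - n_good
  if (extra > 0L) {
    if (length(poor) >= length(good)) {
      n_poor <- min(n_poor + extra, length(poor))
    } else {
      n_good <- min(n_good + extra, length(good))
    }
  }
  train <- with_local_seed(derive_seed(plan$seed, rep_index), {
    c(sample(poor, n_poor), sample(good, n_good))
  })
  list(train = sort(train), test = sort(setdiff(survival$sample_id, train)))
}

#' Univariate proportional-hazards screen of one score vector
#'
#' Fits a Cox proportional-hazards model of survival on a single continuous
#' score and reports the per-unit hazard ratio with its Wald p-value.
#' Constant scores, fewer than two events, or fit failures yield a missing
#' result (treated downstream as non-significant).
#'
#' @param scores Numeric vector named by sample id (or aligned with
#'   `survival` rows).
#' @param survival Survival table (`sample_id`, `time`, `event`).
#' @return List with `hazard_ratio`, `log_hr`, `se`, `p_value`, `n`,
#'   `n_events`; the first four are `NA` on failure.
#' @export
cox_univariate <- function(scores, survival) {
  assert_survival_table(survival)
  if (!is.null(names(scores))) {
    scores <- scores[survival$sample_id]
  } else if (length(scores) != nrow(survival)) {
    stop("'scores' must be named by sample id or aligned with 'survival'")
  }
  n_events <- sum(survival$event)
  miss <- list(hazard_ratio = NA_real_, log_hr = NA_real_, se = NA_real_,
               p_value = NA_real_, n = nrow(survival), n_events = n_events)
  if (anyNA(scores) || n_events < 2L ||
      length(unique(scores)) < 2L) {
    return(miss)
  }
  fit <- tryCatch(
    survival::coxph(survival::Surv(survival$time, survival$event) ~ scores),
    error = function(e) NULL, warning = function(w) {
      tryCatch(suppressWarnings(
        survival::coxph(survival::Surv(survival$time, survival$event) ~ scores)
      ), error = function(e) NULL)
    }
  )
  if (is.null(fit) || anyNA(stats::coef(fit))) return(miss)
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(fit$var))[1L]
  list(hazard_ratio = exp(beta), log_hr = beta, se = se,
       p_value = 2 * stats::pnorm(-abs(beta / se)),
       n = nrow(survival), n_events = n_events)
}

# Fast per-row Wald p-values from univariate Cox fits, used inside the
# resampling loop; equivalent to cox_univariate() row by row but skips the
# formula machinery.
cox_screen_pvalues <- function(score_mat, time, event) {
  p <- rep(NA_real_, nrow(score_mat))
  if (sum(event) < 2L) return(p)
  y <- survival::Surv(time, event)
  ctrl <- survival::coxph.control()
  for (i in seq_len(nrow(score_mat))) {
    x <- score_mat[i, ]
    if (anyNA(x) || length(unique(x)) < 2L) next
    fit <- tryCatch(
      suppressWarnings(
        survival::coxph.fit(matrix(x, ncol = 1L), y, strata = NULL,
                            offset = NULL, init = NULL, control = ctrl,
                            weights = NULL, method = "efron",
                            rownames = NULL)
      ),
      error = function(e) NULL
    )
    if (is.null(fit) || anyNA(fit$coefficients) || anyNA(fit$var)) next
    z <- fit$coefficients[1L] / sqrt(fit$var[1L])
    if (is.finite(z)) p[i] <- 2 * stats::pnorm(-abs(z))
  }
  p
}

#' Rank subpathways by resampled survival-association counts
#'
#' For each of `plan$n_reps` stratified training subsets, every subpathway's
#' activity is screened with a univariate proportional-hazards model; the
#' significance count is the number of replicates with Wald p below
#' `plan$alpha`. Failed fits count as non-significant, keeping the
#' denominator at `n_reps`. Subpathways are dense-ranked by count (ties
#' share a rank).
#'
#' @param profile An `activity_profile` (subpathways x samples).
#' @param survival Survival table covering the profiled samples.
#' @param plan A [resample_plan()].
#' @return Data frame (`subpathway_id`, `count`, `dense_rank`) ordered by
#'   decreasing count, ties by id.
#' @export
rank_subpathways <- function(profile, survival, plan = resample_plan()) {
  assert_survival_table(survival)
  x <- unclass(profile)
  if (!all(survival$sample_id %in% colnames(x))) {
    stop("every survival sample must be present in the profile")
  }
  x <- x[, survival$sample_id, drop = FALSE]
  counts <- integer(nrow(x))
  for (b in seq_len(plan$n_reps)) {
    sp <- stratified_split(survival, plan, b)
    idx <- match(sp$train, survival$sample_id)
    p <- cox_screen_pvalues(x[, idx, drop = FALSE],
                            survival$time[idx], survival$event[idx])
    counts <- counts + (!is.na(p) & p < plan$alpha)
  }
  out <- data.frame(subpathway_id = rownames(x), count = counts,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$subpathway_id), , drop = FALSE]
  out$dense_rank <- match(out$count, sort(unique(out$count),
                                          decreasing = TRUE))
  rownames(out) <- NULL
  out
}

#' Select the signature from a significance-count ranking
#'
#' By default returns every subpathway whose dense rank is at most
#' `top_rank`; ties in counts mean the selection may exceed `top_rank`
#' subpathways. Alternatively, `min_count` selects subpathways whose count
#' strictly exceeds a threshold.
#'
#' @param ranking Data frame from [rank_subpathways()].
#' @param top_rank Dense-rank cutoff (default 25); ignored when `min_count`
#'   is given.
#' @param min_count Optional strict count threshold (select `count > min_count`).
#' @return Character vector of selected subpathway ids.
#' @export
select_signature <- function(ranking, top_rank = 25L, min_count = NULL) {
  if (nrow(ranking) == 0L) stop("'ranking' is empty")
  if (!is.null(min_count)) {
    return(ranking$subpathway_id[ranking$count > min_count])
  }
  if (top_rank > max(ranking$dense_rank)) {
    message("top_rank exceeds the number of distinct counts; returning all subpathways")
    return(ranking$subpathway_id)
  }
  ranking$subpathway_id[ranking$dense_rank <= top_rank]
}

#' Multivariate proportional-hazards model of risk group and covariates
#'
#' Joint Cox fit of survival on the risk-group indicator plus clinical
#' covariates, reporting per-factor hazard ratios with 95% confidence
#' intervals and Wald p-values. Covariate columns with a single observed
#' level are dropped with a warning; a singular (collinear) design is an
#' error naming the offending terms.
#'
#' @param risk_group Factor/character of `"high"`/`"low"` per sample, named
#'   by sample id or aligned with `survival`.
#' @param survival Survival table whose extra columns are treated as
#'   categorical covariates.
#' @param covariates Optional character vector naming which extra columns
#'   to adjust for (default: all extra columns).
#' @return Data frame (`term`, `hazard_ratio`, `ci_lower`, `ci_upper`,
#'   `p_value`).
#' @export
cox_multivariate <- function(risk_group, survival, covariates = NULL) {
  assert_survival_table(survival)
  if (!is.null(names(risk_group))) risk_group <- risk_group[survival$sample_id]
  if (length(risk_group) != nrow(survival)) {
    stop("'risk_group' must cover every survival sample")
  }
  covariates <- covariates %||%
    setdiff(names(survival), c("sample_id", "time", "event"))
  df <- data.frame(risk = factor(as.character(risk_group),
                                 levels = c("low", "high")))
  for (cv in covariates) {
    col <- factor(survival[[cv]])
    if (nlevels(droplevels(col)) < 2L) {
      warning(sprintf("covariate '%s' has a single observed level; dropped", cv))
      next
    }
    df[[cv]] <- col
  }
  fit <- survival::coxph(
    survival::Surv(survival$time, survival$event) ~ ., data = df
  )
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("singular design; collinear factors: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  }
  se <- sqrt(diag(fit$var))
  data.frame(
    term = names(cf),
    hazard_ratio = exp(unname(cf)),
    ci_lower = exp(unname(cf) - 1.96 * se),
    ci_upper = exp(unname(cf) + 1.96 * se),
    p_value = 2 * stats::pnorm(-abs(unname(cf) / se)),
    stringsAsFactors = FALSE
  )
}
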