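test_that("stratified splitting preserves the good/poor ratio exactly", {
  surv <- data.frame(sample_id = sprintf("s%02d", 1:10),
                     time = c(1:5, 101:105), event = 1L,
                     stringsAsFactors = FALSE)
  plan <- resample_plan(n_reps = 5, train_fraction = 0.8, seed = 3)
  sp <- stratified_split(surv, plan, 1)
  expect_length(sp$train, 8L)
  expect_length(sp$test, 2L)
  poor <- surv$sample_id[surv$time <= median(surv$time)]
  expect_equal(sum(sp$train %in% poor), 4L)
  expect_equal(sum(sp$test %in% poor), 1L)
  expect_setequal(c(sp$train, sp$test), surv$sample_id)
  # determinism from (seed, rep_index)
  expect_identical(sp, stratified_split(surv, plan, 1))
  expect_false(identical(sp, stratified_split(surv, plan, 2)))
})

test_that("each sample lands in about train_fraction of training subsets", {
  set.seed(10)
  surv <- sim_survival(rnorm(50))
  plan <- resample_plan(n_reps = 200, train_fraction = 0.8, seed = 8)
  hits <- setNames(integer(50), surv$sample_id)
  for (b in 1:200) {
    tr <- stratified_split(surv, plan, b)$train
    hits[tr] <- hits[tr] + 1L
  }
  # binomial(200, 0.8) spread: essentially all mass within +/- 0.12
  expect_true(all(abs(hits / 200 - 0.8) < 0.12))
})

test_that("univariate hazards screening recovers an injected log-hazard", {
  set.seed(4)
  err <- replicate(10, {
    x <- rnorm(300)
    surv <- sim_survival(x, beta = 0.8, censor = 0.2)
    cox_univariate(setNames(x, surv$sample_id), surv)$log_hr - 0.8
  })
  expect_lt(abs(mean(err)), 0.2)
})

test_that("degenerate inputs give a missing (non-significant) result", {
  set.seed(5)
  surv <- sim_survival(rnorm(40))
  expect_true(is.na(cox_univariate(rep(1, 40), surv)$p_value))
  surv0 <- surv
  surv0$event <- 0L
  expect_true(is.na(cox_univariate(rnorm(40), surv0)$p_value))
})

test_that("the fast screening path agrees with the formula interface", {
  set.seed(6)
  x <- matrix(rnorm(5 * 100), 5, 100,
              dimnames = list(paste0("sp", 1:5), sprintf("s%03d", 1:100)))
  surv <- sim_survival(x[1, ], beta = 0.7)
  fast <- spagm:::cox_screen_pvalues(x, surv$time, surv$event)
  slow <- apply(x, 1, function(v) {
    cox_univariate(setNames(v, surv$sample_id), surv)$p_value
  })
  expect_equal(fast, unname(slow), tolerance = 1e-8)
})

test_that("significance counts behave and respect bounds", {
  set.seed(12)
  n <- 60
  scores <- rbind(
    eff = rnorm(n),
    null = rnorm(n),
    const = rep(1, n)
  )
  colnames(scores) <- sprintf("s%03d", 1:n)
  surv <- sim_survival(scores["eff", ], beta = 1.5, censor = 0.2)
  prof <- activity_profile(scores, "integrated")
  plan <- resample_plan(n_reps = 30, seed = 2)
  rk <- rank_subpathways(prof, surv, plan)
  expect_true(all(rk$count <= 30))
  expect_equal(rk$count[rk$subpathway_id == "const"], 0L)
  expect_equal(rk$subpathway_id[1], "eff")
  # determinism from (seed, plan)
  expect_identical(rk, rank_subpathways(prof, surv, plan))
  # monotonicity: larger alpha never lowers any count
  rk_lo <- rank_subpathways(prof, surv, resample_plan(n_reps = 30, seed = 2,
                                                      alpha = 0.01))
  m <- merge(rk, rk_lo, by = "subpathway_id")
  expect_true(all(m$count.x >= m$count.y))
})

test_that("signature selection uses dense ranks with tie semantics", {
  rk <- data.frame(subpathway_id = c("a", "b", "c", "d"),
                   count = c(900L, 900L, 850L, 400L),
                   stringsAsFactors = FALSE)
  rk$dense_rank <- match(rk$count, sort(unique(rk$count), decreasing = TRUE))
  expect_setequal(select_signature(rk, top_rank = 2), c("a", "b", "c"))
  rk2 <- data.frame(subpathway_id = letters[1:4],
                    count = c(600L, 501L, 500L, 499L),
                    dense_rank = 1:4, stringsAsFactors = FALSE)
  expect_setequal(select_signature(rk2, min_count = 500), c("a", "b"))
  rk3 <- data.frame(subpathway_id = letters[1:3], count = c(9L, 5L, 1L),
                    dense_rank = 1:3, stringsAsFactors = FALSE)
  expect_equal(select_signature(rk3, top_rank = 1), "a")
  expect_message(all_ids <- select_signature(rk3, top_rank = 10),
                 "returning all")
  expect_length(all_ids, 3L)
})

test_that("multivariate hazards adjust for covariates and catch collinearity", {
  set.seed(20)
  n <- 200
  x <- rnorm(n)
  surv <- sim_survival(x, beta = 0.8, censor = 0.2)
  surv$age_group <- sample(c("young", "old"), n, replace = TRUE)
  surv$sex <- sample(c("female", "male"), n, replace = TRUE)
  grp <- setNames(ifelse(x > 0, "high", "low"), surv$sample_id)
  adj <- cox_multivariate(grp, surv)
  unadj <- cox_multivariate(grp, surv, covariates = character())
  hr_a <- adj$hazard_ratio[adj$term == "riskhigh"]
  hr_u <- unadj$hazard_ratio[unadj$term == "riskhigh"]
  expect_equal(log(hr_a), log(hr_u), tolerance = 0.25)
  expect_true(all(c("ci_lower", "ci_upper", "p_value") %in% names(adj)))
  # risk group duplicated as a covariate -> singular design
  surv_bad <- surv
  surv_bad$dup <- unname(grp)
  expect_error(cox_multivariate(grp, surv_bad, covariates = "dup"),
               "collinear")
  # single-level covariate dropped with a warning
  surv_one <- surv
  surv_one$site <- "one"
  expect_warning(cox_multivariate(grp, surv_one, covariates = "site"),
                 "single observed level")
})
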