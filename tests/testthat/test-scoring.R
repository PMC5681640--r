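test_that("rank weights follow w = r * exp(r/|N|) with average-rank ties", {
  w <- rank_weights(c(a = 5, b = 1, c = 3))
  expect_equal(w$rank, c(a = 3, b = 1, c = 2))
  expect_equal(w$weight,
               c(a = 3 * exp(1), b = exp(1 / 3), c = 2 * exp(2 / 3)),
               tolerance = 1e-12)
  # frozen values from independent scalar evaluation of r * exp(r/3)
  expect_equal(unname(w$weight), c(8.1548455, 1.3956124, 3.8954681),
               tolerance = 1e-6)

  expect_equal(rank_weights(c(x = 7))$weight, c(x = exp(1)))
  tie <- rank_weights(c(a = 2, b = 2))
  expect_equal(unname(tie$weight), rep(1.5 * exp(0.75), 2))
  expect_error(rank_weights(numeric()), "empty feature space")
})

test_that("component score is the member-vs-complement weight contrast", {
  w <- rank_weights(c(a = 5, b = 1, c = 3))
  # 8.1548455 - (1.3956124 + 3.8954681) / 2, evaluated independently
  expect_equal(spa_component_score(w, "a"), 5.5093052, tolerance = 1e-6)
  # independent oracle agrees
  expect_equal(spa_component_score(w, "a"),
               oracle_spa_cell(c(a = 5, b = 1, c = 3), "a"))
  # equal expression of both features: tie rule forces zero
  w2 <- rank_weights(c(a = 4, b = 4))
  expect_equal(spa_component_score(w2, "a"), 0)
  # bottom-ranked member scores negative
  expect_lt(spa_component_score(w, "b"), 0)
  expect_true(is.na(spa_component_score(w, "zzz")))
  expect_error(spa_component_score(w, c("a", "b", "c")), "complement")
})

test_that("matrix scoring equals the per-cell brute-force oracle", {
  set.seed(3)
  for (i in 1:20) {
    expr <- random_expr(sample(6:20, 1), sample(2:5, 1))
    members <- lapply(1:3, function(j) {
      sample(rownames(expr), sample(3:(nrow(expr) - 1), 1))
    })
    spws <- Map(make_spw, paste0("sp", 1:3), members)
    got <- score_matrix(expr, spws, "gene")
    expect_equal(mat0(got),
                 oracle_spa_matrix(expr, setNames(members, paste0("sp", 1:3))),
                 tolerance = 1e-12)
  }
})

test_that("scores are invariant to feature order and monotone transforms", {
  set.seed(9)
  expr <- random_expr(15, 4)
  spws <- list(make_spw("sp1", rownames(expr)[1:5]))
  base <- score_matrix(expr, spws, "gene")
  perm <- expr[sample(nrow(expr)), ]
  expect_equal(mat0(score_matrix(perm, spws, "gene")), mat0(base))
  # strictly increasing transform of one sample's values
  expr2 <- expr
  expr2[, 2] <- expr2[, 2]^1.7 + 3
  expect_equal(mat0(score_matrix(expr2, spws, "gene")), mat0(base))
})

test_that("coverage rules yield NA rows for poorly measured subpathways", {
  expr <- random_expr(10, 3)
  spws <- list(make_spw("ok", rownames(expr)[1:4]),
               make_spw("thin", c(rownames(expr)[1:2], "missing1")))
  got <- score_matrix(expr, spws, "gene")
  expect_false(anyNA(got["ok", ]))
  expect_true(all(is.na(got["thin", ])))  # only 2 measured members < 3
  # miRNA level needs just one measured member
  mspws <- list(make_spw("m", "g", mirnas = c(rownames(expr)[1], "gone")))
  expect_false(anyNA(score_matrix(expr, mspws, "mirna")["m", ]))
})

test_that("normalization gives zero-mean unit-SD rows and flags constants", {
  p <- activity_profile(rbind(a = c(1, 2, 3), b = c(4, 4, 4)),
                        level = "gene_raw")
  z <- normalize_profile(p)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_equal(unname(z["b", ]), c(0, 0, 0))
  expect_equal(attr(z, "constant_rows"), "b")
  expect_equal(attr(z, "level"), "gene_norm")

  set.seed(1)
  big <- activity_profile(matrix(rnorm(200), 20, 10,
                                 dimnames = list(paste0("r", 1:20),
                                                 paste0("s", 1:10))),
                          level = "gene_raw")
  zz <- unclass(normalize_profile(big))
  expect_true(all(abs(rowMeans(zz)) < 1e-10))
  expect_true(all(abs(apply(zz, 1, sd) - 1) < 1e-10))

  expect_error(normalize_profile(activity_profile(matrix(1, 1, 1,
    dimnames = list("a", "s1")), "gene_raw")), ">= 2 samples")
})

test_that("integration is elementwise gene minus miRNA with strict alignment", {
  dn <- list(c("sp1", "sp2"), c("s1", "s2"))
  g <- activity_profile(matrix(c(1.5, 0, 0, 0), 2, 2, dimnames = dn),
                        "gene_norm")
  m <- activity_profile(matrix(c(-0.5, 1, -1, 2), 2, 2, dimnames = dn),
                        "mirna_norm")
  out <- integrate_profiles(g, m)
  expect_equal(out["sp1", "s1"], 2.0)
  # constant (all-zero) gene row reduces to the negated miRNA row
  expect_equal(unname(out["sp2", ]), -unname(unclass(m)["sp2", ]))
  bad <- activity_profile(matrix(0, 2, 2,
    dimnames = list(c("sp2", "sp1"), c("s1", "s2"))), "mirna_norm")
  expect_error(integrate_profiles(g, bad), "ordering")
})

test_that("scoring variants decompose the integrated score", {
  set.seed(21)
  ge <- random_expr(30, 8, "g")
  me <- random_expr(12, 8, "m")
  spws <- list(make_spw("sp1", rownames(ge)[1:5], rownames(me)[1:3]),
               make_spw("sp2", rownames(ge)[6:11], rownames(me)[4:5]))
  int <- spa_scores(ge, me, spws, "integrated")
  gonly <- spa_scores(ge, me, spws, "gene_only")
  monly <- spa_scores(ge, me, spws, "mirna_only")
  expect_equal(mat0(int), mat0(gonly) + mat0(monly))
  mn <- normalize_profile(score_matrix(me, spws, "mirna"))
  expect_equal(mat0(monly), -mat0(mn))
  # with constant miRNA rows the integrated score collapses to gene-only
  me_const <- me
  me_const[] <- 1
  int2 <- spa_scores(ge, me_const, spws, "integrated")
  expect_equal(mat0(int2), mat0(spa_scores(ge, me_const, spws,
                                                 "gene_only")))
})

test_that("raising a member miRNA never increases the integrated score", {
  set.seed(33)
  ge <- random_expr(25, 6, "g")
  me <- random_expr(10, 6, "m")
  spws <- list(make_spw("sp1", rownames(ge)[1:6], rownames(me)[1:3]))
  base <- spa_scores(ge, me, spws, "integrated")
  for (rep in 1:10) {
    me2 <- me
    j <- sample(ncol(me), 1)
    f <- rownames(me)[sample(3, 1)]
    me2[f, j] <- me2[f, j] * runif(1, 1.5, 10)
    pert <- spa_scores(ge, me2, spws, "integrated")
    expect_lte(pert["sp1", j], base["sp1", j] + 1e-9)
  }
})

test_that("two-group shifts separate mean integrated activity as designed", {
  set.seed(55)
  ge <- random_expr(40, 20, "g")
  me <- random_expr(20, 20, "m")
  grpA <- 1:10
  memb_g <- rownames(ge)[1:6]
  memb_m <- rownames(me)[1:4]
  ge[memb_g, grpA] <- ge[memb_g, grpA] * 8
  me[memb_m, grpA] <- me[memb_m, grpA] / 8
  spa <- spa_scores(ge, me, list(make_spw("sp1", memb_g, memb_m)))
  expect_gt(mean(spa[1, grpA]), mean(spa[1, -grpA]))
})

test_that("permuting sample columns permutes score columns identically", {
  set.seed(77)
  ge <- random_expr(20, 6, "g")
  me <- random_expr(10, 6, "m")
  spws <- list(make_spw("sp1", rownames(ge)[1:4], rownames(me)[1:2]))
  base <- spa_scores(ge, me, spws)
  perm <- sample(ncol(ge))
  shuffled <- spa_scores(ge[, perm], me[, perm], spws)
  expect_equal(mat0(shuffled), mat0(base)[, perm, drop = FALSE])
})
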