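test_that("k-clique extraction matches hand-enumerated sets on a path graph", {
  pw <- path_graph5()
  expect_equal(extract_k_clique_subpathways(pw, 3),
               list(c("v1", "v2", "v3", "v4"), c("v2", "v3", "v4", "v5")))
  expect_equal(extract_k_clique_subpathways(pw, 2),
               list(c("v1", "v2", "v3"), c("v2", "v3", "v4"),
                    c("v3", "v4", "v5")))
})

test_that("a complete graph yields a single k-clique at any k", {
  nodes <- c("a", "b", "c", "d")
  pw <- pathway_graph("cg", t(utils::combn(nodes, 2)))
  for (k in 1:3) {
    expect_equal(extract_k_clique_subpathways(pw, k), list(nodes))
  }
})

test_that("extraction equals the brute-force distance-clique oracle", {
  set.seed(42)
  for (i in 1:30) {
    g <- random_graph(n = sample(4:12, 1), p = runif(1, 0.15, 0.6))
    for (k in 2:4) {
      expect_identical(extract_k_clique_subpathways(g$pathway, k),
                       oracle_k_cliques(g$adj, k),
                       info = sprintf("graph %d, k=%d", i, k))
    }
  }
})

test_that("every k-clique is contained in some (k+1)-clique", {
  set.seed(7)
  for (i in 1:10) {
    g <- random_graph(n = sample(6:12, 1), p = runif(1, 0.2, 0.5))
    for (k in 1:3) {
      lo <- extract_k_clique_subpathways(g$pathway, k)
      hi <- extract_k_clique_subpathways(g$pathway, k + 1)
      for (s in lo) {
        expect_true(any(vapply(hi, function(h) all(s %in% h), logical(1))))
      }
    }
  }
})

test_that("components are handled independently and empty graphs are empty", {
  pw <- pathway_graph("two", cbind(c("a", "c"), c("b", "d")))
  expect_equal(extract_k_clique_subpathways(pw, 3),
               list(c("a", "b"), c("c", "d")))
  expect_equal(extract_k_clique_subpathways(pathway_graph("e"), 3), list())
})

test_that("miRNA embedding honours the in-set target threshold t", {
  tab <- mirna_target_table(c("m1", "m1", "m2"), c("g1", "g2", "g4"))
  gs <- c("g1", "g2", "g3")
  e1 <- embed_mirnas(gs, tab, t = 1)
  expect_equal(e1$mirna_nodes, "m1")
  expect_equal(e1$mirna_edges$gene_id, c("g1", "g2"))
  e2 <- embed_mirnas(gs, tab, t = 2)
  expect_equal(e2$mirna_nodes, "m1")
  e3 <- embed_mirnas(gs, tab, t = 3)
  expect_equal(e3$mirna_nodes, character())
  expect_equal(nrow(e3$mirna_edges), 0L)
  expect_equal(embed_mirnas(gs, NULL, 1)$mirna_nodes, character())
})

test_that("embedded miRNA sets shrink as t grows", {
  set.seed(11)
  tab <- mirna_target_table(sample(paste0("m", 1:8), 40, replace = TRUE),
                            sample(paste0("g", 1:10), 40, replace = TRUE))
  gs <- paste0("g", 1:6)
  prev <- embed_mirnas(gs, tab, 1)$mirna_nodes
  for (t in 2:4) {
    cur <- embed_mirnas(gs, tab, t)$mirna_nodes
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("low-throughput filtering restricts embeddable interactions", {
  tab <- mirna_target_table(c("m1", "m2"), c("g1", "g2"),
                            low_throughput = c(TRUE, FALSE))
  gs <- c("g1", "g2", "g3")
  expect_equal(embed_mirnas(gs, tab, 1)$mirna_nodes, "m1")
  expect_equal(embed_mirnas(gs, tab, 1, low_throughput_only = FALSE)$mirna_nodes,
               c("m1", "m2"))
})

test_that("size filtering removes small candidates and is idempotent", {
  cands <- list(
    make_spw(NA, paste0("g", 1:5)),                      # 0 miRNAs
    make_spw(NA, paste0("g", 1:3), "m1"),                # boundary: kept
    make_spw(NA, paste0("g", 1:2), c("m1", "m2"))        # 2 genes
  )
  kept <- filter_subpathways(cands, reconstruction_params())
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$gene_nodes, paste0("g", 1:3))
  expect_equal(kept[[1]]$subpathway_id, "pw_1")
  expect_identical(filter_subpathways(kept, reconstruction_params()), kept)
})

test_that("full reconstruction composes extraction, embedding and filtering", {
  pw <- path_graph5()
  empty_tab <- mirna_target_table(character(), character())
  expect_length(reconstruct_subpathways(list(pw), empty_tab), 0L)

  tab <- mirna_target_table("m1", "v2")
  spws <- reconstruct_subpathways(list(pw), tab)
  expect_length(spws, 2L)
  expect_equal(vapply(spws, `[[`, "", "subpathway_id"), c("pw_1", "pw_2"))
  expect_true(all(vapply(spws, function(s) identical(s$mirna_nodes, "m1"),
                         logical(1))))
  # gene edges are induced from the parent
  expect_equal(spws[[1]]$gene_edges[, 1], c("v1", "v2", "v3"))
})

test_that("duplicate pathways give identical node sets with distinct ids", {
  pw1 <- path_graph5()
  pw2 <- pw1
  pw2$pathway_id <- "pw2"
  tab <- mirna_target_table("m1", "v2")
  spws <- reconstruct_subpathways(list(pw1, pw2), tab)
  expect_length(spws, 4L)
  expect_equal(lapply(spws[1:2], `[[`, "gene_nodes"),
               lapply(spws[3:4], `[[`, "gene_nodes"))
  expect_equal(length(unique(vapply(spws, `[[`, "", "subpathway_id"))), 4L)
})

test_that("reconstruction is deterministic down to serialized output", {
  sim_cfg <- simulation_config(n_pathways = 3, n_mirnas = 20, seed = 5)
  pws <- generate_pathways(sim_cfg)
  tab <- generate_interactions(pws, sim_cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_subpathways(reconstruct_subpathways(pws, tab), gmt_path = f1)
  write_subpathways(reconstruct_subpathways(pws, tab), gmt_path = f2)
  expect_identical(readLines(f1), readLines(f2))
})
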