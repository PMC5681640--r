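#' Reconstruction parameters
#'
#' Controls how subpathways are carved out of pathway graphs and how miRNAs
#' are embedded. The defaults (`k = 3`, `t = 1`) keep subpathways local
#' enough to be interpretable while still admitting miRNA integration;
#' raising `k` merges neighbourhoods, raising `t` demands more in-set
#' targets per embedded miRNA.
#'
#' @param k Distance bound: members of one subpathway are pairwise within
#'   shortest-path distance `k` in the parent pathway graph.
#' @param t Minimum number of member genes a miRNA must target (with the
#'   selected evidence class) to be embedded.
#' @param min_genes Minimum gene count a subpathway must retain (default 3).
#' @param min_mirnas Minimum embedded miRNA count (default 1).
#' @param low_throughput_only If `TRUE` (default) only interactions backed by
#'   low-throughput experiments are used for embedding.
#' @return A list of class `reconstruction_params`.
#' @export
reconstruction_params <- function(k = 3L, t = 1L, min_genes = 3L,
                                  min_mirnas = 1L,
                                  low_throughput_only = TRUE) {
  structure(
    list(k = assert_scalar_count(k, "k"),
         t = assert_scalar_count(t, "t"),
         min_genes = assert_scalar_count(min_genes, "min_genes"),
         min_mirnas = assert_scalar_count(min_mirnas, "min_mirnas", min = 0L),
         low_throughput_only = isTRUE(low_throughput_only)),
    class = "reconstruction_params"
  )
}

#' Extract k-clique subpathways from a pathway graph
#'
#' A k-clique is a maximal set of gene nodes whose pairwise shortest-path
#' distances in the pathway graph are all at most `k`; equivalently, a
#' maximal clique of the k-th graph power. Connected components are handled
#' independently (cross-component distances are infinite). Singleton sets
#' are dropped, and no returned set is a subset of another.
#'
#' @param graph A [pathway_graph()].
#' @param k Positive integer distance bound.
#' @return List of sorted character vectors of gene ids, ordered
#'   lexicographically by their sorted members.
#' @examples
#' pw <- pathway_graph("p", cbind(c("v1", "v2", "v3", "v4"),
#'                                c("v2", "v3", "v4", "v5")))
#' extract_k_clique_subpathways(pw, k = 3)
#' @export
extract_k_clique_subpathways <- function(graph, k) {
  stopifnot(inherits(graph, "pathway_graph"))
  assert_scalar_count(k, "k")
  if (length(graph$gene_nodes) == 0L) return(list())
  g <- pathway_igraph(graph)
  d <- igraph::distances(g)
  # adjacency of the k-th graph power; infinite distances (separate
  # components) never connect
  a <- is.finite(d) & d <= k & d > 0
  pg <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  cliques <- igraph::max_cliques(pg, min = 2L)
  sets <- lapply(cliques, function(v) sort(names(v)))
  keys <- vapply(sets, paste, character(1L), collapse = "\r")
  sets[order(keys, method = "radix")]
}

#' Embed miRNAs into a subpathway gene set
#'
#' A miRNA is embedded when it has at least `t` verified target genes inside
#' the gene set; all verified interactions between embedded miRNAs and member
#' genes are kept as miRNA edges.
#'
#' @param gene_set Character vector of member gene ids.
#' @param interactions A [mirna_target_table()].
#' @param t Minimum in-set target count per embedded miRNA.
#' @param low_throughput_only Restrict to low-throughput-verified
#'   interactions (default `TRUE`).
#' @return List with `mirna_nodes` (sorted character vector) and
#'   `mirna_edges` (data frame `mirna_id`, `gene_id`).
#' @export
embed_mirnas <- function(gene_set, interactions, t = 1L,
                         low_throughput_only = TRUE) {
  assert_scalar_count(t, "t")
  empty <- list(
    mirna_nodes = character(),
    mirna_edges = data.frame(mirna_id = character(), gene_id = character(),
                             stringsAsFactors = FALSE)
  )
  if (is.null(interactions) || nrow(interactions) == 0L) return(empty)
  if (low_throughput_only) {
    interactions <- interactions[interactions$low_throughput, , drop = FALSE]
  }
  hits <- interactions[interactions$gene_id %in% gene_set,
                       c("mirna_id", "gene_id"), drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  counts <- table(hits$mirna_id)
  keep <- names(counts)[counts >= t]
  if (length(keep) == 0L) return(empty)
  edges <- hits[hits$mirna_id %in% keep, , drop = FALSE]
  edges <- edges[order(edges$mirna_id, edges$gene_id), , drop = FALSE]
  rownames(edges) <- NULL
  list(mirna_nodes = sort(keep), mirna_edges = edges)
}

#' Filter candidate subpathways by size
#'
#' Removes small-scale candidates: fewer than `min_mirnas` embedded miRNAs or
#' fewer than `min_genes` genes. Order is preserved and subpathway ids are
#' re-assigned as `<parent>_<ordinal>` within each parent pathway.
#'
#' @param candidates List of [subpathway_graph()] objects.
#' @param params A [reconstruction_params()].
#' @return Filtered list with re-assigned ids.
#' @export
filter_subpathways <- function(candidates, params = reconstruction_params()) {
  keep <- vapply(candidates, function(s) {
    length(s$mirna_nodes) >= params$min_mirnas &&
      length(s$gene_nodes) >= params$min_genes
  }, logical(1L))
  kept <- candidates[keep]
  parents <- vapply(kept, `[[`, character(1L), "parent_pathway_id")
  ord <- stats::ave(seq_along(kept), parents, FUN = seq_along)
  for (i in seq_along(kept)) {
    kept[[i]]$subpathway_id <- paste0(parents[i], "_", ord[i])
  }
  kept
}

# Induced gene-gene edges of a parent pathway on a node subset.
induced_gene_edges <- function(graph, gene_set) {
  e <- graph$edges
  e[e[, 1L] %in% gene_set & e[, 2L] %in% gene_set, , drop = FALSE]
}

#' Reconstruct miRNA-embedded subpathways from pathways
#'
#' Runs the full reconstruction over a list of pathways: k-clique extraction,
#' miRNA embedding, and size filtering. Pathways contributing no qualifying
#' subpathway are reported (via `message()` when `verbose = TRUE`) but are
#' not an error.
#'
#' @param pathways List of [pathway_graph()] objects.
#' @param interactions A [mirna_target_table()].
#' @param params A [reconstruction_params()].
#' @param verbose Emit per-pathway counts as messages.
#' @return A list of [subpathway_graph()] objects with class
#'   `subpathway_list`; see [subpathway_stats()] for the global summary.
#' @export
reconstruct_subpathways <- function(pathways, interactions,
                                    params = reconstruction_params(),
                                    verbose = FALSE) {
  if (length(pathways) == 0L) stop("'pathways' must be non-empty")
  out <- list()
  for (pw in pathways) {
    sets <- extract_k_clique_subpathways(pw, params$k)
    cands <- lapply(sets, function(s) {
      emb <- embed_mirnas(s, interactions, params$t,
                          params$low_throughput_only)
      subpathway_graph(subpathway_id = NA_character_,
                       parent_pathway_id = pw$pathway_id,
                       gene_nodes = s,
                       mirna_nodes = emb$mirna_nodes,
                       gene_edges = induced_gene_edges(pw, s),
                       mirna_edges = emb$mirna_edges)
    })
    kept <- filter_subpathways(cands, params)
    if (verbose) {
      message(sprintf("pathway %s: %d candidate k-cliques, %d subpathways kept",
                      pw$pathway_id, length(cands), length(kept)))
    }
    out <- c(out, kept)
  }
  class(out) <- c("subpathway_list", "list")
  out
}

#' Summary statistics of a reconstructed subpathway set
#'
#' @param subpathways A list of [subpathway_graph()] objects.
#' @return List with `n_subpathways`, per-pathway counts, and the mean
#'   numbers of gene nodes, miRNA nodes and miRNA-gene edges per subpathway.
#' @export
subpathway_stats <- function(subpathways) {
  if (length(subpathways) == 0L) {
    return(list(n_subpathways = 0L, per_pathway = table(character()),
                mean_genes = NA_real_, mean_mirnas = NA_real_,
                mean_mirna_edges = NA_real_))
  }
  parents <- vapply(subpathways, `[[`, character(1L), "parent_pathway_id")
  list(
    n_subpathways = length(subpathways),
    per_pathway = table(parents),
    mean_genes = mean(vapply(subpathways,
                             function(s) length(s$gene_nodes), numeric(1L))),
    mean_mirnas = mean(vapply(subpathways,
                              function(s) length(s$mirna_nodes), numeric(1L))),
    mean_mirna_edges = mean(vapply(subpathways,
                                   function(s) nrow(s$mirna_edges),
                                   numeric(1L)))
  )
}

#' @export
print.subpathway_list <- function(x, ...) {
  s <- subpathway_stats(x)
  cat(sprintf("<subpathway_list> %d subpathways from %d pathways\n",
              s$n_subpathways, length(s$per_pathway)))
  if (s$n_subpathways > 0L) {
    cat(sprintf("  mean per subpathway: %.1f genes, %.1f miRNAs, %.1f miRNA-gene edges\n",
                s$mean_genes, s$mean_mirnas, s$mean_mirna_edges))
  }
  invisible(x)
}
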