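#' Construct a pathway graph
#'
#' A pathway is represented as a simple undirected graph whose nodes are gene
#' identifiers, the form in which signalling and metabolic pathway maps are
#' used here after conversion from their native formats. Self-loops and
#' duplicate edges are removed; isolated genes may be supplied via `nodes`.
#'
#' @param pathway_id Single pathway identifier.
#' @param edges Two-column character matrix or data frame of gene-gene edges.
#' @param nodes Optional character vector of additional (possibly isolated)
#'   gene nodes.
#' @param name Human-readable pathway name; defaults to `pathway_id`.
#' @return An object of class `pathway_graph` with elements `pathway_id`,
#'   `name`, `gene_nodes` (sorted) and `edges` (canonical two-column matrix).
#' @examples
#' pathway_graph("path1", cbind(c("a", "b"), c("b", "c")))
#' @export
pathway_graph <- function(pathway_id, edges = NULL, nodes = NULL,
                          name = pathway_id) {
  if (!is.character(pathway_id) || length(pathway_id) != 1L ||
      !nzchar(pathway_id)) {
    stop("'pathway_id' must be a single non-empty string")
  }
  if (is.null(edges) || length(edges) == 0L || NROW(edges) == 0L) {
    edges <- matrix(character(), ncol = 2L)
  } else {
    if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
    edges <- matrix(as.character(edges), ncol = 2L)
  }
  if (any(!nzchar(edges))) stop("edge endpoints must be non-empty ids")
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  flip <- edges[, 1L] > edges[, 2L]
  edges[flip, ] <- edges[flip, 2:1]
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  colnames(edges) <- c("gene_a", "gene_b")
  gene_nodes <- sort(unique(c(as.character(edges), as.character(nodes))))
  structure(
    list(pathway_id = pathway_id, name = name,
         gene_nodes = gene_nodes, edges = edges),
    class = "pathway_graph"
  )
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("<pathway_graph> %s (%s): %d genes, %d edges\n",
              x$pathway_id, x$name, length(x$gene_nodes), nrow(x$edges)))
  invisible(x)
}

# igraph view of a pathway graph (named vertices, undirected).
pathway_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    as.data.frame(graph$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = graph$gene_nodes, stringsAsFactors = FALSE)
  )
}

#' Construct a miRNA-target interaction table
#'
#' Experimentally verified miRNA-target interactions, each flagged by whether
#' the supporting evidence comes from a focused low-throughput experiment
#' (e.g. reporter assay) as opposed to high-throughput screens.
#'
#' @param mirna_id Character vector of miRNA identifiers.
#' @param gene_id Character vector of target gene identifiers.
#' @param low_throughput Logical vector (recycled if length 1); `TRUE` marks
#'   low-throughput evidence.
#' @return A data frame of class `mirna_target_table`, unique on
#'   (`mirna_id`, `gene_id`).
#' @export
mirna_target_table <- function(mirna_id, gene_id, low_throughput = TRUE) {
  mirna_id <- as.character(mirna_id)
  gene_id <- as.character(gene_id)
  if (length(mirna_id) != length(gene_id)) {
    stop("'mirna_id' and 'gene_id' must have the same length")
  }
  if (any(!nzchar(mirna_id)) || any(!nzchar(gene_id))) {
    stop("identifiers must be non-empty")
  }
  low_throughput <- rep_len(as.logical(low_throughput), length(mirna_id))
  tab <- data.frame(mirna_id = mirna_id, gene_id = gene_id,
                    low_throughput = low_throughput,
                    stringsAsFactors = FALSE)
  tab <- unique(tab)
  if (anyDuplicated(tab[, c("mirna_id", "gene_id")])) {
    stop("conflicting duplicate (mirna_id, gene_id) records")
  }
  tab <- tab[order(tab$mirna_id, tab$gene_id), , drop = FALSE]
  rownames(tab) <- NULL
  class(tab) <- c("mirna_target_table", "data.frame")
  tab
}

#' Construct a subpathway graph
#'
#' A reconstructed unit: a local gene neighbourhood of a parent pathway plus
#' the miRNAs verified to regulate genes inside it.
#'
#' @param subpathway_id Identifier (parent pathway id plus ordinal).
#' @param parent_pathway_id Identifier of the parent pathway.
#' @param gene_nodes Character vector of member gene ids.
#' @param mirna_nodes Character vector of embedded miRNA ids.
#' @param gene_edges Two-column matrix of gene-gene edges induced from the
#'   parent pathway.
#' @param mirna_edges Data frame with columns `mirna_id`, `gene_id`.
#' @return An object of class `subpathway_graph`.
#' @export
subpathway_graph <- function(subpathway_id, parent_pathway_id, gene_nodes,
                             mirna_nodes = character(),
                             gene_edges = NULL, mirna_edges = NULL) {
  gene_nodes <- sort(unique(as.character(gene_nodes)))
  mirna_nodes <- sort(unique(as.character(mirna_nodes)))
  if (is.null(gene_edges)) gene_edges <- matrix(character(), ncol = 2L)
  if (is.null(mirna_edges)) {
    mirna_edges <- data.frame(mirna_id = character(), gene_id = character(),
                              stringsAsFactors = FALSE)
  }
  if (nrow(mirna_edges) > 0L && !all(mirna_edges$gene_id %in% gene_nodes)) {
    stop("every miRNA edge must target a member gene")
  }
  structure(
    list(subpathway_id = subpathway_id,
         parent_pathway_id = parent_pathway_id,
         gene_nodes = gene_nodes,
         mirna_nodes = mirna_nodes,
         gene_edges = gene_edges,
         mirna_edges = mirna_edges),
    class = "subpathway_graph"
  )
}

#' @export
print.subpathway_graph <- function(x, ...) {
  cat(sprintf("<subpathway_graph> %s (parent %s): %d genes, %d miRNAs, %d miRNA edges\n",
              x$subpathway_id, x$parent_pathway_id, length(x$gene_nodes),
              length(x$mirna_nodes), nrow(x$mirna_edges)))
  invisible(x)
}
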