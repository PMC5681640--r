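# Small fixture builders shared across tests.

path_graph5 <- function() {
  pathway_graph("pw", cbind(paste0("v", 1:4), paste0("v", 2:5)))
}

# Random simple undirected graph as a logical adjacency matrix plus the
# corresponding pathway_graph; edges drawn i.i.d., possibly disconnected.
random_graph <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (stats::runif(1) < p) adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  pw <- pathway_graph("rg", cbind(nodes[idx[, 1L]], nodes[idx[, 2L]]),
                      nodes = nodes)
  list(adj = adj, pathway = pw)
}

# Random expression matrix with named features/samples.
random_expr <- function(n_feat, n_samp, prefix = "f") {
  m <- matrix(2^stats::rnorm(n_feat * n_samp, 6, 1.5), n_feat, n_samp,
              dimnames = list(sprintf("%s%03d", prefix, seq_len(n_feat)),
                              sprintf("s%03d", seq_len(n_samp))))
  m
}

# Minimal subpathway with given members (no edges; scoring needs none).
make_spw <- function(id, genes, mirnas = character(), parent = "pw") {
  subpathway_graph(id, parent, gene_nodes = genes, mirna_nodes = mirnas)
}

# Exponential survival table with log-hazard beta * x.
sim_survival <- function(x, beta = 0, censor = 0.3, ids = NULL) {
  n <- length(x)
  t_ev <- stats::rexp(n, rate = exp(beta * x) * log(2) / 40)
  cens <- stats::rbinom(n, 1L, censor) == 1L
  data.frame(
    sample_id = ids %||% sprintf("s%03d", seq_len(n)),
    time = ifelse(cens, t_ev * stats::runif(n), t_ev),
    event = as.integer(!cens),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Strip activity_profile attributes down to a plain matrix for comparisons.
mat0 <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)[intersect(names(attributes(x)),
                                           c("dim", "dimnames"))]
  x
}
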