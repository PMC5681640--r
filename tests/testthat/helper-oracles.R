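# Independent brute-force oracles used to validate the package's
# implementations. They share no code path with the package internals:
# distances come from a hand-rolled BFS, ranks from an explicit sort loop,
# and probabilities from exhaustive enumeration of draws.

# All maximal node sets with pairwise BFS distance <= k, via bitmask DP.
# adj: symmetric logical adjacency matrix with dimnames.
oracle_k_cliques <- function(adj, k) {
  n <- nrow(adj)
  stopifnot(n <= 16L)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer()
      for (v in frontier) {
        nb <- which(adj[v, ] & is.infinite(dist))
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
      frontier <- unique(nxt)
    }
    d[s, ] <- dist
  }
  ok <- d <= k
  n_mask <- bitwShiftL(1L, n)
  valid <- logical(n_mask)
  valid[1L] <- TRUE  # empty set (mask 0 stored at index 1)
  bits_of <- lapply(seq_len(n_mask) - 1L, function(m) {
    which(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
  })
  for (m in seq_len(n_mask - 1L)) {
    b <- bits_of[[m + 1L]]
    low <- b[1L]
    rest <- m - bitwShiftL(1L, low - 1L)
    valid[m + 1L] <- valid[rest + 1L] &&
      all(ok[low, bits_of[[rest + 1L]]])
  }
  sets <- list()
  for (m in seq_len(n_mask - 1L)) {
    if (!valid[m + 1L]) next
    b <- bits_of[[m + 1L]]
    if (length(b) < 2L) next
    maximal <- TRUE
    for (v in setdiff(seq_len(n), b)) {
      if (valid[m + bitwShiftL(1L, v - 1L) + 1L]) {
        maximal <- FALSE
        break
      }
    }
    if (maximal) sets[[length(sets) + 1L]] <- sort(rownames(adj)[b])
  }
  sets[order(vapply(sets, paste, character(1L), collapse = "\r"),
             method = "radix")]
}

# Average ranks by explicit sort-and-tie loop, then w = r * exp(r / n).
oracle_weights <- function(x) {
  n <- length(x)
  ord <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  w <- r * exp(r / n)
  names(w) <- names(x)
  w
}

# Member-mean minus complement-mean contrast for one sample.
oracle_spa_cell <- function(sample_values, members) {
  w <- oracle_weights(sample_values)
  inside <- names(w) %in% members
  if (!any(inside)) return(NA_real_)
  sum(w[inside]) / sum(inside) - sum(w[!inside]) / sum(!inside)
}

# Raw score matrix by looping oracle_spa_cell over samples.
oracle_spa_matrix <- function(expr, member_list) {
  out <- matrix(NA_real_, length(member_list), ncol(expr),
                dimnames = list(names(member_list), colnames(expr)))
  for (i in seq_along(member_list)) {
    for (s in seq_len(ncol(expr))) {
      out[i, s] <- oracle_spa_cell(expr[, s], member_list[[i]])
    }
  }
  out
}

# Upper-tail hypergeometric probability by enumerating every size-n draw.
oracle_hypergeom <- function(m, t_sub, n, r) {
  if (r == 0L) return(1)
  if (n == 0L) return(0)
  draws <- utils::combn(m, n)
  mean(colSums(draws <= t_sub) >= r)
}
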