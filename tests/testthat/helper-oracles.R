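# Shared fixtures and independent oracles for the graph algorithms.

fx <- sop_fixtures()

# Reflexive-transitive closure by repeated boolean matrix powers:
# OR of M^k for k = 1..n with a forced diagonal. Independent of the
# Warshall implementation under test.
oracle_closure <- function(B) {
  B <- (unclass(B) != 0) * 1
  diag(B) <- 1
  acc <- B
  P <- B
  for (k in seq_len(nrow(B))) {
    P <- (P %*% B > 0) * 1
    acc <- ((acc + P) > 0) * 1
  }
  dimnames(acc) <- dimnames(B)
  storage.mode(acc) <- "integer"
  acc
}

# Longest-path-to-sink strata of the SCC condensation (igraph for the
# components, explicit recursion for the depths). Independent of
# partition_levels.
oracle_strata <- function(B) {
  B <- (unclass(B) != 0) * 1
  diag(B) <- 0
  g <- igraph::graph_from_adjacency_matrix(B > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  k <- max(comp)
  adj <- matrix(FALSE, k, k)
  e <- which(B == 1, arr.ind = TRUE)
  for (r in seq_len(nrow(e))) {
    u <- comp[e[r, 1]]; v <- comp[e[r, 2]]
    if (u != v) adj[u, v] <- TRUE
  }
  depth <- rep(NA_integer_, k)
  walk <- function(u) {
    if (!is.na(depth[u])) return(depth[u])
    succ <- which(adj[u, ])
    d <- if (!length(succ)) 1L else 1L + max(vapply(succ, walk, 0L))
    depth[u] <<- d
    d
  }
  for (u in seq_len(k)) walk(u)
  unname(depth[comp])
}

# Random reachability matrix (direct diagonal, Bernoulli off-diagonal).
rand_rm <- function(n, p = 0.3) {
  b <- matrix(as.integer(stats::runif(n * n) < p), n, n)
  diag(b) <- 1L
  reachability_matrix(b, flavor = "as_given")
}

# Random transitively closed matrix, closed by the oracle (not by the
# implementation under test).
rand_closed_rm <- function(n, p = 0.25) {
  reachability_matrix(oracle_closure(rand_rm(n, p)), flavor = "full_closure")
}

# A tiny SSIM from an upper-triangle symbol vector, filled row-major.
mk_ssim <- function(n, symbols) {
  m <- matrix(NA_character_, n, n)
  k <- 1
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m[i, j] <- symbols[k]; k <- k + 1
  }
  ssim(m)
}

# Panel of E single-pair (n = 2) experts holding the given symbols.
mk_pair_panel <- function(symbols) {
  lapply(seq_along(symbols), function(e) {
    m <- matrix(NA_character_, 2, 2)
    m[1, 2] <- symbols[e]
    expert_judgments(data.frame(row_code = 1, col_code = 2, symbol = symbols[e]),
                     expert_id = sprintf("E%d", e))
  })
}
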