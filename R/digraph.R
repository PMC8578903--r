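#' Build the level-layered structural digraph
#'
#' Collapses the binary reachability relation to its strongly-connected
#' components (mutually reaching factor sets, typically created by `X`
#' judgments), transitively reduces the resulting acyclic condensation
#' (transitive reduction is only well-defined on a DAG), and attaches the
#' level of each node. The reduced edge set is the minimal one whose
#' closure equals the closure of the condensation — the edges a model
#' diagram actually draws. Mutual pairs inside a component are kept as
#' bidirectional decorations.
#'
#' @param m An `ism_rm` or square 0/1 matrix.
#' @param p Optional [partition_levels()] result; when omitted it is
#'   computed from `m` (which then must not stall).
#' @return An `ism_digraph`: list with `members` (list of factor-code
#'   vectors, one per node), `level` (integer per node), `edges` (data
#'   frame of node indices `from`, `to`), `mutual_pairs` (data frame of
#'   factor codes `a`, `b` inside one component).
#' @export
build_digraph <- function(m, p = NULL) {
  if (!inherits(m, "ism_rm")) m <- reachability_matrix(m, flavor = "as_given")
  if (is.null(p)) p <- partition_levels(m)
  codes <- .codes_of(m)
  b <- rm_binary(m)
  g <- igraph::graph_from_adjacency_matrix(
    (b * (1 - diag(nrow(b)))) > 0, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  k <- max(comp)
  members <- lapply(seq_len(k), function(i) sort(codes[comp == i]))
  # order nodes deterministically by smallest member code
  ord <- order(vapply(members, min, 0))
  members <- members[ord]
  comp <- match(comp, ord)

  # condensation adjacency
  cond <- matrix(FALSE, k, k)
  e <- which(b == 1L, arr.ind = TRUE)
  e <- e[e[, 1] != e[, 2], , drop = FALSE]
  for (r in seq_len(nrow(e))) {
    u <- comp[e[r, 1]]; v <- comp[e[r, 2]]
    if (u != v) cond[u, v] <- TRUE
  }
  reduced <- .hasse_reduce(cond)
  edges <- which(reduced, arr.ind = TRUE)
  edges <- data.frame(from = edges[, 1], to = edges[, 2])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  mut <- which(b == 1L & t(b) == 1L & upper.tri(b), arr.ind = TRUE)
  mutual_pairs <- data.frame(a = codes[mut[, 1]], b = codes[mut[, 2]])

  level <- vapply(members, function(mem) {
    unique(p$assignment[as.character(mem)])[1]
  }, 0L)
  structure(list(members = members, level = as.integer(level),
                 edges = edges, mutual_pairs = mutual_pairs),
            class = "ism_digraph")
}

# Transitive reduction of a DAG given as a logical adjacency matrix:
# keep edge (u,v) of the closure iff no intermediate w routes u -> w -> v.
# For a DAG this Hasse diagram is the unique minimal relation with the
# same closure.
.hasse_reduce <- function(adj) {
  k <- nrow(adj)
  if (k == 0) return(adj)
  C <- .warshall(adj) & !diag(TRUE, k)   # strict closure
  keep <- C
  for (w in seq_len(k)) {
    keep <- keep & !outer(C[, w], C[w, ], "&")
  }
  keep
}

#' @export
print.ism_digraph <- function(x, ...) {
  cat(sprintf("Structural digraph: %d nodes, %d reduced edges\n",
              length(x$members), nrow(x$edges)))
  for (i in seq_along(x$members)) {
    cat(sprintf("  [%d] level %s {%s}\n", i, .roman(x$level[i]),
                .fmt_set(x$members[[i]])))
  }
  for (r in seq_len(nrow(x$edges))) {
    cat(sprintf("  {%s} -> {%s}\n",
                .fmt_set(x$members[[x$edges$from[r]]]),
                .fmt_set(x$members[[x$edges$to[r]]])))
  }
  invisible(x)
}

#' Export a structural digraph to Graphviz DOT
#'
#' One `rank = same` subgraph per level (top level first), nodes labeled
#' with their member codes, mutual pairs annotated as bidirectional
#' decorations.
#'
#' @param g An [build_digraph()] result.
#' @param path Optional file to write; when `NULL` the DOT source is
#'   returned invisibly as a character vector.
#' @return Character vector of DOT lines, invisibly.
#' @export
write_dot <- function(g, path = NULL) {
  lab <- vapply(g$members, function(m) paste(m, collapse = ","), "")
  lines <- c("digraph ism {", "  rankdir = BT;",
             "  node [shape = box];")
  for (lv in sort(unique(g$level))) {
    ids <- which(g$level == lv)
    lines <- c(lines, sprintf(
      "  subgraph level_%s { rank = same; %s }", .roman(lv),
      paste(sprintf("\"%s\";", lab[ids]), collapse = " ")))
  }
  for (r in seq_len(nrow(g$edges))) {
    lines <- c(lines, sprintf("  \"%s\" -> \"%s\";",
                              lab[g$edges$from[r]], lab[g$edges$to[r]]))
  }
  for (r in seq_len(nrow(g$mutual_pairs))) {
    lines <- c(lines, sprintf("  // mutual: %d <-> %d",
                              g$mutual_pairs$a[r], g$mutual_pairs$b[r]))
  }
  lines <- c(lines, "}")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
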