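#' Level partition by iterated top-element removal
#'
#' The classical ISM iteration: for every remaining factor compute its
#' reachability set (factors it reaches, itself included), its antecedent
#' set (factors that reach it) and their intersection, all restricted to
#' the factors still in play. A factor whose reachability set equals the
#' intersection cannot drive anything beyond what also drives it — it is
#' at the current top of the residual hierarchy. All such factors form
#' the current level (Level I on the first iteration) and are removed;
#' the iteration repeats until no factors remain. Level I is the top of
#' the model (least critical factors), the deepest level the bottom
#' (drivers).
#'
#' On a transitively closed matrix every iteration levels at least one
#' factor and the procedure finishes in at most n iterations. A
#' non-closed matrix can stall (no factor satisfies the rule); this is
#' reported as an error naming the residual factors and suggesting a
#' closure mode.
#'
#' @param m An `ism_rm` or square 0/1 matrix (diagonal treated as 1).
#' @return An `ism_levels` object: list with `assignment` (named integer
#'   vector, level per code), `levels` (list of integer code vectors,
#'   named by Roman numeral), and `trace` (one data frame per iteration
#'   with the reachability/antecedent/intersection sets and the leveled
#'   flag).
#' @examples
#' b <- diag(1, 3); b[1, 2] <- b[2, 3] <- b[1, 3] <- 1
#' partition_levels(reachability_matrix(b, flavor = "full_closure"))
#' @export
partition_levels <- function(m) {
  if (!inherits(m, "ism_rm")) m <- reachability_matrix(m, flavor = "as_given")
  b <- rm_binary(m)
  codes <- .codes_of(m)
  remaining <- codes
  trace <- list()
  levels <- list()
  while (length(remaining)) {
    idx <- match(remaining, codes)
    reach <- lapply(idx, function(i) remaining[b[i, idx] == 1L])
    antec <- lapply(idx, function(i) remaining[b[idx, i] == 1L])
    inter <- Map(intersect, reach, antec)
    leveled <- mapply(function(r, s) length(r) == length(s) && setequal(r, s),
                      reach, inter)
    trace[[length(trace) + 1L]] <- data.frame(
      code = remaining,
      reachability = vapply(reach, .fmt_set, ""),
      antecedent = vapply(antec, .fmt_set, ""),
      intersection = vapply(inter, .fmt_set, ""),
      leveled = leveled,
      stringsAsFactors = FALSE
    )
    if (!any(leveled)) {
      .stopf(paste0(
        "level partitioning stalled at iteration %d: no factor among {%s} has ",
        "reachability == intersection. The matrix is not transitively closed; ",
        "apply transitive_closure(mode = \"full\") (or \"one_pass\") first."),
        length(trace), .fmt_set(remaining))
    }
    levels[[length(levels) + 1L]] <- sort(remaining[leveled])
    remaining <- remaining[!leveled]
  }
  names(levels) <- .roman(seq_along(levels))
  assignment <- integer(length(codes))
  names(assignment) <- codes
  for (k in seq_along(levels)) assignment[as.character(levels[[k]])] <- k
  structure(list(assignment = assignment, levels = levels, trace = trace),
            class = "ism_levels")
}

#' @export
print.ism_levels <- function(x, ...) {
  cat(sprintf("ISM level partition: %d levels over %d factors\n",
              length(x$levels), length(x$assignment)))
  for (k in seq_along(x$levels)) {
    cat(sprintf("  Level %-4s {%s}\n", names(x$levels)[k], .fmt_set(x$levels[[k]])))
  }
  invisible(x)
}

#' Conical (level-ordered) reachability matrix
#'
#' Symmetrically permutes the reachability matrix into level order:
#' factors sorted by ascending level (Level I first), ties broken by
#' ascending code. Provenance marks travel with their cells; the cell
#' multiset is exactly that of the source matrix.
#'
#' @param m An `ism_rm`.
#' @param p The [partition_levels()] result for `m`.
#' @return A `conical_matrix`: list with `order` (the code permutation),
#'   `matrix` (the permuted `ism_rm`) and `level` (level index per
#'   permuted row).
#' @export
build_conical_matrix <- function(m, p) {
  if (!inherits(m, "ism_rm")) m <- reachability_matrix(m, flavor = "as_given")
  codes <- .codes_of(m)
  if (!setequal(codes, as.integer(names(p$assignment)))) {
    .stopf("level partition does not cover the matrix factors")
  }
  lev <- p$assignment[as.character(codes)]
  ord <- order(lev, codes)
  perm <- codes[ord]
  idx <- match(perm, codes)
  b <- rm_binary(m)[idx, idx]
  prov <- attr(m, "provenance")[idx, idx]
  dimnames(b) <- dimnames(prov) <- list(perm, perm)
  structure(list(
    order = perm,
    matrix = reachability_matrix(b, prov, flavor = attr(m, "flavor"), codes = perm),
    level = unname(lev[ord])
  ), class = "conical_matrix")
}

#' @export
print.conical_matrix <- function(x, ...) {
  cat(sprintf("Conical matrix, level order: %s\n",
              paste(x$order, collapse = ", ")))
  print(x$matrix)
  invisible(x)
}
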