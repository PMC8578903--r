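#' Construct a reachability matrix with cell provenance
#'
#' A reachability matrix is a square binary relation over the roster;
#' cell (i, j) = 1 means factor i influences (reaches) factor j. Each
#' cell additionally carries a provenance mark — `direct` (elicited),
#' `transitive` (inferred, printed as `1*` in the field's tables) or
#' `absent` — and the matrix carries a flavor tag describing how it was
#' obtained (`initial`, `as_given`, `one_pass`, `full_closure`).
#' The diagonal is always direct: every factor reaches itself.
#'
#' @param binary Square 0/1 matrix (or logical).
#' @param provenance Optional character matrix over
#'   `c("absent","direct","transitive")`; defaults to `direct` wherever
#'   `binary` is 1.
#' @param flavor One of `"initial"`, `"as_given"`, `"one_pass"`,
#'   `"full_closure"`.
#' @param codes Factor codes (defaults to dimnames or `1..n`).
#' @return An `ism_rm` object: integer 0/1 matrix with attributes
#'   `provenance` and `flavor`.
#' @export
reachability_matrix <- function(binary, provenance = NULL,
                                flavor = c("initial", "as_given", "one_pass",
                                           "full_closure"),
                                codes = NULL) {
  flavor <- match.arg(flavor)
  if (!is.matrix(binary) || nrow(binary) != ncol(binary)) {
    .stopf("reachability matrix must be square")
  }
  n <- nrow(binary)
  if (is.null(codes)) {
    codes <- if (is.null(rownames(binary))) seq_len(n) else as.integer(rownames(binary))
  }
  b <- matrix(as.integer(binary != 0), n, n, dimnames = list(codes, codes))
  if (is.null(provenance)) {
    provenance <- ifelse(b == 1L, "direct", "absent")
  }
  if (!all(provenance %in% c("absent", "direct", "transitive"))) {
    .stopf("provenance cells must be absent/direct/transitive")
  }
  diag(b) <- 1L
  diag(provenance) <- "direct"
  if (any((b == 1L) != (provenance != "absent"))) {
    .stopf("provenance inconsistent with binary view")
  }
  dimnames(provenance) <- dimnames(b)
  structure(b, provenance = provenance, flavor = flavor, class = "ism_rm")
}

#' @export
print.ism_rm <- function(x, ...) {
  cat(sprintf("Reachability matrix (%d factors, flavor: %s)\n",
              nrow(x), attr(x, "flavor")))
  disp <- matrix(as.character(unclass(x)), nrow(x), dimnames = dimnames(x))
  disp[attr(x, "provenance") == "transitive"] <- "1*"
  print(disp, quote = FALSE)
  invisible(x)
}

#' Binary 0/1 view of a reachability matrix
#'
#' Strips provenance and class, returning the plain integer matrix
#' (direct and transitive cells both count as 1).
#'
#' @param m An `ism_rm`.
#' @return Integer 0/1 matrix with code dimnames.
#' @export
rm_binary <- function(m) {
  b <- unclass(m)
  attributes(b) <- list(dim = dim(m), dimnames = dimnames(m))
  b
}

#' Convert an SSIM into the initial reachability matrix
#'
#' Applies the classical decoding rules for pair (i, j), i < j:
#' `V` gives (i,j)=1, (j,i)=0; `A` gives (i,j)=0, (j,i)=1; `X` sets both
#' to 1; `O` sets both to 0. The diagonal is 1 (self-reachability). All
#' cells set this way are marked `direct`.
#'
#' @param s An [ssim()].
#' @return An `ism_rm` with flavor `"initial"`.
#' @export
ssim_to_initial_rm <- function(s) {
  s <- ssim(unclass(s))
  n <- nrow(s)
  codes <- .codes_of(s)
  b <- matrix(0L, n, n, dimnames = list(codes, codes))
  up <- which(upper.tri(s), arr.ind = TRUE)
  sym <- unclass(s)[up]
  b[up[sym == "V", , drop = FALSE]] <- 1L
  b[up[sym == "X", , drop = FALSE]] <- 1L
  dn <- up[, 2:1, drop = FALSE]
  b[dn[sym == "A", , drop = FALSE]] <- 1L
  b[dn[sym == "X", , drop = FALSE]] <- 1L
  diag(b) <- 1L
  reachability_matrix(b, flavor = "initial", codes = codes)
}

#' Transitive closure of a reachability matrix
#'
#' Three explicit modes. `"full"` computes the reflexive-transitive
#' closure (Warshall semantics): the i->j and j->k imply i->k rule
#' applied to a fixed point. `"one_pass"` adds exactly the length-2
#' compositions — the binary view of M OR M.M — which is what a single
#' manual round of "evaluate every 0 for evidence of transitivity"
#' produces. `"as_given"` returns the matrix unchanged (used to analyse a
#' published matrix exactly as printed). Newly added cells are marked
#' `transitive`; direct cells are never downgraded.
#'
#' @param m An `ism_rm` (or square 0/1 matrix).
#' @param mode `"full"`, `"one_pass"` or `"as_given"`.
#' @return An `ism_rm` with the corresponding flavor.
#' @examples
#' b <- diag(1, 3); b[1, 2] <- b[2, 3] <- 1
#' transitive_closure(reachability_matrix(b), "full")
#' @export
transitive_closure <- function(m, mode = c("full", "one_pass", "as_given")) {
  mode <- match.arg(mode)
  if (!inherits(m, "ism_rm")) m <- reachability_matrix(m, flavor = "as_given")
  if (mode == "as_given") {
    return(reachability_matrix(rm_binary(m), attr(m, "provenance"),
                               flavor = "as_given"))
  }
  B <- rm_binary(m) == 1L
  closed <- if (mode == "full") .warshall(B) else B | .bool_mult(B, B)
  prov <- attr(m, "provenance")
  prov[closed & prov == "absent"] <- "transitive"
  reachability_matrix((closed) * 1L, prov,
                      flavor = if (mode == "full") "full_closure" else "one_pass",
                      codes = .codes_of(m))
}

#' Driving and dependence powers
#'
#' Driving power of a factor is its row sum in the binary reachability
#' view (how many factors it reaches, itself included); dependence power
#' is its column sum (by how many factors it is reached). The two totals
#' always agree — both count the 1s of the matrix.
#'
#' @param m An `ism_rm` or square 0/1 matrix.
#' @return An `ism_powers` data frame with columns `code`, `driving`,
#'   `dependence`.
#' @export
compute_powers <- function(m) {
  if (!inherits(m, "ism_rm")) m <- reachability_matrix(m, flavor = "as_given")
  b <- rm_binary(m)
  out <- data.frame(code = .codes_of(m),
                    driving = as.integer(rowSums(b)),
                    dependence = as.integer(colSums(b)))
  class(out) <- c("ism_powers", "data.frame")
  out
}
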