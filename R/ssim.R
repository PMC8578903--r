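#' Construct a structural self-interaction matrix (SSIM)
#'
#' The SSIM records, for every factor pair (i, j) with i < j, one of four
#' contextual-relation symbols under the relation "leads to":
#' `V` (row leads to column), `A` (column leads to row), `X` (both
#' directions) and `O` (no relation). Only the strict upper triangle is
#' meaningful; the diagonal and lower triangle are empty.
#'
#' @param x A square character matrix whose strict upper triangle holds
#'   the symbols (lower triangle and diagonal `NA` or `""`), or a long
#'   data frame with columns `row_code`, `col_code`, `symbol`.
#' @param codes Integer factor codes; defaults to the matrix dimnames or
#'   `1..n`.
#' @return An `ssim` object: character matrix with `NA` off the upper
#'   triangle, dimnames set to the codes.
#' @examples
#' m <- matrix(NA_character_, 3, 3)
#' m[upper.tri(m)] <- c("V", "O", "X")
#' ssim(m)
#' @export
ssim <- function(x, codes = NULL) {
  if (is.data.frame(x)) {
    x <- .pairs_to_grid(x, codes)
    codes <- as.integer(rownames(x))
  }
  if (!is.matrix(x) || nrow(x) != ncol(x)) .stopf("SSIM must be a square matrix")
  n <- nrow(x)
  if (n < 2) .stopf("SSIM needs at least 2 factors")
  if (is.null(codes)) {
    codes <- if (is.null(rownames(x))) seq_len(n) else as.integer(rownames(x))
  }
  g <- matrix(NA_character_, n, n, dimnames = list(codes, codes))
  up <- which(upper.tri(x), arr.ind = TRUE)
  sym <- toupper(trimws(x[up]))
  bad <- which(is.na(sym) | !sym %in% SSIM_SYMBOLS)
  if (length(bad)) {
    .stopf("invalid SSIM symbol %s at pair (%s,%s); expected one of V/A/X/O",
           dQuote(x[up][bad[1]]), codes[up[bad[1], 1]], codes[up[bad[1], 2]])
  }
  low <- x[lower.tri(x, diag = TRUE)]
  if (any(!is.na(low) & nzchar(trimws(low)))) {
    .stopf("SSIM must be upper triangle only; found entries on or below the diagonal")
  }
  g[up] <- sym
  structure(g, class = "ssim")
}

.pairs_to_grid <- function(df, codes = NULL) {
  need <- c("row_code", "col_code", "symbol")
  if (!all(need %in% names(df))) {
    .stopf("pair table needs columns %s", paste(need, collapse = ", "))
  }
  r <- as.integer(df$row_code); c <- as.integer(df$col_code)
  if (any(r >= c)) {
    i <- which(r >= c)[1]
    .stopf("pair (%d,%d) violates the strict upper triangle (row < col)", r[i], c[i])
  }
  if (is.null(codes)) codes <- sort(unique(c(r, c)))
  n <- length(codes)
  m <- matrix(NA_character_, n, n, dimnames = list(codes, codes))
  key <- paste(r, c)
  if (anyDuplicated(key)) {
    .stopf("duplicate judgment for pair (%s)", key[duplicated(key)][1])
  }
  m[cbind(match(r, codes), match(c, codes))] <- as.character(df$symbol)
  miss <- which(upper.tri(m) & is.na(m), arr.ind = TRUE)
  if (nrow(miss)) {
    .stopf("incomplete upper triangle; missing pair(s): %s",
           paste(sprintf("(%s,%s)", codes[miss[, 1]], codes[miss[, 2]]),
                 collapse = " ")[1])
  }
  m
}

#' @export
print.ssim <- function(x, ...) {
  cat(sprintf("SSIM over %d factors (V/A/X/O, upper triangle)\n", nrow(x)))
  disp <- unclass(x)
  disp[is.na(disp)] <- "."
  print(disp, quote = FALSE)
  invisible(x)
}

#' Factor codes of an ISM object
#' @param x An `ssim`, reachability matrix, or related object.
#' @return Integer vector of factor codes.
#' @export
ism_codes <- function(x) .codes_of(x)

#' Assemble one expert's complete pairwise judgment set
#'
#' @param df Data frame with columns `row_code`, `col_code`, `symbol`
#'   covering the full strict upper triangle exactly once.
#' @param expert_id Identifier for the expert (opaque string).
#' @param codes Optional roster codes (to detect missing pairs against a
#'   known roster rather than the observed codes).
#' @return An `expert_judgments` object wrapping the validated `ssim`.
#' @export
expert_judgments <- function(df, expert_id = "expert", codes = NULL) {
  s <- ssim(df, codes = codes)
  structure(list(expert_id = as.character(expert_id), ssim = s),
            class = "expert_judgments")
}

#' Aggregate a panel of expert judgment sets into one SSIM
#'
#' Per pair, the symbol counts over the panel are tallied (the
#' spreadsheet "count-if" step) and the most frequent symbol wins
#' (majority rule, implemented as plurality since a pair has four possible
#' symbols). The tally records whether the winner held an absolute
#' majority (count > E/2) or a plurality, and flags ties. Tied pairs are
#' resolved by `tie_policy`:
#' `"priority_order"` (default) picks the tied symbol ranked highest in
#' `priority` — the default order X > V > A > O prefers any asserted
#' relation over "no relation"; `"flag"` does the same but is available
#' to make the always-flagged semantics explicit; `"error"` stops,
#' naming the pair.
#'
#' @param panel A list of [expert_judgments()] objects (or of `ssim`
#'   objects), or a single long data frame with columns `expert_id`,
#'   `row_code`, `col_code`, `symbol`.
#' @param tie_policy `"priority_order"`, `"flag"` or `"error"`.
#' @param priority Character permutation of `c("X","V","A","O")` used to
#'   break ties.
#' @return A list with `ssim` (the aggregated [ssim()]) and `tallies`, a
#'   data frame with per-pair counts of `V`, `A`, `X`, `O`, the `winner`,
#'   `majority_kind` (`"absolute"`, `"plurality"` or `"tie"`) and a `tie`
#'   flag.
#' @examples
#' m <- matrix(NA_character_, 2, 2); m[1, 2] <- "V"
#' s <- ssim(m)
#' agg <- aggregate_judgments(list(s, s, s))
#' agg$tallies
#' @export
aggregate_judgments <- function(panel,
                                tie_policy = c("priority_order", "flag", "error"),
                                priority = c("X", "V", "A", "O")) {
  tie_policy <- match.arg(tie_policy)
  if (!setequal(priority, SSIM_SYMBOLS)) {
    .stopf("priority must be a permutation of V/A/X/O")
  }
  grids <- .panel_grids(panel)
  E <- length(grids)
  if (E < 1L) .stopf("empty expert panel")
  codes <- as.integer(rownames(grids[[1]]))
  for (g in grids[-1]) {
    if (!identical(as.integer(rownames(g)), codes)) {
      .stopf("judgment sets cover different rosters")
    }
  }
  n <- length(codes)
  up <- which(upper.tri(grids[[1]]), arr.ind = TRUE)
  counts <- vapply(SSIM_SYMBOLS, function(s) {
    hits <- vapply(grids, function(g) g[up] == s, logical(nrow(up)))
    rowSums(matrix(hits, nrow = nrow(up)))
  }, numeric(nrow(up)))
  counts <- matrix(counts, nrow = nrow(up), dimnames = list(NULL, SSIM_SYMBOLS))

  winner <- character(nrow(up))
  kind <- character(nrow(up))
  tie <- logical(nrow(up))
  for (k in seq_len(nrow(up))) {
    mx <- max(counts[k, ])
    top <- SSIM_SYMBOLS[counts[k, ] == mx]
    tie[k] <- length(top) > 1L
    if (tie[k] && tie_policy == "error") {
      .stopf("aggregation tie on pair (%s,%s): %s",
             codes[up[k, 1]], codes[up[k, 2]],
             paste(sprintf("%s=%d", top, mx), collapse = " "))
    }
    winner[k] <- if (tie[k]) priority[priority %in% top][1] else top
    kind[k] <- if (tie[k]) "tie" else if (mx > E / 2) "absolute" else "plurality"
  }

  grid <- matrix(NA_character_, n, n, dimnames = list(codes, codes))
  grid[up] <- winner
  tallies <- data.frame(
    row_code = codes[up[, 1]], col_code = codes[up[, 2]],
    counts, winner = winner, majority_kind = kind, tie = tie,
    stringsAsFactors = FALSE
  )
  tallies <- tallies[order(tallies$row_code, tallies$col_code), ]
  rownames(tallies) <- NULL
  list(ssim = ssim(grid), tallies = tallies)
}

.panel_grids <- function(panel) {
  if (is.data.frame(panel)) {
    if (!"expert_id" %in% names(panel)) {
      .stopf("long-form panel needs an 'expert_id' column")
    }
    codes <- sort(unique(c(as.integer(panel$row_code), as.integer(panel$col_code))))
    return(lapply(split(panel, panel$expert_id),
                  function(d) unclass(ssim(d, codes = codes))))
  }
  lapply(panel, function(p) {
    if (inherits(p, "expert_judgments")) unclass(p$ssim) else unclass(ssim(p))
  })
}
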