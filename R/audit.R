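#' Audit a published reachability matrix against mechanical closures
#'
#' Published final reachability matrices are produced by hand and do not
#' always coincide with a mechanical transitive closure of the initial
#' matrix. This audit compares an as-given matrix cell by cell with the
#' one-pass closure and the full Warshall closure of a base matrix, and
#' runs the level partition and MICMAC classification under all three
#' modes side by side. Nothing is "corrected": discrepancies are
#' reported, the published data is left exactly as printed.
#'
#' @param as_given The matrix to audit (an `ism_rm`), e.g. a published
#'   final reachability matrix.
#' @param base The matrix to close (an `ism_rm`), e.g. the corresponding
#'   initial reachability matrix.
#' @return An `ism_audit` object: list with `vs_one_pass` and `vs_full`,
#'   each holding `extra` / `missing` data frames of (row, col) codes
#'   present in `as_given` but not the closure and vice versa, and
#'   `by_mode`, a per-mode list of `levels` ([partition_levels()] result
#'   or the stall message) and `micmac`.
#' @export
audit_closure_consistency <- function(as_given, base) {
  if (!inherits(as_given, "ism_rm")) as_given <- reachability_matrix(as_given, flavor = "as_given")
  if (!inherits(base, "ism_rm")) base <- reachability_matrix(base, flavor = "initial")
  if (!identical(dim(as_given), dim(base))) .stopf("matrices differ in shape")
  codes <- .codes_of(as_given)

  cmp <- function(target) {
    a <- rm_binary(as_given); t0 <- rm_binary(target)
    ex <- which(a == 1L & t0 == 0L, arr.ind = TRUE)
    ms <- which(a == 0L & t0 == 1L, arr.ind = TRUE)
    list(extra = data.frame(row = codes[ex[, 1]], col = codes[ex[, 2]]),
         missing = data.frame(row = codes[ms[, 1]], col = codes[ms[, 2]]))
  }
  one_pass <- transitive_closure(base, "one_pass")
  full <- transitive_closure(base, "full")

  modes <- list(as_given = as_given, one_pass = one_pass, full = full)
  by_mode <- lapply(modes, function(m) {
    lv <- tryCatch(partition_levels(m), error = function(e) conditionMessage(e))
    pw <- compute_powers(m)
    list(levels = lv, micmac = classify_factors(pw))
  })
  structure(list(vs_one_pass = cmp(one_pass), vs_full = cmp(full),
                 by_mode = by_mode),
            class = "ism_audit")
}

#' @export
print.ism_audit <- function(x, ...) {
  fmt <- function(df) {
    if (!nrow(df)) return("none")
    paste(sprintf("(%d,%d)", df$row, df$col), collapse = " ")
  }
  cat("Closure-consistency audit\n")
  cat("  vs one_pass: extra", fmt(x$vs_one_pass$extra),
      "| missing", fmt(x$vs_one_pass$missing), "\n")
  cat("  vs full:     extra", fmt(x$vs_full$extra),
      "| missing", fmt(x$vs_full$missing), "\n")
  for (m in names(x$by_mode)) {
    lv <- x$by_mode[[m]]$levels
    cat(sprintf("  mode %-9s %s\n", m,
                if (is.character(lv)) paste("stalled:", lv)
                else sprintf("%d levels (%s)", length(lv$levels),
                             paste(vapply(lv$levels, .fmt_set, ""), collapse = " | "))))
  }
  invisible(x)
}
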