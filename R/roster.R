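#' Construct a determinant roster
#'
#' A roster is the coded list of factors (determinants) that indexes every
#' matrix in an ISM analysis. Codes must be the contiguous integers
#' `1..n` and every factor needs a non-empty label.
#'
#' @param labels Character vector of factor labels.
#' @param codes Integer codes, defaults to `1..n` in label order.
#' @param description Optional character vector of factor descriptions.
#' @param source_note Optional character vector noting where each factor
#'   came from (a citation, "suggested by experts", ...).
#' @return A `determinant_roster`, a data frame with columns `code`,
#'   `label`, `description`, `source_note`.
#' @seealso [validate_roster()], [sop_fixtures()] for the packaged
#'   11-determinant roster of the mass-gathering SOP study.
#' @examples
#' determinant_roster(c("nature of gathering", "type of community"))
#' @export
determinant_roster <- function(labels, codes = seq_along(labels),
                               description = "", source_note = "") {
  out <- data.frame(
    code = as.integer(codes),
    label = as.character(labels),
    description = rep_len(as.character(description), length(labels)),
    source_note = rep_len(as.character(source_note), length(labels)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("determinant_roster", "data.frame")
  rep <- validate_roster(out)
  if (!rep$valid) {
    .stopf("invalid roster: %s", paste(rep$problems, collapse = "; "))
  }
  out
}

#' Validate a determinant roster
#'
#' Report-style check: never errors, returns a report listing duplicate
#' codes, gaps in the `1..n` sequence, empty labels, and rosters that are
#' too small (n >= 2 is required for any pairwise elicitation).
#'
#' @param roster A [determinant_roster()] or a data frame with at least
#'   `code` and `label` columns.
#' @return A list with elements `valid` (logical), `n` (factor count) and
#'   `problems` (character vector, empty when valid).
#' @export
validate_roster <- function(roster) {
  problems <- character()
  code <- as.integer(roster$code)
  label <- as.character(roster$label)
  n <- length(code)
  if (n < 2) problems <- c(problems, sprintf("roster has %d entries, need at least 2", n))
  if (anyDuplicated(code)) {
    problems <- c(problems, sprintf(
      "duplicate codes: %s", .fmt_set(unique(code[duplicated(code)]))))
  }
  expected <- seq_len(max(n, if (n) max(code) else 0L))
  gaps <- setdiff(expected, code)
  if (n >= 1 && (length(gaps) || !setequal(code, seq_len(n)))) {
    problems <- c(problems, sprintf(
      "codes are not contiguous 1..n (missing: %s)",
      .fmt_set(if (length(gaps)) gaps else setdiff(seq_len(n), code))))
  }
  empty <- which(is.na(label) | !nzchar(trimws(label)))
  if (length(empty)) {
    problems <- c(problems, sprintf("empty labels at positions %s", .fmt_set(empty)))
  }
  structure(list(valid = length(problems) == 0L, n = n, problems = problems),
            class = "roster_validation")
}

#' @export
print.roster_validation <- function(x, ...) {
  cat(sprintf("Roster validation: %s (n = %d)\n",
              if (x$valid) "OK" else "INVALID", x$n))
  for (p in x$problems) cat(" -", p, "\n")
  invisible(x)
}

#' @export
print.determinant_roster <- function(x, ...) {
  cat(sprintf("Determinant roster: %d factors\n", nrow(x)))
  print.data.frame(x[, c("code", "label")], row.names = FALSE)
  invisible(x)
}
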