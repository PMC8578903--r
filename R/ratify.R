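#' Ratify a factor roster from expert inclusion votes
#'
#' Each expert casts a yes/no vote per candidate factor; a factor enters
#' the study when its yes-count strictly exceeds its no-count. Ties
#' (yes == no) are resolved by `tie_policy`: the panel in the source study
#' deadlocked 5-5 on one determinant and the factor was kept, so the
#' default is `"include"`. Tied factors are always flagged, whatever
#' their disposition.
#'
#' @param votes A vote table: data frame with columns `factor_code`,
#'   optionally `label`, then one column per expert holding votes coded
#'   `1`/`0`, `yes`/`no` or `Y`/`N` (case-insensitive). See
#'   [read_votes()] for the file format.
#' @param tie_policy `"include"`, `"exclude"` or `"error"`.
#' @return A `ratification` object: list with `included_codes`,
#'   `excluded_codes`, `tallies` (data frame `code`, `yes`, `no`),
#'   `tie_flags`, `rule_used`, `expert_ids`.
#' @examples
#' v <- data.frame(factor_code = 1:2, e1 = c(1, 0), e2 = c(1, 1), e3 = c(1, 0))
#' ratify_determinants(v)$included_codes
#' @export
ratify_determinants <- function(votes, tie_policy = c("include", "exclude", "error")) {
  tie_policy <- match.arg(tie_policy)
  votes <- as.data.frame(votes)
  if (!"factor_code" %in% names(votes)) {
    .stopf("vote table must have a 'factor_code' column")
  }
  expert_cols <- setdiff(names(votes), c("factor_code", "label"))
  if (length(expert_cols) < 1L) .stopf("empty expert panel: no vote columns")
  code <- as.integer(votes$factor_code)
  if (anyDuplicated(code)) .stopf("duplicate factor codes in vote table")

  vote_mat <- vapply(expert_cols, function(cl) .parse_vote(votes[[cl]], cl),
                     logical(nrow(votes)))
  vote_mat <- matrix(vote_mat, nrow = nrow(votes),
                     dimnames = list(code, expert_cols))

  yes <- rowSums(vote_mat)
  no <- ncol(vote_mat) - yes
  tie <- code[yes == no]
  included <- code[yes > no]
  if (length(tie)) {
    if (tie_policy == "error") {
      .stopf("tie vote (yes == no) on factor(s) %s", .fmt_set(tie))
    }
    if (tie_policy == "include") included <- sort(c(included, tie))
  }
  structure(list(
    included_codes = sort(included),
    excluded_codes = sort(setdiff(code, included)),
    tallies = data.frame(code = code, yes = as.integer(yes), no = as.integer(no)),
    tie_flags = tie,
    rule_used = sprintf("yes > no, ties: %s", tie_policy),
    expert_ids = expert_cols
  ), class = "ratification")
}

.parse_vote <- function(x, col) {
  v <- tolower(trimws(as.character(x)))
  yes <- v %in% c("1", "yes", "y", "true")
  no <- v %in% c("0", "no", "n", "false")
  bad <- which(!(yes | no))
  if (length(bad)) {
    .stopf("unparseable vote %s in expert column '%s' (row %d)",
           dQuote(v[bad[1]]), col, bad[1])
  }
  yes
}

#' @export
print.ratification <- function(x, ...) {
  cat(sprintf("Ratification (%d experts, rule: %s)\n",
              length(x$expert_ids), x$rule_used))
  cat(sprintf("  included: %s\n", .fmt_set(x$included_codes)))
  if (length(x$excluded_codes)) {
    cat(sprintf("  excluded: %s\n", .fmt_set(x$excluded_codes)))
  }
  if (length(x$tie_flags)) {
    cat(sprintf("  ties flagged: %s\n", .fmt_set(x$tie_flags)))
  }
  invisible(x)
}
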