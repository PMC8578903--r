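#' Packaged study fixtures: determinants of SOP effectiveness in mass
#' gatherings
#'
#' The package ships, as plain-text CSV, the full printed data of a
#' published ISM + MICMAC study of the determinants of the effectiveness
#' of COVID-19 standard operating procedures in mass gatherings: the
#' 11-determinant roster, the expert inclusion votes (10 experts, one
#' 5-5 tie), the aggregated SSIM, the initial reachability matrix, the
#' final reachability matrix with `1*` transitive marks and its
#' driving/dependence margins, the published 4-level partition and the
#' juxtaposed summary table. The matrices are stored exactly as printed;
#' [audit_closure_consistency()] documents where the printed final
#' matrix departs from a mechanical closure of the initial one.
#'
#' @return A list with elements `roster`, `votes`, `ssim`, `initial_rm`,
#'   `final_rm`, `published_levels` (data frame `code`, `level`) and
#'   `published_summary`.
#' @examples
#' fx <- sop_fixtures()
#' compute_powers(fx$final_rm)
#' @export
sop_fixtures <- function() {
  p <- function(f) system.file("extdata", f, package = "ismic", mustWork = TRUE)
  roster_df <- utils::read.csv(p("sop_determinants.csv"), stringsAsFactors = FALSE)
  list(
    roster = determinant_roster(roster_df$label, roster_df$code,
                                roster_df$description, roster_df$source_note),
    votes = read_votes(p("sop_votes.csv")),
    ssim = read_ssim(p("sop_ssim.csv")),
    initial_rm = read_matrix(p("sop_initial_rm.csv"), flavor = "initial"),
    final_rm = read_matrix(p("sop_final_rm.csv"), flavor = "as_given"),
    published_levels = utils::read.csv(p("sop_levels.csv")),
    published_summary = utils::read.csv(p("sop_summary.csv"), stringsAsFactors = FALSE)
  )
}
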