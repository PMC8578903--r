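#' Pipeline configuration
#'
#' Collects every knob of an end-to-end run in one serializable object.
#' Inputs may be given as file paths (CSV, see the reader functions) or
#' as in-memory objects; exactly one of `ssim`, `matrix` or `judgments`
#' must supply the pairwise structure.
#'
#' @param votes Optional voting sheet (path or data frame) to ratify.
#' @param judgments Optional expert judgments (path, long data frame, or
#'   list of [expert_judgments()]) to aggregate into an SSIM.
#' @param ssim Optional SSIM (path or [ssim()]).
#' @param matrix Optional reachability matrix (path or `ism_rm`),
#'   analysed as given.
#' @param roster Optional roster (path or [determinant_roster()]).
#' @param closure Transitivity mode, see [transitive_closure()].
#' @param boundary MICMAC boundary (`NULL` = n/2).
#' @param ratify_tie,aggregate_tie Tie policies for
#'   [ratify_determinants()] and [aggregate_judgments()].
#' @param audit Run [audit_closure_consistency()] of the final against
#'   the initial matrix.
#' @param out_dir Optional directory: when set, every intermediate
#'   artifact is written there (CSV/DOT/markdown).
#' @param seed Optional integer seed recorded with the run.
#' @param verbose Log each stage with counts via [message()]. Logging is
#'   side-effect only and never changes an artifact.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(votes = NULL, judgments = NULL, ssim = NULL,
                            matrix = NULL, roster = NULL,
                            closure = c("full", "one_pass", "as_given"),
                            boundary = NULL,
                            ratify_tie = c("include", "exclude", "error"),
                            aggregate_tie = c("priority_order", "flag", "error"),
                            audit = TRUE, out_dir = NULL, seed = NULL,
                            verbose = TRUE) {
  structure(list(votes = votes, judgments = judgments, ssim = ssim,
                 matrix = matrix, roster = roster,
                 closure = match.arg(closure), boundary = boundary,
                 ratify_tie = match.arg(ratify_tie),
                 aggregate_tie = match.arg(aggregate_tie),
                 audit = isTRUE(audit), out_dir = out_dir,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

#' Write / read a pipeline configuration as plain text
#'
#' Scalar fields are serialized in DCF (`Field: value`) form; object
#' inputs are replaced by their file paths, so only path-based configs
#' round-trip.
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `read_config` returns a [pipeline_config()].
#' @export
write_config <- function(config, path) {
  flat <- lapply(config, function(v) {
    if (is.null(v)) NA else if (is.character(v) || is.numeric(v) || is.logical(v)) v
    else NA
  })
  write.dcf(data.frame(flat[!is.na(flat)], check.names = FALSE), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  rec <- as.list(as.data.frame(read.dcf(path), stringsAsFactors = FALSE))
  for (f in c("audit", "verbose")) if (f %in% names(rec)) rec[[f]] <- as.logical(rec[[f]])
  for (f in c("boundary", "seed")) if (f %in% names(rec)) rec[[f]] <- as.numeric(rec[[f]])
  do.call(pipeline_config, rec)
}

#' Run the full elicitation-to-report pipeline
#'
#' Stage order: ratify votes (if given) -> aggregate judgments or load
#' the SSIM / matrix -> decode to the initial reachability matrix ->
#' transitive closure -> powers -> level partition -> conical matrix ->
#' digraph -> MICMAC -> summary -> optional audit and report. Every
#' stage logs its counts when `verbose`; stage errors are rethrown with
#' the stage name prefixed and artifacts produced so far are kept in
#' `out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return An `ism_run`: list with `config`, `ratification`,
#'   `aggregation`, `fit` (the [ism()] object), `summary`, `audit`,
#'   `report` (markdown lines).
#' @examples
#' fx <- sop_fixtures()
#' run <- run_pipeline(pipeline_config(ssim = fx$ssim, roster = fx$roster,
#'                                     closure = "full", verbose = FALSE))
#' run$summary
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- function(...) if (config$verbose) message(sprintf(...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      .stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  is_path <- function(x) is.character(x) && length(x) == 1L && !is.matrix(x)
  out <- list(config = config)
  if (!is.null(config$seed)) set.seed(config$seed)

  roster <- config$roster
  if (is_path(roster)) {
    roster <- stage("roster", {
      df <- utils::read.csv(roster, stringsAsFactors = FALSE)
      determinant_roster(df$label, df$code,
                         if (is.null(df$description)) "" else df$description,
                         if (is.null(df$source_note)) "" else df$source_note)
    })
  }

  if (!is.null(config$votes)) {
    votes <- if (is_path(config$votes)) read_votes(config$votes) else config$votes
    out$ratification <- stage("ratify", ratify_determinants(votes, config$ratify_tie))
    log("ratify: %d/%d factors included (%d tie(s))",
        length(out$ratification$included_codes), nrow(out$ratification$tallies),
        length(out$ratification$tie_flags))
  }

  s <- NULL; m <- NULL
  if (!is.null(config$judgments)) {
    j <- if (is_path(config$judgments)) read_judgments(config$judgments)
         else config$judgments
    out$aggregation <- stage("aggregate", aggregate_judgments(j, config$aggregate_tie))
    s <- out$aggregation$ssim
    log("aggregate: %d pairs, %d tie(s)", nrow(out$aggregation$tallies),
        sum(out$aggregation$tallies$tie))
  } else if (!is.null(config$ssim)) {
    s <- if (is_path(config$ssim)) read_ssim(config$ssim) else config$ssim
  } else if (!is.null(config$matrix)) {
    m <- if (is_path(config$matrix)) read_matrix(config$matrix) else config$matrix
  } else {
    .stopf("config supplies none of judgments / ssim / matrix")
  }

  out$fit <- stage("ism", ism(if (is.null(m)) s else m, closure = config$closure,
                              boundary = config$boundary, roster = roster))
  log("ism: %d factors, %d links, %d levels (%s closure)",
      nrow(out$fit$rm_final), sum(rm_binary(out$fit$rm_final)),
      length(out$fit$levels$levels), config$closure)
  out$summary <- ism_summary(out$fit$levels, out$fit$micmac, roster = roster,
                             ratification = out$ratification)

  if (config$audit) {
    out$audit <- stage("audit", audit_closure_consistency(
      out$fit$rm_final, out$fit$rm_initial))
    log("audit: %d cell(s) beyond one_pass, %d beyond full",
        nrow(out$audit$vs_one_pass$extra), nrow(out$audit$vs_full$extra))
  }
  out$report <- render_report(out)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(f) file.path(config$out_dir, f)
    if (!is.null(s)) write_ssim(s, fp("ssim.csv"))
    write_matrix(out$fit$rm_initial, fp("initial_rm.csv"))
    write_matrix(out$fit$rm_final, fp("final_rm.csv"))
    write_matrix(out$fit$conical$matrix, fp("conical_rm.csv"))
    write_summary(out$summary, fp("summary.csv"))
    write_dot(out$fit$digraph, fp("digraph.dot"))
    writeLines(out$report, fp("report.md"))
    log("artifacts written to %s", config$out_dir)
  }
  class(out) <- "ism_run"
  out
}

#' @export
print.ism_run <- function(x, ...) {
  cat("ISM pipeline run\n")
  print(x$fit)
  invisible(x)
}

#' Render a markdown report of a pipeline run
#'
#' Tables in elicitation order: voting tallies, SSIM, initial and final
#' reachability matrices with powers, level-partition iterations,
#' conical matrix, model levels, MICMAC classification and the
#' juxtaposed summary; a discrepancy ledger is appended when the audit
#' ran. Rendering is pure: regenerating from the same artifacts yields
#' byte-identical output.
#'
#' @param artifacts An `ism_run` (or compatible list with a `fit`).
#' @return Character vector of markdown lines.
#' @export
render_report <- function(artifacts) {
  fit <- artifacts$fit
  lines <- c("# Interpretive structural modeling report", "")
  grid_md <- function(m, star = NULL) {
    cells <- matrix(as.character(unclass(m)), nrow(m))
    if (!is.null(star)) cells[star == "transitive"] <- "1\\*"
    cells[is.na(cells)] <- ""
    df <- data.frame(code = rownames(m), cells, check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("code", colnames(m))
    .md_table(df)
  }
  if (!is.null(artifacts$ratification)) {
    r <- artifacts$ratification
    lines <- c(lines, "## Voting sheet", "",
               .md_table(data.frame(code = r$tallies$code, yes = r$tallies$yes,
                                    no = r$tallies$no,
                                    decision = ifelse(r$tallies$code %in%
                                                        r$included_codes,
                                                      "Included", "Excluded"))),
               "")
  }
  if (!is.null(fit$ssim)) {
    lines <- c(lines, "## Structural self-interaction matrix", "",
               grid_md(fit$ssim), "")
  }
  lines <- c(lines, "## Initial reachability matrix", "",
             grid_md(fit$rm_initial, attr(fit$rm_initial, "provenance")), "",
             "## Final reachability matrix", "",
             grid_md(fit$rm_final, attr(fit$rm_final, "provenance")), "",
             "## Driving and dependence powers", "",
             .md_table(fit$powers), "")
  for (it in seq_along(fit$levels$trace)) {
    lines <- c(lines, sprintf("## Iteration %s", .roman(it)), "",
               .md_table(transform(fit$levels$trace[[it]],
                                   level = ifelse(leveled, .roman(it), ""))), "")
  }
  lines <- c(lines, "## Conical matrix", "",
             sprintf("Level order: %s", paste(fit$conical$order, collapse = ", ")),
             "", grid_md(fit$conical$matrix,
                         attr(fit$conical$matrix, "provenance")), "",
             "## Model levels", "")
  for (k in seq_along(fit$levels$levels)) {
    lines <- c(lines, sprintf("- Level %s = {%s}", names(fit$levels$levels)[k],
                              .fmt_set(fit$levels$levels[[k]])))
  }
  lines <- c(lines, "", "## MICMAC classification", "",
             .md_table(fit$micmac), "")
  if (!is.null(artifacts$summary)) {
    s <- artifacts$summary
    lines <- c(lines, "## Summarized and juxtaposed results", "",
               .md_table(data.frame(
                 code = s$code, label = s$label, driving = s$driving,
                 dependence = s$dependence,
                 effectiveness = .ascii_minus(as.character(s$net_influence)),
                 cluster = s$quadrant, level = s$level,
                 comment = ifelse(s$key_factor, "Key factor", ""))), "")
  }
  lines <- c(lines, "## Discrepancy ledger", "")
  if (is.null(artifacts$audit)) {
    lines <- c(lines, "Audit not run.")
  } else {
    a <- artifacts$audit
    fmt <- function(df) paste(sprintf("(%d,%d)", df$row, df$col), collapse = " ")
    if (!nrow(a$vs_one_pass$extra) && !nrow(a$vs_one_pass$missing) &&
        !nrow(a$vs_full$extra) && !nrow(a$vs_full$missing)) {
      lines <- c(lines, "No discrepancies between the analysed matrix and its closures.")
    } else {
      if (nrow(a$vs_one_pass$extra)) lines <- c(lines, sprintf(
        "- Cells present as given but unsupported by any length-2 path: %s",
        fmt(a$vs_one_pass$extra)))
      if (nrow(a$vs_one_pass$missing)) lines <- c(lines, sprintf(
        "- Length-2 compositions absent from the matrix as given: %s",
        fmt(a$vs_one_pass$missing)))
      if (nrow(a$vs_full$extra)) lines <- c(lines, sprintf(
        "- Cells present as given but outside the full closure: %s",
        fmt(a$vs_full$extra)))
      if (nrow(a$vs_full$missing)) lines <- c(lines, sprintf(
        "- Full-closure cells absent from the matrix as given: %s",
        fmt(a$vs_full$missing)))
      for (mode in names(a$by_mode)) {
        lv <- a$by_mode[[mode]]$levels
        lines <- c(lines, sprintf(
          "- Partition under %s: %s", mode,
          if (is.character(lv)) "stalls (matrix not closed)"
          else paste(vapply(lv$levels, .fmt_set, ""), collapse = " | ")))
      }
    }
  }
  lines
}
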