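# CSV readers/writers for every pipeline artifact. The dialect is plain
# comma-separated UTF-8; reachability cells use the `1*` token for
# transitive provenance, SSIM files carry letters in the upper triangle
# and leave the rest blank. Readers are strict and name the offending
# row/column; writers and readers round-trip bit-exact.

#' Read / write an SSIM CSV
#'
#' Wide format: first header cell empty, remaining header = factor
#' codes; one row per factor, first cell the row code, upper-triangle
#' cells a V/A/X/O letter, diagonal and lower triangle empty. Any letter
#' below the diagonal is rejected.
#'
#' @param path File path.
#' @return [read_ssim()] returns an [ssim()]; `write_ssim` returns
#'   `path` invisibly.
#' @export
read_ssim <- function(path) {
  tab <- .read_grid(path, "SSIM")
  m <- tab$cells
  m[m == ""] <- NA_character_
  low <- which(lower.tri(m, diag = TRUE) & !is.na(m), arr.ind = TRUE)
  if (nrow(low)) {
    .stopf("SSIM file %s: upper triangle only, found entry at row %s column %s",
           path, tab$codes[low[1, 1]], tab$codes[low[1, 2]])
  }
  dimnames(m) <- list(tab$codes, tab$codes)
  ssim(m)
}

#' @rdname read_ssim
#' @param s An [ssim()] to write.
#' @export
write_ssim <- function(s, path) {
  m <- unclass(s)
  m[is.na(m)] <- ""
  .write_grid(m, path)
}

#' Read / write a reachability-matrix CSV
#'
#' Same grid layout as the SSIM files; cells are `0`, `1` or `1*`
#' (asterisk marking transitive provenance). A zero diagonal cell is
#' normalized to 1 (self-reachability convention) with a warning.
#'
#' @param path File path.
#' @param flavor Flavor tag to attach; matrices read from files default
#'   to `"as_given"` since their provenance is whatever was printed.
#' @return [read_matrix()] returns an `ism_rm`; `write_matrix` returns
#'   `path` invisibly.
#' @export
read_matrix <- function(path, flavor = "as_given") {
  tab <- .read_grid(path, "matrix")
  cells <- tab$cells
  ok <- matrix(cells %in% c("0", "1", "1*"), nrow(cells))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    .stopf("matrix file %s: cell value %s at row %s column %s (expected 0, 1 or 1*)",
           path, dQuote(cells[!ok][1]), tab$codes[bad[1]], tab$codes[bad[2]])
  }
  b <- matrix(as.integer(cells != "0"), nrow(cells), ncol(cells))
  prov <- matrix(ifelse(cells == "1*", "transitive",
                        ifelse(cells == "1", "direct", "absent")),
                 nrow(cells))
  if (any(diag(b) == 0L)) {
    .warnf("matrix file %s: zero diagonal cell(s) at %s normalized to 1 (direct)",
           path, .fmt_set(tab$codes[diag(b) == 0L]))
  }
  reachability_matrix(b, {diag(prov) <- "direct"; prov},
                      flavor = flavor, codes = tab$codes)
}

#' @rdname read_matrix
#' @param m An `ism_rm` to write.
#' @export
write_matrix <- function(m, path) {
  cells <- matrix(as.character(rm_binary(m)), nrow(m))
  cells[attr(m, "provenance") == "transitive"] <- "1*"
  dimnames(cells) <- dimnames(m)
  .write_grid(cells, path)
}

#' Read / write a voting-sheet CSV
#'
#' Header `factor_code,label,<expert_id>,...`; vote cells `1`/`0`
#' (also `yes`/`no`, `Y`/`N`, case-insensitive).
#'
#' @param path File path.
#' @return A data frame suitable for [ratify_determinants()].
#' @export
read_votes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  if (!"factor_code" %in% names(df)) {
    .stopf("vote file %s: missing 'factor_code' header", path)
  }
  df$factor_code <- as.integer(df$factor_code)
  df
}

#' @rdname read_votes
#' @param votes Vote table to write.
#' @export
write_votes <- function(votes, path) {
  utils::write.csv(votes, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a long-form expert judgment CSV
#'
#' Columns `expert_id,row_code,col_code,symbol`, one row per expert and
#' pair, strict upper triangle (`row_code < col_code`).
#'
#' @param path File path.
#' @return A long data frame accepted by [aggregate_judgments()].
#' @export
read_judgments <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        strip.white = TRUE)
  need <- c("expert_id", "row_code", "col_code", "symbol")
  if (!all(need %in% names(df))) {
    .stopf("judgment file %s: need columns %s", path, paste(need, collapse = ","))
  }
  df$row_code <- as.integer(df$row_code)
  df$col_code <- as.integer(df$col_code)
  df$symbol <- toupper(trimws(df$symbol))
  df
}

#' @rdname read_judgments
#' @param judgments Long judgment table to write.
#' @export
write_judgments <- function(judgments, path) {
  utils::write.csv(judgments, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write an analysis summary table
#'
#' Column order mirrors the published juxtaposed-results layout:
#' code, label, driving, dependence, effectiveness (net influence),
#' cluster (quadrant), level, comment. Negative values are written with
#' an ASCII minus.
#'
#' @param summary An [ism_summary()].
#' @param path File path.
#' @param format `"csv"` or `"markdown"`.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path, format = c("csv", "markdown")) {
  format <- match.arg(format)
  tab <- data.frame(code = summary$code, label = summary$label,
                    driving = summary$driving, dependence = summary$dependence,
                    effectiveness = .ascii_minus(as.character(summary$net_influence)),
                    cluster = summary$quadrant, level = summary$level,
                    comment = ifelse(summary$key_factor, "Key factor", ""),
                    stringsAsFactors = FALSE)
  if (format == "csv") {
    utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  } else {
    writeLines(.md_table(tab), path)
  }
  invisible(path)
}

.md_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep(" --- ", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}

# Shared grid reader: square table, first row/column = factor codes.
.read_grid <- function(path, what) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) .stopf("%s file %s is empty", what, path)
  cells <- lapply(lines, function(l) strsplit(l, ",", fixed = TRUE)[[1]])
  width <- max(lengths(cells))
  cells <- t(vapply(cells, function(r) c(r, rep("", width - length(r))),
                    character(width)))
  header <- trimws(cells[1, -1])
  codes <- suppressWarnings(as.integer(header))
  if (any(is.na(codes))) {
    .stopf("%s file %s: non-numeric factor code %s in header",
           what, path, dQuote(header[is.na(codes)][1]))
  }
  body <- cells[-1, , drop = FALSE]
  if (nrow(body) != length(codes)) {
    .stopf("%s file %s is not square: %d header codes but %d rows",
           what, path, length(codes), nrow(body))
  }
  row_codes <- suppressWarnings(as.integer(trimws(body[, 1])))
  if (!identical(row_codes, codes)) {
    .stopf("%s file %s: row codes do not match header codes", what, path)
  }
  list(codes = codes, cells = matrix(trimws(body[, -1, drop = FALSE]),
                                     length(codes), length(codes)))
}

.write_grid <- function(cells, path) {
  codes <- rownames(cells)
  lines <- c(paste(c("", codes), collapse = ","),
             vapply(seq_along(codes), function(i) {
               paste(c(codes[i], cells[i, ]), collapse = ",")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}
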