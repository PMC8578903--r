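#' Fit an interpretive structural model
#'
#' The central modelling function: takes pairwise expert structure — an
#' [ssim()], a reachability matrix, or a raw 0/1 matrix — and runs the
#' full ISM pipeline: decoding to the initial reachability matrix (for
#' SSIM input), transitive closure under an explicit `closure` mode,
#' driving/dependence powers, level partitioning by iterated top-element
#' removal, the conical (level-ordered) matrix, the transitively reduced
#' level-layered digraph, and the MICMAC quadrant classification.
#'
#' `closure = "full"` (default) is the mathematically closed analysis.
#' `"one_pass"` adds only length-2 compositions, which is what one
#' manual round of transitivity marking produces. `"as_given"` analyses
#' the matrix exactly as supplied — the right mode for reproducing a
#' published final reachability matrix, whose hand-marked transitive
#' cells need not equal any mechanical closure.
#'
#' @param x An `ssim`, an `ism_rm`, or a square 0/1 matrix.
#' @param closure `"full"`, `"one_pass"` or `"as_given"`.
#' @param boundary MICMAC quadrant boundary; default `n/2`.
#' @param roster Optional [determinant_roster()] for labels.
#' @return An object of class `ism`: list with components `ssim` (or
#'   `NULL`), `rm_initial`, `rm_final`, `closure`, `powers`, `levels`,
#'   `conical`, `digraph`, `micmac`, `summary`, `roster`, `call`.
#' @examples
#' fx <- sop_fixtures()
#' fit <- ism(fx$ssim, closure = "full", roster = fx$roster)
#' summary(fit)
#' @export
ism <- function(x, closure = c("full", "one_pass", "as_given"),
                boundary = NULL, roster = NULL) {
  closure <- match.arg(closure)
  cl <- match.call()
  s <- NULL
  if (inherits(x, "ssim")) {
    s <- x
    rm0 <- ssim_to_initial_rm(x)
  } else if (inherits(x, "ism_rm")) {
    rm0 <- x
  } else {
    rm0 <- reachability_matrix(x, flavor = "as_given")
  }
  rmf <- transitive_closure(rm0, closure)
  powers <- compute_powers(rmf)
  n <- nrow(rmf)
  cfg <- micmac_config(n, boundary = if (is.null(boundary)) n / 2 else boundary)
  lev <- partition_levels(rmf)
  structure(list(
    ssim = s,
    rm_initial = rm0,
    rm_final = rmf,
    closure = closure,
    powers = powers,
    levels = lev,
    conical = build_conical_matrix(rmf, lev),
    digraph = build_digraph(rmf, lev),
    micmac = classify_factors(powers, cfg),
    roster = roster,
    call = cl
  ), class = "ism")
}

#' @export
print.ism <- function(x, ...) {
  cat("Interpretive structural model\n")
  cat(sprintf("  factors: %d, closure: %s\n", nrow(x$rm_final), x$closure))
  print(x$levels)
  tab <- table(factor(x$micmac$quadrant,
                      c("independent", "dependent", "linkage", "autonomous")))
  cat("  MICMAC:", paste(sprintf("%s %d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a fitted interpretive structural model
#'
#' @param object An [ism()] fit.
#' @param ... Passed on (unused).
#' @return A `summary.ism` object wrapping the per-factor
#'   [ism_summary()] table and the key-factor codes.
#' @export
summary.ism <- function(object, ...) {
  tab <- ism_summary(object$levels, object$micmac, roster = object$roster)
  structure(list(table = tab, key_factors = tab$code[tab$key_factor],
                 closure = object$closure, n_levels = length(object$levels$levels)),
            class = "summary.ism")
}

#' @export
print.summary.ism <- function(x, ...) {
  cat(sprintf("ISM summary (%s closure): %d levels, key factor(s): %s\n",
              x$closure, x$n_levels,
              if (length(x$key_factors)) .fmt_set(x$key_factors) else "none"))
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Level assignment of a fitted model
#'
#' @param x An [ism()] fit.
#' @return Named integer vector: model level (1 = Level I, the top) per
#'   factor code.
#' @export
levels.ism <- function(x) x$levels$assignment

#' Plot a fitted interpretive structural model
#'
#' `type = "micmac"` draws the driving-dependence diagram: one point per
#' factor at (dependence, driving), quadrant boundaries at the
#' configured threshold, quadrant names in the corners. `type = "model"`
#' draws the level-layered digraph with the reduced edge set, one row of
#' nodes per level, Level I on top.
#'
#' @param x An [ism()] fit.
#' @param type `"micmac"` or `"model"`.
#' @param ... Further graphical parameters passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.ism <- function(x, type = c("micmac", "model"), ...) {
  type <- match.arg(type)
  if (type == "micmac") .plot_micmac(x$micmac, ...) else .plot_model(x$digraph, ...)
  invisible(x)
}

.plot_micmac <- function(mc, ...) {
  cfg <- attr(mc, "config")
  n <- cfg$n
  graphics::plot(mc$dependence, mc$driving, xlim = c(0, n + 1), ylim = c(0, n + 1),
                 xlab = "Dependence power", ylab = "Driving power",
                 main = "MICMAC driving-dependence diagram", pch = 19, ...)
  graphics::abline(h = cfg$boundary, v = cfg$boundary, lty = 2)
  graphics::text(mc$dependence, mc$driving, mc$code, pos = 3, cex = 0.8)
  lab <- c("autonomous", "independent", "dependent", "linkage")
  graphics::text(c(0.5, 0.5, n + 0.5, n + 0.5), c(0.5, n + 0.5, 0.5, n + 0.5),
                 lab, adj = c(0.5, 0.5), col = "grey40", cex = 0.8)
}

.plot_model <- function(g, ...) {
  L <- max(g$level)
  xs <- numeric(length(g$members))
  for (lv in seq_len(L)) {
    ids <- which(g$level == lv)
    xs[ids] <- seq_along(ids) / (length(ids) + 1)
  }
  ys <- (L - g$level + 1) / L
  graphics::plot(NA, xlim = 0:1, ylim = c(0, 1.1), axes = FALSE,
                 xlab = "", ylab = "", main = "ISM model", ...)
  for (r in seq_len(nrow(g$edges))) {
    graphics::arrows(xs[g$edges$from[r]], ys[g$edges$from[r]],
                     xs[g$edges$to[r]], ys[g$edges$to[r]],
                     length = 0.08, col = "grey50")
  }
  lab <- vapply(g$members, function(m) paste(m, collapse = ","), "")
  graphics::rect(xs - 0.04, ys - 0.03, xs + 0.04, ys + 0.03, col = "white")
  graphics::text(xs, ys, lab, cex = 0.9)
  graphics::text(rep(0.02, L), (L - seq_len(L) + 1) / L,
                 paste("Level", .roman(seq_len(L))), adj = 0, cex = 0.8,
                 col = "grey40")
}
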