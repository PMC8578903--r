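#' MICMAC configuration
#'
#' The scale-centric quadrant rule: the driving/dependence axes both run
#' over `1..n`, the plane is split at `boundary` (default `n/2`), and a
#' power counts as "high" when it is strictly greater than the boundary.
#'
#' @param n Factor count.
#' @param boundary Threshold; must satisfy `0 < boundary < n`.
#' @return A `micmac_config` list.
#' @export
micmac_config <- function(n, boundary = n / 2) {
  n <- as.integer(n)
  if (!(boundary > 0 && boundary < n)) {
    .stopf("boundary must lie strictly between 0 and n = %d", n)
  }
  structure(list(n = n, boundary = boundary, high_rule = "strictly greater"),
            class = "micmac_config")
}

#' Classify factors into MICMAC quadrants
#'
#' Each factor is plotted at (dependence, driving) and labeled:
#' `independent` (high driving, low dependence — the critical drivers),
#' `dependent` (low driving, high dependence — driven by the rest),
#' `linkage` (both high — unstable, any action feeds back) or
#' `autonomous` (both low — weakly coupled to the system). "High" means
#' strictly greater than `config$boundary`. The net influence
#' (driving minus dependence) is carried per factor.
#'
#' @param powers An [compute_powers()] result (or data frame with
#'   `code`, `driving`, `dependence`).
#' @param config A [micmac_config()]; defaults to `micmac_config(n)` for
#'   the implied factor count.
#' @return A `micmac` data frame with columns `code`, `driving`,
#'   `dependence`, `net_influence`, `quadrant`; the config is attached as
#'   attribute `config`.
#' @examples
#' pw <- data.frame(code = 1:2, driving = c(2, 1), dependence = c(1, 2))
#' classify_factors(pw, micmac_config(2, boundary = 1.5))
#' @export
classify_factors <- function(powers, config = NULL) {
  powers <- as.data.frame(powers)
  n <- nrow(powers)
  if (is.null(config)) config <- micmac_config(n)
  if (config$n != n) {
    .stopf("config is for n = %d factors but powers cover %d", config$n, n)
  }
  hi_drv <- powers$driving > config$boundary
  hi_dep <- powers$dependence > config$boundary
  quadrant <- ifelse(hi_drv & hi_dep, "linkage",
              ifelse(hi_drv, "independent",
              ifelse(hi_dep, "dependent", "autonomous")))
  out <- data.frame(code = powers$code,
                    driving = powers$driving,
                    dependence = powers$dependence,
                    net_influence = net_influence(powers),
                    quadrant = quadrant,
                    stringsAsFactors = FALSE)
  attr(out, "config") <- config
  class(out) <- c("micmac", "data.frame")
  out
}

#' Net influence of a factor
#'
#' Driving power minus dependence power — positive for net drivers,
#' negative for net driven factors; it sums to zero over any square
#' reachability matrix.
#'
#' @param driving Driving power(s), or a data frame with `driving` and
#'   `dependence` columns.
#' @param dependence Dependence power(s) when `driving` is numeric.
#' @return Integer vector of net influences.
#' @export
net_influence <- function(driving, dependence = NULL) {
  if (is.data.frame(driving) || is.list(driving)) {
    dependence <- driving$dependence
    driving <- driving$driving
  }
  as.integer(driving) - as.integer(dependence)
}

#' Juxtaposed summary of an ISM + MICMAC analysis
#'
#' One row per factor: code, label, driving and dependence power, net
#' influence, quadrant, model level (Roman), and a key-factor flag
#' marking the factor(s) at the deepest level that also classify as
#' independent — the determinants the method singles out for immediate
#' attention.
#'
#' @param partition An [partition_levels()] result.
#' @param micmac A [classify_factors()] result.
#' @param roster Optional [determinant_roster()] supplying labels.
#' @param ratification Optional [ratify_determinants()] result; when
#'   given, its included codes must match the analysed factors.
#' @return An `ism_summary` data frame with columns `code`, `label`,
#'   `driving`, `dependence`, `net_influence`, `quadrant`, `level`,
#'   `key_factor`.
#' @export
ism_summary <- function(partition, micmac, roster = NULL, ratification = NULL) {
  codes <- micmac$code
  if (!setequal(codes, as.integer(names(partition$assignment)))) {
    .stopf("level partition and MICMAC results cover different factors")
  }
  if (!is.null(ratification) && !setequal(codes, ratification$included_codes)) {
    .stopf("ratified factor set does not match the analysed factors")
  }
  label <- rep("", length(codes))
  if (!is.null(roster)) {
    if (!all(codes %in% roster$code)) {
      .stopf("roster does not cover all analysed factors")
    }
    label <- roster$label[match(codes, roster$code)]
  }
  lev <- partition$assignment[as.character(codes)]
  deepest <- max(lev)
  out <- data.frame(code = codes, label = label,
                    driving = micmac$driving, dependence = micmac$dependence,
                    net_influence = micmac$net_influence,
                    quadrant = micmac$quadrant,
                    level = .roman(lev),
                    key_factor = lev == deepest & micmac$quadrant == "independent",
                    stringsAsFactors = FALSE)
  out <- out[order(out$code), ]
  rownames(out) <- NULL
  class(out) <- c("ism_summary", "data.frame")
  out
}

#' @export
print.micmac <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("MICMAC classification (n = %d, boundary = %g, high = %s)\n",
              cfg$n, cfg$boundary, cfg$high_rule))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
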