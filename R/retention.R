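#' Convert retardation factors to R_M values
#'
#' The TLC retention transform \eqn{R_M = \log_{10}(1/R_F - 1)}. \eqn{R_M}
#' is the planar-chromatography analogue of a log retention factor and is,
#' for well-behaved reversed-phase systems, linear in the organic-modifier
#' content of the mobile phase.
#'
#' @param rf numeric vector of retardation factors, strictly inside (0, 1).
#' @return numeric vector of R_M values. `rf = 0.5` maps to exactly 0;
#'   the transform is strictly decreasing in `rf`.
#' @seealso [rm_to_rf()] for the inverse, [fit_sw()] for the retention model.
#' @export
#' @examples
#' rf_to_rm(c(0.25, 0.5, 0.75))
rf_to_rm <- function(rf) {
  if (!is.numeric(rf)) stop("'rf' must be numeric", call. = FALSE)
  bad <- which(!is.finite(rf) | rf <= 0 | rf >= 1)
  if (length(bad)) {
    stop(sprintf(
      "R_M is undefined for R_F outside (0, 1): offending measurement%s %s (value%s %s)",
      if (length(bad) > 1) "s" else "",
      paste(bad, collapse = ", "),
      if (length(bad) > 1) "s" else "",
      paste(format(rf[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  log10(1 / rf - 1)
}

#' Convert R_M values back to retardation factors
#'
#' Inverse of [rf_to_rm()]: \eqn{R_F = 1/(1 + 10^{R_M})}.
#'
#' @param rm numeric vector of R_M values.
#' @return retardation factors in (0, 1).
#' @export
rm_to_rf <- function(rm) {
  if (!is.numeric(rm)) stop("'rm' must be numeric", call. = FALSE)
  1 / (1 + 10^rm)
}

#' Construct a retention series
#'
#' A retention series holds, for one compound in one modifier system, the
#' aggregated \eqn{(\varphi, R_M)} points that the retention models are
#' fitted to.
#'
#' @param compound_id compound identifier.
#' @param modifier `"methanol"` or `"acetone"`.
#' @param phi numeric vector of modifier volume fractions in \[0, 1\].
#' @param rm numeric vector of R_M values, same length as `phi`.
#' @return an object of class `retention_series`.
#' @export
retention_series <- function(compound_id, modifier, phi, rm) {
  modifier <- match.arg(modifier, c("methanol", "acetone"))
  stopifnot(length(phi) == length(rm))
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("'phi' values must lie in [0, 1]", call. = FALSE)
  ord <- order(phi)
  structure(
    list(compound_id = as.character(compound_id), modifier = modifier,
         points = data.frame(phi = phi[ord], rm = rm[ord])),
    class = "retention_series"
  )
}

#' @export
print.retention_series <- function(x, ...) {
  cat(sprintf("Retention series: %s (%s-water), %d points\n",
              x$compound_id, x$modifier, nrow(x$points)))
  print(x$points, row.names = FALSE)
  invisible(x)
}

#' Aggregate replicate spots into a retention series
#'
#' Chromatograms are typically spotted in triplicate. Replicate R_F values
#' at each modifier fraction are combined and transformed to R_M. The
#' default combines on the measured scale (mean R_F, then transform);
#' `aggregate = "rm"` transforms each replicate first and averages the R_M
#' values instead.
#'
#' @param measurements data frame with columns `compound`, `modifier`,
#'   `phi`, `rf`, `replicate` (see [read_measurements()]). All rows must
#'   belong to one compound and one modifier.
#' @param aggregate `"rf"` (default) or `"rm"`.
#' @return a [retention_series()] with one point per distinct `phi`,
#'   sorted by `phi`. Measurements with `rf` exactly 0 or 1 are dropped
#'   with a warning (the transform is undefined there).
#' @export
aggregate_replicates <- function(measurements, aggregate = c("rf", "rm")) {
  aggregate <- match.arg(aggregate)
  req <- c("compound", "modifier", "phi", "rf")
  if (!all(req %in% names(measurements)))
    stop("measurements must have columns compound, modifier, phi, rf",
         call. = FALSE)
  if (length(unique(measurements$compound)) != 1L ||
      length(unique(measurements$modifier)) != 1L)
    stop("aggregate_replicates() expects a single compound and modifier; ",
         "got mixed groups", call. = FALSE)
  end <- measurements$rf <= 0 | measurements$rf >= 1
  if (any(end)) {
    warning(sprintf(
      "dropped %d measurement(s) with R_F at or beyond the endpoints {0, 1}",
      sum(end)), call. = FALSE)
    measurements <- measurements[!end, , drop = FALSE]
  }
  if (!nrow(measurements))
    stop("no usable measurements after endpoint filtering", call. = FALSE)
  if (aggregate == "rf") {
    m <- tapply(measurements$rf, measurements$phi, mean)
    rm <- rf_to_rm(as.numeric(m))
  } else {
    m <- tapply(rf_to_rm(measurements$rf), measurements$phi, mean)
    rm <- as.numeric(m)
  }
  retention_series(measurements$compound[1L], measurements$modifier[1L],
                   phi = as.numeric(names(m)), rm = rm)
}

#' Fit the Soczewinski-Wachtmeister retention model
#'
#' Ordinary least squares of R_M on the modifier volume fraction,
#' \eqn{R_M = R_{MW} - S\varphi}. The intercept `rmws` is the retention
#' extrapolated to pure water and is the principal chromatographic
#' lipophilicity descriptor; `slope_s` (\eqn{S > 0} for reversed-phase
#' systems) measures solvent-strength sensitivity; their ratio
#' \eqn{\varphi_0 = R_{MW}/S} is the modifier fraction at which the analyte
#' migrates exactly half the development distance.
#'
#' @param series a [retention_series()], or a data frame with columns
#'   `phi` and `rm`.
#' @return an object of class `sw_fit` with elements `rmws`, `slope_s`,
#'   `phi0`, `r` (Pearson correlation of phi and R_M; negative for
#'   well-behaved data), `s_resid`, `n`, and `nonphysical` (`TRUE`, with a
#'   warning, when the fitted `slope_s` is not positive).
#' @export
#' @examples
#' s <- retention_series("x", "methanol", seq(0.6, 1, 0.1), 2 - 3 * seq(0.6, 1, 0.1))
#' fit_sw(s)
fit_sw <- function(series) {
  pts <- if (inherits(series, "retention_series")) series$points else series
  if (!all(c("phi", "rm") %in% names(pts)))
    stop("series must supply 'phi' and 'rm'", call. = FALSE)
  phi <- pts$phi; rm <- pts$rm
  if (length(unique(phi)) < 3L)
    stop("insufficient data: the retention model needs >= 3 distinct ",
         "modifier fractions, got ", length(unique(phi)), call. = FALSE)
  if (var(phi) == 0)
    stop("degenerate design: no variance in the modifier fraction",
         call. = FALSE)
  fit <- lm(rm ~ phi)
  sm <- suppressWarnings(summary(fit))  # noiseless series trip lm's perfect-fit warning
  rmws <- unname(coef(fit)[1L])
  slope_s <- -unname(coef(fit)[2L])
  nonphysical <- slope_s <= 0
  if (nonphysical)
    warning("fitted slope S <= 0: retention increases with modifier ",
            "content, which is non-physical for reversed-phase data",
            call. = FALSE)
  structure(
    list(
      compound_id = if (inherits(series, "retention_series")) series$compound_id else NA_character_,
      modifier = if (inherits(series, "retention_series")) series$modifier else NA_character_,
      rmws = rmws,
      slope_s = slope_s,
      phi0 = if (slope_s != 0) rmws / slope_s else NA_real_,
      r = cor(phi, rm),
      s_resid = sm$sigma,
      n = length(phi),
      nonphysical = nonphysical
    ),
    class = "sw_fit"
  )
}

#' @export
print.sw_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Soczewinski-Wachtmeister fit%s\n",
              if (!is.na(x$compound_id)) paste0(": ", x$compound_id,
                                                " (", x$modifier, "-water)") else ""))
  cat(sprintf("  R_M = %.*f - %.*f * phi   (n = %d, r = %.3f, s = %.3f)\n",
              digits, x$rmws, digits, x$slope_s, x$n, x$r, x$s_resid))
  cat(sprintf("  phi0 = %.3f%s\n", x$phi0,
              if (x$nonphysical) "   [warning: non-physical slope]" else ""))
  invisible(x)
}

#' Isocratic hydrophobicity index phi0
#'
#' \eqn{\varphi_0 = R_{MW}/S}: the organic-modifier volume fraction at which
#' R_M = 0, i.e. at which the analyte would migrate exactly half of the
#' solvent-front distance.
#'
#' @param fit an `sw_fit` object, or a numeric R_MW value (then `slope_s`
#'   must be given).
#' @param slope_s slope of the retention model (ignored when `fit` is an
#'   `sw_fit`).
#' @return the volume fraction `rmws / slope_s`.
#' @export
compute_phi0 <- function(fit, slope_s = NULL) {
  if (inherits(fit, "sw_fit")) {
    rmws <- fit$rmws; slope_s <- fit$slope_s
  } else {
    rmws <- fit
    if (is.null(slope_s)) stop("'slope_s' required", call. = FALSE)
  }
  if (slope_s == 0)
    stop("phi0 is undefined for slope S = 0", call. = FALSE)
  rmws / slope_s
}
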