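#' Solvent constants for mole-fraction conversion
#'
#' Molar masses (g/mol) and densities (g/mL, ~22 degrees C) used by
#' [volume_to_mole_fraction()]. Kept in one place so the conversion is
#' auditable and overridable.
#'
#' @return named list with entries `water`, `methanol`, `acetone`, each a
#'   list with `M` (molar mass) and `rho` (density).
#' @export
solvent_constants <- function() {
  list(
    water    = list(M = 18.015, rho = 0.9978),
    methanol = list(M = 32.04,  rho = 0.7914),
    acetone  = list(M = 58.08,  rho = 0.7845)
  )
}

#' Convert modifier volume fraction to mole fraction
#'
#' Ideal (additive-volume) mixing: with organic density/molar mass
#' \eqn{\rho_o, M_o} and water \eqn{\rho_w, M_w},
#' \deqn{x = \frac{\varphi \rho_o / M_o}{\varphi \rho_o / M_o + (1-\varphi)\rho_w / M_w}.}
#' Strictly increasing in \eqn{\varphi}, with the endpoints 0 and 1
#' preserved.
#'
#' @param phi volume fraction(s) of the organic modifier, in \[0, 1\].
#' @param modifier `"methanol"` or `"acetone"`.
#' @param constants solvent constants, see [solvent_constants()].
#' @return mole fraction(s) of the organic modifier.
#' @export
#' @examples
#' volume_to_mole_fraction(0.5, "methanol")
volume_to_mole_fraction <- function(phi, modifier,
                                    constants = solvent_constants()) {
  if (!modifier %in% setdiff(names(constants), "water"))
    stop("unknown modifier '", modifier, "'; supported: ",
         paste(setdiff(names(constants), "water"), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(phi)) || any(phi < 0) || any(phi > 1))
    stop("'phi' must lie in [0, 1]", call. = FALSE)
  org <- constants[[modifier]]
  w <- constants$water
  n_org <- phi * org$rho / org$M
  n_w <- (1 - phi) * w$rho / w$M
  n_org / (n_org + n_w)
}

#' Default validity thresholds for the Oscik fit
#'
#' An extrapolation to pure water from a mixed-solvent series can fail for
#' chemically unsuitable systems; such fits are flagged invalid rather than
#' reported as numbers.
#'
#' @param r2_min minimum coefficient of determination.
#' @param rmwo_max maximum plausible magnitude of the extrapolated R_MWO.
#' @return list of thresholds for [fit_oscik()].
#' @export
oscik_validity <- function(r2_min = 0.5, rmwo_max = 15) {
  list(r2_min = r2_min, rmwo_max = rmwo_max)
}

#' Fit the Oscik excess-retention model
#'
#' Decomposes mixed-solvent retention into an ideal mole-fraction blend of
#' the pure-solvent retentions plus a quadratic excess term,
#' \deqn{R_M = x R_{M,org} + (1 - x) R_{MWO} + x(1 - x)(a x + b),}
#' where \eqn{x} is the mole fraction of the organic modifier. Equivalently
#' the excess function \eqn{G(x) = a x + b} is linear in \eqn{x}. With
#' the pure-organic retention `rm_org` held at its measured value the model
#' is linear in the unknowns \eqn{(R_{MWO}, a, b)} and is estimated by
#' least squares.
#'
#' @param series a [retention_series()] (phi on the volume-fraction scale),
#'   or a data frame with columns `x` (mole fraction) and `rm`.
#' @param rm_org retention R_M measured in the pure organic solvent
#'   (\eqn{\varphi = 1}). If `NULL` and the series contains a point at
#'   phi = 1, that point is used (and removed from the interior set).
#' @param validity thresholds from [oscik_validity()].
#' @param constants solvent constants for the mole-fraction conversion.
#' @return object of class `oscik_fit` with `rmwo`, `a`, `b`, `rm_org`,
#'   `r2`, `n`, and logical `valid`. `valid` is `FALSE` when the fit is
#'   degenerate: r2 below threshold, non-finite coefficients, or an
#'   implausibly large extrapolation.
#' @export
fit_oscik <- function(series, rm_org = NULL, validity = oscik_validity(),
                      constants = solvent_constants()) {
  if (inherits(series, "retention_series")) {
    phi <- series$points$phi
    rm <- series$points$rm
    if (is.null(rm_org) && any(phi == 1)) {
      rm_org <- mean(rm[phi == 1])
    }
    keep <- phi > 0 & phi < 1
    x <- volume_to_mole_fraction(phi[keep], series$modifier, constants)
    rm <- rm[keep]
  } else {
    if (!all(c("x", "rm") %in% names(series)))
      stop("series must supply 'x' and 'rm'", call. = FALSE)
    keep <- series$x > 0 & series$x < 1
    x <- series$x[keep]
    rm <- series$rm[keep]
  }
  if (is.null(rm_org) || !is.finite(rm_org))
    stop("'rm_org' (retention in the pure organic solvent) is required ",
         "and was not supplied or measurable", call. = FALSE)
  if (length(unique(x)) < 4L)
    stop("the excess-retention model needs >= 4 distinct interior mole ",
         "fractions, got ", length(unique(x)), call. = FALSE)

  # design for the unknowns (rmwo, a, b); rm_org enters as a known offset
  z <- rm - x * rm_org
  d1 <- 1 - x
  d2 <- x^2 * (1 - x)
  d3 <- x * (1 - x)
  fit <- lm(z ~ 0 + d1 + d2 + d3)
  cf <- coef(fit)
  if (any(is.na(cf)))
    stop("degenerate fit: rank-deficient design (collinear mole fractions)",
         call. = FALSE)
  rmwo <- unname(cf["d1"]); a <- unname(cf["d2"]); b <- unname(cf["d3"])
  fitted_rm <- x * rm_org + fitted(fit)
  sst <- sum((rm - mean(rm))^2)
  r2 <- if (sst > 0) 1 - sum((rm - fitted_rm)^2) / sst else NA_real_
  valid <- is.finite(rmwo) && is.finite(a) && is.finite(b) &&
    !is.na(r2) && r2 >= validity$r2_min && abs(rmwo) <= validity$rmwo_max
  structure(
    list(
      compound_id = if (inherits(series, "retention_series")) series$compound_id else NA_character_,
      modifier = if (inherits(series, "retention_series")) series$modifier else NA_character_,
      rmwo = rmwo, a = a, b = b, rm_org = rm_org,
      r2 = r2, n = length(x), valid = valid
    ),
    class = "oscik_fit"
  )
}

#' @export
print.oscik_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Oscik excess-retention fit%s\n",
              if (!is.na(x$compound_id)) paste0(": ", x$compound_id,
                                                " (", x$modifier, "-water)") else ""))
  if (x$valid) {
    cat(sprintf("  R_MWO = %.*f, a = %.*f, b = %.*f, R_Morg = %.*f  (n = %d, R2 = %.3f)\n",
                digits, x$rmwo, digits, x$a, digits, x$b, digits, x$rm_org,
                x$n, x$r2))
  } else {
    cat(sprintf("  invalid fit (n = %d, R2 = %s): mobile phase unsuitable for extrapolation\n",
                x$n, format(x$r2, digits = 3)))
  }
  invisible(x)
}
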