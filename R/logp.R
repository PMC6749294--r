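#' Round half away from zero
#'
#' Reporting-layer rounding used for descriptor tables: ties go away from
#' zero (0.175 -> 0.18, -0.175 -> -0.18), unlike [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded vector.
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Mean and sample standard deviation of literature logP values
#'
#' Compounds often have several published shake-flask logP values; the
#' summary used downstream is their arithmetic mean with an n-1 standard
#' deviation (defined only for two or more values).
#'
#' @param values numeric vector of logP values (NAs dropped).
#' @return list with `mean`, `sd` (NA when fewer than 2 values) and `n`.
#'   An empty input yields NA mean, not zero.
#' @export
#' @examples
#' mean_sd_logp(c(-0.22, -0.10, -0.02, 0.75))
mean_sd_logp <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  list(
    mean = if (n >= 1) mean(values) else NA_real_,
    sd = if (n >= 2) sd(values) else NA_real_,
    n = n
  )
}

#' Simple linear regression with classical inference
#'
#' Ordinary least squares of a partition-coefficient scale on a
#' chromatographic descriptor (or any paired numeric columns). Pairs with
#' a missing value in either variable are dropped listwise. Reports the
#' coefficients with their classical standard errors, the Pearson
#' correlation, the residual standard error, and the F test of the slope
#' with (1, n-2) degrees of freedom.
#'
#' @param x predictor values.
#' @param y response values.
#' @param xname,yname names used in printing.
#' @return object of class `logp_regression` with `intercept`, `slope`,
#'   `se_intercept`, `se_slope`, `r`, `s_resid`, `f_stat`, `p_value`, `n`,
#'   `predictor_name`, `response_name`.
#' @export
#' @examples
#' ols_fit(1:5, 2 * (1:5) + 1)
ols_fit <- function(x, y, xname = deparse(substitute(x)),
                    yname = deparse(substitute(y))) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3)
    stop("insufficient data: need >= 3 complete pairs, got ", n,
         call. = FALSE)
  if (var(x) == 0)
    stop("degenerate regression: predictor has zero variance", call. = FALSE)
  fit <- lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  r <- cor(x, y)
  f_stat <- (n - 2) * r^2 / (1 - r^2)
  structure(
    list(
      intercept = unname(coef(fit)[1L]),
      slope = unname(coef(fit)[2L]),
      se_intercept = sm$coefficients[1L, 2L],
      se_slope = sm$coefficients[2L, 2L],
      r = r,
      s_resid = sm$sigma,
      f_stat = f_stat,
      p_value = pf(f_stat, 1, n - 2, lower.tail = FALSE),
      n = n,
      predictor_name = xname,
      response_name = yname
    ),
    class = "logp_regression"
  )
}

#' @export
print.logp_regression <- function(x, ...) {
  p_disp <- if (x$p_value < 1e-4) "< 0.0001" else
    if (x$p_value < 5e-4) "< 0.0005" else sprintf("= %.4f", x$p_value)
  cat(sprintf("%s = %.3f(±%.3f) + %.3f(±%.3f) · %s\n",
              x$response_name, x$intercept, x$se_intercept,
              x$slope, x$se_slope, x$predictor_name))
  cat(sprintf("n = %d, r = %.3f, s = %.2f, F = %.0f, p %s\n",
              x$n, x$r, x$s_resid, x$f_stat, p_disp))
  invisible(x)
}

#' Predict logP from a fitted descriptor regression
#'
#' @param model a `logp_regression`.
#' @param phi0 descriptor value(s) at which to predict.
#' @return predicted response, `intercept + slope * phi0`.
#' @export
predict_logp <- function(model, phi0) {
  stopifnot(inherits(model, "logp_regression"), all(is.finite(phi0)))
  model$intercept + model$slope * phi0
}

#' Pairwise Pearson correlation matrix with per-cell sample sizes
#'
#' Correlations between descriptor columns handled pairwise: each cell uses
#' the rows complete for that pair; cells with fewer than 3 complete pairs
#' are reported as missing.
#'
#' @param table data frame of descriptors (rows = compounds).
#' @param columns character vector (>= 2) of column names to correlate.
#' @return object of class `cor_matrix`: list with symmetric matrices `r`
#'   (unit diagonal) and `n`.
#' @export
correlation_matrix <- function(table, columns) {
  if (length(columns) < 2)
    stop("need at least 2 columns", call. = FALSE)
  missing_cols <- setdiff(columns, names(table))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  k <- length(columns)
  r <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  nmat <- matrix(0L, k, k, dimnames = list(columns, columns))
  for (i in seq_len(k)) {
    for (j in i:k) {
      xi <- table[[columns[i]]]; xj <- table[[columns[j]]]
      keep <- is.finite(xi) & is.finite(xj)
      nmat[i, j] <- nmat[j, i] <- sum(keep)
      if (i == j) {
        r[i, j] <- 1
      } else if (sum(keep) >= 3 && var(xi[keep]) > 0 && var(xj[keep]) > 0) {
        r[i, j] <- r[j, i] <- cor(xi[keep], xj[keep])
      }
    }
  }
  structure(list(r = r, n = nmat), class = "cor_matrix")
}

#' @export
print.cor_matrix <- function(x, digits = 3, ...) {
  cat("Pairwise Pearson correlations (n per cell in attr 'n'):\n")
  print(round(x$r, digits))
  invisible(x)
}
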