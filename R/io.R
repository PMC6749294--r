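#' Read a retention-measurement CSV
#'
#' The measurement schema is one row per spotted replicate:
#' `compound,modifier,phi,rf,replicate`, with `phi` the modifier volume
#' fraction as a decimal (not a percent) and `rf` strictly inside (0, 1).
#' Every violated row is reported with its row number before the function
#' stops.
#'
#' @param path path to a CSV file with the exact header above.
#' @return validated data frame of measurements.
#' @export
read_measurements <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  required <- c("compound", "modifier", "phi", "rf", "replicate")
  if (!identical(names(tab), required))
    stop("measurement file must have columns exactly: ",
         paste(required, collapse = ","), "; got: ",
         paste(names(tab), collapse = ","), call. = FALSE)
  problems <- character()
  row_issue <- function(i, msg) sprintf("row %d: %s", i, msg)
  for (i in seq_len(nrow(tab))) {
    phi <- tab$phi[i]; rf <- tab$rf[i]; rep_i <- tab$replicate[i]
    if (!is.finite(phi) || phi < 0 || phi > 1) {
      hint <- if (is.finite(phi) && phi > 1 && phi <= 100)
        " (value looks like a percent; use a decimal fraction, e.g. 0.60)"
      else ""
      problems <- c(problems, row_issue(i, paste0("phi = ", phi,
                                                  " outside [0, 1]", hint)))
    }
    if (!is.finite(rf) || rf <= 0 || rf >= 1)
      problems <- c(problems, row_issue(i, paste0("rf = ", rf,
                                                  " outside the open interval (0, 1)")))
    if (!is.finite(rep_i) || rep_i < 1 || rep_i != round(rep_i))
      problems <- c(problems, row_issue(i, paste0("replicate = ", rep_i,
                                                  " is not a positive integer")))
    if (!tab$modifier[i] %in% c("methanol", "acetone"))
      problems <- c(problems, row_issue(i, paste0("unknown modifier '",
                                                  tab$modifier[i], "'")))
  }
  if (length(problems))
    stop("invalid measurement file '", path, "':\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  tab
}

#' Fit retention models for every compound/modifier group
#'
#' Runs [aggregate_replicates()] and [fit_sw()] on each
#' compound-by-modifier group of a measurement table, and additionally
#' [fit_oscik()] for groups that include the pure-organic point
#' (`phi = 1`) and enough interior compositions.
#'
#' @param measurements measurement data frame (see [read_measurements()]).
#' @param aggregate replicate aggregation scale, `"rf"` or `"rm"`.
#' @param oscik fit the excess-retention model where possible?
#' @param validity Oscik validity thresholds, see [oscik_validity()].
#' @return data frame with one row per group and columns
#'   `compound,modifier,rmws,S,phi0,r,s_resid,n,rmwo,a,b,rm_org,oscik_valid`.
#'   Oscik columns are NA where the model was not (or could not be)
#'   fitted, and also where it was fitted but judged invalid.
#' @export
fit_all <- function(measurements, aggregate = c("rf", "rm"), oscik = TRUE,
                    validity = oscik_validity()) {
  aggregate <- match.arg(aggregate)
  groups <- unique(measurements[, c("compound", "modifier")])
  out <- vector("list", nrow(groups))
  for (g in seq_len(nrow(groups))) {
    sub <- measurements[measurements$compound == groups$compound[g] &
                          measurements$modifier == groups$modifier[g], ]
    series <- aggregate_replicates(sub, aggregate = aggregate)
    sw <- fit_sw(series)
    row <- data.frame(
      compound = groups$compound[g], modifier = groups$modifier[g],
      rmws = sw$rmws, S = sw$slope_s, phi0 = sw$phi0, r = sw$r,
      s_resid = sw$s_resid, n = sw$n,
      rmwo = NA_real_, a = NA_real_, b = NA_real_, rm_org = NA_real_,
      oscik_valid = NA
    )
    interior <- series$points$phi > 0 & series$points$phi < 1
    if (oscik && any(series$points$phi == 1) && sum(interior) >= 4) {
      of <- fit_oscik(series, validity = validity)
      row$rm_org <- of$rm_org
      row$oscik_valid <- of$valid
      if (of$valid) {
        row$rmwo <- of$rmwo; row$a <- of$a; row$b <- of$b
      }
    }
    out[[g]] <- row
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Write a fit table to CSV
#'
#' @param fits data frame from [fit_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fits <- function(fits, path) {
  write.csv(fits, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Default run configuration
#'
#' One place for every tunable default: replicate aggregation scale,
#' Oscik validity thresholds, solvent constants, simulator noise defaults,
#' and the clustering linkage.
#'
#' @return nested list of defaults.
#' @export
default_config <- function() {
  list(
    aggregate = "rf",
    oscik = list(r2_min = 0.5, rmwo_max = 15),
    solvents = lapply(solvent_constants(), function(s) list(M = s$M, rho = s$rho)),
    noise_sd = 0.05,
    replicates = 3,
    linkage = "single",
    seed = NA
  )
}

#' Read a YAML run configuration
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_config()] value.
#'
#' @param path YAML file path (NULL gives the defaults).
#' @return configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modify_list <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(new[[nm]]))
        modify_list(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  modify_list(cfg, user)
}

#' Write a run configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}
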