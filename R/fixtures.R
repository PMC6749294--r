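#' Names of the computed logP scales
#'
#' The seven structure-based partition-coefficient predictors carried in
#' the bundled descriptor tables.
#'
#' @return character vector of column names.
#' @export
theoretical_scales <- function() {
  c("alogps", "aclogp", "milogp", "alogp", "mlogp", "xlogp2", "xlogp3")
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "rptlc")
  if (p == "") stop("bundled fixture not found: ", file, call. = FALSE)
  p
}

read_fixture_csv <- function(file) {
  read.csv(extdata_path(file), comment.char = "#", check.names = TRUE,
           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Load the bundled descriptor tables
#'
#' Per-compound chromatographic descriptors (R_MW from the linear
#' retention model in both modifier systems, the Oscik R_MWO where the
#' system allowed it, and phi0) together with the seven computed logP
#' scales, for the fifteen studied drugs. The acetone-water Oscik column
#' is entirely missing for the NSAIDs: that mobile phase was unsuitable
#' for the extrapolation.
#'
#' @return data frame with 15 rows and columns `compound`, `class`, the
#'   seven scales of [theoretical_scales()], `rmws_a`, `rmws_m`, `rmwo_a`,
#'   `rmwo_m`, `phi0_m`, `phi0_a`.
#' @export
load_descriptor_tables <- function() {
  tab <- rbind(read_fixture_csv("table1.csv"),
               read_fixture_csv("table2.csv"),
               read_fixture_csv("table3.csv"))
  expected <- c("compound", "class", theoretical_scales(),
                "rmws_a", "rmws_m", "rmwo_a", "rmwo_m", "phi0_m", "phi0_a")
  if (!identical(names(tab), expected) || nrow(tab) != 15L)
    stop("descriptor fixture integrity check failed: expected 15 compounds ",
         "with the standard column set", call. = FALSE)
  # spot checks against known entries
  if (abs(tab$xlogp3[tab$compound == "felodipine"] - 3.86) > 1e-9 ||
      abs(tab$rmws_a[tab$compound == "metronidazole"] - 0.65) > 1e-9 ||
      !all(is.na(tab$rmwo_a[tab$class == "nsaid"])))
    stop("descriptor fixture integrity check failed: spot values do not match",
         call. = FALSE)
  tab
}

#' Load the literature experimental logP values
#'
#' Long-format table of published shake-flask logP values, one row per
#' literature report. Nilvadipine, lacidipine and carprofen have no
#' experimental value.
#'
#' @return data frame with columns `compound`, `value`, `source_tag`.
#' @export
load_logp_exp <- function() {
  tab <- read_fixture_csv("table4_logp_exp.csv")
  if (!identical(names(tab), c("compound", "value", "source_tag")))
    stop("logP fixture integrity check failed", call. = FALSE)
  tab
}

#' Load the published logP summary column
#'
#' The printed 2-dp mean (+/- sample sd) of the experimental logP values
#' for compounds with more than one literature report.
#'
#' @return data frame with columns `compound`, `logp_mean`, `logp_sd`.
#' @export
load_logp_summary <- function() {
  read_fixture_csv("table4_summary.csv")
}

#' Assemble the full per-compound descriptor table
#'
#' Joins the descriptor tables with the experimental-logP summaries.
#' `logp_exp_mean` carries the published 2-dp mean for multi-source
#' compounds and the single literature value otherwise (no imputation:
#' compounds without any experimental value stay missing).
#' `logp_exp_mean_raw`/`logp_exp_sd_raw` are recomputed at full precision
#' from the individual literature values via [mean_sd_logp()].
#'
#' @return data frame with 15 rows: the columns of
#'   [load_descriptor_tables()] plus `logp_exp_mean`, `logp_exp_sd`,
#'   `logp_exp_mean_raw`, `logp_exp_sd_raw`, `logp_exp_n`.
#' @export
assemble_descriptor_table <- function() {
  desc <- load_descriptor_tables()
  raw <- load_logp_exp()
  summ <- load_logp_summary()
  desc$logp_exp_mean <- NA_real_
  desc$logp_exp_sd <- NA_real_
  desc$logp_exp_mean_raw <- NA_real_
  desc$logp_exp_sd_raw <- NA_real_
  desc$logp_exp_n <- 0L
  for (i in seq_len(nrow(desc))) {
    cmp <- desc$compound[i]
    vals <- raw$value[raw$compound == cmp]
    ms <- mean_sd_logp(vals)
    desc$logp_exp_mean_raw[i] <- ms$mean
    desc$logp_exp_sd_raw[i] <- ms$sd
    desc$logp_exp_n[i] <- ms$n
    j <- match(cmp, summ$compound)
    if (!is.na(j)) {
      desc$logp_exp_mean[i] <- summ$logp_mean[j]
      desc$logp_exp_sd[i] <- summ$logp_sd[j]
    } else if (ms$n == 1L) {
      desc$logp_exp_mean[i] <- vals
    }
  }
  desc
}
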