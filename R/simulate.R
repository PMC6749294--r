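#' Gradient design presets
#'
#' The modifier-fraction grids of the three experimental designs, one per
#' drug class and modifier: antiparasitic plates ran methanol 20-100% in
#' 10% steps and acetone 10-100% in 10% steps; antihypertensive plates ran
#' both modifiers 60-100% in 5% steps; NSAID plates ran methanol 60-100%
#' in 5% steps and acetone 20-100% in 10% steps.
#'
#' @return named list of numeric phi grids (volume fractions).
#' @export
design_presets <- function() {
  list(
    antiparasitic_methanol    = seq(0.20, 1.00, by = 0.10),
    antiparasitic_acetone     = seq(0.10, 1.00, by = 0.10),
    antihypertensive_methanol = seq(0.60, 1.00, by = 0.05),
    antihypertensive_acetone  = seq(0.60, 1.00, by = 0.05),
    nsaid_methanol            = seq(0.60, 1.00, by = 0.05),
    nsaid_acetone             = seq(0.20, 1.00, by = 0.10)
  )
}

#' Resolve a design argument to a phi grid and modifier
#' @noRd
resolve_design <- function(design, modifier = NULL) {
  if (is.character(design)) {
    presets <- design_presets()
    if (!design %in% names(presets))
      stop("unknown design preset '", design, "'", call. = FALSE)
    if (is.null(modifier))
      modifier <- sub("^.*_", "", design)
    list(grid = presets[[design]], modifier = modifier)
  } else {
    if (is.null(modifier)) modifier <- "methanol"
    list(grid = as.numeric(design), modifier = modifier)
  }
}

#' Ground-truth record for the retention simulator
#'
#' @param compound_id compound identifier.
#' @param true_rmws true extrapolated pure-water retention (intercept).
#' @param true_s true slope of the retention line (must be positive).
#' @param noise_sd standard deviation of the Gaussian noise added on the
#'   R_M scale.
#' @param oscik optional list `(rmwo, a, b, rm_org)` describing an
#'   excess-retention truth for [simulate_oscik_series()].
#' @return a `truth_record` list.
#' @export
truth_record <- function(compound_id, true_rmws, true_s, noise_sd = 0.05,
                         oscik = NULL) {
  stopifnot(true_s > 0, noise_sd >= 0)
  structure(list(compound_id = as.character(compound_id),
                 true_rmws = true_rmws, true_s = true_s,
                 noise_sd = noise_sd, oscik = oscik),
            class = "truth_record")
}

rf_from_rm_clipped <- function(rm) {
  rf <- 1 / (1 + 10^rm)
  n_trunc <- sum(rf < 0.01 | rf > 0.99)
  if (n_trunc > 0)
    message(sprintf("truncated %d simulated R_F value(s) to [0.01, 0.99]",
                    n_trunc))
  pmin(pmax(rf, 0.01), 0.99)
}

#' Simulate a linear retention series
#'
#' Generates replicate R_F measurements whose underlying structure is the
#' linear retention model \eqn{R_M = R_{MW} - S\varphi} with additive
#' Gaussian noise on the R_M scale, inverted to the R_F scale. Simulated
#' R_F values are truncated to \[0.01, 0.99\] (with a message stating how
#' many were truncated); a warning is raised when the noiseless design
#' already puts more than half the grid outside that window, since such a
#' design could not have been measured.
#'
#' @param truth a [truth_record()].
#' @param design preset name (see [design_presets()]) or numeric phi grid.
#' @param replicates number of replicate spots per phi (default 3).
#' @param seed integer seed; the same seed reproduces the output exactly.
#'   `NULL` uses the current RNG state.
#' @param modifier overrides the modifier implied by a preset name.
#' @return data frame with columns `compound`, `modifier`, `phi`, `rf`,
#'   `replicate`.
#' @export
#' @examples
#' tr <- truth_record("drug1", true_rmws = 2, true_s = 3, noise_sd = 0)
#' m <- simulate_sw_series(tr, "antihypertensive_methanol", seed = 1)
#' fit_sw(aggregate_replicates(m))
simulate_sw_series <- function(truth, design, replicates = 3, seed = NULL,
                               modifier = NULL) {
  stopifnot(inherits(truth, "truth_record"), replicates >= 1)
  d <- resolve_design(design, modifier)
  if (!is.null(seed)) set.seed(seed)
  rm_true <- truth$true_rmws - truth$true_s * d$grid
  rf_true <- 1 / (1 + 10^rm_true)
  if (sum(rf_true < 0.01 | rf_true > 0.99) > length(d$grid) / 2)
    warning("design mismatch: most of the grid puts the true R_F outside ",
            "the measurable window for this compound", call. = FALSE)
  phi <- rep(d$grid, each = replicates)
  rm <- truth$true_rmws - truth$true_s * phi +
    rnorm(length(phi), sd = truth$noise_sd)
  data.frame(
    compound = truth$compound_id,
    modifier = d$modifier,
    phi = phi,
    rf = rf_from_rm_clipped(rm),
    replicate = rep(seq_len(replicates), times = length(d$grid))
  )
}

#' Simulate an excess-retention series
#'
#' Generates retention data from the Oscik model at the mole fractions
#' corresponding to the design's volume fractions, with Gaussian noise on
#' the R_M scale. The pure-organic point (phi = 1) carrying `rm_org` is
#' always included.
#'
#' @inheritParams simulate_sw_series
#' @param replicates replicate spots per phi (default 1).
#' @return data frame as in [simulate_sw_series()].
#' @export
simulate_oscik_series <- function(truth, design, seed = NULL,
                                  replicates = 1, modifier = NULL) {
  stopifnot(inherits(truth, "truth_record"))
  if (is.null(truth$oscik))
    stop("truth record carries no 'oscik' parameters (rmwo, a, b, rm_org)",
         call. = FALSE)
  p <- truth$oscik
  stopifnot(all(c("rmwo", "a", "b", "rm_org") %in% names(p)))
  d <- resolve_design(design, modifier)
  grid <- unique(c(d$grid, 1))
  if (!is.null(seed)) set.seed(seed)
  phi <- rep(grid, each = replicates)
  x <- volume_to_mole_fraction(phi, d$modifier)
  rm_true <- x * p$rm_org + (1 - x) * p$rmwo + x * (1 - x) * (p$a * x + p$b)
  rm <- rm_true + rnorm(length(phi), sd = truth$noise_sd)
  data.frame(
    compound = truth$compound_id,
    modifier = d$modifier,
    phi = phi,
    rf = rf_from_rm_clipped(rm),
    replicate = rep(seq_len(replicates), times = length(grid))
  )
}

cohort_classes <- function() {
  # rmws ranges observed per drug class; phi0 windows chosen to mirror the
  # descriptor tables so the implied slope S stays physical
  list(
    antiparasitic    = list(rmws = c(0.65, 1.46), phi0 = c(0.40, 0.70),
                            design = "antiparasitic_methanol"),
    nsaid            = list(rmws = c(1.26, 3.12), phi0 = c(0.64, 0.93),
                            design = "nsaid_methanol"),
    antihypertensive = list(rmws = c(3.13, 5.01), phi0 = c(0.75, 0.95),
                            design = "antihypertensive_methanol")
  )
}

#' Simulate a cohort of compounds across the three drug classes
#'
#' Draws per-compound true retention parameters uniformly within the
#' class-specific R_MW ranges (antiparasitic 0.65-1.46, NSAID 1.26-3.12,
#' antihypertensive 3.13-5.01), with slopes chosen so the implied phi0
#' falls in a plausible window, and simulates replicate measurements on
#' each class's methanol design.
#'
#' @param n_per_class compounds per class (0 gives empty outputs).
#' @param seed integer seed (required for reproducibility).
#' @param noise_sd Gaussian noise sd on the R_M scale.
#' @param replicates replicate spots per phi.
#' @return list with `measurements` (stacked measurement data frame) and
#'   `truth` (one row per compound: class, true_rmws, true_s, true_phi0).
#' @export
make_cohort <- function(n_per_class, seed, noise_sd = 0.05, replicates = 3) {
  stopifnot(n_per_class >= 0)
  set.seed(seed)
  classes <- cohort_classes()
  meas <- list(); truth <- list()
  for (cl in names(classes)) {
    spec <- classes[[cl]]
    for (i in seq_len(n_per_class)) {
      id <- sprintf("%s_%02d", cl, i)
      rmws <- runif(1, spec$rmws[1], spec$rmws[2])
      phi0 <- runif(1, spec$phi0[1], spec$phi0[2])
      tr <- truth_record(id, true_rmws = rmws, true_s = rmws / phi0,
                         noise_sd = noise_sd)
      meas[[id]] <- suppressMessages(
        simulate_sw_series(tr, spec$design, replicates = replicates,
                           seed = NULL))
      truth[[id]] <- data.frame(compound = id, class = cl,
                                true_rmws = rmws, true_s = rmws / phi0,
                                true_phi0 = phi0)
    }
  }
  list(
    measurements = if (length(meas)) do.call(rbind, c(meas, list(make.row.names = FALSE)))
                   else data.frame(compound = character(), modifier = character(),
                                   phi = numeric(), rf = numeric(),
                                   replicate = integer()),
    truth = if (length(truth)) do.call(rbind, c(truth, list(make.row.names = FALSE)))
            else data.frame(compound = character(), class = character(),
                            true_rmws = numeric(), true_s = numeric(),
                            true_phi0 = numeric())
  )
}
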