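test_that("design presets carry the experimental gradient grids", {
  p <- design_presets()
  expect_named(p, c("antiparasitic_methanol", "antiparasitic_acetone",
                    "antihypertensive_methanol", "antihypertensive_acetone",
                    "nsaid_methanol", "nsaid_acetone"))
  expect_equal(vapply(p, length, integer(1)),
               c(antiparasitic_methanol = 9L, antiparasitic_acetone = 10L,
                 antihypertensive_methanol = 9L, antihypertensive_acetone = 9L,
                 nsaid_methanol = 9L, nsaid_acetone = 9L))
  expect_equal(p$antiparasitic_methanol, seq(0.2, 1, 0.1))
  expect_equal(p$antihypertensive_acetone, seq(0.6, 1, 0.05))
  expect_equal(range(p$nsaid_acetone), c(0.2, 1))
})

test_that("the simulator is deterministic under a fixed seed", {
  tr <- truth_record("cpd", 1.5, 2.5, noise_sd = 0.05)
  m1 <- simulate_sw_series(tr, "antiparasitic_methanol", seed = 42)
  m2 <- simulate_sw_series(tr, "antiparasitic_methanol", seed = 42)
  expect_identical(m1, m2)
  m3 <- simulate_sw_series(tr, "antiparasitic_methanol", seed = 43)
  expect_false(identical(m1, m3))
  # byte-identical CSV serialisation
  f1 <- tempfile(); f2 <- tempfile()
  write.csv(m1, f1, row.names = FALSE); write.csv(m2, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("noiseless simulation inverts exactly through the fitting chain", {
  tr <- truth_record("cpd", 2.0, 3.0, noise_sd = 0)
  m <- simulate_sw_series(tr, "antihypertensive_methanol", seed = 1)
  fit <- fit_sw(aggregate_replicates(m))
  expect_equal(fit$rmws, 2.0, tolerance = 1e-9)
  expect_equal(fit$slope_s, 3.0, tolerance = 1e-9)

  # R_M at phi = 0.2 for the worked truth (0.91, 1.614)
  tr2 <- truth_record("cpd2", 0.91, 1.614, noise_sd = 0)
  m2 <- simulate_sw_series(tr2, "antiparasitic_methanol", seed = 1, replicates = 1)
  rm_02 <- rf_to_rm(m2$rf[m2$phi == 0.2])
  expect_equal(rm_02, 0.5872, tolerance = 1e-4)
})

test_that("simulated R_F values are truncated into the measurable window", {
  # extreme lipophilicity: most of the grid sits outside [0.01, 0.99]
  tr <- truth_record("cpd", 8, 2, noise_sd = 0)
  expect_warning(
    expect_message(
      m <- simulate_sw_series(tr, "antiparasitic_methanol", seed = 1),
      "truncated"),
    "design mismatch")
  expect_true(all(m$rf >= 0.01 & m$rf <= 0.99))
})

test_that("the excess-model simulator round-trips its parameters", {
  pars <- list(rmwo = 1.5, a = 0.8, b = -0.4, rm_org = -0.2)
  tr <- truth_record("cpd", 1, 1, noise_sd = 0, oscik = pars)
  m <- simulate_oscik_series(tr, "antiparasitic_methanol", seed = 7)
  fit <- fit_oscik(aggregate_replicates(m))
  expect_equal(fit$rmwo, pars$rmwo, tolerance = 1e-9)
  expect_equal(fit$a, pars$a, tolerance = 1e-9)
  expect_equal(fit$b, pars$b, tolerance = 1e-9)
  expect_equal(fit$rm_org, pars$rm_org, tolerance = 1e-9)

  tr_plain <- truth_record("cpd", 1, 1)
  expect_error(simulate_oscik_series(tr_plain, "antiparasitic_methanol", seed = 1),
               "oscik")
})

test_that("make_cohort spans the class parameter ranges and is recoverable", {
  empty <- make_cohort(0, seed = 1)
  expect_equal(nrow(empty$measurements), 0L)
  expect_equal(nrow(empty$truth), 0L)

  noiseless <- make_cohort(5, seed = 3, noise_sd = 0)
  fits <- fit_all(noiseless$measurements, oscik = FALSE)
  merged <- merge(fits, noiseless$truth, by = "compound")
  expect_equal(nrow(merged), 15L)
  expect_equal(merged$rmws, merged$true_rmws, tolerance = 1e-9)
  expect_equal(merged$S, merged$true_s, tolerance = 1e-9)
  expect_true(all(merged$true_phi0 > 0.3 & merged$true_phi0 < 1))
  cls <- cohort_ranges <- list(antiparasitic = c(0.65, 1.46),
                               nsaid = c(1.26, 3.12),
                               antihypertensive = c(3.13, 5.01))
  for (cl in names(cls)) {
    vals <- noiseless$truth$true_rmws[noiseless$truth$class == cl]
    expect_true(all(vals >= cls[[cl]][1] & vals <= cls[[cl]][2]))
  }

  noisy <- make_cohort(5, seed = 1, noise_sd = 0.05)
  fits_n <- fit_all(noisy$measurements, oscik = FALSE)
  merged_n <- merge(fits_n, noisy$truth, by = "compound")
  expect_lt(mean(abs(merged_n$rmws - merged_n$true_rmws)), 0.15)
})

test_that("replicate averaging reduces estimation error of the intercept", {
  errs <- sapply(1:40, function(s) {
    tr <- truth_record("cpd", 2, 2.5, noise_sd = 0.08)
    e1 <- abs(fit_sw(aggregate_replicates(
      simulate_sw_series(tr, "nsaid_methanol", replicates = 1, seed = s)))$rmws - 2)
    e25 <- abs(fit_sw(aggregate_replicates(
      simulate_sw_series(tr, "nsaid_methanol", replicates = 25, seed = s + 1e4)))$rmws - 2)
    c(e1, e25)
  })
  expect_lt(mean(errs[2, ]), mean(errs[1, ]))
  expect_lt(mean(errs[2, ]), 0.05)  # near-unbiased at high replication
})
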