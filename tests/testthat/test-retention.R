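test_that("rf_to_rm implements the logit-type retention transform", {
  expect_identical(rf_to_rm(0.5), 0)
  expect_equal(rf_to_rm(0.25), log10(3))
  expect_equal(rf_to_rm(0.75), -log10(3))  # antisymmetric about 0.5
  # strictly decreasing
  grid <- seq(0.01, 0.99, length.out = 200)
  expect_true(all(diff(rf_to_rm(grid)) < 0))
})

test_that("rf_to_rm rejects endpoint and out-of-range values, naming the offender", {
  expect_error(rf_to_rm(c(0.4, 1, 0.6)), "measurement 2")
  expect_error(rf_to_rm(0), "outside \\(0, 1\\)")
  expect_error(rf_to_rm(-0.1), "outside")
  expect_error(rf_to_rm(1.2), "outside")
})

test_that("rm_to_rf inverts rf_to_rm on (0,1)", {
  rf <- seq(0.001, 0.999, length.out = 500)
  expect_equal(rm_to_rf(rf_to_rm(rf)), rf, tolerance = 1e-12)
  rm <- seq(-3, 3, length.out = 101)
  expect_equal(rf_to_rm(rm_to_rf(rm)), rm, tolerance = 1e-12)
})

make_meas <- function(phi, rf, compound = "cpd", modifier = "methanol") {
  data.frame(compound = compound, modifier = modifier, phi = phi, rf = rf,
             replicate = seq_along(rf))
}

test_that("replicates are averaged on the R_F scale by default", {
  m <- make_meas(rep(0.6, 3), c(0.40, 0.42, 0.38))
  s <- aggregate_replicates(m)
  expect_equal(s$points$phi, 0.6)
  expect_equal(s$points$rm, rf_to_rm(0.40))

  m2 <- make_meas(rep(0.7, 2), c(0.30, 0.50))
  expect_equal(aggregate_replicates(m2)$points$rm, rf_to_rm(0.40))
  expect_equal(aggregate_replicates(m2)$points$rm, 0.1761, tolerance = 1e-4)

  # single replicate passes through
  m3 <- make_meas(0.8, 0.33)
  expect_equal(aggregate_replicates(m3)$points$rm, rf_to_rm(0.33))

  # rm-scale aggregation differs from rf-scale for asymmetric replicates
  rm_agg <- aggregate_replicates(m2, aggregate = "rm")
  expect_equal(rm_agg$points$rm, mean(rf_to_rm(c(0.30, 0.50))))
  expect_false(isTRUE(all.equal(rm_agg$points$rm,
                                aggregate_replicates(m2)$points$rm)))
})

test_that("aggregation sorts by phi, rejects mixed groups, drops endpoint R_F", {
  m <- make_meas(c(0.9, 0.6, 0.7), c(0.8, 0.3, 0.5))
  expect_equal(aggregate_replicates(m)$points$phi, c(0.6, 0.7, 0.9))

  mixed <- rbind(make_meas(0.6, 0.4, compound = "a"),
                 make_meas(0.7, 0.5, compound = "b"))
  expect_error(aggregate_replicates(mixed), "single compound")

  with_end <- make_meas(c(0.6, 0.7), c(0.4, 1.0))
  expect_warning(s <- aggregate_replicates(with_end), "endpoint")
  expect_equal(nrow(s$points), 1L)
})

test_that("fit_sw recovers a noiseless retention line exactly", {
  phi <- c(0.6, 0.7, 0.8, 0.9, 1.0)
  s <- retention_series("x", "methanol", phi, 2.0 - 3.0 * phi)
  fit <- fit_sw(s)
  expect_equal(fit$rmws, 2.0, tolerance = 1e-9)
  expect_equal(fit$slope_s, 3.0, tolerance = 1e-9)
  expect_equal(fit$r, -1, tolerance = 1e-12)
  expect_equal(fit$phi0, 2 / 3, tolerance = 1e-9)
  expect_equal(fit$s_resid, 0, tolerance = 1e-9)
  expect_equal(fit$n, 5L)
  expect_false(fit$nonphysical)
  # phi0 * S = rmws invariant
  expect_equal(fit$phi0 * fit$slope_s, fit$rmws, tolerance = 1e-12)
})

test_that("fit_sw recovery holds across random noiseless lines", {
  set.seed(71)
  for (i in 1:25) {
    rmws <- runif(1, 0.5, 5); s_true <- runif(1, 1, 6)
    phi <- sort(runif(5, 0.1, 1))
    fit <- fit_sw(data.frame(phi = phi, rm = rmws - s_true * phi))
    expect_equal(fit$rmws, rmws, tolerance = 1e-9)
    expect_equal(fit$slope_s, s_true, tolerance = 1e-9)
    expect_equal(abs(fit$r), 1, tolerance = 1e-9)
  }
})

test_that("fit_sw enforces preconditions and flags non-physical slopes", {
  expect_error(fit_sw(data.frame(phi = c(0.6, 0.7), rm = c(1, 0.5))),
               "insufficient data")
  expect_error(fit_sw(data.frame(phi = rep(0.6, 4), rm = 1:4)),
               "insufficient data")  # one distinct phi
  phi <- c(0.6, 0.7, 0.8)
  expect_warning(fit <- fit_sw(data.frame(phi = phi, rm = 1 + 2 * phi)),
                 "non-physical")
  expect_true(fit$nonphysical)
})

test_that("compute_phi0 is the intercept-to-slope ratio", {
  expect_equal(compute_phi0(2.0, 3.0), 2 / 3)
  expect_equal(compute_phi0(0, 5), 0)
  expect_error(compute_phi0(1, 0), "undefined")
  # consistency with the bundled descriptor rows (inverting phi0 = rmws/S)
  expect_equal(0.65 / 0.398, 1.633, tolerance = 5e-4)   # implied S, acetone
  expect_equal(compute_phi0(0.91, 0.91 / 0.564), 0.564, tolerance = 1e-12)
})

test_that("every bundled descriptor row implies a strictly positive slope", {
  tab <- load_descriptor_tables()
  expect_true(all(tab$rmws_a / tab$phi0_a > 0))
  expect_true(all(tab$rmws_m / tab$phi0_m > 0))
  expect_equal(nrow(tab), 15L)
})
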