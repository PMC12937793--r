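test_that("baseline normalization maps the baseline to 1 and is idempotent", {
  x <- c(2, 4, 8)
  expect_equal(normalize_curve(x), c(1, 2, 4))
  expect_equal(normalize_curve(rep(3, 5)), rep(1, 5))
  expect_equal(normalize_curve(normalize_curve(x)), normalize_curve(x))
  expect_equal(normalize_curve(x, baseline_index = 2)[2], 1)
  expect_error(normalize_curve(c(0, 1, 2)), "zero")
})

test_that("quadratic fit recovers exact and noisy coefficients", {
  x <- seq(0, 0.9, length.out = 10)
  y <- 2 + 3 * x + 4 * x^2
  fit <- quadratic_fit(x, y, n_bootstrap = 50)
  expect_equal(unname(fit$coefficients), c(2, 3, 4), tolerance = 1e-10)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)
  # seeded noise: truth inside the bootstrap CIs
  xn <- seq(0, 1, length.out = 40)
  yn <- 2 + 3 * xn + 4 * xn^2 + withr::with_seed(9, rnorm(40, sd = 0.01))
  fitn <- quadratic_fit(xn, yn, seed = 9)
  expect_true(all(fitn$ci95[, "lo"] <= c(2, 3, 4)))
  expect_true(all(fitn$ci95[, "hi"] >= c(2, 3, 4)))
  # constant y: R^2 defined as 0 by convention
  fit0 <- quadratic_fit(x, rep(5, 10), n_bootstrap = 10)
  expect_equal(fit0$r_squared, 0)
  expect_equal(unname(fit0$coefficients[2:3]), c(0, 0), tolerance = 1e-10)
  expect_error(quadratic_fit(c(0, 1), c(1, 2)), "distinct")
  # fixed seed => bit-reproducible bootstrap
  expect_identical(quadratic_fit(xn, yn, seed = 4)$ci95,
                   quadratic_fit(xn, yn, seed = 4)$ci95)
})

test_that("breakpoint fit recovers a synthetic hinge exactly on-grid", {
  x <- seq(0, 1, by = 0.05)
  y <- 1 + 10 * pmax(x - 0.5, 0)          # slopes 0 then 10, hinge at 0.5
  fit <- breakpoint_fit(x, y)
  expect_equal(fit$breakpoint, 0.5)
  expect_equal(fit$slope_left, 0, tolerance = 1e-8)
  expect_equal(fit$slope_right, 10, tolerance = 1e-8)
  expect_lt(fit$sse, 1e-16)
  # pure line: SSE flat across candidates, earliest candidate returned
  line <- breakpoint_fit(x, 2 + 3 * x)
  expect_equal(line$breakpoint, x[2])
  # breakpoint invariant to y rescaling
  expect_equal(breakpoint_fit(x, 1000 * y)$breakpoint, fit$breakpoint)
  expect_error(breakpoint_fit(1:4, 1:4), ">= 5")
})

test_that("slope-doubling severity follows the closed form", {
  mk <- function(a0, a1, a2) {
    x <- seq(0, 1, length.out = 20)
    quadratic_fit(x, a0 + a1 * x + a2 * x^2, n_bootstrap = 10)
  }
  expect_equal(slope_doubling_sigma(mk(0, 1, 1)), 0.5)
  expect_equal(slope_doubling_sigma(mk(1, 2, 5)), 0.2)
  expect_error(slope_doubling_sigma(mk(1, 2, 0)), "a2 > 0")
  expect_error(slope_doubling_sigma(mk(1, -2, 3)), "a1 > 0")
})

test_that("pearson r and rmse follow their definitions", {
  x <- seq_len(20)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  null_r <- withr::with_seed(1, pearson_r(rnorm(1000), rnorm(1000)))
  expect_lt(abs(null_r), 0.1)
  expect_error(pearson_r(x, rep(1, 20)), "variance")
  expect_error(pearson_r(1:2, 1:2), ">= 3")
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(3, 4)), sqrt(12.5))
})

test_that("discrete Frechet distance matches brute force and its axioms", {
  a <- cbind(0:4, c(0, 1, 0, 1, 0))
  expect_equal(frechet_distance(a, a), 0)
  # parallel horizontal lines offset by d
  b <- cbind(0:4, rep(2, 5))
  c0 <- cbind(0:4, rep(0, 5))
  expect_equal(frechet_distance(c0, b), 2)
  # random small instances vs exhaustive coupling enumeration
  for (k in 1:10) {
    pq <- withr::with_seed(k, list(p = matrix(runif(12), ncol = 2),
                                   q = matrix(runif(10), ncol = 2)))
    d_dp <- frechet_distance(pq$p, pq$q)
    expect_equal(d_dp, oracle_frechet(pq$p, pq$q))
    expect_equal(frechet_distance(pq$q, pq$p), d_dp)      # symmetry
    expect_gte(d_dp, hausdorff_distance(pq$p, pq$q) - 1e-12)
  }
  expect_error(frechet_distance(matrix(numeric(0), ncol = 2), a), "empty")
})

test_that("one-at-a-time sensitivity isolates each parameter", {
  sig <- seq(0, 0.8, by = 0.2)
  model <- function(p) {
    v <- vessel_segment(viscosity_mu = p$mu, youngs_E = p$E)
    vapply(sig, function(s) {
      res <- suppressWarnings(total_pressure_loss(
        stenosis_spec(s, vessel = v), flow_condition(mls_to_m3s(1))))
      res$dp_total
    }, numeric(1))
  }
  base <- list(mu = 3.5e-3, E = 0.4e6, frequency = 50)
  tab <- oat_sensitivity(model, base)
  # the loss model ignores drive frequency: all-zero response
  f_rows <- tab[tab$parameter == "frequency", ]
  expect_true(all(f_rows$relative_change == 0))
  # +20% viscosity at sigma = 0 raises the loss by exactly 20%
  mu_up <- tab[tab$parameter == "mu" & tab$direction == 1, ]
  expect_equal(mu_up$relative_change[1], 0.2, tolerance = 1e-12)
  # smooth model: near-antisymmetric first-order response at +/- 1%
  small <- oat_sensitivity(model, base, perturbation = 0.01)
  up <- small[small$parameter == "mu" & small$direction == 1, "relative_change"]
  dn <- small[small$parameter == "mu" & small$direction == -1, "relative_change"]
  expect_equal(up, -dn, tolerance = 1e-2)
  # failing model: flagged, not fatal
  bad <- oat_sensitivity(function(p) if (p$a > 1) stop("boom") else sig,
                         list(a = 1))
  expect_true(any(!is.na(bad$error)))
})

test_that("repeatability statistics detect stability and drift", {
  levels <- seq(100, 500, length.out = 40)   # one row per sweep level
  # identical series: CV zero, no drift
  runs <- cbind(levels, levels, levels)
  rep0 <- repeatability_stats(runs, levels)
  expect_true(all(rep0$per_level$cv == 0))
  expect_equal(rep0$drift_p_value, 1)
  # three replicates with 1% noise: all CVs below 5%
  noisy <- withr::with_seed(2, sapply(1:3, function(i) {
    levels * (1 + rnorm(length(levels), sd = 0.01))
  }))
  repn <- repeatability_stats(noisy, levels)
  expect_true(all(repn$per_level$cv < 0.05))
  # shift the last series by 10 sd: drift detected
  sd_lvl <- apply(noisy, 1, sd)
  shifted <- noisy
  shifted[, 3] <- shifted[, 3] + 10 * sd_lvl
  expect_lt(repeatability_stats(shifted, levels)$drift_p_value, 0.01)
  expect_error(repeatability_stats(noisy[, 1, drop = FALSE]), ">= 2")
  expect_error(repeatability_stats(noisy, levels[-1]), "mismatch")
})
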