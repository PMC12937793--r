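ref_vessel <- vessel_segment()

test_that("throat radius and loss coefficients follow the severity law", {
  expect_equal(throat_radius(0, 1.5e-3), 1.5e-3)
  expect_equal(throat_radius(0.5, 1.5e-3), 0.75e-3)
  expect_equal(throat_radius(0.9, 1.5e-3), 0.15e-3)
  expect_error(throat_radius(1, 1.5e-3), "sigma")
  lc0 <- loss_coefficient(0)
  expect_equal(lc0$beta, 1)
  expect_equal(lc0$zeta, 0)
  lc5 <- loss_coefficient(0.5)
  expect_equal(lc5$beta, 0.25)
  expect_equal(lc5$zeta, 9)
  lc9 <- loss_coefficient(0.9)
  expect_equal(lc9$beta, 0.01)
  expect_equal(lc9$zeta, 9801)
  expect_error(loss_coefficient(1.2), "sigma")
})

test_that("form loss is zero for a healthy lumen and quadratic in flow", {
  expect_identical(form_loss(0, ref_vessel, mls_to_m3s(1)), 0)
  fl <- form_loss(0.5, ref_vessel, mls_to_m3s(1))
  expect_equal(fl, 1527.4, tolerance = 1e-4)
  expect_equal(form_loss(0.5, ref_vessel, mls_to_m3s(3)) / fl, 9)
})

test_that("the reference sweep reproduces every self-consistent table cell", {
  tab <- stenosis_sweep()
  rest <- tab[tab$label == "rest", ]
  hyper <- tab[tab$label == "hyperemia", ]
  # rest pressures at printed precision
  expect_equal(round(rest$dP_mmHg[rest$sigma == 0], 2), 0.40)
  expect_equal(round(rest$dP_mmHg[rest$sigma == 0.25], 2), 0.76)
  expect_equal(round(rest$dP_mmHg[rest$sigma == 0.50], 2), 12.91)
  expect_equal(signif(rest$dP_mmHg[rest$sigma == 0.75], 3), 4.60e3)
  expect_equal(signif(rest$dP_mmHg[rest$sigma == 0.90], 3), 7.80e6)
  # hyperemia pressures (self-consistent cells only)
  expect_equal(round(hyper$dP_mmHg[hyper$sigma == 0], 2), 1.19)
  expect_equal(round(hyper$dP_mmHg[hyper$sigma == 0.25], 2), 3.18)
  expect_equal(round(hyper$dP_mmHg[hyper$sigma == 0.50], 2), 107.47)
  # FFR
  expect_equal(round(rest$ffr[rest$sigma == 0], 3), 0.996)
  expect_equal(round(rest$ffr[rest$sigma == 0.25], 3), 0.992)
  expect_equal(round(rest$ffr[rest$sigma == 0.50], 3), 0.871)
  expect_equal(round(hyper$ffr[hyper$sigma == 0], 3), 0.988)
  expect_equal(round(hyper$ffr[hyper$sigma == 0.25], 3), 0.968)
  expect_true(hyper$clamped[hyper$sigma == 0.50])
  expect_true(all(rest$clamped[rest$sigma >= 0.75]))
})

test_that("throat velocity and wall shear match the reported magnitudes", {
  expect_equal(round(throat_velocity(stenosis_spec(0), mls_to_m3s(1)), 2), 0.14)
  expect_equal(round(throat_velocity(stenosis_spec(0.5), mls_to_m3s(1)), 2), 0.57)
  expect_gt(throat_velocity(stenosis_spec(0.9), mls_to_m3s(3)), 42)
  expect_gt(throat_velocity(stenosis_spec(0.9), mls_to_m3s(1)), 14)
  expect_equal(wall_shear(stenosis_spec(0), mls_to_m3s(1)), 1.32,
               tolerance = 1e-3)
  expect_gt(wall_shear(stenosis_spec(0.9), mls_to_m3s(3)), 3900)
  # tau_w ~ r^-3: halving the throat radius multiplies shear by 8
  expect_equal(wall_shear(stenosis_spec(0.5), mls_to_m3s(1)) /
                 wall_shear(stenosis_spec(0), mls_to_m3s(1)), 8)
})

test_that("severity bins are exhaustive and match the clinical mapping", {
  expect_equal(severity_class(0.25), "mild")
  expect_equal(severity_class(0.50), "moderate")
  expect_equal(severity_class(0.75), "severe")
  expect_equal(severity_class(0.95), "critical")
  expect_equal(severity_class(c(0, 0.30, 0.70, 0.90)),
               c("mild", "moderate", "severe", "critical"))
  grid <- seq(0, 0.999, by = 0.001)
  expect_false(any(is.na(severity_class(grid))))
})

test_that("loss components scale exactly linearly (viscous) and quadratically (form) in Q", {
  spec <- stenosis_spec(0.5)
  r1 <- total_pressure_loss(spec, flow_condition(mls_to_m3s(1)))
  r3 <- suppressWarnings(total_pressure_loss(spec, flow_condition(mls_to_m3s(3))))
  expect_equal(r3$dp_baseline / r1$dp_baseline, 3)
  expect_equal(r3$dp_throat / r1$dp_throat, 3)
  expect_equal(r3$dp_form / r1$dp_form, 9)
  # conservation: the total is the exact sum of its components
  expect_identical(r1$dp_total, r1$dp_baseline + r1$dp_throat + r1$dp_form)
  expect_identical(r3$dp_total, r3$dp_baseline + r3$dp_throat + r3$dp_form)
})

test_that("model equals brute-force formula evaluation on random (sigma, Q) pairs", {
  set.seed(42)
  sigmas <- runif(100, 0, 0.95)
  flows <- runif(100, 0.2e-6, 5e-6)
  for (k in seq_len(100)) {
    res <- suppressWarnings(total_pressure_loss(
      stenosis_spec(sigmas[k]), flow_condition(flows[k])))
    expect_equal(res$dp_total, oracle_dp_total(sigmas[k], flows[k]),
                 tolerance = 1e-12)
  }
})

test_that("FFR stays in [0,1], clamps with a warning, and dP grows with severity and flow", {
  expect_warning(total_pressure_loss(stenosis_spec(0.75),
                                     flow_condition(mls_to_m3s(1))),
                 "clamped")
  grid <- expand.grid(sigma = seq(0, 0.9, length.out = 10),
                      Q = seq(0.5e-6, 3e-6, length.out = 10))
  dp <- mapply(function(s, q) {
    res <- suppressWarnings(total_pressure_loss(stenosis_spec(s),
                                                flow_condition(q)))
    expect_gte(res$ffr, 0); expect_lte(res$ffr, 1)
    expect_lte(res$ffr_raw, 1)
    if (!res$clamped) expect_equal(res$ffr, res$ffr_raw)
    res$dp_total
  }, grid$sigma, grid$Q)
  m <- matrix(dp, 10, 10)
  expect_true(all(diff(m) > 0))        # increasing in sigma at fixed Q
  expect_true(all(t(diff(t(m))) > 0))  # increasing in Q at fixed sigma
})

test_that("replace-throat mode removes the double-counted window", {
  spec <- stenosis_spec(0.5)
  cond <- flow_condition(mls_to_m3s(1))
  add <- total_pressure_loss(spec, cond)
  rep <- total_pressure_loss(spec, cond, mode = "replace-throat")
  win <- 8 * ref_vessel$viscosity_mu * spec$throat_length_Ls /
    (pi * ref_vessel$radius_r0^4) * cond$flow_Q
  expect_equal(add$dp_total - rep$dp_total, win)
  # identical at sigma = 0 (no throat term in either mode)
  s0 <- stenosis_spec(0)
  expect_equal(total_pressure_loss(s0, cond)$dp_total,
               total_pressure_loss(s0, cond, mode = "replace-throat")$dp_total)
})

test_that("surrogate maps reduce to the point model and are monotone", {
  one <- surrogate_maps(0.5, mls_to_m3s(1))
  expect_equal(dim(one$dP_mmHg), c(1, 1))
  expect_equal(one$dP_mmHg[1, 1], 12.91, tolerance = 1e-4)
  m <- surrogate_maps(seq(0, 0.9, by = 0.1), mls_to_m3s(c(0.5, 1, 2, 3)))
  expect_true(all(diff(m$dP_mmHg) > 0))
  expect_true(all(t(diff(t(m$dP_mmHg))) > 0))
  expect_true(all(diff(m$WSS) > 0))
  expect_true(all(diff(m$V_mps) > 0))
  mlog <- surrogate_maps(c(0, 0.5), mls_to_m3s(1), log10_wss = TRUE)
  expect_equal(10^mlog$WSS, surrogate_maps(c(0, 0.5), mls_to_m3s(1))$WSS)
})

test_that("sweep flags invalid rows instead of aborting", {
  tab <- suppressWarnings(
    stenosis_sweep(sigmas = c(0, 0.5),
                   conditions = list(flow_condition(mls_to_m3s(1), label = "rest")),
                   throat_length_Ls = 1))  # Ls > vessel length: per-row error
  expect_true(all(!is.na(tab$error)))
  expect_equal(nrow(tab), 2)
})
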