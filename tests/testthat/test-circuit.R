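test_that("solver reproduces the two-element closed forms", {
  # resistive divider: |u_out/u_in| = Rb / (Ra + Rb)
  div <- circuit_network(
    data.frame(kind = c("R", "R"), value = c(100, 300),
               n1 = c("in", "out"), n2 = c("out", "gnd"),
               label = c("Ra", "Rb")),
    source = list(amplitude = 2, frequency = 50, offset = 0),
    variable_branch = "Rb")
  resp <- mna_solve(div)
  expect_equal(resp$u_out / resp$u_in, 300 / 400, tolerance = 1e-12)
  # series R + shunt C: solved current recovers |Z_C| = 1/(2 pi f C)
  C <- 1e-6; f <- 50; R <- 50
  rc <- circuit_network(
    data.frame(kind = c("R", "C"), value = c(R, C),
               n1 = c("in", "out"), n2 = c("out", "gnd"),
               label = c("R", "C")),
    source = list(amplitude = 1, frequency = f, offset = 0),
    variable_branch = "R")
  resp <- mna_solve(rc)
  i_mag <- Mod((resp$node_phasors[["in"]] - resp$node_phasors[["out"]]) / R)
  expect_equal(resp$u_out / i_mag, 1 / (2 * pi * f * C), tolerance = 1e-10)
})

test_that("default ladder agrees with brute-force impedance reduction", {
  for (R in c(25, 100, 400, 1000)) {
    net <- set_variable_resistance(build_default_network(), R)
    resp <- mna_solve(net)
    ref <- oracle_ladder_uout(R)
    expect_equal(resp$u_out, ref$prox, tolerance = 1e-10)
    expect_equal(Mod(resp$node_phasors[["dist"]]), ref$dist,
                 tolerance = 1e-10)
  }
  # and off the nominal frequency
  resp <- mna_solve(set_variable_resistance(build_default_network(), 250),
                    f = 120)
  expect_equal(resp$u_out, oracle_ladder_uout(250, f = 120)$prox,
               tolerance = 1e-10)
})

test_that("unclipped solver is linear in the source amplitude", {
  n1 <- build_default_network(amplitude = 1)
  n5 <- build_default_network(amplitude = 5)
  r1 <- mna_solve(n1)
  r5 <- mna_solve(n5)
  expect_equal(r5$node_phasors, 5 * r1$node_phasors, tolerance = 1e-12)
})

test_that("the 40-level sweep is passive, consistent and monotone", {
  tab <- resistance_sweep()
  expect_equal(nrow(tab), 40)
  expect_true(all(is.na(tab$error)))
  expect_true(all(tab$Uout_V <= tab$Uin_V))
  expect_true(all(diff(tab$Uout_V) > 0))   # more lesion resistance, more output
  # a single sweep row equals a direct solve at that level
  net <- set_variable_resistance(build_default_network(), tab$R_ohm[17])
  expect_equal(mna_solve(net)$u_out, tab$Uout_V[17])
  # oscilloscope semantics: v_pp = 2 A, v_avg = (2/pi) A
  expect_equal(tab$Vpp_mV, 2e3 * tab$Uout_V)
  expect_equal(tab$Vavg_mV, (2 / pi) * 1e3 * tab$Uout_V)
})

test_that("response at 49.9 Hz deviates under 1% from 50 Hz", {
  net <- build_default_network()
  u50 <- mna_solve(net, f = 50)$u_out
  u499 <- mna_solve(net, f = 49.9)$u_out
  expect_lt(abs(u499 - u50) / u50, 0.01)
})

test_that("severity maps to lesion resistance by the inverse fourth-power law", {
  expect_equal(stenosis_to_resistance(0, 100), 100)
  expect_equal(stenosis_to_resistance(0.5, 100), 1600)
  sig <- seq(0, 0.95, by = 0.05)
  expect_equal(resistance_to_stenosis(stenosis_to_resistance(sig, 83.4), 83.4),
               sig, tolerance = 1e-12)
  expect_error(resistance_to_stenosis(50, 100), ">=")
})

test_that("netlists survive a JSON round trip", {
  net <- build_default_network()
  path <- withr::local_tempfile(fileext = ".json")
  netlist_to_json(net, path)
  back <- netlist_from_json(path)
  expect_equal(back$branches, net$branches)
  expect_equal(back$source$amplitude, net$source$amplitude)
  expect_equal(back$variable_full_scale, net$variable_full_scale)
  expect_equal(mna_solve(back)$u_out, mna_solve(net)$u_out)
})

test_that("a floating subnetwork is diagnosed by node name", {
  expect_error(circuit_network(
    data.frame(kind = c("R", "R"), value = c(10, 10),
               n1 = c("in", "orphanA"), n2 = c("gnd", "orphanB"),
               label = c("Ra", "Rb")),
    source = list(amplitude = 1, frequency = 50, offset = 0),
    variable_branch = "Ra"),
    "orphan")
})

test_that("waveform synthesis clips at the rails and keeps oscilloscope semantics", {
  net <- build_default_network()
  resp <- mna_solve(net)
  # amplitude below the rails: phasor prediction preserved
  w <- synthesize_waveform(resp, rails = 10, samples_per_cycle = 2000)
  expect_false(w$clipped)
  expect_equal(w$v_pp, resp$v_pp, tolerance = 1e-5)
  expect_equal(w$v_avg, (2 / pi) * resp$u_out, tolerance = 1e-3)
  # rails at half the amplitude: saturated square-ish wave, v_pp = 2 rails
  w2 <- synthesize_waveform(resp, rails = resp$u_out / 2)
  expect_true(w2$clipped)
  expect_equal(w2$v_pp, resp$u_out)
  expect_true(all(abs(w2$u) <= resp$u_out / 2 + 1e-12))
})
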