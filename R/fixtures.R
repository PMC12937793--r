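# Packaged reference tables (machine-readable fixtures of the bench
# sweep, the 0D stenosis sweep and the clinical cohort summary) plus
# seeded synthetic generators so every module is testable offline.

fixture_path <- function(name) {
  p <- system.file("extdata", name, package = "padflow")
  if (p == "") stop("packaged fixture not found: ", name)
  p
}

#' Load the packaged 40-level bench sweep recording
#'
#' The measured-hardware sweep: one row per resistance level (2.5% steps of
#' full scale), with input voltage `Uin_V`, mean output `Uoff_V`,
#' peak-to-peak `Vpp_mV` and rectified-mean `Vavg_mV`. This is a measured
#' artifact of the physical board, packaged for the statistics module; the
#' circuit solver is not expected to regenerate it numerically. Two
#' transcription notes: rows 33/34 were recorded out of order in the source
#' and are stored sorted by test index with values preserved, and row 3's
#' `Vavg` carried a trailing stray character, stored as 49. A basic
#' integrity checksum is verified on load.
#'
#' @return data.frame with columns `test`, `Uin_V`, `Uoff_V`, `Vpp_mV`,
#'   `Vavg_mV`, `resistance_fraction`.
#' @export
load_table2 <- function() {
  x <- utils::read.csv(fixture_path("table2_sweep.csv"))
  if (nrow(x) != 40 || !identical(x$test, 1:40) ||
      abs(x$Uoff_V[1] - 3.520) > 1e-9 || abs(x$Uoff_V[40] - 5.421) > 1e-9 ||
      abs(x$Vpp_mV[40] - 32190.56) > 1e-6) {
    stop("bench sweep fixture failed its integrity check")
  }
  x$resistance_fraction <- 0.025 * x$test
  x
}

#' Load the packaged 0D stenosis reference sweep
#'
#' Pressure loss and FFR versus stenosis severity at rest (Q = 1 mL/s) and
#' hyperemia (Q = 3 mL/s). Clamped FFR cells (printed "~0.00") are encoded
#' as 0.0 with a `*_clamped` flag; `*_sigfigs` records the printed
#' precision; the 75% and 90% hyperemia pressure cells are flagged
#' `unit_suspect_hyper` (their printed magnitudes correspond to the model's
#' value in pascals, not mmHg).
#'
#' @return data.frame; one row per severity (0, 25, 50, 75, 90 percent).
#' @export
load_table3 <- function() {
  x <- utils::read.csv(fixture_path("table3_stenosis.csv"))
  if (nrow(x) != 5 || abs(x$dP_rest_mmHg[3] - 12.91) > 1e-9) {
    stop("stenosis reference fixture failed its integrity check")
  }
  x
}

#' Load the packaged clinical cohort summary
#'
#' Group means and SDs for 20 patients in five severity groups: Doppler PSV
#' and PSVR, simplified-Bernoulli clinical gradient, ABI, and the analog's
#' voltage difference with its pressure equivalent. `psvr_rep` is a
#' representative ratio inside each printed range; the normal group's
#' clinical gradient is printed only as "< 2" and stored as 1 with the
#' original text in `dP_clin_note`.
#'
#' @return data.frame; one row per severity group, `n` summing to 20.
#' @export
load_table5 <- function() {
  x <- utils::read.csv(fixture_path("table5_cohort.csv"))
  if (nrow(x) != 5 || sum(x$n) != 20) {
    stop("cohort fixture failed its integrity check")
  }
  x
}

#' Synthetic bench-style sweep recordings
#'
#' Emulates the bench pattern — output voltage nearly constant at low
#' resistance levels, then rising steeply once the level passes a mid-range
#' inflection — as a continuous linear hinge plus seeded Gaussian noise.
#' Defaults emulate the packaged recording's range: baseline 3.52 V rising
#' to about 5.42 V over 40 levels with the inflection at mid-range.
#' Deterministic for a fixed seed.
#'
#' @param n_levels Number of levels (>= 4), default 40.
#' @param baseline_u Baseline mean output voltage (V).
#' @param inflection_level Level fraction in (0, 1) where the steep rise
#'   starts, default 0.5.
#' @param slope_low,slope_high Voltage slope (V per unit level fraction)
#'   below and above the inflection.
#' @param noise_sd Gaussian noise SD (V), >= 0.
#' @param seed RNG seed.
#' @return data.frame with `test`, `resistance_fraction`, `Uoff_V` and the
#'   noiseless mean curve `Uoff_mean_V`.
#' @export
synth_sweep <- function(n_levels = 40, baseline_u = 3.52,
                        inflection_level = 0.5, slope_low = 0.1,
                        slope_high = 3.6, noise_sd = 0.01, seed = 0) {
  stopifnot(n_levels >= 4, inflection_level > 0, inflection_level < 1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  frac <- seq_len(n_levels) / n_levels
  mu <- baseline_u + slope_low * frac +
    slope_high * pmax(frac - inflection_level, 0)
  noise <- if (noise_sd > 0) {
    with_seed(seed, stats::rnorm(n_levels, sd = noise_sd))
  } else rep(0, n_levels)
  data.frame(test = seq_len(n_levels), resistance_fraction = frac,
             Uoff_V = mu + noise, Uoff_mean_V = mu)
}

#' Synthetic calibration pairs
#'
#' Reference pressure differences on a uniform grid with voltage
#' differences \eqn{\Delta U = k_P \Delta P (1 + \epsilon)}, where
#' \eqn{\epsilon} is seeded Gaussian noise relative to the signal
#' (`noise_rel`, e.g. 0.02 for 2%). Feeds [fit_kp()] recovery experiments.
#'
#' @param n Number of pairs (>= 2), default 20.
#' @param k_P_true True constant (V/mmHg), default 0.125.
#' @param noise_rel Relative noise SD (fraction of each dU), >= 0.
#' @param dP_range Range of reference pressures (mmHg), default 2-45.
#' @param seed RNG seed.
#' @return data.frame with `dP_mmHg` and `dU_V`.
#' @export
synth_calibration_pairs <- function(n = 20, k_P_true = 0.125,
                                    noise_rel = 0, dP_range = c(2, 45),
                                    seed = 0) {
  stopifnot(n >= 2, k_P_true > 0, noise_rel >= 0)
  dP <- seq(dP_range[1], dP_range[2], length.out = n)
  dU <- k_P_true * dP
  if (noise_rel > 0) {
    dU <- dU * (1 + with_seed(seed, stats::rnorm(n, sd = noise_rel)))
  }
  data.frame(dP_mmHg = dP, dU_V = dU)
}

#' Export the packaged fixtures as CSV files
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
export_fixtures <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  out <- vapply(c("table2_sweep.csv", "table3_stenosis.csv",
                  "table5_cohort.csv"), function(f) {
    dest <- file.path(dir, f)
    file.copy(fixture_path(f), dest, overwrite = TRUE)
    dest
  }, character(1))
  invisible(out)
}
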