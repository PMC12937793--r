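# Pressure-voltage calibration: k_P fitting and voltage->pressure conversion.

#' Default pressure-voltage calibration constant
#'
#' k_P = 0.125 V/mmHg, the experimentally calibrated constant of the PCB
#' analog, shipped as a package default.
#' @export
KP_DEFAULT <- 0.125

#' Convert a measured voltage difference to a pressure equivalent
#'
#' \eqn{\Delta p = \Delta U / k_P} with `k_P` in V/mmHg. Note the source
#' hardware documentation writes the relation as a product, which is
#' dimensionally inconsistent with k_P in V/mmHg; every printed numeric use
#' (e.g. 0.5 V -> 4 mmHg, 5.4 V -> 43 mmHg at k_P = 0.125) corresponds to
#' division, which is what is implemented.
#'
#' @param dU Voltage difference (V). Vectorised.
#' @param k_P Calibration constant (V/mmHg), > 0.
#' @return Pressure difference (mmHg).
#' @examples
#' voltage_to_pressure(0.5)   # 4 mmHg
#' voltage_to_pressure(5.42)  # ~43 mmHg
#' @export
voltage_to_pressure <- function(dU, k_P = KP_DEFAULT) {
  stopifnot(is.numeric(dU), all(is.finite(dU)))
  if (!is.finite(k_P) || k_P <= 0) stop("k_P must be > 0")
  dU / k_P
}

#' Fit the calibration constant k_P from paired data
#'
#' Origin-constrained least squares of voltage difference on reference
#' pressure difference: \eqn{\Delta U = k_P \Delta P}. A zero voltage
#' difference must map to zero pressure difference, hence the fit through
#' the origin. The 95% CI is a case-resampling percentile bootstrap
#' (default 1000 draws, seeded). R^2 is the origin-constrained
#' (uncentered) coefficient of determination.
#'
#' @param pairs data.frame with columns `dU_V` (volts) and `dP_mmHg`
#'   (reference pressure differences).
#' @param n_bootstrap Bootstrap draws (default 1000).
#' @param seed RNG seed for the bootstrap.
#' @return Object of class `calibration_fit`: `k_P`, `ci95` (length 2),
#'   `r_squared`, `n_pairs`.
#' @examples
#' p <- data.frame(dP_mmHg = c(4, 10, 24, 43))
#' p$dU_V <- 0.125 * p$dP_mmHg
#' fit_kp(p)$k_P  # 0.125 exactly
#' @export
fit_kp <- function(pairs, n_bootstrap = 1000, seed = 0) {
  stopifnot(is.data.frame(pairs), all(c("dU_V", "dP_mmHg") %in% names(pairs)))
  dU <- pairs$dU_V
  dP <- pairs$dP_mmHg
  if (length(dU) < 2) stop("at least 2 calibration pairs are required")
  if (stats::var(dP) == 0) stop("dP_mmHg has zero variance; need distinct reference pressures")
  point <- function(u, p) sum(u * p) / sum(p * p)
  k <- point(dU, dP)
  resid <- dU - k * dP
  r2 <- 1 - sum(resid^2) / sum(dU^2)
  boots <- with_seed(seed, {
    vapply(seq_len(n_bootstrap), function(i) {
      take <- sample.int(length(dU), replace = TRUE)
      point(dU[take], dP[take])
    }, numeric(1))
  })
  structure(list(k_P = k,
                 ci95 = unname(stats::quantile(boots, c(0.025, 0.975))),
                 r_squared = r2, n_pairs = length(dU),
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit> k_P = %.4g V/mmHg (95%% CI %.4g-%.4g), R2 = %.4f, n = %d\n",
              x$k_P, x$ci95[1], x$ci95[2], x$r_squared, x$n_pairs))
  invisible(x)
}

# Run code under a local RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
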