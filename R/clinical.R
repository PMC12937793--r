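# Clinical-side quantities: ankle-brachial index, Doppler PSV ratio
# grading, simplified-Bernoulli gradients, and concordance of the analog's
# pressure equivalents with clinical group data.

#' Ankle-brachial index (ABI)
#'
#' Ratio of ankle to brachial systolic pressure; the lower of the two limb
#' values is used. ABI of 0.9 or less indicates peripheral artery disease;
#' values above 1.0 are flagged with a warning (outside the usual inclusion
#' range for PAD assessment).
#'
#' @param brachial Brachial systolic pressure (mmHg), > 0.
#' @param ankle_left,ankle_right Ankle systolic pressures (mmHg), > 0.
#' @return The ABI (dimensionless).
#' @examples
#' abi(120, 60, 80)  # 0.5
#' @export
abi <- function(brachial, ankle_left, ankle_right = ankle_left) {
  if (!is.finite(brachial) || brachial <= 0) {
    stop("brachial pressure must be > 0")
  }
  stopifnot(ankle_left > 0, ankle_right > 0)
  value <- min(ankle_left, ankle_right) / brachial
  if (value > 1) {
    warning(sprintf("ABI %.2f exceeds 1.0 (outside the usual inclusion range)",
                    value))
  }
  value
}

#' Peak systolic velocity ratio (PSVR) and its duplex severity grade
#'
#' \eqn{PSVR = PSV_{stenosis} / PSV_{proximal}}. Duplex grading: a ratio
#' below 2.0 corresponds to less than 30% stenosis (normal/mild), 2.0-4.0
#' to moderate stenosis (30-69%), and above 4.0 to severe or critical
#' stenosis (70% or more). Boundary values fall in the moderate bin; the
#' bins are exhaustive and mutually exclusive over (0, Inf).
#'
#' @param psv_sten Peak systolic velocity at the stenosis (m/s), >= 0.
#' @param psv_prox Proximal reference velocity (m/s), > 0.
#' @param psvr A precomputed ratio (for `psvr_grade`).
#' @return `psvr()`: the ratio; `psvr_grade()`: one of `"normal/mild"`,
#'   `"moderate"`, `"severe/critical"`.
#' @examples
#' psvr_grade(psvr(3.0, 1.0))  # moderate
#' @export
psvr <- function(psv_sten, psv_prox) {
  if (!is.finite(psv_prox) || psv_prox <= 0) {
    stop("proximal velocity must be > 0")
  }
  stopifnot(psv_sten >= 0)
  psv_sten / psv_prox
}

#' @rdname psvr
#' @export
psvr_grade <- function(psvr) {
  stopifnot(is.numeric(psvr), all(psvr > 0))
  ifelse(psvr < 2, "normal/mild",
         ifelse(psvr <= 4, "moderate", "severe/critical"))
}

#' Simplified-Bernoulli translesional pressure gradient
#'
#' \eqn{\Delta P_{clin} = 4 (V_{sten}^2 - V_{prox}^2)} with velocities in
#' m/s and the result in mmHg; the factor 4 is the conventional constant
#' folding blood density and the mmHg conversion into the kinetic-energy
#' term. Antisymmetric under swapping the velocities; a negative gradient
#' (stenotic velocity below proximal) is returned with a warning.
#'
#' @param v_sten Peak systolic velocity at the stenosis (m/s), >= 0.
#' @param v_prox Proximal reference velocity (m/s), >= 0.
#' @return Pressure gradient (mmHg).
#' @examples
#' bernoulli_dp(2.3, 0.767)  # 18.8 mmHg
#' @export
bernoulli_dp <- function(v_sten, v_prox) {
  stopifnot(is.finite(v_sten), is.finite(v_prox), v_sten >= 0, v_prox >= 0)
  dp <- 4 * (v_sten^2 - v_prox^2)
  if (dp < 0) warning("negative gradient: stenotic velocity below proximal")
  dp
}

#' Concordance of analog pressure equivalents with clinical group data
#'
#' For a severity-group table carrying mean voltage differences (`dU_V`)
#' and clinical gradients (`dP_clin_mmHg`), recomputes the pressure
#' equivalent of each group via the calibration constant
#' (\eqn{\Delta P_{eq} = \Delta U / k_P}) and correlates the group means:
#' Pearson r between clinical and analog-equivalent gradients, and between
#' ABI and the analog equivalent (expected strongly negative).
#'
#' @param groups data.frame with columns `label`, `dU_V`, `dP_clin_mmHg`
#'   and optionally `abi_mean`; >= 3 groups.
#' @param k_P Calibration constant (V/mmHg).
#' @return A list: `groups` (input plus recomputed `dP_eq_mmHg`),
#'   `r_clin_eq`, `r_abi_eq` (or `NA` if ABI absent).
#' @export
cohort_concordance <- function(groups, k_P = KP_DEFAULT) {
  need <- c("label", "dU_V", "dP_clin_mmHg")
  missing_cols <- setdiff(need, names(groups))
  if (length(missing_cols) > 0) {
    stop("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(groups) < 3) stop("need >= 3 severity groups")
  groups$dP_eq_mmHg <- voltage_to_pressure(groups$dU_V, k_P)
  r_abi <- if ("abi_mean" %in% names(groups)) {
    pearson_r(groups$abi_mean, groups$dP_eq_mmHg)
  } else NA_real_
  list(groups = groups,
       r_clin_eq = pearson_r(groups$dP_clin_mmHg, groups$dP_eq_mmHg),
       r_abi_eq = r_abi)
}
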