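# 0D surrogate stenosis model: composite viscous + form pressure loss,
# FFR, throat velocity, wall shear stress, severity bins and sweeps.

#' Describe a focal stenosis on a vessel segment
#'
#' Severity is the fractional diameter reduction
#' \eqn{\sigma = 1 - r_s/r_0}, so the throat radius is
#' \eqn{r_s = r_0 (1 - \sigma)}. The throat occupies a short focal window of
#' length `throat_length_Ls` inside the parent segment.
#'
#' @param sigma Fractional diameter reduction, in `[0, 1)`.
#' @param throat_length_Ls Throat length (m), `0 < Ls <= vessel$length_l`.
#' @param vessel The parent [vessel_segment()].
#' @return An object of class `stenosis_spec`.
#' @examples
#' stenosis_spec(0.5)
#' @export
stenosis_spec <- function(sigma, throat_length_Ls = 5e-3,
                          vessel = vessel_segment()) {
  stopifnot(inherits(vessel, "vessel_segment"))
  check_sigma(sigma)
  if (!is.finite(throat_length_Ls) || throat_length_Ls <= 0 ||
      throat_length_Ls > vessel$length_l) {
    stop("throat_length_Ls must satisfy 0 < Ls <= vessel length")
  }
  structure(list(sigma = sigma, throat_length_Ls = throat_length_Ls,
                 vessel = vessel),
            class = "stenosis_spec")
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || any(!is.finite(sigma)) ||
      any(sigma < 0) || any(sigma >= 1)) {
    stop("sigma must lie in [0, 1): sigma >= 1 leaves no lumen")
  }
  invisible(sigma)
}

#' Describe a flow condition
#'
#' @param flow_Q Volumetric flow (m^3/s), > 0. Resting flow in the reference
#'   configuration is 1.0 mL/s; hyperemia 3.0 mL/s.
#' @param proximal_pressure_Pa Proximal (aortic) pressure (Pa), > 0;
#'   default 100 mmHg.
#' @param label Free-text label, e.g. `"rest"` or `"hyperemia"`.
#' @return An object of class `flow_condition`.
#' @examples
#' flow_condition(mls_to_m3s(1), label = "rest")
#' @export
flow_condition <- function(flow_Q,
                           proximal_pressure_Pa = mmhg_to_pa(100),
                           label = "") {
  stopifnot(is.numeric(flow_Q), is.finite(flow_Q), flow_Q > 0,
            is.finite(proximal_pressure_Pa), proximal_pressure_Pa > 0)
  structure(list(flow_Q = flow_Q,
                 proximal_pressure_Pa = proximal_pressure_Pa,
                 label = as.character(label)),
            class = "flow_condition")
}

#' Rest and hyperemia reference conditions
#'
#' Resting flow Q = 1.0 mL/s and hyperemic flow Q = 3.0 mL/s at a proximal
#' pressure of 100 mmHg.
#' @return A list of two [flow_condition()] objects.
#' @export
reference_conditions <- function() {
  list(rest = flow_condition(mls_to_m3s(1), label = "rest"),
       hyperemia = flow_condition(mls_to_m3s(3), label = "hyperemia"))
}

#' Throat radius of a stenosed lumen
#'
#' \eqn{r_s = r_0 (1 - \sigma)}.
#' @param sigma Fractional diameter reduction in `[0, 1)`. Vectorised.
#' @param r0 Reference radius (m), > 0.
#' @return Throat radius (m).
#' @export
throat_radius <- function(sigma, r0) {
  check_sigma(sigma)
  stopifnot(is.finite(r0), r0 > 0)
  r0 * (1 - sigma)
}

#' Area ratio and form-loss coefficient of a stenosis
#'
#' The throat-to-reference area ratio is \eqn{\beta = A_s/A_0 = (1-\sigma)^2}
#' and the separation (minor) loss coefficient is
#' \eqn{\zeta = (1/\beta - 1)^2}. At \eqn{\sigma = 0}, \eqn{\beta = 1} and
#' \eqn{\zeta = 0}: no narrowing, no form loss.
#'
#' @inheritParams throat_radius
#' @return A list with components `beta` and `zeta`.
#' @examples
#' loss_coefficient(0.5)  # beta 0.25, zeta 9
#' @export
loss_coefficient <- function(sigma) {
  check_sigma(sigma)
  beta <- (1 - sigma)^2
  list(beta = beta, zeta = (1 / beta - 1)^2)
}

#' Form (minor) pressure loss across a stenosis throat
#'
#' \eqn{\Delta p_{form} = \tfrac12 \rho \zeta (Q/A_s)^2} with
#' \eqn{A_s = \beta \pi r_0^2}. Zero at \eqn{\sigma = 0}; exactly quadratic
#' in Q.
#'
#' @param sigma Fractional diameter reduction in `[0, 1)`.
#' @param vessel A [vessel_segment()].
#' @param Q Volumetric flow (m^3/s), > 0.
#' @return Pressure loss (Pa).
#' @export
form_loss <- function(sigma, vessel, Q) {
  check_sigma(sigma)
  stopifnot(inherits(vessel, "vessel_segment"), is.finite(Q), Q > 0)
  lc <- loss_coefficient(sigma)
  As <- lc$beta * pi * vessel$radius_r0^2
  0.5 * vessel$density_rho * lc$zeta * (Q / As)^2
}

#' Mean velocity at the stenosis throat
#'
#' \eqn{V = Q / A_s}; at \eqn{\sigma = 0} this is the mean velocity of the
#' healthy lumen.
#'
#' @param spec A [stenosis_spec()].
#' @param Q Volumetric flow (m^3/s), > 0.
#' @return Velocity (m/s).
#' @export
throat_velocity <- function(spec, Q) {
  stopifnot(inherits(spec, "stenosis_spec"), is.finite(Q), Q > 0)
  As <- loss_coefficient(spec$sigma)$beta * pi * spec$vessel$radius_r0^2
  Q / As
}

#' Poiseuille wall shear stress at the stenosis throat
#'
#' \eqn{\tau_w = 4 \mu Q / (\pi r_s^3)}. The physiological band is roughly
#' 1-4 Pa; severe stenoses under hyperemia exceed it by orders of magnitude.
#'
#' @inheritParams throat_velocity
#' @return Wall shear stress (Pa).
#' @export
wall_shear <- function(spec, Q) {
  stopifnot(inherits(spec, "stenosis_spec"), is.finite(Q), Q > 0)
  rs <- throat_radius(spec$sigma, spec$vessel$radius_r0)
  4 * spec$vessel$viscosity_mu * Q / (pi * rs^3)
}

#' Clinical severity class of a stenosis
#'
#' Bins follow duplex-grading convention: diameter reduction up to 25% is
#' mild, 30-60% moderate, 70-80% severe and 90% or more critical. The
#' printed ranges leave gaps; half-open bins covering `[0, 1)` are used:
#' mild < 0.30 <= moderate < 0.70 <= severe < 0.90 <= critical.
#'
#' @param sigma Fractional diameter reduction in `[0, 1)`. Vectorised.
#' @return Character vector of labels among
#'   `"mild"`, `"moderate"`, `"severe"`, `"critical"`.
#' @export
severity_class <- function(sigma) {
  check_sigma(sigma)
  cut(sigma, breaks = c(-Inf, 0.30, 0.70, 0.90, Inf), right = FALSE,
      labels = c("mild", "moderate", "severe", "critical")) |>
    as.character()
}

#' Total pressure loss and derived hemodynamics across a stenosis
#'
#' Composite 0D loss model (mode `"additive-throat"`, the default):
#' \deqn{\Delta P = \underbrace{\frac{8\mu l}{\pi r_0^4} Q}_{baseline}
#'   + \underbrace{\frac{8\mu L_s}{\pi r_s^4} Q}_{throat,\ \sigma>0}
#'   + \underbrace{\tfrac12 \rho \zeta (Q/A_s)^2}_{form}}
#' The baseline term is full-length Poiseuille loss at the reference radius;
#' the throat term adds the Poiseuille loss of the narrowed window at
#' \eqn{r_s} (absent at \eqn{\sigma = 0}); the form term is the separation
#' loss. Mode `"replace-throat"` instead subtracts the throat window's
#' reference-radius contribution before adding the \eqn{r_s} term
#' (physically consistent accounting; non-default).
#'
#' Distal pressure is \eqn{P_d = P_a - \Delta P} and fractional flow reserve
#' \eqn{FFR = P_d/P_a}, clamped to `[0, 1]` (the unclamped value is kept in
#' `ffr_raw`). When \eqn{\Delta P > P_a} a warning is raised and `ffr` is 0.
#'
#' @param spec A [stenosis_spec()].
#' @param cond A [flow_condition()].
#' @param mode Loss composition, `"additive-throat"` (default) or
#'   `"replace-throat"`.
#' @return An object of class `hemo_result`: a list with components
#'   `dp_baseline`, `dp_throat`, `dp_form`, `dp_total` (Pa),
#'   `distal_pressure_Pd` (Pa), `ffr_raw`, `ffr`, `throat_velocity` (m/s),
#'   `wss_throat` (Pa), `throat_radius_rs` (m), `area_ratio_beta`,
#'   `loss_coeff_zeta`, `sigma`, `flow_Q`, `label`, `clamped`.
#' @examples
#' res <- total_pressure_loss(stenosis_spec(0.5),
#'                            flow_condition(mls_to_m3s(1), label = "rest"))
#' pa_to_mmhg(res$dp_total)  # 12.91 mmHg
#' res$ffr                   # 0.871
#' @export
total_pressure_loss <- function(spec, cond,
                                mode = c("additive-throat", "replace-throat")) {
  stopifnot(inherits(spec, "stenosis_spec"), inherits(cond, "flow_condition"))
  mode <- match.arg(mode)
  v <- spec$vessel
  Q <- cond$flow_Q
  lc <- loss_coefficient(spec$sigma)
  rs <- throat_radius(spec$sigma, v$radius_r0)

  dp_baseline <- 8 * v$viscosity_mu * v$length_l / (pi * v$radius_r0^4) * Q
  dp_throat <- if (spec$sigma > 0) {
    dpt <- 8 * v$viscosity_mu * spec$throat_length_Ls / (pi * rs^4) * Q
    if (mode == "replace-throat") {
      dpt <- dpt - 8 * v$viscosity_mu * spec$throat_length_Ls /
        (pi * v$radius_r0^4) * Q
    }
    dpt
  } else 0
  dp_form <- form_loss(spec$sigma, v, Q)
  dp_total <- dp_baseline + dp_throat + dp_form

  Pa <- cond$proximal_pressure_Pa
  ffr_raw <- 1 - dp_total / Pa
  clamped <- ffr_raw < 0
  if (clamped) {
    warning(sprintf(
      "dp_total (%.3g Pa) exceeds proximal pressure (%.3g Pa); FFR clamped to 0",
      dp_total, Pa))
  }
  structure(list(
    dp_baseline = dp_baseline, dp_throat = dp_throat, dp_form = dp_form,
    dp_total = dp_total,
    distal_pressure_Pd = Pa - dp_total,
    ffr_raw = ffr_raw, ffr = min(1, max(0, ffr_raw)),
    throat_velocity = throat_velocity(spec, Q),
    wss_throat = wall_shear(spec, Q),
    throat_radius_rs = rs, area_ratio_beta = lc$beta,
    loss_coeff_zeta = lc$zeta,
    sigma = spec$sigma, flow_Q = Q, label = cond$label, clamped = clamped
  ), class = "hemo_result")
}

#' @export
print.hemo_result <- function(x, ...) {
  cat(sprintf("<hemo_result> sigma = %g, Q = %g mL/s%s\n", x$sigma,
              x$flow_Q * 1e6,
              if (nzchar(x$label)) paste0(" (", x$label, ")") else ""))
  cat(sprintf("  dP = %.4g mmHg (baseline %.3g + throat %.3g + form %.3g Pa)\n",
              pa_to_mmhg(x$dp_total), x$dp_baseline, x$dp_throat, x$dp_form))
  ffr_txt <- if (x$clamped) "~0.00 (clamped)" else sprintf("%.3f", x$ffr)
  cat(sprintf("  FFR = %s, V = %.3g m/s, WSS = %.3g Pa\n",
              ffr_txt, x$throat_velocity, x$wss_throat))
  invisible(x)
}

#' Sweep the stenosis model over severities and flow conditions
#'
#' One row per (sigma, condition) pair. Pressures are reported in mmHg; FFR
#' is clamped with the unclamped value in `ffr_raw` and a `clamped` flag
#' (clamped cells print as "~0.00" in table renderings). Per-row failures
#' are flagged in the `error` column rather than aborting the sweep.
#'
#' @param sigmas Numeric vector of severities; default the reference grid
#'   `c(0, 0.25, 0.50, 0.75, 0.90)`.
#' @param conditions List of [flow_condition()]s; default rest + hyperemia.
#' @param vessel Parent [vessel_segment()].
#' @param throat_length_Ls Throat length (m).
#' @param mode Passed to [total_pressure_loss()].
#' @return A data.frame with columns `sigma`, `label`, `Q_mLs`, `dP_mmHg`,
#'   `ffr`, `ffr_raw`, `clamped`, `V_mps`, `WSS_Pa`, `error`.
#' @examples
#' stenosis_sweep()
#' @export
stenosis_sweep <- function(sigmas = c(0, 0.25, 0.50, 0.75, 0.90),
                           conditions = reference_conditions(),
                           vessel = vessel_segment(),
                           throat_length_Ls = 5e-3,
                           mode = "additive-throat") {
  rows <- list()
  for (s in sigmas) {
    for (cond in conditions) {
      row <- tryCatch({
        res <- suppressWarnings(total_pressure_loss(
          stenosis_spec(s, throat_length_Ls, vessel), cond, mode = mode))
        data.frame(sigma = s, label = cond$label, Q_mLs = cond$flow_Q * 1e6,
                   dP_mmHg = pa_to_mmhg(res$dp_total), ffr = res$ffr,
                   ffr_raw = res$ffr_raw, clamped = res$clamped,
                   V_mps = res$throat_velocity, WSS_Pa = res$wss_throat,
                   error = NA_character_)
      }, error = function(e) {
        data.frame(sigma = s, label = cond$label, Q_mLs = NA_real_,
                   dP_mmHg = NA_real_, ffr = NA_real_, ffr_raw = NA_real_,
                   clamped = NA, V_mps = NA_real_, WSS_Pa = NA_real_,
                   error = conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Surrogate maps of pressure loss, WSS and velocity over a sigma x Q grid
#'
#' Dense gridded fields suitable for contour plotting: pressure loss (mmHg),
#' throat wall shear stress (Pa, optionally log10) and throat velocity
#' (m/s), each as a matrix with severities in rows and flows in columns.
#'
#' @param sigmas Severity grid (non-empty, each in `[0, 1)`).
#' @param flows_Q Flow grid (m^3/s, each > 0).
#' @param vessel Parent [vessel_segment()].
#' @param throat_length_Ls Throat length (m).
#' @param log10_wss If `TRUE`, the WSS map is log10-transformed.
#' @return A list with matrices `dP_mmHg`, `WSS`, `V_mps` (dimnames give the
#'   grids) and the grids themselves.
#' @export
surrogate_maps <- function(sigmas, flows_Q, vessel = vessel_segment(),
                           throat_length_Ls = 5e-3, log10_wss = FALSE) {
  stopifnot(length(sigmas) >= 1, length(flows_Q) >= 1)
  check_sigma(sigmas)
  dims <- list(sigma = as.character(sigmas), Q = as.character(flows_Q))
  dP <- WSS <- V <- matrix(NA_real_, length(sigmas), length(flows_Q),
                           dimnames = dims)
  for (i in seq_along(sigmas)) {
    spec <- stenosis_spec(sigmas[i], throat_length_Ls, vessel)
    for (j in seq_along(flows_Q)) {
      res <- suppressWarnings(total_pressure_loss(
        spec, flow_condition(flows_Q[j])))
      dP[i, j] <- pa_to_mmhg(res$dp_total)
      WSS[i, j] <- res$wss_throat
      V[i, j] <- res$throat_velocity
    }
  }
  if (log10_wss) WSS <- log10(WSS)
  list(dP_mmHg = dP, WSS = WSS, V_mps = V, sigmas = sigmas, flows_Q = flows_Q)
}
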