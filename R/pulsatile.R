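# Quasi-steady pulsatile driving of the 0D stenosis model and a standard
# three-element Windkessel terminal load.

#' Describe a sinusoidal flow waveform
#'
#' \eqn{Q(t) = \bar Q + Q_a \sin(2\pi f t)}, a stand-in for the cardiac
#' pulse with a fundamental frequency in the physiological 1.2-1.5 Hz band.
#' The amplitude must be smaller than the mean so the flow stays positive.
#'
#' @param mean_Q Mean flow (m^3/s), > 0.
#' @param amplitude_Q Oscillation amplitude (m^3/s), `0 <= amplitude < mean`.
#' @param frequency Fundamental frequency (Hz), default 1.2.
#' @param n_cycles Number of cycles to sample, default 5.
#' @param samples_per_cycle Samples per cycle, default 200.
#' @return Object of class `flow_waveform`.
#' @export
flow_waveform <- function(mean_Q, amplitude_Q = 0, frequency = 1.2,
                          n_cycles = 5, samples_per_cycle = 200) {
  stopifnot(is.finite(mean_Q), mean_Q > 0, is.finite(amplitude_Q),
            amplitude_Q >= 0, frequency > 0, n_cycles >= 1,
            samples_per_cycle >= 8)
  if (amplitude_Q >= mean_Q) {
    stop("amplitude_Q must be < mean_Q so the flow stays positive")
  }
  structure(list(mean_Q = mean_Q, amplitude_Q = amplitude_Q,
                 frequency = frequency, n_cycles = n_cycles,
                 samples_per_cycle = samples_per_cycle),
            class = "flow_waveform")
}

#' Sample a flow waveform on a uniform time grid
#'
#' @param w A [flow_waveform()].
#' @return data.frame with columns `t` (s) and `Q` (m^3/s); the grid is
#'   half-open over whole cycles so the time mean of a sinusoid is exact.
#' @export
sample_waveform <- function(w) {
  stopifnot(inherits(w, "flow_waveform"))
  n <- w$n_cycles * w$samples_per_cycle
  tt <- seq(0, w$n_cycles / w$frequency, length.out = n + 1)[-(n + 1)]
  data.frame(t = tt,
             Q = w$mean_Q + w$amplitude_Q * sin(2 * pi * w$frequency * tt))
}

#' Quasi-steady pulsatile pressure loss across a stenosis
#'
#' Applies the steady composite loss model sample-by-sample to a pulsatile
#' flow (quasi-steady assumption: the loss at each instant is that of the
#' steady flow of the same magnitude). Because the Q -> dP map is convex
#' for sigma > 0, the cycle mean of dP exceeds dP at the mean flow.
#'
#' @param spec A [stenosis_spec()].
#' @param w A [flow_waveform()].
#' @param mode Loss composition, passed to [total_pressure_loss()].
#' @return A list with `series` (data.frame: `t`, `Q`, `dP_mmHg`) and
#'   `summary` (final-cycle mean/max/min of dP in mmHg).
#' @export
quasi_steady_dp <- function(spec, w, mode = "additive-throat") {
  stopifnot(inherits(spec, "stenosis_spec"), inherits(w, "flow_waveform"))
  s <- sample_waveform(w)
  dp <- vapply(s$Q, function(q) {
    res <- suppressWarnings(total_pressure_loss(spec, flow_condition(q),
                                                mode = mode))
    pa_to_mmhg(res$dp_total)
  }, numeric(1))
  last <- s$t >= (w$n_cycles - 1) / w$frequency
  list(series = data.frame(t = s$t, Q = s$Q, dP_mmHg = dp),
       summary = c(mean = mean(dp[last]), max = max(dp[last]),
                   min = min(dp[last])))
}

#' Three-element Windkessel terminal load
#'
#' @param char_impedance_Z Characteristic impedance (Pa s/m^3), > 0.
#' @param peripheral_R Peripheral resistance (Pa s/m^3), > 0.
#' @param compliance_C Peripheral compliance (m^3/Pa), > 0.
#' @return Object of class `windkessel_spec`.
#' @export
windkessel_spec <- function(char_impedance_Z, peripheral_R, compliance_C) {
  vals <- c(char_impedance_Z, peripheral_R, compliance_C)
  if (any(!is.finite(vals) | vals <= 0)) stop("all Windkessel elements must be > 0")
  structure(list(char_impedance_Z = char_impedance_Z,
                 peripheral_R = peripheral_R, compliance_C = compliance_C),
            class = "windkessel_spec")
}

#' Integrate the three-element Windkessel pressure response
#'
#' Standard WK3 governing equation (venous outlet pressure taken as zero):
#' \deqn{p + R C \frac{dp}{dt} = (Z + R)\, q + Z R C \frac{dq}{dt}}
#' integrated from `p(0) = 0` with an explicit trapezoidal (Heun) scheme;
#' `dq/dt` is taken by central differences on the uniform grid. For a
#' constant inflow the steady state is \eqn{p = (Z + R) q}; for very large
#' compliance the pulsatile component is absorbed and \eqn{p \approx Z q}
#' above the mean.
#'
#' @param q Inflow series (m^3/s), length >= 2, uniform spacing.
#' @param wk A [windkessel_spec()].
#' @param dt Time step (s), > 0.
#' @return Numeric vector of pressures (Pa), same length as `q`.
#' @export
wk3_pressure <- function(q, wk, dt) {
  stopifnot(inherits(wk, "windkessel_spec"), length(q) >= 2)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  Z <- wk$char_impedance_Z
  R <- wk$peripheral_R
  C <- wk$compliance_C
  n <- length(q)
  dqdt <- c(q[2] - q[1], (q[-(1:2)] - q[-((n - 1):n)]) / 2, q[n] - q[n - 1]) / dt
  rhs <- ((Z + R) * q + Z * R * C * dqdt)
  deriv <- function(p, k) (rhs[k] - p) / (R * C)
  p <- numeric(n)
  for (k in seq_len(n - 1)) {
    k1 <- deriv(p[k], k)
    k2 <- deriv(p[k] + dt * k1, k + 1)
    p[k + 1] <- p[k] + dt * (k1 + k2) / 2
  }
  p
}
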