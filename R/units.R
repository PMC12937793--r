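# Unit conventions: all internal computation is SI (Pa, m, s, m^3/s).
# mmHg and mL/s are accepted at the interface and converted on entry/exit.

#' Conversion constant: pascals per millimetre of mercury
#'
#' Fixed at 133.322 Pa/mmHg throughout the package.
#' @export
PA_PER_MMHG <- 133.322

#' Convert between mmHg and pascals
#'
#' Exact linear conversions using the fixed constant 1 mmHg = 133.322 Pa.
#' The round trip `pa_to_mmhg(mmhg_to_pa(x))` is the identity to machine
#' precision.
#'
#' @param p Pressure (mmHg for `mmhg_to_pa`, Pa for `pa_to_mmhg`). Vectorised.
#' @return Numeric vector of converted pressures.
#' @examples
#' mmhg_to_pa(100)   # 13332.2 Pa
#' pa_to_mmhg(133.322)
#' @export
mmhg_to_pa <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  p * PA_PER_MMHG
}

#' @rdname mmhg_to_pa
#' @export
pa_to_mmhg <- function(p) {
  stopifnot(is.numeric(p), all(is.finite(p)))
  p / PA_PER_MMHG
}

#' Convert mL/s to m^3/s
#' @param q Flow in mL/s.
#' @return Flow in m^3/s.
#' @export
mls_to_m3s <- function(q) {
  stopifnot(is.numeric(q), all(is.finite(q)))
  q * 1e-6
}

#' Describe an arterial segment
#'
#' A `vessel_segment` holds the physical description of a straight arterial
#' segment: geometry (length, lumen radius, wall thickness), wall stiffness
#' (Young's modulus) and the fluid (density, dynamic viscosity). All fields
#' are SI. The default values describe the representative epicardial segment
#' used throughout the stenosis model: l = 30 mm, r0 = 1.5 mm, h = 0.2 r0,
#' E = 0.4 MPa, rho = 1060 kg/m^3, mu = 3.5e-3 Pa s.
#'
#' @param length_l Segment length (m), > 0.
#' @param radius_r0 Lumen radius (m), > 0.
#' @param wall_thickness_h Wall thickness (m), > 0 and < `radius_r0`.
#' @param youngs_E Young's modulus of the wall (Pa), > 0.
#' @param density_rho Fluid density (kg/m^3), > 0.
#' @param viscosity_mu Dynamic viscosity (Pa s), > 0.
#' @return An object of class `vessel_segment`.
#' @examples
#' v <- vessel_segment()
#' vessel_resistance(v)
#' @export
vessel_segment <- function(length_l = 0.03,
                           radius_r0 = 1.5e-3,
                           wall_thickness_h = 0.2 * radius_r0,
                           youngs_E = 0.4e6,
                           density_rho = 1060,
                           viscosity_mu = 3.5e-3) {
  fields <- c(length_l = length_l, radius_r0 = radius_r0,
              wall_thickness_h = wall_thickness_h, youngs_E = youngs_E,
              density_rho = density_rho, viscosity_mu = viscosity_mu)
  if (!all(is.finite(fields)) || any(fields <= 0)) {
    stop("all vessel_segment fields must be finite and strictly positive")
  }
  if (wall_thickness_h >= radius_r0) {
    stop("wall_thickness_h must be smaller than radius_r0")
  }
  structure(as.list(fields), class = "vessel_segment")
}

#' @export
print.vessel_segment <- function(x, ...) {
  cat("<vessel_segment>\n")
  cat(sprintf("  l = %g mm, r0 = %g mm, h = %g mm\n",
              x$length_l * 1e3, x$radius_r0 * 1e3, x$wall_thickness_h * 1e3))
  cat(sprintf("  E = %g MPa, rho = %g kg/m3, mu = %g mPa.s\n",
              x$youngs_E / 1e6, x$density_rho, x$viscosity_mu * 1e3))
  invisible(x)
}

#' Read a vessel segment from a JSON configuration block
#'
#' Keys mirror the `vessel_segment` field names. Unit-suffixed aliases are
#' accepted and converted on entry: `length_mm`, `radius_mm`,
#' `wall_thickness_mm` (millimetres), `youngs_E_MPa` (megapascals) and
#' `viscosity_mPas` (millipascal-seconds).
#'
#' @param path Path to a JSON file, or a JSON string.
#' @return A `vessel_segment`.
#' @export
vessel_from_json <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  args <- list()
  take <- function(si, alias, scale) {
    if (!is.null(cfg[[si]])) return(cfg[[si]])
    if (!is.null(cfg[[alias]])) return(cfg[[alias]] * scale)
    NULL
  }
  args$length_l <- take("length_l", "length_mm", 1e-3)
  args$radius_r0 <- take("radius_r0", "radius_mm", 1e-3)
  args$wall_thickness_h <- take("wall_thickness_h", "wall_thickness_mm", 1e-3)
  args$youngs_E <- take("youngs_E", "youngs_E_MPa", 1e6)
  args$viscosity_mu <- take("viscosity_mu", "viscosity_mPas", 1e-3)
  if (!is.null(cfg$density_rho)) args$density_rho <- cfg$density_rho
  do.call(vessel_segment, args[!vapply(args, is.null, logical(1))])
}

#' Hemodynamic-electrical analog components of a vessel segment
#'
#' The classical 0D mapping of a straight elastic vessel to an electrical
#' R-L-C triplet:
#' \describe{
#'   \item{resistance}{Poiseuille hydraulic resistance
#'     \eqn{R = 8 \mu l / (\pi r^4)}, Pa s/m^3 — viscous losses.}
#'   \item{inertance}{\eqn{L = \rho l / (\pi r^2)}, kg/m^4 — inertia of the
#'     blood column (electrical inductance).}
#'   \item{compliance}{\eqn{C = 3 \pi r^3 l / (2 E h)}, m^3/Pa — elastic
#'     volume storage of the wall (electrical capacitance).}
#' }
#'
#' @param v A [vessel_segment()].
#' @return For `vessel_resistance`/`vessel_inertance`/`vessel_compliance`, a
#'   single number in the units above. `vessel_rlc()` returns all three as a
#'   named list of class `analog_rlc`.
#' @examples
#' v <- vessel_segment()
#' vessel_resistance(v)  # 5.28e7 Pa s/m3
#' vessel_rlc(v)
#' @export
vessel_resistance <- function(v) {
  stopifnot(inherits(v, "vessel_segment"))
  8 * v$viscosity_mu * v$length_l / (pi * v$radius_r0^4)
}

#' @rdname vessel_resistance
#' @export
vessel_inertance <- function(v) {
  stopifnot(inherits(v, "vessel_segment"))
  v$density_rho * v$length_l / (pi * v$radius_r0^2)
}

#' @rdname vessel_resistance
#' @export
vessel_compliance <- function(v) {
  stopifnot(inherits(v, "vessel_segment"))
  3 * pi * v$radius_r0^3 * v$length_l / (2 * v$youngs_E * v$wall_thickness_h)
}

#' @rdname vessel_resistance
#' @export
vessel_rlc <- function(v) {
  structure(list(resistance_R = vessel_resistance(v),
                 inertance_L = vessel_inertance(v),
                 compliance_C = vessel_compliance(v)),
            class = "analog_rlc")
}

#' @export
print.analog_rlc <- function(x, ...) {
  cat("<analog_rlc>\n")
  cat(sprintf("  R = %.4e Pa.s/m3\n  L = %.4e kg/m4\n  C = %.4e m3/Pa\n",
              x$resistance_R, x$inertance_L, x$compliance_C))
  invisible(x)
}
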