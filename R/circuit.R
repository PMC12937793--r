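# Frequency-domain R-L-C network solver (complex modified nodal analysis),
# the 40-step variable-resistance sweep, stenosis<->resistance mapping and
# oscilloscope-style waveform measurements with supply-rail clipping.

#' Build an R-L-C circuit network
#'
#' A network is a set of two-terminal branches (resistor `R` in ohms,
#' inductor `L` in henry, capacitor `C` in farad) between named nodes, an AC
#' voltage source between the input node and ground, and one designated
#' variable branch representing the stenosis resistor.
#'
#' @param branches data.frame with columns `kind` ("R"/"L"/"C"), `value`
#'   (Ohm/H/F, all > 0), `n1`, `n2` (node names) and `label`.
#' @param source List with `amplitude` (V), `frequency` (Hz), `offset` (V).
#' @param input,output,ground Node names.
#' @param variable_branch Label of the stenosis resistor.
#' @param variable_full_scale Full-scale resistance (Ohm) of the variable
#'   element; sweep levels are fractions of this value.
#' @return Object of class `circuit_network`.
#' @seealso [build_default_network()], [mna_solve()]
#' @export
circuit_network <- function(branches, source, input = "in", output = "out",
                            ground = "gnd", variable_branch = "stenosis",
                            variable_full_scale = 1000) {
  stopifnot(is.data.frame(branches),
            all(c("kind", "value", "n1", "n2", "label") %in% names(branches)))
  branches$kind <- as.character(branches$kind)
  branches$n1 <- as.character(branches$n1)
  branches$n2 <- as.character(branches$n2)
  branches$label <- as.character(branches$label)
  if (!all(branches$kind %in% c("R", "L", "C"))) {
    stop("branch kind must be one of R, L, C")
  }
  if (any(!is.finite(branches$value) | branches$value <= 0)) {
    stop("all component values must be finite and > 0")
  }
  nodes <- sort(unique(c(branches$n1, branches$n2, input, output, ground)))
  net <- structure(list(nodes = nodes, branches = branches, source = source,
                        input = input, output = output, ground = ground,
                        variable_branch = variable_branch,
                        variable_full_scale = variable_full_scale),
                   class = "circuit_network")
  check_connected(net)
  if (!variable_branch %in% branches$label) {
    stop("variable_branch '", variable_branch, "' not found among branch labels")
  }
  net
}

# Every node must be reachable from ground through branches; a floating
# subnetwork makes the nodal system singular.
check_connected <- function(net) {
  adj <- rbind(net$branches[, c("n1", "n2")],
               data.frame(n1 = net$input, n2 = net$ground))
  reached <- net$ground
  repeat {
    nxt <- unique(c(adj$n2[adj$n1 %in% reached], adj$n1[adj$n2 %in% reached]))
    nxt <- setdiff(nxt, reached)
    if (length(nxt) == 0) break
    reached <- c(reached, nxt)
  }
  floating <- setdiff(net$nodes, reached)
  if (length(floating) > 0) {
    stop("singular network: node(s) disconnected from ground: ",
         paste(floating, collapse = ", "))
  }
  invisible(net)
}

#' @export
print.circuit_network <- function(x, ...) {
  cat(sprintf("<circuit_network> %d nodes, %d branches\n",
              length(x$nodes), nrow(x$branches)))
  cat(sprintf("  source: %g V @ %g Hz at '%s'; output at '%s'\n",
              x$source$amplitude, x$source$frequency, x$input, x$output))
  cat(sprintf("  variable branch '%s' (full scale %g Ohm)\n",
              x$variable_branch, x$variable_full_scale))
  invisible(x)
}

#' The default PCB analog network
#'
#' Canonical ladder honoring the printed component values
#' (R1 = 71.6, R2 = 0.8, R3 = 83.4 Ohm; C1 = C2 = 490 nF;
#' L = 0.000209 mH): source -> R1 -> R2 -> L1 -> proximal node `prox` with
#' C1 to ground -> stenosis resistor (variable, alias P1/R4) -> L2 ->
#' distal node `dist` with C2 to ground and the load cell R3 parallel C3 to
#' ground. Two symmetric series cells and one parallel load cell. Unprinted
#' values default to C3 = C1 and L1 = L2 = L. Excitation is 5 V AC at
#' 50 Hz.
#'
#' The measured output is the proximal node `prox`: as the lesion
#' resistance rises, pressure (voltage) builds up proximal to the
#' constriction, reproducing the monotone rise of the bench recordings; the
#' node distal to the lesion is available as `dist` in the solved phasors
#' and falls with severity as distal perfusion collapses. The topology is
#' an explicit modelling assumption and fully overridable via
#' [netlist_from_json()].
#'
#' @param variable_resistance Initial stenosis resistance (Ohm); default
#'   2.5% of the 1 kOhm full scale.
#' @param amplitude,frequency Source amplitude (V) and frequency (Hz).
#' @return A [circuit_network()].
#' @export
build_default_network <- function(variable_resistance = 25,
                                  amplitude = 5, frequency = 50) {
  L <- 0.000209e-3
  br <- data.frame(
    kind = c("R", "R", "L", "C", "R", "L", "C", "R", "C"),
    value = c(71.6, 0.8, L, 490e-9, variable_resistance, L, 490e-9,
              83.4, 490e-9),
    n1 = c("in", "m1", "m2", "prox", "prox", "d", "dist", "dist", "dist"),
    n2 = c("m1", "m2", "prox", "gnd", "d", "dist", "gnd", "gnd", "gnd"),
    label = c("R1", "R2", "L1", "C1", "stenosis", "L2", "C2", "R3", "C3"))
  circuit_network(br, source = list(amplitude = amplitude,
                                    frequency = frequency, offset = 0),
                  output = "prox")
}

#' Serialize a network to JSON / read it back
#'
#' @param net A [circuit_network()].
#' @param path Output (input) file path.
#' @return `netlist_from_json()` returns a [circuit_network()];
#'   `netlist_to_json()` returns `path` invisibly.
#' @export
netlist_to_json <- function(net, path) {
  stopifnot(inherits(net, "circuit_network"))
  jsonlite::write_json(
    list(branches = net$branches, source = net$source, input = net$input,
         output = net$output, ground = net$ground,
         variable_branch = net$variable_branch,
         variable_full_scale = net$variable_full_scale),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname netlist_to_json
#' @export
netlist_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  circuit_network(x$branches, source = x$source, input = x$input,
                  output = x$output, ground = x$ground,
                  variable_branch = x$variable_branch,
                  variable_full_scale = x$variable_full_scale)
}

branch_admittance <- function(kind, value, omega) {
  switch(kind,
         R = complex(real = 1 / value),
         L = 1 / complex(imaginary = omega * value),
         C = complex(imaginary = omega * value))
}

#' Solve the network at one frequency (complex nodal analysis)
#'
#' Assembles the complex node admittance system at angular frequency
#' \eqn{2\pi f} with the voltage source handled by a modified-nodal
#' constraint row, and solves for all node phasors. Oscilloscope-style
#' measurements are derived from the output phasor: `v_pp` is twice the
#' amplitude and `v_avg` is the rectified cycle mean \eqn{(2/\pi) A} of an
#' unclipped sinusoid.
#'
#' @param net A [circuit_network()].
#' @param f Frequency (Hz), > 0; defaults to the source frequency.
#' @return Object of class `ac_response`: `node_phasors` (named complex,
#'   ground included as 0), `u_in`, `u_out` (amplitudes, V), `v_pp`,
#'   `v_avg` (V), `frequency` (Hz), `phase_out` (rad).
#' @export
mna_solve <- function(net, f = net$source$frequency) {
  stopifnot(inherits(net, "circuit_network"), is.finite(f), f > 0)
  check_connected(net)
  omega <- 2 * pi * f
  nodes <- setdiff(net$nodes, net$ground)
  idx <- stats::setNames(seq_along(nodes), nodes)
  n <- length(nodes)
  A <- matrix(complex(real = 0), n + 1, n + 1)   # +1: source current unknown
  b <- complex(real = rep(0, n + 1))
  for (k in seq_len(nrow(net$branches))) {
    br <- net$branches[k, ]
    y <- branch_admittance(br$kind, br$value, omega)
    i <- if (br$n1 == net$ground) 0L else idx[[br$n1]]
    j <- if (br$n2 == net$ground) 0L else idx[[br$n2]]
    if (i > 0) A[i, i] <- A[i, i] + y
    if (j > 0) A[j, j] <- A[j, j] + y
    if (i > 0 && j > 0) {
      A[i, j] <- A[i, j] - y
      A[j, i] <- A[j, i] - y
    }
  }
  si <- idx[[net$input]]
  A[si, n + 1] <- 1        # source current into the input node
  A[n + 1, si] <- 1        # constraint: v_in = amplitude
  b[n + 1] <- net$source$amplitude
  x <- tryCatch(solve(A, b), error = function(e) {
    stop("singular nodal system: ", conditionMessage(e))
  })
  phasors <- c(x[seq_len(n)], complex(real = 0))
  names(phasors) <- c(nodes, net$ground)
  amp_out <- Mod(phasors[[net$output]])
  structure(list(node_phasors = phasors,
                 u_in = Mod(phasors[[net$input]]),
                 u_out = amp_out,
                 v_pp = 2 * amp_out,
                 v_avg = (2 / pi) * amp_out,
                 phase_out = Arg(phasors[[net$output]]),
                 frequency = f),
            class = "ac_response")
}

#' @export
print.ac_response <- function(x, ...) {
  cat(sprintf("<ac_response> f = %g Hz: Uin %.4g V, Uout %.4g V, Vpp %.4g V, Vavg %.4g V\n",
              x$frequency, x$u_in, x$u_out, x$v_pp, x$v_avg))
  invisible(x)
}

#' Map stenosis severity to lesion resistance and back
#'
#' Poiseuille resistance scales as the inverse fourth power of the radius,
#' so a fractional diameter reduction sigma maps to
#' \eqn{R_v = R_{base} (1-\sigma)^{-4}}, with exact inverse
#' \eqn{\sigma = 1 - (R_{base}/R_v)^{1/4}}.
#'
#' @param sigma Fractional diameter reduction in `[0, 1)`. Vectorised.
#' @param R_base Baseline (healthy) resistance (Ohm), > 0.
#' @param Rv Lesion resistance (Ohm), must be `>= R_base`.
#' @return Resistance (Ohm) or severity (dimensionless).
#' @export
stenosis_to_resistance <- function(sigma, R_base) {
  check_sigma(sigma)
  stopifnot(is.finite(R_base), R_base > 0)
  R_base * (1 - sigma)^-4
}

#' @rdname stenosis_to_resistance
#' @export
resistance_to_stenosis <- function(Rv, R_base) {
  stopifnot(all(is.finite(Rv)), is.finite(R_base), R_base > 0)
  if (any(Rv < R_base)) stop("Rv must be >= R_base")
  1 - (R_base / Rv)^(1 / 4)
}

#' Sweep the variable resistance over the measurement grid
#'
#' Reproduces the bench protocol: the stenosis resistance is stepped from
#' 2.5% to 100% of full scale in 2.5% increments (40 levels), solving the
#' network at 50 Hz at each step. Per-level solver failures are flagged in
#' the `error` column rather than aborting.
#'
#' @param net A [circuit_network()].
#' @param levels Fractions of full scale; default `seq(0.025, 1, by = 0.025)`.
#' @return data.frame with columns `test`, `level`, `R_ohm`, `Uin_V`,
#'   `Uout_V`, `Vpp_mV`, `Vavg_mV`, `error`.
#' @export
resistance_sweep <- function(net = build_default_network(),
                             levels = seq(0.025, 1, by = 0.025)) {
  stopifnot(inherits(net, "circuit_network"), all(levels > 0))
  rows <- lapply(seq_along(levels), function(i) {
    R <- levels[i] * net$variable_full_scale
    tryCatch({
      resp <- mna_solve(set_variable_resistance(net, R))
      data.frame(test = i, level = levels[i], R_ohm = R,
                 Uin_V = resp$u_in, Uout_V = resp$u_out,
                 Vpp_mV = resp$v_pp * 1e3, Vavg_mV = resp$v_avg * 1e3,
                 error = NA_character_)
    }, error = function(e) {
      data.frame(test = i, level = levels[i], R_ohm = R, Uin_V = NA_real_,
                 Uout_V = NA_real_, Vpp_mV = NA_real_, Vavg_mV = NA_real_,
                 error = conditionMessage(e))
    })
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Set the variable (stenosis) resistance of a network
#'
#' @param net A [circuit_network()].
#' @param R New resistance (Ohm), > 0.
#' @return The modified network.
#' @export
set_variable_resistance <- function(net, R) {
  stopifnot(inherits(net, "circuit_network"), is.finite(R), R > 0)
  net$branches$value[net$branches$label == net$variable_branch] <- R
  net
}

#' Synthesize the time-domain output waveform with rail clipping
#'
#' Reconstructs the output sinusoid from the solved phasor, hard-clips it at
#' the supply rails and recomputes the oscilloscope measurements from the
#' clipped trace: `v_pp` is max minus min over the final full cycle and
#' `v_avg` is the rectified mean \eqn{\langle |u(t)| \rangle}. Clipping
#' reproduces the flattened, rectangular-like traces seen when the solved
#' amplitude exceeds the excitation range.
#'
#' @param resp An [mna_solve()] result.
#' @param rails Clipping rail (V), > 0; trace limited to `[-rails, +rails]`.
#'   Default 5 V (the 0-5 V excitation range).
#' @param n_cycles Number of cycles to synthesize.
#' @param samples_per_cycle Samples per cycle.
#' @return A list with `t` (s), `u` (V, clipped), `u_ideal` (V), `v_pp`,
#'   `v_avg` (V, from the clipped trace) and `clipped` (logical).
#' @export
synthesize_waveform <- function(resp, rails = 5, n_cycles = 5,
                                samples_per_cycle = 1000) {
  stopifnot(inherits(resp, "ac_response"), is.finite(rails), rails > 0,
            n_cycles >= 1, samples_per_cycle >= 8)
  f <- resp$frequency
  tt <- seq(0, n_cycles / f, length.out = n_cycles * samples_per_cycle + 1)
  tt <- tt[-length(tt)]                       # half-open cycle grid
  A <- resp$u_out
  u_ideal <- A * cos(2 * pi * f * tt + resp$phase_out)
  u <- pmin(pmax(u_ideal, -rails), rails)
  last <- tt >= (n_cycles - 1) / f
  list(t = tt, u = u, u_ideal = u_ideal,
       v_pp = max(u[last]) - min(u[last]),
       v_avg = mean(abs(u[last])),
       clipped = A > rails)
}
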