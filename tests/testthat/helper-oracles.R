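# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: direct formula evaluation, series/parallel
# impedance reduction, and exhaustive coupling enumeration.

# Composite stenosis loss by direct formula evaluation (Pa).
oracle_dp_total <- function(sigma, Q, l = 0.03, r0 = 1.5e-3, Ls = 5e-3,
                            mu = 3.5e-3, rho = 1060) {
  rs <- r0 * (1 - sigma)
  beta <- (1 - sigma)^2
  zeta <- (1 / beta - 1)^2
  As <- beta * pi * r0^2
  base <- 8 * mu * l / (pi * r0^4) * Q
  throat <- if (sigma > 0) 8 * mu * Ls / (pi * rs^4) * Q else 0
  form <- 0.5 * rho * zeta * (Q / As)^2
  base + throat + form
}

# Output amplitude of the default ladder by series/parallel reduction.
oracle_ladder_uout <- function(R_sten, f = 50, amplitude = 5,
                               R1 = 71.6, R2 = 0.8, R3 = 83.4,
                               C1 = 490e-9, C2 = 490e-9, C3 = 490e-9,
                               L = 0.000209e-3) {
  w <- 2 * pi * f
  par <- function(...) 1 / sum(1 / c(...))
  ZC <- function(C) complex(imaginary = -1 / (w * C))
  ZL <- complex(imaginary = w * L)
  Zsh_out <- par(ZC(C2), complex(real = R3), ZC(C3))
  Zdown_c <- complex(real = R_sten) + ZL + Zsh_out
  Zc <- par(ZC(C1), Zdown_c)
  v_prox <- amplitude * Zc / (complex(real = R1 + R2) + ZL + Zc)
  v_dist <- v_prox * Zsh_out / Zdown_c
  list(prox = Mod(v_prox), dist = Mod(v_dist))
}

# Discrete Frechet distance by exhaustive enumeration of all monotone
# couplings (exponential; n <= 6 only).
oracle_frechet <- function(a, b) {
  d <- function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))
  rec <- function(i, j) {
    here <- d(i, j)
    if (i == 1 && j == 1) return(here)
    prev <- Inf
    if (i > 1) prev <- min(prev, rec(i - 1, j))
    if (j > 1) prev <- min(prev, rec(i, j - 1))
    if (i > 1 && j > 1) prev <- min(prev, rec(i - 1, j - 1))
    max(here, prev)
  }
  rec(nrow(a), nrow(b))
}

hausdorff_distance <- function(a, b) {
  dmat <- outer(seq_len(nrow(a)), seq_len(nrow(b)),
                Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))))
  max(max(apply(dmat, 1, min)), max(apply(dmat, 2, min)))
}
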