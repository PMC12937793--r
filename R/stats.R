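# Validation-statistics toolkit: normalization, quadratic and segmented
# fits with bootstrap CIs, Pearson r / RMSE, discrete Frechet distance,
# slope-doubling severity, one-at-a-time sensitivity and repeatability.

#' Normalize a curve to its baseline value
#'
#' Elementwise division by the value at `baseline_index`, so the baseline
#' element maps to exactly 1. Idempotent.
#'
#' @param values Numeric vector.
#' @param baseline_index Index of the baseline element (default 1).
#' @return Normalized vector.
#' @export
normalize_curve <- function(values, baseline_index = 1) {
  stopifnot(is.numeric(values), baseline_index >= 1,
            baseline_index <= length(values))
  b <- values[baseline_index]
  if (b == 0) stop("baseline value is zero; cannot normalize")
  values / b
}

#' Quadratic fit with bootstrap confidence intervals
#'
#' Ordinary least squares of \eqn{y = a_0 + a_1 x + a_2 x^2} via
#' [stats::lm()], with per-coefficient 95% CIs from case-resampling
#' percentile bootstrap (default 1000 draws, seeded). For constant `y`
#' (zero variance) R^2 is defined as 0 by convention.
#'
#' @param x,y Numeric vectors (>= 3 distinct `x`).
#' @param n_bootstrap Bootstrap draws.
#' @param seed RNG seed.
#' @return Object of class `curve_fit`: `coefficients` (a0, a1, a2),
#'   `r_squared`, `rmse`, `ci95` (3 x 2 matrix), `n`, `seed`.
#' @export
quadratic_fit <- function(x, y, n_bootstrap = 1000, seed = 0) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 3) stop("need >= 3 distinct x values for a quadratic fit")
  fit1 <- function(x, y) {
    m <- stats::lm(y ~ x + I(x^2))
    stats::coef(m)
  }
  m <- stats::lm(y ~ x + I(x^2))
  co <- stats::setNames(stats::coef(m), c("a0", "a1", "a2"))
  res <- stats::residuals(m)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 0 else 1 - sum(res^2) / ss_tot
  boots <- with_seed(seed, {
    t(vapply(seq_len(n_bootstrap), function(i) {
      take <- sample.int(length(x), replace = TRUE)
      b <- tryCatch(fit1(x[take], y[take]), error = function(e) rep(NA_real_, 3))
      if (length(b) < 3) b <- c(b, rep(NA_real_, 3 - length(b)))
      b
    }, numeric(3)))
  })
  ci <- t(apply(boots, 2, stats::quantile, probs = c(0.025, 0.975),
                na.rm = TRUE))
  dimnames(ci) <- list(c("a0", "a1", "a2"), c("lo", "hi"))
  structure(list(coefficients = co, r_squared = r2,
                 rmse = sqrt(mean(res^2)), ci95 = ci, n = length(x),
                 seed = seed),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("<curve_fit> y = %.4g + %.4g x + %.4g x^2, R2 = %.4f, RMSE = %.4g, n = %d\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' Continuous two-segment (hinge) linear fit with a data-driven breakpoint
#'
#' Fits \eqn{y = b_0 + b_1 x + b_2 (x - \tau)_+} by least squares for each
#' candidate breakpoint \eqn{\tau} among the observed interior `x` values
#' and keeps the SSE-minimizing one; ties are broken toward the smallest
#' breakpoint, so on degenerate (purely linear) data the earliest candidate
#' is returned. The breakpoint is invariant to rescaling `y`. An optional
#' case-resampling bootstrap gives a percentile CI of the breakpoint.
#'
#' @param x,y Numeric vectors (>= 5 points).
#' @param n_bootstrap Bootstrap draws for the breakpoint CI (0 = skip).
#' @param seed RNG seed.
#' @return Object of class `breakpoint_fit`: `breakpoint`, `slope_left`,
#'   `slope_right`, `intercept`, `sse`, `ci95` (or `NULL`), `n`.
#' @export
breakpoint_fit <- function(x, y, n_bootstrap = 0, seed = 0) {
  stopifnot(length(x) == length(y))
  if (length(x) < 5) stop("need >= 5 points for a segmented fit")
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  fit_at <- function(x, y, tau) {
    h <- pmax(x - tau, 0)
    m <- stats::lm(y ~ x + h)
    list(sse = sum(stats::residuals(m)^2), coef = stats::coef(m))
  }
  pick <- function(x, y) {
    cands <- sort(unique(x))
    cands <- cands[cands > min(x) & cands < max(x)]
    if (length(cands) == 0) stop("no interior candidate breakpoints")
    best <- NULL
    for (tau in cands) {    # ascending: strict '<' keeps the smallest tie
      f <- fit_at(x, y, tau)
      if (is.null(best) || f$sse < best$sse - 1e-12 * max(1, best$sse)) {
        best <- c(f, tau = tau)
      }
    }
    best
  }
  best <- pick(x, y)
  co <- best$coef
  ci <- NULL
  if (n_bootstrap > 0) {
    bt <- with_seed(seed, {
      vapply(seq_len(n_bootstrap), function(i) {
        take <- sample.int(length(x), replace = TRUE)
        tryCatch(pick(x[take], y[take])$tau, error = function(e) NA_real_)
      }, numeric(1))
    })
    ci <- unname(stats::quantile(bt, c(0.025, 0.975), na.rm = TRUE))
  }
  structure(list(breakpoint = best$tau,
                 slope_left = unname(co[2]),
                 slope_right = unname(co[2] + co[3]),
                 intercept = unname(co[1]),
                 sse = best$sse, ci95 = ci, n = length(x)),
            class = "breakpoint_fit")
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("<breakpoint_fit> breakpoint = %.4g; slopes %.4g -> %.4g; SSE %.4g; n = %d\n",
              x$breakpoint, x$slope_left, x$slope_right, x$sse, x$n))
  invisible(x)
}

#' Severity at which the fitted slope doubles
#'
#' For a quadratic fit \eqn{y = a_0 + a_1 \sigma + a_2 \sigma^2} with
#' positive `a1` and `a2`, the slope \eqn{a_1 + 2 a_2 \sigma} doubles its
#' initial value at \eqn{\sigma^* = a_1 / (2 a_2)}.
#'
#' @param fit A [quadratic_fit()] result.
#' @return The severity `sigma*` in `[0, 1]`.
#' @export
slope_doubling_sigma <- function(fit) {
  stopifnot(inherits(fit, "curve_fit"))
  a1 <- fit$coefficients[["a1"]]
  a2 <- fit$coefficients[["a2"]]
  if (!is.finite(a1) || !is.finite(a2) || a1 <= 0 || a2 <= 0) {
    stop("slope-doubling severity undefined: need a1 > 0 and a2 > 0")
  }
  s <- a1 / (2 * a2)
  if (s > 1) stop("slope-doubling severity falls outside [0, 1]")
  s
}

#' Pearson correlation and root-mean-square error
#'
#' Thin wrappers with the toolkit's error conventions: equal lengths >= 3
#' and nonzero variance are required for `pearson_r`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return `pearson_r`: the product-moment correlation; `rmse`:
#'   \eqn{\sqrt{\mathrm{mean}((x-y)^2)}}.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need >= 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("zero variance: correlation undefined")
  }
  stats::cor(x, y)
}

#' @rdname pearson_r
#' @export
rmse <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 1)
  sqrt(mean((x - y)^2))
}

#' Discrete Frechet distance between two polygonal curves
#'
#' Standard dynamic-programming recurrence over all monotone couplings of
#' the two point sequences:
#' \eqn{d_F(i,j) = \max(\|a_i - b_j\|, \min(d_F(i-1,j), d_F(i-1,j-1),
#' d_F(i,j-1)))}. Symmetric, non-negative, zero iff the sequences coincide,
#' and never smaller than the Hausdorff distance of the point sets.
#'
#' @param curve_a,curve_b Matrices (n x 2) of 2D points, or numeric vectors
#'   (taken as y-values at x = 1..n).
#' @return The discrete Frechet distance.
#' @export
frechet_distance <- function(curve_a, curve_b) {
  as_pts <- function(cv) {
    if (is.null(dim(cv))) cv <- cbind(seq_along(cv), cv)
    as.matrix(cv)
  }
  a <- as_pts(curve_a)
  b <- as_pts(curve_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty curve")
  n <- nrow(a); m <- nrow(b)
  d <- outer(seq_len(n), seq_len(m),
             Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))))
  ca <- matrix(0, n, m)
  ca[1, 1] <- d[1, 1]
  for (i in seq_len(n)[-1]) ca[i, 1] <- max(ca[i - 1, 1], d[i, 1])
  for (j in seq_len(m)[-1]) ca[1, j] <- max(ca[1, j - 1], d[1, j])
  for (i in seq_len(n)[-1]) {
    for (j in seq_len(m)[-1]) {
      ca[i, j] <- max(d[i, j],
                      min(ca[i - 1, j], ca[i - 1, j - 1], ca[i, j - 1]))
    }
  }
  ca[n, m]
}

#' One-at-a-time (OAT) parameter sensitivity of a model curve
#'
#' Perturbs each named parameter by +/- `perturbation` (default 20%) while
#' holding the others at baseline, re-evaluates the model and reports the
#' relative change of the output curve at each grid point. Model failures
#' are flagged per cell rather than aborting.
#'
#' @param model Function taking a named list of parameters and returning a
#'   numeric vector (the output curve on a fixed grid).
#' @param parameters Named list of baseline parameter values.
#' @param perturbation Relative perturbation (default 0.2).
#' @return data.frame with columns `parameter`, `direction` (+1/-1),
#'   `grid_index`, `relative_change`, `error`.
#' @export
oat_sensitivity <- function(model, parameters, perturbation = 0.2) {
  stopifnot(is.function(model), length(parameters) > 0,
            !is.null(names(parameters)))
  base <- model(parameters)
  rows <- list()
  for (pn in names(parameters)) {
    for (sgn in c(1, -1)) {
      p <- parameters
      p[[pn]] <- p[[pn]] * (1 + sgn * perturbation)
      out <- tryCatch(model(p), error = function(e) e)
      if (inherits(out, "error")) {
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = pn, direction = sgn, grid_index = NA_integer_,
          relative_change = NA_real_, error = conditionMessage(out))
      } else {
        rel <- ifelse(base == 0, ifelse(out == 0, 0, Inf), (out - base) / base)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = pn, direction = sgn, grid_index = seq_along(base),
          relative_change = rel, error = NA_character_)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Repeatability statistics across measurement series
#'
#' Given several independent measurement series over an identical grid of
#' levels, computes the per-level mean, standard deviation and coefficient
#' of variation, and a two-sided paired t-test between the first and last
#' series as a drift check. Identical series give CV 0 everywhere and a
#' degenerate drift p of 1 (no paired differences).
#'
#' @param runs Numeric matrix or data.frame, one column per series, one row
#'   per level (all series on the same level grid).
#' @param levels Optional level labels (length `nrow(runs)`).
#' @return Object of class `repeatability_report`: `per_level` (data.frame
#'   with `level`, `mean`, `sd`, `cv`) and `drift_p_value`.
#' @export
repeatability_stats <- function(runs, levels = NULL) {
  runs <- as.matrix(runs)
  if (ncol(runs) < 2) stop("need >= 2 measurement series")
  if (!is.null(levels) && length(levels) != nrow(runs)) {
    stop("levels length must match the number of rows (mismatched level grids)")
  }
  if (is.null(levels)) levels <- seq_len(nrow(runs))
  mu <- rowMeans(runs)
  sdv <- apply(runs, 1, stats::sd)
  per <- data.frame(level = levels, mean = mu, sd = sdv,
                    cv = ifelse(mu == 0, NA_real_, sdv / abs(mu)))
  diffs <- runs[, ncol(runs)] - runs[, 1]
  p <- if (stats::sd(diffs) == 0) {
    if (all(diffs == 0)) 1 else 0   # exactly constant shift: certain drift
  } else {
    stats::t.test(runs[, ncol(runs)], runs[, 1], paired = TRUE)$p.value
  }
  structure(list(per_level = per, drift_p_value = p),
            class = "repeatability_report")
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("<repeatability_report> %d levels; max CV %.3g%%; drift p = %.3g\n",
              nrow(x$per_level), 100 * max(x$per_level$cv, na.rm = TRUE),
              x$drift_p_value))
  invisible(x)
}
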