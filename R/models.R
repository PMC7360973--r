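#' Bound-complex concentration under ligand depletion
#'
#' Closed-form (quadratic) solution of the law of mass action for the
#' concentration of a 1:1 complex when neither partner is in large excess,
#' so free and total concentrations cannot be equated:
#' \deqn{LR = \frac{(L + R + K_D) - \sqrt{(L + R + K_D)^2 - 4 L R}}{2}}
#' with `L`, `R` the total concentrations and `Kd` the dissociation
#' constant, all in the same units (nM by package convention).
#'
#' @param ligandTotal,receptorTotal total concentrations (>= 0), vectorized.
#' @param Kd dissociation constant (> 0).
#' @return complex concentration, bounded by `0 <= LR <= min(L, R)`.
#' @examples
#' quadraticBound(5, 5, 5)        # 1.90983...
#' quadraticBound(0, 10, 5)       # no ligand -> 0
#' quadraticBound(5, 5, 1e-9)     # stoichiometric limit -> ~5
#' @export
quadraticBound <- function(ligandTotal, receptorTotal, Kd) {
  if (any(ligandTotal < 0) || any(receptorTotal < 0))
    stop("concentrations must be non-negative")
  if (any(Kd <= 0)) stop("Kd must be positive")
  s <- ligandTotal + receptorTotal + Kd
  disc <- s^2 - 4 * ligandTotal * receptorTotal
  (s - sqrt(pmax(disc, 0))) / 2
}

#' Fit an equilibrium titration under ligand depletion
#'
#' Least-squares fit of polarization versus titrant concentration to
#' `signal = signal_free + (signal_bound - signal_free) * LR / probe_total`
#' where `LR` is [quadraticBound()] of the fixed labelled-probe total and
#' the titrant total. The free parameters are `Kd`, `signal_free` and
#' `signal_bound`.
#'
#' @param points data.frame with columns `titrant_nM` and `signal`
#'   (>= 5 points spanning the apparent Kd).
#' @param probeTotal fixed labelled-probe concentration in nM.
#' @return a [ModelFit-class]; on data-quality failure (e.g. zero
#'   amplitude) a non-converged result with a diagnostic message.
#' @examples
#' tt <- genTitration(Kd = 4.7, noiseSd = 0, seed = 1)
#' fitTitration(tt, probeTotal = 5)
#' @export
fitTitration <- function(points, probeTotal) {
  stopifnot(is.data.frame(points),
            all(c("titrant_nM", "signal") %in% names(points)))
  x <- points$titrant_nM
  y <- points$signal
  details <- list(probe_total = probeTotal)
  if (length(x) < 5L)
    return(.fitFailure("titration", "need at least 5 titration points",
                       nobs = length(x), details = details))
  if (any(x < 0) || any(!is.finite(y)))
    return(.fitFailure("titration", "invalid titration data",
                       nobs = length(x), details = details))
  amp <- diff(range(y))
  if (amp <= .Machine$double.eps^0.5 * max(1, max(abs(y))))
    return(.fitFailure("titration", "zero amplitude", nobs = length(x),
                       details = details))

  o <- order(x)
  sf0 <- y[o][1L]
  sb0 <- y[o][length(y)]
  half <- (sf0 + sb0) / 2
  kd0 <- stats::approx(y[o], x[o], xout = half, ties = mean)$y
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- stats::median(x[x > 0])

  model_fn <- function(p, xx)
    p["signal_free"] + (p["signal_bound"] - p["signal_free"]) *
      quadraticBound(probeTotal, xx, p["Kd"]) / probeTotal
  resid_fn <- function(p) y - model_fn(p, x)

  start <- c(Kd = kd0, signal_free = sf0, signal_bound = sb0)
  lower <- c(Kd = 1e-12, signal_free = -Inf, signal_bound = -Inf)
  upper <- c(Kd = Inf, signal_free = Inf, signal_bound = Inf)
  ans <- .lmSolve(resid_fn, start, lower, upper)
  if (is.null(ans) || !(ans$info %in% 1:4))
    return(.fitFailure("titration", "optimizer failed to converge",
                       parameters = if (is.null(ans)) start else ans$par,
                       nobs = length(x), details = details))
  .fitSuccess("titration", ans, nobs = length(x), details = details)
}

#' Delayed single-exponential dissociation model
#'
#' Composite dissociation curve with an initial lag: the signal stays at
#' `y_max` until the delay `t0`, then decays exponentially to `y_0`:
#' \deqn{y(t) = y_{max} \ \mathrm{for}\ t \le t_0;\quad
#'       y(t) = y_0 + (y_{max} - y_0) e^{-k (t - t_0)}\ \mathrm{for}\ t > t_0}
#' Continuous at `t0`.
#'
#' @param t time in minutes (vectorized).
#' @param yMax,y0 plateau and asymptote polarization.
#' @param k dissociation rate, per minute (>= 0).
#' @param t0 delay in minutes (>= 0).
#' @return model signal at `t`.
#' @examples
#' delayExponential(10 + log(2) / 0.05, 200, 80, 0.05, 10)  # 140
#' @export
delayExponential <- function(t, yMax, y0, k, t0) {
  ifelse(t <= t0, yMax, y0 + (yMax - y0) * exp(-k * (t - t0)))
}

#' Fit a single dissociation trace to the delay-exponential model
#'
#' Nonlinear least squares of [delayExponential()] to one trace; `t0` is
#' a free parameter bounded to \[0, 15\] minutes (the lag observed before
#' the exponential phase), `k >= 0`. A monotonically non-decreasing or
#' flat trace is flagged `"no decay"` rather than fitted.
#'
#' @param trace a [KineticTrace-class] or a data.frame with columns
#'   `time_min` and `signal` (>= 10 strictly increasing time points).
#' @param t0Bounds numeric length 2, bounds for the delay (minutes).
#' @return a [ModelFit-class] with parameters `y_max`, `y_0`, `k`, `t0`.
#' @examples
#' tr <- genDissociationTrace(yMax = 200, y0 = 80, k = 0.03, t0 = 7,
#'                            noiseSd = 0, seed = 1)
#' fitDissociation(tr)
#' @export
fitDissociation <- function(trace, t0Bounds = c(0, 15)) {
  if (is(trace, "KineticTrace")) {
    t <- times(trace); y <- signals(trace)
  } else {
    stopifnot(is.data.frame(trace),
              all(c("time_min", "signal") %in% names(trace)))
    t <- trace$time_min; y <- trace$signal
    if (length(t) < 10L)
      return(.fitFailure("dissociation", "need at least 10 time points",
                         nobs = length(t)))
    if (any(diff(t) <= 0))
      return(.fitFailure("dissociation", "time must be strictly increasing",
                         nobs = length(t)))
  }

  n <- length(t)
  amp <- max(y) - min(y)
  head_m <- mean(y[seq_len(min(3L, n))])
  tail_m <- mean(y[seq.int(max(1L, n - 2L), n)])
  scale <- max(abs(y), 1)
  if (amp <= 1e-10 * scale || tail_m >= head_m - 1e-10 * scale)
    return(.fitFailure("dissociation", "no decay", nobs = n))

  ymax0 <- max(y)
  y00 <- min(y)
  half <- (ymax0 + y00) / 2
  below <- which(y < ymax0 - 0.05 * (ymax0 - y00))
  t00 <- if (length(below)) max(t[1L], t[below[1L]] - 1) else t[1L]
  t00 <- min(max(t00, t0Bounds[1]), t0Bounds[2])
  cross <- which(y <= half)
  thalf <- if (length(cross)) t[cross[1L]] else stats::median(t)
  k0 <- log(2) / max(thalf - t00, diff(range(t)) / 50)

  resid_fn <- function(p)
    y - delayExponential(t, p["y_max"], p["y_0"], p["k"], p["t0"])
  start <- c(y_max = ymax0, y_0 = y00, k = k0, t0 = t00)
  lower <- c(y_max = -Inf, y_0 = -Inf, k = 0, t0 = t0Bounds[1])
  upper <- c(y_max = Inf, y_0 = Inf, k = Inf, t0 = t0Bounds[2])
  ans <- .lmSolve(resid_fn, start, lower, upper)
  if (is.null(ans) || !(ans$info %in% 1:4))
    return(.fitFailure("dissociation", "optimizer failed to converge",
                       parameters = if (is.null(ans)) start else ans$par,
                       nobs = n))
  .fitSuccess("dissociation", ans, nobs = n)
}

#' Two-state thermal transition model
#'
#' Four-parameter Boltzmann sigmoid on the trimeric fraction versus
#' incubation temperature, with flat baselines:
#' \deqn{f(T) = b_{low} + \frac{b_{high} - b_{low}}
#'   {1 + e^{-s (T - T_m)}}}
#' `s` (`steepness`, per degree C) sets the transition width; `f(Tm)` is
#' the midpoint of the baselines.
#'
#' @param T temperature in degrees C (vectorized).
#' @param Tm midpoint temperature (degrees C).
#' @param steepness transition steepness, per degree C (> 0).
#' @param baselineLow,baselineHigh low/high-temperature plateau fractions.
#' @return trimeric fraction at `T`.
#' @examples
#' thermalFraction(36, 36, 0.8, 0.05, 0.95)  # midpoint = 0.5
#' @export
thermalFraction <- function(T, Tm, steepness, baselineLow, baselineHigh) {
  baselineLow + (baselineHigh - baselineLow) /
    (1 + exp(-steepness * (T - Tm)))
}

#' Fit a thermal trimerization transition
#'
#' Least-squares fit of [thermalFraction()] to (temperature, trimeric
#' fraction) data, returning `Tm` with its standard error. Constant data
#' or a midpoint outside the measured range are flagged as failures.
#'
#' @param points data.frame with columns `temp_C` and `fraction_trimer`
#'   (>= 5 temperatures bracketing the transition).
#' @return a [ModelFit-class] with parameters `Tm`, `steepness`,
#'   `baseline_low`, `baseline_high`.
#' @examples
#' m <- genMelt(Tm = 36, noiseSd = 0, seed = 1)
#' fitThermal(m)
#' @export
fitThermal <- function(points) {
  stopifnot(is.data.frame(points),
            all(c("temp_C", "fraction_trimer") %in% names(points)))
  T <- points$temp_C
  y <- points$fraction_trimer
  n <- length(T)
  if (n < 5L)
    return(.fitFailure("thermal", "need at least 5 temperatures", nobs = n))
  if (diff(range(y)) <= 1e-8)
    return(.fitFailure("thermal", "no transition", nobs = n))

  o <- order(T)
  bl0 <- min(y); bh0 <- max(y)
  half <- (bl0 + bh0) / 2
  tm0 <- stats::approx(y[o], T[o], xout = half, ties = mean)$y
  if (!is.finite(tm0)) tm0 <- stats::median(T)

  resid_fn <- function(p)
    y - thermalFraction(T, p["Tm"], p["steepness"],
                        p["baseline_low"], p["baseline_high"])
  start <- c(Tm = tm0, steepness = 0.5, baseline_low = bl0,
             baseline_high = bh0)
  lower <- c(Tm = -Inf, steepness = 1e-6, baseline_low = -Inf,
             baseline_high = -Inf)
  upper <- c(Tm = Inf, steepness = Inf, baseline_low = Inf,
             baseline_high = Inf)
  ans <- .lmSolve(resid_fn, start, lower, upper)
  if (is.null(ans) || !(ans$info %in% 1:4))
    return(.fitFailure("thermal", "optimizer failed to converge",
                       parameters = if (is.null(ans)) start else ans$par,
                       nobs = n))
  if (ans$par["Tm"] < min(T) || ans$par["Tm"] > max(T))
    return(.fitFailure("thermal", "no transition within range",
                       parameters = ans$par, nobs = n))
  .fitSuccess("thermal", ans, nobs = n)
}
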