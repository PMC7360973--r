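#' Binomial trimer composition from a monomer mixing ratio
#'
#' When wild-type and binding-site-deficient monomers are mixed `a : b`
#' and heat-shocked to trimerize, homo- and heterotrimers assemble with
#' binomial probabilities (expansion of `(a + b)^3`). With
#' `p = a / (a + b)`, the fractions of trimers exposing 3, 2, 1 or 0
#' accessible chaperone sites are `p^3`, `3 p^2 (1-p)`, `3 p (1-p)^2`
#' and `(1-p)^3`.
#'
#' @param a,b non-negative parts of wild-type and mutant monomer
#'   (`a + b > 0`). Alternatively pass a length-2 vector as `a`.
#' @return a [MixtureComposition-class].
#' @examples
#' trimerComposition(2, 1)  # 29.6 / 44.4 / 22.2 / 3.7 %
#' fractions(trimerComposition(1, 1))
#' @export
trimerComposition <- function(a, b = NULL) {
  if (is.null(b)) { stopifnot(length(a) == 2L); b <- a[2]; a <- a[1] }
  if (a < 0 || b < 0) stop("mixing ratio parts must be non-negative")
  if (a + b == 0) stop("mixing ratio must have a positive sum")
  p <- a / (a + b)
  q <- 1 - p
  f <- c(f3 = p^3, f2 = 3 * p^2 * q, f1 = 3 * p * q^2, f0 = q^3)
  f <- f / sum(f)
  new("MixtureComposition", fractions = f, ratio = c(a, b))
}

# Species decay factor: 1 during the lag, exponential afterwards.
.decayFactor <- function(t, k, t0) {
  ifelse(t <= t0, 1, exp(-k * (t - t0)))
}

#' Species-weighted mixture dissociation signal
#'
#' Predicted polarization for a trace containing a binomial mixture of
#' trimer species, each dissociating with a rate set by its number of
#' accessible chaperone sites:
#' \deqn{y(t) = y_0 + (y_{max} - y_0)\,[f_0 + f_1 E(k_1) + f_2 E(k_2)
#'   + f_3 E(k_3)]}
#' with `E(k) = 1` for `t <= t0` and `exp(-k (t - t0))` after the lag.
#' The 0-site species never dissociates: its contribution stays at full
#' amplitude, so the curve plateaus above `y_0` whenever `f0 > 0`.
#'
#' @param t time in minutes (vectorized).
#' @param rates named or plain numeric length 3, `(k1, k2, k3)` per
#'   minute for species with 1, 2, 3 sites.
#' @param comp a [MixtureComposition-class] (or its `fractions` vector).
#' @param yMax,y0 trace amplitude parameters.
#' @param t0 trace lag in minutes.
#' @return model signal at `t`.
#' @examples
#' cmp <- trimerComposition(1, 1)
#' mixtureSignal(0:10, c(0.005, 0.02, 0.05), cmp, 200, 80, 7)
#' @export
mixtureSignal <- function(t, rates, comp, yMax, y0, t0) {
  f <- if (is(comp, "MixtureComposition")) fractions(comp) else comp
  stopifnot(length(rates) == 3L, length(f) == 4L)
  surv <- f[["f0"]] +
    f[["f1"]] * .decayFactor(t, rates[[1]], t0) +
    f[["f2"]] * .decayFactor(t, rates[[2]], t0) +
    f[["f3"]] * .decayFactor(t, rates[[3]], t0)
  y0 + (yMax - y0) * surv
}

#' Null-model trace prediction
#'
#' Competing hypotheses for the mixture experiment, both using a single
#' shared rate (the rate fitted on the pure wild-type trace):
#' \describe{
#'   \item{`single_site_null`}{one accessible site suffices for
#'     dissociation at the full rate, so every species with >= 1 site
#'     decays and only the amplitude changes with the mixing ratio
#'     (decaying fraction `1 - f0`).}
#'   \item{`three_sites_null`}{all three sites are required, so only the
#'     all-wild-type species decays (decaying fraction `f3`).}
#' }
#'
#' @param variant `"single_site_null"` or `"three_sites_null"`.
#' @param t time in minutes (vectorized).
#' @param comp a [MixtureComposition-class] or fractions vector.
#' @param sharedK rate (per minute) fitted on the pure wild-type trace.
#' @param yMax,y0,t0 trace parameters.
#' @return predicted signal at `t`.
#' @examples
#' cmp <- trimerComposition(1, 2)
#' nullPrediction("single_site_null", 0:10, cmp, 0.05, 200, 80, 7)
#' @export
nullPrediction <- function(variant, t, comp, sharedK, yMax, y0, t0) {
  f <- if (is(comp, "MixtureComposition")) fractions(comp) else comp
  decaying <- switch(variant,
    single_site_null = 1 - f[["f0"]],
    three_sites_null = f[["f3"]],
    stop("unknown variant: ", variant))
  surv <- (1 - decaying) + decaying * .decayFactor(t, sharedK, t0)
  y0 + (yMax - y0) * surv
}

# Pick the trace whose composition has the largest f3 (ideally pure wt)
# and fit it alone to initialize/fix the shared rate.
.pureWtIndex <- function(comps) {
  which.max(vapply(comps, function(cc) fractions(cc)[["f3"]], 0))
}

.traceStarts <- function(trace, t0Bounds) {
  y <- signals(trace); t <- times(trace)
  ymax0 <- max(y); y00 <- min(y)
  below <- which(y < ymax0 - 0.05 * max(ymax0 - y00, 1e-12))
  t00 <- if (length(below)) max(t[1L], t[below[1L]] - 1) else t[1L]
  c(y_max = ymax0, y_0 = y00,
    t0 = min(max(t00, t0Bounds[1]), t0Bounds[2]))
}

#' Global fit of the multi-rate mixture model
#'
#' Fits all traces of a mixing-ratio series simultaneously. The rates
#' `k1`, `k2`, `k3` are shared across traces; `y_max` and the lag `t0`
#' are fitted per trace, while the free-DNA baseline `y_0` is a single
#' shared parameter — every trace uses the same labelled probe, and a
#' common baseline is what makes the residual plateaus (the
#' non-dissociating species fractions) informative.
#' Compositions are computed from each trace's
#' mixing ratio via [trimerComposition()]. Rates whose species carry no
#' weight in any supplied trace (e.g. `k1`, `k2` with only a pure
#' wild-type trace) are held at their start value and reported with
#' infinite standard error, and the fit is flagged `"under-determined"`.
#'
#' Rates are initialized from a single delay-exponential fit of the trace
#' with the largest all-wild-type fraction (`k3` start), with
#' `k2 = k3 / 2` and `k1 = k3 / 10`.
#'
#' @param traces list of [KineticTrace-class] objects.
#' @param variant `"full"` (free `k1`,`k2`,`k3`), `"single_site_null"`
#'   or `"three_sites_null"` (single rate fixed from the pure-wt trace;
#'   see [nullPrediction()]).
#' @param t0Bounds numeric length 2, per-trace lag bounds in minutes.
#' @return a [GlobalKineticFit-class].
#' @examples
#' tr <- genMixtureExperiment(noiseSd = 0, seed = 1)
#' globalFitMixture(tr)
#' @export
globalFitMixture <- function(traces, variant = c("full",
                             "single_site_null", "three_sites_null"),
                             t0Bounds = c(0, 15)) {
  variant <- match.arg(variant)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, is, TRUE, "KineticTrace")))
  nt <- length(traces)
  comps <- lapply(traces, function(tr) trimerComposition(mixRatio(tr)))
  labels <- vapply(traces, traceLabel, "")
  labels[!nzchar(labels)] <- paste0("trace", which(!nzchar(labels)))

  # reference single-trace fit on the most wild-type-like trace
  iwt <- .pureWtIndex(comps)
  wt_fit <- fitDissociation(traces[[iwt]], t0Bounds = t0Bounds)
  k_wt <- if (converged(wt_fit)) parameters(wt_fit)[["k"]] else 0.05

  f_mat <- vapply(comps, fractions, numeric(4))  # 4 x nt, rows f3 f2 f1 f0
  weight <- c(k1 = sum(f_mat["f1", ]), k2 = sum(f_mat["f2", ]),
              k3 = sum(f_mat["f3", ]))
  free_rate <- if (variant == "full") weight > 1e-9 else
    c(k1 = FALSE, k2 = FALSE, k3 = FALSE)
  msg <- ""
  if (variant == "full" && !all(free_rate))
    msg <- paste0("under-determined: ",
                  paste(names(free_rate)[!free_rate], collapse = ", "),
                  " carry no weight in the supplied ratios")

  rate_start <- c(k1 = k_wt / 10, k2 = k_wt / 2, k3 = k_wt)
  # Parameter vector: free rates, one shared y_0 (the free-DNA baseline,
  # a property of the common labelled probe), then per-trace (y_max, t0).
  pt_names <- as.vector(t(outer(labels, c("y_max", "t0"),
                                paste, sep = ".")))
  starts_by_trace <- lapply(traces, .traceStarts, t0Bounds = t0Bounds)
  y0_start <- min(vapply(starts_by_trace, `[[`, 0, "y_0"))
  trace_start <- unlist(lapply(starts_by_trace, function(s)
    s[c("y_max", "t0")]))
  nfree_rates <- sum(free_rate)
  lower <- c(rep(0, nfree_rates), -Inf,
             rep(c(-Inf, t0Bounds[1]), nt))
  upper <- c(rep(Inf, nfree_rates), Inf,
             rep(c(Inf, t0Bounds[2]), nt))

  y_all <- unlist(lapply(traces, signals))
  predict_all <- function(p) {
    rr <- rate_start
    rr[free_rate] <- p[seq_len(nfree_rates)]
    y0 <- p[nfree_rates + 1L]
    unlist(lapply(seq_len(nt), function(i) {
      q <- p[nfree_rates + 1L + (i - 1L) * 2L + 1:2]
      if (variant == "full")
        mixtureSignal(times(traces[[i]]), rr, comps[[i]],
                      q[1L], y0, q[2L])
      else
        nullPrediction(variant, times(traces[[i]]), comps[[i]], k_wt,
                       q[1L], y0, q[2L])
    }))
  }
  resid_fn <- function(p) y_all - predict_all(p)

  # Deterministic multi-start over rate patterns (graded, equal, widely
  # spread) guards against the local optimum in which a slow rate pins
  # at zero and trace amplitudes compensate.
  patterns <- list(c(0.1, 0.5, 1), c(1, 1, 1), c(0.02, 0.2, 1),
                   c(0.3, 1, 3))
  ans <- NULL
  for (pat in patterns) {
    st <- c((k_wt * pat)[free_rate], y0_start, trace_start)
    names(st) <- c(names(rate_start)[free_rate], "y_0", pt_names)
    cand <- .lmSolve(resid_fn, st, lower, upper)
    if (is.null(cand)) next
    if (is.null(ans) || cand$deviance < ans$deviance - 1e-12)
      ans <- cand
    if (nfree_rates == 0L) break  # rates fixed: one start suffices
  }
  nobs <- length(y_all)
  if (is.null(ans) || !(ans$info %in% 1:4)) {
    return(new("GlobalKineticFit", variant = variant,
               rates = rate_start,
               rateStderr = c(k1 = NA_real_, k2 = NA_real_, k3 = NA_real_),
               perTrace = data.frame(label = labels),
               rss = NA_real_, nobs = as.integer(nobs), nparams = 0L,
               aic = NA_real_, aicc = NA_real_, bic = NA_real_,
               converged = FALSE,
               message = "optimizer failed to converge"))
  }

  se <- .lmStderr(ans)
  est <- ans$par
  out_rates <- rate_start
  out_rse <- c(k1 = Inf, k2 = Inf, k3 = Inf)
  if (variant == "full") {
    out_rates[free_rate] <- est[seq_len(nfree_rates)]
    out_rse[free_rate] <- se[seq_len(nfree_rates)]
  } else {
    out_rates[] <- k_wt
    out_rse[] <- if (converged(wt_fit)) stderrs(wt_fit)[["k"]] else NA_real_
  }

  y0_est <- est[nfree_rates + 1L]
  y0_se <- se[nfree_rates + 1L]
  pt <- do.call(rbind, lapply(seq_len(nt), function(i) {
    idx <- nfree_rates + 1L + (i - 1L) * 2L + 1:2
    data.frame(label = labels[i],
               ratio_wt = mixRatio(traces[[i]])[1],
               ratio_mut = mixRatio(traces[[i]])[2],
               y_max = est[idx[1L]], y_0 = y0_est,
               t0 = est[idx[2L]],
               y_max_se = se[idx[1L]], y_0_se = y0_se,
               t0_se = se[idx[2L]], stringsAsFactors = FALSE)
  }))
  rownames(pt) <- NULL

  nparams <- length(est)
  ic <- .infoCriteria(ans$deviance, nobs, nparams)
  new("GlobalKineticFit", variant = variant, rates = out_rates,
      rateStderr = out_rse, perTrace = pt, rss = ans$deviance,
      nobs = as.integer(nobs), nparams = as.integer(nparams),
      aic = ic[["aic"]], aicc = ic[["aicc"]], bic = ic[["bic"]],
      converged = TRUE, message = msg)
}

#' Compare the full multi-rate model against the null hypotheses
#'
#' Fits the same traces under the full model (rates depend on the number
#' of accessible sites), the single-site-sufficient null and the
#' three-sites-required null, and tabulates residual sum of squares,
#' parameter counts and information criteria. The lowest-AIC variant is
#' flagged as preferred.
#'
#' @param traces list of [KineticTrace-class] objects.
#' @param t0Bounds per-trace lag bounds in minutes.
#' @return list with `table` (data.frame: `variant`, `converged`, `rss`,
#'   `n_params`, `aic`, `aicc`, `bic`, `daic`, `preferred`) and `fits`
#'   (named list of [GlobalKineticFit-class]).
#' @examples
#' tr <- genMixtureExperiment(noiseSd = 2, seed = 1)
#' compareModels(tr)$table
#' @export
compareModels <- function(traces, t0Bounds = c(0, 15)) {
  variants <- c("full", "single_site_null", "three_sites_null")
  fits <- lapply(variants, function(v)
    globalFitMixture(traces, variant = v, t0Bounds = t0Bounds))
  names(fits) <- variants
  tab <- data.frame(
    variant = variants,
    converged = vapply(fits, converged, TRUE),
    rss = vapply(fits, function(f) f@rss, 0),
    n_params = vapply(fits, function(f) f@nparams, 0L),
    aic = vapply(fits, function(f) f@aic, 0),
    aicc = vapply(fits, function(f) f@aicc, 0),
    bic = vapply(fits, function(f) f@bic, 0),
    stringsAsFactors = FALSE)
  ok <- tab$converged & is.finite(tab$aic)
  tab$daic <- tab$aic - min(tab$aic[ok])
  tab$preferred <- ok & tab$daic == 0
  rownames(tab) <- NULL
  list(table = tab, fits = fits)
}
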