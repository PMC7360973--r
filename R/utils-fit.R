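# Shared nonlinear least-squares machinery: bounded Levenberg-Marquardt
# (minpack.lm::nls.lm) with a deterministic multi-start fallback and
# asymptotic standard errors from the Jacobian at the optimum.

.LM_CTRL <- minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                       maxiter = 500)

# Deterministic start perturbations used when the first start fails to
# converge; scale factors, not random draws, so results are seed-free.
.START_SCALES <- list(1, 0.5, 2, 0.2, 5)

.lmSolve <- function(resid_fn, start, lower, upper) {
  best <- NULL
  for (s in .START_SCALES) {
    st <- pmin(pmax(start * unlist(s), lower), upper)
    ans <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                         fn = resid_fn, control = .LM_CTRL),
      error = function(e) NULL)
    if (is.null(ans)) next
    if (is.null(best) || ans$deviance < best$deviance - 1e-12)
      best <- ans
    if (ans$info %in% 1:4) break  # converged; no further restarts
  }
  best
}

# Standard errors via sigma^2 * (J'J)^-1 at the optimum. Parameters the
# data carry no information on (zero curvature, e.g. the lag of a trace
# that never decays) get Inf; if the identifiable block is still
# singular, NA.
.lmStderr <- function(ans, npar_free = length(ans$par)) {
  n <- length(ans$fvec)
  p <- npar_free
  dof <- max(n - p, 1L)
  s2 <- ans$deviance / dof
  hess <- ans$hessian
  se <- rep(NA_real_, length(ans$par))
  d <- diag(hess)
  ok <- is.finite(d) & d > max(d, 0) * 1e-12
  if (any(ok)) {
    cov <- tryCatch(s2 * solve(hess[ok, ok, drop = FALSE]),
                    error = function(e) NULL)
    if (!is.null(cov)) {
      dv <- diag(cov)
      se[ok] <- ifelse(dv >= 0, sqrt(dv), NA_real_)
      se[!ok] <- Inf
    }
  }
  names(se) <- names(ans$par)
  se
}

.fitFailure <- function(model, message, parameters = numeric(),
                        nobs = 0L, details = list()) {
  new("ModelFit", model = model, parameters = parameters,
      stderr = rep(NA_real_, length(parameters)) |>
        stats::setNames(names(parameters)),
      converged = FALSE, message = message, rss = NA_real_,
      nobs = as.integer(nobs), details = details)
}

.fitSuccess <- function(model, ans, nobs, details = list()) {
  se <- .lmStderr(ans)
  new("ModelFit", model = model, parameters = ans$par, stderr = se,
      converged = TRUE, message = "", rss = ans$deviance,
      nobs = as.integer(nobs), details = details)
}

# Gaussian-likelihood information criteria; residual variance counts as
# one extra parameter.
.infoCriteria <- function(rss, n, p_free) {
  p <- p_free + 1
  ll <- -n / 2 * (log(2 * pi) + log(rss / n) + 1)
  aic <- -2 * ll + 2 * p
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else Inf
  bic <- -2 * ll + log(n) * p
  c(aic = aic, aicc = aicc, bic = bic)
}
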