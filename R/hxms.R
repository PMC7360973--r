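#' Intensity-weighted centroid of an isotope envelope
#'
#' @param envelope an [IsotopeEnvelope-class], or a numeric mass vector
#'   (then `intensity` must be supplied).
#' @param intensity optional numeric intensities when `envelope` is a
#'   plain mass vector.
#' @return centroid mass in Da, `sum(m_i I_i) / sum(I_i)`.
#' @examples
#' centroidMass(c(1250, 1251), c(1, 3))  # 1250.75
#' @export
centroidMass <- function(envelope, intensity = NULL) {
  if (is(envelope, "IsotopeEnvelope")) {
    m <- masses(envelope); i <- intensities(envelope)
  } else {
    m <- envelope; i <- intensity
  }
  tot <- sum(i)
  if (!is.finite(tot) || tot <= 0) stop("total intensity must be positive")
  sum(m * i) / tot
}

#' Maximum number of exchangeable backbone amides of a peptic peptide
#'
#' Standard HX bookkeeping: the N-terminal two residues back-exchange too
#' fast to retain label and prolines have no backbone amide, so the
#' exchangeable count is `length - 2 - (prolines at positions 3..end)`.
#'
#' @param peptide a [PeptideRecord-class] or an amino-acid string
#'   (length >= 3).
#' @return integer count of exchangeable amides.
#' @examples
#' maxExchangeable("NRILGVKRKC")    # 8
#' maxExchangeable("GVKRKIPLMLNC")  # 9 (internal proline)
#' @export
maxExchangeable <- function(peptide) {
  seqc <- if (is(peptide, "PeptideRecord")) peptide@sequence else
    toupper(as.character(peptide))
  n <- nchar(seqc)
  if (n < 3L) stop("peptide too short: fewer than 3 residues")
  chars <- strsplit(seqc, "")[[1L]]
  n - 2L - sum(chars[3:n] == "P")
}

#' Back-exchange-corrected deuteron incorporation
#'
#' Converts an observed centroid into a deuteron count using the
#' undeuterated and 100 %-deuterated reference centroids of the same
#' peptide: the fully deuterated control calibrates out deuterium lost
#' during workup (back-exchange).
#'
#' @param observed observed centroid (Da), vectorized.
#' @param undeut undeuterated reference centroid (Da).
#' @param fulldeut 100 %-deuterated reference centroid (Da);
#'   must exceed `undeut`.
#' @param nMax maximum exchangeable amides ([maxExchangeable()]).
#' @return data.frame with columns `centroid`, `deuterons`
#'   (`(obs - undeut) / (fulldeut - undeut) * nMax`, may be fractional)
#'   and `relative` (`deuterons / nMax`).
#' @examples
#' correctBackExchange(1250.60, 1250.00, 1256.00, nMax = 10)
#' @export
correctBackExchange <- function(observed, undeut, fulldeut, nMax) {
  if (any(fulldeut <= undeut))
    stop("fully deuterated centroid must exceed the undeuterated centroid")
  frac <- (observed - undeut) / (fulldeut - undeut)
  data.frame(centroid = observed, deuterons = frac * nMax,
             relative = frac)
}

#' Per-peptide deuteration difference table between two conditions
#'
#' Computes, for each peptide present in both conditions, the difference
#' in mean deuteron incorporation (condition minus reference; protection
#' is negative), the pooled standard deviation, and a conservative
#' significance flag requiring both a Welch t-test at `alpha` and
#' `|dD| > 2 x pooled SD`. Peptides present on only one side are listed
#' under `unmatched`, never dropped silently.
#'
#' @param condition,reference data.frames with columns `peptide_id` and
#'   `deuterons`, one row per replicate (>= 2 replicates per side).
#' @param alpha Welch t-test significance level.
#' @return list with `differences` (data.frame: `peptide_id`, `n_cond`,
#'   `n_ref`, `dD`, `pooled_sd`, `p_value`, `significant`) and
#'   `unmatched` (data.frame: `peptide_id`, `side`).
#' @examples
#' cond <- data.frame(peptide_id = rep("A", 3), deuterons = c(2.1, 2.0, 2.2))
#' ref <- data.frame(peptide_id = rep("A", 3), deuterons = c(3.0, 2.9, 3.1))
#' differenceTable(cond, ref)$differences
#' @export
differenceTable <- function(condition, reference, alpha = 0.05) {
  stopifnot(all(c("peptide_id", "deuterons") %in% names(condition)),
            all(c("peptide_id", "deuterons") %in% names(reference)))
  pc <- unique(condition$peptide_id)
  pr <- unique(reference$peptide_id)
  shared <- intersect(pc, pr)
  unmatched <- rbind(
    if (length(setdiff(pc, pr)))
      data.frame(peptide_id = setdiff(pc, pr), side = "condition_only"),
    if (length(setdiff(pr, pc)))
      data.frame(peptide_id = setdiff(pr, pc), side = "reference_only"))
  if (is.null(unmatched))
    unmatched <- data.frame(peptide_id = character(), side = character())

  rows <- lapply(shared, function(pid) {
    xc <- condition$deuterons[condition$peptide_id == pid]
    xr <- reference$deuterons[reference$peptide_id == pid]
    nc <- length(xc); nr <- length(xr)
    dD <- mean(xc) - mean(xr)
    pooled <- sqrt(((nc - 1) * stats::var(xc) + (nr - 1) * stats::var(xr)) /
                     max(nc + nr - 2, 1))
    pval <- if (nc >= 2 && nr >= 2 &&
                (stats::sd(xc) > 0 || stats::sd(xr) > 0))
      tryCatch(stats::t.test(xc, xr)$p.value, error = function(e) NA_real_)
    else NA_real_
    sig <- isTRUE(pval < alpha) && is.finite(pooled) && pooled > 0 &&
      abs(dD) > 2 * pooled
    data.frame(peptide_id = pid, n_cond = nc, n_ref = nr, dD = dD,
               pooled_sd = pooled, p_value = pval, significant = sig,
               stringsAsFactors = FALSE)
  })
  diffs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(peptide_id = character(), n_cond = integer(),
               n_ref = integer(), dD = numeric(), pooled_sd = numeric(),
               p_value = numeric(), significant = logical())
  rownames(diffs) <- NULL
  list(differences = diffs, unmatched = unmatched)
}

#' Deconvolve a bimodal isotope envelope into two Gaussian subpopulations
#'
#' Least-squares fit of a two-Gaussian mixture to the stick intensities:
#' \deqn{I(m) = A\,[(1 - p)\,G(m; \mu_{low}, \sigma_{low})
#'   + p\,G(m; \mu_{low} + \delta, \sigma_{high})]}
#' with `G` a normal density, `p` the weight of the high-exchanging mode
#' and `delta > 0` enforcing `mu_low < mu_high`. Sigmas are fitted
#' independently with a common lower bound of 0.3 Da (natural isotope
#' envelope width floor); means are initialized from the 25th/75th
#' intensity-weighted mass percentiles. A fit with `p < 0.02` or
#' `p > 0.98` is flagged `"effectively unimodal"`.
#'
#' If reference centroids are supplied the relative deuteration of each
#' subpopulation is computed from its mean via [correctBackExchange()].
#'
#' @param envelope an [IsotopeEnvelope-class] (>= 8 sticks recommended).
#' @param undeut,fulldeut optional reference centroids (Da) for the
#'   per-subpopulation relative deuteration.
#' @param nMax optional exchangeable-amide count (only used with the
#'   references).
#' @return a [BimodalFit-class].
#' @examples
#' env <- genEnvelope(pHigh = 0.3, noiseSd = 0, seed = 1)
#' fitBimodal(env)
#' @export
fitBimodal <- function(envelope, undeut = NULL, fulldeut = NULL,
                       nMax = NULL) {
  stopifnot(is(envelope, "IsotopeEnvelope"))
  m <- masses(envelope)
  i <- intensities(envelope)
  n <- length(m)

  w <- i / sum(i)
  cum <- cumsum(w)
  q25 <- m[which(cum >= 0.25)[1L]]
  q75 <- m[which(cum >= 0.75)[1L]]
  mu0 <- q25
  delta0 <- max(q75 - q25, 0.5)
  mid <- mu0 + delta0 / 2
  p0 <- min(max(sum(w[m > mid]), 0.05), 0.95)
  spacing <- stats::median(diff(m))
  a0 <- sum(i) * spacing

  model_fn <- function(p) {
    p[["A"]] * ((1 - p[["p"]]) * stats::dnorm(m, p[["mu_low"]],
                                              p[["sigma_low"]]) +
                p[["p"]] * stats::dnorm(m, p[["mu_low"]] + p[["delta"]],
                                        p[["sigma_high"]]))
  }
  resid_fn <- function(p) i - model_fn(p)

  start <- c(p = p0, mu_low = mu0, delta = delta0, sigma_low = 0.6,
             sigma_high = 0.6, A = a0)
  lower <- c(p = 0, mu_low = min(m) - 5, delta = spacing / 10,
             sigma_low = 0.3, sigma_high = 0.3, A = 1e-12)
  upper <- c(p = 1, mu_low = max(m) + 5, delta = diff(range(m)) + 5,
             sigma_low = diff(range(m)), sigma_high = diff(range(m)),
             A = Inf)
  ans <- .lmSolve(resid_fn, start, lower, upper)
  if (is.null(ans) || !(ans$info %in% 1:4))
    return(new("BimodalFit", converged = FALSE,
               message = "optimizer failed to converge"))

  est <- ans$par
  se <- .lmStderr(ans)
  p_high <- est[["p"]]
  mu_low <- est[["mu_low"]]
  mu_high <- est[["mu_low"]] + est[["delta"]]

  # Degenerate ridge: when the two modes coincide within the width of
  # either component the split of weight between them is arbitrary (a
  # single Gaussian is represented equally well by any p). Collapse to
  # the one-mode description, p = 0, instead of reporting an arbitrary
  # mixture of two indistinguishable components.
  if (est[["delta"]] <= max(est[["sigma_low"]], est[["sigma_high"]])) {
    pooled_mu <- (1 - p_high) * mu_low + p_high * mu_high
    mu_low <- pooled_mu
    mu_high <- pooled_mu + est[["delta"]]
    p_high <- 0
  }
  flag <- if (p_high < 0.02 || p_high > 0.98) "effectively unimodal" else ""

  rel_low <- rel_high <- NA_real_
  if (!is.null(undeut) && !is.null(fulldeut)) {
    nm <- if (is.null(nMax)) 1 else nMax
    rel_low <- correctBackExchange(mu_low, undeut, fulldeut, nm)$relative
    rel_high <- correctBackExchange(mu_high, undeut, fulldeut, nm)$relative
  }

  new("BimodalFit", pHigh = p_high, muLow = mu_low, muHigh = mu_high,
      sigmaLow = est[["sigma_low"]], sigmaHigh = est[["sigma_high"]],
      amplitude = est[["A"]], relLow = rel_low, relHigh = rel_high,
      stderr = se, flag = flag, converged = TRUE, message = "",
      rss = ans$deviance)
}

#' Summarize high-exchanging subpopulation fractions across conditions
#'
#' Aggregates bimodal-fit results (mean +/- SD of the high-exchanging
#' fraction per peptide per condition) and flags conditions whose mean
#' exceeds a reference condition's mean by more than two pooled standard
#' deviations — the signature of a chaperone-unfolded subpopulation.
#'
#' @param fits data.frame with columns `peptide_id`, `condition` and
#'   `p_high`, one row per replicate fit (build it from
#'   [fitBimodal()] results).
#' @param reference character, the reference condition name; defaults to
#'   the first condition in the table.
#' @return data.frame with `peptide_id`, `condition`, `n`, `mean_p_high`,
#'   `sd_p_high`, `flagged`.
#' @export
subpopulationSummary <- function(fits, reference = NULL) {
  stopifnot(all(c("peptide_id", "condition", "p_high") %in% names(fits)))
  if (is.null(reference)) reference <- fits$condition[1L]
  if (!reference %in% fits$condition)
    stop("reference condition not present: ", reference)

  agg <- stats::aggregate(p_high ~ peptide_id + condition, data = fits,
                          FUN = function(x) c(n = length(x),
                                              mean = mean(x),
                                              sd = stats::sd(x)))
  out <- data.frame(peptide_id = agg$peptide_id,
                    condition = agg$condition,
                    n = as.integer(agg$p_high[, "n"]),
                    mean_p_high = agg$p_high[, "mean"],
                    sd_p_high = agg$p_high[, "sd"],
                    stringsAsFactors = FALSE)
  out$flagged <- FALSE
  for (pid in unique(out$peptide_id)) {
    iref <- which(out$peptide_id == pid & out$condition == reference)
    if (!length(iref)) next
    for (j in which(out$peptide_id == pid & out$condition != reference)) {
      pooled <- sqrt(mean(c(out$sd_p_high[iref]^2, out$sd_p_high[j]^2),
                          na.rm = TRUE))
      if (is.finite(pooled) && pooled > 0 &&
          out$mean_p_high[j] > out$mean_p_high[iref] + 2 * pooled)
        out$flagged[j] <- TRUE
    }
  }
  out <- out[order(out$peptide_id, out$condition), ]
  rownames(out) <- NULL
  out
}
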