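# Seeded generators for every input the analysis stages consume. Defaults
# reproduce the study conditions: 5 nM labelled probe titrated with
# 0.2-100 nM trimer, dissociation followed 0-100 min at 1-min spacing
# with amplitudes ~200 -> 80 mP and a ~7-min lag, the five-ratio mixing
# design (1:0, 2:1, 1:1, 1:2, 0:1), and the 4-42 degree temperature
# series. Noise is additive homoscedastic Gaussian on the signal
# (multiplicative on envelope intensities). Every generator requires an
# explicit seed and embeds its ground truth in the output metadata.

.withSeed <- function(seed, expr) {
  force(seed)
  withr::with_seed(as.integer(seed), expr)
}

#' Generate a synthetic equilibrium titration
#'
#' Polarization versus titrant concentration under ligand depletion
#' ([quadraticBound()]) plus additive Gaussian noise.
#'
#' @param Kd true dissociation constant (nM).
#' @param probeTotal labelled-probe concentration (nM).
#' @param titrant numeric vector of titrant totals (nM).
#' @param signalFree,signalBound polarization of free and bound probe.
#' @param noiseSd additive Gaussian noise SD (signal units).
#' @param seed integer RNG seed (mandatory).
#' @return data.frame with columns `titrant_nM`, `signal`; the true
#'   parameters are stored in `attr(, "truth")`.
#' @examples
#' head(genTitration(Kd = 4.7, noiseSd = 0, seed = 1))
#' @export
genTitration <- function(Kd = 4.7, probeTotal = 5,
                         titrant = c(0.2, 0.5, 1, 2, 3.5, 5, 7.5, 10, 15,
                                     25, 50, 100),
                         signalFree = 60, signalBound = 210,
                         noiseSd = 0, seed) {
  stopifnot(noiseSd >= 0, Kd > 0)
  mu <- signalFree + (signalBound - signalFree) *
    quadraticBound(probeTotal, titrant, Kd) / probeTotal
  y <- .withSeed(seed, mu + stats::rnorm(length(titrant), 0, noiseSd))
  out <- data.frame(titrant_nM = titrant, signal = y)
  attr(out, "truth") <- list(Kd = Kd, probe_total = probeTotal,
                             signal_free = signalFree,
                             signal_bound = signalBound,
                             noise_sd = noiseSd, seed = seed)
  out
}

#' Generate a synthetic dissociation trace
#'
#' One delay-exponential dissociation trace ([delayExponential()]) plus
#' additive Gaussian noise.
#'
#' @param yMax,y0,k,t0 true curve parameters (signal, signal, per
#'   minute, minutes).
#' @param times time grid in minutes (default 0-100 at 1-min spacing).
#' @param noiseSd additive Gaussian noise SD (signal units).
#' @param ratio,label passed to the [KineticTrace-class].
#' @param seed integer RNG seed (mandatory).
#' @return a [KineticTrace-class]; ground truth in `@metadata$truth`.
#' @examples
#' genDissociationTrace(k = 0.03, noiseSd = 0, seed = 1)
#' @export
genDissociationTrace <- function(yMax = 200, y0 = 80, k = 0.03, t0 = 7,
                                 times = 0:100, noiseSd = 0,
                                 ratio = c(1, 0), label = "wt", seed) {
  stopifnot(noiseSd >= 0)
  mu <- delayExponential(times, yMax, y0, k, t0)
  y <- .withSeed(seed, mu + stats::rnorm(length(times), 0, noiseSd))
  KineticTrace(times, y, ratio = ratio, label = label,
               metadata = list(truth = list(y_max = yMax, y_0 = y0, k = k,
                                            t0 = t0, noise_sd = noiseSd,
                                            seed = seed)))
}

#' Generate a synthetic mixing-ratio experiment
#'
#' Traces for a series of wild-type:mutant mixing ratios, each following
#' the species-weighted mixture model ([mixtureSignal()]) with
#' compositions from [trimerComposition()], plus additive Gaussian noise.
#'
#' @param rates numeric length 3, true `(k1, k2, k3)` per minute.
#' @param ratios list of length-2 mixing ratios; default the five-ratio
#'   design 1:0, 2:1, 1:1, 1:2, 0:1.
#' @param yMax,y0,t0 shared true trace parameters.
#' @param times time grid in minutes.
#' @param noiseSd additive Gaussian noise SD (signal units; 2 % of the
#'   120 mP amplitude by default).
#' @param seed integer RNG seed (mandatory).
#' @return list of [KineticTrace-class]; ground truth in each
#'   `@metadata$truth`.
#' @examples
#' tr <- genMixtureExperiment(noiseSd = 0, seed = 1)
#' length(tr)
#' @export
genMixtureExperiment <- function(rates = c(k1 = 0.005, k2 = 0.02,
                                           k3 = 0.05),
                                 ratios = list(c(1, 0), c(2, 1), c(1, 1),
                                               c(1, 2), c(0, 1)),
                                 yMax = 200, y0 = 80, t0 = 7,
                                 times = 0:100, noiseSd = 2.4, seed) {
  stopifnot(noiseSd >= 0, length(rates) == 3L)
  .withSeed(seed, lapply(seq_along(ratios), function(i) {
    r <- ratios[[i]]
    comp <- trimerComposition(r[1], r[2])
    mu <- mixtureSignal(times, rates, comp, yMax, y0, t0)
    y <- mu + stats::rnorm(length(times), 0, noiseSd)
    KineticTrace(times, y, ratio = r,
                 label = paste0(r[1], ":", r[2]),
                 metadata = list(truth = list(rates = rates, y_max = yMax,
                                              y_0 = y0, t0 = t0,
                                              noise_sd = noiseSd,
                                              seed = seed)))
  }))
}

#' Generate a synthetic (optionally bimodal) isotope envelope
#'
#' Stick intensities from a mixture of two Gaussian mass distributions
#' sampled at the isotopic spacing, multiplied by `(1 + noise)` and
#' clamped at zero.
#'
#' @param pHigh weight of the high-mass (high-exchanging) mode, in
#'   \[0, 1\].
#' @param muLow low-mode centroid (Da); `muHigh = muLow + separation`.
#' @param separation mode separation (Da).
#' @param sigmaLow,sigmaHigh mode widths (Da).
#' @param spacing stick spacing (Da); the average isotopic spacing.
#' @param nSticks number of sticks; the grid starts 4 sigma below
#'   `muLow`.
#' @param amplitude overall intensity scale.
#' @param noiseSd relative (multiplicative) Gaussian noise SD.
#' @param peptideId,condition,replicate envelope annotation.
#' @param undeut,fulldeut reference centroids stored in the metadata for
#'   downstream back-exchange correction.
#' @param seed integer RNG seed (mandatory).
#' @return an [IsotopeEnvelope-class]; ground truth in `@metadata$truth`,
#'   references in `@metadata$undeut` / `@metadata$fulldeut`.
#' @examples
#' genEnvelope(pHigh = 0.3, noiseSd = 0, seed = 1)
#' @export
genEnvelope <- function(pHigh = 0.3, muLow = 1252, separation = 3,
                        sigmaLow = 0.6, sigmaHigh = 0.6,
                        spacing = 1.0024, nSticks = 16,
                        amplitude = 1000, noiseSd = 0.01,
                        peptideId = "pep", condition = "cond",
                        replicate = 1L,
                        undeut = 1250, fulldeut = 1258, seed) {
  stopifnot(pHigh >= 0, pHigh <= 1, noiseSd >= 0)
  mass <- muLow - 4 * sigmaLow + spacing * (seq_len(nSticks) - 1L)
  mu_high <- muLow + separation
  shape <- (1 - pHigh) * stats::dnorm(mass, muLow, sigmaLow) +
    pHigh * stats::dnorm(mass, mu_high, sigmaHigh)
  ii <- amplitude * spacing * shape
  ii <- .withSeed(seed, ii * (1 + stats::rnorm(nSticks, 0, noiseSd)))
  ii <- pmax(ii, 0)
  IsotopeEnvelope(mass, ii, peptideId = peptideId, condition = condition,
                  replicate = replicate,
                  metadata = list(
                    truth = list(p_high = pHigh, mu_low = muLow,
                                 mu_high = mu_high, sigma_low = sigmaLow,
                                 sigma_high = sigmaHigh,
                                 noise_sd = noiseSd, seed = seed),
                    undeut = undeut, fulldeut = fulldeut))
}

#' Generate a synthetic thermal transition
#'
#' Trimeric fraction at the study's incubation temperatures from the
#' two-state sigmoid ([thermalFraction()]) plus additive Gaussian noise,
#' clamped to \[0, 1\].
#'
#' @param Tm true midpoint (degrees C).
#' @param steepness transition steepness (per degree C).
#' @param baselineLow,baselineHigh plateau fractions.
#' @param temps temperature grid (degrees C).
#' @param noiseSd additive Gaussian noise SD (fraction units).
#' @param seed integer RNG seed (mandatory).
#' @return data.frame with columns `temp_C`, `fraction_trimer`; the true
#'   parameters are stored in `attr(, "truth")`.
#' @examples
#' genMelt(Tm = 36, noiseSd = 0, seed = 1)
#' @export
genMelt <- function(Tm = 36, steepness = 0.8, baselineLow = 0.05,
                    baselineHigh = 0.95,
                    temps = c(4, 20, 25, 30, 35, 39, 42),
                    noiseSd = 0, seed) {
  stopifnot(noiseSd >= 0)
  mu <- thermalFraction(temps, Tm, steepness, baselineLow, baselineHigh)
  y <- .withSeed(seed, mu + stats::rnorm(length(temps), 0, noiseSd))
  y <- pmin(pmax(y, 0), 1)
  out <- data.frame(temp_C = temps, fraction_trimer = y)
  attr(out, "truth") <- list(Tm = Tm, steepness = steepness,
                             baseline_low = baselineLow,
                             baseline_high = baselineHigh,
                             noise_sd = noiseSd, seed = seed)
  out
}

#' Generate a random protein sequence
#'
#' Uniform random sequence over the 20-letter alphabet; used by the
#' property tests and the `simulate` pipeline command.
#'
#' @param length sequence length.
#' @param seed integer RNG seed (mandatory).
#' @return character scalar.
#' @export
genSequence <- function(length = 100, seed) {
  .withSeed(seed, paste(sample(.AA20, length, replace = TRUE),
                        collapse = ""))
}
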