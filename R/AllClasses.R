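#' @import methods
NULL

#' KineticTrace: a time-stamped polarization dissociation trace
#'
#' Container for one fluorescence-polarization dissociation reaction:
#' signal versus time for a trimer/DNA complex after chaperone addition,
#' together with the wild-type:mutant monomer mixing ratio used to form
#' the trimers and a free-text label.
#'
#' @slot time numeric, strictly increasing time points in minutes.
#' @slot signal numeric, polarization signal (unit-agnostic, mP-like).
#' @slot ratio numeric length 2, parts of wild-type (`a`) and mutant (`b`)
#'   monomer mixed before trimerization; `a + b > 0`. A pure wild-type
#'   trace is `c(1, 0)`.
#' @slot label character scalar naming the trace.
#' @slot metadata list of free-form annotations (generators store the
#'   ground-truth parameters here).
#'
#' @seealso [KineticTrace()] for the constructor,
#'   [fitDissociation()], [globalFitMixture()].
#' @name KineticTrace-class
#' @rdname KineticTrace-class
#' @exportClass KineticTrace
setClass("KineticTrace",
  representation(
    time = "numeric",
    signal = "numeric",
    ratio = "numeric",
    label = "character",
    metadata = "list"
  ),
  prototype(ratio = c(1, 0), label = "", metadata = list())
)

setValidity("KineticTrace", function(object) {
  msg <- character()
  if (length(object@time) != length(object@signal))
    msg <- c(msg, "time and signal must have equal length")
  if (length(object@time) < 10L)
    msg <- c(msg, "a kinetic trace needs at least 10 time points")
  if (length(object@time) > 1L && any(diff(object@time) <= 0))
    msg <- c(msg, "time must be strictly increasing")
  if (!all(is.finite(object@time)) || !all(is.finite(object@signal)))
    msg <- c(msg, "time and signal must be finite")
  if (length(object@ratio) != 2L || any(object@ratio < 0) ||
      sum(object@ratio) <= 0)
    msg <- c(msg, "ratio must be two non-negative numbers with positive sum")
  if (length(msg)) msg else TRUE
})

#' MixtureComposition: trimer species fractions by accessible-site count
#'
#' Fractions of trimers carrying 3, 2, 1 or 0 accessible chaperone binding
#' sites, as produced by random (binomial) co-assembly of wild-type and
#' binding-site-deficient monomers.
#'
#' @slot fractions named numeric of length 4 (`f3`, `f2`, `f1`, `f0`),
#'   each in \[0, 1\], summing to 1 within 1e-12.
#' @slot ratio numeric length 2, the generating mixing ratio (wt, mutant).
#'
#' @seealso [trimerComposition()]
#' @name MixtureComposition-class
#' @rdname MixtureComposition-class
#' @exportClass MixtureComposition
setClass("MixtureComposition",
  representation(fractions = "numeric", ratio = "numeric"),
  prototype(fractions = c(f3 = 1, f2 = 0, f1 = 0, f0 = 0), ratio = c(1, 0))
)

setValidity("MixtureComposition", function(object) {
  f <- object@fractions
  msg <- character()
  if (length(f) != 4L || !identical(names(f), c("f3", "f2", "f1", "f0")))
    msg <- c(msg, "fractions must be named f3, f2, f1, f0")
  if (any(f < -1e-12) || any(f > 1 + 1e-12))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (abs(sum(f) - 1) > 1e-12)
    msg <- c(msg, "fractions must sum to 1 (tolerance 1e-12)")
  if (length(msg)) msg else TRUE
})

#' PeptideRecord: one peptic peptide with residue coordinates
#'
#' @slot id character scalar identifier (e.g. `"159-168"`).
#' @slot sequence character scalar over the 20-letter amino-acid alphabet.
#' @slot start,end integer residue numbers (1-based, inclusive) in the
#'   parent protein; `end - start + 1 == nchar(sequence)`.
#'
#' @seealso [PeptideRecord()], [maxExchangeable()]
#' @name PeptideRecord-class
#' @rdname PeptideRecord-class
#' @exportClass PeptideRecord
setClass("PeptideRecord",
  representation(id = "character", sequence = "character",
                 start = "integer", end = "integer")
)

setValidity("PeptideRecord", function(object) {
  msg <- character()
  if (object@end - object@start + 1L != nchar(object@sequence))
    msg <- c(msg, "end - start + 1 must equal the sequence length")
  if (!grepl("^[ACDEFGHIKLMNPQRSTVWY]+$", object@sequence))
    msg <- c(msg, "sequence must use the 20 standard amino-acid letters")
  if (length(msg)) msg else TRUE
})

#' IsotopeEnvelope: a decharged isotope stick spectrum
#'
#' Discrete (mass, intensity) sticks for one peptide under one labelling
#' condition, one replicate. Masses are neutral (decharged) and roughly
#' uniformly spaced at the isotopic spacing.
#'
#' @slot mass numeric, strictly increasing stick masses in Da.
#' @slot intensity numeric, non-negative stick intensities with positive
#'   total.
#' @slot peptideId character scalar.
#' @slot condition character scalar labelling condition.
#' @slot replicate integer replicate index.
#' @slot metadata list of annotations (generator ground truth, reference
#'   centroids).
#'
#' @seealso [IsotopeEnvelope()], [centroidMass()], [fitBimodal()]
#' @name IsotopeEnvelope-class
#' @rdname IsotopeEnvelope-class
#' @exportClass IsotopeEnvelope
setClass("IsotopeEnvelope",
  representation(
    mass = "numeric",
    intensity = "numeric",
    peptideId = "character",
    condition = "character",
    replicate = "integer",
    metadata = "list"
  ),
  prototype(peptideId = "", condition = "", replicate = 1L,
            metadata = list())
)

setValidity("IsotopeEnvelope", function(object) {
  msg <- character()
  if (length(object@mass) != length(object@intensity))
    msg <- c(msg, "mass and intensity must have equal length")
  if (length(object@mass) < 4L)
    msg <- c(msg, "an envelope needs at least 4 sticks")
  if (length(object@mass) > 1L && any(diff(object@mass) <= 0))
    msg <- c(msg, "mass must be strictly increasing")
  if (any(object@intensity < 0))
    msg <- c(msg, "intensities must be non-negative")
  if (sum(object@intensity) <= 0)
    msg <- c(msg, "total intensity must be positive")
  if (length(msg)) msg else TRUE
})

#' ScoringMatrix: position-specific chaperone-binding scores
#'
#' A 20 x 13 table of score contributions, one per (amino acid, window
#' offset) pair, for 13-residue sliding-window scanning. Offsets run -6
#' to +6 relative to the window center. Lower (more negative) window sums
#' indicate better Hsp70/Hsc70 binding.
#'
#' @slot entries numeric matrix, 20 rows named by the standard amino-acid
#'   one-letter codes, 13 columns named `"-6"` .. `"6"`; all finite.
#' @slot name character scalar, provenance of the matrix.
#'
#' @seealso [ScoringMatrix()], [readScoringMatrix()], [windowScores()]
#' @name ScoringMatrix-class
#' @rdname ScoringMatrix-class
#' @exportClass ScoringMatrix
setClass("ScoringMatrix",
  representation(entries = "matrix", name = "character"),
  prototype(name = "unnamed")
)

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
.OFFSETS <- as.character(-6:6)

setValidity("ScoringMatrix", function(object) {
  e <- object@entries
  msg <- character()
  if (!is.numeric(e) || nrow(e) != 20L || ncol(e) != 13L)
    msg <- c(msg, "entries must be a numeric 20 x 13 matrix")
  else {
    if (!setequal(rownames(e), .AA20))
      msg <- c(msg, "rows must cover the 20 standard amino acids")
    if (!identical(colnames(e), .OFFSETS))
      msg <- c(msg, "columns must be offsets -6..6")
    if (!all(is.finite(e)))
      msg <- c(msg, "all entries must be finite")
  }
  if (length(msg)) msg else TRUE
})

#' ScoreProfile: per-residue window scores for one sequence
#'
#' Window scores assigned to the center residue of each full 13-residue
#' window; centers span positions 7..(L-6) of a length-L sequence (the
#' termini are untiled).
#'
#' @slot seqId character scalar.
#' @slot centers integer residue numbers (1-based) of window centers.
#' @slot scores numeric, one score per center.
#'
#' @seealso [windowScores()], [callSites()], [countSitesInRange()]
#' @name ScoreProfile-class
#' @rdname ScoreProfile-class
#' @exportClass ScoreProfile
setClass("ScoreProfile",
  representation(seqId = "character", centers = "integer",
                 scores = "numeric")
)

setValidity("ScoreProfile", function(object) {
  msg <- character()
  if (length(object@centers) != length(object@scores))
    msg <- c(msg, "centers and scores must have equal length")
  if (length(object@centers) > 1L && any(diff(object@centers) <= 0))
    msg <- c(msg, "centers must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' ModelFit: result of a single-curve nonlinear least-squares fit
#'
#' Structured result of the bounded trust-region fits used throughout the
#' package. A failed fit is a valid object with `converged = FALSE` and a
#' diagnostic message, never an error, so data-quality problems propagate
#' as flags.
#'
#' @slot model character scalar naming the fitted model
#'   (`"titration"`, `"dissociation"`, `"thermal"`).
#' @slot parameters named numeric, point estimates.
#' @slot stderr named numeric, asymptotic standard errors (NA when the
#'   Jacobian is singular, Inf for non-identifiable parameters).
#' @slot converged logical scalar.
#' @slot message character scalar diagnostic.
#' @slot rss numeric scalar residual sum of squares.
#' @slot nobs integer number of observations.
#' @slot details list of model-specific extras (e.g. `probe_total`).
#'
#' @seealso [fitTitration()], [fitDissociation()], [fitThermal()]
#' @name ModelFit-class
#' @rdname ModelFit-class
#' @exportClass ModelFit
setClass("ModelFit",
  representation(
    model = "character",
    parameters = "numeric",
    stderr = "numeric",
    converged = "logical",
    message = "character",
    rss = "numeric",
    nobs = "integer",
    details = "list"
  ),
  prototype(model = "", parameters = numeric(), stderr = numeric(),
            converged = FALSE, message = "", rss = NA_real_,
            nobs = 0L, details = list())
)

#' GlobalKineticFit: shared-rate global fit across mixing-ratio traces
#'
#' Result of fitting the species-weighted multi-exponential dissociation
#' model to several traces simultaneously: dissociation rates `k1`, `k2`,
#' `k3` (trimers with 1, 2 or 3 accessible sites) shared across traces,
#' `y_max` and delay fitted per trace, the free-DNA baseline `y_0`
#' shared, and the 0-site species held non-dissociating.
#'
#' @slot variant character, one of `"full"`, `"single_site_null"`,
#'   `"three_sites_null"`.
#' @slot rates named numeric (`k1`, `k2`, `k3`), per minute.
#' @slot rateStderr named numeric asymptotic standard errors; `Inf` for
#'   rates not identifiable from the supplied mixing ratios.
#' @slot perTrace data.frame, one row per trace: `label`, `y_max`, `y_0`,
#'   `t0` and their standard errors.
#' @slot rss,nobs,nparams fit statistics.
#' @slot aic,aicc,bic information criteria (Gaussian likelihood, residual
#'   variance counted as one parameter).
#' @slot converged logical.
#' @slot message character diagnostic (e.g. `"under-determined"`).
#'
#' @seealso [globalFitMixture()], [compareModels()]
#' @name GlobalKineticFit-class
#' @rdname GlobalKineticFit-class
#' @exportClass GlobalKineticFit
setClass("GlobalKineticFit",
  representation(
    variant = "character",
    rates = "numeric",
    rateStderr = "numeric",
    perTrace = "data.frame",
    rss = "numeric",
    nobs = "integer",
    nparams = "integer",
    aic = "numeric",
    aicc = "numeric",
    bic = "numeric",
    converged = "logical",
    message = "character"
  ),
  prototype(variant = "full",
            rates = c(k1 = NA_real_, k2 = NA_real_, k3 = NA_real_),
            rateStderr = c(k1 = NA_real_, k2 = NA_real_, k3 = NA_real_),
            perTrace = data.frame(), rss = NA_real_, nobs = 0L,
            nparams = 0L, aic = NA_real_, aicc = NA_real_,
            bic = NA_real_, converged = FALSE, message = "")
)

#' BimodalFit: two-Gaussian deconvolution of a bimodal isotope envelope
#'
#' Mixture of two Gaussian mass distributions fitted to stick intensities,
#' resolving a low- and a high-exchanging conformational subpopulation
#' (EX1-type exchange). The mean ordering `mu_low < mu_high` is enforced
#' by parameterizing `mu_high = mu_low + delta`, `delta > 0`.
#'
#' @slot pHigh numeric in \[0, 1\], weight of the high-exchanging mode.
#' @slot muLow,muHigh numeric mode centroids in Da.
#' @slot sigmaLow,sigmaHigh numeric mode widths in Da (floor 0.3 Da).
#' @slot amplitude numeric overall intensity scale.
#' @slot relLow,relHigh numeric relative deuteration of each mode
#'   (NA unless reference centroids were supplied).
#' @slot stderr named numeric standard errors of the raw parameters.
#' @slot flag character, `""` or `"effectively unimodal"` when
#'   `pHigh < 0.02` or `> 0.98`.
#' @slot converged logical; @slot message character; @slot rss numeric.
#'
#' @seealso [fitBimodal()], [subpopulationSummary()]
#' @name BimodalFit-class
#' @rdname BimodalFit-class
#' @exportClass BimodalFit
setClass("BimodalFit",
  representation(
    pHigh = "numeric",
    muLow = "numeric",
    muHigh = "numeric",
    sigmaLow = "numeric",
    sigmaHigh = "numeric",
    amplitude = "numeric",
    relLow = "numeric",
    relHigh = "numeric",
    stderr = "numeric",
    flag = "character",
    converged = "logical",
    message = "character",
    rss = "numeric"
  ),
  prototype(pHigh = NA_real_, muLow = NA_real_, muHigh = NA_real_,
            sigmaLow = NA_real_, sigmaHigh = NA_real_,
            amplitude = NA_real_, relLow = NA_real_, relHigh = NA_real_,
            stderr = numeric(), flag = "", converged = FALSE,
            message = "", rss = NA_real_)
)
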