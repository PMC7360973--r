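#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: `times()` and
#' `signals()` for [KineticTrace-class], `fractions()` for
#' [MixtureComposition-class], `masses()` and `intensities()` for
#' [IsotopeEnvelope-class], `centers()` and `scores()` for
#' [ScoreProfile-class], and `parameters()`, `stderrs()`, `converged()`
#' for the fit-result classes.
#'
#' @param x an object of the matching class.
#' @return the slot contents (numeric vectors, named numerics or a
#'   logical scalar).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("times", function(x) standardGeneric("times"))

#' @rdname accessors
#' @export
setGeneric("signals", function(x) standardGeneric("signals"))

#' @rdname accessors
#' @export
setGeneric("mixRatio", function(x) standardGeneric("mixRatio"))

#' @rdname accessors
#' @export
setGeneric("traceLabel", function(x) standardGeneric("traceLabel"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("masses", function(x) standardGeneric("masses"))

#' @rdname accessors
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname accessors
#' @export
setGeneric("centers", function(x) standardGeneric("centers"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("parameters", function(x) standardGeneric("parameters"))

#' @rdname accessors
#' @export
setGeneric("stderrs", function(x) standardGeneric("stderrs"))

#' @rdname accessors
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname accessors
#' @export
setGeneric("rates", function(x) standardGeneric("rates"))

setMethod("times", "KineticTrace", function(x) x@time)
setMethod("signals", "KineticTrace", function(x) x@signal)
setMethod("mixRatio", "KineticTrace", function(x) x@ratio)
setMethod("traceLabel", "KineticTrace", function(x) x@label)
setMethod("fractions", "MixtureComposition", function(x) x@fractions)
setMethod("masses", "IsotopeEnvelope", function(x) x@mass)
setMethod("intensities", "IsotopeEnvelope", function(x) x@intensity)
setMethod("centers", "ScoreProfile", function(x) x@centers)
setMethod("scores", "ScoreProfile", function(x) x@scores)
setMethod("parameters", "ModelFit", function(x) x@parameters)
setMethod("stderrs", "ModelFit", function(x) x@stderr)
setMethod("converged", "ModelFit", function(x) x@converged)
setMethod("rates", "GlobalKineticFit", function(x) x@rates)
setMethod("stderrs", "GlobalKineticFit", function(x) x@rateStderr)
setMethod("converged", "GlobalKineticFit", function(x) x@converged)
setMethod("parameters", "BimodalFit", function(x)
  c(p_high = x@pHigh, mu_low = x@muLow, mu_high = x@muHigh,
    sigma_low = x@sigmaLow, sigma_high = x@sigmaHigh,
    amplitude = x@amplitude))
setMethod("converged", "BimodalFit", function(x) x@converged)

setMethod("show", "KineticTrace", function(object) {
  cat("KineticTrace '", object@label, "': ", length(object@time),
      " points, t = ", min(object@time), "-", max(object@time),
      " min, ratio wt:mut = ", object@ratio[1], ":", object@ratio[2],
      "\n", sep = "")
})

setMethod("show", "MixtureComposition", function(object) {
  f <- object@fractions
  cat("MixtureComposition (wt:mut = ", object@ratio[1], ":",
      object@ratio[2], ")\n", sep = "")
  cat(sprintf("  sites 3/2/1/0: %.4f / %.4f / %.4f / %.4f\n",
              f["f3"], f["f2"], f["f1"], f["f0"]))
})

setMethod("show", "IsotopeEnvelope", function(object) {
  cat("IsotopeEnvelope '", object@peptideId, "' [", object@condition,
      ", rep ", object@replicate, "]: ", length(object@mass),
      " sticks, ", sprintf("%.2f-%.2f Da", min(object@mass),
      max(object@mass)), "\n", sep = "")
})

setMethod("show", "ScoreProfile", function(object) {
  cat("ScoreProfile '", object@seqId, "': centers ",
      min(object@centers), "-", max(object@centers),
      ", min score ", sprintf("%.2f", min(object@scores)), "\n",
      sep = "")
})

setMethod("show", "ScoringMatrix", function(object) {
  cat("ScoringMatrix '", object@name,
      "': 20 residues x offsets -6..6\n", sep = "")
})

setMethod("show", "ModelFit", function(object) {
  cat("ModelFit [", object@model, "] ",
      if (object@converged) "converged" else
        paste0("FAILED (", object@message, ")"), "\n", sep = "")
  if (length(object@parameters)) {
    est <- sprintf("%.6g", object@parameters)
    se <- sprintf("%.3g", object@stderr)
    cat(paste0("  ", format(names(object@parameters)), " = ", est,
               " (se ", se, ")"), sep = "\n")
  }
})

setMethod("show", "GlobalKineticFit", function(object) {
  cat("GlobalKineticFit [", object@variant, "] ",
      if (object@converged) "converged" else
        paste0("FAILED (", object@message, ")"),
      "; ", nrow(object@perTrace), " traces\n", sep = "")
  cat(sprintf("  k1 = %.5g (se %.3g), k2 = %.5g (se %.3g), k3 = %.5g (se %.3g) /min\n",
              object@rates["k1"], object@rateStderr["k1"],
              object@rates["k2"], object@rateStderr["k2"],
              object@rates["k3"], object@rateStderr["k3"]))
  cat(sprintf("  RSS = %.4g, AIC = %.2f\n", object@rss, object@aic))
  if (nzchar(object@message) && object@converged)
    cat("  note:", object@message, "\n")
})

setMethod("show", "BimodalFit", function(object) {
  cat("BimodalFit ", if (object@converged) "converged" else
        paste0("FAILED (", object@message, ")"), "\n", sep = "")
  cat(sprintf("  p_high = %.3f, mu = %.2f / %.2f Da, sigma = %.2f / %.2f Da\n",
              object@pHigh, object@muLow, object@muHigh,
              object@sigmaLow, object@sigmaHigh))
  if (nzchar(object@flag)) cat("  flag:", object@flag, "\n")
})
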