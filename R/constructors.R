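#' Construct a KineticTrace
#'
#' @param time numeric, strictly increasing times in minutes (>= 10 points).
#' @param signal numeric polarization signal, same length as `time`.
#' @param ratio numeric length 2, wild-type and mutant monomer parts.
#' @param label character label.
#' @param metadata list of annotations.
#' @return a [KineticTrace-class] object.
#' @examples
#' tr <- KineticTrace(0:20, 200 - 5 * (0:20), ratio = c(1, 0), label = "wt")
#' tr
#' @export
KineticTrace <- function(time, signal, ratio = c(1, 0), label = "",
                         metadata = list()) {
  new("KineticTrace", time = as.numeric(time), signal = as.numeric(signal),
      ratio = as.numeric(ratio), label = as.character(label),
      metadata = metadata)
}

#' Construct a PeptideRecord
#'
#' @param id character identifier.
#' @param sequence amino-acid string (20-letter alphabet).
#' @param start,end 1-based inclusive residue coordinates in the parent
#'   protein.
#' @return a [PeptideRecord-class] object.
#' @examples
#' PeptideRecord("159-168", "LFDQNFSVKE", 159, 168)
#' @export
PeptideRecord <- function(id, sequence, start, end) {
  new("PeptideRecord", id = as.character(id),
      sequence = toupper(as.character(sequence)),
      start = as.integer(start), end = as.integer(end))
}

#' Construct an IsotopeEnvelope
#'
#' @param mass numeric, strictly increasing stick masses (Da), >= 4 sticks.
#' @param intensity numeric non-negative intensities, positive total.
#' @param peptideId,condition character labels.
#' @param replicate integer replicate index.
#' @param metadata list of annotations.
#' @return an [IsotopeEnvelope-class] object.
#' @examples
#' IsotopeEnvelope(1250:1257, c(1, 4, 9, 6, 2, 1, 0.5, 0.1), "159-168", "apo")
#' @export
IsotopeEnvelope <- function(mass, intensity, peptideId = "",
                            condition = "", replicate = 1L,
                            metadata = list()) {
  new("IsotopeEnvelope", mass = as.numeric(mass),
      intensity = as.numeric(intensity), peptideId = as.character(peptideId),
      condition = as.character(condition), replicate = as.integer(replicate),
      metadata = metadata)
}

#' Construct a ScoringMatrix
#'
#' @param entries numeric 20 x 13 matrix; rownames the standard amino-acid
#'   one-letter codes, colnames the window offsets `-6` .. `6` (coerced if
#'   unnamed and dimensions match).
#' @param name character provenance label.
#' @return a [ScoringMatrix-class] object.
#' @examples
#' m <- matrix(0, 20, 13, dimnames = list(
#'   strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], as.character(-6:6)))
#' ScoringMatrix(m, name = "null matrix")
#' @export
ScoringMatrix <- function(entries, name = "unnamed") {
  entries <- as.matrix(entries)
  if (is.null(rownames(entries)) && nrow(entries) == 20L)
    rownames(entries) <- .AA20
  if (is.null(colnames(entries)) && ncol(entries) == 13L)
    colnames(entries) <- .OFFSETS
  # canonical ordering so lookups by name are stable
  entries <- entries[.AA20, , drop = FALSE]
  colnames(entries) <- .OFFSETS
  new("ScoringMatrix", entries = entries, name = as.character(name))
}

#' Construct a ScoreProfile
#'
#' @param seqId character sequence identifier.
#' @param centers integer window-center residue numbers (1-based).
#' @param scores numeric window scores, one per center.
#' @return a [ScoreProfile-class] object.
#' @export
ScoreProfile <- function(seqId, centers, scores) {
  new("ScoreProfile", seqId = as.character(seqId),
      centers = as.integer(centers), scores = as.numeric(scores))
}

#' Coerce a ScoreProfile to a data.frame
#'
#' @param x a [ScoreProfile-class].
#' @param row.names,optional,... passed through for compatibility.
#' @return data.frame with columns `seq_id`, `center`, `score`.
#' @export
as.data.frame.ScoreProfile <- function(x, row.names = NULL,
                                       optional = FALSE, ...) {
  data.frame(seq_id = x@seqId, center = x@centers, score = x@scores,
             stringsAsFactors = FALSE)
}

setAs("ScoreProfile", "data.frame",
      function(from) as.data.frame.ScoreProfile(from))
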