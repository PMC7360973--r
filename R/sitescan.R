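.seqChars <- function(sequence) {
  if (is(sequence, "AAString"))
    sequence <- as.character(sequence)
  s <- toupper(as.character(sequence))
  chars <- strsplit(s, "")[[1L]]
  bad <- setdiff(unique(chars), .AA20)
  if (length(bad))
    stop("sequence contains non-standard residues: ",
         paste(bad, collapse = ", "))
  chars
}

#' Sliding-window chaperone-binding score profile
#'
#' Scans a protein sequence with a 13-residue window (offsets -6..+6):
#' each window's score is the sum of the matrix entries for its 13
#' (residue, offset) pairs and is assigned to the window's center
#' residue. Termini are untiled (no padding), so centers span positions
#' 7..(L-6). Scores at or below -5 mark good Hsp70/Hsc70 binding sites
#' under the published convention.
#'
#' @param sequence amino-acid string, `Biostrings::AAString`, or a
#'   [PeptideRecord-class]; length >= 13.
#' @param matrix a [ScoringMatrix-class].
#' @param seqId identifier stored in the profile (defaults to
#'   `"seq"` or the peptide id).
#' @return a [ScoreProfile-class].
#' @examples
#' toy <- ScoringMatrix(matrix(-1, 20, 13), name = "constant")
#' windowScores("AAAAAALAAAAAA", toy)  # one center (7), score -13
#' @export
windowScores <- function(sequence, matrix, seqId = NULL) {
  stopifnot(is(matrix, "ScoringMatrix"))
  if (is(sequence, "PeptideRecord")) {
    if (is.null(seqId)) seqId <- sequence@id
    sequence <- sequence@sequence
  }
  if (is.null(seqId)) seqId <- "seq"
  chars <- .seqChars(sequence)
  L <- length(chars)
  if (L < 13L) stop("sequence shorter than window (13 residues)")
  e <- matrix@entries
  ctr <- 7:(L - 6L)
  # per-position contribution at each offset, then sum across offsets
  contrib <- vapply(-6:6, function(off)
    e[cbind(chars[ctr + off], as.character(off))], numeric(length(ctr)))
  sc <- if (is.matrix(contrib)) rowSums(contrib) else sum(contrib)
  ScoreProfile(seqId, ctr, sc)
}

#' Call binding sites from a score profile
#'
#' Maximal runs of consecutive window centers with score at or below the
#' threshold are merged into sites. The boundary rule is inclusive: a
#' center scoring exactly the threshold belongs to a site.
#'
#' @param profile a [ScoreProfile-class].
#' @param threshold score cutoff (default -5).
#' @return data.frame with one row per site: `seq_id`, `start`, `end`
#'   (center residue numbers, 1-based inclusive), `min_score`.
#' @examples
#' toy <- ScoringMatrix(matrix(0, 20, 13))
#' callSites(windowScores("AAAAAALAAAAAAAA", toy))  # empty
#' @export
callSites <- function(profile, threshold = -5) {
  stopifnot(is(profile, "ScoreProfile"))
  hit <- scores(profile) <= threshold
  if (!any(hit))
    return(data.frame(seq_id = character(), start = integer(),
                      end = integer(), min_score = numeric()))
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ctr <- centers(profile)
  sc <- scores(profile)
  out <- data.frame(
    seq_id = profile@seqId,
    start = ctr[starts[keep]],
    end = ctr[ends[keep]],
    min_score = vapply(keep, function(j)
      min(sc[starts[j]:ends[j]]), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Count below-threshold window centers in a residue range
#'
#' Counts the window centers within `range` (1-based inclusive) whose
#' score is at or below the threshold. Per-center counting is the
#' primary tally; the number of maximal runs within the range is
#' attached as attribute `"runs"` for the coarser per-segment view.
#'
#' @param profile a [ScoreProfile-class].
#' @param range numeric length 2, residue range (inclusive).
#' @param threshold score cutoff (default -5).
#' @return integer count (with attribute `runs`); 0 with a warning when
#'   the range does not overlap the profile.
#' @examples
#' toy <- ScoringMatrix(matrix(-1, 20, 13))
#' p <- windowScores(strrep("A", 30), toy)
#' countSitesInRange(p, c(10, 20))
#' @export
countSitesInRange <- function(profile, range, threshold = -5) {
  stopifnot(is(profile, "ScoreProfile"), length(range) == 2L)
  inr <- centers(profile) >= range[1] & centers(profile) <= range[2]
  if (!any(inr)) {
    warning("range [", range[1], ", ", range[2],
            "] does not overlap the profile centers")
    out <- 0L
    attr(out, "runs") <- 0L
    return(out)
  }
  hit <- scores(profile)[inr] <= threshold
  out <- sum(hit)
  r <- rle(hit)
  attr(out, "runs") <- sum(r$values)
  out
}

#' Rescore a sequence variant (substitutions and/or deletions)
#'
#' Applies point substitutions and internal deletions to a sequence and
#' rescans it with [windowScores()]. Deleted regions are excised before
#' scanning; the returned profile's centers carry the ORIGINAL residue
#' numbering of each surviving residue, so wild-type and variant
#' profiles align position-by-position.
#'
#' @param sequence amino-acid string (length >= 13 after deletions).
#' @param matrix a [ScoringMatrix-class].
#' @param substitutions named character vector (`c("202" = "S")`) or
#'   data.frame with columns `position`, `residue`; empty for none.
#' @param deletions list of length-2 numeric ranges (1-based inclusive)
#'   to excise, e.g. `list(c(202, 213))`.
#' @param seqId identifier for the returned profile.
#' @return a [ScoreProfile-class] with centers in original coordinates.
#' @examples
#' toy <- ScoringMatrix(matrix(0, 20, 13))
#' p <- rescoreVariant(strrep("A", 30), toy,
#'                     substitutions = c("15" = "S"))
#' @export
rescoreVariant <- function(sequence, matrix, substitutions = NULL,
                           deletions = NULL, seqId = "variant") {
  chars <- .seqChars(sequence)
  L <- length(chars)

  if (!is.null(substitutions) && length(substitutions)) {
    if (is.data.frame(substitutions)) {
      pos <- as.integer(substitutions$position)
      res <- toupper(as.character(substitutions$residue))
    } else {
      pos <- as.integer(names(substitutions))
      res <- toupper(as.character(substitutions))
    }
    if (any(is.na(pos)) || any(pos < 1L) || any(pos > L))
      stop("substitution position out of range")
    if (!all(res %in% .AA20))
      stop("substitution residue outside the 20-letter alphabet")
    chars[pos] <- res
  }

  keep <- rep(TRUE, L)
  if (!is.null(deletions)) {
    for (d in deletions) {
      if (length(d) != 2L || d[1] < 1 || d[2] > L || d[1] > d[2])
        stop("invalid deletion range")
      keep[d[1]:d[2]] <- FALSE
    }
  }
  coords <- which(keep)        # original numbering of surviving residues
  variant <- chars[keep]
  if (length(variant) < 13L)
    stop("sequence shorter than window (13 residues) after deletions")

  prof <- windowScores(paste(variant, collapse = ""), matrix,
                       seqId = seqId)
  # map variant-coordinate centers back to original numbering
  ScoreProfile(seqId, coords[centers(prof)], scores(prof))
}
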