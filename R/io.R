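# CSV dialects (comma-separated, header row, '.' decimal, UTF-8):
#   titration:      titrant_nM,signal
#   trace:          time_min,signal
#   multi-trace:    trace_id,ratio_wt,ratio_mut,time_min,signal
#   melt:           temp_C,fraction_trimer
#   envelopes:      peptide_id,condition,replicate,mass_da,intensity
#   peptide table:  peptide_id,sequence,start,end
#   references:     peptide_id,undeut_da,fulldeut_da
#   scoring matrix: rows = 20 amino acids (first column `aa`),
#                   columns = offsets -6..6
# Coordinates are 1-based inclusive throughout (NOT BED half-open).

.readCsv <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop("file ", path, " lacks required columns: ",
         paste(missing, collapse = ", "))
  x
}

#' Read analysis input tables
#'
#' Readers for the package's CSV dialects (see the vignette for column
#' definitions). All return plain data.frames except
#' `readMultiTraceCsv()`, which splits on `trace_id` into a list of
#' [KineticTrace-class] objects, and `readEnvelopeCsv()`, which returns a
#' list of [IsotopeEnvelope-class] objects.
#'
#' @param path CSV file path.
#' @return see above.
#' @name io-readers
NULL

#' @rdname io-readers
#' @export
readTitrationCsv <- function(path) .readCsv(path, c("titrant_nM", "signal"))

#' @rdname io-readers
#' @export
readTraceCsv <- function(path) .readCsv(path, c("time_min", "signal"))

#' @rdname io-readers
#' @export
readMeltCsv <- function(path) .readCsv(path, c("temp_C", "fraction_trimer"))

#' @rdname io-readers
#' @export
readMultiTraceCsv <- function(path) {
  x <- .readCsv(path, c("trace_id", "ratio_wt", "ratio_mut", "time_min",
                        "signal"))
  lapply(split(x, x$trace_id), function(d) {
    d <- d[order(d$time_min), ]
    KineticTrace(d$time_min, d$signal,
                 ratio = c(d$ratio_wt[1L], d$ratio_mut[1L]),
                 label = as.character(d$trace_id[1L]))
  })
}

#' @rdname io-readers
#' @export
readEnvelopeCsv <- function(path) {
  x <- .readCsv(path, c("peptide_id", "condition", "replicate", "mass_da",
                        "intensity"))
  key <- interaction(x$peptide_id, x$condition, x$replicate, drop = TRUE)
  lapply(split(x, key), function(d) {
    d <- d[order(d$mass_da), ]
    IsotopeEnvelope(d$mass_da, d$intensity,
                    peptideId = as.character(d$peptide_id[1L]),
                    condition = as.character(d$condition[1L]),
                    replicate = as.integer(d$replicate[1L]))
  })
}

#' @rdname io-readers
#' @export
readPeptideTableCsv <- function(path) {
  x <- .readCsv(path, c("peptide_id", "sequence", "start", "end"))
  lapply(seq_len(nrow(x)), function(i)
    PeptideRecord(x$peptide_id[i], x$sequence[i], x$start[i], x$end[i]))
}

#' @rdname io-readers
#' @export
readReferenceCsv <- function(path)
  .readCsv(path, c("peptide_id", "undeut_da", "fulldeut_da"))

#' Read a position-specific scoring matrix from CSV
#'
#' Expects a first column `aa` with the 20 one-letter codes and 13 score
#' columns for offsets -6..6 (headers `-6`..`6`, tolerant of the `X.6`
#' mangling `read.csv` applies to numeric headers).
#'
#' @param path CSV file path.
#' @param name provenance label (defaults to the file name).
#' @return a [ScoringMatrix-class].
#' @export
readScoringMatrix <- function(path, name = basename(path)) {
  x <- .readCsv(path, "aa")
  m <- as.matrix(x[, setdiff(names(x), "aa"), drop = FALSE])
  if (ncol(m) != 13L)
    stop("scoring matrix must have 13 offset columns (-6..6)")
  rownames(m) <- toupper(x$aa)
  colnames(m) <- .OFFSETS
  ScoringMatrix(m, name = name)
}

#' Read protein sequences from FASTA
#'
#' Thin wrapper over `Biostrings::readAAStringSet()` returning a named
#' character vector of sequences.
#'
#' @param path FASTA file path (multi-record allowed).
#' @return named character vector.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  aa <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aa),
                  vapply(strsplit(names(aa), "\\s+"), `[`, "", 1L))
}

#' Serialize a fit result to JSON
#'
#' Writes parameter estimates, standard errors and the convergence flag
#' of a [ModelFit-class] or [GlobalKineticFit-class] as JSON.
#'
#' @param fit the fit object.
#' @param path output file; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
writeFitJson <- function(fit, path = NULL) {
  rep <- if (is(fit, "GlobalKineticFit")) {
    list(model = "global_mixture", variant = fit@variant,
         converged = fit@converged, message = fit@message,
         rates = as.list(fit@rates), rate_stderr = as.list(fit@rateStderr),
         per_trace = fit@perTrace, rss = fit@rss, n_obs = fit@nobs,
         n_params = fit@nparams, aic = fit@aic, aicc = fit@aicc,
         bic = fit@bic)
  } else if (is(fit, "ModelFit")) {
    list(model = fit@model, converged = fit@converged,
         message = fit@message, parameters = as.list(fit@parameters),
         stderr = as.list(fit@stderr), rss = fit@rss, n_obs = fit@nobs,
         details = fit@details)
  } else stop("unsupported fit object")
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(js, path)
  invisible(as.character(js))
}

#' Write a mixing-ratio experiment to the multi-trace CSV dialect
#'
#' @param traces list of [KineticTrace-class] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMultiTraceCsv <- function(traces, path) {
  rows <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trace_id = traceLabel(tr),
               ratio_wt = mixRatio(tr)[1], ratio_mut = mixRatio(tr)[2],
               time_min = times(tr), signal = signals(tr))))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
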