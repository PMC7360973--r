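#' Run one pipeline command
#'
#' Orchestrates the analysis stages behind a single entry point, the
#' same surface the `inst/scripts/chaperkin.R` command-line wrapper
#' exposes. Each command reads the CSV/FASTA dialects documented in the
#' vignette, writes CSV/JSON results into `output_dir`, and appends a
#' run log (`run_log.txt`: package version, seed, parameter echo).
#' Existing output files are never overwritten unless
#' `config$overwrite` is `TRUE`; results are written via a temporary
#' file and renamed, so a failing run leaves no partial output.
#'
#' Commands and their config fields:
#' \describe{
#'   \item{`simulate`}{`kind` (one of `titration`, `trace`,
#'     `mixture_experiment`, `envelope`, `melt`, `sequence`), `seed`,
#'     plus any generator parameters (`params` list).}
#'   \item{`fit-titration`}{`input`, `probe_total`.}
#'   \item{`fit-dissociation`}{`input` (trace CSV).}
#'   \item{`fit-mixture`}{`input` (multi-trace CSV); global fit plus
#'     model comparison.}
#'   \item{`hx-deconvolve`}{`input` (envelope CSV), optional
#'     `references` (reference-centroid CSV) and `peptides` (peptide
#'     table CSV) for per-subpopulation relative deuteration.}
#'   \item{`hx-diff`}{`input`, `reference` (deuteron tables:
#'     `peptide_id,deuterons` CSV).}
#'   \item{`scan-sites`}{`fasta`, `matrix` (scoring-matrix CSV),
#'     optional `threshold` (default -5).}
#'   \item{`fit-melt`}{`input` (melt CSV).}
#' }
#'
#' @param command character, one of the commands above.
#' @param config named list, or path to a YAML/JSON config file.
#' @param overrides named list merged over the file config (flags win).
#' @return invisibly, a list with `status` (0 on success), the paths of
#'   the written `outputs`, and command-specific `results`.
#' @examples
#' out <- tempfile(); dir.create(out)
#' runPipeline("simulate", list(kind = "melt", seed = 1,
#'                              output_dir = out))
#' @export
runPipeline <- function(command, config = list(), overrides = list()) {
  command <- match.arg(command, c("simulate", "fit-titration",
                                  "fit-dissociation", "fit-mixture",
                                  "hx-deconvolve", "hx-diff",
                                  "scan-sites", "fit-melt"))
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config[names(overrides)] <- overrides

  outdir <- config$output_dir %||% "."
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  overwrite <- isTRUE(config$overwrite)

  log_path <- file.path(outdir, "run_log.txt")
  logline <- function(...) cat(..., "\n", sep = "", file = log_path,
                               append = TRUE)
  logline("== ", command, " | ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
          " | ChaperKin ",
          as.character(utils::packageVersion("ChaperKin")))
  cfg_echo <- config[setdiff(names(config), "output_dir")]
  if (length(cfg_echo))
    logline("   config: ", jsonlite::toJSON(cfg_echo, auto_unbox = TRUE))

  outputs <- character()
  emit <- function(writer, filename) {
    dest <- file.path(outdir, filename)
    if (file.exists(dest) && !overwrite)
      stop("output exists (set overwrite: true to replace): ", dest)
    tmp <- tempfile(tmpdir = outdir)
    writer(tmp)
    file.rename(tmp, dest)
    outputs <<- c(outputs, dest)
    logline("   wrote ", dest)
    dest
  }

  results <- switch(command,
    "simulate" = .cmdSimulate(config, emit),
    "fit-titration" = .cmdFitTitration(config, emit),
    "fit-dissociation" = .cmdFitDissociation(config, emit),
    "fit-mixture" = .cmdFitMixture(config, emit),
    "hx-deconvolve" = .cmdHxDeconvolve(config, emit),
    "hx-diff" = .cmdHxDiff(config, emit),
    "scan-sites" = .cmdScanSites(config, emit),
    "fit-melt" = .cmdFitMelt(config, emit))

  invisible(list(status = 0L, outputs = outputs, results = results))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.needSeed <- function(config) {
  if (is.null(config$seed)) stop("simulate requires an explicit seed")
  as.integer(config$seed)
}

.cmdSimulate <- function(config, emit) {
  kind <- config$kind %||% stop("simulate requires 'kind'")
  seed <- .needSeed(config)
  params <- config$params %||% list()
  params$seed <- seed
  manifest <- list(kind = kind, seed = seed, params = params)

  if (kind == "titration") {
    d <- do.call(genTitration, params)
    emit(function(p) utils::write.csv(d, p, row.names = FALSE),
         "titration.csv")
    manifest$truth <- attr(d, "truth")
  } else if (kind == "trace") {
    tr <- do.call(genDissociationTrace, params)
    emit(function(p) utils::write.csv(
      data.frame(time_min = times(tr), signal = signals(tr)), p,
      row.names = FALSE), "trace.csv")
    manifest$truth <- tr@metadata$truth
  } else if (kind == "mixture_experiment") {
    trs <- do.call(genMixtureExperiment, params)
    emit(function(p) writeMultiTraceCsv(trs, p), "mixture_traces.csv")
    manifest$truth <- trs[[1L]]@metadata$truth
  } else if (kind == "envelope") {
    env <- do.call(genEnvelope, params)
    emit(function(p) utils::write.csv(
      data.frame(peptide_id = env@peptideId, condition = env@condition,
                 replicate = env@replicate, mass_da = masses(env),
                 intensity = intensities(env)), p, row.names = FALSE),
      "envelope.csv")
    manifest$truth <- env@metadata$truth
  } else if (kind == "melt") {
    d <- do.call(genMelt, params)
    emit(function(p) utils::write.csv(d, p, row.names = FALSE),
         "melt.csv")
    manifest$truth <- attr(d, "truth")
  } else if (kind == "sequence") {
    sq <- do.call(genSequence, params)
    emit(function(p) writeLines(c(">synthetic", sq), p),
         "sequence.fasta")
    manifest$truth <- list(length = nchar(sq))
  } else stop("unknown simulate kind: ", kind)

  emit(function(p) writeLines(jsonlite::toJSON(manifest,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"), p),
    "manifest.json")
  manifest
}

.cmdFitTitration <- function(config, emit) {
  d <- readTitrationCsv(config$input %||% stop("fit-titration needs 'input'"))
  probe <- config$probe_total %||% stop("fit-titration needs 'probe_total'")
  fit <- fitTitration(d, probeTotal = probe)
  emit(function(p) writeFitJson(fit, p), "titration_fit.json")
  fit
}

.cmdFitDissociation <- function(config, emit) {
  d <- readTraceCsv(config$input %||% stop("fit-dissociation needs 'input'"))
  fit <- fitDissociation(d)
  emit(function(p) writeFitJson(fit, p), "dissociation_fit.json")
  fit
}

.cmdFitMixture <- function(config, emit) {
  traces <- readMultiTraceCsv(config$input %||%
                                stop("fit-mixture needs 'input'"))
  cmp <- compareModels(traces)
  fit <- cmp$fits$full
  emit(function(p) writeFitJson(fit, p), "mixture_fit.json")
  emit(function(p) utils::write.csv(cmp$table, p, row.names = FALSE),
       "model_comparison.csv")
  emit(function(p) writeLines(jsonlite::toJSON(cmp$table,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"), p),
    "model_comparison.json")
  cmp
}

.cmdHxDeconvolve <- function(config, emit) {
  envs <- readEnvelopeCsv(config$input %||%
                            stop("hx-deconvolve needs 'input'"))
  refs <- if (!is.null(config$references))
    readReferenceCsv(config$references) else NULL
  peps <- if (!is.null(config$peptides))
    readPeptideTableCsv(config$peptides) else NULL
  nmax_of <- function(pid) {
    if (is.null(peps)) return(1)
    hit <- Filter(function(p) p@id == pid, peps)
    if (length(hit)) maxExchangeable(hit[[1L]]) else 1
  }
  rows <- lapply(envs, function(env) {
    ref <- if (!is.null(refs)) refs[refs$peptide_id == env@peptideId, ]
    fit <- if (!is.null(ref) && nrow(ref) == 1L)
      fitBimodal(env, undeut = ref$undeut_da, fulldeut = ref$fulldeut_da,
                 nMax = nmax_of(env@peptideId))
    else fitBimodal(env)
    data.frame(peptide_id = env@peptideId, condition = env@condition,
               replicate = env@replicate, converged = converged(fit),
               p_high = fit@pHigh, mu_low = fit@muLow,
               mu_high = fit@muHigh, sigma_low = fit@sigmaLow,
               sigma_high = fit@sigmaHigh, rel_low = fit@relLow,
               rel_high = fit@relHigh, flag = fit@flag,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  emit(function(p) utils::write.csv(tab, p, row.names = FALSE),
       "bimodal_fits.csv")
  tab
}

.cmdHxDiff <- function(config, emit) {
  cond <- .readCsv(config$input %||% stop("hx-diff needs 'input'"),
                   c("peptide_id", "deuterons"))
  ref <- .readCsv(config$reference %||% stop("hx-diff needs 'reference'"),
                  c("peptide_id", "deuterons"))
  res <- differenceTable(cond, ref, alpha = config$alpha %||% 0.05)
  emit(function(p) utils::write.csv(res$differences, p,
                                    row.names = FALSE),
       "differences.csv")
  emit(function(p) utils::write.csv(res$unmatched, p, row.names = FALSE),
       "unmatched.csv")
  res
}

.cmdScanSites <- function(config, emit) {
  seqs <- readFastaSequences(config$fasta %||%
                               stop("scan-sites needs 'fasta'"))
  sm <- readScoringMatrix(config$matrix %||%
                            stop("scan-sites needs 'matrix'"))
  thr <- config$threshold %||% -5
  profiles <- lapply(names(seqs), function(id)
    windowScores(seqs[[id]], sm, seqId = id))
  prof_tab <- do.call(rbind, lapply(profiles, as.data.frame))
  site_tab <- do.call(rbind, lapply(profiles, callSites,
                                    threshold = thr))
  emit(function(p) utils::write.csv(prof_tab, p, row.names = FALSE),
       "score_profiles.csv")
  emit(function(p) utils::write.csv(site_tab, p, row.names = FALSE),
       "binding_sites.csv")
  list(profiles = profiles, sites = site_tab)
}

.cmdFitMelt <- function(config, emit) {
  d <- readMeltCsv(config$input %||% stop("fit-melt needs 'input'"))
  fit <- fitThermal(d)
  emit(function(p) writeFitJson(fit, p), "melt_fit.json")
  fit
}
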