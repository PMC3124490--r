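#' Read and write the tabular spike-train format
#'
#' The interchange format is tab-delimited text with a header and one row per
#' spike: \code{trial_id}, \code{neuron_id}, \code{stimulus_id},
#' \code{spike_time_s}.  Times are written with 9 decimal places
#' (nanosecond), so a write/read cycle is lossless at that precision.
#'
#' @param x a spike table data.frame or a [SpikeExperiment-class].
#' @param path file path.
#' @return \code{readSpikeTable} returns the spike table data.frame (with a
#'   warning and zero rows for an empty file); \code{writeSpikeTable} returns
#'   \code{path} invisibly.
#' @export
writeSpikeTable <- function(x, path) {
  if (is(x, "SpikeExperiment")) x <- x@spikes
  stopifnot(is.data.frame(x))
  out <- x
  out$spike_time_s <- sprintf("%.9f", out$spike_time_s)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSpikeTable
#' @export
readSpikeTable <- function(path) {
  need <- c("trial_id", "neuron_id", "stimulus_id", "spike_time_s")
  raw <- readLines(path)
  if (length(raw) <= 1L) {
    warning("spike table ", path, " is empty")
    empty <- data.frame(trial_id = character(0), neuron_id = character(0),
                        stimulus_id = character(0), spike_time_s = numeric(0))
    return(empty)
  }
  header <- strsplit(raw[1L], "\t", fixed = TRUE)[[1L]]
  if (!identical(header, need))
    stop("spike table header must be: ", paste(need, collapse = ", "))
  fields <- strsplit(raw[-1L], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 4L))
    stop("malformed spike table row at line ", which(nf != 4L)[1L] + 1L,
         " of ", path)
  tm <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 4L)))
  if (anyNA(tm))
    stop("non-numeric spike time at line ", which(is.na(tm))[1L] + 1L,
         " of ", path)
  data.frame(trial_id = vapply(fields, `[[`, character(1), 1L),
             neuron_id = vapply(fields, `[[`, character(1), 2L),
             stimulus_id = vapply(fields, `[[`, character(1), 3L),
             spike_time_s = tm)
}

#' Read and write per-bin intensity tables
#'
#' Tab-delimited with columns \code{bin_start_s}, \code{lambda_hz}.
#'
#' @param model an [IntensityModel-class].
#' @param path file path.
#' @return \code{readIntensityTable} reconstructs the [IntensityModel-class]
#'   (grid inferred from the bin starts).
#' @export
writeIntensityTable <- function(model, path) {
  stopifnot(is(model, "IntensityModel"))
  starts <- model@interval[1L] +
    (seq_along(model@lambda) - 1L) * model@delta
  utils::write.table(
    data.frame(bin_start_s = sprintf("%.9f", starts),
               lambda_hz = sprintf("%.9g", model@lambda)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeIntensityTable
#' @export
readIntensityTable <- function(path) {
  d <- utils::read.delim(path)
  stopifnot(all(c("bin_start_s", "lambda_hz") %in% names(d)), nrow(d) >= 1L)
  delta <- if (nrow(d) > 1L) stats::median(diff(d$bin_start_s)) else
    stop("cannot infer bin width from a single bin")
  intensityModel(d$lambda_hz, delta = delta,
                 interval = c(d$bin_start_s[1L],
                              d$bin_start_s[nrow(d)] + delta))
}

#' Export a filter trace
#'
#' Writes the per-bin filter records of a fitted intensity (bin, predicted
#' and posterior state, posterior variance, innovation, gain, fitted rate) as
#' tab-delimited text.
#'
#' @param model an [IntensityModel-class] from [fitIntensity()].
#' @param path file path.
#' @export
writeFilterTrace <- function(model, path) {
  tr <- filterTrace(model)
  if (!nrow(tr)) stop("model carries no filter trace")
  utils::write.table(tr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write population recordings
#'
#' Tab-delimited with columns \code{time_s}, \code{neuron_id} (integer mark).
#'
#' @param rec a [PopulationRecording-class].
#' @param path file path.
#' @param nNeurons,interval needed on read when they cannot be inferred
#'   (defaults: largest mark, \code{(0, max time]}).
#' @export
writePopulationRecording <- function(rec, path) {
  stopifnot(is(rec, "PopulationRecording"))
  utils::write.table(
    data.frame(time_s = sprintf("%.9f", rec@times), neuron_id = rec@marks),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePopulationRecording
#' @export
readPopulationRecording <- function(path, nNeurons = NULL, interval = NULL) {
  d <- utils::read.delim(path)
  stopifnot(all(c("time_s", "neuron_id") %in% names(d)))
  if (is.null(nNeurons)) nNeurons <- max(d$neuron_id, 1L)
  if (is.null(interval)) interval <- c(0, max(d$time_s, 1))
  ord <- order(d$time_s, d$neuron_id)
  new("PopulationRecording", times = as.numeric(d$time_s[ord]),
      marks = as.integer(d$neuron_id[ord]), nNeurons = as.integer(nNeurons),
      interval = as.numeric(interval))
}

#' Read and write likelihood-coordinate tables
#'
#' Tab-delimited with \code{trial_id}, \code{true_stimulus}, then one
#' \code{coord_<label>} column per projecting distribution (nats).
#'
#' @param coords M x P matrix from [projectSet()].
#' @param path file path.
#' @param trialIds,trueStimulus optional per-row annotation.
#' @export
writeLikelihoodTable <- function(coords, path, trialIds = NULL,
                                 trueStimulus = NULL) {
  coords <- as.matrix(coords)
  if (is.null(trueStimulus)) trueStimulus <- attr(coords, "trueStimulus")
  if (is.null(trueStimulus)) trueStimulus <- rep(NA_character_, nrow(coords))
  if (is.null(trialIds)) trialIds <- sprintf("t%04d", seq_len(nrow(coords)))
  d <- data.frame(trial_id = trialIds, true_stimulus = trueStimulus)
  cn <- colnames(coords)
  if (is.null(cn)) cn <- paste0("s", seq_len(ncol(coords)))
  for (j in seq_len(ncol(coords))) d[[paste0("coord_", cn[j])]] <- coords[, j]
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLikelihoodTable
#' @export
readLikelihoodTable <- function(path) {
  d <- utils::read.delim(path)
  cc <- grep("^coord_", names(d))
  stopifnot(length(cc) >= 2L)
  m <- as.matrix(d[, cc, drop = FALSE])
  colnames(m) <- sub("^coord_", "", names(d)[cc])
  attr(m, "trueStimulus") <- as.character(d$true_stimulus)
  attr(m, "trialIds") <- as.character(d$trial_id)
  m
}

#' Read and write labelled dissimilarity matrices
#'
#' Tab-delimited square matrix with row and column labels.
#'
#' @param d symmetric dissimilarity matrix.
#' @param path file path.
#' @export
writeDissimilarity <- function(d, path) {
  d <- as.matrix(d)
  if (is.null(rownames(d))) rownames(d) <- paste0("s", seq_len(nrow(d)))
  utils::write.table(format(d, digits = 12), path, sep = "\t", quote = FALSE,
                     row.names = TRUE, col.names = NA)
  invisible(path)
}

#' @rdname writeDissimilarity
#' @export
readDissimilarity <- function(path) {
  d <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  as.matrix(d)
}

#' Read and write pipeline run configurations
#'
#' The run configuration bundles every knob of a pipeline run (bin width,
#' window sizes, filter hyperparameters, priors, seed, paths) in YAML; it is
#' validated on read and a copy is serialised into every output directory so
#' runs are reproducible from the config alone.
#'
#' @param config named list of settings.
#' @param path YAML file path.
#' @return \code{readRunConfig} returns the validated list.
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  config <- yaml::read_yaml(path)
  num1 <- function(nm, lo = 0)
    if (!is.null(config[[nm]]) &&
        (!is.numeric(config[[nm]]) || config[[nm]] <= lo))
      stop("run config field '", nm, "' must be a number > ", lo)
  for (nm in c("delta", "window", "step", "stateNoise")) num1(nm)
  if (!is.null(config$priors)) {
    if (abs(sum(config$priors) - 1) > 1e-6 || any(config$priors < 0))
      stop("run config priors must be nonnegative and sum to 1")
  }
  if (!is.null(config$seed)) config$seed <- as.integer(config$seed)
  config
}
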