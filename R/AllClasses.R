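#' @import methods
NULL

.checkInterval <- function(interval) {
  if (length(interval) != 2L || !is.numeric(interval) || any(!is.finite(interval)))
    return("interval must be a finite numeric vector (t_start, t_end)")
  if (interval[2L] <= interval[1L])
    return("interval end must exceed interval start")
  NULL
}

#' SpikeTrain: ordered spike times of one neuron in one trial
#'
#' A point-process realisation: strictly increasing spike times on an
#' observation interval \eqn{(t_{start}, t_{end}]}, in seconds, together with
#' opaque neuron / trial / stimulus labels.  Spike times lying exactly on the
#' interval end are allowed (the interval is half-open on the left).
#'
#' @slot times numeric, strictly increasing spike times in seconds.
#' @slot interval numeric length 2, \code{c(t_start, t_end)}.
#' @slot neuronId,trialId,stimulusId length-1 character labels
#'   (\code{stimulusId} may be \code{NA} when the stimulus is unknown).
#'
#' @seealso [spikeTrain()], [binSpikeTrain()]
#' @export
setClass("SpikeTrain",
  representation(times = "numeric", interval = "numeric",
                 neuronId = "character", trialId = "character",
                 stimulusId = "character"),
  prototype(times = numeric(0), interval = c(0, 1),
            neuronId = "n1", trialId = "t1", stimulusId = NA_character_))

setValidity("SpikeTrain", function(object) {
  msg <- .checkInterval(object@interval)
  if (!is.null(msg)) return(msg)
  t0 <- object@interval[1L]; t1 <- object@interval[2L]
  if (length(object@times)) {
    if (any(!is.finite(object@times))) return("spike times must be finite")
    if (any(object@times <= t0) || any(object@times > t1))
      return(sprintf("spike times must lie in (%g, %g]", t0, t1))
    if (any(diff(object@times) <= 0))
      return("spike times must be strictly increasing")
  }
  for (s in c("neuronId", "trialId", "stimulusId"))
    if (length(slot(object, s)) != 1L) return(sprintf("%s must have length 1", s))
  TRUE
})

#' BinnedSpikeTrain: binary spike-increment vector
#'
#' Discretisation of a [SpikeTrain-class] on a regular grid of width
#' \eqn{\Delta}: element \eqn{\Delta N_k \in \{0,1\}} indicates a spike in bin
#' \eqn{k}.  The discretisation is only valid when \eqn{\Delta} is small enough
#' that no bin holds two spikes.
#'
#' @slot increments integer vector of 0/1 of length \eqn{J}.
#' @slot delta bin width in seconds.
#' @slot interval numeric length 2, as for [SpikeTrain-class].
#' @slot truncated logical; \code{TRUE} when the final bin was shortened to fit
#'   an interval whose span is not an integer multiple of \code{delta}.
#' @export
setClass("BinnedSpikeTrain",
  representation(increments = "integer", delta = "numeric",
                 interval = "numeric", truncated = "logical"),
  prototype(increments = integer(0), delta = 0.001, interval = c(0, 1),
            truncated = FALSE))

setValidity("BinnedSpikeTrain", function(object) {
  msg <- .checkInterval(object@interval)
  if (!is.null(msg)) return(msg)
  if (length(object@delta) != 1L || object@delta <= 0)
    return("delta must be a single positive number")
  if (length(object@increments) && !all(object@increments %in% c(0L, 1L)))
    return("increments must be 0 or 1 (at most one spike per bin)")
  span <- diff(object@interval)
  J <- length(object@increments)
  if (!object@truncated && abs(J * object@delta - span) > 1e-6 * max(span, 1))
    return("J * delta must span the interval unless truncated is TRUE")
  TRUE
})

#' IntensityModel: per-bin conditional intensity
#'
#' A conditional-intensity function \eqn{\lambda_k} (in Hz) evaluated on the
#' same regular bin grid used for [BinnedSpikeTrain-class] objects.  When the
#' intensity was estimated by the state-space filter, the latent-state
#' trajectory and the filter trace are carried along.
#'
#' @slot lambda positive numeric of length \eqn{J}, intensity per bin in Hz.
#' @slot delta bin width in seconds.
#' @slot interval numeric length 2.
#' @slot state numeric matrix (\eqn{J \times d}) of posterior state means, or a
#'   0-row matrix when the model was not produced by filtering.
#' @slot trace data.frame filter trace (one row per bin), possibly empty.
#' @export
setClass("IntensityModel",
  representation(lambda = "numeric", delta = "numeric", interval = "numeric",
                 state = "matrix", trace = "data.frame"),
  prototype(lambda = numeric(0), delta = 0.001, interval = c(0, 1),
            state = matrix(numeric(0), 0, 0), trace = data.frame()))

setValidity("IntensityModel", function(object) {
  msg <- .checkInterval(object@interval)
  if (!is.null(msg)) return(msg)
  if (length(object@delta) != 1L || object@delta <= 0)
    return("delta must be a single positive number")
  if (any(!is.finite(object@lambda)) || any(object@lambda <= 0))
    return("all intensities must be finite and strictly positive")
  TRUE
})

#' PopulationRecording: pooled, marked event stream of a neural ensemble
#'
#' The spikes of \eqn{K} simultaneously observed neurons pooled into a single
#' ordered sequence of (time, mark) pairs, the mark being the index of the
#' neuron that fired.  The pooled stream is the ground process; the marks form
#' the mark process.
#'
#' @slot times increasing event times in seconds.
#' @slot marks integer neuron indices in \code{1:nNeurons}.
#' @slot nNeurons number of neurons \eqn{K}.
#' @slot interval numeric length 2.
#' @export
setClass("PopulationRecording",
  representation(times = "numeric", marks = "integer", nNeurons = "integer",
                 interval = "numeric"),
  prototype(times = numeric(0), marks = integer(0), nNeurons = 1L,
            interval = c(0, 1)))

setValidity("PopulationRecording", function(object) {
  msg <- .checkInterval(object@interval)
  if (!is.null(msg)) return(msg)
  if (length(object@times) != length(object@marks))
    return("times and marks must have equal length")
  if (length(object@times)) {
    if (any(diff(object@times) < 0)) return("event times must be nondecreasing")
    if (any(object@times <= object@interval[1L]) ||
        any(object@times > object@interval[2L]))
      return("event times must lie inside the observation interval")
    if (any(object@marks < 1L) || any(object@marks > object@nNeurons))
      return("marks must be neuron indices in 1:nNeurons")
  }
  if (object@nNeurons < 1L) return("nNeurons must be at least 1")
  TRUE
})

#' PopulationIntensity: per-neuron intensities on a common grid
#'
#' @slot models list of [IntensityModel-class], one per neuron, all sharing the
#'   same bin grid (delta, interval, length).
#' @export
setClass("PopulationIntensity",
  representation(models = "list"),
  prototype(models = list()))

setValidity("PopulationIntensity", function(object) {
  if (!length(object@models)) return("at least one neuron model is required")
  if (!all(vapply(object@models, is, logical(1), "IntensityModel")))
    return("models must all be IntensityModel objects")
  ref <- object@models[[1L]]
  for (m in object@models[-1L]) {
    if (length(m@lambda) != length(ref@lambda) ||
        abs(m@delta - ref@delta) > 1e-12 ||
        any(abs(m@interval - ref@interval) > 1e-9))
      return("all neuron models must share one bin grid")
  }
  TRUE
})

#' ProjectingDistributions: the stimulus-conditional models spanning the space
#'
#' A set of \eqn{P \ge 2} stimulus-conditional intensity models (single-neuron
#' [IntensityModel-class] or [PopulationIntensity-class]) together with prior
#' stimulus probabilities.  Projecting an observation yields its
#' \eqn{P}-dimensional log-likelihood coordinates.
#'
#' @slot models list of length \eqn{P}, all of one kind, on one grid.
#' @slot priors numeric of length \eqn{P}, nonnegative, summing to 1.
#' @slot labels character stimulus labels of length \eqn{P}.
#' @export
setClass("ProjectingDistributions",
  representation(models = "list", priors = "numeric", labels = "character"))

setValidity("ProjectingDistributions", function(object) {
  P <- length(object@models)
  if (P < 2L) return("at least two projecting distributions are required")
  kinds <- vapply(object@models, function(m)
    if (is(m, "IntensityModel")) "single" else if (is(m, "PopulationIntensity"))
      "population" else "other", character(1))
  if (any(kinds == "other"))
    return("models must be IntensityModel or PopulationIntensity objects")
  if (length(unique(kinds)) != 1L)
    return("models must all be of the same kind")
  if (length(object@priors) != P) return("priors must match the model count")
  if (any(object@priors < 0) || abs(sum(object@priors) - 1) > 1e-8)
    return("priors must be nonnegative and sum to 1")
  if (length(object@labels) != P) return("labels must match the model count")
  TRUE
})

#' SpikeExperiment: a simulated multi-stimulus, multi-neuron recording
#'
#' Container for a synthetic experiment: a long-format spike table (one row per
#' spike), the configuration that generated it, and the ground-truth per-bin
#' intensities for every (neuron, stimulus) pair, kept for recovery tests.
#'
#' @slot spikes data.frame with columns \code{trial_id}, \code{neuron_id},
#'   \code{stimulus_id}, \code{spike_time_s}.
#' @slot config list, the [experimentConfig()] used.
#' @slot truth list of ground-truth intensities indexed
#'   \code{truth[[neuron]][[stimulus]]} (each an [IntensityModel-class]);
#'   empty when the data were read from disk.
#' @export
setClass("SpikeExperiment",
  representation(spikes = "data.frame", config = "list", truth = "list"),
  prototype(spikes = data.frame(trial_id = character(0),
                                neuron_id = character(0),
                                stimulus_id = character(0),
                                spike_time_s = numeric(0)),
            config = list(), truth = list()))

setValidity("SpikeExperiment", function(object) {
  need <- c("trial_id", "neuron_id", "stimulus_id", "spike_time_s")
  if (!all(need %in% names(object@spikes)))
    return(paste("spike table must have columns", paste(need, collapse = ", ")))
  TRUE
})
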