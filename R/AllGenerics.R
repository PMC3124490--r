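#' @rdname spikeTrain
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))

#' @rdname spikeTrain
#' @export
setGeneric("observationInterval",
           function(x) standardGeneric("observationInterval"))

#' @rdname spikeTrain
#' @export
setGeneric("nSpikes", function(x) standardGeneric("nSpikes"))

#' @rdname binSpikeTrain
#' @export
setGeneric("increments", function(x) standardGeneric("increments"))

#' @rdname binSpikeTrain
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname intensityModel
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))

#' Point-process log-likelihood of spike observations
#'
#' One generic covers the three likelihood evaluations of the framework:
#' the discrete likelihood of a [BinnedSpikeTrain-class] under an
#' [IntensityModel-class]; the continuous-time likelihood of a
#' [SpikeTrain-class] under an intensity function (or piecewise-constant
#' [IntensityModel-class]); and the marked-point-process likelihood of a
#' [PopulationRecording-class] under a [PopulationIntensity-class].
#' All values are natural-log likelihoods (nats).
#'
#' @param observation spike observation (see above).
#' @param model intensity model matching the observation.
#' @param ... method arguments; the binned method accepts
#'   \code{form = c("local-poisson", "bernoulli")}.
#' @return log-likelihood in nats.
#' @export
setGeneric("logLikelihood", function(observation, model, ...)
  standardGeneric("logLikelihood"))

#' @rdname poolPopulation
#' @export
setGeneric("marks", function(x) standardGeneric("marks"))

#' @rdname poolPopulation
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))
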