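#' Pool single-neuron spike trains into a marked point process
#'
#' Merges the spikes of \eqn{K} simultaneously observed neurons into one
#' ordered event stream in which each event carries the index of the neuron
#' that fired (its mark).  Exact time collisions across neurons are kept and
#' ordered by neuron index, with a warning, so the pooled stream is
#' reproducible.
#'
#' @param trains list of [SpikeTrain-class], one per neuron, sharing the same
#'   observation interval; the list order defines the neuron indices.
#' @param x a [PopulationRecording-class] (for the accessors).
#' @return a [PopulationRecording-class]; \code{marks} and \code{nNeurons} are
#'   its accessors.
#' @examples
#' rec <- poolPopulation(list(spikeTrain(0.1, c(0, 1)),
#'                            spikeTrain(0.2, c(0, 1))))
#' cbind(spikeTimes(rec), marks(rec))
#' @export
poolPopulation <- function(trains) {
  stopifnot(length(trains) >= 1L,
            all(vapply(trains, is, logical(1), "SpikeTrain")))
  interval <- trains[[1L]]@interval
  for (tr in trains[-1L])
    if (any(abs(tr@interval - interval) > 1e-9))
      stop("all neurons must share one observation interval")
  times <- unlist(lapply(trains, slot, "times"), use.names = FALSE)
  mk <- rep.int(seq_along(trains),
                vapply(trains, function(tr) length(tr@times), integer(1)))
  ord <- order(times, mk)   # ties broken by neuron index
  times <- times[ord]; mk <- mk[ord]
  if (anyDuplicated(times))
    warning("exact spike-time collision across neurons; ties ordered by neuron index")
  new("PopulationRecording", times = times, marks = as.integer(mk),
      nNeurons = length(trains), interval = interval)
}

#' @rdname poolPopulation
#' @export
setMethod("spikeTimes", "PopulationRecording", function(x) x@times)

#' @rdname poolPopulation
#' @export
setMethod("marks", "PopulationRecording", function(x) x@marks)

#' @rdname poolPopulation
#' @export
setMethod("nNeurons", "PopulationRecording", function(x) x@nNeurons)

#' @rdname poolPopulation
#' @export
setMethod("nSpikes", "PopulationRecording", function(x) length(x@times))

#' @rdname poolPopulation
#' @export
setMethod("observationInterval", "PopulationRecording", function(x) x@interval)

setMethod("show", "PopulationRecording", function(object) {
  cat(sprintf("PopulationRecording: %d events from %d neurons on (%g, %g] s\n",
              length(object@times), object@nNeurons,
              object@interval[1L], object@interval[2L]))
})

#' Bundle per-neuron intensity models into a population model
#'
#' @param models list of [IntensityModel-class], one per neuron, on a common
#'   bin grid.
#' @return a [PopulationIntensity-class].
#' @export
populationIntensity <- function(models) new("PopulationIntensity", models = models)

#' @rdname populationIntensity
#' @export
setMethod("nNeurons", "PopulationIntensity",
          function(x) length(x@models))

setMethod("show", "PopulationIntensity", function(object) {
  cat(sprintf("PopulationIntensity: %d neurons on %d bins of %g s\n",
              length(object@models), length(object@models[[1L]]@lambda),
              object@models[[1L]]@delta))
})

#' Ground-process intensity of a neural population
#'
#' The pooled (unmarked) event stream of independent neurons is itself a point
#' process whose intensity is the sum of the per-neuron intensities,
#' \eqn{\lambda_G(t) = \sum_c \lambda_c(t)}.
#'
#' @param pop a [PopulationIntensity-class].
#' @return an [IntensityModel-class] on the same grid.
#' @export
groundIntensity <- function(pop) {
  stopifnot(is(pop, "PopulationIntensity"))
  ref <- pop@models[[1L]]
  lam <- Reduce(`+`, lapply(pop@models, slot, "lambda"))
  # the ground process feeds the continuous-time marked likelihood, where
  # lambda * delta >= 1 is legitimate, so no Bernoulli-validity warning here
  new("IntensityModel", lambda = lam, delta = ref@delta,
      interval = ref@interval, state = matrix(numeric(0), 0, 0),
      trace = data.frame())
}

#' Mark probabilities at each bin
#'
#' Given that a pooled event occurs in bin \eqn{k}, the neuron it came from is
#' multinomial with probabilities
#' \eqn{p_c = \lambda_{c,k} / \lambda_{G,k}}.
#'
#' @param pop a [PopulationIntensity-class].
#' @param bin bin index (1-based), or \code{NULL} for all bins.
#' @return probability vector of length \eqn{K} (or a \eqn{J \times K} matrix
#'   when \code{bin} is \code{NULL}); rows sum to 1.
#' @export
markProbabilities <- function(pop, bin = NULL) {
  stopifnot(is(pop, "PopulationIntensity"))
  lam <- vapply(pop@models, slot, numeric(length(pop@models[[1L]]@lambda)),
                "lambda")
  lam <- matrix(lam, ncol = length(pop@models))
  pr <- lam / rowSums(lam)
  if (is.null(bin)) pr else pr[bin, ]
}

#' @describeIn logLikelihood marked-point-process likelihood of a pooled
#'   population recording:
#'   \eqn{\sum_j [\log\lambda_G(w_j) + \log p_{c_j}(w_j)] - \int \lambda_G}.
#'   For independent neurons this decomposes exactly into the sum of the
#'   per-neuron likelihoods.
#' @export
setMethod("logLikelihood",
          signature("PopulationRecording", "PopulationIntensity"),
  function(observation, model, ...) {
    K <- length(model@models)
    if (observation@nNeurons != K)
      stop("recording has ", observation@nNeurons, " neurons but the model has ", K)
    if (length(observation@times) &&
        (max(observation@marks) > K || min(observation@marks) < 1L))
      stop("mark out of range")
    ground <- groundIntensity(model)
    lamG <- .evalIntensityAt(ground, observation@times)
    lamC <- vapply(seq_along(observation@times), function(j)
      .evalIntensityAt(model@models[[observation@marks[j]]],
                       observation@times[j]), numeric(1))
    sum(log(lamG)) + sum(log(lamC / lamG)) -
      sum(ground@lambda) * ground@delta
  })
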