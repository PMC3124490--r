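#' Construct a spike train
#'
#' @param times numeric spike times in seconds, strictly increasing, all inside
#'   \code{(interval[1], interval[2]]}.
#' @param interval observation interval \code{c(t_start, t_end)} in seconds.
#' @param neuronId,trialId,stimulusId labels; \code{stimulusId} may be
#'   \code{NA} for unlabelled data.
#' @param x an object with spike-train semantics.
#' @return [spikeTrain()] returns a [SpikeTrain-class]; \code{spikeTimes},
#'   \code{observationInterval} and \code{nSpikes} are its accessors (the
#'   latter two also apply to binned trains and population recordings).
#' @examples
#' st <- spikeTrain(c(0.05, 0.25), interval = c(0, 1))
#' nSpikes(st)
#' @export
spikeTrain <- function(times, interval, neuronId = "n1", trialId = "t1",
                       stimulusId = NA_character_) {
  new("SpikeTrain", times = as.numeric(sort(times)),
      interval = as.numeric(interval),
      neuronId = as.character(neuronId), trialId = as.character(trialId),
      stimulusId = as.character(stimulusId))
}

#' @rdname spikeTrain
#' @export
setMethod("spikeTimes", "SpikeTrain", function(x) x@times)

#' @rdname spikeTrain
#' @export
setMethod("observationInterval", "SpikeTrain", function(x) x@interval)

#' @rdname spikeTrain
#' @export
setMethod("nSpikes", "SpikeTrain", function(x) length(x@times))

setMethod("show", "SpikeTrain", function(object) {
  cat(sprintf("SpikeTrain: %d spikes on (%g, %g] s  [neuron %s, trial %s, stimulus %s]\n",
              length(object@times), object@interval[1L], object@interval[2L],
              object@neuronId, object@trialId, object@stimulusId))
})

#' Restrict a spike train to a sub-interval
#'
#' Keeps the spikes falling in \code{(interval[1], interval[2]]} and rebases
#' the observation interval, e.g. to analyse only the response window of a
#' trial.
#'
#' @param train a [SpikeTrain-class].
#' @param interval numeric length 2 inside the train's interval.
#' @return a [SpikeTrain-class] on the new interval.
#' @export
cropSpikeTrain <- function(train, interval) {
  stopifnot(is(train, "SpikeTrain"),
            interval[1L] >= train@interval[1L] - 1e-12,
            interval[2L] <= train@interval[2L] + 1e-12)
  .cropTrain(train, interval[1L], interval[2L])
}

#' Discretise a spike train into binary increments
#'
#' Divides the observation interval into bins of width \code{delta}; bin
#' \eqn{k} (1-based) covers \eqn{[t_{start}+(k-1)\Delta, t_{start}+k\Delta)}
#' and a spike falling exactly on the interval end is assigned to the last
#' bin.  The discretisation requires at most one spike per bin; two spikes in
#' one bin raise an error naming the offending bin.
#'
#' @param train a [SpikeTrain-class].
#' @param delta bin width in seconds.
#' @param truncateLast allow a shortened final bin when the interval span is
#'   not an integer multiple of \code{delta}; the result is flagged.
#' @param onCollision what to do when two spikes fall in one bin:
#'   \code{"error"} (the default; the discretisation is invalid) or
#'   \code{"collapse"}, which records a single spike for the bin with a
#'   warning — useful in windowed pipeline analyses where an occasional
#'   coincidence should not abort the run.
#' @param x a [BinnedSpikeTrain-class] (for the accessors).
#' @return a [BinnedSpikeTrain-class]; \code{increments} and \code{binWidth}
#'   are its accessors.
#' @examples
#' b <- binSpikeTrain(spikeTrain(c(0.05, 0.25), c(0, 1)), delta = 0.1)
#' increments(b)
#' @export
binSpikeTrain <- function(train, delta, truncateLast = FALSE,
                          onCollision = c("error", "collapse")) {
  onCollision <- match.arg(onCollision)
  stopifnot(is(train, "SpikeTrain"), delta > 0)
  span <- diff(train@interval)
  ratio <- span / delta
  if (abs(ratio - round(ratio)) < 1e-6) {
    J <- as.integer(round(ratio))
    truncated <- FALSE
  } else if (truncateLast) {
    J <- as.integer(ceiling(ratio - 1e-9))
    truncated <- TRUE
  } else {
    stop("interval span ", span, " s is not an integer multiple of delta = ",
         delta, " s; pass truncateLast = TRUE to allow a shortened last bin")
  }
  idx <- floor((train@times - train@interval[1L]) / delta) + 1L
  idx[idx > J] <- J  # spike exactly at t_end goes to the last bin
  if (anyDuplicated(idx)) {
    bad <- idx[duplicated(idx)][1L]
    if (onCollision == "error")
      stop("bin ", bad, " holds more than one spike; choose a smaller delta ",
           "(current delta = ", delta, " s)")
    warning("bin ", bad, " holds more than one spike; collapsing to one")
    idx <- unique(idx)
  }
  inc <- integer(J)
  inc[idx] <- 1L
  new("BinnedSpikeTrain", increments = inc, delta = as.numeric(delta),
      interval = train@interval, truncated = truncated)
}

#' @rdname binSpikeTrain
#' @export
setMethod("increments", "BinnedSpikeTrain", function(x) x@increments)

#' @rdname binSpikeTrain
#' @export
setMethod("binWidth", "BinnedSpikeTrain", function(x) x@delta)

#' @rdname binSpikeTrain
#' @export
setMethod("nSpikes", "BinnedSpikeTrain", function(x) sum(x@increments))

#' @rdname binSpikeTrain
#' @export
setMethod("observationInterval", "BinnedSpikeTrain", function(x) x@interval)

setMethod("show", "BinnedSpikeTrain", function(object) {
  cat(sprintf("BinnedSpikeTrain: J = %d bins of %g s, %d spikes%s\n",
              length(object@increments), object@delta, sum(object@increments),
              if (object@truncated) " (last bin truncated)" else ""))
})

#' Construct a per-bin conditional-intensity model
#'
#' @param lambda positive per-bin intensity in Hz (recycled if length 1).
#' @param delta bin width in seconds.
#' @param interval observation interval; defaults to \code{(0, J * delta]}.
#' @param nBins number of bins when \code{lambda} has length 1.
#' @param state optional latent-state trajectory (J x d matrix).
#' @param trace optional filter trace data.frame.
#' @param x an [IntensityModel-class] (for the accessors).
#' @return an [IntensityModel-class]; \code{intensity} returns the per-bin
#'   rates in Hz.  A warning is issued when \eqn{\lambda\Delta \ge 1}
#'   anywhere, since the per-bin Bernoulli reading then breaks down.
#' @examples
#' m <- intensityModel(20, delta = 0.001, nBins = 1000)
#' head(intensity(m))
#' @export
intensityModel <- function(lambda, delta, interval = NULL, nBins = NULL,
                           state = matrix(numeric(0), 0, 0),
                           trace = data.frame()) {
  if (length(lambda) == 1L) {
    if (is.null(nBins)) {
      if (is.null(interval)) stop("give nBins or interval for scalar lambda")
      nBins <- as.integer(round(diff(interval) / delta))
    }
    lambda <- rep(as.numeric(lambda), nBins)
  }
  if (is.null(interval)) interval <- c(0, length(lambda) * delta)
  if (any(lambda * delta >= 1))
    warning("lambda * delta >= 1 in ", sum(lambda * delta >= 1),
            " bin(s); the Bernoulli reading of the discretised process is invalid there")
  new("IntensityModel", lambda = as.numeric(lambda), delta = as.numeric(delta),
      interval = as.numeric(interval), state = state, trace = trace)
}

#' @rdname intensityModel
#' @export
setMethod("intensity", "IntensityModel", function(x) x@lambda)

#' @rdname intensityModel
#' @export
setMethod("binWidth", "IntensityModel", function(x) x@delta)

#' @rdname intensityModel
#' @export
setMethod("observationInterval", "IntensityModel", function(x) x@interval)

setMethod("show", "IntensityModel", function(object) {
  cat(sprintf("IntensityModel: %d bins of %g s, mean rate %.2f Hz%s\n",
              length(object@lambda), object@delta, mean(object@lambda),
              if (nrow(object@trace)) " (with filter trace)" else ""))
})

#' Filter trace of a fitted intensity model
#'
#' @param model an [IntensityModel-class] produced by [fitIntensity()].
#' @return data.frame with one row per bin: predicted and posterior state mean,
#'   posterior variance, innovation, Kalman gain and fitted rate.
#' @export
filterTrace <- function(model) {
  stopifnot(is(model, "IntensityModel"))
  model@trace
}

.evalIntensityAt <- function(model, times) {
  # step-function lookup on the bin grid; times on (t_start, t_end]
  idx <- floor((times - model@interval[1L]) / model@delta) + 1L
  idx[idx > length(model@lambda)] <- length(model@lambda)
  idx[idx < 1L] <- 1L
  model@lambda[idx]
}

#' @describeIn logLikelihood discrete likelihood of a binned train.  Default
#'   \code{form = "local-poisson"} evaluates
#'   \eqn{\sum_k \Delta N_k \log(\lambda_k\Delta) - \sum_k \lambda_k\Delta};
#'   \code{form = "bernoulli"} uses the exact Bernoulli mass
#'   \eqn{\prod (\lambda_k\Delta)^{\Delta N_k}(1-\lambda_k\Delta)^{1-\Delta N_k}}.
#'   The two agree to second order in \eqn{\lambda\Delta}.
#' @export
setMethod("logLikelihood", signature("BinnedSpikeTrain", "IntensityModel"),
  function(observation, model, form = c("local-poisson", "bernoulli"), ...) {
    form <- match.arg(form)
    dN <- observation@increments
    lam <- model@lambda
    if (length(dN) != length(lam))
      stop("observation has ", length(dN), " bins but the model has ",
           length(lam))
    if (abs(observation@delta - model@delta) > 1e-12)
      stop("observation and model bin widths differ")
    p <- lam * model@delta
    if (form == "local-poisson") {
      sum(dN * log(p)) - sum(p)
    } else {
      if (any(p >= 1))
        stop("bernoulli form requires lambda * delta < 1 in every bin")
      sum(dN * log(p) + (1 - dN) * log1p(-p))
    }
  })

#' @describeIn logLikelihood continuous-time likelihood
#'   \eqn{\sum_j \log\lambda(u_j) - \int_{t_0}^{t_1} \lambda(t)\,dt} for an
#'   intensity given as a function of time (Hz); the integral uses adaptive
#'   quadrature.
#' @export
setMethod("logLikelihood", signature("SpikeTrain", "function"),
  function(observation, model, ...) {
    lamU <- vapply(observation@times, model, numeric(1))
    if (length(lamU) && any(lamU <= 0))
      stop("intensity must be strictly positive at every spike time")
    int <- stats::integrate(function(t) vapply(t, model, numeric(1)),
                            observation@interval[1L], observation@interval[2L],
                            rel.tol = 1e-9, subdivisions = 500L)$value
    sum(log(lamU)) - int
  })

#' @describeIn logLikelihood continuous-time likelihood under a
#'   piecewise-constant [IntensityModel-class] (exact integral on the grid).
#' @export
setMethod("logLikelihood", signature("SpikeTrain", "IntensityModel"),
  function(observation, model, ...) {
    lamU <- .evalIntensityAt(model, observation@times)
    if (length(lamU) && any(lamU <= 0))
      stop("intensity must be strictly positive at every spike time")
    sum(log(lamU)) - sum(model@lambda) * model@delta
  })

#' Remove the bin-width Jacobian from a discrete log-likelihood
#'
#' The discrete likelihood of a binned train and the continuous-time density
#' of the underlying spike times differ by the Jacobian \eqn{n\log\Delta} of
#' the time-to-bin mapping.  This helper converts a discrete value to the
#' density scale so the two can be compared as \eqn{\Delta \to 0}.
#'
#' @param logLik discrete log-likelihood in nats.
#' @param n number of spikes in the observation.
#' @param delta bin width in seconds.
#' @return log-density in nats, \code{logLik - n * log(delta)}.
#' @export
densityScaleLogLik <- function(logLik, n, delta) logLik - n * log(delta)
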