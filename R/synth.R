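#' Configuration of a synthetic visual-categorisation experiment
#'
#' Defaults mirror a passive-fixation single-unit study design: 36 grey-scale
#' object stimuli in 6 categories, each presented about 50 times for 300 ms
#' with a 700-ms interstimulus interval, a 100-ms pre-stimulus baseline, and
#' a population of up to 100 recorded neurons.  Spike times are generated in
#' continuous time; \code{delta} is the bin width used for the ground-truth
#' intensity grids.
#'
#' @param nStimuli number of stimuli (divisible by \code{nCategories}).
#' @param nCategories number of stimulus categories.
#' @param trialsPerStimulus repetitions of each stimulus.
#' @param stimDuration,isi,baseline stimulus-on, interstimulus and
#'   pre-stimulus durations in seconds.
#' @param nNeurons number of neurons.
#' @param delta intensity-grid bin width in seconds.
#' @param seed RNG seed (mandatory: the generator is fully reproducible).
#' @return validated list of class \code{"ExperimentConfig"}; the trial
#'   interval is \code{(0, baseline + stimDuration + isi]} with stimulus onset
#'   at \code{baseline}.
#' @export
experimentConfig <- function(nStimuli = 36L, nCategories = 6L,
                             trialsPerStimulus = 50L, stimDuration = 0.300,
                             isi = 0.700, baseline = 0.100, nNeurons = 100L,
                             delta = 0.001, seed) {
  if (missing(seed)) stop("seed is mandatory for a reproducible experiment")
  stopifnot(nStimuli >= 2L, nCategories >= 1L, nStimuli %% nCategories == 0L,
            trialsPerStimulus >= 1L, stimDuration > 0, isi >= 0, baseline >= 0,
            nNeurons >= 1L, delta > 0)
  cfg <- list(nStimuli = as.integer(nStimuli),
              nCategories = as.integer(nCategories),
              trialsPerStimulus = as.integer(trialsPerStimulus),
              stimDuration = stimDuration, isi = isi, baseline = baseline,
              nNeurons = as.integer(nNeurons), delta = delta,
              seed = as.integer(seed),
              trialDuration = baseline + stimDuration + isi)
  class(cfg) <- "ExperimentConfig"
  cfg
}

#' @export
print.ExperimentConfig <- function(x, ...) {
  cat(sprintf(paste0("ExperimentConfig: %d stimuli in %d categories, ",
                     "%d trials each, %d neurons, trial (0, %g] s, seed %d\n"),
              x$nStimuli, x$nCategories, x$trialsPerStimulus, x$nNeurons,
              x$trialDuration, x$seed))
  invisible(x)
}

#' Simulate an inhomogeneous Poisson spike train by thinning
#'
#' Lewis-Shedler thinning: candidate events are drawn from a homogeneous
#' process at the majorant rate and kept with probability
#' \eqn{\lambda(t)/\lambda_{max}}, which is exact in continuous time for any
#' bounded intensity.
#'
#' @param intensity intensity in Hz: a function of time, a scalar, or an
#'   [IntensityModel-class] (evaluated as a step function).
#' @param interval observation interval \code{c(t_start, t_end)}; defaults to
#'   the model interval for an [IntensityModel-class].
#' @param lambdaMax majorant rate; required to exceed the intensity
#'   everywhere.  Defaults to the exact maximum for scalar and step
#'   intensities, and to 1.05 times the maximum on a 2000-point grid for a
#'   function (pass an explicit bound for spiky intensities).
#' @param seed optional RNG seed (\code{set.seed} is called when given).
#' @param ... labels passed to [spikeTrain()].
#' @return a [SpikeTrain-class].
#' @examples
#' st <- simulateSpikeTrain(function(t) 20 + 15 * sin(2 * pi * t), c(0, 2),
#'                          lambdaMax = 35, seed = 1)
#' @export
simulateSpikeTrain <- function(intensity, interval = NULL, lambdaMax = NULL,
                               seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is(intensity, "IntensityModel")) {
    if (is.null(interval)) interval <- intensity@interval
    if (is.null(lambdaMax)) lambdaMax <- max(intensity@lambda)
    lamFun <- function(t) .evalIntensityAt(intensity, t)
  } else if (is.numeric(intensity) && length(intensity) == 1L) {
    if (is.null(interval)) stop("interval is required for a scalar intensity")
    if (is.null(lambdaMax)) lambdaMax <- intensity
    rate <- intensity
    lamFun <- function(t) rep(rate, length(t))
  } else if (is.function(intensity)) {
    if (is.null(interval)) stop("interval is required for a function intensity")
    if (is.null(lambdaMax)) {
      grid <- seq(interval[1L], interval[2L], length.out = 2000L)
      lambdaMax <- 1.05 * max(vapply(grid, intensity, numeric(1)))
    }
    lamFun <- function(t) vapply(t, intensity, numeric(1))
  } else stop("intensity must be a function, a scalar, or an IntensityModel")
  span <- diff(interval)
  if (lambdaMax <= 0)
    return(spikeTrain(numeric(0), interval, ...))
  nCand <- stats::rpois(1L, lambdaMax * span)
  if (nCand == 0L) return(spikeTrain(numeric(0), interval, ...))
  cand <- sort(stats::runif(nCand, interval[1L], interval[2L]))
  lam <- lamFun(cand)
  if (any(lam > lambdaMax + 1e-9))
    stop("lambdaMax is not a majorant of the intensity")
  keep <- stats::runif(nCand) < lam / lambdaMax
  spikeTrain(cand[keep], interval, ...)
}

# transient-plus-decay response kernel: 0 before onset, peaks at 1 at lag tau
.alphaKernel <- function(t, tau = 0.06) {
  u <- pmax(t, 0) / tau
  ifelse(t > 0, u * exp(1 - u), 0)
}

#' Default category-selective tuning for the synthetic experiment
#'
#' Each neuron gets a preferred category with a strong log-gain and weaker
#' gains elsewhere, a per-stimulus jitter so stimuli within a category are
#' distinguishable, a response latency, and a baseline rate.  Log-intensity is
#' \code{log(baseline) + gain * kernel(t - onset - latency)} with a
#' transient-plus-decay kernel, so the peak evoked rate of a preferred
#' stimulus is about \code{baseline * exp(gain)}.
#'
#' @param cfg an [experimentConfig()].
#' @param baselineRate mean spontaneous rate in Hz.
#' @param prefGain,nonprefGain mean log-gain for preferred / non-preferred
#'   categories.
#' @param stimJitterSD per-stimulus gain jitter (log scale).
#' @param meanLatency,latencySD response latency distribution (s).
#' @return list of per-neuron tuning parameters (gains, latency, baseline,
#'   preferred category), drawn with \code{cfg$seed}.
#' @export
makeTuning <- function(cfg, baselineRate = 5, prefGain = 1.8,
                       nonprefGain = 0.4, stimJitterSD = 0.15,
                       meanLatency = 0.080, latencySD = 0.010) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  set.seed(cfg$seed)
  perCat <- cfg$nStimuli %/% cfg$nCategories
  stimCategory <- rep(seq_len(cfg$nCategories), each = perCat)
  lapply(seq_len(cfg$nNeurons), function(n) {
    pref <- sample.int(cfg$nCategories, 1L)
    catGain <- stats::rnorm(cfg$nCategories, nonprefGain, 0.1)
    catGain[pref] <- stats::rnorm(1L, prefGain, 0.2)
    list(preferred = pref,
         stimCategory = stimCategory,
         stimGain = catGain[stimCategory] +
           stats::rnorm(cfg$nStimuli, 0, stimJitterSD),
         latency = max(stats::rnorm(1L, meanLatency, latencySD), 0.02),
         baseline = baselineRate * exp(stats::rnorm(1L, 0, 0.2)))
  })
}

.truthIntensity <- function(cfg, tun, stim) {
  mids <- seq(cfg$delta / 2, cfg$trialDuration - cfg$delta / 2,
              by = cfg$delta)
  lam <- tun$baseline *
    exp(tun$stimGain[stim] *
        .alphaKernel(mids - cfg$baseline - tun$latency))
  intensityModel(pmax(lam, 1e-6), delta = cfg$delta,
                 interval = c(0, cfg$trialDuration))
}

#' Simulate a full multi-neuron, multi-stimulus experiment
#'
#' Draws every (neuron, stimulus, trial) spike train from its ground-truth
#' inhomogeneous Poisson intensity by thinning, with trials of the same
#' stimulus sharing trial identifiers across neurons (simultaneous
#' recording).  The ground-truth intensities are stored for parameter-recovery
#' tests.  The same seed reproduces the dataset exactly.
#'
#' @param cfg an [experimentConfig()].
#' @param tuning per-neuron tuning list; defaults to [makeTuning()] drawn from
#'   \code{cfg$seed}.
#' @return a [SpikeExperiment-class].
#' @export
simulateExperiment <- function(cfg, tuning = NULL) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  if (is.null(tuning)) tuning <- makeTuning(cfg)
  set.seed(cfg$seed + 1L)
  truth <- lapply(seq_len(cfg$nNeurons), function(n)
    lapply(seq_len(cfg$nStimuli), function(s)
      .truthIntensity(cfg, tuning[[n]], s)))
  rows <- vector("list", cfg$nNeurons * cfg$nStimuli * cfg$trialsPerStimulus)
  r <- 0L
  for (s in seq_len(cfg$nStimuli)) {
    for (tr in seq_len(cfg$trialsPerStimulus)) {
      trialId <- sprintf("s%02d_t%03d", s, tr)
      for (n in seq_len(cfg$nNeurons)) {
        st <- simulateSpikeTrain(truth[[n]][[s]])
        r <- r + 1L
        if (length(st@times))
          rows[[r]] <- data.frame(trial_id = trialId,
                                  neuron_id = sprintf("n%03d", n),
                                  stimulus_id = sprintf("s%02d", s),
                                  spike_time_s = st@times)
      }
    }
  }
  spikes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(spikes))
    spikes <- data.frame(trial_id = character(0), neuron_id = character(0),
                         stimulus_id = character(0), spike_time_s = numeric(0))
  names(truth) <- sprintf("n%03d", seq_len(cfg$nNeurons))
  truth <- lapply(truth, function(x) {
    names(x) <- sprintf("s%02d", seq_len(cfg$nStimuli)); x
  })
  new("SpikeExperiment", spikes = spikes, config = unclass(cfg), truth = truth)
}

setMethod("show", "SpikeExperiment", function(object) {
  cat(sprintf("SpikeExperiment: %d spikes, %d neurons, %d stimuli, %d trials\n",
              nrow(object@spikes),
              length(unique(object@spikes$neuron_id)),
              length(unique(object@spikes$stimulus_id)),
              length(unique(object@spikes$trial_id))))
})

#' Extract the trials of one (neuron, stimulus) pair as spike trains
#'
#' @param x a [SpikeExperiment-class] or a spike table data.frame.
#' @param neuron,stimulus identifiers as they appear in the table.
#' @param interval trial interval; taken from the experiment config when
#'   available.
#' @return list of [SpikeTrain-class], one per trial (empty trials included
#'   when the trial roster can be inferred from the table).
#' @export
experimentTrains <- function(x, neuron, stimulus, interval = NULL) {
  spikes <- if (is(x, "SpikeExperiment")) x@spikes else x
  if (is.null(interval)) {
    if (is(x, "SpikeExperiment") && !is.null(x@config$trialDuration))
      interval <- c(0, x@config$trialDuration)
    else
      interval <- c(0, max(spikes$spike_time_s))
  }
  sub <- spikes[spikes$stimulus_id == stimulus, ]
  # a generated experiment knows its full trial roster, so trials in which
  # this stimulus evoked no spikes anywhere are still returned (empty)
  trialIds <- if (is(x, "SpikeExperiment") &&
                  !is.null(x@config$trialsPerStimulus))
    paste0(stimulus, sprintf("_t%03d",
                             seq_len(x@config$trialsPerStimulus)))
  else sort(unique(sub$trial_id))
  sub <- sub[sub$neuron_id == neuron, ]
  lapply(trialIds, function(id)
    spikeTrain(sub$spike_time_s[sub$trial_id == id], interval,
               neuronId = neuron, trialId = id, stimulusId = stimulus))
}

#' Ground-truth intensity of a simulated (neuron, stimulus) pair
#'
#' @param x a [SpikeExperiment-class] produced by [simulateExperiment()].
#' @param neuron,stimulus identifiers.
#' @return the [IntensityModel-class] the spikes were drawn from.
#' @export
groundTruth <- function(x, neuron, stimulus) {
  stopifnot(is(x, "SpikeExperiment"))
  if (!length(x@truth)) stop("this experiment carries no ground truth")
  x@truth[[neuron]][[stimulus]]
}

#' Simulate a marked population recording from per-neuron intensities
#'
#' Generative reading of the marked-point-process model: pooled events are
#' drawn from the ground process (intensity \eqn{\lambda_G = \sum_c
#' \lambda_c}) by thinning, and each event's neuron label is sampled from the
#' multinomial mark distribution \eqn{p_c = \lambda_c / \lambda_G} at the
#' event's bin.  Distributionally equivalent to simulating each neuron
#' independently and pooling.
#'
#' @param pop a [PopulationIntensity-class].
#' @param seed optional RNG seed.
#' @return a [PopulationRecording-class].
#' @export
simulatePopulationMarked <- function(pop, seed = NULL) {
  stopifnot(is(pop, "PopulationIntensity"))
  if (!is.null(seed)) set.seed(seed)
  ground <- groundIntensity(pop)
  st <- simulateSpikeTrain(ground)
  K <- length(pop@models)
  if (!length(st@times))
    return(new("PopulationRecording", times = numeric(0), marks = integer(0),
               nNeurons = K, interval = ground@interval))
  pr <- markProbabilities(pop)
  bins <- floor((st@times - ground@interval[1L]) / ground@delta) + 1L
  bins[bins > nrow(pr)] <- nrow(pr)
  mk <- vapply(bins, function(b) sample.int(K, 1L, prob = pr[b, ]),
               integer(1))
  new("PopulationRecording", times = st@times, marks = mk, nNeurons = K,
      interval = ground@interval)
}

#' Per-neuron spike trains of a marked recording
#'
#' @param rec a [PopulationRecording-class].
#' @param neuron neuron index.
#' @return the [SpikeTrain-class] of that neuron's events.
#' @export
extractNeuron <- function(rec, neuron) {
  stopifnot(is(rec, "PopulationRecording"),
            neuron >= 1L, neuron <= rec@nNeurons)
  spikeTrain(rec@times[rec@marks == neuron], rec@interval,
             neuronId = as.character(neuron))
}
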