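#' Classical (Torgerson) multidimensional scaling to two dimensions
#'
#' Double-centres the squared dissimilarities, eigendecomposes, and returns
#' the coordinates along the eigenvectors of the two largest eigenvalues,
#' scaled by the square roots of the eigenvalues (via [stats::cmdscale()]).
#' For genuinely 2-D Euclidean distances the embedding reproduces the input
#' distances exactly up to rigid motion.  Negative eigenvalues — the signature
#' of a non-Euclidean dissimilarity — are truncated with a warning and the
#' fraction of dispersion explained by the retained axes is reported.
#'
#' @param d symmetric nonnegative dissimilarity matrix with zero diagonal (or
#'   a [stats::dist] object).
#' @param k embedding dimension (2 throughout the analyses here).
#' @return list with \code{points} (n x k, column-centred),
#'   \code{eigenvalues} (all n of them) and \code{explained} (fraction of the
#'   positive dispersion captured by the k axes).
#' @export
classicalMDS <- function(d, k = 2L) {
  m <- as.matrix(d)
  if (nrow(m) < k + 1L) stop("need at least k + 1 objects")
  if (max(abs(m - t(m))) > 1e-8) stop("dissimilarity matrix must be symmetric")
  if (any(diag(m) != 0)) stop("dissimilarity matrix must have a zero diagonal")
  if (any(m < 0)) stop("dissimilarities must be nonnegative")
  if (max(m) == 0) {
    pts <- matrix(0, nrow(m), k, dimnames = list(rownames(m), NULL))
    return(list(points = pts, eigenvalues = rep(0, nrow(m)), explained = 1))
  }
  fit <- stats::cmdscale(m, k = k, eig = TRUE)
  ev <- fit$eig
  if (any(ev < -1e-8 * max(abs(ev))))
    warning("negative eigenvalues truncated: the dissimilarities are not Euclidean")
  pos <- pmax(ev, 0)
  pts <- fit$points
  if (ncol(pts) < k)   # degenerate inputs can yield fewer axes
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  rownames(pts) <- rownames(m)
  list(points = pts, eigenvalues = ev,
       explained = sum(pos[seq_len(k)]) / sum(pos))
}

#' Pairwise dissimilarity matrix of row vectors
#'
#' @param points numeric matrix, one object per row.
#' @param metric \code{"euclidean"} (amplitude of the vector difference, the
#'   observation-space distance between binary spike vectors) or
#'   \code{"correlation"} (\eqn{1 - r}, the rate-vector distance).
#' @param normalize divide the matrix by its maximum entry, the convention
#'   used before MDS display; off by default.
#' @return symmetric matrix with zero diagonal, row names preserved.
#' @export
pairwiseDistances <- function(points, metric = c("euclidean", "correlation"),
                              normalize = FALSE) {
  metric <- match.arg(metric)
  points <- as.matrix(points)
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(points))
  } else {
    if (ncol(points) < 2L)
      stop("correlation distance needs vectors of length >= 2")
    1 - stats::cor(t(points))
  }
  diag(d) <- 0
  d[d < 0] <- 0   # clip the tiny negatives of correlation round-off
  if (normalize && max(d) > 0) d <- d / max(d)
  d
}

#' Normalised population rate vectors per stimulus
#'
#' For each stimulus, the mean firing rate of every neuron inside a response
#' window (70-270 ms after trial start by default) is computed across trials,
#' z-scored per neuron across stimuli, and the resulting per-stimulus vector
#' is scaled to unit Euclidean length.  These are the rate-framework
#' population response vectors whose correlation distances form the baseline
#' stimulus geometry.
#'
#' @param spikes spike table data.frame (\code{trial_id}, \code{neuron_id},
#'   \code{stimulus_id}, \code{spike_time_s}) or a [SpikeExperiment-class].
#' @param window numeric length 2, response window in seconds.
#' @return matrix, one unit-norm row per stimulus, one column per neuron.
#' @export
rateVectors <- function(spikes, window = c(0.070, 0.270)) {
  if (is(spikes, "SpikeExperiment")) spikes <- spikes@spikes
  stopifnot(all(c("trial_id", "neuron_id", "stimulus_id", "spike_time_s") %in%
                names(spikes)))
  stims <- sort(unique(spikes$stimulus_id))
  neurons <- sort(unique(spikes$neuron_id))
  span <- diff(window)
  rate <- matrix(0, length(stims), length(neurons),
                 dimnames = list(stims, neurons))
  for (s in seq_along(stims)) {
    sub <- spikes[spikes$stimulus_id == stims[s], ]
    nTrials <- length(unique(sub$trial_id))
    inWin <- sub$spike_time_s > window[1L] & sub$spike_time_s <= window[2L]
    cnt <- table(factor(sub$neuron_id[inWin], levels = neurons))
    rate[s, ] <- as.numeric(cnt) / (max(nTrials, 1L) * span)
  }
  z <- scale(rate)                       # per-neuron z-score across stimuli
  z[!is.finite(z)] <- 0                  # silent neurons carry no signal
  norms <- sqrt(rowSums(z^2))
  norms[norms == 0] <- 1
  out <- z / norms
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Sliding-window stimulus dissimilarity in the rate and likelihood frameworks
#'
#' Tracks the dissimilarity between two stimuli through the trial.  In each
#' window the rate framework computes the correlation distance \eqn{1 - r}
#' between the two per-stimulus population rate vectors (over neurons), and
#' the likelihood framework computes the information-based stimulus distance
#' \eqn{|I_{ssi}(s_1) - I_{ssi}(s_2)|} from per-window refit intensity models
#' (per-neuron log-likelihoods summed over the simultaneously recorded
#' population).  The latency of maximum dissimilarity is reported for both.
#'
#' @param trains nested list: \code{trains[[stimulus]][[neuron]]} is a list of
#'   [SpikeTrain-class] trials on a common interval; exactly two stimuli.
#'   Trials are matched across neurons by position (simultaneous recording).
#' @param window,step window length and step in seconds.
#' @param delta bin width (s) for the likelihood-framework fits.
#' @param stateNoise EKF state-noise variance for the per-window fits.
#' @return list with \code{series} (data.frame \code{window_center_s},
#'   \code{distance_rate}, \code{distance_likelihood}) and the two peak
#'   latencies \code{peakLatencyRate}, \code{peakLatencyLikelihood} (s).
#' @export
slidingDistance <- function(trains, window = 0.1, step = 0.01, delta = 0.001,
                            stateNoise = 1e-4) {
  stopifnot(length(trains) == 2L)
  K <- length(trains[[1L]])
  interval <- trains[[1L]][[1L]][[1L]]@interval
  starts <- .windowStarts(interval, window, step)
  ser <- data.frame(window_center_s = starts + window / 2,
                    distance_rate = NA_real_, distance_likelihood = NA_real_)
  for (w in seq_along(starts)) {
    w0 <- starts[w]; w1 <- w0 + window
    binned <- lapply(trains, function(byNeuron) lapply(byNeuron, function(trs)
      lapply(trs, function(tr)
        suppressWarnings(binSpikeTrain(.cropTrain(tr, w0, w1), delta,
                                       truncateLast = TRUE,
                                       onCollision = "collapse")))))
    # rate framework: per-stimulus mean rate vector over neurons
    rv <- vapply(binned, function(byNeuron) vapply(byNeuron, function(bs)
      mean(vapply(bs, function(b) sum(b@increments), numeric(1))) / window,
      numeric(1)), numeric(K))
    ser$distance_rate[w] <- if (K >= 2L && stats::sd(rv[, 1L]) > 0 &&
                                stats::sd(rv[, 2L]) > 0)
      1 - stats::cor(rv[, 1L], rv[, 2L]) else 0
    # likelihood framework: per-neuron fits, population log-likelihoods
    fits <- lapply(binned, function(byNeuron)
      lapply(byNeuron, fitIntensity, stateNoise = stateNoise))
    popLL <- function(sObs, sModel) {
      # sum over neurons of per-trial log-likelihoods under stimulus sModel
      nTr <- length(binned[[sObs]][[1L]])
      vapply(seq_len(nTr), function(tr)
        sum(vapply(seq_len(K), function(n)
          logLikelihood(binned[[sObs]][[n]][[tr]], fits[[sModel]][[n]],
                        form = "bernoulli"), numeric(1))), numeric(1))
    }
    info <- vapply(1:2, function(s) {
      llSame <- popLL(s, s)
      llOther <- popLL(s, 3L - s)
      terms <- (llSame - mapply(function(a, b) .logSumExp(c(a, b) + log(0.5)),
                                llSame, llOther)) / log(2)
      mean(terms)
    }, numeric(1))
    ser$distance_likelihood[w] <- abs(info[1L] - info[2L])
  }
  list(series = ser,
       peakLatencyRate = ser$window_center_s[which.max(ser$distance_rate)],
       peakLatencyLikelihood =
         ser$window_center_s[which.max(ser$distance_likelihood)])
}
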