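.log2safe <- function(num, den) {
  # 0 * log(0 / .) := 0; support violations are handled by callers
  out <- rep(0, length(num))
  pos <- num > 0
  out[pos] <- log2(num[pos] / den[pos])
  out
}

#' Stimulus-specific information of a discrete response table
#'
#' The information specifically conveyed about one stimulus is the
#' Kullback-Leibler divergence (in bits) between the response distribution
#' given that stimulus and the stimulus-averaged response distribution:
#' \eqn{I_{ssi}(s_i) = \sum_r p(r \mid s_i) \log_2 [p(r \mid s_i) / \bar p(r)]}.
#' Terms with \eqn{p(r \mid s_i) = 0} contribute zero.
#'
#' @param cond probability vector \eqn{p(r \mid s_i)} over a finite response
#'   alphabet.
#' @param marginal stimulus-averaged response distribution \eqn{\bar p(r)} on
#'   the same alphabet.
#' @return nonnegative scalar, bits.
#' @examples
#' specificInformation(c(0.75, 0.25), c(0.5, 0.5))  # 0.18872 bits
#' @export
specificInformation <- function(cond, marginal) {
  stopifnot(length(cond) == length(marginal),
            all(cond >= 0), all(marginal >= 0),
            abs(sum(cond) - 1) < 1e-8, abs(sum(marginal) - 1) < 1e-8)
  if (any(cond > 0 & marginal == 0))
    stop("marginal has zero mass where the conditional does not (support violation)")
  sum(cond * .log2safe(cond, marginal))
}

#' Mutual information of a joint stimulus-response table
#'
#' \eqn{I(S;R)} in bits, computed as the prior-weighted mean of the per-stimulus
#' specific information, \eqn{I(S;R) = \sum_i p(s_i) I_{ssi}(s_i)}.
#'
#' @param joint matrix of joint probabilities \eqn{p(s, r)} with one row per
#'   stimulus and one column per response; entries sum to 1.
#' @return nonnegative scalar, bits.
#' @examples
#' mutualInformation(rbind(c(0.375, 0.125), c(0.125, 0.375)))  # 0.18872
#' @export
mutualInformation <- function(joint) {
  joint <- as.matrix(joint)
  stopifnot(all(joint >= 0), abs(sum(joint) - 1) < 1e-8)
  ps <- rowSums(joint)
  pr <- colSums(joint)
  sum(vapply(seq_len(nrow(joint)), function(i) {
    if (ps[i] == 0) return(0)
    ps[i] * specificInformation(joint[i, ] / ps[i], pr)
  }, numeric(1)))
}

.logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Monte-Carlo stimulus-specific information in the likelihood space
#'
#' Estimates \eqn{I_{ssi}(s_i)} from observations recorded (or simulated)
#' under stimulus \eqn{s_i} by averaging
#' \eqn{\log_2 [p(x \mid s_i) / \bar p(x)]} over them, where
#' \eqn{\bar p(x) = \sum_j p(s_j) p(x \mid s_j)} is the stimulus-averaged
#' model.  Each likelihood is the exact Bernoulli product over bins, so for
#' binary responses on few bins the estimate converges to the enumerated
#' table value.
#'
#' @param models a [ProjectingDistributions-class] (single-neuron models).
#' @param stimulus index \eqn{i} of the stimulus the observations came from.
#' @param observations list of [BinnedSpikeTrain-class] recorded under
#'   \eqn{s_i}.
#' @param form per-bin likelihood form; the exact \code{"bernoulli"} form is
#'   the default so that probabilities normalise over the response alphabet.
#' @return list with \code{bits} (the estimate), \code{se} (Monte-Carlo
#'   standard error) and \code{n}.
#' @export
specificInformationMC <- function(models, stimulus, observations,
                                  form = c("bernoulli", "local-poisson")) {
  stopifnot(is(models, "ProjectingDistributions"))
  form <- match.arg(form)
  lv <- projectSet(observations, models, form = form)   # M x P, nats
  logPrior <- log(models@priors)
  terms <- vapply(seq_len(nrow(lv)), function(m) {
    logpbar <- .logSumExp(lv[m, ] + logPrior)
    if (!is.finite(logpbar)) stop("stimulus-averaged probability is zero (support violation)")
    (lv[m, stimulus] - logpbar) / log(2)
  }, numeric(1))
  list(bits = mean(terms),
       se = stats::sd(terms) / sqrt(length(terms)),
       n = length(terms))
}

#' Information-based distance between two stimuli
#'
#' The distance between stimuli is the absolute difference of the information
#' each conveys specifically, \eqn{D(s_i, s_j) = |I_{ssi}(s_i) - I_{ssi}(s_j)|}
#' (bits).  The absolute value makes \eqn{D} symmetric with zero diagonal — a
#' pseudo-metric (it satisfies the triangle inequality but distinct stimuli
#' with equal specific information have distance zero).
#'
#' @param infoI,infoJ specific information of the two stimuli, bits.
#' @return nonnegative scalar, bits.
#' @seealso [stimulusDistanceMatrix()]
#' @export
stimulusDistance <- function(infoI, infoJ) abs(infoI - infoJ)

#' @param info numeric vector of per-stimulus specific information (bits),
#'   optionally named.
#' @return [stimulusDistanceMatrix()] returns the symmetric P x P matrix of
#'   pairwise distances with zero diagonal.
#' @rdname stimulusDistance
#' @export
stimulusDistanceMatrix <- function(info) {
  d <- abs(outer(info, info, `-`))
  dimnames(d) <- list(names(info), names(info))
  d
}

.windowStarts <- function(interval, window, step) {
  starts <- seq(interval[1L], interval[2L] - window + 1e-12, by = step)
  starts[starts + window <= interval[2L] + 1e-9]
}

.cropTrain <- function(train, w0, w1) {
  keep <- train@times > w0 & train@times <= w1
  new("SpikeTrain", times = train@times[keep], interval = c(w0, w1),
      neuronId = train@neuronId, trialId = train@trialId,
      stimulusId = train@stimulusId)
}

#' Sliding-window stimulus-specific information, two frameworks
#'
#' Tracks the temporal dynamics of the information a neuron conveys about one
#' stimulus.  In each 100-ms window (stepped by 10 ms by default) the
#' stimulus-conditional intensity models are refit from the windowed trials
#' and the specific information is estimated two ways: in the likelihood
#' framework via [specificInformationMC()] on the windowed observations, and
#' in the rate framework from the empirical distribution of per-window spike
#' counts (PSTH-style), Laplace-smoothed with \eqn{\alpha = 0.5} to avoid
#' zero-probability responses.
#'
#' @param trainsByStimulus named list (one element per stimulus) of lists of
#'   [SpikeTrain-class] trials, all on a common trial interval.
#' @param stimulus index of the stimulus whose specific information is
#'   tracked.
#' @param window,step window length and step in seconds.
#' @param delta bin width (s) for the likelihood-framework models.
#' @param priors prior stimulus probabilities; default uniform.
#' @param stateNoise EKF state-noise variance used for the per-window fits.
#' @return data.frame with \code{window_center_s}, \code{bits_likelihood},
#'   \code{bits_rate}.
#' @export
slidingWindowInformation <- function(trainsByStimulus, stimulus,
                                     window = 0.1, step = 0.01,
                                     delta = 0.001, priors = NULL,
                                     stateNoise = 1e-4) {
  P <- length(trainsByStimulus)
  stopifnot(P >= 2L, stimulus >= 1L, stimulus <= P)
  if (is.null(priors)) priors <- rep(1 / P, P)
  interval <- trainsByStimulus[[1L]][[1L]]@interval
  starts <- .windowStarts(interval, window, step)
  out <- data.frame(window_center_s = starts + window / 2,
                    bits_likelihood = NA_real_, bits_rate = NA_real_)
  for (w in seq_along(starts)) {
    w0 <- starts[w]; w1 <- w0 + window
    binned <- lapply(trainsByStimulus, function(trs)
      lapply(trs, function(tr)
        suppressWarnings(binSpikeTrain(.cropTrain(tr, w0, w1), delta,
                                       truncateLast = TRUE,
                                       onCollision = "collapse"))))
    fits <- lapply(binned, fitIntensity, stateNoise = stateNoise)
    pd <- projectingDistributions(fits, priors = priors,
                                  labels = names(trainsByStimulus))
    mc <- specificInformationMC(pd, stimulus, binned[[stimulus]])
    out$bits_likelihood[w] <- mc$bits
    counts <- lapply(binned, function(bs)
      vapply(bs, function(b) sum(b@increments), integer(1)))
    alphabet <- 0:max(1L, unlist(counts))
    tab <- t(vapply(counts, function(cn) {
      h <- tabulate(cn + 1L, nbins = length(alphabet)) + 0.5
      h / sum(h)
    }, numeric(length(alphabet))))
    marginal <- drop(priors %*% tab)
    out$bits_rate[w] <- specificInformation(tab[stimulus, ], marginal)
  }
  out
}
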