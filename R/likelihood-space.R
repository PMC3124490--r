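#' Construct the set of projecting distributions
#'
#' @param models list of \eqn{P \ge 2} stimulus-conditional models, either all
#'   [IntensityModel-class] (single neuron) or all
#'   [PopulationIntensity-class] (population), on one bin grid.
#' @param priors prior stimulus probabilities; default uniform.
#' @param labels stimulus labels; default names of \code{models} or
#'   \code{"s1" ... "sP"}.
#' @return a [ProjectingDistributions-class].
#' @export
projectingDistributions <- function(models, priors = NULL, labels = NULL) {
  P <- length(models)
  if (is.null(priors)) priors <- rep(1 / P, P)
  if (is.null(labels))
    labels <- if (!is.null(names(models))) names(models) else paste0("s", seq_len(P))
  new("ProjectingDistributions", models = models, priors = as.numeric(priors),
      labels = as.character(labels))
}

setMethod("show", "ProjectingDistributions", function(object) {
  cat(sprintf("ProjectingDistributions: P = %d stimuli (%s)\n",
              length(object@models),
              paste(utils::head(object@labels, 6), collapse = ", ")))
})

#' Project an observation into the likelihood space
#'
#' The likelihood projection maps a spike observation to the
#' \eqn{P}-dimensional vector of its log-likelihoods under the \eqn{P}
#' stimulus-conditional models.  Whatever the number of bins \eqn{J}, the
#' image has dimension \eqn{P}, so for \eqn{J > P} the projection reduces
#' dimensionality while preserving exactly the statistics the Bayes classifier
#' needs.
#'
#' @param observation a [BinnedSpikeTrain-class] (single-neuron models) or
#'   [PopulationRecording-class] (population models).
#' @param models a [ProjectingDistributions-class].
#' @param form likelihood form passed to the single-neuron method of
#'   [logLikelihood()].
#' @return named numeric of length \eqn{P}: log-likelihood coordinates (nats).
#' @seealso [projectSet()] for many observations, [classifyLikelihood()]
#' @export
project <- function(observation, models,
                    form = c("local-poisson", "bernoulli")) {
  stopifnot(is(models, "ProjectingDistributions"))
  form <- match.arg(form)
  coords <- vapply(models@models, function(m)
    if (is(m, "IntensityModel")) logLikelihood(observation, m, form = form)
    else logLikelihood(observation, m), numeric(1))
  names(coords) <- models@labels
  coords
}

#' Project many observations at once
#'
#' @param observations list of observations, all compatible with the models.
#' @inheritParams project
#' @param trueStimulus optional character vector of true labels, kept as an
#'   attribute for downstream scoring.
#' @return an M x P matrix of log-likelihood coordinates with the stimulus
#'   labels as column names and \code{attr(, "trueStimulus")} when given.
#' @export
projectSet <- function(observations, models,
                       form = c("local-poisson", "bernoulli"),
                       trueStimulus = NULL) {
  form <- match.arg(form)
  out <- t(vapply(observations, project, numeric(length(models@models)),
                  models = models, form = form))
  colnames(out) <- models@labels
  if (!is.null(trueStimulus)) attr(out, "trueStimulus") <- trueStimulus
  out
}

#' Bayes-optimal classification in the likelihood space
#'
#' In likelihood coordinates the minimum-error Bayes rule is the linear
#' discriminant with unit slope: assign stimulus
#' \eqn{\arg\max_i [\ell_i + \log p(s_i)]}.  Ties go to the smallest index,
#' deterministically.
#'
#' @param coords numeric vector of \eqn{P} log-likelihood coordinates, or an
#'   M x P matrix of them.
#' @param priors prior probabilities; default uniform.
#' @return integer stimulus index (or vector of them for a matrix input).
#' @examples
#' classifyLikelihood(c(-10, -12))               # 1
#' classifyLikelihood(c(-10, -10.5), priors = c(0.25, 0.75))  # 2
#' @export
classifyLikelihood <- function(coords, priors = NULL) {
  if (is.matrix(coords))
    return(apply(coords, 1L, classifyLikelihood, priors = priors))
  P <- length(coords)
  if (is.null(priors)) priors <- rep(1 / P, P)
  score <- coords + log(priors)
  which.max(score)   # which.max takes the first maximum: ties -> smallest index
}

#' Observation-space plug-in Bayes classifier
#'
#' Classifies a binned spike train directly in the observation space by the
#' plug-in Bayes rule \eqn{\arg\max_i \hat p(x \mid s_i) p(s_i)}, evaluating
#' each per-bin mass with [stats::dpois()] (local-Poisson form) or
#' [stats::dbinom()] (Bernoulli form).  This is an independent route to the
#' same decision as [classifyLikelihood()] applied to [project()] output; the
#' two agree exactly for every observation.
#'
#' @param observation a [BinnedSpikeTrain-class].
#' @param models a [ProjectingDistributions-class] with single-neuron models.
#' @param form per-bin mass function used.
#' @return integer stimulus index.
#' @export
classifyObservation <- function(observation, models,
                                form = c("local-poisson", "bernoulli")) {
  stopifnot(is(models, "ProjectingDistributions"),
            is(observation, "BinnedSpikeTrain"))
  form <- match.arg(form)
  dN <- observation@increments
  score <- vapply(seq_along(models@models), function(i) {
    m <- models@models[[i]]
    p <- m@lambda * m@delta
    ll <- if (form == "local-poisson")
      sum(stats::dpois(dN, p, log = TRUE))
    else
      sum(stats::dbinom(dN, 1L, p, log = TRUE))
    ll + log(models@priors[i])
  }, numeric(1))
  which.max(score)
}

#' Empirical check that likelihood-space decision regions are convex
#'
#' The decision region of stimulus \eqn{i} in the likelihood space is an
#' intersection of half-spaces, hence convex and connected.  This routine
#' verifies the property empirically: it simulates observations from the model
#' mixture, keeps the projected points classified as \eqn{i}, and checks that
#' every convex combination (11 equispaced \eqn{\alpha}) of sampled point
#' pairs is still classified as \eqn{i}.
#'
#' @param models a [ProjectingDistributions-class] with single-neuron models.
#' @param stimulus index of the decision region to probe.
#' @param nPairs number of point pairs to test.
#' @param seed RNG seed used for the simulated observations.
#' @return list with \code{pass}, \code{nPairs} actually tested, and
#'   \code{fractionInside} (1 when the property holds).  When fewer than two
#'   points fall in the region the check passes vacuously.
#' @export
decisionRegionConvexityCheck <- function(models, stimulus, nPairs = 200L,
                                         seed = 1L) {
  stopifnot(is(models, "ProjectingDistributions"))
  set.seed(seed)
  P <- length(models@models)
  ref <- models@models[[1L]]
  J <- length(ref@lambda)
  nDraw <- max(20L * nPairs %/% 10L, 200L)
  pts <- matrix(NA_real_, nDraw, P)
  for (r in seq_len(nDraw)) {
    m <- models@models[[sample.int(P, 1L)]]
    inc <- as.integer(stats::runif(J) < pmin(m@lambda * m@delta, 1))
    b <- new("BinnedSpikeTrain", increments = inc, delta = m@delta,
             interval = m@interval, truncated = FALSE)
    pts[r, ] <- project(b, models)
  }
  cls <- classifyLikelihood(pts, priors = models@priors)
  inside <- pts[cls == stimulus, , drop = FALSE]
  if (nrow(inside) < 2L)
    return(list(pass = TRUE, nPairs = 0L, fractionInside = 1))
  alphas <- seq(0, 1, length.out = 11L)
  ok <- logical(nPairs)
  for (q in seq_len(nPairs)) {
    ij <- sample.int(nrow(inside), 2L)
    combo <- outer(alphas, inside[ij[1L], ]) + outer(1 - alphas, inside[ij[2L], ])
    ok[q] <- all(classifyLikelihood(combo, priors = models@priors) == stimulus)
  }
  list(pass = all(ok), nPairs = nPairs, fractionInside = mean(ok))
}

#' Fisher discriminant ratio between two point clusters
#'
#' Projects both clusters onto the Fisher direction
#' \eqn{w = (S_a + S_b)^{-1}(m_a - m_b)} and returns the 1-D separability
#' \eqn{(\tilde m_a - \tilde m_b)^2 / (\tilde s_a^2 + \tilde s_b^2)}.  A
#' singular pooled scatter is regularised with a ridge of \code{1e-8} on the
#' diagonal, with a warning.
#'
#' @param a,b numeric matrices (rows = points) with the same column count;
#'   plain vectors are taken as 1-D clusters.
#' @return nonnegative scalar; 0 for clusters with identical means.
#' @export
fisherRatio <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1L)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1L)
  stopifnot(ncol(a) == ncol(b), nrow(a) >= 2L, nrow(b) >= 2L)
  dm <- colMeans(a) - colMeans(b)
  if (all(abs(dm) < 1e-15)) return(0)
  Sw <- stats::cov(a) + stats::cov(b)
  w <- tryCatch(solve(Sw, dm), error = function(e) NULL)
  if (is.null(w) || !all(is.finite(w))) {
    warning("singular pooled scatter; adding ridge 1e-8 * I")
    w <- solve(Sw + diag(1e-8, ncol(a)), dm)
  }
  pa <- drop(a %*% w); pb <- drop(b %*% w)
  (mean(pa) - mean(pb))^2 / (stats::var(pa) + stats::var(pb))
}

#' Cluster separability gain of the likelihood space over the observation space
#'
#' Compares how separable the stimulus clusters are in the observation space
#' (binary spike vectors, Euclidean distance between vector pairs) and in the
#' likelihood space (projected log-likelihood coordinates), as the mean
#' pairwise Fisher ratio, and reports the relative improvement in percent,
#' \eqn{100 (FR_{lik} - FR_{obs}) / FR_{obs}}.
#'
#' By default (\code{embed = TRUE}) each space is first reduced to the 2-D
#' classical-MDS embedding of its max-normalised Euclidean distance matrix
#' and the Fisher ratios are computed on those embeddings, so the two spaces
#' are compared through cluster pictures of equal dimension.  This matters:
#' the log-likelihood coordinates are an affine function of the binary vector
#' under per-bin Bernoulli or local-Poisson models, so the Fisher ratio taken
#' in the full J-dimensional observation space can never fall below the
#' likelihood-space one — and with trial counts near J its sample estimate
#' also overfits badly.  The low-dimensional geometry each space actually
#' presents is what the comparison is about.  Set \code{embed = FALSE} to
#' compare the raw coordinate matrices instead.
#'
#' @param obsPoints M x J matrix of observation-space points (binary vectors).
#' @param likPoints M x P matrix of likelihood-space coordinates of the same
#'   observations, in the same row order.
#' @param labels length-M vector of stimulus labels.
#' @param embed compare 2-D MDS embeddings (default) or raw coordinates.
#' @return list with \code{improvementPercent}, \code{fisherObs},
#'   \code{fisherLik} (the mean pairwise ratios) and the per-pair values.
#' @export
separabilityImprovement <- function(obsPoints, likPoints, labels,
                                    embed = TRUE) {
  stopifnot(nrow(obsPoints) == nrow(likPoints),
            nrow(obsPoints) == length(labels))
  labs <- unique(labels)
  stopifnot(length(labs) >= 2L)
  if (embed) {
    obsPoints <- classicalMDS(
      pairwiseDistances(obsPoints, "euclidean", normalize = TRUE))$points
    likPoints <- classicalMDS(
      pairwiseDistances(likPoints, "euclidean", normalize = TRUE))$points
  }
  pairs <- utils::combn(labs, 2L, simplify = FALSE)
  pairFR <- function(pts) vapply(pairs, function(pr)
    fisherRatio(pts[labels == pr[1L], , drop = FALSE],
                pts[labels == pr[2L], , drop = FALSE]), numeric(1))
  frObs <- pairFR(obsPoints)
  frLik <- pairFR(likPoints)
  list(improvementPercent = 100 * (mean(frLik) - mean(frObs)) / mean(frObs),
       fisherObs = mean(frObs), fisherLik = mean(frLik),
       perPairObs = frObs, perPairLik = frLik)
}
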