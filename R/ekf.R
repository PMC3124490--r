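#' State-space configuration for point-process filtering
#'
#' The latent state \eqn{x_k} follows the linear Gaussian system
#' \eqn{x_k = F x_{k-1} + \varepsilon_k}, \eqn{\varepsilon_k \sim N(0, Q)},
#' and drives the conditional intensity through the exponential link
#' \eqn{\lambda_k = \exp(c^\top x_k)} (Hz).  The observation at bin \eqn{k} is
#' the spike count pooled over \eqn{M} repeated trials.
#'
#' @slot transition state-transition matrix \eqn{F} (d x d).
#' @slot stateNoise state-noise covariance \eqn{Q} (d x d), symmetric PSD.
#' @slot x0 initial state mean (length d).
#' @slot S0 initial state covariance (d x d), symmetric PSD.
#' @slot loading link loading \eqn{c} (length d).
#' @slot delta bin width in seconds.
#' @slot nTrials number of pooled trials \eqn{M}.
#' @export
setClass("StateSpaceConfig",
  representation(transition = "matrix", stateNoise = "matrix", x0 = "numeric",
                 S0 = "matrix", loading = "numeric", delta = "numeric",
                 nTrials = "integer"))

setValidity("StateSpaceConfig", function(object) {
  d <- length(object@x0)
  for (nm in c("transition", "stateNoise", "S0")) {
    m <- slot(object, nm)
    if (!all(dim(m) == c(d, d))) return(sprintf("%s must be %d x %d", nm, d, d))
  }
  for (nm in c("stateNoise", "S0")) {
    m <- slot(object, nm)
    if (max(abs(m - t(m))) > 1e-10) return(sprintf("%s must be symmetric", nm))
    if (any(eigen(m, symmetric = TRUE, only.values = TRUE)$values < -1e-10))
      return(sprintf("%s must be positive semidefinite", nm))
  }
  if (length(object@loading) != d) return("loading must have length d")
  if (object@delta <= 0) return("delta must be positive")
  if (object@nTrials < 1L) return("nTrials must be at least 1")
  TRUE
})

#' @param transition,stateNoise,x0,S0,loading,delta,nTrials see slots.  Scalars
#'   are promoted to 1 x 1 matrices, so the common random-walk scalar-state
#'   model is \code{stateSpaceConfig(delta = 1e-3, x0 = log(20))}.
#' @rdname StateSpaceConfig-class
#' @export
stateSpaceConfig <- function(delta, x0 = 0, transition = NULL, stateNoise = NULL,
                             S0 = NULL, loading = NULL, nTrials = 1L) {
  d <- length(x0)
  asM <- function(m, default) {
    if (is.null(m)) m <- default
    if (!is.matrix(m)) m <- diag(as.numeric(m), d)
    m
  }
  new("StateSpaceConfig",
      transition = asM(transition, diag(1, d)),
      stateNoise = asM(stateNoise, diag(1e-5, d)),
      x0 = as.numeric(x0),
      S0 = asM(S0, diag(1, d)),
      loading = if (is.null(loading)) rep(1, d) else as.numeric(loading),
      delta = as.numeric(delta), nTrials = as.integer(nTrials))
}

setMethod("show", "StateSpaceConfig", function(object) {
  cat(sprintf("StateSpaceConfig: d = %d, delta = %g s, M = %d trials, Q[1,1] = %g\n",
              length(object@x0), object@delta, object@nTrials,
              object@stateNoise[1L, 1L]))
})

# lambda * delta kept inside [1e-6, 0.99] so it remains a valid per-bin
# Bernoulli probability even when the state excursion is large
.LAMDELTA_MIN <- 1e-6
.LAMDELTA_MAX <- 0.99

#' Linearised observation model at the predicted state
#'
#' Taylor-expands the expected pooled spike count \eqn{M\lambda\Delta} with
#' \eqn{\lambda = \exp(c^\top x)} about the one-step prediction mean, giving
#' the expected count, its Jacobian in the state, and the observation-noise
#' variance, which is set equal to the expected count (the Poisson-matching
#' choice, valid for small \eqn{\Delta}).
#'
#' @param xPred predicted state mean (length d).
#' @param cfg a [StateSpaceConfig-class].
#' @return list with \code{expected} (\eqn{M\lambda\Delta}), \code{jacobian}
#'   (1 x d), \code{noiseVar} (scalar \eqn{R = M\lambda\Delta}) and
#'   \code{lambda} (Hz).  When the exponential overflows, \eqn{\lambda\Delta}
#'   is clamped with a warning.
#' @export
linearizedObservation <- function(xPred, cfg) {
  stopifnot(is(cfg, "StateSpaceConfig"))
  eta <- sum(cfg@loading * xPred)
  p <- exp(eta) * cfg@delta          # lambda * delta
  if (!is.finite(p) || p > .LAMDELTA_MAX) {
    warning("lambda * delta = ", signif(p, 3),
            " clamped to ", .LAMDELTA_MAX, "; state excursion too large")
    p <- .LAMDELTA_MAX
  }
  if (p < .LAMDELTA_MIN) p <- .LAMDELTA_MIN
  M <- as.numeric(cfg@nTrials)
  list(expected = M * p,
       jacobian = matrix(M * p * cfg@loading, nrow = 1L),
       noiseVar = M * p,
       lambda = p / cfg@delta)
}

#' One recursion of the point-process extended Kalman filter
#'
#' Propagates the posterior through the state equation and updates it with the
#' pooled spike count of one bin: predict
#' \eqn{x_{k|k-1} = F x_{k-1|k-1}}, \eqn{S_{k|k-1} = F S F^\top + Q};
#' innovate \eqn{e_k = \Delta N_k - M\lambda\Delta}; gain
#' \eqn{K = S C^\top (C S C^\top + R)^{-1}}; update
#' \eqn{x_{k|k} = x_{k|k-1} + K e_k} and
#' \eqn{S_{k|k} = (I - KC) S_{k|k-1}} (or the numerically robust Joseph form).
#'
#' @param prev list with \code{x} (posterior mean) and \code{S} (posterior
#'   covariance) from the previous bin; use \code{list(x = cfg@x0, S = cfg@S0)}
#'   to start.
#' @param dN pooled spike count of the bin, in \code{0:nTrials}.
#' @param cfg a [StateSpaceConfig-class].
#' @param joseph use the Joseph-form covariance update.
#' @return list with \code{xPred}, \code{SPred}, \code{x}, \code{S},
#'   \code{innovation}, \code{innovationVar}, \code{gain}, \code{lambda}.
#' @examples
#' cfg <- stateSpaceConfig(delta = 0.1, x0 = 0, stateNoise = 0, S0 = 1)
#' st <- ekfStep(list(x = 0, S = diag(1, 1)), dN = 1, cfg)
#' st$gain      # 0.9091
#' st$x         # 0.8182
#' @export
ekfStep <- function(prev, dN, cfg, joseph = FALSE) {
  stopifnot(is(cfg, "StateSpaceConfig"))
  if (dN < 0 || dN > cfg@nTrials)
    stop("pooled count dN must lie in 0:", cfg@nTrials)
  d <- length(cfg@x0)
  x <- matrix(prev$x, ncol = 1L)
  S <- as.matrix(prev$S)
  Fm <- cfg@transition
  xPred <- Fm %*% x
  SPred <- Fm %*% S %*% t(Fm) + cfg@stateNoise
  SPred <- (SPred + t(SPred)) / 2
  lin <- linearizedObservation(drop(xPred), cfg)
  C <- lin$jacobian                       # 1 x d
  innov <- dN - lin$expected
  Sinn <- drop(C %*% SPred %*% t(C)) + lin$noiseVar
  if (!is.finite(Sinn) || Sinn <= 0)
    stop("singular innovation covariance (", Sinn, ")")
  K <- (SPred %*% t(C)) / Sinn            # d x 1
  xPost <- xPred + K * innov
  IKC <- diag(1, d) - K %*% C
  SPost <- if (joseph)
    IKC %*% SPred %*% t(IKC) + K %*% t(K) * lin$noiseVar
  else
    IKC %*% SPred
  SPost <- (SPost + t(SPost)) / 2
  list(xPred = drop(xPred), SPred = SPred, x = drop(xPost), S = SPost,
       innovation = innov, innovationVar = Sinn, gain = drop(K),
       lambda = lin$lambda)
}

#' Estimate a conditional intensity from repeated trials by EKF
#'
#' Pools the per-bin spike counts of \eqn{M} repeated trials of one stimulus
#' and runs the point-process extended Kalman filter across bins.  The fitted
#' single-trial intensity is \eqn{\hat\lambda_k = \exp(c^\top x_{k|k})}; the
#' pooled expected count \eqn{M\hat\lambda_k\Delta} is only used inside the
#' filter, so the returned rate is on the per-trial (Hz) scale.
#'
#' @param trains list of [BinnedSpikeTrain-class], one per trial, sharing one
#'   bin grid.
#' @param cfg optional [StateSpaceConfig-class].  By default a scalar
#'   random-walk state is used (\eqn{F = 1}, \eqn{Q = 10^{-5}},
#'   \eqn{S_0 = 1}) started at the log overall mean rate (floored at 1 Hz).
#' @param stateNoise convenience override of \eqn{Q} (scalar) when \code{cfg}
#'   is not given.
#' @param joseph use the Joseph-form covariance update throughout.
#' @return an [IntensityModel-class] whose \code{trace} holds the per-bin
#'   filter records (see [filterTrace()]).
#' @examples
#' set.seed(1)
#' tr <- replicate(20, binSpikeTrain(
#'   simulateSpikeTrain(function(t) 20, c(0, 1)), 0.005))
#' fit <- fitIntensity(tr)
#' mean(intensity(fit))   # close to 20 Hz
#' @export
fitIntensity <- function(trains, cfg = NULL, stateNoise = 1e-5,
                         joseph = FALSE) {
  if (is(trains, "BinnedSpikeTrain")) trains <- list(trains)
  stopifnot(length(trains) >= 1L,
            all(vapply(trains, is, logical(1), "BinnedSpikeTrain")))
  ref <- trains[[1L]]
  J <- length(ref@increments)
  for (tr in trains[-1L])
    if (length(tr@increments) != J || abs(tr@delta - ref@delta) > 1e-12 ||
        any(abs(tr@interval - ref@interval) > 1e-9))
      stop("all trials must share one bin grid (same delta, interval, J)")
  M <- length(trains)
  counts <- Reduce(`+`, lapply(trains, function(tr) as.numeric(tr@increments)))
  if (is.null(cfg)) {
    meanRate <- sum(counts) / (M * J * ref@delta)
    cfg <- stateSpaceConfig(delta = ref@delta, x0 = log(max(meanRate, 1)),
                            stateNoise = stateNoise, nTrials = M)
  } else if (cfg@nTrials != M) {
    stop("cfg@nTrials (", cfg@nTrials, ") does not match the number of trials (",
         M, ")")
  }
  d <- length(cfg@x0)
  state <- list(x = cfg@x0, S = cfg@S0)
  xPost <- matrix(NA_real_, J, d)
  rec <- data.frame(bin = seq_len(J), x_pred = NA_real_, x_post = NA_real_,
                    var_post = NA_real_, innovation = NA_real_,
                    gain = NA_real_, lambda_hat = NA_real_)
  lam <- numeric(J)
  for (k in seq_len(J)) {
    st <- ekfStep(state, counts[k], cfg, joseph = joseph)
    state <- list(x = st$x, S = st$S)
    xPost[k, ] <- st$x
    lam[k] <- exp(sum(cfg@loading * st$x))
    rec$x_pred[k] <- st$xPred[1L]
    rec$x_post[k] <- st$x[1L]
    rec$var_post[k] <- st$S[1L, 1L]
    rec$innovation[k] <- st$innovation
    rec$gain[k] <- st$gain[1L]
    rec$lambda_hat[k] <- lam[k]
  }
  lam <- pmin(pmax(lam, .LAMDELTA_MIN / ref@delta), .LAMDELTA_MAX / ref@delta)
  intensityModel(lam, delta = ref@delta, interval = ref@interval,
                 state = xPost, trace = rec)
}
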