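#' RescaledTimes: time-rescaled interspike intervals
#'
#' @slot taus rescaled intervals \eqn{\tau_j = \int_{u_{j-1}}^{u_j}\lambda};
#'   unit-rate exponential under the true intensity.
#' @slot zs \eqn{z_j = 1 - e^{-\tau_j} \in [0,1]}; uniform under the true
#'   intensity.
#' @export
setClass("RescaledTimes",
  representation(taus = "numeric", zs = "numeric"),
  prototype(taus = numeric(0), zs = numeric(0)))

setValidity("RescaledTimes", function(object) {
  if (any(object@taus < 0)) return("rescaled intervals must be nonnegative")
  if (length(object@zs) != length(object@taus))
    return("zs and taus must have equal length")
  if (length(object@zs) && (min(object@zs) < 0 || max(object@zs) > 1))
    return("zs must lie in [0, 1]")
  TRUE
})

setMethod("show", "RescaledTimes", function(object) {
  cat(sprintf("RescaledTimes: %d intervals, mean tau = %.3f (1 expected under the true model)\n",
              length(object@taus),
              if (length(object@taus)) mean(object@taus) else NA_real_))
})

# cumulative integral of a piecewise-constant intensity from t_start to t
.cumIntensity <- function(model, t) {
  t0 <- model@interval[1L]; d <- model@delta
  lam <- model@lambda
  cums <- c(0, cumsum(lam) * d)
  vapply(t, function(tt) {
    full <- floor((tt - t0) / d + 1e-12)
    full <- min(max(full, 0), length(lam))
    part <- if (full < length(lam)) lam[full + 1L] * (tt - t0 - full * d) else 0
    cums[full + 1L] + max(part, 0)
  }, numeric(1))
}

#' Time-rescale a spike train under a candidate intensity
#'
#' By the time-rescaling theorem, the integrals of the true conditional
#' intensity between successive spikes,
#' \eqn{\tau_j = \int_{u_{j-1}}^{u_j} \lambda(t)\,dt} (with \eqn{u_0} the
#' interval start), are independent unit-rate exponential variables; the
#' transform \eqn{z_j = 1 - e^{-\tau_j}} makes them uniform on \eqn{[0,1]}.
#' Departures from uniformity diagnose lack of fit of the intensity model.
#'
#' @param train a [SpikeTrain-class].
#' @param model candidate intensity: a function of time (Hz, integrated by
#'   adaptive quadrature) or a piecewise-constant [IntensityModel-class]
#'   (integrated exactly on its grid).
#' @return a [RescaledTimes-class].
#' @examples
#' rt <- rescaleTimes(spikeTrain(c(1, 2), c(0, 2)), function(t) 2 * t)
#' rt@taus   # (1, 3): integral of 2t over (0,1] and (1,2]
#' @export
rescaleTimes <- function(train, model) {
  stopifnot(is(train, "SpikeTrain"))
  u <- c(train@interval[1L], train@times)
  if (is.function(model)) {
    taus <- vapply(seq_len(length(u) - 1L), function(j)
      stats::integrate(function(t) vapply(t, model, numeric(1)),
                       u[j], u[j + 1L], rel.tol = 1e-9,
                       subdivisions = 500L)$value, numeric(1))
  } else if (is(model, "IntensityModel")) {
    taus <- diff(.cumIntensity(model, u))
  } else stop("model must be a function or an IntensityModel")
  if (length(taus) == 0L) taus <- numeric(0)
  new("RescaledTimes", taus = taus, zs = 1 - exp(-taus))
}

#' Kolmogorov-Smirnov uniformity test with the 95% asymptotic band
#'
#' Computes the KS statistic \eqn{\sup_z |ECDF(z) - z|} of the rescaled-time
#' transforms against the uniform CDF, together with the asymptotic 95%
#' confidence half-width \eqn{1.36 / \sqrt n}; the model passes when the
#' statistic stays inside the band (the KS plot stays within the band around
#' the 45-degree line).
#'
#' @param zs numeric vector in \eqn{[0,1]}, or a [RescaledTimes-class].
#' @return list with \code{statistic}, \code{band} (half-width), \code{pass}
#'   and \code{n}.  At least two rescaled times are required.
#' @export
ksTestUniform <- function(zs) {
  if (is(zs, "RescaledTimes")) zs <- zs@zs
  n <- length(zs)
  if (n < 2L) stop("at least 2 rescaled times are required for the KS test")
  z <- sort(zs)
  i <- seq_len(n)
  stat <- max(i / n - z, z - (i - 1) / n)
  band <- 1.36 / sqrt(n)
  list(statistic = stat, band = band, pass = stat < band, n = n)
}

#' Quantile pairs for a KS plot
#'
#' @param zs numeric vector in \eqn{[0,1]}, or a [RescaledTimes-class].
#' @return data.frame with \code{model_quantile} \eqn{(k - 0.5)/n} and
#'   \code{empirical_quantile} (sorted \code{zs}); a perfect model lies on the
#'   45-degree line.
#' @export
ksPlotData <- function(zs) {
  if (is(zs, "RescaledTimes")) zs <- zs@zs
  n <- length(zs)
  data.frame(model_quantile = (seq_len(n) - 0.5) / n,
             empirical_quantile = sort(zs))
}
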