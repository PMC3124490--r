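# shared fixture builders; everything is generated in code under fixed seeds

# collapse-binning for simulated continuous-time trains, where an occasional
# within-bin coincidence is expected and should not abort a test
sbin <- function(st, delta) {
  suppressWarnings(binSpikeTrain(st, delta, onCollision = "collapse"))
}

# a binned train from an explicit 0/1 vector
binFromIncrements <- function(inc, delta, t0 = 0) {
  new("BinnedSpikeTrain", increments = as.integer(inc), delta = delta,
      interval = c(t0, t0 + length(inc) * delta), truncated = FALSE)
}

# draw a binary observation from a per-bin Bernoulli model
drawBernoulli <- function(model) {
  p <- pmin(intensity(model) * binWidth(model), 1)
  binFromIncrements(stats::runif(length(p)) < p, binWidth(model),
                    observationInterval(model)[1L])
}

# two sinusoidal log-intensity models with identical mean rate but opposite
# temporal phase: the matched-rate, distinct-pattern stimulus pair
phasePairModels <- function(J = 60, T = 0.3, rate = 15, depth = 0.9,
                            freq = 5) {
  delta <- T / J
  tt <- seq(delta / 2, T - delta / 2, by = delta)
  list(intensityModel(exp(log(rate) + depth * sin(2 * pi * freq * tt)),
                      delta = delta),
       intensityModel(exp(log(rate) + depth * sin(2 * pi * freq * tt + pi)),
                      delta = delta))
}

# exact per-stimulus response tables of Bernoulli-bin models by enumeration
# over all 2^J binary outcomes (independent oracle for the information module)
enumerateBernoulli <- function(probList) {
  J <- length(probList[[1L]])
  grid <- as.matrix(expand.grid(rep(list(0:1), J)))
  lapply(probList, function(p)
    apply(grid, 1L, function(x) prod(p^x * (1 - p)^(1 - x))))
}
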