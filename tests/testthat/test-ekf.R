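test_that("linearised observation returns M*lambda*delta, its jacobian, and matched noise", {
  cfg1 <- stateSpaceConfig(delta = 0.1, x0 = 0)
  lin <- linearizedObservation(0, cfg1)
  expect_equal(c(lin$expected, drop(lin$jacobian), lin$noiseVar),
               c(0.1, 0.1, 0.1), tolerance = 1e-12)
  cfg2 <- stateSpaceConfig(delta = 0.001, x0 = 0, nTrials = 50)
  lin2 <- linearizedObservation(log(20), cfg2)
  expect_equal(c(lin2$expected, drop(lin2$jacobian), lin2$noiseVar),
               c(1, 1, 1), tolerance = 1e-12)
  # insensitive observation: zero loading gives a zero jacobian, so no update
  cfg3 <- stateSpaceConfig(delta = 0.1, x0 = 0.3, loading = 0)
  expect_equal(drop(linearizedObservation(0.3, cfg3)$jacobian), 0)
  st <- ekfStep(list(x = 0.3, S = diag(1, 1)), 1, cfg3)
  expect_equal(st$x, 0.3)
})

test_that("one filter step reproduces the hand-worked scalar update", {
  cfg <- stateSpaceConfig(delta = 0.1, x0 = 0, stateNoise = 0, S0 = 1)
  st <- ekfStep(list(x = 0, S = diag(1, 1)), dN = 1, cfg)
  expect_equal(st$innovation, 0.9, tolerance = 1e-10)
  expect_equal(st$innovationVar, 0.11, tolerance = 1e-10)
  expect_equal(st$gain, 0.9091, tolerance = 5e-5)
  expect_equal(st$x, 0.8182, tolerance = 5e-5)
  # no spike: negative innovation pulls the posterior below the prediction
  st0 <- ekfStep(list(x = 0, S = diag(1, 1)), dN = 0, cfg)
  expect_lt(st0$innovation, 0)
  expect_lt(st0$x, st0$xPred)
  expect_error(ekfStep(list(x = 0, S = diag(1, 1)), dN = 2, cfg), "0:1")
})

test_that("covariances stay symmetric and the Joseph form agrees with the standard update", {
  set.seed(21)
  cfg <- stateSpaceConfig(delta = 0.005, x0 = c(log(15), 0),
                          transition = diag(c(1, 0.95)),
                          stateNoise = diag(c(1e-4, 1e-3)),
                          S0 = diag(0.5, 2), loading = c(1, 1), nTrials = 10L)
  stA <- list(x = cfg@x0, S = cfg@S0)
  stB <- stA
  for (k in 1:200) {
    dN <- rbinom(1, 10, 0.1)
    stA <- ekfStep(stA, dN, cfg, joseph = FALSE)
    stB <- ekfStep(stB, dN, cfg, joseph = TRUE)
    expect_lt(max(abs(stA$S - t(stA$S))), 1e-10)
    expect_lt(max(abs(stA$S - stB$S)), 1e-8)
    expect_lt(max(abs(stA$x - stB$x)), 1e-8)
    stA <- list(x = stA$x, S = stA$S)
    stB <- list(x = stB$x, S = stB$S)
  }
})

test_that("filtering matches an exact dense-grid filter on a 3-bin scalar problem", {
  # independent oracle: numerical filtering on a fine state grid with the
  # same Poisson observation model, mode compared at a 0.05 grid resolution
  M <- 50L; delta <- 0.02; Q <- 0.05; S0 <- 0.5; x0 <- log(10)
  y <- c(12, 8, 15)
  cfg <- stateSpaceConfig(delta = delta, x0 = x0, stateNoise = Q, S0 = S0,
                          nTrials = M)
  st <- list(x = x0, S = diag(S0, 1))
  for (k in 1:3) {
    st <- ekfStep(st, y[k], cfg)
    st <- list(x = st$x, S = st$S)
  }
  xs <- seq(x0 - 2, x0 + 2, by = 0.002)
  dens <- dnorm(xs, x0, sqrt(S0 + Q))
  for (k in 1:3) {
    if (k > 1)
      dens <- vapply(xs, function(x) sum(dens * dnorm(x, xs, sqrt(Q))),
                     numeric(1))
    dens <- dens * dpois(y[k], M * exp(xs) * delta)
    dens <- dens / sum(dens)
  }
  expect_lt(abs(st$x - xs[which.max(dens)]), 0.05)
})

test_that("the filter recovers a homogeneous rate and its static limit is the MLE", {
  set.seed(42)
  trains <- lapply(1:50, function(i)
    sbin(simulateSpikeTrain(20, c(0, 1)), 0.001))
  fit <- fitIntensity(trains, stateNoise = 1e-6)
  mle <- sum(vapply(trains, nSpikes, numeric(1))) / 50
  expect_lt(abs(mean(intensity(fit)) - 20) / 20, 0.10)
  # Q = 0, F = I: the filter converges to the constant-rate MLE as J grows
  set.seed(9)
  tr2 <- lapply(1:30, function(i)
    sbin(simulateSpikeTrain(25, c(0, 2)), 0.001))
  cfg <- stateSpaceConfig(delta = 0.001, x0 = log(10), stateNoise = 0,
                          nTrials = 30L)
  f0 <- fitIntensity(tr2, cfg = cfg)
  mle2 <- sum(vapply(tr2, nSpikes, numeric(1))) / (30 * 2)
  lamEnd <- intensity(f0)[length(intensity(f0))]
  expect_lt(abs(lamEnd - mle2) / mle2, 0.10)
})

test_that("sinusoidal intensity dynamics are recovered across 50 trials", {
  set.seed(13)
  lamFun <- function(t) exp(log(20) + sin(2 * pi * 2 * t))
  trains <- lapply(1:50, function(i)
    sbin(simulateSpikeTrain(lamFun, c(0, 2), lambdaMax = 60), 0.001))
  fit <- fitIntensity(trains, stateNoise = 1e-3)
  truth <- lamFun(seq(0.0005, 1.9995, by = 0.001))
  expect_gte(cor(intensity(fit), truth), 0.8)
})

test_that("all-empty observations drive the fitted intensity monotonically down", {
  empty <- replicate(5, binFromIncrements(integer(200), 0.001),
                     simplify = FALSE)
  cfg <- stateSpaceConfig(delta = 0.001, x0 = log(10), stateNoise = 0,
                          nTrials = 5L)
  fit <- fitIntensity(empty, cfg = cfg)
  expect_true(all(diff(intensity(fit)) < 0))
})

test_that("trials on mismatched grids are rejected", {
  a <- binFromIncrements(integer(10), 0.01)
  b <- binFromIncrements(integer(20), 0.01)
  expect_error(fitIntensity(list(a, b)), "share one bin grid")
  cfgBad <- stateSpaceConfig(delta = 0.01, x0 = 0, nTrials = 3L)
  expect_error(fitIntensity(list(a), cfg = cfgBad), "does not match")
})
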