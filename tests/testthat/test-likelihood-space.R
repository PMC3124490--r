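test_that("projection yields P log-likelihood coordinates whatever the bin count", {
  m1 <- intensityModel(10, delta = 0.001, nBins = 1000)
  m2 <- intensityModel(10, delta = 0.001, nBins = 1000)
  m3 <- intensityModel(25, delta = 0.001, nBins = 1000)
  pd <- projectingDistributions(list(a = m1, b = m2, c = m3))
  b <- sbin(simulateSpikeTrain(15, c(0, 1), seed = 2), 0.001)
  lv <- project(b, pd)
  expect_length(lv, 3L)
  expect_named(lv, c("a", "b", "c"))
  # identical models put every observation on the diagonal
  expect_equal(lv[["a"]], lv[["b"]], tolerance = 1e-12)
  # hand value: single spike in bin 2 of a two-bin grid
  mc <- intensityModel(10, delta = 0.1, nBins = 2)
  md <- suppressWarnings(intensityModel(c(5, 10), delta = 0.1))
  pd2 <- projectingDistributions(list(mc, md))
  lv2 <- project(binFromIncrements(c(0, 1), 0.1), pd2)
  expect_equal(unname(lv2), c(log(1) - 2.0, log(1) - 1.5), tolerance = 1e-12)
  # a set of M observations becomes an M x P matrix: dimension reduction for J > P
  obs <- lapply(1:7, function(i) sbin(simulateSpikeTrain(15, c(0, 1)), 0.001))
  mat <- projectSet(obs, pd)
  expect_equal(dim(mat), c(7L, 3L))
  expect_lt(ncol(mat), length(increments(obs[[1]])))
})

test_that("the likelihood-space rule is the unit-slope discriminant with prior offsets", {
  expect_equal(classifyLikelihood(c(-10, -12)), 1L)
  expect_equal(classifyLikelihood(c(-10, -10.5), priors = c(0.25, 0.75)), 2L)
  # exact tie goes to the smallest index
  expect_equal(classifyLikelihood(c(-3, -3)), 1L)
  expect_equal(classifyLikelihood(rbind(c(-1, -2), c(-5, -4), c(0, 0))),
               c(1L, 2L, 1L))
})

test_that("likelihood-space classification agrees exactly with the observation-space Bayes rule", {
  set.seed(7)
  delta <- 0.005; J <- 100
  tt <- seq(delta / 2, 0.5 - delta / 2, by = delta)
  pd <- projectingDistributions(
    list(intensityModel(exp(log(15) + 0.8 * sin(2 * pi * 3 * tt)), delta = delta),
         intensityModel(exp(log(15) + 0.8 * cos(2 * pi * 3 * tt)), delta = delta),
         intensityModel(25, delta = delta, nBins = J)),
    priors = c(0.5, 0.3, 0.2))
  for (form in c("local-poisson", "bernoulli")) {
    agree <- vapply(1:300, function(i) {
      b <- drawBernoulli(pd@models[[sample.int(3, 1)]])
      classifyLikelihood(project(b, pd, form = form), priors = pd@priors) ==
        classifyObservation(b, pd, form = form)
    }, logical(1))
    expect_true(all(agree))
  }
})

test_that("decision regions in the likelihood space are convex", {
  delta <- 0.01
  set.seed(7)
  mods <- lapply(1:3, function(i)
    intensityModel(runif(50, 2, 35), delta = delta))
  pd <- projectingDistributions(mods)
  chk <- decisionRegionConvexityCheck(pd, stimulus = 2, nPairs = 500, seed = 7)
  expect_true(chk$pass)
  expect_equal(chk$fractionInside, 1)
})

test_that("fisher ratio matches exact moments and is affine invariant", {
  set.seed(11)
  mkUnit <- function(n) { x <- rnorm(n); (x - mean(x)) / sd(x) }
  a <- mkUnit(200)               # sample mean 0, variance 1 exactly
  b <- mkUnit(200) + 2           # mean 2, variance 1
  expect_equal(fisherRatio(a, b), 2, tolerance = 1e-12)
  expect_equal(fisherRatio(a, a), 0)
  # scaling all points leaves the ratio unchanged
  X <- matrix(rnorm(300), 150, 2); Y <- matrix(rnorm(300, 1), 150, 2)
  expect_equal(fisherRatio(5 * X, 5 * Y), fisherRatio(X, Y), tolerance = 1e-9)
})

test_that("identical spaces give zero improvement and degraded models lose it", {
  set.seed(5)
  X <- matrix(rnorm(200), 100, 2)
  labs <- rep(c("a", "b"), each = 50)
  X[labs == "b", ] <- X[labs == "b", ] + 1.5
  same <- separabilityImprovement(X, X, labs, embed = FALSE)
  expect_equal(same$improvementPercent, 0, tolerance = 1e-9)

  mods <- phasePairModels()
  pd <- projectingDistributions(mods)
  avg <- intensityModel((intensity(mods[[1]]) + intensity(mods[[2]])) / 2,
                        delta = binWidth(mods[[1]]))
  pdAvg <- projectingDistributions(list(avg, avg))
  obs <- do.call(rbind, lapply(rep(1:2, each = 50), function(s)
    increments(drawBernoulli(mods[[s]]))))
  toB <- function(r) binFromIncrements(r, binWidth(mods[[1]]))
  likTrue <- t(apply(obs, 1, function(r) project(toB(r), pd)))
  likAvg <- t(apply(obs, 1, function(r) project(toB(r), pdAvg)))
  labs2 <- rep(c("a", "b"), each = 50)
  impTrue <- separabilityImprovement(obs, likTrue, labs2)$improvementPercent
  impAvg <- separabilityImprovement(obs, likAvg, labs2)$improvementPercent
  # collapsing the projecting models onto their common average destroys the gain
  expect_gt(impTrue, impAvg)
  expect_gt(impTrue, 0)
})

test_that("held-out classification on well-separated simulated stimuli is accurate", {
  set.seed(17)
  mods <- phasePairModels(rate = 20, depth = 1.2)
  pd <- projectingDistributions(mods)
  acc <- mean(vapply(1:200, function(i) {
    s <- sample.int(2, 1)
    classifyLikelihood(project(drawBernoulli(mods[[s]]), pd)) == s
  }, logical(1)))
  expect_gte(acc, 0.9)
})
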