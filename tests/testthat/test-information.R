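test_that("specific information matches enumeration on small tables", {
  expect_equal(specificInformation(c(0.5, 0.5), c(0.5, 0.5)), 0)
  # two equiprobable stimuli, disjoint deterministic responses: 1 bit
  expect_equal(specificInformation(c(1, 0), c(0.5, 0.5)), 1)
  expect_equal(specificInformation(c(0.75, 0.25), c(0.5, 0.5)),
               0.75 * log2(1.5) + 0.25 * log2(0.5), tolerance = 1e-12)
  expect_equal(specificInformation(c(0.75, 0.25), c(0.5, 0.5)), 0.18872,
               tolerance = 1e-4)
  expect_gte(specificInformation(c(0.1, 0.9), c(0.4, 0.6)), 0)
  expect_error(specificInformation(c(1, 0), c(0, 1)), "support")
})

test_that("mutual information is the prior-weighted mean of specific information", {
  # independent joint
  expect_equal(mutualInformation(outer(c(0.3, 0.7), c(0.2, 0.8))), 0,
               tolerance = 1e-12)
  # deterministic bijection over P uniform stimuli
  expect_equal(mutualInformation(diag(4) / 4), 2)
  j <- rbind(c(0.375, 0.125), c(0.125, 0.375))
  expect_equal(mutualInformation(j), 0.18872, tolerance = 1e-4)
  # consistency on random tables: I(S;R) = E_s[I_ssi] to 1e-10
  set.seed(23)
  for (i in 1:20) {
    joint <- matrix(rexp(12), 3, 4); joint <- joint / sum(joint)
    ps <- rowSums(joint); pr <- colSums(joint)
    bySpecific <- sum(vapply(1:3, function(s)
      ps[s] * specificInformation(joint[s, ] / ps[s], pr), numeric(1)))
    expect_lt(abs(mutualInformation(joint) - bySpecific), 1e-10)
    expect_gte(mutualInformation(joint), 0)
  }
})

test_that("the Monte-Carlo estimator agrees with exact enumeration for toy models", {
  set.seed(11)
  J <- 8; delta <- 0.02
  p1 <- runif(J, 0.05, 0.6); p2 <- runif(J, 0.05, 0.6)
  pd <- projectingDistributions(list(intensityModel(p1 / delta, delta = delta),
                                     intensityModel(p2 / delta, delta = delta)))
  # independent oracle: full probability tables over all 2^J outcomes
  tabs <- enumerateBernoulli(list(p1, p2))
  pbar <- 0.5 * tabs[[1]] + 0.5 * tabs[[2]]
  exact <- sum(tabs[[1]] * log2(tabs[[1]] / pbar))
  obs <- lapply(1:20000, function(i)
    binFromIncrements(runif(J) < p1, delta))
  mc <- specificInformationMC(pd, 1, obs)
  expect_lt(abs(mc$bits - exact), 3 * mc$se)
  # identical models: exactly zero for any sample
  pdSame <- projectingDistributions(list(intensityModel(p1 / delta, delta = delta),
                                         intensityModel(p1 / delta, delta = delta)))
  mc0 <- specificInformationMC(pdSame, 1, obs[1:50])
  expect_equal(mc0$bits, 0, tolerance = 1e-12)
})

test_that("the Monte-Carlo standard error shrinks like one over root sample size", {
  set.seed(19)
  J <- 6; delta <- 0.02
  p1 <- runif(J, 0.1, 0.5); p2 <- runif(J, 0.1, 0.5)
  pd <- projectingDistributions(list(intensityModel(p1 / delta, delta = delta),
                                     intensityModel(p2 / delta, delta = delta)))
  obs <- lapply(1:8000, function(i) binFromIncrements(runif(J) < p1, delta))
  seSmall <- specificInformationMC(pd, 1, obs[1:2000])$se
  seLarge <- specificInformationMC(pd, 1, obs)$se
  expect_equal(seSmall / seLarge, 2, tolerance = 0.35)
})

test_that("stimulus distances are symmetric absolute information differences", {
  expect_equal(stimulusDistance(0.4, 0.4), 0)
  # hand-worked pair: deterministic vs uninformative conditionals
  pbar <- c(0.75, 0.25)
  i1 <- specificInformation(c(1, 0), pbar)
  i2 <- specificInformation(c(0.5, 0.5), pbar)
  expect_equal(i1, log2(4 / 3), tolerance = 1e-12)
  expect_equal(i2, 0.2075, tolerance = 1e-4)
  expect_equal(stimulusDistance(i1, i2), 0.2075, tolerance = 1e-3)
  # matrix form: symmetry, zero diagonal, triangle inequality on random inputs
  set.seed(29)
  for (i in 1:20) {
    info <- runif(5, 0, 2)
    D <- stimulusDistanceMatrix(info)
    expect_equal(D, t(D))
    expect_true(all(diag(D) == 0))
    for (a in 1:5) for (b in 1:5) for (cc in 1:5)
      expect_lte(D[a, b], D[a, cc] + D[cc, b] + 1e-12)
  }
})

test_that("sliding windows count correctly and track an injected rate change", {
  # T = 1000 ms, 100-ms window, 10-ms step: 91 windows
  flat <- lapply(1:30, function(i)
    simulateSpikeTrain(10, c(0, 1), seed = 100 + i))
  byStim <- list(s1 = flat,
                 s2 = lapply(1:30, function(i)
                   simulateSpikeTrain(10, c(0, 1), seed = 200 + i)))
  ts <- slidingWindowInformation(byStim, 1, window = 0.1, step = 0.01,
                                 delta = 0.002)
  expect_equal(nrow(ts), 91L)
  # both stimuli flat and identical in law: little information anywhere
  expect_lt(max(ts$bits_rate), 0.5)
  expect_true(all(ts$bits_rate >= 0))

  # a rate step at 300 ms in stimulus 1 peaks the information after 300 ms
  stepFun <- function(t) ifelse(t > 0.3, 40, 10)
  byStim2 <- list(s1 = lapply(1:30, function(i)
                    simulateSpikeTrain(stepFun, c(0, 1), lambdaMax = 40,
                                       seed = 300 + i)),
                  s2 = flat)
  ts2 <- slidingWindowInformation(byStim2, 1, window = 0.1, step = 0.01,
                                  delta = 0.002)
  expect_gte(ts2$window_center_s[which.max(ts2$bits_likelihood)], 0.3)
  expect_gte(ts2$window_center_s[which.max(ts2$bits_rate)], 0.3)
})
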