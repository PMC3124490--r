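test_that("thinning simulation honours the intensity law", {
  # zero (numerically negligible) intensity gives an empty train
  expect_equal(nSpikes(simulateSpikeTrain(0, c(0, 1), seed = 1)), 0)
  # homogeneous 20 Hz: mean count over 2000 replicates within 3 binomial SEs
  set.seed(12)
  counts <- vapply(1:2000, function(i)
    nSpikes(simulateSpikeTrain(20, c(0, 1))), numeric(1))
  expect_lt(abs(mean(counts) - 20), 3 * sqrt(20 / 2000))
  # Poisson law of counts (chi-square goodness of fit on binned counts)
  br <- c(-0.5, seq(12.5, 27.5, by = 3), Inf)
  obsTab <- table(cut(counts, br))
  pTab <- diff(ppois(c(-1, seq(12, 27, by = 3), Inf), 20))
  expect_gt(suppressWarnings(chisq.test(obsTab, p = pTab)$p.value), 0.001)
  # a violated majorant is detected
  expect_error(simulateSpikeTrain(function(t) 30, c(0, 1), lambdaMax = 10),
               "majorant")
})

test_that("rescaling simulated trains with the generating intensity passes KS at the nominal rate", {
  lamFun <- function(t) 20 + 15 * sin(2 * pi * t)
  set.seed(77)
  pass <- vapply(1:60, function(i) {
    st <- simulateSpikeTrain(lamFun, c(0, 2), lambdaMax = 35)
    ksTestUniform(rescaleTimes(st, lamFun))$pass
  }, logical(1))
  expect_gte(mean(pass), 0.85)   # ~95% nominal, 60 draws
})

test_that("the experiment generator is reproducible and category selective", {
  cfg <- experimentConfig(nStimuli = 4, nCategories = 2,
                          trialsPerStimulus = 12, nNeurons = 3, seed = 5)
  e1 <- simulateExperiment(cfg)
  e2 <- simulateExperiment(cfg)
  expect_identical(e1@spikes, e2@spikes)   # same seed, same dataset
  expect_s4_class(groundTruth(e1, "n001", "s03"), "IntensityModel")
  # trials carry the full trial structure
  trs <- experimentTrains(e1, "n002", "s02")
  expect_length(trs, 12L)
  expect_equal(observationInterval(trs[[1]]), c(0, 1.1))

  # a strongly driven preferred-category stimulus conveys more specific
  # information than a near-baseline one (ground-truth models as projectors)
  tun <- makeTuning(cfg)
  pref <- tun[[1]]$preferred
  prefStim <- which(tun[[1]]$stimCategory == pref)[1]
  nonStim <- which(tun[[1]]$stimCategory != pref)[1]
  stims <- sprintf("s%02d", c(prefStim, nonStim))
  byStim <- lapply(stims, function(s) experimentTrains(e1, "n001", s))
  binned <- lapply(byStim, function(trs) lapply(trs, sbin, delta = 0.001))
  pd <- projectingDistributions(
    lapply(c(prefStim, nonStim), function(s) groundTruth(e1, "n001", s)),
    labels = stims)
  iPref <- specificInformationMC(pd, 1, binned[[1]])$bits
  iNon <- specificInformationMC(pd, 2, binned[[2]])$bits
  expect_gt(iPref, iNon)
})

test_that("zero selectivity leaves the stimuli indistinguishable", {
  cfg <- experimentConfig(nStimuli = 2, nCategories = 2,
                          trialsPerStimulus = 40, nNeurons = 1, seed = 8)
  tun <- makeTuning(cfg, prefGain = 0, nonprefGain = 0, stimJitterSD = 0)
  e <- simulateExperiment(cfg, tuning = tun)
  delta <- 0.005
  binned <- lapply(c("s01", "s02"), function(s)
    lapply(experimentTrains(e, "n001", s), sbin, delta = delta))
  # split trials: fit on the first half, classify the held-out half
  fits <- lapply(binned, function(b) fitIntensity(b[1:20], stateNoise = 1e-4))
  pd <- projectingDistributions(fits)
  pred <- vapply(1:2, function(s) mean(vapply(binned[[s]][21:40], function(b)
    classifyLikelihood(project(b, pd)) == s, logical(1))), numeric(1))
  expect_lt(abs(mean(pred) - 0.5), 0.25)   # chance-level accuracy
})

test_that("marked population simulation matches the superposition law", {
  mods <- list(intensityModel(10, delta = 0.001, nBins = 1000),
               intensityModel(30, delta = 0.001, nBins = 1000))
  pop <- populationIntensity(mods)
  set.seed(2)
  recs <- lapply(1:300, function(i) simulatePopulationMarked(pop))
  allMarks <- unlist(lapply(recs, marks))
  expect_gt(length(allMarks), 1e4)
  # mark-1 fraction converges to lambda_1 / lambda_G = 0.25
  se <- sqrt(0.25 * 0.75 / length(allMarks))
  expect_lt(abs(mean(allMarks == 1L) - 0.25), 4 * se)
  # pooled event count matches the ground-process mean 40 Hz
  totals <- vapply(recs, nSpikes, numeric(1))
  expect_lt(abs(mean(totals) - 40), 4 * sqrt(40 / 300))
  # each extracted neuron passes KS under its own intensity
  big <- simulatePopulationMarked(
    populationIntensity(list(intensityModel(15, delta = 0.001, nBins = 30000),
                             intensityModel(25, delta = 0.001, nBins = 30000))),
    seed = 31)
  for (k in 1:2) {
    rate <- c(15, 25)[k]
    rt <- rescaleTimes(extractNeuron(big, k), function(t) rate)
    expect_true(ksTestUniform(rt)$pass)
  }
})

test_that("marked and independent per-neuron simulation agree in law", {
  mods <- list(intensityModel(12, delta = 0.002, nBins = 500),
               intensityModel(24, delta = 0.002, nBins = 500))
  pop <- populationIntensity(mods)
  set.seed(44)
  nm <- vapply(1:400, function(i) {
    r <- simulatePopulationMarked(pop)
    c(nSpikes(r), sum(marks(r) == 1L))
  }, numeric(2))
  ni <- vapply(1:400, function(i) {
    t1 <- simulateSpikeTrain(mods[[1]]); t2 <- simulateSpikeTrain(mods[[2]])
    c(nSpikes(t1) + nSpikes(t2), nSpikes(t1))
  }, numeric(2))
  # pooled counts and neuron-1 counts: equal means within Monte-Carlo error
  expect_lt(abs(mean(nm[1, ]) - mean(ni[1, ])) /
              sqrt(var(nm[1, ]) / 400 + var(ni[1, ]) / 400), 4)
  expect_lt(abs(mean(nm[2, ]) - mean(ni[2, ])) /
              sqrt(var(nm[2, ]) / 400 + var(ni[2, ]) / 400), 4)
})
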