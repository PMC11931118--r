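test_that("latent pattern: zero amplitude, determinism, zero mean", {
  cfg0 <- latentPatternConfig(amplitude = 0, seed = 3)
  expect_true(all(seriesValues(generateLatentPattern(cfg0)) == 0))

  cfg <- latentPatternConfig(seed = 11)
  a <- generateLatentPattern(cfg)
  b <- generateLatentPattern(cfg)
  expect_identical(seriesValues(a), seriesValues(b))
  expect_lt(abs(mean(seriesValues(a))), 1e-12)
  expect_equal(sqrt(mean(seriesValues(a)^2)), 0.5, tolerance = 1e-12)
  expect_length(seriesValues(a), round(90 * 8.7))
})

test_that("latent spectrum is concentrated below the analysis cutoff", {
  for (seed in 1:5) {
    lat <- generateLatentPattern(latentPatternConfig(seed = seed))
    frac <- powerFractionAbove(seriesValues(lat), fps = 8.7, f0 = 0.08)
    expect_lt(frac, 0.05)
  }
})

test_that("latent config invariants are enforced", {
  expect_error(latentPatternConfig(duration = 0), class = "configError")
  expect_error(latentPatternConfig(bandwidth = 5, fps = 8.7),
               class = "configError")
  expect_error(latentPatternConfig(amplitude = -1), class = "configError")
})

noiseless <- function() noiseConfig(sensorSd = 0, respirationAmp = 0,
                                    cardiacAmp = 0, outlierRate = 0)

test_that("full coupling and no noise make the regions identical", {
  cfg <- syntheticSampleConfig(coupling = 1, eyeNoise = noiseless(),
                               muzzleNoise = noiseless(), seed = 4)
  p <- generatePairedSeries(cfg)
  expect_equal(seriesValues(p$eye) - 36, seriesValues(p$muzzle) - 33,
               tolerance = 1e-12)
})

test_that("paired series are deterministic under a fixed seed", {
  cfg <- syntheticSampleConfig(seed = 9)
  p1 <- generatePairedSeries(cfg)
  p2 <- generatePairedSeries(cfg)
  expect_identical(seriesValues(p1$eye), seriesValues(p2$eye))
  expect_identical(seriesValues(p1$muzzle), seriesValues(p2$muzzle))
  expect_identical(p1$nSpikes, p2$nSpikes)
  expect_gt(sum(p1$nSpikes), 0)   # 1% of 2 x 783 frames makes spikes likely
})

test_that("uncoupled regions give near-zero mean pattern correlation", {
  ## 50-replicate Monte-Carlo oracle: with coupling 0 the conditioned
  ## patterns share nothing; their correlations average to ~0 with standard
  ## error ~ 0.19 / sqrt(50)
  cors <- vapply(1:50, function(i) {
    cfg <- syntheticSampleConfig(coupling = 0, seed = 1000 + i)
    p <- generatePairedSeries(cfg)
    e <- conditionSeries(p$eye)
    m <- conditionSeries(p$muzzle)
    pr <- alignPair(e, m)
    cor(pr@v1, pr@v2)
  }, numeric(1L))
  expect_lt(abs(mean(cors)), 0.1)
})

test_that("expected pattern similarity is non-decreasing in coupling", {
  meanCos <- vapply(c(0, 0.5, 1), function(cp) {
    mean(vapply(1:12, function(i) {
      cfg <- syntheticSampleConfig(coupling = cp, seed = 2000 + i)
      p <- generatePairedSeries(cfg)
      pr <- alignPair(conditionSeries(p$eye), conditionSeries(p$muzzle))
      cosineSimilarity(pr)
    }, numeric(1L)))
  }, numeric(1L))
  expect_true(all(diff(meanCos) > 0))
})

test_that("dropout frames appear as missing values at the configured rate", {
  cfg <- syntheticSampleConfig(
    eyeNoise = noiseConfig(dropoutRate = 0.2),
    muzzleNoise = noiseConfig(dropoutRate = 0), seed = 6)
  p <- generatePairedSeries(cfg)
  nmiss <- sum(is.na(seriesValues(p$eye)))
  expect_gt(nmiss, 0)
  ## binomial(783, 0.2): stay within 5 sd of the mean
  expect_lt(abs(nmiss - 783 * 0.2), 5 * sqrt(783 * 0.2 * 0.8))
  expect_false(anyNA(seriesValues(p$muzzle)))
})

test_that("noiseless render + extraction round-trips the series exactly", {
  cfg <- syntheticSampleConfig(
    latent = latentPatternConfig(duration = 10, seed = 5),
    eyeNoise = noiseless(), muzzleNoise = noiseless(), seed = 5)
  p <- generatePairedSeries(cfg)
  r <- renderFrameSequence(p$eye, p$muzzle, frameGeometry())
  for (lab in c("eye", "muzzle")) {
    got <- extractMeanTemperature(r$frames, r$track, lab)
    expect_equal(seriesValues(got), seriesValues(p[[lab]]), tolerance = 1e-12)
  }
})

test_that("rendered frames have the camera geometry (60 rows x 80 cols)", {
  cfg <- syntheticSampleConfig(latent = latentPatternConfig(duration = 3,
                                                            seed = 2),
                               seed = 2)
  p <- generatePairedSeries(cfg)
  r <- renderFrameSequence(p$eye, p$muzzle, frameGeometry())
  expect_identical(frameDim(r$frames), c(60L, 80L))
  expect_identical(nFrames(r$frames), length(p$eye))
})

test_that("eye-detection failure renders a track that reads background", {
  cfg <- syntheticSampleConfig(
    latent = latentPatternConfig(duration = 10, seed = 7),
    eyeNoise = noiseless(), muzzleNoise = noiseless(), seed = 7)
  p <- generatePairedSeries(cfg)
  r <- renderFrameSequence(p$eye, p$muzzle, frameGeometry(),
                           failureMode = "eye_detection_failure")
  got <- extractMeanTemperature(r$frames, r$track, "eye")
  expect_true(all(abs(seriesValues(got) - 20) < 1e-9))
  ## the muzzle is unaffected
  gm <- extractMeanTemperature(r$frames, r$track, "muzzle")
  expect_equal(seriesValues(gm), seriesValues(p$muzzle), tolerance = 1e-12)
})

test_that("sideways-muzzle mode shrinks the detected muzzle to <= 10% area", {
  cfg <- syntheticSampleConfig(
    latent = latentPatternConfig(duration = 3, seed = 8), seed = 8)
  p <- generatePairedSeries(cfg)
  geom <- frameGeometry()
  r <- renderFrameSequence(p$eye, p$muzzle, geom,
                           failureMode = "sideways_muzzle")
  det <- r$track@polygons$muzzle[[1L]]
  expect_lte(shoelaceArea(det), 0.1 * shoelaceArea(geom$muzzlePolygon) + 1e-9)
})

test_that("cohorts are reproducible and honour failure-mode counts", {
  c1 <- generateCohort(33, seed = 42)
  expect_length(c1, 33)
  c2 <- generateCohort(33, seed = 42)
  expect_identical(
    lapply(c1, function(s) seriesValues(s$eye)),
    lapply(c2, function(s) seriesValues(s$eye)))

  c3 <- generateCohort(33, seed = 42,
                       failureModes = c(eye_detection_failure = 4))
  modes <- vapply(c3, function(s) s$failureMode, character(1L))
  expect_identical(sum(modes == "eye_detection_failure"), 4L)
  ## mode assignment must not perturb the other samples' draws
  expect_identical(seriesValues(c3[[1L]]$muzzle),
                   seriesValues(c1[[1L]]$muzzle))
})
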