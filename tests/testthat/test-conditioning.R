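test_that("Tukey fences reproduce the worked hinge example", {
  f <- computeTukeyFences(c(1:9, 100), g = 1.5)
  expect_equal(f$q1, 3)
  expect_equal(f$q3, 8)
  expect_equal(f$lower, -4.5)
  expect_equal(f$upper, 15.5)
  h <- bruteHinges(c(1:9, 100))
  expect_equal(c(f$q1, f$q3), unname(h))
})

test_that("hinges match the brute-force median-of-halves oracle", {
  set.seed(31)
  for (n in 4:8) {
    for (rep in 1:20) {
      v <- round(rnorm(n, sd = 5), 2)
      f <- computeTukeyFences(v, g = 1.5)
      h <- bruteHinges(v)
      expect_equal(f$q1, unname(h["q1"]))
      expect_equal(f$q3, unname(h["q3"]))
      ## hinge computation must be permutation-invariant
      f2 <- computeTukeyFences(sample(v), g = 1.5)
      expect_equal(f2$lower, f$lower)
      expect_equal(f2$upper, f$upper)
    }
  }
})

test_that("fences collapse on zero spread and reject degenerate input", {
  f <- computeTukeyFences(rep(7, 10))
  expect_equal(c(f$lower, f$upper), c(7, 7))
  expect_error(computeTukeyFences(c(1, 2, 3)),
               class = "degenerateInputError")
  expect_error(computeTukeyFences(c(1, 2, 3, NA, NA)),
               class = "degenerateInputError")
})

test_that("outlier rejection removes exactly the out-of-fence values", {
  out <- rejectOutliers(c(1:9, 100), g = 1.5)
  expect_identical(out$report$n_rejected, 1L)
  expect_identical(out$report$rejected, 10L)
  expect_identical(out$report$n_retained, 9L)
  expect_true(is.na(out$series[10L]))
  expect_identical(out$series[1:9], as.numeric(1:9))

  ## conservation: rejected + retained + already-missing = input
  s <- TemperatureSeries(c(NA, 1:9, 100, NA), fps = 1)
  out2 <- rejectOutliers(s)
  rep2 <- out2$report
  expect_identical(rep2$n_rejected + rep2$n_retained + rep2$n_missing_input,
                   rep2$n_input)

  within <- rejectOutliers(c(5, 6, 7, 8, 9))
  expect_identical(within$report$n_rejected, 0L)
  expect_identical(within$series, c(5, 6, 7, 8, 9))

  flat <- rejectOutliers(rep(3, 6))
  expect_identical(flat$report$n_rejected, 0L)
})

test_that("standardization is a z-score with n-1 sd and is idempotent", {
  expect_equal(standardizeSeries(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(8)
  x <- rnorm(50, mean = 33, sd = 2)
  x[c(3, 17)] <- NA
  z <- standardizeSeries(x)
  expect_equal(standardizeSeries(z), z)
  expect_equal(mean(z, na.rm = TRUE), 0)
  expect_equal(sd(z, na.rm = TRUE), 1)
  expect_identical(which(is.na(z)), c(3L, 17L))
  expect_error(standardizeSeries(rep(4, 10)), class = "degenerateInputError")
})

test_that("regridding interpolates interior gaps and trims the edges", {
  s <- TemperatureSeries(c(1, NA, 3), times = c(0, 1, 2), fps = 1)
  u <- regridSeries(s, fps = 1)
  expect_equal(seriesValues(u), c(1, 2, 3))

  gapless <- TemperatureSeries(c(2, 4, 6, 8), fps = 2)
  expect_equal(seriesValues(regridSeries(gapless, fps = 2)),
               c(2, 4, 6, 8))

  lead <- TemperatureSeries(c(NA, NA, NA, 5, 6, 7, 8), fps = 1)
  u2 <- regridSeries(lead, fps = 1)
  expect_length(seriesValues(u2), 4L)
  expect_equal(seriesTimes(u2)[1L], 3)

  expect_error(regridSeries(TemperatureSeries(c(NA, NA, 1), fps = 1)),
               class = "degenerateInputError")
})

test_that("low-pass filter matches the analytic Butterworth response", {
  fps <- 8.7; n <- round(90 * fps)
  t <- (seq_len(n) - 1L) / fps
  trim <- seq(round(15 * fps), n - round(15 * fps))   # drop edge transients
  rms <- function(x) sqrt(mean(x^2))

  ## passband: 0.01 Hz passes within 5%
  x <- sin(2 * pi * 0.01 * t)
  expect_equal(rms(lowpassFilter(x)[trim]) / rms(x[trim]),
               butterworthGain(0.01), tolerance = 0.05)

  ## transition band: measurable attenuation, still within 5% of analytic
  x <- sin(2 * pi * 0.12 * t)
  expect_equal(rms(lowpassFilter(x)[trim]) / rms(x[trim]),
               butterworthGain(0.12), tolerance = 0.05)

  ## stopband: a 0.5 Hz tone is attenuated essentially to zero
  x <- sin(2 * pi * 0.5 * t)
  expect_lt(rms(lowpassFilter(x)[trim]) / rms(x[trim]), 0.05)
  expect_lt(rms(lowpassFilter(x)[trim]) / rms(x[trim]),
            butterworthGain(0.5) + 0.005)
})

test_that("low-pass filter passes constants and is linear", {
  expect_lt(max(abs(lowpassFilter(rep(3.3, 200)) - 3.3)), 1e-9)
  set.seed(12)
  x <- rnorm(300); y <- rnorm(300)
  lhs <- lowpassFilter(2.5 * x - 1.3 * y)
  rhs <- 2.5 * lowpassFilter(x) - 1.3 * lowpassFilter(y)
  expect_lt(max(abs(lhs - rhs)), 1e-8)
})

test_that("low-pass filter rejects too-short or gapped input", {
  expect_error(lowpassFilter(rnorm(10)), class = "degenerateInputError")
  expect_error(lowpassFilter(c(rnorm(50), NA)), class = "inputError")
  expect_error(lowpassFilter(rnorm(50), cutoffHz = 5, fps = 8.7),
               class = "configError")
})

test_that("conditioning a smooth noiseless series is near-identity", {
  s <- smoothSeries()
  pat <- conditionSeries(s)
  ref <- standardizeSeries(seriesValues(s))
  expect_lt(max(abs(seriesValues(pat) - ref)), 0.05)
  expect_identical(length(pat), length(s))
})

test_that("conditioning removes injected spikes", {
  s <- smoothSeries()
  clean <- conditionSeries(s)
  spiked <- seriesValues(s)
  set.seed(21)
  hit <- runif(length(spiked)) < 0.01
  spiked[hit] <- spiked[hit] + 5
  pat <- conditionSeries(TemperatureSeries(spiked, fps = 8.7))
  expect_identical(pat@report$n_rejected, sum(hit))
  expect_lt(max(abs(seriesValues(pat))), max(abs(seriesValues(clean))) + 0.1)
})

test_that("conditioning errors on constants and names the failing stage", {
  err <- tryCatch(conditionSeries(TemperatureSeries(rep(36, 100), fps = 8.7)),
                  degenerateInputError = function(e) e)
  expect_s3_class(err, "degenerateInputError")
  expect_match(conditionMessage(err), "standardize")
})

test_that("conditioned patterns are invariant to affine degC transforms", {
  set.seed(33)
  raw <- 36 + cumsum(rnorm(500, sd = 0.05))
  a <- conditionSeries(TemperatureSeries(raw, fps = 8.7))
  b <- conditionSeries(TemperatureSeries(1.8 * raw + 32, fps = 8.7))
  expect_lt(max(abs(seriesValues(a) - seriesValues(b))), 1e-6)
})

test_that("pattern energy above twice the cutoff is under 1%", {
  set.seed(44)
  for (rep in 1:3) {
    s <- TemperatureSeries(36 + rnorm(783, sd = 0.5), fps = 8.7)
    pat <- conditionSeries(s)
    frac <- powerFractionAbove(seriesValues(pat), fps = 8.7, f0 = 2 * 0.08)
    expect_lt(frac, 0.01)
  }
})

test_that("both stage orders yield patterns with cosine ~ 1 to each other", {
  set.seed(55)
  s <- TemperatureSeries(36 + cumsum(rnorm(600, sd = 0.05)) +
                           rnorm(600, sd = 0.07), fps = 8.7)
  a <- conditionSeries(s, stageOrder = "standardize_first")
  b <- conditionSeries(s, stageOrder = "filter_first")
  expect_gt(cosineSimilarity(seriesValues(a), seriesValues(b)), 0.99)
})
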