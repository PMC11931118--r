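#' Configuration for the shared latent temperature pattern
#'
#' The latent pattern stands in for the slow physiological drift a thermal
#' window shows over a 1-2 minute recording. It is generated as Gaussian
#' white noise low-pass filtered at `bandwidth` (strictly below the 0.08 Hz
#' analysis cutoff, so the analysis pipeline preserves it), centred to zero
#' mean and rescaled to `amplitude` RMS.
#'
#' @param duration Recording length in seconds (default 90).
#' @param fps Frame rate in frames/second (default 8.7).
#' @param bandwidth Latent bandwidth in Hz (default 0.05).
#' @param amplitude RMS amplitude in degrees Celsius (default 0.5).
#' @param seed Integer seed or `NULL`.
#' @return A validated list of class `LatentPatternConfig`.
#' @export
latentPatternConfig <- function(duration = 90, fps = 8.7, bandwidth = 0.05,
                                amplitude = 0.5, seed = NULL) {
  .checkNumber(duration, "duration", lower = 0, strict_lower = TRUE)
  .checkNumber(fps, "fps", lower = 0, strict_lower = TRUE)
  .checkNumber(bandwidth, "bandwidth", lower = 0, strict_lower = TRUE)
  if (bandwidth >= fps / 2)
    configError("bandwidth (%g Hz) must be below the Nyquist rate %g Hz",
                bandwidth, fps / 2)
  .checkNumber(amplitude, "amplitude", lower = 0)
  structure(list(duration = duration, fps = fps, bandwidth = bandwidth,
                 amplitude = amplitude, seed = seed),
            class = "LatentPatternConfig")
}

#' Noise configuration for one region's synthetic series
#'
#' Models the contaminants of a field thermal recording: sensor noise at the
#' camera's stated sensitivity (0.07 degC), respiration and cardiac
#' oscillations, sporadic outlier spikes (frame artefacts, wind), and
#' detection dropouts.
#'
#' @param sensorSd Per-frame sensor noise sd in degC (default 0.07).
#' @param respirationFreq Respiration frequency in Hz (default 0.5).
#' @param respirationAmp Respiration amplitude in degC (default 0.3; used on
#'   the muzzle — pass 0 for the eye).
#' @param cardiacFreq Cardiac frequency in Hz (default 1.5).
#' @param cardiacAmp Cardiac amplitude in degC (default 0.05).
#' @param outlierRate Per-frame spike probability (default 0.01).
#' @param outlierMagnitude Spike magnitude in degC (default 5).
#' @param dropoutRate Per-frame probability of a missed detection
#'   (default 0).
#' @return A validated list of class `NoiseConfig`.
#' @export
noiseConfig <- function(sensorSd = 0.07, respirationFreq = 0.5,
                        respirationAmp = 0.3, cardiacFreq = 1.5,
                        cardiacAmp = 0.05, outlierRate = 0.01,
                        outlierMagnitude = 5, dropoutRate = 0) {
  .checkNumber(sensorSd, "sensorSd", lower = 0)
  .checkNumber(respirationFreq, "respirationFreq", lower = 0)
  .checkNumber(respirationAmp, "respirationAmp", lower = 0)
  .checkNumber(cardiacFreq, "cardiacFreq", lower = 0)
  .checkNumber(cardiacAmp, "cardiacAmp", lower = 0)
  .checkNumber(outlierRate, "outlierRate", lower = 0, upper = 1)
  .checkNumber(outlierMagnitude, "outlierMagnitude", lower = 0)
  .checkNumber(dropoutRate, "dropoutRate", lower = 0, upper = 1)
  structure(list(sensorSd = sensorSd, respirationFreq = respirationFreq,
                 respirationAmp = respirationAmp, cardiacFreq = cardiacFreq,
                 cardiacAmp = cardiacAmp, outlierRate = outlierRate,
                 outlierMagnitude = outlierMagnitude,
                 dropoutRate = dropoutRate),
            class = "NoiseConfig")
}

#' Configuration for one synthetic eye/muzzle sample
#'
#' `coupling` is the fraction of each region's slow variance carried by the
#' shared latent pattern: both regions are
#' `baseline + sqrt(coupling) * latent + sqrt(1 - coupling) * own smooth
#' process + noise`, so it is the single knob that sets how similar the two
#' conditioned patterns are expected to be.
#'
#' Failure modes emulate the field recordings that broke the real analysis:
#' `"eye_detection_failure"` — the detected "eye" region sits on inert
#' background, so its series carries only sensor noise and no physiological
#' signal; `"sideways_muzzle"` — the head is turned, the visible muzzle is
#' small and nostril-dominated, so the muzzle's latent share is cut (to
#' `0.2 * coupling / 0.9`-equivalent, fixed at 0.2) and its respiration
#' amplitude is multiplied by 5.
#'
#' @param latent A [latentPatternConfig()].
#' @param eyeNoise,muzzleNoise [noiseConfig()]s; the eye default has no
#'   respiration component.
#' @param coupling Shared-variance fraction in `[0, 1]` (default 0.9).
#' @param failureMode `"none"`, `"eye_detection_failure"` or
#'   `"sideways_muzzle"`.
#' @param baselineEye,baselineMuzzle Baseline temperatures in degC
#'   (defaults 36 and 33).
#' @param backgroundTemp Background (ambient) temperature in degC
#'   (default 20), the level a mislocated ROI reads.
#' @param seed Integer seed or `NULL`.
#' @return A validated list of class `SyntheticSampleConfig`.
#' @export
syntheticSampleConfig <- function(latent = latentPatternConfig(),
                                  eyeNoise = noiseConfig(respirationAmp = 0),
                                  muzzleNoise = noiseConfig(),
                                  coupling = 0.9,
                                  failureMode = c("none",
                                                  "eye_detection_failure",
                                                  "sideways_muzzle"),
                                  baselineEye = 36, baselineMuzzle = 33,
                                  backgroundTemp = 20, seed = NULL) {
  failureMode <- match.arg(failureMode)
  stopifnot(inherits(latent, "LatentPatternConfig"),
            inherits(eyeNoise, "NoiseConfig"),
            inherits(muzzleNoise, "NoiseConfig"))
  .checkNumber(coupling, "coupling", lower = 0, upper = 1)
  .checkNumber(baselineEye, "baselineEye")
  .checkNumber(baselineMuzzle, "baselineMuzzle")
  .checkNumber(backgroundTemp, "backgroundTemp")
  structure(list(latent = latent, eyeNoise = eyeNoise,
                 muzzleNoise = muzzleNoise, coupling = coupling,
                 failureMode = failureMode, baselineEye = baselineEye,
                 baselineMuzzle = baselineMuzzle,
                 backgroundTemp = backgroundTemp, seed = seed),
            class = "SyntheticSampleConfig")
}

## latent share of muzzle variance in sideways mode; the small, partly
## off-window ROI is dominated by nostril airflow and independent drift
.SIDEWAYS_COUPLING <- 0.2
.SIDEWAYS_RESP_FACTOR <- 5

#' Generate a smooth low-frequency latent pattern
#'
#' White Gaussian noise, zero-phase low-pass filtered at `cfg$bandwidth`,
#' centred to zero mean and rescaled to `cfg$amplitude` RMS. By
#' construction its spectral power is concentrated below the bandwidth,
#' hence below the 0.08 Hz analysis cutoff for the default 0.05 Hz.
#'
#' @param cfg A [latentPatternConfig()].
#' @return A [TemperatureSeries-class] labelled `"latent"`, zero mean,
#'   length `round(duration * fps)`.
#' @export
#' @examples
#' lat <- generateLatentPattern(latentPatternConfig(seed = 1))
#' abs(mean(seriesValues(lat))) < 1e-12
generateLatentPattern <- function(cfg) {
  stopifnot(inherits(cfg, "LatentPatternConfig"))
  n <- round(cfg$duration * cfg$fps)
  if (n < 16L)
    configError("duration x fps = %d frames is too short for a latent pattern", n)
  vals <- withSeed(cfg$seed, {
    w <- rnorm(n)
    x <- lowpassFilter(w, cutoffHz = cfg$bandwidth, fps = cfg$fps)
    x <- x - mean(x)
    rms <- sqrt(mean(x^2))
    if (cfg$amplitude == 0 || rms == 0) rep(0, n)
    else x * (cfg$amplitude / rms)
  })
  TemperatureSeries(vals, fps = cfg$fps, label = "latent",
                    sampleId = "latent")
}

.regionSeries <- function(latent, noise, baseline, couplingShare,
                          amplitude, bandwidth, fps, seed) {
  n <- length(latent)
  t <- (seq_len(n) - 1L) / fps
  withSeed(seed, {
    own <- if (couplingShare < 1) {
      w <- lowpassFilter(rnorm(n), cutoffHz = bandwidth, fps = fps)
      w <- w - mean(w)
      r <- sqrt(mean(w^2))
      if (r == 0 || amplitude == 0) rep(0, n) else w * (amplitude / r)
    } else rep(0, n)
    ## fixed-frequency sinusoids with random phase; respiration gets a mild
    ## random-walk phase drift so it is not perfectly periodic
    phiR <- runif(1L, 0, 2 * pi)
    drift <- cumsum(rnorm(n, sd = 0.02))
    resp <- noise$respirationAmp *
      sin(2 * pi * noise$respirationFreq * t + phiR + drift)
    phiC <- runif(1L, 0, 2 * pi)
    card <- noise$cardiacAmp * sin(2 * pi * noise$cardiacFreq * t + phiC)
    v <- baseline + sqrt(couplingShare) * latent +
      sqrt(1 - couplingShare) * own + resp + card +
      rnorm(n, sd = noise$sensorSd)
    spike <- runif(n) < noise$outlierRate
    v[spike] <- v[spike] +
      sample(c(-1, 1), sum(spike), replace = TRUE) * noise$outlierMagnitude
    v[runif(n) < noise$dropoutRate] <- NA_real_
    list(values = v, n_spikes = sum(spike))
  })
}

#' Generate a paired eye/muzzle synthetic recording
#'
#' Both regions share one latent realization (weight `sqrt(coupling)`) plus
#' their own independent smooth process (weight `sqrt(1 - coupling)`),
#' sensor noise and a cardiac oscillation; the muzzle additionally carries a
#' respiration oscillation. Outlier spikes and detection dropouts are
#' injected at the configured per-frame rates. Failure modes are applied at
#' the series level (see [syntheticSampleConfig()]); frame-level rendering
#' applies the corresponding geometric distortions.
#'
#' @param cfg A [syntheticSampleConfig()].
#' @param sampleId Identifier stamped on both series.
#' @return A list with elements `eye` and `muzzle`
#'   ([TemperatureSeries-class]), `latent`, `failureMode` and `nSpikes`
#'   (named count of injected spikes per region).
#' @export
#' @examples
#' p <- generatePairedSeries(syntheticSampleConfig(seed = 1))
#' p$eye
generatePairedSeries <- function(cfg, sampleId = "sample") {
  stopifnot(inherits(cfg, "SyntheticSampleConfig"))
  lat <- cfg$latent
  if (is.null(lat$seed) && !is.null(cfg$seed))
    lat <- latentPatternConfig(lat$duration, lat$fps, lat$bandwidth,
                               lat$amplitude, seed = deriveSeed(cfg$seed, 1L))
  latent <- generateLatentPattern(lat)
  lv <- latent@values
  fps <- lat$fps
  eyeCoupling <- cfg$coupling
  muzzleCoupling <- cfg$coupling
  muzzleNoise <- cfg$muzzleNoise
  if (cfg$failureMode == "sideways_muzzle") {
    muzzleCoupling <- min(cfg$coupling, .SIDEWAYS_COUPLING)
    muzzleNoise$respirationAmp <-
      muzzleNoise$respirationAmp * .SIDEWAYS_RESP_FACTOR
  }
  eye <- .regionSeries(lv, cfg$eyeNoise, cfg$baselineEye, eyeCoupling,
                       lat$amplitude, lat$bandwidth, fps,
                       seed = deriveSeed(cfg$seed, 2L))
  if (cfg$failureMode == "eye_detection_failure") {
    ## the detected "eye" sits on inert background: sensor noise only
    n <- length(lv)
    eye <- withSeed(deriveSeed(cfg$seed, 4L), {
      v <- cfg$backgroundTemp + rnorm(n, sd = cfg$eyeNoise$sensorSd)
      v[runif(n) < cfg$eyeNoise$dropoutRate] <- NA_real_
      list(values = v, n_spikes = 0L)
    })
  }
  muzzle <- .regionSeries(lv, muzzleNoise, cfg$baselineMuzzle,
                          muzzleCoupling, lat$amplitude, lat$bandwidth, fps,
                          seed = deriveSeed(cfg$seed, 3L))
  list(eye = TemperatureSeries(eye$values, fps = fps, label = "eye",
                               sampleId = sampleId),
       muzzle = TemperatureSeries(muzzle$values, fps = fps,
                                  label = "muzzle", sampleId = sampleId),
       latent = latent, failureMode = cfg$failureMode,
       nSpikes = c(eye = eye$n_spikes, muzzle = muzzle$n_spikes))
}

#' Frame geometry for synthetic rendering
#'
#' Default geometry matches a small mobile thermal camera: 80 x 60 pixels.
#' Polygons are vertex matrices in pixel coordinates (0-based, origin
#' top-left, x = column, y = row).
#'
#' @param width,height Frame size in pixels (defaults 80 x 60).
#' @param backgroundTemp Background temperature in degC (default 20).
#' @param eyePolygon,muzzlePolygon Two-column vertex matrices; defaults are
#'   an octagonal "eye" (radius 6 px around (20, 20)) and a larger octagonal
#'   "muzzle" (radius 12 px around (55, 35)).
#' @return A validated list of class `FrameGeometry`.
#' @export
frameGeometry <- function(width = 80, height = 60, backgroundTemp = 20,
                          eyePolygon = .regularPolygon(20, 20, 6),
                          muzzlePolygon = .regularPolygon(55, 35, 12)) {
  .checkNumber(width, "width", lower = 1)
  .checkNumber(height, "height", lower = 1)
  stopifnot(is.matrix(eyePolygon), ncol(eyePolygon) == 2L,
            is.matrix(muzzlePolygon), ncol(muzzlePolygon) == 2L)
  structure(list(width = as.integer(width), height = as.integer(height),
                 backgroundTemp = backgroundTemp, eyePolygon = eyePolygon,
                 muzzlePolygon = muzzlePolygon),
            class = "FrameGeometry")
}

.regularPolygon <- function(cx, cy, r, k = 8L) {
  a <- 2 * pi * (seq_len(k) - 1L) / k
  cbind(x = cx + r * cos(a), y = cy + r * sin(a))
}

.shrinkPolygon <- function(poly, areaFactor) {
  c0 <- colMeans(poly)
  sweep(sweep(poly, 2L, c0) * sqrt(areaFactor), 2L, c0, "+")
}

#' Render a paired sample as a thermal frame sequence
#'
#' Each frame is `backgroundTemp` everywhere except the two region
#' interiors, which are set to that frame's region temperature plus
#' independent per-pixel sensor noise. The returned [RoiTrack-class] holds
#' the *detected* polygons per frame (absent on dropout frames):
#' `"eye_detection_failure"` relocates the eye polygon onto background for
#' all frames, and `"sideways_muzzle"` shrinks the muzzle polygon to 10% of
#' its area, so extraction through the track reproduces the corresponding
#' failure behaviour.
#'
#' @param eye,muzzle [TemperatureSeries-class] of equal length (as from
#'   [generatePairedSeries()]; `NA` frames become dropout frames).
#' @param geom A [frameGeometry()].
#' @param failureMode `"none"`, `"eye_detection_failure"` or
#'   `"sideways_muzzle"`.
#' @param pixelNoiseSd Per-pixel sensor noise sd in degC (default 0; the
#'   series already carry frame-level sensor noise).
#' @param seed Integer seed for per-pixel noise, or `NULL`.
#' @return A list with elements `frames` ([ThermalFrameSequence-class]) and
#'   `track` ([RoiTrack-class], provenance `"synthetic"`).
#' @export
renderFrameSequence <- function(eye, muzzle, geom = frameGeometry(),
                                failureMode = c("none",
                                                "eye_detection_failure",
                                                "sideways_muzzle"),
                                pixelNoiseSd = 0, seed = NULL) {
  failureMode <- match.arg(failureMode)
  stopifnot(is(eye, "TemperatureSeries"), is(muzzle, "TemperatureSeries"),
            inherits(geom, "FrameGeometry"))
  if (length(eye) != length(muzzle))
    inputError("eye and muzzle series must have equal length (%d vs %d)",
               length(eye), length(muzzle))
  n <- length(eye)
  trueEye <- geom$eyePolygon
  trueMuzzle <- geom$muzzlePolygon
  detEye <- trueEye
  detMuzzle <- trueMuzzle
  if (failureMode == "eye_detection_failure") {
    ## detector latches onto featureless background near the frame corner
    r <- 4
    detEye <- .regularPolygon(geom$width - r - 2, geom$height - r - 2, r)
  }
  if (failureMode == "sideways_muzzle")
    detMuzzle <- .shrinkPolygon(trueMuzzle, 0.1)
  eyeMask <- rasterizePolygon(trueEye, geom$width, geom$height)
  muzMask <- rasterizePolygon(trueMuzzle, geom$width, geom$height)
  ev <- eye@values; mv <- muzzle@values
  frames <- withSeed(seed, lapply(seq_len(n), function(i) {
    f <- matrix(geom$backgroundTemp, nrow = geom$height, ncol = geom$width)
    if (!is.na(ev[i])) f[eyeMask] <- ev[i]
    if (!is.na(mv[i])) f[muzMask] <- mv[i]
    if (pixelNoiseSd > 0)
      f <- f + matrix(rnorm(length(f), sd = pixelNoiseSd), nrow(f), ncol(f))
    f
  }))
  polyOrNull <- function(p, present)
    lapply(seq_len(n), function(i) if (present[i]) p else NULL)
  track <- RoiTrack(
    nFrames = n,
    polygons = list(eye = polyOrNull(detEye, !is.na(ev)),
                    muzzle = polyOrNull(detMuzzle, !is.na(mv))),
    provenance = "synthetic")
  list(frames = ThermalFrameSequence(frames, times = eye@times,
                                     fps = 1 / median(diff(eye@times))),
       track = track)
}

#' Generate a reproducible cohort of synthetic samples
#'
#' Draws `nSamples` independent samples from `baseCfg`, with per-sample
#' seeds spawned deterministically from the master seed by a fixed counter
#' scheme ([deriveSeed()]). Failure modes can be assigned deterministically:
#' `failureModes` may be a character vector of length `nSamples`, or a named
#' count vector (e.g. `c(eye_detection_failure = 4, sideways_muzzle = 3)`)
#' assigned to the last samples in order.
#'
#' @param nSamples Number of samples (>= 1).
#' @param baseCfg A [syntheticSampleConfig()]; its `seed` is ignored in
#'   favour of per-sample derived seeds.
#' @param seed Master seed.
#' @param failureModes `NULL`, a length-`nSamples` character vector, or a
#'   named integer vector of counts.
#' @return A list of sample bundles; each bundle is the
#'   [generatePairedSeries()] output plus `sampleId` and `config`.
#' @export
#' @examples
#' cohort <- generateCohort(3, seed = 7)
#' length(cohort)
generateCohort <- function(nSamples, baseCfg = syntheticSampleConfig(),
                           seed = 1, failureModes = NULL) {
  if (!is.numeric(nSamples) || nSamples < 1)
    inputError("nSamples must be >= 1")
  nSamples <- as.integer(nSamples)
  modes <- rep("none", nSamples)
  if (!is.null(failureModes)) {
    if (!is.null(names(failureModes))) {
      counts <- failureModes
      if (sum(counts) > nSamples)
        inputError("failure-mode counts exceed nSamples")
      at <- nSamples
      for (m in rev(names(counts))) {
        k <- as.integer(counts[[m]])
        if (k > 0L) modes[(at - k + 1L):at] <- m
        at <- at - k
      }
    } else {
      if (length(failureModes) != nSamples)
        inputError("failureModes must have length nSamples")
      modes <- as.character(failureModes)
    }
  }
  lapply(seq_len(nSamples), function(i) {
    cfg <- syntheticSampleConfig(
      latent = baseCfg$latent, eyeNoise = baseCfg$eyeNoise,
      muzzleNoise = baseCfg$muzzleNoise, coupling = baseCfg$coupling,
      failureMode = modes[i], baselineEye = baseCfg$baselineEye,
      baselineMuzzle = baseCfg$baselineMuzzle,
      backgroundTemp = baseCfg$backgroundTemp,
      seed = deriveSeed(seed, 100L + i))
    id <- sprintf("sample_%02d", i)
    c(generatePairedSeries(cfg, sampleId = id),
      list(sampleId = id, config = cfg))
  })
}
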