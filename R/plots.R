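#' Overlay plot of paired temperature change patterns
#'
#' Writes a PNG overlaying the eye and muzzle conditioned patterns, the
#' visual check for whether the two thermal windows moved together. The
#' output directory is created if needed.
#'
#' @param eye,muzzle [ConditionedPattern-class] objects.
#' @param path Output PNG path.
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
plotPatterns <- function(eye, muzzle, path, width = 900, height = 450) {
  stopifnot(is(eye, "ConditionedPattern"), is(muzzle, "ConditionedPattern"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  rng <- range(eye@values, muzzle@values)
  graphics::plot(eye@times, eye@values, type = "l", col = "darkgreen",
                 lwd = 2, ylim = rng, xlab = "time (s)",
                 ylab = "standardized temperature",
                 main = sprintf("Temperature change patterns (%s)",
                                sampleId(eye)))
  graphics::lines(muzzle@times, muzzle@values, col = "firebrick", lwd = 2)
  graphics::legend("topright", legend = c(eye@label, muzzle@label),
                   col = c("darkgreen", "firebrick"), lwd = 2, bty = "n")
  invisible(path)
}

#' Stage-by-stage conditioning panels
#'
#' Writes a five-panel PNG showing one region's series at each processing
#' stage: raw mean temperatures, after outlier rejection, after
#' standardization, the standardized series with its low-pass-filtered
#' version overlaid, and the final temperature change pattern.
#'
#' @param series Raw [TemperatureSeries-class].
#' @param path Output PNG path.
#' @param g,cutoffHz,fps Conditioning parameters, see [conditionSeries()].
#' @param width,height Device size in pixels.
#' @return `path`, invisibly.
#' @export
plotStages <- function(series, path, g = 1.5, cutoffHz = 0.08, fps = NULL,
                       width = 800, height = 1100) {
  stopifnot(is(series, "TemperatureSeries"))
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  if (is.null(fps)) fps <- 1 / median(diff(series@times))
  rej <- rejectOutliers(series, g = g)
  std <- standardizeSeries(rej$series)
  uni <- regridSeries(std, fps = fps)
  filt <- lowpassFilter(uni@values, cutoffHz = cutoffHz, fps = fps)
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  op <- graphics::par(mfrow = c(5, 1), mar = c(3.5, 4, 2, 1))
  on.exit(graphics::par(op), add = TRUE)
  pl <- function(t, v, main, ylab, ...)
    graphics::plot(t, v, type = "l", xlab = "", ylab = ylab, main = main,
                   ...)
  pl(series@times, series@values, "A: raw mean temperature", "degC")
  pl(rej$series@times, rej$series@values,
     sprintf("B: after outlier rejection (%d rejected)",
             rej$report$n_rejected), "degC")
  pl(std@times, std@values, "C: after standardization", "z")
  pl(uni@times, uni@values, "D: low-pass filter overlay", "z")
  graphics::lines(uni@times, filt, col = "darkgreen", lwd = 2)
  pl(uni@times, filt, "E: temperature change pattern", "z",
     col = "darkgreen", lwd = 2)
  invisible(path)
}
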