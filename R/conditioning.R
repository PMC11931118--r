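#' Tukey fences for outlier rejection
#'
#' Computes the first and third quartiles of the non-missing values and the
#' acceptance interval `[Q1 - g * (Q3 - Q1), Q3 + g * (Q3 - Q1)]`. Quartiles
#' default to Tukey's hinges — medians of the lower and upper halves of the
#' sorted data, each half including the overall median when the count is odd
#' (as computed by [stats::fivenum()]). An interpolated-quantile alternative
#' (type-7 [stats::quantile()]) is available for sensitivity analysis.
#'
#' @param values Numeric vector (missing values ignored); at least 4
#'   non-missing values required.
#' @param g Tukey's constant (default 1.5).
#' @param method `"hinges"` (default) or `"quantile"`.
#' @return A list of class `TukeyFences` with elements `q1`, `q3`, `g`,
#'   `lower`, `upper`, `method`.
#' @export
#' @examples
#' computeTukeyFences(c(1:9, 100))   # fences [-4.5, 15.5]
computeTukeyFences <- function(values, g = 1.5,
                               method = c("hinges", "quantile")) {
  method <- match.arg(method)
  .checkNumber(g, "g", lower = 0)
  v <- values[!is.na(values)]
  if (length(v) < 4L)
    degenerateInputError(
      "need at least 4 non-missing values to place Tukey fences (got %d)",
      length(v))
  if (method == "hinges") {
    fn <- fivenum(v)
    q1 <- fn[2L]; q3 <- fn[4L]
  } else {
    q <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
    q1 <- q[1L]; q3 <- q[2L]
  }
  iqr <- q3 - q1
  structure(list(q1 = q1, q3 = q3, g = g, lower = q1 - g * iqr,
                 upper = q3 + g * iqr, method = method),
            class = "TukeyFences")
}

#' @export
print.TukeyFences <- function(x, ...) {
  cat(sprintf("TukeyFences (%s): Q1 = %g, Q3 = %g, g = %g -> [%g, %g]\n",
              x$method, x$q1, x$q3, x$g, x$lower, x$upper))
  invisible(x)
}

#' Reject outliers by Tukey fences
#'
#' Values strictly outside the fences are replaced by missing values
#' (`NA`). Fences are computed once from the full series, not iteratively,
#' and already-missing values are passed through untouched. The attached
#' report accounts for every input frame:
#' `n_rejected + n_retained + n_missing_input = n_input`.
#'
#' @param series A [TemperatureSeries-class] or numeric vector.
#' @param g Tukey's constant (default 1.5).
#' @param method Quartile convention, see [computeTukeyFences()].
#' @return A list with elements `series` (same type as the input, outliers
#'   set to `NA`) and `report` (list: `n_input`, `n_rejected`,
#'   `n_missing_input`, `n_retained`, `fences`, `rejected` indices).
#' @export
#' @examples
#' out <- rejectOutliers(c(1:9, 100))
#' out$report$n_rejected   # 1: the value 100
rejectOutliers <- function(series, g = 1.5, method = c("hinges", "quantile")) {
  method <- match.arg(method)
  isSeries <- is(series, "TemperatureSeries")
  v <- if (isSeries) series@values else as.numeric(series)
  fences <- computeTukeyFences(v, g = g, method = method)
  bad <- which(!is.na(v) & (v < fences$lower | v > fences$upper))
  out <- v
  out[bad] <- NA_real_
  report <- list(n_input = length(v), n_rejected = length(bad),
                 n_missing_input = sum(is.na(v)),
                 n_retained = length(v) - length(bad) - sum(is.na(v)),
                 fences = fences, rejected = bad)
  if (isSeries) {
    series@values <- out
    list(series = series, report = report)
  } else {
    list(series = out, report = report)
  }
}

#' Standardize a series to zero mean and unit variance
#'
#' z-scores the non-missing values: `(x - mean) / sd`, with the sample
#' standard deviation (n - 1 denominator). Missing values stay missing.
#' Standardization is what makes patterns comparable across individuals and
#' recording conditions: absolute temperature offsets (individual, ambient)
#' and scale differences are removed before any cross-region comparison.
#'
#' @param series A [TemperatureSeries-class] or numeric vector with at least
#'   2 non-missing values and non-zero spread.
#' @return Same type as the input, standardized.
#' @export
#' @examples
#' standardizeSeries(c(1, 2, 3))   # -1 0 1
standardizeSeries <- function(series) {
  isSeries <- is(series, "TemperatureSeries")
  v <- if (isSeries) series@values else as.numeric(series)
  ok <- !is.na(v)
  if (sum(ok) < 2L)
    degenerateInputError("need at least 2 non-missing values to standardize")
  s <- sd(v[ok])
  if (!is.finite(s) || s == 0)
    degenerateInputError(
      "series has zero standard deviation; its pattern direction is undefined")
  out <- (v - mean(v[ok])) / s
  if (isSeries) { series@values <- out; series } else out
}

#' Regrid a series onto a uniform time grid
#'
#' Linearly interpolates onto a grid with spacing `1/fps` anchored at the
#' first non-missing time point. Interior gaps (rejected outliers, detection
#' dropouts) are bridged by interpolation; leading and trailing missing runs
#' are trimmed, never extrapolated.
#'
#' @param series A [TemperatureSeries-class] or numeric vector (a vector is
#'   taken to be sampled at `1/fps` starting at 0).
#' @param fps Target grid rate in frames/second (default 8.7).
#' @return Same type as the input, gapless and uniformly gridded.
#' @export
regridSeries <- function(series, fps = 8.7) {
  .checkNumber(fps, "fps", lower = 0, strict_lower = TRUE)
  isSeries <- is(series, "TemperatureSeries")
  v <- if (isSeries) series@values else as.numeric(series)
  t <- if (isSeries) series@times else (seq_along(v) - 1L) / fps
  ok <- which(!is.na(v))
  if (length(ok) < 2L)
    degenerateInputError(
      "need at least 2 non-missing anchor points to regrid (got %d)",
      length(ok))
  t0 <- t[ok[1L]]; t1 <- t[ok[length(ok)]]
  grid <- t0 + seq(0L, floor((t1 - t0) * fps + 1e-9)) / fps
  vals <- approx(t[ok], v[ok], xout = grid, method = "linear", rule = 1)$y
  ## rule = 1 cannot produce NA inside [t0, t1]; guard the grid endpoint
  ## against floating overshoot all the same
  if (anyNA(vals)) vals[is.na(vals)] <- v[ok[length(ok)]]
  if (isSeries) {
    new("TemperatureSeries", label = series@label, times = grid,
        values = vals, sampleId = series@sampleId)
  } else vals
}

#' Derive a temperature change pattern from a raw mean-temperature series
#'
#' Runs the full conditioning pipeline on one region's mean-temperature
#' series: Tukey-fence outlier rejection (g = 1.5) -> z-score
#' standardization -> uniform regridding -> zero-phase low-pass filtering at
#' 0.08 Hz. The result is the "temperature change pattern": a dimensionless,
#' gapless, uniformly sampled vector in which sensor spikes, absolute
#' offsets and fast physiological oscillations (respiration ~0.5 Hz,
#' cardiac ~1.5 Hz) have been removed, leaving the slow within-session
#' change.
#'
#' Stage order is configurable: `"standardize_first"` (default) standardizes
#' before filtering; `"filter_first"` filters first and standardizes the
#' filtered pattern. Cosine similarity is scale-invariant, so the two orders
#' differ only through the interpolation of rejected values.
#'
#' @param series A [TemperatureSeries-class] (or numeric vector sampled at
#'   `fps`).
#' @param g Tukey's constant (default 1.5).
#' @param cutoffHz Low-pass cutoff in Hz (default 0.08).
#' @param fps Grid rate in frames/second; defaults to the rate implied by
#'   the series' median time step.
#' @param stageOrder `"standardize_first"` or `"filter_first"`.
#' @param hingeMethod Quartile convention for the fences.
#' @param filterOrder Butterworth order per pass (default 4).
#' @return A [ConditionedPattern-class]. Degenerate inputs raise a
#'   `degenerateInputError` whose message names the failing stage.
#' @export
#' @examples
#' raw <- TemperatureSeries(36 + 0.5 * sin(2 * pi * 0.02 * (0:434) / 8.7),
#'                          fps = 8.7)
#' pat <- conditionSeries(raw)
#' pat
conditionSeries <- function(series, g = 1.5, cutoffHz = 0.08, fps = NULL,
                            stageOrder = c("standardize_first",
                                           "filter_first"),
                            hingeMethod = c("hinges", "quantile"),
                            filterOrder = 4L) {
  stageOrder <- match.arg(stageOrder)
  hingeMethod <- match.arg(hingeMethod)
  if (!is(series, "TemperatureSeries"))
    series <- TemperatureSeries(as.numeric(series),
                                fps = fps %||% 8.7)
  if (is.null(fps)) {
    dt <- median(diff(series@times))
    fps <- 1 / dt
  }
  stage <- function(name, expr) {
    tryCatch(expr, degenerateInputError = function(e)
      degenerateInputError("stage '%s': %s", name, conditionMessage(e)))
  }
  rej <- stage("reject_outliers",
               rejectOutliers(series, g = g, method = hingeMethod))
  if (stageOrder == "standardize_first") {
    std <- stage("standardize", standardizeSeries(rej$series))
    uni <- stage("regrid", regridSeries(std, fps = fps))
    val <- stage("lowpass_filter",
                 lowpassFilter(uni@values, cutoffHz = cutoffHz, fps = fps,
                               order = filterOrder))
  } else {
    uni <- stage("regrid", regridSeries(rej$series, fps = fps))
    filt <- stage("lowpass_filter",
                  lowpassFilter(uni@values, cutoffHz = cutoffHz, fps = fps,
                                order = filterOrder))
    val <- stage("standardize", standardizeSeries(filt))
  }
  new("ConditionedPattern", label = series@label, times = uni@times,
      values = val, cutoffHz = cutoffHz, fps = fps, report = rej$report,
      params = list(g = g, cutoffHz = cutoffHz, fps = fps,
                    stageOrder = stageOrder, hingeMethod = hingeMethod,
                    filterOrder = as.integer(filterOrder)),
      sampleId = series@sampleId)
}
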