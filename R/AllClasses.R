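#' ThermalFrameSequence: a stack of radiometric frames
#'
#' Ordered stack of 2-D temperature rasters (degrees Celsius) with per-frame
#' timestamps in seconds and a nominal frame rate. All frames share one
#' geometry; rasters are matrices indexed `[row, col]` with the origin at the
#' top-left of the image.
#'
#' @slot frames List of numeric matrices, one per frame, all the same
#'   dimension, values in degrees Celsius.
#' @slot timestamps Numeric vector of acquisition times in seconds, strictly
#'   increasing, one per frame.
#' @slot fps Nominal frame rate in frames per second.
#'
#' @seealso [readFrameSequence()], [renderFrameSequence()],
#'   [extractMeanTemperature()]
#' @export
setClass("ThermalFrameSequence",
  representation(frames = "list", timestamps = "numeric", fps = "numeric"))

setValidity("ThermalFrameSequence", function(object) {
  f <- object@frames
  if (length(f) == 0L) return("sequence must contain at least one frame")
  if (!all(vapply(f, is.matrix, logical(1L))))
    return("all frames must be matrices")
  d <- dim(f[[1L]])
  if (!all(vapply(f, function(m) identical(dim(m), d), logical(1L))))
    return("all frames must share one geometry")
  if (length(object@timestamps) != length(f))
    return("one timestamp per frame required")
  if (any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  if (length(object@fps) != 1L || object@fps <= 0)
    return("fps must be a single positive number")
  TRUE
})

#' Construct a ThermalFrameSequence
#'
#' @param frames List of numeric matrices (degrees Celsius), identical dims.
#' @param timestamps Strictly increasing times in seconds; if `NULL`,
#'   synthesized as `(0:(n-1))/fps`.
#' @param fps Nominal frame rate (frames/second).
#' @return A [ThermalFrameSequence-class] object.
#' @export
#' @examples
#' seq <- ThermalFrameSequence(list(matrix(30, 2, 2)), fps = 8.7)
#' nFrames(seq)
ThermalFrameSequence <- function(frames, timestamps = NULL, fps = 8.7) {
  if (is.null(timestamps)) timestamps <- (seq_along(frames) - 1L) / fps
  new("ThermalFrameSequence", frames = frames,
      timestamps = as.numeric(timestamps), fps = as.numeric(fps))
}

#' RoiTrack: per-frame region annotations
#'
#' Holds, for each region label (`"eye"`, `"muzzle"`), one optional polygon
#' (and/or pre-rasterized binary mask) per frame. An absent entry (`NULL`)
#' means the region was not detected on that frame — detection dropout is a
#' first-class state, never silently filled.
#'
#' @slot nFrames Number of frames the track spans.
#' @slot polygons Named list (by label); each element a list of length
#'   `nFrames` whose entries are two-column `(x, y)` vertex matrices in pixel
#'   coordinates, or `NULL` when the region is absent on that frame.
#' @slot masks Named list (by label) of per-frame logical matrices or `NULL`;
#'   may be empty, in which case polygons are rasterized on demand.
#' @slot provenance One of `"annotation"`, `"synthetic"`,
#'   `"external_detector"`.
#' @export
setClass("RoiTrack",
  representation(nFrames = "integer", polygons = "list", masks = "list",
                 provenance = "character"))

setValidity("RoiTrack", function(object) {
  n <- object@nFrames
  if (length(n) != 1L || n < 1L) return("nFrames must be a positive integer")
  for (lab in names(object@polygons)) {
    pl <- object@polygons[[lab]]
    if (length(pl) != n)
      return(sprintf("polygon list for '%s' must have one slot per frame", lab))
    ok <- vapply(pl, function(p) is.null(p) ||
                   (is.matrix(p) && ncol(p) == 2L && nrow(p) >= 3L), logical(1L))
    if (!all(ok))
      return(sprintf("polygons for '%s' must be NULL or >=3-vertex matrices", lab))
  }
  for (lab in names(object@masks)) {
    ml <- object@masks[[lab]]
    if (length(ml) != n)
      return(sprintf("mask list for '%s' must have one slot per frame", lab))
  }
  if (!object@provenance %in% c("annotation", "synthetic", "external_detector"))
    return("unknown provenance")
  TRUE
})

#' Construct an RoiTrack
#'
#' @param nFrames Number of frames spanned.
#' @param polygons Named list by label of per-frame vertex matrices (or
#'   `NULL` entries for missed detections).
#' @param masks Optional named list by label of per-frame logical masks.
#' @param provenance `"annotation"`, `"synthetic"` or `"external_detector"`.
#' @return An [RoiTrack-class] object.
#' @export
RoiTrack <- function(nFrames, polygons = list(), masks = list(),
                     provenance = "annotation") {
  new("RoiTrack", nFrames = as.integer(nFrames), polygons = polygons,
      masks = masks, provenance = provenance)
}

#' TemperatureSeries: one region's mean-temperature time series
#'
#' Time-indexed mean temperatures for one region, in degrees Celsius.
#' Missing values (`NA`) mark frames where the region was absent or its mask
#' empty; they are carried through explicitly so the conditioning stage owns
#' all gap policy.
#'
#' @slot label Region label (e.g. `"eye"`, `"muzzle"`, `"latent"`).
#' @slot times Times in seconds, strictly increasing.
#' @slot values Temperatures in degrees Celsius; `NA` allowed.
#' @slot sampleId Identifier of the imaging sample.
#' @export
setClass("TemperatureSeries",
  representation(label = "character", times = "numeric", values = "numeric",
                 sampleId = "character"))

setValidity("TemperatureSeries", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' Construct a TemperatureSeries
#'
#' @param values Temperatures (degrees Celsius), `NA` for missing frames.
#' @param times Times in seconds; if `NULL`, synthesized from `fps`.
#' @param label Region label.
#' @param fps Frame rate used to synthesize `times` when absent.
#' @param sampleId Sample identifier.
#' @return A [TemperatureSeries-class] object.
#' @export
#' @examples
#' s <- TemperatureSeries(c(36.1, 36.2, NA, 36.0), fps = 8.7, label = "eye")
#' seriesValues(s)
TemperatureSeries <- function(values, times = NULL, label = "eye", fps = 8.7,
                              sampleId = "sample") {
  if (is.null(times)) times <- (seq_along(values) - 1L) / fps
  new("TemperatureSeries", label = label, times = as.numeric(times),
      values = as.numeric(values), sampleId = sampleId)
}

#' ConditionedPattern: a temperature change pattern
#'
#' The end product of the conditioning pipeline: a standardized (z-scored),
#' uniformly gridded, low-pass-filtered pattern vector in dimensionless
#' units. These are the vectors compared by cosine similarity.
#'
#' @slot label Region label.
#' @slot times Uniform time grid in seconds (spacing `1/fps`).
#' @slot values Dimensionless pattern values, no missing entries.
#' @slot cutoffHz Low-pass cutoff used, in Hz.
#' @slot fps Grid rate in frames/second.
#' @slot report Outlier-rejection report (list; see [rejectOutliers()]).
#' @slot params Conditioning parameters used (list), kept for provenance.
#' @slot sampleId Sample identifier.
#' @export
setClass("ConditionedPattern",
  representation(label = "character", times = "numeric", values = "numeric",
                 cutoffHz = "numeric", fps = "numeric", report = "list",
                 params = "list", sampleId = "character"))

setValidity("ConditionedPattern", function(object) {
  if (length(object@times) != length(object@values))
    return("times and values must have equal length")
  if (anyNA(object@values)) return("conditioned pattern must be gapless")
  if (length(object@times) >= 2L) {
    dt <- diff(object@times)
    if (max(abs(dt - dt[1L])) > 1e-6 * dt[1L])
      return("time grid must be uniform")
  }
  TRUE
})

#' AlignedPair: two patterns on a shared grid
#'
#' Equal-length eye/muzzle pattern vectors restricted to the intersection of
#' their valid time spans, ready for cosine comparison.
#'
#' @slot v1,v2 Numeric pattern vectors of equal length (>= 2), non-zero.
#' @slot times Shared uniform time grid in seconds.
#' @slot labels Character vector of length 2, labels of `v1` and `v2`.
#' @slot sampleId Sample identifier.
#' @export
setClass("AlignedPair",
  representation(v1 = "numeric", v2 = "numeric", times = "numeric",
                 labels = "character", sampleId = "character"))

setValidity("AlignedPair", function(object) {
  if (length(object@v1) != length(object@v2))
    return("v1 and v2 must have equal length")
  if (length(object@v1) < 2L) return("pair must have length >= 2")
  if (all(object@v1 == 0) || all(object@v2 == 0))
    return("pattern vectors must be non-zero")
  TRUE
})

#' PermutationNull: permutation-test result
#'
#' Summary of the permutation null distribution of cosine similarities and
#' the resulting p-value, `p = count(null >= observed) / n_permutations`.
#'
#' @slot nPermutations Number of permutations drawn.
#' @slot seed Seed used (`NA` if unseeded).
#' @slot countGeObserved Count of null similarities >= the observed one.
#' @slot pValue The permutation p-value in `[0, 1]`.
#' @slot nullMean,nullSd,nullMax Summary of the null similarities.
#' @export
setClass("PermutationNull",
  representation(nPermutations = "integer", seed = "integer",
                 countGeObserved = "integer", pValue = "numeric",
                 nullMean = "numeric", nullSd = "numeric", nullMax = "numeric"))

setValidity("PermutationNull", function(object) {
  if (object@countGeObserved < 0L ||
      object@countGeObserved > object@nPermutations)
    return("countGeObserved out of range")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("pValue out of [0, 1]")
  TRUE
})

#' SimilarityResult: one sample's similarity analysis
#'
#' Observed eye/muzzle cosine similarity, its permutation test, the
#' similarity band it falls in, and any quality flags raised during
#' processing. Failed samples carry `NA` cosine and a `failed:<stage>` flag.
#'
#' @slot sampleId Sample identifier.
#' @slot observedCosine Observed cosine similarity in `[-1, 1]` (`NA` if the
#'   sample could not be processed).
#' @slot null A [PermutationNull-class] (zero-permutation placeholder for
#'   failed samples).
#' @slot bin Similarity band label: `"0.5-1"`, `"0.3-0.5"` or `"<0.3"`
#'   (`NA` for failed samples).
#' @slot flags Character vector of quality flags (may be empty).
#' @slot n Length of the aligned pattern vectors.
#' @export
setClass("SimilarityResult",
  representation(sampleId = "character", observedCosine = "numeric",
                 null = "PermutationNull", bin = "character",
                 flags = "character", n = "integer"))

#' CohortSummary: cohort-level aggregation
#'
#' Per-sample results plus the similarity-band table (band, sample count,
#' p-value summary), the mean observed cosine, and the flagged samples.
#'
#' @slot results List of [SimilarityResult-class], one per sample.
#' @slot table Data frame with one row per similarity band: columns
#'   `bin`, `n_samples`, `median_p`, `max_p`.
#' @slot meanCosine Mean observed cosine over analyzed (non-failed) samples.
#' @slot flagged Data frame of flagged samples: `sample_id`, `flags`.
#' @export
setClass("CohortSummary",
  representation(results = "list", table = "data.frame",
                 meanCosine = "numeric", flagged = "data.frame"))
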