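#' @include AllClasses.R
NULL

#' Accessors for thermopattern objects
#'
#' Small accessor generics so downstream code never touches slots directly.
#'
#' @param x A thermopattern object.
#' @param ... Passed on to methods.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "ThermalFrameSequence", function(x) length(x@frames))
#' @rdname accessors
#' @export
setMethod("nFrames", "RoiTrack", function(x) x@nFrames)

#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setMethod("frames", "ThermalFrameSequence", function(x) x@frames)

#' @rdname accessors
#' @export
setGeneric("timestamps", function(x) standardGeneric("timestamps"))
#' @rdname accessors
#' @export
setMethod("timestamps", "ThermalFrameSequence", function(x) x@timestamps)

#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setMethod("frameRate", "ThermalFrameSequence", function(x) x@fps)
#' @rdname accessors
#' @export
setMethod("frameRate", "ConditionedPattern", function(x) x@fps)

#' @rdname accessors
#' @export
setGeneric("frameDim", function(x) standardGeneric("frameDim"))
#' @rdname accessors
#' @export
setMethod("frameDim", "ThermalFrameSequence", function(x) dim(x@frames[[1L]]))

#' @rdname accessors
#' @export
setGeneric("roiLabels", function(x) standardGeneric("roiLabels"))
#' @rdname accessors
#' @export
setMethod("roiLabels", "RoiTrack",
          function(x) union(names(x@polygons), names(x@masks)))

#' Fraction of frames on which a region was detected
#'
#' @param x An [RoiTrack-class].
#' @param label Region label.
#' @return Fraction in `[0, 1]`.
#' @export
roiCoverage <- function(x, label) {
  stopifnot(is(x, "RoiTrack"))
  pl <- x@polygons[[label]]
  ml <- x@masks[[label]]
  if (is.null(pl) && is.null(ml)) return(0)
  present <- function(lst) !vapply(lst, is.null, logical(1L))
  has <- if (!is.null(pl)) present(pl) else rep(FALSE, x@nFrames)
  if (!is.null(ml)) has <- has | present(ml)
  mean(has)
}

#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))
#' @rdname accessors
#' @export
setMethod("seriesValues", "TemperatureSeries", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("seriesValues", "ConditionedPattern", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))
#' @rdname accessors
#' @export
setMethod("seriesTimes", "TemperatureSeries", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("seriesTimes", "ConditionedPattern", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("seriesLabel", function(x) standardGeneric("seriesLabel"))
#' @rdname accessors
#' @export
setMethod("seriesLabel", "TemperatureSeries", function(x) x@label)
#' @rdname accessors
#' @export
setMethod("seriesLabel", "ConditionedPattern", function(x) x@label)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "TemperatureSeries", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "ConditionedPattern", function(x) x@sampleId)
#' @rdname accessors
#' @export
setMethod("sampleId", "SimilarityResult", function(x) x@sampleId)

#' @rdname accessors
#' @export
setMethod("length", "TemperatureSeries", function(x) length(x@values))
#' @rdname accessors
#' @export
setMethod("length", "ConditionedPattern", function(x) length(x@values))

#' @rdname accessors
#' @export
setGeneric("observedCosine", function(x) standardGeneric("observedCosine"))
#' @rdname accessors
#' @export
setMethod("observedCosine", "SimilarityResult", function(x) x@observedCosine)

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "PermutationNull", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("pValue", "SimilarityResult", function(x) x@null@pValue)

#' @rdname accessors
#' @export
setGeneric("similarityBin", function(x) standardGeneric("similarityBin"))
#' @rdname accessors
#' @export
setMethod("similarityBin", "SimilarityResult", function(x) x@bin)

#' @rdname accessors
#' @export
setGeneric("resultFlags", function(x) standardGeneric("resultFlags"))
#' @rdname accessors
#' @export
setMethod("resultFlags", "SimilarityResult", function(x) x@flags)

#' @rdname accessors
#' @export
setGeneric("cohortResults", function(x) standardGeneric("cohortResults"))
#' @rdname accessors
#' @export
setMethod("cohortResults", "CohortSummary", function(x) x@results)

#' @rdname accessors
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))
#' @rdname accessors
#' @export
setMethod("cohortTable", "CohortSummary", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("meanCosine", function(x) standardGeneric("meanCosine"))
#' @rdname accessors
#' @export
setMethod("meanCosine", "CohortSummary", function(x) x@meanCosine)

#' @rdname accessors
#' @export
setGeneric("flaggedSamples", function(x) standardGeneric("flaggedSamples"))
#' @rdname accessors
#' @export
setMethod("flaggedSamples", "CohortSummary", function(x) x@flagged)

setMethod("show", "ThermalFrameSequence", function(object) {
  d <- frameDim(object)
  cat(sprintf(
    "ThermalFrameSequence: %d frames of %d x %d px, %.2f fps, %.1f s\n",
    nFrames(object), d[1L], d[2L], object@fps,
    diff(range(object@timestamps))))
})

setMethod("show", "RoiTrack", function(object) {
  cat(sprintf("RoiTrack (%s): %d frames\n", object@provenance, object@nFrames))
  for (lab in roiLabels(object))
    cat(sprintf("  %s: detected on %.0f%% of frames\n", lab,
                100 * roiCoverage(object, lab)))
})

setMethod("show", "TemperatureSeries", function(object) {
  v <- object@values
  cat(sprintf(
    "TemperatureSeries '%s' (%s): %d frames, %d missing, range %.2f-%.2f degC\n",
    object@label, object@sampleId, length(v), sum(is.na(v)),
    suppressWarnings(min(v, na.rm = TRUE)),
    suppressWarnings(max(v, na.rm = TRUE))))
})

setMethod("show", "ConditionedPattern", function(object) {
  cat(sprintf(
    "ConditionedPattern '%s' (%s): %d points at %.2f fps, cutoff %.3g Hz\n",
    object@label, object@sampleId, length(object@values), object@fps,
    object@cutoffHz))
})

setMethod("show", "PermutationNull", function(object) {
  cat(sprintf(
    "PermutationNull: p = %.4g (%d of %d >= observed), null mean %.3g sd %.3g\n",
    object@pValue, object@countGeObserved, object@nPermutations,
    object@nullMean, object@nullSd))
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("SimilarityResult '%s': cosine = %.3f, p = %.4g, bin %s\n",
              object@sampleId, object@observedCosine, pValue(object),
              object@bin))
  if (length(object@flags))
    cat("  flags:", paste(object@flags, collapse = ", "), "\n")
})

setMethod("show", "CohortSummary", function(object) {
  cat(sprintf("CohortSummary: %d samples, mean cosine %.3f\n",
              length(object@results), object@meanCosine))
  print(object@table, row.names = FALSE)
  if (nrow(object@flagged))
    cat(sprintf("  %d flagged sample(s)\n", nrow(object@flagged)))
})
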