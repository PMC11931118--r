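#' Pipeline configuration
#'
#' One home for every tunable of the end-to-end analysis. Defaults are the
#' study conditions: Tukey constant 1.5, 0.08 Hz cutoff, 8.7 fps, 10,000
#' permutations.
#'
#' @param g Tukey's constant for outlier fences (default 1.5).
#' @param cutoffHz Low-pass cutoff in Hz (default 0.08).
#' @param fps Frame rate in frames/second (default 8.7).
#' @param nPermutations Permutation count (default 10000).
#' @param seed Master seed for the permutation draws, or `NULL`.
#' @param stageOrder `"standardize_first"` (default) or `"filter_first"`;
#'   see [conditionSeries()].
#' @param hingeMethod Quartile convention (`"hinges"` or `"quantile"`).
#' @param permute Which pattern the permutation test scrambles (`"muzzle"`,
#'   the default, or `"eye"`).
#' @param pCorrection `"none"` (count/N, default) or `"add_one"`.
#' @param minValidFraction Minimum fraction of frames with a detected,
#'   retained value for a region before the sample is flagged
#'   `"detection-failure suspected"` (default 0.5).
#' @param flatSdThreshold Standard deviation (degC) of the region's
#'   low-pass-filtered retained series below which the region is considered
#'   background-flat and the same flag is raised (default 0.1). A live
#'   thermal window drifts several times this over a 1-2 min recording,
#'   while a mislocated region on inert background retains only the
#'   low-frequency leakage of sensor noise (~0.01 degC); raw or
#'   post-rejection standard deviations do not separate the two cases as
#'   cleanly, because Tukey fences can clip genuine slow excursions.
#' @return A validated list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(g = 1.5, cutoffHz = 0.08, fps = 8.7,
                           nPermutations = 10000L, seed = NULL,
                           stageOrder = c("standardize_first",
                                          "filter_first"),
                           hingeMethod = c("hinges", "quantile"),
                           permute = c("muzzle", "eye"),
                           pCorrection = c("none", "add_one"),
                           minValidFraction = 0.5, flatSdThreshold = 0.1) {
  .checkNumber(g, "g", lower = 0)
  .checkNumber(cutoffHz, "cutoffHz", lower = 0, strict_lower = TRUE)
  .checkNumber(fps, "fps", lower = 0, strict_lower = TRUE)
  .checkNumber(nPermutations, "nPermutations", lower = 1)
  .checkNumber(minValidFraction, "minValidFraction", lower = 0, upper = 1,
               strict_lower = TRUE)
  .checkNumber(flatSdThreshold, "flatSdThreshold", lower = 0)
  structure(list(g = g, cutoffHz = cutoffHz, fps = fps,
                 nPermutations = as.integer(nPermutations), seed = seed,
                 stageOrder = match.arg(stageOrder),
                 hingeMethod = match.arg(hingeMethod),
                 permute = match.arg(permute),
                 pCorrection = match.arg(pCorrection),
                 minValidFraction = minValidFraction,
                 flatSdThreshold = flatSdThreshold),
            class = "PipelineConfig")
}

## Slow-variation scale of a raw series in degC: outlier rejection ->
## regrid -> low-pass, then sd. NA when the series is too degenerate to
## measure (it will fail conditioning anyway).
.slowVariationSd <- function(series, config) {
  tryCatch({
    rej <- rejectOutliers(series, g = config$g, method = config$hingeMethod)
    uni <- regridSeries(rej$series, fps = config$fps)
    sd(lowpassFilter(seriesValues(uni), cutoffHz = config$cutoffHz,
                     fps = config$fps))
  }, degenerateInputError = function(e) NA_real_)
}

.emptyNull <- function() new("PermutationNull", nPermutations = 0L,
                             seed = NA_integer_, countGeObserved = 0L,
                             pValue = NA_real_, nullMean = NA_real_,
                             nullSd = NA_real_, nullMax = NA_real_)

.qualityFlags <- function(series, config) {
  flags <- character(0)
  v <- seriesValues(series)
  validFrac <- mean(!is.na(v))
  reason <- character(0)
  if (validFrac < config$minValidFraction)
    reason <- c(reason, sprintf("%s valid-frame fraction %.2f < %.2f",
                                seriesLabel(series), validFrac,
                                config$minValidFraction))
  slowSd <- .slowVariationSd(series, config)
  if (!is.na(slowSd) && slowSd < config$flatSdThreshold)
    reason <- c(reason,
                sprintf("%s series is background-flat (slow sd %.3f degC)",
                        seriesLabel(series), slowSd))
  if (length(reason))
    flags <- c("detection-failure suspected", reason)
  flags
}

#' Run the full analysis on one sample
#'
#' End-to-end per-sample pipeline: extract eye and muzzle mean-temperature
#' series (when given frames and a track), condition each into a
#' temperature change pattern, align, compute the observed cosine
#' similarity, and run the permutation test. Samples whose valid-frame
#' fraction falls below `minValidFraction`, or whose retained series is
#' background-flat, are flagged `"detection-failure suspected"` but still
#' processed when possible; a stage that fails on degenerate input marks
#' the sample failed (cosine `NA`, flag `failed: ...`) rather than
#' aborting a cohort run.
#'
#' @param x A [ThermalFrameSequence-class], or the eye
#'   [TemperatureSeries-class].
#' @param y The matching [RoiTrack-class], or the muzzle
#'   [TemperatureSeries-class].
#' @param config A [pipelineConfig()].
#' @param permSeed Seed for the permutation draws (defaults to
#'   `config$seed`).
#' @return A [SimilarityResult-class].
#' @export
#' @examples
#' p <- generatePairedSeries(syntheticSampleConfig(seed = 1))
#' res <- runSample(p$eye, p$muzzle,
#'                  config = pipelineConfig(nPermutations = 200, seed = 1))
#' res
setGeneric("runSample", function(x, y, config = pipelineConfig(),
                                 permSeed = NULL) standardGeneric("runSample"))

#' @rdname runSample
#' @export
setMethod("runSample",
          signature(x = "ThermalFrameSequence", y = "RoiTrack"),
          function(x, y, config = pipelineConfig(), permSeed = NULL) {
  eye <- extractMeanTemperature(x, y, "eye")
  muzzle <- extractMeanTemperature(x, y, "muzzle")
  runSample(eye, muzzle, config = config, permSeed = permSeed)
})

#' @rdname runSample
#' @export
setMethod("runSample",
          signature(x = "TemperatureSeries", y = "TemperatureSeries"),
          function(x, y, config = pipelineConfig(), permSeed = NULL) {
  id <- sampleId(x)
  flags <- c(.qualityFlags(x, config), .qualityFlags(y, config))
  failed <- function(stage, e) new("SimilarityResult", sampleId = id,
    observedCosine = NA_real_, null = .emptyNull(), bin = NA_character_,
    flags = unique(c(flags, sprintf("failed:%s", stage),
                     conditionMessage(e))), n = 0L)
  res <- tryCatch({
    cond <- function(s) conditionSeries(s, g = config$g,
                                        cutoffHz = config$cutoffHz,
                                        fps = config$fps,
                                        stageOrder = config$stageOrder,
                                        hingeMethod = config$hingeMethod)
    eyePat <- cond(x)
    muzPat <- cond(y)
    pair <- if (config$permute == "muzzle") alignPair(eyePat, muzPat)
            else alignPair(muzPat, eyePat)
    observed <- cosineSimilarity(pair)
    null <- permutationTest(pair, nPermutations = config$nPermutations,
                            seed = permSeed %||% config$seed,
                            permute = "v2", correction = config$pCorrection)
    new("SimilarityResult", sampleId = id, observedCosine = observed,
        null = null, bin = classifySimilarity(observed),
        flags = unique(flags), n = length(pair@v1))
  },
  degenerateInputError = function(e) failed("conditioning", e),
  alignmentError = function(e) failed("alignment", e))
  res
})

#' Run the analysis over a cohort of samples
#'
#' Applies [runSample()] to every sample bundle (as produced by
#' [generateCohort()], or any list with `eye` and `muzzle`
#' [TemperatureSeries-class] elements) and aggregates the results into a
#' [CohortSummary-class]. Per-sample permutation seeds are derived from
#' `config$seed` so the whole cohort run is reproducible. Failed and
#' flagged samples stay in the summary — they are reported, never silently
#' excluded.
#'
#' @param samples Non-empty list of sample bundles.
#' @param config A [pipelineConfig()].
#' @return A [CohortSummary-class].
#' @export
runCohort <- function(samples, config = pipelineConfig()) {
  if (!is.list(samples) || !length(samples))
    inputError("runCohort needs a non-empty list of samples")
  results <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    if (!is.list(s) || is.null(s$eye) || is.null(s$muzzle))
      inputError("sample %d lacks eye/muzzle series", i)
    runSample(s$eye, s$muzzle, config = config,
              permSeed = deriveSeed(config$seed, 500L + i))
  })
  summarizeTable(results)
}

#' Aggregate per-sample results into the similarity-band table
#'
#' Builds the cohort-level table — similarity band, number of samples,
#' p-value summary — plus the mean observed cosine over analyzed samples
#' and the roster of flagged samples. Band counts (plus failed samples)
#' always sum to the number of input results.
#'
#' @param results List of [SimilarityResult-class].
#' @return A [CohortSummary-class].
#' @export
summarizeTable <- function(results) {
  stopifnot(is.list(results),
            all(vapply(results, is, logical(1L), "SimilarityResult")))
  bins <- vapply(results, similarityBin, character(1L))
  ps <- vapply(results, pValue, numeric(1L))
  cs <- vapply(results, observedCosine, numeric(1L))
  levels <- c("0.5-1", "0.3-0.5", "<0.3")
  tab <- do.call(rbind, lapply(levels, function(b) {
    sel <- !is.na(bins) & bins == b
    data.frame(bin = b, n_samples = sum(sel),
               median_p = if (any(sel)) median(ps[sel]) else NA_real_,
               max_p = if (any(sel)) max(ps[sel]) else NA_real_)
  }))
  nFailed <- sum(is.na(bins))
  if (nFailed)
    tab <- rbind(tab, data.frame(bin = "failed", n_samples = nFailed,
                                 median_p = NA_real_, max_p = NA_real_))
  flaggedSel <- vapply(results, function(r) length(resultFlags(r)) > 0L,
                       logical(1L))
  flagged <- data.frame(
    sample_id = vapply(results[flaggedSel], sampleId, character(1L)),
    flags = vapply(results[flaggedSel],
                   function(r) paste(resultFlags(r), collapse = "; "),
                   character(1L)))
  new("CohortSummary", results = results, table = tab,
      meanCosine = mean(cs, na.rm = TRUE), flagged = flagged)
}

#' Write the cohort table as CSV
#'
#' @param summary A [CohortSummary-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeCohortTable <- function(summary, path) {
  stopifnot(is(summary, "CohortSummary"))
  write.csv(cohortTable(summary), path, row.names = FALSE)
  invisible(path)
}

#' Serialize a similarity result to JSON
#'
#' Writes `{sample_id, observed_cosine, p_value, n_permutations, seed, bin,
#' flags, n}` — everything needed to audit one sample's outcome.
#'
#' @param result A [SimilarityResult-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeSimilarityResult <- function(result, path) {
  stopifnot(is(result, "SimilarityResult"))
  jsonlite::write_json(list(
    sample_id = sampleId(result),
    observed_cosine = observedCosine(result),
    p_value = pValue(result),
    n_permutations = result@null@nPermutations,
    seed = result@null@seed,
    bin = similarityBin(result),
    flags = resultFlags(result),
    n = result@n), path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
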