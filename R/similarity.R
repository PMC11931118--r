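#' Align two conditioned patterns on their common time span
#'
#' Restricts both patterns to the intersection of their valid time spans on
#' the shared `1/fps` grid. Both patterns must come from the same recording
#' (same grid rate); differing spans arise when leading/trailing dropout
#' runs were trimmed differently per region.
#'
#' @param eye,muzzle [ConditionedPattern-class] objects on the same grid
#'   rate.
#' @return An [AlignedPair-class].
#' @export
alignPair <- function(eye, muzzle) {
  stopifnot(is(eye, "ConditionedPattern"), is(muzzle, "ConditionedPattern"))
  if (abs(eye@fps - muzzle@fps) > 1e-6 * eye@fps)
    alignmentError("patterns are on different grid rates (%g vs %g fps)",
                   eye@fps, muzzle@fps)
  ## snap times to integer grid indices to make intersection exact
  k1 <- round(eye@times * eye@fps)
  k2 <- round(muzzle@times * muzzle@fps)
  common <- intersect(k1, k2)
  if (length(common) < 2L)
    alignmentError("patterns share fewer than 2 grid points")
  common <- sort(common)
  i1 <- match(common, k1)
  i2 <- match(common, k2)
  new("AlignedPair", v1 = eye@values[i1], v2 = muzzle@values[i2],
      times = common / eye@fps, labels = c(eye@label, muzzle@label),
      sampleId = eye@sampleId)
}

#' Cosine similarity between two pattern vectors
#'
#' `cos(v1, v2) = (v1 . v2) / (||v1|| ||v2||)`, clamped to `[-1, 1]`
#' against floating rounding. Values near 1 mean the two temperature change
#' patterns rise and fall together; near 0, unrelated; negative, opposed.
#'
#' @param v1 An [AlignedPair-class], or a numeric vector.
#' @param v2 A numeric vector (ignored when `v1` is an `AlignedPair`).
#' @return Cosine similarity in `[-1, 1]`.
#' @export
#' @examples
#' cosineSimilarity(c(1, 2), c(2, 4))   # 1: positive scaling is invisible
setGeneric("cosineSimilarity",
           function(v1, v2) standardGeneric("cosineSimilarity"))

#' @rdname cosineSimilarity
#' @export
setMethod("cosineSimilarity", signature("AlignedPair", "missing"),
          function(v1, v2) cosineSimilarity(v1@v1, v1@v2))

#' @rdname cosineSimilarity
#' @export
setMethod("cosineSimilarity", signature("numeric", "numeric"),
          function(v1, v2) {
  if (length(v1) != length(v2))
    inputError("vectors must have equal length (%d vs %d)",
               length(v1), length(v2))
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    degenerateInputError("cosine similarity is undefined for a zero vector")
  min(1, max(-1, sum(v1 * v2) / (n1 * n2)))
})

#' Permutation test for pattern uniqueness
#'
#' Builds the null distribution by uniformly permuting the elements of one
#' vector (by default the muzzle pattern, `v2`) and recomputing the cosine
#' similarity against the unpermuted vector, `nPermutations` times. The
#' p-value is `count(null >= observed) / nPermutations` — one-sided, and
#' zero is attainable when no permutation reaches the observed similarity.
#' The `"add_one"` correction reports `(count + 1) / (nPermutations + 1)`
#' instead.
#'
#' A smooth pattern scrambled by permutation loses its low-frequency
#' ordering, so null similarities concentrate near 0 with spread of order
#' `1/sqrt(n)`; an observed similarity produced by a genuinely shared slow
#' pattern then sits far in the null's upper tail.
#'
#' @param pair An [AlignedPair-class].
#' @param nPermutations Number of permutations (default 10000).
#' @param seed Integer seed for reproducible draws, or `NULL`.
#' @param permute Which side to permute: `"v2"` (muzzle, default) or
#'   `"v1"`.
#' @param correction `"none"` (default, the plain count/N estimate) or
#'   `"add_one"`.
#' @return A [PermutationNull-class].
#' @export
permutationTest <- function(pair, nPermutations = 10000L, seed = NULL,
                            permute = c("v2", "v1"),
                            correction = c("none", "add_one")) {
  stopifnot(is(pair, "AlignedPair"))
  permute <- match.arg(permute)
  correction <- match.arg(correction)
  if (!is.numeric(nPermutations) || nPermutations < 1)
    inputError("nPermutations must be >= 1")
  nPermutations <- as.integer(nPermutations)
  fixed <- if (permute == "v2") pair@v1 else pair@v2
  moving <- if (permute == "v2") pair@v2 else pair@v1
  observed <- cosineSimilarity(pair@v1, pair@v2)
  nrmF <- sqrt(sum(fixed^2)); nrmM <- sqrt(sum(moving^2))
  if (nrmF == 0 || nrmM == 0)
    degenerateInputError("cosine similarity is undefined for a zero vector")
  e <- fixed / (nrmF * nrmM)   # fold both norms in once
  n <- length(moving)
  null <- withSeed(seed, vapply(seq_len(nPermutations), function(i)
    sum(e * moving[sample.int(n)]), numeric(1L)))
  count <- sum(null >= observed)
  p <- if (correction == "none") count / nPermutations
       else (count + 1L) / (nPermutations + 1L)
  new("PermutationNull", nPermutations = nPermutations,
      seed = as.integer(seed %||% NA_integer_),
      countGeObserved = as.integer(count), pValue = p,
      nullMean = mean(null), nullSd = sd(null), nullMax = max(null))
}

#' Classify a cosine similarity into its reporting band
#'
#' Band boundaries are lower-inclusive: `[0.5, 1]` -> `"0.5-1"`,
#' `[0.3, 0.5)` -> `"0.3-0.5"`, below 0.3 -> `"<0.3"`.
#'
#' @param observed Cosine similarity value(s) in `[-1, 1]`.
#' @return Character band label(s).
#' @export
#' @examples
#' classifySimilarity(c(0.72, 0.3, -0.2))
classifySimilarity <- function(observed) {
  if (any(observed < -1 - 1e-12 | observed > 1 + 1e-12, na.rm = TRUE))
    inputError("cosine similarity must lie in [-1, 1]")
  ifelse(is.na(observed), NA_character_,
         ifelse(observed >= 0.5, "0.5-1",
                ifelse(observed >= 0.3, "0.3-0.5", "<0.3")))
}
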