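#' Rasterize a polygon to a binary pixel mask
#'
#' A pixel `(col = x, row = y)` (0-based) is inside the mask when its centre
#' `(x + 0.5, y + 0.5)` falls inside the polygon under the even-odd rule.
#' Coordinates are 0-based with the origin at the image top-left, x running
#' along columns and y along rows. Boundary rule: edges are treated as
#' half-open (a crossing is counted when exactly one endpoint lies strictly
#' below the test row), so centres lying exactly on a shared edge belong to
#' exactly one of two adjacent polygons and tilings do not overlap.
#'
#' A polygon entirely outside the frame yields an all-`FALSE` mask, not an
#' error; downstream extraction treats an empty mask as a missed detection.
#'
#' @param poly Two-column `(x, y)` vertex matrix (>= 3 vertices).
#' @param width,height Frame size in pixels.
#' @return Logical `height x width` matrix (rows = y, columns = x).
#' @export
#' @examples
#' sq <- cbind(x = c(0.6, 3.6, 3.6, 0.6), y = c(0.6, 0.6, 3.6, 3.6))
#' sum(rasterizePolygon(sq, 10, 10))   # 9 pixel centres covered
rasterizePolygon <- function(poly, width, height) {
  stopifnot(is.matrix(poly), ncol(poly) == 2L)
  if (nrow(poly) < 3L) inputError("polygon needs at least 3 vertices")
  width <- as.integer(width); height <- as.integer(height)
  px <- rep(seq_len(width) - 0.5, each = height)    # centre x, column-major
  py <- rep(seq_len(height) - 0.5, times = width)   # centre y
  inside <- rep(FALSE, width * height)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  nv <- nrow(poly)
  j <- nv
  for (i in seq_len(nv)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- (yi > py) != (yj > py)
    if (any(crosses)) {
      xint <- xi + (py[crosses] - yi) / (yj - yi) * (xj - xi)
      flip <- px[crosses] < xint
      idx <- which(crosses)[flip]
      inside[idx] <- !inside[idx]
    }
    j <- i
  }
  matrix(inside, nrow = height, ncol = width)
}

#' Per-frame ROI mean temperatures
#'
#' For each frame, the arithmetic mean of the raster values under the
#' region's binary mask (a pre-rasterized mask if the track carries one,
#' otherwise the rasterized polygon). Frames where the region is absent, or
#' where the mask covers no pixel, yield a missing value; the series carries
#' the sequence's timestamps.
#'
#' @param seq A [ThermalFrameSequence-class].
#' @param track An [RoiTrack-class].
#' @param label Region label (`"eye"` or `"muzzle"`).
#' @return A [TemperatureSeries-class], one value (or `NA`) per frame.
#' @export
setGeneric("extractMeanTemperature",
           function(seq, track, label) standardGeneric("extractMeanTemperature"))

#' @rdname extractMeanTemperature
#' @export
setMethod("extractMeanTemperature",
          signature(seq = "ThermalFrameSequence", track = "RoiTrack"),
          function(seq, track, label) {
  n <- nFrames(seq)
  if (nFrames(track) != n)
    inputError("track spans %d frames but the sequence has %d",
               nFrames(track), n)
  d <- frameDim(seq)
  polys <- track@polygons[[label]]
  masks <- track@masks[[label]]
  if (is.null(polys) && is.null(masks)) {
    warning(sprintf("label '%s' absent from track; returning all-missing series",
                    label))
    return(TemperatureSeries(rep(NA_real_, n), times = timestamps(seq),
                             label = label))
  }
  ## identical polygons are common (static annotations); cache their masks
  cache <- new.env(parent = emptyenv())
  maskFor <- function(i) {
    m <- if (!is.null(masks)) masks[[i]] else NULL
    if (!is.null(m)) return(m)
    p <- if (!is.null(polys)) polys[[i]] else NULL
    if (is.null(p)) return(NULL)
    key <- paste(format(p, digits = 10), collapse = ",")
    got <- cache[[key]]
    if (is.null(got)) {
      got <- rasterizePolygon(p, width = d[2L], height = d[1L])
      cache[[key]] <- got
    }
    got
  }
  vals <- vapply(seq_len(n), function(i) {
    m <- maskFor(i)
    if (is.null(m) || !any(m)) return(NA_real_)
    mean(frames(seq)[[i]][m])
  }, numeric(1L))
  TemperatureSeries(vals, times = timestamps(seq), label = label)
})
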