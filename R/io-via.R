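#' Read VIA-style polygon annotations into an RoiTrack
#'
#' Parses a VGG Image Annotator (VIA-2) project JSON: per-image entries
#' whose `regions` carry polygon `shape_attributes` (`all_points_x` /
#' `all_points_y`) and whose `region_attributes` name the label. Both the
#' bare per-image map and projects wrapping it in `_via_img_metadata` are
#' accepted.
#'
#' Frames are assigned by an explicit integer `frame_index` in the image's
#' `file_attributes` (0-based) when present, otherwise by sorted filename
#' order. Regions with labels other than `eye` / `muzzle` are ignored with a
#' warning naming the count; polygons with fewer than 3 points are skipped
#' with a warning. When one frame carries several polygons with the same
#' label, the largest-area polygon (shoelace formula) is kept — the analogue
#' of taking a detector's most salient detection. Frames with no annotation
#' are left absent.
#'
#' @param path Path to the VIA project JSON.
#' @param nFrames Number of frames the track must span.
#' @return An [RoiTrack-class] with provenance `"annotation"`.
#' @export
readViaAnnotations <- function(path, nFrames) {
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e)
                    formatError("malformed VIA JSON '%s': %s", path,
                                conditionMessage(e)))
  if (!is.null(doc[["_via_img_metadata"]])) doc <- doc[["_via_img_metadata"]]
  if (!length(doc)) formatError("VIA project '%s' contains no images", path)
  fnames <- vapply(doc, function(e) e$filename %||% "", character(1L))
  ord <- order(fnames)
  labels <- c("eye", "muzzle")
  polys <- lapply(labels, function(l) vector("list", nFrames))
  names(polys) <- labels
  nUnknown <- 0L; nSkipped <- 0L
  for (k in seq_along(ord)) {
    entry <- doc[[ord[k]]]
    fi <- entry$file_attributes$frame_index
    frame <- if (!is.null(fi)) as.integer(fi) + 1L else k
    if (frame < 1L || frame > nFrames) {
      warning(sprintf("image '%s' maps to frame %d outside 1..%d; skipped",
                      entry$filename %||% "?", frame, nFrames))
      next
    }
    for (reg in entry$regions) {
      sa <- reg$shape_attributes
      if (is.null(sa) || !identical(sa$name, "polygon")) next
      lab <- reg$region_attributes$label %||%
        (if (length(reg$region_attributes)) reg$region_attributes[[1L]]
         else NULL)
      if (is.null(lab) || !lab %in% labels) { nUnknown <- nUnknown + 1L; next }
      xs <- as.numeric(unlist(sa$all_points_x))
      ys <- as.numeric(unlist(sa$all_points_y))
      if (length(xs) < 3L || length(xs) != length(ys)) {
        nSkipped <- nSkipped + 1L
        next
      }
      p <- cbind(x = xs, y = ys)
      old <- polys[[lab]][[frame]]
      if (is.null(old) || .polygonArea(p) > .polygonArea(old))
        polys[[lab]][[frame]] <- p
    }
  }
  if (nUnknown > 0L)
    warning(sprintf("%d region(s) with labels other than eye/muzzle ignored",
                    nUnknown))
  if (nSkipped > 0L)
    warning(sprintf("%d polygon(s) with fewer than 3 points skipped",
                    nSkipped))
  RoiTrack(nFrames = nFrames, polygons = polys, provenance = "annotation")
}

## shoelace formula
.polygonArea <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

#' Write an RoiTrack as VIA-style JSON
#'
#' Inverse of [readViaAnnotations()]: one image entry per frame carrying the
#' frame's polygons, with `frame_index` in `file_attributes`.
#'
#' @param track An [RoiTrack-class].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
writeViaAnnotations <- function(track, path) {
  stopifnot(is(track, "RoiTrack"))
  entries <- list()
  for (i in seq_len(track@nFrames)) {
    regions <- list()
    for (lab in names(track@polygons)) {
      p <- track@polygons[[lab]][[i]]
      if (is.null(p)) next
      regions[[length(regions) + 1L]] <- list(
        shape_attributes = list(name = "polygon",
                                all_points_x = as.numeric(p[, 1L]),
                                all_points_y = as.numeric(p[, 2L])),
        region_attributes = list(label = lab))
    }
    if (!length(regions)) next
    fname <- sprintf("frame_%06d.png", i)
    entries[[fname]] <- list(
      filename = fname, size = 0L,
      file_attributes = list(frame_index = i - 1L),
      regions = regions)
  }
  jsonlite::write_json(entries, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
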