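#' Write a frame sequence to disk
#'
#' Writes a multi-page 32-bit-float TIFF plus a JSON sidecar
#' (`<stem>.json`) holding `fps`, `timestamps` and the affine temperature
#' calibration. TIFF pages store values scaled to `[0, 1]`; the sidecar's
#' `temp_min` / `temp_max` restore degrees Celsius on read (the same
#' counts-plus-calibration layout radiometric formats use). Alternatively,
#' `path` may be a directory, in which case one CSV raster per frame is
#' written (`frame_000001.csv`, ...) with the sidecar as `sidecar.json`;
#' the CSV route is lossless.
#'
#' @param seq A [ThermalFrameSequence-class].
#' @param path Output path: `*.tif`/`*.tiff` file or a directory.
#' @return `path`, invisibly.
#' @seealso [readFrameSequence()]
#' @export
writeFrameSequence <- function(seq, path) {
  stopifnot(is(seq, "ThermalFrameSequence"))
  sidecar <- list(fps = seq@fps, timestamps = seq@timestamps)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    rng <- range(unlist(lapply(frames(seq), range)))
    if (diff(rng) == 0) rng[2L] <- rng[1L] + 1
    sidecar$temp_min <- rng[1L]
    sidecar$temp_max <- rng[2L]
    scaled <- lapply(frames(seq),
                     function(f) (f - rng[1L]) / (rng[2L] - rng[1L]))
    tiff::writeTIFF(scaled, path, bits.per.sample = 32L,
                    compression = "deflate", reduce = FALSE)
    jsonlite::write_json(sidecar,
                         paste0(tools::file_path_sans_ext(path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    for (i in seq_len(nFrames(seq))) {
      m <- frames(seq)[[i]]
      ## full double precision so the CSV route is lossless
      writeLines(apply(m, 1L, function(r)
        paste(sprintf("%.17g", r), collapse = ",")),
        file.path(path, sprintf("frame_%06d.csv", i)))
    }
    jsonlite::write_json(sidecar, file.path(path, "sidecar.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a frame sequence from disk
#'
#' Accepts either a multi-page float TIFF with its JSON sidecar (see
#' [writeFrameSequence()]) or a directory of per-frame CSV rasters with a
#' `sidecar.json`. Timestamps come from the sidecar; if absent they are
#' synthesized from `fps`. A sidecar providing neither `fps` nor
#' `timestamps` is a format error, as are mixed raster geometries and
#' non-monotone timestamps.
#'
#' @param path Path to a `.tif`/`.tiff` file or a raster directory.
#' @return A [ThermalFrameSequence-class].
#' @export
readFrameSequence <- function(path) {
  if (dir.exists(path)) {
    sidecarPath <- file.path(path, "sidecar.json")
    files <- sort(list.files(path, pattern = "^frame_.*\\.csv$",
                             full.names = TRUE))
    if (!length(files)) formatError("no frame_*.csv rasters in '%s'", path)
    rasters <- lapply(files, function(f)
      as.matrix(read.csv(f, header = FALSE)))
    rasters <- lapply(rasters, unname)
  } else {
    if (!file.exists(path)) formatError("no such file: '%s'", path)
    sidecarPath <- paste0(tools::file_path_sans_ext(path), ".json")
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    rasters <- pages
  }
  if (!file.exists(sidecarPath))
    formatError("missing JSON sidecar '%s'", sidecarPath)
  sidecar <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  if (is.null(sidecar$fps) && is.null(sidecar$timestamps))
    formatError("sidecar '%s' provides neither 'fps' nor 'timestamps'",
                sidecarPath)
  if (!is.null(sidecar$temp_min)) {
    lo <- sidecar$temp_min; hi <- sidecar$temp_max
    rasters <- lapply(rasters, function(f) f * (hi - lo) + lo)
  }
  d <- dim(rasters[[1L]])
  if (!all(vapply(rasters, function(m) identical(dim(m), d), logical(1L))))
    formatError("mixed frame geometries in '%s'", path)
  ts <- sidecar$timestamps
  fps <- sidecar$fps %||% (1 / median(diff(ts)))
  if (is.null(ts)) ts <- (seq_along(rasters) - 1L) / fps
  if (length(ts) != length(rasters))
    formatError("sidecar lists %d timestamps for %d frames",
                length(ts), length(rasters))
  if (any(diff(ts) <= 0))
    formatError("sidecar timestamps are not strictly increasing")
  ThermalFrameSequence(rasters, timestamps = ts, fps = fps)
}

#' Write a temperature series as CSV
#'
#' Two columns, `time_s` and `temp_c`; missing values are written as empty
#' cells.
#'
#' @param series A [TemperatureSeries-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeSeriesCsv <- function(series, path) {
  stopifnot(is(series, "TemperatureSeries"))
  df <- data.frame(time_s = series@times, temp_c = series@values)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a temperature series from CSV
#'
#' @param path CSV with columns `time_s`, `temp_c` (empty cells = missing).
#' @param label Region label to stamp on the series.
#' @param sampleId Sample identifier.
#' @return A [TemperatureSeries-class].
#' @export
readSeriesCsv <- function(path, label = "eye", sampleId = "sample") {
  df <- read.csv(path)
  if (!all(c("time_s", "temp_c") %in% names(df)))
    formatError("'%s' must have columns time_s and temp_c", path)
  new("TemperatureSeries", label = label, times = as.numeric(df$time_s),
      values = as.numeric(df$temp_c), sampleId = sampleId)
}
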