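#' Calibrated micrograph
#'
#' A single grayscale micrograph with its pixel scale and optional condition
#' metadata (sugar type, solid concentration, cooling rate, ...). Pixels are
#' stored as a plain numeric matrix `m[row, col]`, row 1 at the top.
#'
#' @param pixels numeric H x W matrix of gray levels.
#' @param pixel_scale pixel size in micrometres per pixel (> 0).
#' @param time_s optional acquisition time stamp in seconds.
#' @param meta optional named list of free-form condition metadata.
#' @return an object of class `micrograph`.
#' @export
micrograph <- function(pixels, pixel_scale, time_s = NULL, meta = list()) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("'pixels' must be a numeric matrix")
  if (nrow(pixels) < 16 || ncol(pixels) < 16)
    stop("micrograph must be at least 16 x 16 pixels")
  stopifnot_scalar(pixel_scale, "pixel_scale")
  if (pixel_scale <= 0) stop("'pixel_scale' must be > 0")
  structure(
    list(pixels = pixels, pixel_scale = pixel_scale,
         time_s = time_s, meta = meta),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("micrograph: %d x %d px, %.4g um/px", nrow(x$pixels),
              ncol(x$pixels), x$pixel_scale))
  if (!is.null(x$time_s)) cat(sprintf(", t = %g s", x$time_s))
  cat("\n")
  invisible(x)
}

# Accept either a micrograph or a bare matrix plus explicit scale.
as_micrograph <- function(img, pixel_scale = NULL) {
  if (inherits(img, "micrograph")) return(img)
  if (is.null(pixel_scale))
    stop("a bare matrix needs an explicit 'pixel_scale'")
  micrograph(img, pixel_scale)
}

#' Time-lapse frame sequence
#'
#' An ordered set of micrograph frames of the same field of view taken at
#' strictly increasing times (default cadence: one frame every 60 s).
#'
#' @param frames list of numeric H x W matrices, identical dimensions.
#' @param times_s numeric vector of acquisition times in seconds, strictly
#'   increasing, same length as `frames`.
#' @param pixel_scale micrometres per pixel.
#' @param meta optional named list of metadata.
#' @return an object of class `frame_sequence`.
#' @export
frame_sequence <- function(frames, times_s, pixel_scale, meta = list()) {
  if (!is.list(frames) || length(frames) < 1)
    stop("'frames' must be a non-empty list of matrices")
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all frames must share the same dimensions")
  if (length(times_s) != length(frames))
    stop("'times_s' must match the number of frames")
  if (any(diff(times_s) <= 0))
    stop("'times_s' must be strictly increasing")
  stopifnot_scalar(pixel_scale, "pixel_scale")
  if (pixel_scale <= 0) stop("'pixel_scale' must be > 0")
  structure(
    list(frames = frames, times_s = as.numeric(times_s),
         pixel_scale = pixel_scale, meta = meta),
    class = "frame_sequence"
  )
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("frame_sequence: %d frames, %d x %d px, t = %g..%g s\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              min(x$times_s), max(x$times_s)))
  invisible(x)
}

#' Read a grayscale micrograph from TIFF or PNG
#'
#' Multi-channel images are averaged to one gray channel.
#'
#' @param path file path ending in .tif/.tiff/.png.
#' @param pixel_scale micrometres per pixel.
#' @inheritParams micrograph
#' @return a [micrograph].
#' @export
read_micrograph <- function(path, pixel_scale, time_s = NULL, meta = list()) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    stop("unsupported image format: .", ext)
  )
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)
  micrograph(a, pixel_scale, time_s = time_s, meta = meta)
}

#' Write a grayscale image to TIFF or PNG
#'
#' Values are clipped to `[0, 1]`.
#' @param pixels numeric matrix or [micrograph].
#' @param path destination path (.tif/.tiff/.png).
#' @return `path`, invisibly.
#' @export
write_image <- function(pixels, path) {
  if (inherits(pixels, "micrograph")) pixels <- pixels$pixels
  m <- pmin(pmax(pixels, 0), 1)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(m, path, bits.per.sample = 16L),
    png = png::writePNG(m, path),
    stop("unsupported image format: .", ext)
  )
  invisible(path)
}

#' Write a labeled pore map as a 16-bit TIFF
#'
#' Integer labels are stored in the 16-bit sample values (label / 65535).
#' @param labels integer label matrix (0 = background).
#' @param path destination .tif path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels cannot be stored")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a labeled pore map written by [write_labels()]
#' @param path .tif path.
#' @return integer label matrix.
#' @export
read_labels <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(as.integer(round(m * 65535)), nrow = nrow(m))
}

#' Write a frame sequence as numbered PNGs plus a frame-time manifest
#'
#' Creates `frame_0001.png`, ... and `manifest.csv` with columns
#' `file,time_s,pixel_scale`.
#' @param fs a [frame_sequence].
#' @param dir output directory (created if missing).
#' @return the manifest path, invisibly.
#' @export
write_frame_sequence <- function(fs, dir) {
  stopifnot(inherits(fs, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("frame_%04d.png", seq_along(fs$frames))
  for (i in seq_along(fs$frames))
    write_image(fs$frames[[i]], file.path(dir, files[i]))
  manifest <- data.frame(file = files, time_s = fs$times_s,
                         pixel_scale = fs$pixel_scale)
  mpath <- file.path(dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}

#' Read a frame sequence from a directory with a manifest
#' @param dir directory containing images and `manifest.csv`.
#' @return a [frame_sequence].
#' @export
read_frame_sequence <- function(dir) {
  mpath <- file.path(dir, "manifest.csv")
  if (!file.exists(mpath)) stop("no manifest.csv in ", dir)
  manifest <- read.csv(mpath, stringsAsFactors = FALSE)
  frames <- lapply(file.path(dir, manifest$file), function(p) {
    read_micrograph(p, pixel_scale = manifest$pixel_scale[1])$pixels
  })
  frame_sequence(frames, manifest$time_s, manifest$pixel_scale[1])
}
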