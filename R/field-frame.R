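#' Create a field frame
#'
#' A `field_frame` is one raster from a microscopy recording: either a
#' single-channel intensity image (a numeric matrix) or an RGB image (a
#' height x width x 3 array), together with the physical scale of the
#' optics in micrometres per pixel and, for video input, the ordinal of
#' the frame within the recording.
#'
#' Pixel values live on the 8-bit scale \[0, 255\] (stored as doubles so
#' that intermediate results such as luminance need not be quantised).
#' Pixel coordinates are 0-based with the pixel-centre convention: pixel
#' `(x, y)` is centred at `x = column - 1`, `y = row - 1`.
#'
#' @param pixels numeric matrix (intensity) or height x width x 3 array
#'   (RGB) with values in \[0, 255\].
#' @param scale micrometres per pixel; must be > 0.
#' @param frame_index 0-based ordinal of the frame within a video; 0 for
#'   stills.
#' @return an object of class `field_frame`.
#' @examples
#' f <- field_frame(matrix(0, 64, 64), scale = 0.5)
#' dim(f)
#' @export
field_frame <- function(pixels, scale = 1, frame_index = 0L) {
  if (is.matrix(pixels)) {
    channels <- 1L
  } else if (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3) {
    channels <- 3L
  } else {
    stop("`pixels` must be a matrix (intensity) or an H x W x 3 array (RGB)")
  }
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1) stop("image must be at least 1 x 1")
  rng <- range(pixels)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 255) {
    stop("pixel values must lie in [0, 255] and contain no NA")
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("`scale` (um/pixel) must be a single positive number")
  }
  structure(
    list(
      pixels = pixels,
      scale = as.numeric(scale),
      frame_index = as.integer(frame_index),
      channels = channels
    ),
    class = "field_frame"
  )
}

#' @export
dim.field_frame <- function(x) dim(x$pixels)[1:2]

#' @export
print.field_frame <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<field_frame> %d x %d px, %s, %.4g um/px, frame %d\n",
    d[2], d[1], if (x$channels == 3) "RGB" else "intensity", x$scale, x$frame_index
  ))
  invisible(x)
}

#' @rdname field_frame
#' @param x object to test.
#' @export
is_field_frame <- function(x) inherits(x, "field_frame")

frame_width <- function(frame) dim(frame$pixels)[2]
frame_height <- function(frame) dim(frame$pixels)[1]

#' Read a still image as a field frame
#'
#' Reads PNG or TIFF rasters. Grayscale files become intensity frames;
#' colour files become RGB frames (an alpha channel, if present, is
#' dropped). Values are rescaled from the file's \[0, 1\] encoding to
#' \[0, 255\].
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams field_frame
#' @return a [field_frame()].
#' @export
read_field <- function(path, scale = 1, frame_index = 0L) {
  if (!file.exists(path)) stop("input image not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format '.", ext, "' (use PNG or TIFF): ", path)
  )
  if (length(dim(px)) == 3) {
    if (dim(px)[3] >= 3) {
      px <- px[, , 1:3, drop = FALSE]
    } else {
      px <- px[, , 1]
    }
  }
  field_frame(round(px * 255), scale = scale, frame_index = frame_index)
}

#' Write a field frame to disk
#'
#' @param frame a [field_frame()].
#' @param path output path ending in `.png`, `.tif` or `.tiff`.
#' @return `path`, invisibly.
#' @export
write_field <- function(frame, path) {
  stopifnot(is_field_frame(frame))
  px <- frame$pixels / 255
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(px, path),
    tif = ,
    tiff = tiff::writeTIFF(px, path),
    stop("unsupported output format '.", ext, "' (use PNG or TIFF)")
  )
  invisible(path)
}

#' Read a video as a sequence of field frames
#'
#' A "video" is a directory of numbered still frames (PNG or TIFF),
#' read in lexicographic order of their zero-padded names. Container
#' formats such as AVI are not decoded; pass such recordings through an
#' external frame extractor first and point `read_video()` at the
#' resulting frame directory.
#'
#' @param path directory containing the frame images.
#' @param scale micrometres per pixel.
#' @param fps frame rate, recorded on the result for time-axis labelling.
#' @return list of [field_frame()] with attributes `fps` and `source`.
#' @export
read_video <- function(path, scale = 1, fps = 25) {
  if (file.exists(path) && !dir.exists(path)) {
    stop(
      "cannot decode video container '", path,
      "': unsupported codec. Extract the frames to numbered PNG/TIFF files ",
      "and pass that frame directory instead."
    )
  }
  if (!dir.exists(path)) stop("video input not found: ", path)
  files <- sort(list.files(path, pattern = "\\.(png|tif|tiff)$",
                           ignore.case = TRUE, full.names = TRUE))
  if (length(files) == 0) stop("no frame images (PNG/TIFF) found in: ", path)
  frames <- lapply(seq_along(files), function(i) {
    read_field(files[[i]], scale = scale, frame_index = i - 1L)
  })
  attr(frames, "fps") <- fps
  attr(frames, "source") <- path
  frames
}

#' Write a sequence of frames as a video directory
#'
#' @param frames list of [field_frame()].
#' @param path output directory (created if needed); frames are written
#'   as zero-padded `frame_0000.png`, ...
#' @return `path`, invisibly.
#' @export
write_video <- function(frames, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(frames)) {
    write_field(frames[[i]], file.path(path, sprintf("frame_%04d.png", i - 1L)))
  }
  invisible(path)
}
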