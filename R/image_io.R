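#' @keywords internal
round_half_up <- function(x) floor(x + 0.5)

#' Coerce a numeric array to an 8-bit RGB image
#'
#' The package works on plain integer arrays of dimension rows x cols x 3 with
#' values in \[0, 255\], channel order R, G, B. This coercer accepts:
#' \itemize{
#'   \item an existing \code{rgb_image} (returned unchanged);
#'   \item a rows x cols x 3 (or x 4, alpha dropped with a warning) array of
#'     doubles in \[0, 1\], as returned by the png/tiff/jpeg readers — scaled
#'     to \[0, 255\] and rounded half-up;
#'   \item an integer-valued array already in \[0, 255\] — passed through;
#'   \item any other numeric array — linearly rescaled to \[0, 255\] with a
#'     warning (non-8-bit input).
#' }
#'
#' @param x numeric array.
#' @return an \code{rgb_image}: integer array rows x cols x 3 in \[0, 255\].
#' @export
as_rgb_image <- function(x) {
  if (inherits(x, "rgb_image")) return(x)
  if (is.null(dim(x)) || length(dim(x)) != 3L)
    stop("expected a rows x cols x channels array", call. = FALSE)
  d <- dim(x)
  if (d[1] < 1L || d[2] < 1L || length(x) == 0L) stop("empty input", call. = FALSE)
  if (d[3] == 4L) {
    warning("alpha channel dropped", call. = FALSE)
    x <- x[, , 1:3, drop = FALSE]
  } else if (d[3] != 3L) {
    stop("expected 3 (or 4, RGBA) channels, got ", d[3], call. = FALSE)
  }
  if (anyNA(x)) stop("NA pixel values", call. = FALSE)
  mx <- max(x); mn <- min(x)
  if (mn >= 0 && mx <= 1 && !all(x == trunc(x))) {
    x <- round_half_up(x * 255)
  } else if (mn >= 0 && mx <= 255 && all(x == trunc(x))) {
    # 8-bit passthrough
  } else {
    warning("input not 8-bit; rescaled to [0, 255]", call. = FALSE)
    if (mx > mn) x <- (x - mn) / (mx - mn) * 255 else x <- x * 0
    x <- round_half_up(x)
  }
  storage.mode(x) <- "integer"
  structure(x, class = "rgb_image")
}

#' Read an RGB raster from PNG, TIFF or JPEG
#'
#' @param path file path; format inferred from the extension.
#' @return an \code{rgb_image}.
#' @export
read_rgb_image <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format '.", ext, "' (use PNG, TIFF or JPEG)", call. = FALSE)
  )
  if (length(dim(raw)) == 2L) dim(raw) <- c(dim(raw), 1L)
  if (dim(raw)[3] == 1L)
    stop("grayscale image: the method needs three color channels", call. = FALSE)
  as_rgb_image(raw)
}

#' Write an RGB image as PNG
#'
#' @param image an \code{rgb_image}.
#' @param path output path.
#' @export
write_rgb_png <- function(image, path) {
  image <- as_rgb_image(image)
  png::writePNG(unclass(image) / 255, path)
  invisible(path)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d, 8-bit RGB, range [%d, %d]\n",
              d[1], d[2], min(x), max(x)))
  invisible(x)
}
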