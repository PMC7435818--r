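#' Convert an RGB image to its luma raster
#'
#' Per-pixel weighted sum L = 0.299 R + 0.587 G + 0.114 B, rounded half-up to
#' the nearest integer. The rounding rule matters: the trough thresholds are
#' located on the luma histogram, so it is fixed package-wide.
#'
#' @param image an \code{rgb_image} (or coercible).
#' @return integer matrix rows x cols with values in \[0, 255\].
#' @export
to_luma <- function(image) {
  image <- as_rgb_image(image)
  l <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  l <- round_half_up(l)
  storage.mode(l) <- "integer"
  l
}

#' Extract the energy spectrum of an image
#'
#' The "energy" of a color channel is its 256-bin gray-level histogram: the
#' count of pixels at each gray level h in 0..255. The luma histogram is
#' computed alongside; the adaptive filter locates its troughs.
#'
#' @param image an \code{rgb_image} (or coercible).
#' @return an \code{energy_spectrum}: list with integer count vectors
#'   \code{R}, \code{G}, \code{B}, \code{luma} (length 256, bin i holds gray
#'   level i-1), pixel count \code{n_pixels}, and filter state.
#' @export
compute_energy <- function(image) {
  image <- as_rgb_image(image)
  tally <- function(v) tabulate(as.integer(v) + 1L, nbins = 256L)
  structure(list(
    R = tally(image[, , 1]),
    G = tally(image[, , 2]),
    B = tally(image[, , 3]),
    luma = tally(to_luma(image)),
    n_pixels = prod(dim(image)[1:2]),
    filtered = FALSE,
    thresholds = NULL
  ), class = "energy_spectrum")
}

#' @export
print.energy_spectrum <- function(x, ...) {
  cat(sprintf("<energy_spectrum> %d pixels%s\n", x$n_pixels,
              if (x$filtered) sprintf(", filtered to band (%d, %d)",
                                      x$thresholds$T1, x$thresholds$T2) else ""))
  invisible(x)
}

#' Export an energy spectrum as CSV
#'
#' One row per gray level (0..255), columns \code{h, R, G, B, luma}.
#'
#' @param spectrum an \code{energy_spectrum}.
#' @param path output path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  df <- data.frame(h = 0:255, R = spectrum$R, G = spectrum$G,
                   B = spectrum$B, luma = spectrum$luma)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read an energy spectrum written by \code{write_spectrum_csv}
#'
#' @param path CSV path.
#' @return an \code{energy_spectrum} (filter state not preserved).
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(nrow(df) == 256L, all(c("h", "R", "G", "B", "luma") %in% names(df)))
  structure(list(R = as.integer(df$R), G = as.integer(df$G),
                 B = as.integer(df$B), luma = as.integer(df$luma),
                 n_pixels = sum(df$luma), filtered = FALSE, thresholds = NULL),
            class = "energy_spectrum")
}
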