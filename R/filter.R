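#' Construct a pair of filter thresholds
#'
#' @param T1 left trough gray level, in \[0, 125\].
#' @param T2 right trough gray level, in \[126, 255\].
#' @return a \code{filter_thresholds} object.
#' @export
filter_thresholds <- function(T1, T2) {
  T1 <- as.integer(T1); T2 <- as.integer(T2)
  if (!(T1 >= 0L && T1 <= 125L && T2 >= 126L && T2 <= 255L))
    stop("thresholds out of range: need 0 <= T1 <= 125 < T2 <= 255", call. = FALSE)
  if (T2 - T1 < 2L) stop("degenerate histogram: empty retained band", call. = FALSE)
  structure(list(T1 = T1, T2 = T2), class = "filter_thresholds")
}

#' Locate the two troughs of the luma histogram
#'
#' Tea images on a white conveyor produce a luma histogram with up to three
#' masses: dark leaf-overlap shadows, the leaf body, and the bright
#' background. The filter thresholds are the gray levels minimizing the luma
#' count over the low range h in \[0, 125\] (T1) and the high range
#' h in \[126, 255\] (T2); ties go to the smallest gray level. The band
#' strictly between them is taken as genuine leaf information.
#'
#' @param spectrum an \code{energy_spectrum} of the whole image (background
#'   included — that is what creates the background trough).
#' @return a \code{filter_thresholds} object.
#' @export
find_thresholds <- function(spectrum) {
  stopifnot(inherits(spectrum, "energy_spectrum"))
  luma <- spectrum$luma
  if (all(luma == 0L)) stop("all-zero luma histogram", call. = FALSE)
  if (sum(luma > 0L) == 1L)
    stop("degenerate histogram: all luma mass at one gray level", call. = FALSE)
  t1 <- which.min(luma[1:126]) - 1L          # h in [0, 125]; which.min = first/smallest h
  t2 <- 125L + which.min(luma[127:256])      # h in [126, 255]
  filter_thresholds(t1, t2)
}

#' Zero out energy outside the retained band
#'
#' For each color channel, bins at gray levels h <= T1 and h >= T2 are set to
#' zero; bins strictly inside (T1, T2) are untouched. The luma histogram is
#' kept unmodified for diagnostics. Idempotent.
#'
#' @param spectrum an \code{energy_spectrum}.
#' @param thresholds a \code{filter_thresholds} object.
#' @return the filtered \code{energy_spectrum}.
#' @export
apply_filter <- function(spectrum, thresholds) {
  stopifnot(inherits(spectrum, "energy_spectrum"),
            inherits(thresholds, "filter_thresholds"))
  h <- 0:255
  kill <- h <= thresholds$T1 | h >= thresholds$T2
  for (ch in c("R", "G", "B")) spectrum[[ch]][kill] <- 0L
  spectrum$filtered <- TRUE
  spectrum$thresholds <- thresholds
  spectrum
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat(sprintf("<filter_thresholds> T1 = %d, T2 = %d (retained band %d..%d)\n",
              x$T1, x$T2, x$T1 + 1L, x$T2 - 1L))
  invisible(x)
}
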