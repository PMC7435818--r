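#' Pipeline configuration
#'
#' Collects every tunable of the feature pipeline and the decision rule.
#' Defaults follow the method's reference settings: mapping constants
#' H = 800, s = 700, S = 25000; attention window half-width n = 2; decision
#' weight alpha = 0.2. The remaining switches select between numerically
#' equivalent readings of the published formulas:
#' \itemize{
#'   \item \code{int_mode}: how the mapping's integer cast is performed —
#'     \code{"round"} (half-up, default) or \code{"floor"}; they differ by at
#'     most one count unit.
#'   \item \code{distance_mode}: \code{"euclidean"} (plain L2 between centers,
#'     default — this is what reproduces the reference distance tables) or
#'     \code{"literal"} (a 0.5 prefactor on each distance).
#'   \item \code{window_mode}: when the attention window of 2n+1 bins is
#'     clipped by the band edge, divide by the number of bins actually used
#'     (\code{"clipped"}, default — avoids deflating edge peaks) or always by
#'     2n+1 (\code{"strict"}).
#'   \item \code{x_scale}, \code{y_scale}: optional per-axis scales applied to
#'     mapped points; the decision rule is relative, so any consistent
#'     rescaling yields the same verdicts.
#' }
#'
#' @param H vertical mapping range; mapped y lies in \[0, H\].
#' @param s,S scaling numerator/denominator: y = H - int(n_ave * s / S).
#' @param n attention window half-width in gray levels (n >= 0).
#' @param alpha decision weight: a batch is normal iff
#'   |sum_S - sum_M| < alpha * sum_S.
#' @param x_scale,y_scale per-axis scales on mapped points.
#' @param int_mode "round" or "floor".
#' @param distance_mode "euclidean" or "literal".
#' @param window_mode "clipped" or "strict".
#' @return a \code{mapping_config} object.
#' @export
mapping_config <- function(H = 800, s = 700, S = 25000, n = 2, alpha = 0.2,
                           x_scale = 1, y_scale = 1,
                           int_mode = c("round", "floor"),
                           distance_mode = c("euclidean", "literal"),
                           window_mode = c("clipped", "strict")) {
  stopifnot(H > 0, s > 0, S > 0, n >= 0, alpha > 0, x_scale > 0, y_scale > 0)
  structure(list(H = as.numeric(H), s = as.numeric(s), S = as.numeric(S),
                 n = as.integer(n), alpha = as.numeric(alpha),
                 x_scale = as.numeric(x_scale), y_scale = as.numeric(y_scale),
                 int_mode = match.arg(int_mode),
                 distance_mode = match.arg(distance_mode),
                 window_mode = match.arg(window_mode)),
            class = "mapping_config")
}

#' @export
print.mapping_config <- function(x, ...) {
  cat(sprintf(paste0("<mapping_config> H=%g s=%g S=%g n=%d alpha=%g ",
                     "scales=(%g,%g) int=%s dist=%s window=%s\n"),
              x$H, x$s, x$S, x$n, x$alpha, x$x_scale, x$y_scale,
              x$int_mode, x$distance_mode, x$window_mode))
  invisible(x)
}

config_equal <- function(a, b) {
  fields <- c("H", "s", "S", "n", "alpha", "x_scale", "y_scale",
              "int_mode", "distance_mode", "window_mode")
  all(vapply(fields, function(f) identical(a[[f]], b[[f]]), logical(1)))
}

#' Locate a channel's attention peak in the retained band
#'
#' The attention point of a channel is the gray level with the largest pixel
#' count inside the retained band (T1, T2) — ties to the smallest gray level —
#' together with the mean count over the window of gray levels
#' \[h* - n, h* + n\] intersected with the band.
#'
#' @param filtered a filtered \code{energy_spectrum}.
#' @param thresholds the \code{filter_thresholds} used.
#' @param channel one of "R", "G", "B".
#' @param n window half-width; n = 0 degenerates to the peak count itself.
#' @param window_mode see \code{\link{mapping_config}}.
#' @return an \code{attention_point}: list(channel, h_star, n_ave).
#' @export
attention_peak <- function(filtered, thresholds, channel = c("R", "G", "B"),
                           n = 2, window_mode = c("clipped", "strict")) {
  stopifnot(inherits(filtered, "energy_spectrum"),
            inherits(thresholds, "filter_thresholds"), n >= 0)
  channel <- match.arg(channel)
  window_mode <- match.arg(window_mode)
  counts <- filtered[[channel]]
  band <- (thresholds$T1 + 1L):(thresholds$T2 - 1L)   # gray levels, open interval
  in_band <- counts[band + 1L]
  if (all(in_band == 0L)) stop("no tea energy in band", call. = FALSE)
  h_star <- band[which.max(in_band)]                  # first max = smallest h
  window <- intersect((h_star - n):(h_star + n), band)
  divisor <- if (window_mode == "clipped") length(window) else 2 * n + 1
  n_ave <- sum(counts[window + 1L]) / divisor
  structure(list(channel = channel, h_star = h_star, n_ave = n_ave),
            class = "attention_point")
}

#' Map an attention point to a 2-D feature point
#'
#' x is the peak gray level; y = H - int(n_ave * s / S), clamped at 0, so a
#' brighter (higher-count) peak maps lower on the plot. Optional per-axis
#' scales are applied last.
#'
#' @param point an \code{attention_point}.
#' @param config a \code{mapping_config}.
#' @return numeric length-2 vector c(x, y).
#' @export
map_point <- function(point, config = mapping_config()) {
  stopifnot(inherits(point, "attention_point"), inherits(config, "mapping_config"))
  int_cast <- if (config$int_mode == "round") round_half_up else floor
  y <- config$H - int_cast(point$n_ave * config$s / config$S)
  y <- max(y, 0)
  c(x = point$h_star * config$x_scale, y = y * config$y_scale)
}

#' Run the full per-image feature pipeline
#'
#' Composition of histogram extraction, trough thresholding, band filtering,
#' and per-channel attention + mapping. The result is one 2-D feature point
#' per color channel.
#'
#' @param image an \code{rgb_image} (or coercible).
#' @param config a \code{mapping_config}.
#' @param id optional image identifier attached to errors and diagnostics.
#' @return a \code{mapped_triple}: list with \code{points} (3 x 2 matrix,
#'   rows R/G/B, columns x/y), \code{thresholds}, per-channel \code{peaks},
#'   the \code{config}, and \code{id}.
#' @export
process_image <- function(image, config = mapping_config(), id = NULL) {
  run <- function() {
    spec <- compute_energy(image)
    thr <- find_thresholds(spec)
    filt <- apply_filter(spec, thr)
    peaks <- lapply(c(R = "R", G = "G", B = "B"), function(ch)
      attention_peak(filt, thr, ch, n = config$n, window_mode = config$window_mode))
    pts <- t(vapply(peaks, map_point, numeric(2), config = config))
    colnames(pts) <- c("x", "y")
    structure(list(points = pts, thresholds = thr, peaks = peaks,
                   config = config, id = id),
              class = "mapped_triple")
  }
  if (is.null(id)) return(run())
  tryCatch(run(), error = function(e)
    stop("image '", id, "': ", conditionMessage(e), call. = FALSE))
}

#' @export
print.mapped_triple <- function(x, ...) {
  cat(sprintf("<mapped_triple>%s T1=%d T2=%d\n",
              if (is.null(x$id)) "" else paste0(" [", x$id, "]"),
              x$thresholds$T1, x$thresholds$T2))
  print(round(x$points, 2))
  invisible(x)
}
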