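# Run code under a fixed RNG seed without disturbing the caller's stream.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed for item i of a batch, kept inside 32-bit range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + i * 104729) %% 2147483629)
}

#' Default foreground channel-mean schedule
#'
#' Per-channel mean gray levels of the leaf foreground as a function of the
#' fixation degree d in \[0, 1\]: linear interpolation from (R, G, B) =
#' (70, 102, 72) at d = 0 (under-fixed: bright, green-dominant) to
#' (56, 57, 56) at d = 1 (fully fixed: darker, channels converged). These
#' endpoints are the attention gray levels observed at the earliest and
#' latest fixation times in the bundled reference data, so the generator's
#' trajectory mirrors the darkening and convergence seen in real pan-fired
#' green tea.
#'
#' @param degree fixation degree in \[0, 1\].
#' @return named numeric vector c(R=, G=, B=).
#' @export
channel_means <- function(degree) {
  stopifnot(degree >= 0, degree <= 1)
  (1 - degree) * c(R = 70, G = 102, B = 72) + degree * c(R = 56, G = 57, B = 56)
}

#' Parameters of the synthetic tea-image generator
#'
#' Describes a simplified tea-fixation scene: a near-white conveyor
#' background, elliptical leaf blobs whose per-channel gray levels follow
#' \code{channel_means(degree)}, and small near-black patches where leaves
#' overlap and shadow each other. This reproduces the luma-histogram
#' structure the adaptive filter assumes (dark overlap mass, mid-gray leaf
#' mass, bright background mass) without any claim of photorealism — the
#' pipeline only ever sees histograms.
#'
#' @param degree fixation degree in \[0, 1\].
#' @param rows,cols image size in pixels.
#' @param background_level mean background gray (near-white conveyor).
#' @param foreground_fraction target fraction of pixels covered by leaves.
#' @param overlap_fraction fraction of the foreground that is dark overlap;
#'   must be <= 1 (overlap cannot exceed the foreground).
#' @param channel_sds per-channel foreground standard deviations.
#' @param noise_sd background noise standard deviation.
#' @param seed RNG seed; the same params generate bit-identical images.
#' @return a \code{generator_params} object.
#' @export
generator_params <- function(degree = 0, rows = 120, cols = 160,
                             background_level = 245,
                             foreground_fraction = 0.5,
                             overlap_fraction = 0.08,
                             channel_sds = c(8, 8, 8), noise_sd = 6,
                             seed = 1L) {
  stopifnot(degree >= 0, degree <= 1, rows >= 8, cols >= 8,
            background_level > 125, background_level <= 255,
            foreground_fraction > 0, foreground_fraction <= 1,
            overlap_fraction >= 0, noise_sd > 0, all(channel_sds > 0))
  if (overlap_fraction > 1)
    stop("overlap_fraction exceeds the foreground", call. = FALSE)
  means <- channel_means(degree)
  if (any(means <= 0) || any(means >= 125))
    stop("foreground channel means must lie in (0, 125)", call. = FALSE)
  structure(list(degree = degree, rows = as.integer(rows), cols = as.integer(cols),
                 background_level = background_level,
                 foreground_fraction = foreground_fraction,
                 overlap_fraction = overlap_fraction,
                 channel_means = means, channel_sds = channel_sds,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "generator_params")
}

# Logical mask of one random ellipse on a rows x cols grid.
random_ellipse_mask <- function(rows, cols, min_ax = 0.06, max_ax = 0.22) {
  cx <- stats::runif(1, 1, cols); cy <- stats::runif(1, 1, rows)
  a <- stats::runif(1, min_ax, max_ax) * cols
  b <- stats::runif(1, min_ax, max_ax) * rows
  th <- stats::runif(1, 0, pi)
  x <- matrix(seq_len(cols), rows, cols, byrow = TRUE) - cx
  y <- matrix(seq_len(rows), rows, cols) - cy
  u <- x * cos(th) + y * sin(th)
  v <- -x * sin(th) + y * cos(th)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one synthetic tea image
#'
#' Deterministic given the seed in \code{params}. Leaf ellipses are added
#' until the target foreground coverage is reached; overlap patches are small
#' ellipses clipped to the foreground, filled with a neutral shadow gray
#' (clipped Gaussian around gray 14, never above 45).
#'
#' @param params a \code{generator_params} object.
#' @return an \code{rgb_image}.
#' @export
generate_image <- function(params) {
  stopifnot(inherits(params, "generator_params"))
  with_seed(params$seed, {
    rows <- params$rows; cols <- params$cols; npx <- rows * cols
    clip8 <- function(x) pmin(pmax(round_half_up(x), 0), 255)

    img <- array(0L, c(rows, cols, 3))
    for (c in 1:3)
      img[, , c] <- clip8(stats::rnorm(npx, params$background_level, params$noise_sd))

    fg <- matrix(FALSE, rows, cols)
    it <- 0L
    while (mean(fg) < params$foreground_fraction && it < 400L) {
      fg <- fg | random_ellipse_mask(rows, cols)
      it <- it + 1L
    }
    nfg <- sum(fg)
    for (c in 1:3) {
      ch <- img[, , c]
      ch[fg] <- clip8(stats::rnorm(nfg, params$channel_means[c], params$channel_sds[c]))
      img[, , c] <- ch
    }

    ov <- matrix(FALSE, rows, cols)
    target <- params$overlap_fraction * nfg
    it <- 0L
    while (sum(ov) < target && it < 400L) {
      ov <- ov | (random_ellipse_mask(rows, cols, 0.02, 0.07) & fg)
      it <- it + 1L
    }
    nov <- sum(ov)
    if (nov > 0) {
      # gray shadow: one value per pixel, equal across channels, mass reaching
      # gray 0 so the low-range trough sits between the overlap and leaf modes
      g <- clip8(pmin(stats::rnorm(nov, 14, 7), 45))
      for (c in 1:3) {
        ch <- img[, , c]
        ch[ov] <- g
        img[, , c] <- ch
      }
    }
    as_rgb_image(img)
  })
}

#' Generate a reproducible batch of synthetic tea images
#'
#' Image i uses a sub-seed derived deterministically from the master seed, so
#' batches are reproducible and images within a batch are independent draws.
#'
#' @param params a \code{generator_params} object (its seed is the master seed).
#' @param n_images number of images, >= 1.
#' @return list of \code{rgb_image}.
#' @export
generate_batch <- function(params, n_images) {
  stopifnot(inherits(params, "generator_params"), n_images >= 1)
  lapply(seq_len(n_images), function(i) {
    p <- params
    p$seed <- derive_seed(params$seed, i)
    generate_image(p)
  })
}
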