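#' Pairwise distances between the three channel centers
#'
#' The three centers (R, G, B) form a triangle in feature space whose
#' perimeter shrinks as fixation progresses; its total pairwise distance is
#' the monitored statistic. Distances are plain Euclidean by default;
#' \code{distance_mode = "literal"} applies a 0.5 prefactor to each (a
#' uniform rescaling, so verdicts are unchanged).
#'
#' @param centers 3 x 2 numeric matrix with rows R, G, B.
#' @param distance_mode "euclidean" or "literal".
#' @return a \code{distance_summary}: list(d_RG, d_RB, d_GB, sum).
#' @export
pairwise_center_distances <- function(centers,
                                      distance_mode = c("euclidean", "literal")) {
  distance_mode <- match.arg(distance_mode)
  centers <- rbind(centers)
  stopifnot(nrow(centers) == 3L, ncol(centers) == 2L, all(is.finite(centers)))
  pre <- if (distance_mode == "literal") 0.5 else 1
  d <- function(i, j) pre * sqrt(sum((centers[i, ] - centers[j, ])^2))
  out <- list(d_RG = d(1, 2), d_RB = d(1, 3), d_GB = d(2, 3))
  out$sum <- out$d_RG + out$d_RB + out$d_GB
  structure(out, class = "distance_summary")
}

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("<distance_summary> R-G=%.4f R-B=%.4f G-B=%.4f sum=%.4f\n",
              x$d_RG, x$d_RB, x$d_GB, x$sum))
  invisible(x)
}

#' Normal/abnormal decision from standard and monitoring distance sums
#'
#' The monitored batch is normal iff the deviation |sum_S - sum_M| is
#' strictly below the tolerance alpha * sum_S; equality at the boundary is
#' abnormal.
#'
#' @param sum_s total center distance of the trained (standard) model; > 0.
#' @param sum_m total center distance of the monitoring batch.
#' @param alpha tolerance weight (default 0.2).
#' @return a \code{decision}: list(verdict, sum_s, sum_m, alpha, threshold,
#'   deviation).
#' @export
decide <- function(sum_s, sum_m, alpha = 0.2) {
  stopifnot(alpha > 0, is.finite(sum_m), sum_m >= 0)
  if (!is.finite(sum_s) || sum_s <= 0)
    stop("untrained or degenerate model: sum_S must be positive", call. = FALSE)
  deviation <- abs(sum_s - sum_m)
  threshold <- alpha * sum_s
  structure(list(
    verdict = if (deviation < threshold) "normal" else "abnormal",
    sum_s = sum_s, sum_m = sum_m, alpha = alpha,
    threshold = threshold, deviation = deviation
  ), class = "decision")
}

#' @export
print.decision <- function(x, ...) {
  cat(sprintf("<decision> %s  (|sum_S - sum_M| = %.4f vs alpha*sum_S = %.4f)\n",
              toupper(x$verdict), x$deviation, x$threshold))
  invisible(x)
}

#' Monitor a batch of images against a trained model
#'
#' Runs the feature pipeline on every image, averages the per-channel points
#' into monitoring centers, computes their total pairwise distance sum_M, and
#' applies the decision rule. Images that fail the pipeline (e.g. degenerate
#' histograms) are skipped with a warning; the batch errors only if no image
#' survives.
#'
#' @param images list of \code{rgb_image} (or coercibles).
#' @param model a \code{trained_model}.
#' @param ids optional character vector of image identifiers for diagnostics.
#' @return a \code{decision} with a \code{report} attribute: list(centers,
#'   distances, triples, n_used, n_failed, failures).
#' @export
monitor_set <- function(images, model, ids = NULL) {
  stopifnot(inherits(model, "trained_model"), length(images) >= 1L)
  if (is.null(ids)) ids <- sprintf("image_%03d", seq_along(images))
  stopifnot(length(ids) == length(images))
  triples <- list(); failures <- character()
  for (i in seq_along(images)) {
    tr <- tryCatch(process_image(images[[i]], config = model$config, id = ids[[i]]),
                   error = function(e) {
                     warning(conditionMessage(e), call. = FALSE)
                     NULL
                   })
    if (is.null(tr)) failures <- c(failures, ids[[i]]) else triples[[length(triples) + 1L]] <- tr
  }
  if (length(triples) == 0L)
    stop("no usable images in monitoring set", call. = FALSE)
  centers <- Reduce(`+`, lapply(triples, `[[`, "points")) / length(triples)
  distances <- pairwise_center_distances(centers,
                                         distance_mode = model$config$distance_mode)
  dec <- decide(model$sum_s, distances$sum, alpha = model$config$alpha)
  attr(dec, "report") <- list(centers = centers, distances = distances,
                              triples = triples, n_used = length(triples),
                              n_failed = length(failures), failures = failures)
  dec
}
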