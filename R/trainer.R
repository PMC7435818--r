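#' Sum of squared Euclidean distances to a center
#'
#' The clustering objective: the per-channel center is the point minimizing
#' this over the training points, which for squared L2 is their mean.
#'
#' @param points n x 2 numeric matrix of feature points.
#' @param center length-2 numeric center.
#' @return non-negative scalar.
#' @export
sse <- function(points, center) {
  points <- rbind(points)
  stopifnot(nrow(points) >= 1L, ncol(points) == 2L, length(center) == 2L)
  sum((points[, 1] - center[1])^2 + (points[, 2] - center[2])^2)
}

#' Train per-channel cluster centers from a batch of mapped triples
#'
#' Each channel's center is the arithmetic mean of that channel's feature
#' points over all training images — the SSE-optimal centroid. The model
#' stores the centers, their total pairwise distance sum_S (the standard the
#' decision rule compares against), and a snapshot of the configuration.
#'
#' @param triples list of \code{mapped_triple}, all produced under the same
#'   \code{mapping_config}.
#' @param label state label of the training batch, e.g. "6 min".
#' @return a \code{trained_model}.
#' @export
train_centers <- function(triples, label = "standard") {
  if (length(triples) < 1L) stop("empty training batch", call. = FALSE)
  stopifnot(all(vapply(triples, inherits, logical(1), "mapped_triple")))
  cfg <- triples[[1]]$config
  if (!all(vapply(triples, function(tr) config_equal(tr$config, cfg), logical(1))))
    stop("mixed configurations in training batch", call. = FALSE)
  centers <- Reduce(`+`, lapply(triples, `[[`, "points")) / length(triples)
  dist_sum <- pairwise_center_distances(centers, distance_mode = cfg$distance_mode)
  structure(list(schema_version = 1L, label = label, centers = centers,
                 distances = dist_sum, sum_s = dist_sum$sum,
                 n_train = length(triples), config = cfg,
                 created = format(Sys.time(), tz = "UTC")),
            class = "trained_model")
}

#' @export
print.trained_model <- function(x, ...) {
  cat(sprintf("<trained_model> label='%s' n_train=%d sum_S=%.4f\n",
              x$label, x$n_train, x$sum_s))
  print(round(x$centers, 3))
  invisible(x)
}

#' Save a trained model as JSON
#'
#' Numbers are written at full double precision so that load reproduces the
#' centers and sum_S exactly.
#'
#' @param model a \code{trained_model}.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  out <- list(
    schema_version = model$schema_version,
    label = model$label,
    centers = list(R = unname(model$centers["R", ]),
                   G = unname(model$centers["G", ]),
                   B = unname(model$centers["B", ])),
    distances = model$distances[c("d_RG", "d_RB", "d_GB", "sum")],
    sum_s = model$sum_s,
    n_train = model$n_train,
    config = unclass(model$config),
    created = model$created
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Load a trained model saved by \code{save_model}
#'
#' @param path JSON path.
#' @return a \code{trained_model}.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file '", path, "' not found", call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(raw$schema_version) || raw$schema_version != 1L)
    stop("unsupported model schema", call. = FALSE)
  centers <- rbind(R = raw$centers$R, G = raw$centers$G, B = raw$centers$B)
  colnames(centers) <- c("x", "y")
  cfg <- do.call(mapping_config, raw$config[c("H", "s", "S", "n", "alpha",
                                              "x_scale", "y_scale", "int_mode",
                                              "distance_mode", "window_mode")])
  dist_sum <- structure(as.list(raw$distances), class = "distance_summary")
  structure(list(schema_version = 1L, label = raw$label, centers = centers,
                 distances = dist_sum, sum_s = raw$sum_s,
                 n_train = as.integer(raw$n_train), config = cfg,
                 created = raw$created),
            class = "trained_model")
}

#' Reference cluster-center statistics for green-tea fixation
#'
#' Per-channel cluster-center coordinates, attention gray levels h and mapped
#' values f reported for pan-fixation of green tea at 2, 4, 6 and 8 minutes
#' (220 °C, drum fixation; 700 training images per time). The center
#' coordinates are in the normalized plotting units of the original report;
#' distances between them are what the decision rule consumes, and those are
#' scale-consistent. Bundled for validation and as a worked example.
#'
#' @return data.frame with columns \code{label}, \code{x_R}, \code{y_R},
#'   \code{x_G}, \code{y_G}, \code{x_B}, \code{y_B}, \code{h_R}, \code{h_G},
#'   \code{h_B}, \code{f_R}, \code{f_G}, \code{f_B}.
#' @export
reference_centers <- function() {
  path <- system.file("extdata", "reference_centers.csv", package = "teafix",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = FALSE)
}

#' Distance table from a set of center rows
#'
#' For each row of a centers data.frame (as returned by
#' \code{\link{reference_centers}}), computes the three pairwise center
#' distances rounded to \code{digits} decimals and their sum \emph{of the
#' rounded values} — the convention of the reference report's printed tables.
#'
#' @param centers_df data.frame with columns x_R, y_R, x_G, y_G, x_B, y_B and
#'   a label column.
#' @param digits rounding for the printed-table convention; NULL for raw.
#' @param distance_mode see \code{\link{mapping_config}}.
#' @return data.frame with columns label, d_RG, d_RB, d_GB, sum.
#' @export
distance_table <- function(centers_df, digits = 2,
                           distance_mode = c("euclidean", "literal")) {
  distance_mode <- match.arg(distance_mode)
  rows <- lapply(seq_len(nrow(centers_df)), function(i) {
    r <- centers_df[i, ]
    centers <- rbind(R = c(r$x_R, r$y_R), G = c(r$x_G, r$y_G), B = c(r$x_B, r$y_B))
    colnames(centers) <- c("x", "y")
    d <- pairwise_center_distances(centers, distance_mode = distance_mode)
    v <- c(d$d_RG, d$d_RB, d$d_GB)
    if (!is.null(digits)) v <- round(v, digits)
    data.frame(label = r$label, d_RG = v[1], d_RB = v[2], d_GB = v[3],
               sum = sum(v))
  })
  do.call(rbind, rows)
}
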