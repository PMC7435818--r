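# Shared fixtures and independent oracles, built in code.

# uniform random 8-bit RGB image
random_image <- function(rows, cols, seed) {
  set.seed(seed)
  as_rgb_image(array(sample(0:255, rows * cols * 3, replace = TRUE),
                     c(rows, cols, 3)))
}

# naive double-loop tally: the histogram oracle
naive_tally <- function(mat) {
  counts <- integer(256)
  for (i in seq_len(nrow(mat)))
    for (j in seq_len(ncol(mat)))
      counts[mat[i, j] + 1L] <- counts[mat[i, j] + 1L] + 1L
  counts
}

# exhaustive argmin/argmax over gray levels, smallest-h ties
scan_argmin <- function(counts, h_range) {
  best <- h_range[1]
  for (h in h_range) if (counts[h + 1L] < counts[best + 1L]) best <- h
  best
}
scan_argmax <- function(counts, h_range) {
  best <- h_range[1]
  for (h in h_range) if (counts[h + 1L] > counts[best + 1L]) best <- h
  best
}

# build an energy_spectrum directly from count vectors
make_spectrum <- function(R = integer(256), G = integer(256), B = integer(256),
                          luma = integer(256)) {
  structure(list(R = as.integer(R), G = as.integer(G), B = as.integer(B),
                 luma = as.integer(luma), n_pixels = sum(luma),
                 filtered = FALSE, thresholds = NULL),
            class = "energy_spectrum")
}

# build a mapped_triple directly from a 3x2 point matrix
make_triple <- function(points, config = mapping_config(), id = NULL) {
  rownames(points) <- c("R", "G", "B")
  colnames(points) <- c("x", "y")
  structure(list(points = points, thresholds = filter_thresholds(10, 200),
                 peaks = NULL, config = config, id = id),
            class = "mapped_triple")
}

# geometric transforms of an rgb_image (channel-wise)
rot90_image <- function(img) {
  a <- unclass(img)
  out <- array(0L, c(dim(a)[2], dim(a)[1], 3))
  for (c in 1:3) out[, , c] <- t(a[dim(a)[1]:1, , c])
  as_rgb_image(out)
}
flip_image <- function(img) {
  a <- unclass(img)
  as_rgb_image(a[dim(a)[1]:1, , , drop = FALSE])
}

# printed reference distance table (three distances + sum at four times)
reference_distance_table <- function() {
  data.frame(
    label = c("2 min", "4 min", "6 min", "8 min"),
    d_RG = c(0.25, 0.16, 0.09, 0.04),
    d_RB = c(0.44, 0.38, 0.30, 0.20),
    d_GB = c(0.61, 0.50, 0.36, 0.21),
    sum  = c(1.30, 1.04, 0.75, 0.45)
  )
}
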