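test_that("attention peak degenerates to the single peak bin when n = 0", {
  R <- integer(256); R[100 + 1L] <- 500L
  spec <- make_spectrum(R = R, luma = rep(1L, 256))
  t <- filter_thresholds(10, 200)
  a <- attention_peak(apply_filter(spec, t), t, "R", n = 0)
  expect_equal(a$h_star, 100L)
  expect_equal(a$n_ave, 500)
})

test_that("window averaging over 2n+1 bins matches the hand-computed mean", {
  R <- integer(256); R[(99:101) + 1L] <- c(100L, 500L, 300L)
  spec <- make_spectrum(R = R, luma = rep(1L, 256))
  t <- filter_thresholds(10, 200)
  a <- attention_peak(apply_filter(spec, t), t, "R", n = 1)
  expect_equal(a$h_star, 100L)
  expect_equal(a$n_ave, (100 + 500 + 300) / 3)
})

test_that("band-edge windows are clipped (or strict-divided) per config", {
  t <- filter_thresholds(50, 200)
  R <- integer(256)
  R[(51:55) + 1L] <- c(900L, 10L, 20L, 30L, 40L)     # peak at band edge 51
  spec <- apply_filter(make_spectrum(R = R, luma = rep(1L, 256)), t)
  # oracle: explicit loop over the clipped window [49,53] ∩ (50,200) = 51..53
  window <- intersect(49:53, 51:199)
  oracle <- sum(R[window + 1L]) / length(window)
  a <- attention_peak(spec, t, "R", n = 2, window_mode = "clipped")
  expect_equal(a$h_star, 51L)
  expect_equal(a$n_ave, oracle)
  strict <- attention_peak(spec, t, "R", n = 2, window_mode = "strict")
  expect_equal(strict$n_ave, sum(R[window + 1L]) / 5)
})

test_that("peak ties break to the smallest gray level and match the scan oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    R <- as.integer(sample(0:30, 256, replace = TRUE))
    t <- filter_thresholds(20, 230)
    spec <- apply_filter(make_spectrum(R = R, luma = rep(1L, 256)), t)
    a <- attention_peak(spec, t, "R", n = 2)
    expect_equal(a$h_star, scan_argmax(spec$R, 21:229))
  }
  R <- integer(256); R[c(80, 120) + 1L] <- 7L        # exact tie
  t <- filter_thresholds(10, 200)
  a <- attention_peak(apply_filter(make_spectrum(R = R, luma = rep(1L, 256)), t),
                      t, "R", n = 0)
  expect_equal(a$h_star, 80L)
})

test_that("an all-zero retained band is an error", {
  R <- integer(256); R[5 + 1L] <- 10L; R[250 + 1L] <- 10L
  t <- filter_thresholds(10, 200)
  spec <- apply_filter(make_spectrum(R = R, luma = rep(1L, 256)), t)
  expect_error(attention_peak(spec, t, "R"), "no tea energy in band")
})

test_that("n_ave never exceeds the window maximum and equals it for flat windows", {
  set.seed(21)
  t <- filter_thresholds(20, 230)
  for (i in 1:5) {
    R <- as.integer(sample(0:1000, 256, replace = TRUE))
    spec <- apply_filter(make_spectrum(R = R, luma = rep(1L, 256)), t)
    a <- attention_peak(spec, t, "R", n = 3)
    window <- intersect((a$h_star - 3):(a$h_star + 3), 21:229)
    expect_lte(a$n_ave, max(spec$R[window + 1L]))
  }
  flat <- integer(256); flat[(21:229) + 1L] <- 50L   # flat across the whole band
  spec <- apply_filter(make_spectrum(R = flat, luma = rep(1L, 256)), t)
  a <- attention_peak(spec, t, "R", n = 2)
  expect_equal(a$n_ave, 50)
})

test_that("mapping sends counts to y = H - round(n_ave * s / S), clamped at 0", {
  cfg <- mapping_config()
  pt <- function(n_ave) structure(list(channel = "R", h_star = 60L, n_ave = n_ave),
                                  class = "attention_point")
  expect_equal(unname(map_point(pt(0), cfg)), c(60, 800))
  expect_equal(unname(map_point(pt(25000), cfg))[2], 100)     # 800 - 700
  expect_equal(unname(map_point(pt(40000), cfg))[2], 0)       # clamped
  # round-trip against a published mapped value: y = 271 implies
  # n_ave = (800 - 271) * 25000 / 700; mapping back must reproduce 271
  n_ave <- (800 - 271) * 25000 / 700
  expect_equal(unname(map_point(pt(n_ave), cfg))[2], 271)
  # floor mode differs from round mode by at most one unit
  cfg_f <- mapping_config(int_mode = "floor")
  for (nv in c(0, 123.4, 5000.5, 18892.9))
    expect_lte(abs(map_point(pt(nv), cfg)[2] - map_point(pt(nv), cfg_f)[2]), 1)
})

test_that("mapped y is monotonically non-increasing in n_ave", {
  cfg <- mapping_config()
  pt <- function(n_ave) structure(list(channel = "R", h_star = 60L, n_ave = n_ave),
                                  class = "attention_point")
  ys <- vapply(seq(0, 30000, by = 500),
               function(nv) unname(map_point(pt(nv), cfg)[2]), numeric(1))
  expect_true(all(diff(ys) <= 0))
})

test_that("process_image equals the hand-composed pipeline, stage by stage", {
  img <- generate_image(generator_params(degree = 0.25, seed = 3))
  cfg <- mapping_config()
  spec <- compute_energy(img)
  t <- find_thresholds(spec)
  filt <- apply_filter(spec, t)
  expected <- t(vapply(c(R = "R", G = "G", B = "B"), function(ch)
    map_point(attention_peak(filt, t, ch, n = cfg$n), cfg), numeric(2)))
  tr <- process_image(img, cfg)
  expect_equal(unname(tr$points), unname(expected))
  expect_equal(tr$thresholds$T1, t$T1)
  expect_equal(tr$thresholds$T2, t$T2)
  # x strictly inside the retained band, y within [0, H]
  expect_true(all(tr$points[, "x"] > t$T1 & tr$points[, "x"] < t$T2))
  expect_true(all(tr$points[, "y"] >= 0 & tr$points[, "y"] <= cfg$H))
})

test_that("the per-image pipeline is invariant to rotations and flips", {
  img <- generate_image(generator_params(degree = 0.5, seed = 8))
  ref <- process_image(img)
  r1 <- rot90_image(img); r2 <- rot90_image(r1); r3 <- rot90_image(r2)
  for (variant in list(r1, r2, r3, flip_image(img)))
    expect_identical(process_image(variant)$points, ref$points)
})

test_that("pipeline errors carry the image identifier", {
  white <- as_rgb_image(array(255L, c(8, 8, 3)))
  expect_error(process_image(white, id = "frame_07"), "frame_07.*degenerate")
})
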