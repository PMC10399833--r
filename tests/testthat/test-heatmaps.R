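test_that("the color transform pins its offsets and kills chroma on gray input", {
  # black input maps to (16, 128, 128)
  black <- image_grid(array(0, c(4, 4, 3)))
  y <- rgb_to_ycbcr(black)
  expect_equal(y$pixels[1, 1, ], c(16, 128, 128))
  expect_equal(y$colorspace, "YCbCr")
  # white input: luma row sums to 16 + 65.481 + 128.553 + 24.966 = 235
  white <- image_grid(array(1, c(4, 4, 3)))
  expect_equal(rgb_to_ycbcr(white)$pixels[1, 1, 1], 235, tolerance = 1e-9)
  # achromatic ramp: Cb and Cr constant at 128
  ramp <- array(rep(seq(0, 1, length.out = 16), 3), c(4, 4, 3))
  yr <- rgb_to_ycbcr(image_grid(ramp))
  expect_lt(max(abs(yr$pixels[, , 2] - 128)), 1e-6)
  expect_lt(max(abs(yr$pixels[, , 3] - 128)), 1e-6)
  expect_error(rgb_to_ycbcr(yr), "RGB")
})

test_that("the squared-error map equals its per-pixel definition", {
  x <- rand_img(10, 1); y <- rand_img(10, 2)
  hm <- pse_map(x, y)
  # brute-force double loop
  ref <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    ref[i, j] <- sum((x$pixels[i, j, ] - y$pixels[i, j, ])^2)
  expect_equal(hm$values, ref, tolerance = 1e-12)
  # identity: all-zero map
  expect_true(all(pse_map(x, x)$values == 0))
  # single differing pixel of gap d scores d^2
  y2 <- x
  y2$pixels[3, 4, 2] <- y2$pixels[3, 4, 2] + 0.25
  hm2 <- pse_map(x, y2)
  expect_equal(hm2$values[3, 4], 0.25^2)
  expect_equal(sum(hm2$values > 0), 1L)
  expect_error(pse_map(x, rand_img(8, 1)), "shape mismatch")
})

test_that("windowed SSIM matches direct window statistics and is symmetric", {
  set.seed(3)
  x <- rand_img(24, 5)
  # constant offset on a textured patch lowers SSIM via the luminance term
  y <- x
  y$pixels <- pmin(y$pixels + 0.2, 1)
  hm <- ssim_map(x, y, window = 7)
  expect_true(all(hm$values >= 0))
  # direct evaluation at an interior pixel (full 7x7 window)
  i <- 12; j <- 12
  L <- 1; c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  ssim_chan <- vapply(1:3, function(k) {
    wx <- as.numeric(x$pixels[(i - 3):(i + 3), (j - 3):(j + 3), k])
    wy <- as.numeric(y$pixels[(i - 3):(i + 3), (j - 3):(j + 3), k])
    n <- length(wx)
    mx <- mean(wx); my <- mean(wy)
    vx <- mean(wx^2) - mx^2; vy <- mean(wy^2) - my^2
    cxy <- mean(wx * wy) - mx * my
    ((2 * mx * my + c1) * (2 * cxy + c2)) /
      ((mx^2 + my^2 + c1) * (vx + vy + c2))
  }, 0)
  expect_equal(hm$values[i, j], max(1 - mean(ssim_chan), 0), tolerance = 1e-9)
  expect_gt(hm$values[i, j], 0)
  # identical images: zero map; symmetry
  expect_true(all(ssim_map(x, x)$values == 0))
  hm_xy <- ssim_map(x, y); hm_yx <- ssim_map(y, x)
  expect_lt(max(abs(hm_xy$values - hm_yx$values)), 1e-9)
  expect_error(ssim_map(x, y, window = 25), "larger than")
  expect_error(ssim_map(x, y, window = 6), "odd")
})

test_that("the perceptual map aggregates back to the scalar distance", {
  x <- rand_img(16, 7); y <- rand_img(16, 8)
  hm <- perceptual_map(pb_rc, x, y)
  expect_equal(mean(hm$values), perceptual_distance(pb_rc, x, y),
               tolerance = 0.02 * perceptual_distance(pb_rc, x, y))
  expect_true(all(perceptual_map(pb_rc, x, x)$values == 0))
})

test_that("a planted local anomaly is localized by the perceptual map", {
  hits <- 0
  for (s in 1:10) {
    f <- make_face(64, seed = 200 + s)
    xa <- plant_anomaly(f$image, f$landmarks, 0.8, seed = 200 + s)
    hm <- perceptual_map(pb_rc, xa, f$image)
    peak <- which(hm$values == max(hm$values), arr.ind = TRUE)[1, ]
    mask <- build_mask(f$landmarks, "oral_nasal", 64)
    hits <- hits + mask$mask[peak[1], peak[2]]
  }
  expect_gte(hits, 9)
})

test_that("erosion equals the brute-force 3x3 in-bounds minimum filter", {
  for (seed in 1:4) {
    img <- rand_img(12, seed)
    expect_identical(erode(img)$pixels, brute_erode(img$pixels))
  }
  # constant image unchanged; a lone bright pixel is removed
  const <- image_grid(array(0.3, c(8, 8, 3)))
  expect_identical(erode(const)$pixels, const$pixels)
  spike <- array(0, c(8, 8, 3)); spike[4, 4, ] <- 1
  expect_true(all(erode(image_grid(spike))$pixels == 0))
  # anti-extensivity: never increases any pixel
  img <- rand_img(16, 9)
  expect_true(all(erode(img)$pixels <= img$pixels))
})

test_that("any processing chain gives a zero map for identical inputs", {
  x <- rand_img(20, 11)
  for (m in c("pse", "ssim", "perceptual"))
    for (ycbcr in c(FALSE, TRUE))
      for (er in c(FALSE, TRUE)) {
        hm <- compute_heatmap(x, x, method = m, ycbcr = ycbcr, erosion = er,
                              backend = pb_rc)
        expect_true(all(hm$values == 0),
                    info = paste(m, ycbcr, er))
        expect_identical(hm$flags,
                         list(ycbcr_applied = ycbcr, erosion_applied = er))
      }
})

test_that("masked heatmap energy grows with planted amplitude for all methods", {
  f <- make_face(64, seed = 77)
  mask <- build_mask(f$landmarks, "oral_nasal", 64)
  amps <- c(0.2, 0.5, 0.8)
  for (m in c("pse", "ssim", "perceptual")) {
    e <- vapply(amps, function(a) {
      xa <- plant_anomaly(f$image, f$landmarks, a, seed = 77)
      hm <- compute_heatmap(xa, f$image, method = m, ycbcr = m != "perceptual",
                            erosion = TRUE, backend = pb_rc)
      mean(hm$values[mask$mask])
    }, 0)
    expect_true(all(diff(e) > 0), info = m)
  }
})

test_that("erosion can be redirected to the heatmap itself", {
  x <- rand_img(16, 13); y <- rand_img(16, 14)
  hm_img <- compute_heatmap(x, y, "pse", erosion = TRUE,
                            erode_target = "images")
  hm_hm <- compute_heatmap(x, y, "pse", erosion = TRUE,
                           erode_target = "heatmap")
  base <- compute_heatmap(x, y, "pse")
  expect_false(identical(hm_img$values, hm_hm$values))
  expect_true(all(hm_hm$values <= base$values))
})
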