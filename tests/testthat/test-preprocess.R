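test_that("adjust_background reaches the target face fraction from both sides", {
  f <- make_face(100, seed = 3)
  # oversized face: 90x90 box in a 100x100 frame (fraction 0.81)
  box <- face_box(5, 5, 90, 90)
  out <- adjust_background(f$image, box, 0.6, blur_sigma = 0)
  off <- attr(out, "offset")
  d <- dim(out$pixels)
  frac <- 90 * 90 / (d[1] * d[2])
  expect_gte(frac, 0.55); expect_lte(frac, 0.65)
  expect_true(all(off >= 0))

  # undersized face: small box, background cropped away
  box2 <- face_box(40, 40, 20, 20)
  out2 <- adjust_background(f$image, box2, 0.6, blur_sigma = 0)
  d2 <- dim(out2$pixels)
  frac2 <- 20 * 20 / (d2[1] * d2[2])
  expect_gte(frac2, 0.55); expect_lte(frac2, 0.65)

  # already at target: untouched
  box3 <- face_box(11, 11, 77, 77)   # 0.5929, within 5% of 0.6
  out3 <- adjust_background(f$image, box3, 0.6, blur_sigma = 0)
  expect_identical(out3$pixels, f$image$pixels)

  expect_error(face_box(0, 0, 1, 5), "degenerate")
})

test_that("mirrored margin reflects the original border (pre-blur)", {
  f <- make_face(100, seed = 4)
  box <- face_box(5, 5, 90, 90)
  out <- adjust_background(f$image, box, 0.6, blur_sigma = 0)
  off <- attr(out, "offset")
  # pixel just above the original top border equals the first original row
  expect_equal(out$pixels[off[1], off[2] + 1, ],
               f$image$pixels[1, 1, ])
  expect_equal(out$pixels[off[1] - 1, off[2] + 5, ],
               f$image$pixels[2, 5, ])
})

test_that("blur_background keeps the face sharp and calms the background", {
  # constant image is a fixed point
  const <- image_grid(array(0.4, c(32, 32, 3)))
  out <- blur_background(const, face_box(8, 8, 16, 16), sigma = 3)
  expect_lt(max(abs(out$pixels - 0.4)), 1e-12)

  # all-foreground box is the identity
  img <- rand_img(32, seed = 5)
  out2 <- blur_background(img, face_box(0, 0, 32, 32), sigma = 3)
  expect_identical(out2$pixels, img$pixels)

  # checkerboard background: local variance strictly decreases outside the
  # box, face-box interior unchanged within 1/255
  chk <- array(rep(c(0, 1), length.out = 48 * 48 * 3), c(48, 48, 3))
  img3 <- image_grid(chk)
  box <- face_box(16, 16, 16, 16)
  out3 <- blur_background(img3, box, sigma = 3)
  inner <- 18:30
  expect_lt(max(abs(out3$pixels[inner, inner, ] - chk[inner, inner, ])),
            1 / 255)
  bg_before <- var(as.numeric(chk[1:10, 1:10, 1]))
  bg_after <- var(as.numeric(out3$pixels[1:10, 1:10, 1]))
  expect_lt(bg_after, bg_before)
})

test_that("align_eyes levels the inter-ocular segment", {
  f <- make_face(120, seed = 6)
  lm <- f$landmarks
  # tilt the landmarks/image synthetically: rotate landmarks by 15 degrees
  th <- 15 * pi / 180
  p0 <- colMeans(eye_centers(lm))
  pts <- sweep(lm$points, 2, p0)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  lm_tilt <- landmark_set(t(R %*% t(pts)) + rep(p0, each = 68))
  al <- align_eyes(f$image, lm_tilt)
  ec <- eye_centers(al$landmarks)
  expect_lt(abs(ec[1, 1] - ec[2, 1]), 0.5)
  # distance preserved by the rotation
  expect_equal(eye_distance(al$landmarks), eye_distance(lm_tilt),
               tolerance = 1e-9)

  # already horizontal: zero angle, image untouched
  al0 <- align_eyes(f$image, lm)
  expect_equal(al0$angle, 0)
  expect_identical(al0$image$pixels, f$image$pixels)

  # aligning twice: second angle negligible
  al2 <- align_eyes(al$image, al$landmarks)
  expect_lt(abs(al2$angle), 0.01 * pi / 180)

  lm_bad <- lm
  lm_bad$points[37:48, ] <- rep(c(10, 10), each = 12)
  expect_error(align_eyes(f$image, lm_bad), "degenerate")
})

test_that("scale_to_interocular hits the target distance linearly", {
  f <- make_face(120, seed = 7)
  d0 <- eye_distance(f$landmarks)
  sc <- scale_to_interocular(f$image, f$landmarks, target_distance = 2 * d0)
  expect_equal(sc$scale, 2)
  expect_equal(eye_distance(sc$landmarks), 2 * d0, tolerance = 0.5)
  sc2 <- scale_to_interocular(f$image, f$landmarks, target_distance = d0 / 2)
  expect_equal(sc2$scale, 0.5)
  # already at target: unity scale, no resampling
  sc3 <- scale_to_interocular(f$image, f$landmarks, target_distance = d0)
  expect_equal(sc3$scale, 1)
  expect_identical(sc3$image$pixels, f$image$pixels)
})

test_that("crop_canonical centers on the configured anchor", {
  f <- make_face(64, seed = 8)
  cr <- crop_canonical(f$image, f$landmarks, side = 32, center_drop = 0.1)
  expect_equal(dim(cr$image$pixels), c(32L, 32L, 3L))
  ec <- colMeans(eye_centers(f$landmarks))
  anchor <- c(ec[1] + 0.1 * 32, ec[2])
  center_in <- cr$origin + (32 - 1) / 2
  expect_lt(max(abs(center_in - anchor)), 1)
  # integer-aligned crop is exact pixel extraction where in bounds
  rows <- (cr$origin[1] + 1):(cr$origin[1] + 32)
  cols <- (cr$origin[2] + 1):(cr$origin[2] + 32)
  rok <- rows >= 1 & rows <= 64
  cok <- cols >= 1 & cols <= 64
  expect_equal(cr$image$pixels[rok, cok, ],
               f$image$pixels[rows[rok], cols[cok], ])
})

test_that("full preprocessing is canonical and idempotent", {
  # target inter-ocular distance of 0.35 x side keeps the canonical frame
  # self-consistent with the 60% face-fraction convention
  f <- make_face(160, seed = 9, eye_dist = 40)
  pre <- preprocess_face(f$image, f$landmarks, eye_dist = 44.8, side = 128)
  expect_equal(dim(pre$image$pixels), c(128L, 128L, 3L))
  ec <- eye_centers(pre$landmarks)
  expect_lt(abs(ec[1, 1] - ec[2, 1]), 0.5)
  expect_equal(eye_distance(pre$landmarks), 44.8, tolerance = 0.5)
  # second pass changes nothing beyond interpolation error
  pre2 <- preprocess_face(pre$image, pre$landmarks, eye_dist = 44.8,
                          side = 128)
  expect_lt(max(abs(pre2$image$pixels - pre$image$pixels)), 2 / 255)
})

test_that("fixture detector backend supplies deterministic ground truth", {
  f <- make_face(64, seed = 10)
  det <- fixture_detector(f$landmarks)
  box1 <- det$detect_face(f$image)
  box2 <- det$detect_face(f$image)
  expect_identical(box1, box2)
  pre <- preprocess_face(f$image, detector = det, eye_dist = 22.4, side = 64)
  expect_equal(dim(pre$image$pixels), c(64L, 64L, 3L))
})
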