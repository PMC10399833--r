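test_that("landmark masks cover their generators and respect exclusions", {
  for (s in 1:20) {
    f <- make_face(64, seed = 300 + s)
    p <- f$landmarks$points
    oral <- build_mask(f$landmarks, "oral_nasal", 64)
    face <- build_mask(f$landmarks, "face_excluding_eyes", 64)
    # every outer-mouth landmark pixel is inside the oral/nasal mask
    for (i in 49:60)
      expect_true(oral$mask[round(p[i, 1]) + 1, round(p[i, 2]) + 1])
    # both eye centers are excluded from the face mask
    ec <- eye_centers(f$landmarks)
    expect_false(face$mask[round(ec[1, 1]) + 1, round(ec[1, 2]) + 1])
    expect_false(face$mask[round(ec[2, 1]) + 1, round(ec[2, 2]) + 1])
    # the oral/nasal mask lies within the face-outline hull (pre-exclusion)
    outline <- facenorm:::hull_mask(p[c(1:17, 18:27), ], 64, 0.04 * 64)
    expect_true(all(outline[oral$mask]))
  }
})

test_that("the negative-log score obeys its closed forms", {
  lm <- make_face(64, seed = 1)$landmarks
  mask <- build_mask(lm, "oral_nasal", 64)
  N <- sum(mask$mask)
  # uniform ones over the mask: ||.||_F = sqrt(N), S = log(N) / 2
  ones <- heatmap(matrix(1, 64, 64), "pse")
  s1 <- anomaly_score(ones, mask)
  expect_equal(s1$raw_energy, 1 / sqrt(N), tolerance = 1e-12)
  expect_equal(s1$score, 0.5 * log(N), tolerance = 1e-12)
  expect_equal(s1$n_mask, N)
  # raw energy exactly 1 gives S = 0
  vals <- matrix(0, 64, 64); vals[mask$mask] <- sqrt(N)   # ||.||_F = N
  s0 <- anomaly_score(heatmap(vals, "pse"), mask)
  expect_equal(s0$raw_energy, 1, tolerance = 1e-12)
  expect_equal(s0$score, 0)
  # doubling every value lowers S by exactly log 2
  set.seed(9)
  hm <- heatmap(matrix(runif(64 * 64), 64), "pse")
  hm2 <- heatmap(2 * hm$values, "pse")
  expect_equal(anomaly_score(hm, mask)$score - anomaly_score(hm2, mask)$score,
               log(2), tolerance = 1e-12)
  # all-zero masked heatmap: +Inf sentinel, flagged perfect
  z <- anomaly_score(heatmap(matrix(0, 64, 64), "pse"), mask)
  expect_identical(z$score, Inf)
  expect_true(z$perfect)
  # the prose variant: plain masked mean
  sm <- anomaly_score(ones, mask, energy = "mean")
  expect_equal(sm$raw_energy, 1)
  expect_equal(sm$score, 0)
})

test_that("score scaling is affine, order preserving, and correlation neutral", {
  expect_equal(scale_scores(c(0, 1)), c(1, 7))
  set.seed(4)
  x <- rnorm(20); y <- 3 * x + rnorm(20)
  expect_identical(order(scale_scores(x)), order(x))
  expect_equal(pearson(scale_scores(x), y), pearson(x, y), tolerance = 1e-12)
  expect_warning(out <- scale_scores(c(2, 2, 2)), "identical")
  expect_equal(out, rep(4, 3))
  expect_error(scale_scores(c(1, Inf)), "finite")
})

test_that("rating aggregation enforces the minimum-ratings filter", {
  tbl <- rating_table(tibble::tibble(
    image_id = rep(c("a", "b"), c(19, 21)),
    rater_id = sprintf("r%02d", c(1:19, 1:21)),
    rating = c(rep(6L, 19), rep(c(3L, 4L), c(10, 11)))))
  agg <- aggregate_ratings(tbl, min_ratings = 20)
  expect_equal(agg$image_id, "b")          # 19 ratings is not enough
  expect_equal(agg$mean_rating, mean(c(rep(3, 10), rep(4, 11))))
  agg2 <- aggregate_ratings(tbl, min_ratings = 10)
  expect_equal(agg2$mean_rating[agg2$image_id == "a"], 6)
  expect_error(aggregate_ratings(tbl, min_ratings = 50), "no image")
  bad <- tbl; bad$rating[1] <- 9L
  expect_error(rating_table(bad), "1..7")
})

test_that("noiseless simulated tables recover the planted response curve", {
  amps <- c(0, 0.5, 1)
  R <- 30
  tbl <- simulate_ratings(amps, rater_count = R, noise_sd = 0, seed = 2)
  agg <- aggregate_ratings(tbl, min_ratings = 20)
  planted <- pmin(pmax(7 - 6 * amps / (amps + 0.35), 1), 7)
  # rater dither makes the mean a 1/R-quantized estimate of the curve
  expect_equal(agg$mean_rating[order(agg$image_id)], planted,
               tolerance = 1 / R)
})

test_that("pearson matches the longhand product-moment formula", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2.2, 2.8, 4.5, 8.1, 10.9)
  # longhand: dx = x - 5, dy = y - 5.7
  dx <- x - mean(x); dy <- y - mean(y)
  longhand <- sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  expect_equal(pearson(x, y), longhand, tolerance = 1e-12)
  expect_equal(pearson(x, y), stats::cor(x, y), tolerance = 1e-12)
  expect_equal(pearson(x, 2 * x + 1), 1)
  expect_equal(pearson(x, -x), -1)
  expect_error(pearson(x, y[1:3]), "length")
  expect_error(pearson(c(1, 2), c(3, 4)), "at least 3")
  expect_error(pearson(c(1, 1, 1), y[1:3]), "zero variance")
})

test_that("evaluate_scores joins, filters and correlates", {
  amps <- seq(0, 1, length.out = 8)
  tbl <- simulate_ratings(amps, rater_count = 25, noise_sd = 0.2, seed = 5)
  scores <- tibble::tibble(image_id = sprintf("img%03d", 1:8),
                           score = 5 - 4 * amps + rnorm(8, sd = 0.05))
  ev <- evaluate_scores(scores, tbl, min_ratings = 20)
  expect_equal(ev$n, 8)
  expect_gt(ev$r, 0.9)
})
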