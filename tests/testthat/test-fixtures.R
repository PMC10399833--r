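test_that("fixture faces are bit-deterministic and anatomically consistent", {
  f1 <- make_face(64, seed = 5)
  f2 <- make_face(64, seed = 5)
  expect_identical(f1$image$pixels, f2$image$pixels)
  expect_identical(f1$landmarks$points, f2$landmarks$points)
  expect_false(identical(f1$image$pixels, make_face(64, seed = 6)$image$pixels))
  # inter-ocular distance equals the construction parameter exactly
  expect_equal(eye_distance(f1$landmarks), 0.35 * 64, tolerance = 1e-9)
  f3 <- make_face(96, seed = 5, eye_dist = 30)
  expect_equal(eye_distance(f3$landmarks), 30, tolerance = 1e-9)
  # all landmarks inside the frame
  expect_true(all(f1$landmarks$points >= 0 & f1$landmarks$points <= 63))
})

test_that("eye landmarks fall inside the drawn eye blobs", {
  for (s in c(1, 9, 33)) {
    f <- make_face(64, seed = s)
    p <- f$landmarks$points
    ec <- eye_centers(f$landmarks)
    s_ <- 64
    for (side_i in 1:2) {
      idx <- if (side_i == 1) 37:42 else 43:48
      d <- sweep(p[idx, ], 2, ec[side_i, ])
      # within the drawn eye ellipse (semi-axes 0.035 s x 0.07 s)
      expect_true(all((d[, 1] / (0.035 * s_))^2 + (d[, 2] / (0.07 * s_))^2 <= 1 + 1e-9))
    }
  }
})

test_that("planted anomalies are graded, local, and vanish at amplitude zero", {
  f <- make_face(64, seed = 13)
  expect_identical(plant_anomaly(f$image, f$landmarks, 0)$pixels,
                   f$image$pixels)
  mask <- build_mask(f$landmarks, "oral_nasal", 64)
  amps <- seq(0.1, 1, by = 0.1)
  energies <- vapply(amps, function(a) {
    xa <- plant_anomaly(f$image, f$landmarks, a, seed = 13)
    hm <- pse_map(xa, f$image)
    # locality: outside the oral/nasal mask nothing moves beyond 1/255
    expect_lt(max(abs(xa$pixels - f$image$pixels) *
                    array(!mask$mask, dim(xa$pixels))), 1 / 255)
    sum(hm$values[mask$mask])
  }, 0)
  expect_true(all(diff(energies) > 0))
})

test_that("fixture batches carry paired pre-anomaly references", {
  fb <- fixture_faces(c(0.2, 0.6), side = 64, seed = 3)
  expect_equal(nrow(fb), 2)
  expect_s3_class(fb$x_org[[1]], "image_grid")
  hm <- pse_map(fb$x_org[[2]], fb$x_ref[[2]])
  expect_gt(max(hm$values), 0)
  # same_base mode reuses one face
  fb2 <- fixture_faces(c(0, 0.5), side = 64, seed = 3, same_base = TRUE)
  expect_identical(fb2$x_ref[[1]]$pixels, fb2$x_ref[[2]]$pixels)
})

test_that("simulated ratings follow the saturating response", {
  # zero amplitude, zero noise: everyone says 7
  tbl <- simulate_ratings(0, rater_count = 10, noise_sd = 0, seed = 1)
  expect_true(all(tbl$rating == 7L))
  # noiseless means strictly decrease with amplitude
  amps <- seq(0, 1, length.out = 6)
  tbl2 <- simulate_ratings(amps, rater_count = 5, noise_sd = 0, seed = 1)
  agg <- aggregate_ratings(tbl2, min_ratings = 1)
  expect_true(all(diff(agg$mean_rating[order(agg$image_id)]) < 0))
  # determinism
  expect_identical(simulate_ratings(amps, seed = 7)$rating,
                   simulate_ratings(amps, seed = 7)$rating)
})

test_that("rating noise averages out at the stated rate", {
  amps <- rep(seq(0.1, 0.9, length.out = 20), 3)
  tbl <- simulate_ratings(amps, rater_count = 25, noise_sd = 0.5, seed = 11)
  agg <- aggregate_ratings(tbl, min_ratings = 20)
  noiseless <- aggregate_ratings(
    simulate_ratings(amps, rater_count = 25, noise_sd = 0, seed = 11),
    min_ratings = 20)
  joined <- dplyr::inner_join(agg, noiseless, by = "image_id",
                              suffix = c("", "_true"))
  frac <- mean(abs(joined$mean_rating - joined$mean_rating_true) <= 0.3)
  expect_gte(frac, 0.95)
})
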