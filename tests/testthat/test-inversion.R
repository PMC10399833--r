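test_that("noise regularizer matches the brute-force double loop", {
  for (seed in 1:4) {
    set.seed(seed)
    maps <- list(matrix(rnorm(16^2), 16), matrix(rnorm(32^2), 32),
                 matrix(rnorm(64^2), 64))
    expect_equal(noise_regularizer(maps), brute_noise_reg(maps),
                 tolerance = 1e-12)
  }
})

test_that("constant maps give the closed-form autocorrelation value", {
  # for an r x r constant map c the lag-1 sum is r(r-1)c^2, each direction,
  # and every pyramid level of a constant map is the same constant
  c0 <- 0.7
  closed <- function(r, c_) {
    tot <- 0
    while (TRUE) {
      tot <- tot + 2 * (r * (r - 1) * c_^2 / r^2)^2
      if (r <= 8) break
      r <- r / 2
    }
    tot
  }
  expect_equal(noise_regularizer(list(matrix(c0, 16, 16))), closed(16, c0),
               tolerance = 1e-12)
  expect_equal(noise_regularizer(list(matrix(c0, 8, 8))), closed(8, c0),
               tolerance = 1e-12)
})

test_that("alternating-column maps score the anti-correlation closed form", {
  # columns alternate +1/-1: row-lag products all +1, column-lag all -1
  r <- 8
  m <- matrix(rep(c(1, -1), length.out = r), r, r, byrow = TRUE)
  expect_equal(noise_regularizer(list(m)), brute_noise_reg(list(m)),
               tolerance = 1e-12)
  expect_equal(noise_regularizer(list(m)),
               (r * (r - 1) / r^2)^2 + (-r * (r - 1) / r^2)^2,
               tolerance = 1e-12)
})

test_that("i.i.d. noise scores far below structured maps", {
  vals <- vapply(1:100, function(s) {
    set.seed(s)
    noise_regularizer(list(matrix(rnorm(64^2), 64)))
  }, 0)
  const_val <- noise_regularizer(list(matrix(1, 64, 64)))
  expect_lt(stats::quantile(vals, 0.99), const_val)
})

test_that("regularizer gradients match finite differences", {
  set.seed(5)
  maps <- list(matrix(rnorm(32^2), 32), matrix(rnorm(8^2), 8))
  g <- facenorm:::noise_regularizer_grad(maps)
  d <- matrix(rnorm(32^2), 32)
  num <- (noise_regularizer(list(maps[[1]] + 1e-5 * d, maps[[2]])) -
          noise_regularizer(list(maps[[1]] - 1e-5 * d, maps[[2]]))) / 2e-5
  expect_lt(abs(num - sum(g[[1]] * d)) / abs(num), 1e-6)
})

test_that("zero-iteration inversion returns the mean-latent initialization", {
  target <- synthesize(tg, mean_latent(tg, 100, seed = 1))
  st <- invert(tg, target, pb_px,
               inversion_config(iterations = 0, seed = 3,
                                mean_latent_samples = 100))
  expect_equal(st$step, 0)
  expect_equal(st$w, mean_latent(tg, 100, seed = 3))
  expect_identical(st$noise_maps, init_noise(tg, 4))
  expect_equal(nrow(st$loss_trace), 0)
})

test_that("inversion is bit-deterministic for a fixed seed", {
  set.seed(17)
  target <- synthesize(tg, map_latent(tg, rnorm(tg$latent_dim)))
  cfg <- inversion_config(iterations = 15, seed = 5, mean_latent_samples = 200)
  s1 <- invert(tg, target, pb_rc, cfg)
  s2 <- invert(tg, target, pb_rc, cfg)
  expect_identical(s1$loss_trace, s2$loss_trace)
  expect_identical(s1$w, s2$w)
})

test_that("self-inversion recovers most of the perceptual loss", {
  set.seed(23)
  wstar <- map_latent(tg, rnorm(tg$latent_dim))
  target <- synthesize(tg, wstar)
  st <- invert(tg, target, pb_rc,
               inversion_config(iterations = 150, seed = 2,
                                mean_latent_samples = 1000))
  final <- st$loss_trace$image_loss[st$step]
  expect_lt(final / st$init_image_loss, 0.1)
  # noise maps stay noise-like: regularizer at most twice its initial value
  expect_lte(st$loss_trace$reg_loss[st$step],
             2 * st$loss_trace$reg_loss[1] + 1e-8)
})

test_that("dropping the regularizer trades noise randomness for image fit", {
  set.seed(29)
  target <- synthesize(tg, map_latent(tg, rnorm(tg$latent_dim)),
                       init_noise(tg, 30))
  cfg_on <- inversion_config(iterations = 80, seed = 6,
                             mean_latent_samples = 500, alpha = 1e5)
  cfg_off <- inversion_config(iterations = 80, seed = 6,
                              mean_latent_samples = 500, alpha = 0)
  st_on <- invert(tg, target, pb_rc, cfg_on)
  st_off <- invert(tg, target, pb_rc, cfg_off)
  expect_lt(st_off$loss_trace$image_loss[80], st_on$loss_trace$image_loss[80])
  expect_gt(st_off$loss_trace$reg_loss[80], st_on$loss_trace$reg_loss[80])
})

test_that("inversion rejects mismatched targets", {
  small <- rand_img(16, 1)
  expect_error(invert(tg, small, pb_px), "output side")
})
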