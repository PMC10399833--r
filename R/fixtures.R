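#' Synthetic faces, anomalies and rating tables
#'
#' The package's test inputs are generated, never shipped: smooth face-like
#' rasters with analytically placed 68-point landmarks, graded structural
#' anomalies planted in the philtrum/upper-lip region, and simulated rater
#' tables whose mean rating is a noisy saturating function of the planted
#' amplitude.  Everything is a deterministic function of (seed, parameters).
#'
#' @name synthetic_fixtures
#' @keywords internal
NULL

#' Fixture parameter bundle
#'
#' @param seed Integer seed.
#' @param image_side Face raster side, pixels (`>= 32`).
#' @param anomaly_amplitude Planted anomaly magnitude (`>= 0`; 0 = none).
#' @param rater_count Simulated raters per image (default 25, matching a
#'   typical ratings-per-image load in human studies of this size).
#' @param rating_noise_sd Rating noise standard deviation (default 0.5).
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1, image_side = 64, anomaly_amplitude = 0,
                         rater_count = 25, rating_noise_sd = 0.5) {
  stopifnot(image_side >= 32)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic face with ground-truth landmarks
#'
#' Draws a deterministic smooth "face": textured background, elliptical skin
#' region with shading, two eye blobs with brows, a nose ridge, and a mouth
#' band; the 68 landmarks are placed analytically on the drawn features
#' (each eye's six landmarks are symmetric about the drawn eye center, so
#' the landmark centroid equals the construction parameter exactly).
#'
#' @param side Image side in pixels (`>= 32`).
#' @param seed Integer seed (controls texture and face tint).
#' @param eye_dist Inter-ocular distance in pixels (default `0.35 * side`).
#' @return `list(image =, landmarks =)`; the image is unit-range RGB.
#' @export
make_face <- function(side = 64, seed = 1, eye_dist = 0.35 * side) {
  stopifnot(side >= 32)
  rng <- rng_state(seed); on.exit(restore_rng(rng))
  set.seed(seed)
  s <- side
  rr <- matrix(rep(0:(s - 1), s), s)
  cc <- matrix(rep(0:(s - 1), each = s), s)
  cm <- (s - 1) / 2
  re <- 0.40 * s                       # eye row
  ce_l <- cm - eye_dist / 2; ce_r <- cm + eye_dist / 2
  rn <- 0.62 * s                       # nose base row
  rm <- 0.78 * s                       # mouth center row
  # background: smooth seeded texture
  low <- matrix(stats::rnorm(64), 8)
  tex <- up_bilinear(low, s) * 0.06
  px <- array(0, c(s, s, 3))
  bgcol <- c(0.35, 0.45, 0.55) + stats::runif(3, -0.05, 0.05)
  for (k in 1:3) px[, , k] <- bgcol[k] + tex
  # skin ellipse with radial shading
  fc <- c(0.52 * s, cm); ar <- 0.42 * s; ac <- 0.34 * s
  dist2 <- ((rr - fc[1]) / ar)^2 + ((cc - fc[2]) / ac)^2
  face <- dist2 <= 1
  shade <- pmax(1 - 0.25 * dist2, 0)
  skin <- c(0.85, 0.68, 0.58) + stats::runif(3, -0.04, 0.04)
  for (k in 1:3) px[, , k][face] <- (skin[k] * shade)[face]
  # eyes: dark ellipses
  er <- 0.035 * s; ec <- 0.07 * s
  for (ce in c(ce_l, ce_r)) {
    eye <- ((rr - re) / er)^2 + ((cc - ce) / ec)^2 <= 1
    for (k in 1:3) px[, , k][eye] <- c(0.95, 0.95, 0.95)[k]
    iris <- ((rr - re) / (er * 0.8))^2 + ((cc - ce) / (er * 0.8))^2 <= 1
    for (k in 1:3) px[, , k][iris] <- c(0.15, 0.1, 0.08)[k]
  }
  # brows
  rb <- re - 0.09 * s
  for (ce in c(ce_l, ce_r)) {
    brow <- abs(rr - (rb + 0.015 * s * ((cc - ce) / ec)^2)) <= 0.015 * s &
      abs(cc - ce) <= 1.2 * ec
    for (k in 1:3) px[, , k][brow] <- c(0.25, 0.15, 0.1)[k]
  }
  # nose ridge: brightness ridge down the midline plus nostril shadows
  ridge <- exp(-((cc - cm) / (0.03 * s))^2) *
    (rr > re + 0.02 * s & rr < rn)
  for (k in 1:3) px[, , k] <- px[, , k] + 0.10 * ridge * face
  for (dc in c(-0.045, 0.045) * s) {
    nost <- ((rr - rn) / (0.02 * s))^2 + ((cc - (cm + dc)) / (0.025 * s))^2 <= 1
    for (k in 1:3) px[, , k][nost] <- px[, , k][nost] * 0.55
  }
  # mouth band
  wm <- 0.16 * s; hm <- 0.04 * s
  mouth <- ((rr - rm) / hm)^2 + ((cc - cm) / wm)^2 <= 1
  mcol <- c(0.62, 0.25, 0.25)
  for (k in 1:3) px[, , k][mouth] <- mcol[k]
  lip_line <- abs(rr - rm) <= 0.008 * s & abs(cc - cm) <= wm
  for (k in 1:3) px[, , k][lip_line] <- mcol[k] * 0.6
  px <- pmin(pmax(px, 0), 1)
  img <- image_grid(px, range = "unit", colorspace = "RGB")

  # --- landmarks (0-based row/col) ---
  pts <- matrix(0, 68, 2)
  t_jaw <- seq(pi, 0, length.out = 17)
  pts[LM_JAW, ] <- cbind(fc[1] + ar * 0.98 * sin(t_jaw),
                         fc[2] + ac * 0.98 * cos(t_jaw))
  for (side_i in 1:2) {
    ce <- if (side_i == 1) ce_l else ce_r
    idx <- if (side_i == 1) 18:22 else 23:27
    off <- seq(-1.1, 1.1, length.out = 5) * ec
    pts[idx, ] <- cbind(rb + 0.015 * s * (off / ec)^2, ce + off)
  }
  pts[28:31, ] <- cbind(seq(re + 0.04 * s, rn - 0.03 * s, length.out = 4), cm)
  pts[32:36, ] <- cbind(rn, cm + seq(-0.055, 0.055, length.out = 5) * s)
  ang6 <- seq(0, 2 * pi, length.out = 7)[-7]
  for (side_i in 1:2) {
    ce <- if (side_i == 1) ce_l else ce_r
    idx <- if (side_i == 1) LM_EYE_L else LM_EYE_R
    pts[idx, ] <- cbind(re + er * 0.9 * sin(ang6), ce + ec * 0.9 * cos(ang6))
  }
  ang12 <- seq(0, 2 * pi, length.out = 13)[-13]
  pts[LM_MOUTH_OUT, ] <- cbind(rm + hm * sin(ang12), cm + wm * cos(ang12))
  ang8 <- seq(0, 2 * pi, length.out = 9)[-9]
  pts[LM_MOUTH_IN, ] <- cbind(rm + 0.5 * hm * sin(ang8),
                              cm + 0.6 * wm * cos(ang8))
  list(image = img, landmarks = landmark_set(pts))
}

#' Plant a graded cleft-like anomaly
#'
#' Applies a localized structural warp (upward pull of the upper lip on one
#' side of the philtrum) plus an intensity notch, both scaled by
#' `amplitude`, inside a compactly supported window over the philtrum /
#' upper-lip region.  The window is hard-limited to the convex hull of the
#' nose and outer-mouth landmarks, so every planted change lies strictly
#' inside the oral/nasal scoring region.  Amplitude 0 returns the image
#' unchanged; pixels outside the window's support are untouched.
#'
#' @param img Unit- or byte-range RGB [image_grid()].
#' @param lm The face's [landmark_set()].
#' @param amplitude Anomaly magnitude (`>= 0`; 1 is a gross anomaly).
#' @param seed Controls which side of the philtrum is affected.
#' @return An [image_grid()] like `img`.
#' @export
plant_anomaly <- function(img, lm, amplitude, seed = 1) {
  stopifnot(amplitude >= 0)
  if (amplitude == 0) return(img)
  u <- convert_range(img, "unit")
  px <- u$pixels
  s <- dim(px)[1]
  nose_base <- max(lm$points[LM_NOSE, 1])
  mouth_top <- min(lm$points[LM_MOUTH_OUT, 1])
  cm <- mean(lm$points[LM_MOUTH_OUT, 2])
  pr <- (nose_base + mouth_top) / 2 + 0.02 * s
  pc <- cm + (if (seed %% 2 == 0) 1 else -1) * 0.05 * s
  rr <- matrix(rep(0:(s - 1), s), s)
  cc <- matrix(rep(0:(s - 1), each = s), s)
  w <- exp(-((rr - pr)^2 / (2 * (0.05 * s)^2) +
             (cc - pc)^2 / (2 * (0.04 * s)^2)))
  w[w < 0.002] <- 0
  # confine the support to the (undilated) oral/nasal hull: locality holds
  # by construction with respect to any dilated scoring mask
  support <- hull_mask(lm$points[c(LM_NOSE, LM_MOUTH_OUT), , drop = FALSE],
                       s, margin = 0)
  w[!support] <- 0
  # structural warp: sample from below, pulling the lip upward
  dr <- amplitude * 0.08 * s * w
  out <- px
  for (k in 1:3) out[, , k] <- bilinear_sample(px[, , k], rr + dr, cc)
  # intensity notch
  for (k in 1:3) out[, , k] <- out[, , k] - amplitude * 0.45 * w
  keep <- w == 0
  for (k in 1:3) out[, , k][keep] <- px[, , k][keep]
  out <- pmin(pmax(out, 0), 1)
  res <- image_grid(out, range = "unit", colorspace = "RGB")
  convert_range(res, img$range)
}

#' A batch of graded-anomaly fixture faces
#'
#' @param amplitudes Numeric vector of planted amplitudes, one face each.
#' @param side Image side (default 64).
#' @param seed Base seed; face `i` uses `seed + i`.
#' @param same_base Use one base face for all amplitudes (default: vary).
#' @return Tibble with `image_id`, `amplitude`, and list-columns `x_org`
#'   (anomalous face), `x_ref` (pre-anomaly face) and `landmarks`.
#' @export
fixture_faces <- function(amplitudes, side = 64, seed = 1,
                          same_base = FALSE) {
  purrr::imap_dfr(as.list(amplitudes), function(a, i) {
    fseed <- if (same_base) seed else seed + i
    f <- make_face(side, seed = fseed)
    tibble::tibble(
      image_id = sprintf("img%03d", i),
      amplitude = a,
      x_org = list(plant_anomaly(f$image, f$landmarks, a, seed = fseed)),
      x_ref = list(f$image),
      landmarks = list(f$landmarks))
  })
}

#' Simulate a human rating table
#'
#' Each rater's score for a face of planted amplitude `a` is
#' `clamp(round(7 - 6 * a / (a + k) + d_j + noise), 1, 7)`: a saturating
#' monotone response (human sensitivity flattens as the anomaly grows), a
#' deterministic per-rater threshold offset `d_j` evenly spread over
#' (-0.5, 0.5) (raters differ in where they cross integer boundaries, which
#' keeps per-image means on the response curve rather than on integer
#' steps), plus Gaussian noise.
#'
#' @param amplitudes Amplitude per image (names or default ids become
#'   `image_id`).
#' @param rater_count Raters per image (default 25).
#' @param noise_sd Rating noise SD (default 0.5; 0 = deterministic).
#' @param k Half-saturation constant of the response curve (default 0.35).
#' @param seed Integer seed.
#' @param image_ids Optional character ids (default `img001`, ...).
#' @return A [rating_table()] tibble.
#' @export
simulate_ratings <- function(amplitudes, rater_count = 25, noise_sd = 0.5,
                             k = 0.35, seed = 1, image_ids = NULL) {
  stopifnot(rater_count >= 1)
  if (is.null(image_ids))
    image_ids <- sprintf("img%03d", seq_along(amplitudes))
  rng <- rng_state(seed); on.exit(restore_rng(rng))
  set.seed(seed)
  df <- tidyr::expand_grid(
    image_id = image_ids,
    rater_id = sprintf("rater%03d", seq_len(rater_count)))
  amp <- stats::setNames(amplitudes, image_ids)[df$image_id]
  base <- 7 - 6 * amp / (amp + k)
  rater_j <- as.integer(sub("rater", "", df$rater_id))
  dither <- (rater_j - 0.5) / rater_count - 0.5
  df$rating <- as.integer(pmin(pmax(round(
    base + dither + stats::rnorm(nrow(df), sd = noise_sd)), 1), 7))
  rating_table(df)
}
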