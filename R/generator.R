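#' The differentiable-generator contract
#'
#' A generator backend is any object implementing [map_latent()],
#' [synthesize()], [init_noise()] and (for inversion/adaptation) the reverse
#' pass [synthesize_grad()]: a deterministic, differentiable map from a
#' latent vector plus a profile of per-resolution noise maps to an RGB
#' raster.  The full-scale face generator (a style-based convolutional
#' synthesizer with an 18-map noise profile at resolutions 1024 down to 8
#' and a 512-dimensional latent) plugs in behind the same contract via
#' opaque weight checkpoints; the package ships [toy_generator()], a
#' CPU-scale backend used throughout the tests.
#'
#' @name generator_backend
#' @keywords internal
NULL

#' Map a raw latent z to the intermediate latent w
#' @param gen A generator backend.
#' @param z Numeric vector of length `gen$latent_dim`.
#' @return Numeric vector `w` of the same length.
#' @export
map_latent <- function(gen, z) UseMethod("map_latent")

#' Synthesize an image from a latent and noise maps
#' @param gen A generator backend.
#' @param w Intermediate latent vector.
#' @param noise A noise-map set from [init_noise()] or [zero_noise()], or
#'   `NULL` for all-zero noise.
#' @param ... Backend-specific arguments (the toy backend accepts
#'   `keep_cache`).
#' @return A unit-range RGB [image_grid()] of side `gen$output_side`.
#' @export
synthesize <- function(gen, w, noise = NULL, ...) UseMethod("synthesize")

#' Reverse-mode gradients of a synthesis
#'
#' Given the pixel-space gradient of a scalar loss, returns gradients with
#' respect to the latent, every noise map, and the generator weights.
#'
#' @param gen A generator backend.
#' @param cache Forward cache from `synthesize(..., keep_cache = TRUE)`.
#' @param d_pixels Array of `dL/dx`, same shape as the synthesized image.
#' @param ... Backend-specific arguments.
#' @return `list(d_w =, d_noise =, d_weights =)`.
#' @export
synthesize_grad <- function(gen, cache, d_pixels, ...) UseMethod("synthesize_grad")

#' Construct the CPU-scale toy generator
#'
#' A small differentiable synthesizer: the mapped latent drives a `tanh`
#' hidden layer whose activations mix a bank of smooth image bases; seeded
#' noise maps are nearest-neighbour upsampled, scaled by per-map gains, and
#' added pre-activation; a logistic squash keeps pixels in the unit range.
#' Weights are fixed random functions of `seed` (no training): inversion and
#' adaptation only require an expressive differentiable map, not a
#' photorealistic one.
#'
#' @param latent_dim Latent dimensionality (default 16).
#' @param output_side Output image side in pixels (default 64).
#' @param noise_profile Integer vector of square noise-map resolutions
#'   (default `c(64, 32, 16, 8)`).
#' @param hidden Hidden-layer width (default 32).
#' @param mapping `"orthogonal"` for a fixed random orthogonal mapping
#'   network, `"identity"` for the identity map.
#' @param seed Integer seed; identical seeds give bit-identical weights.
#' @return An object of classes `toy_generator`, `generator_spec`.
#' @export
toy_generator <- function(latent_dim = 16, output_side = 64,
                          noise_profile = c(64, 32, 16, 8), hidden = 32,
                          mapping = c("orthogonal", "identity"), seed = 1) {
  mapping <- match.arg(mapping)
  stopifnot(all(output_side %% noise_profile == 0))
  P <- output_side^2 * 3
  rng <- rng_state(seed)
  on.exit(restore_rng(rng))
  set.seed(seed)
  M <- if (mapping == "identity") diag(latent_dim) else
    qr.Q(qr(matrix(stats::rnorm(latent_dim^2), latent_dim)))
  A <- matrix(stats::rnorm(hidden * latent_dim, sd = 1 / sqrt(latent_dim)),
              hidden, latent_dim)
  b <- stats::rnorm(hidden, sd = 0.1)
  # smooth image bases: low-resolution noise bilinearly upsampled per channel
  Phi <- matrix(0, P, hidden)
  base_res <- rep(c(4L, 8L, 16L), length.out = hidden)
  for (k in seq_len(hidden)) {
    res <- base_res[k]
    chs <- lapply(1:3, function(ch) {
      low <- matrix(stats::rnorm(res^2), res)
      up_bilinear(low, output_side)
    })
    col <- c(chs[[1]], chs[[2]], chs[[3]])
    Phi[, k] <- col / stats::sd(col)
  }
  Phi <- Phi * (1.6 / sqrt(hidden))
  b0 <- matrix(stats::rnorm(16), 4)
  b_img <- rep(c(up_bilinear(b0, output_side)), 3) * 0.5
  g <- rep(0.05, length(noise_profile))
  structure(list(latent_dim = latent_dim, output_side = output_side,
                 noise_profile = as.integer(noise_profile), hidden = hidden,
                 mapping = mapping, seed = seed,
                 weights = list(A = A, b = b, Phi = Phi, b_img = b_img, g = g),
                 map_M = M),
            class = c("toy_generator", "generator_spec"))
}

#' @export
print.toy_generator <- function(x, ...) {
  cat(sprintf("<toy_generator: latent %d, out %dx%d, noise maps {%s}, seed %d>\n",
              x$latent_dim, x$output_side, x$output_side,
              paste(x$noise_profile, collapse = ", "), x$seed))
  invisible(x)
}

# save/restore the caller's RNG so seeded constructors do not perturb it
rng_state <- function(seed) {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
}
restore_rng <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}

# bilinear upsample of a square matrix to side n (align-corners)
up_bilinear <- function(m, n) {
  r <- nrow(m)
  if (r == n) return(m)
  pos <- seq(0, r - 1, length.out = n)
  i0 <- pmin(floor(pos), r - 2); f <- pos - i0
  W <- matrix(0, n, r)
  W[cbind(seq_len(n), i0 + 1)] <- 1 - f
  W[cbind(seq_len(n), i0 + 2)] <- W[cbind(seq_len(n), i0 + 2)] + f
  W %*% m %*% t(W)
}

# nearest-neighbour upsample of r x r to n x n (n divisible by r)
up_nearest <- function(m, n) {
  f <- n / nrow(m)
  m[rep(seq_len(nrow(m)), each = f), rep(seq_len(ncol(m)), each = f)]
}

# adjoint of up_nearest: sum over f x f blocks
block_sum <- function(m, r) {
  f <- nrow(m) / r
  P <- matrix(0, nrow(m), r)
  P[cbind(seq_len(nrow(m)), rep(seq_len(r), each = f))] <- 1
  crossprod(P, m %*% P)
}

#' @export
map_latent.toy_generator <- function(gen, z) as.numeric(gen$map_M %*% z)

#' All-zero noise maps for a generator's profile
#' @param gen A generator backend.
#' @return List of zero matrices matching `gen$noise_profile`.
#' @export
zero_noise <- function(gen) lapply(gen$noise_profile, function(r) matrix(0, r, r))

#' Draw a fresh standard-normal noise-map set
#'
#' One N(0,1) map per entry of the generator's noise profile; deterministic
#' for a fixed seed.
#'
#' @param gen A generator backend.
#' @param seed Integer seed.
#' @return List of matrices, shapes per `gen$noise_profile`.
#' @export
init_noise <- function(gen, seed = 1) {
  rng <- rng_state(seed); on.exit(restore_rng(rng))
  set.seed(seed)
  lapply(gen$noise_profile, function(r) matrix(stats::rnorm(r * r), r, r))
}

#' Mean intermediate latent
#'
#' Draws `n_samples` standard-normal raw latents, maps each through the
#' mapping network, and returns their mean -- the standard initialization
#' for latent-space projection (production default: 10,000 samples).
#'
#' @param gen A generator backend.
#' @param n_samples Number of samples (`>= 1`).
#' @param seed Integer seed.
#' @return Numeric latent vector of length `gen$latent_dim`.
#' @export
mean_latent <- function(gen, n_samples = 10000, seed = 1) {
  if (n_samples < 1) stop("invalid parameter: n_samples must be >= 1")
  rng <- rng_state(seed); on.exit(restore_rng(rng))
  set.seed(seed)
  Z <- matrix(stats::rnorm(gen$latent_dim * n_samples), gen$latent_dim)
  W <- apply(Z, 2, function(z) map_latent(gen, z))
  if (is.null(dim(W))) W <- matrix(W, nrow = gen$latent_dim)
  rowMeans(W)
}

#' @rdname synthesize
#' @param keep_cache Keep intermediate activations for [synthesize_grad()].
#' @export
synthesize.toy_generator <- function(gen, w, noise = NULL, keep_cache = FALSE) {
  stopifnot(length(w) == gen$latent_dim)
  if (is.null(noise)) noise <- zero_noise(gen)
  if (length(noise) != length(gen$noise_profile) ||
      !all(vapply(noise, nrow, 1L) == gen$noise_profile))
    stop("noise-map set does not match the generator profile")
  wt <- gen$weights
  S <- gen$output_side
  pre_h <- as.numeric(wt$A %*% w + wt$b)
  h <- tanh(pre_h)
  y <- as.numeric(wt$Phi %*% h) + wt$b_img
  nsum <- matrix(0, S, S)
  for (i in seq_along(noise))
    nsum <- nsum + wt$g[i] * up_nearest(noise[[i]], S)
  y <- array(y, c(S, S, 3))
  for (k in 1:3) y[, , k] <- y[, , k] + nsum
  x <- 1 / (1 + exp(-y))
  img <- image_grid(x, range = "unit", colorspace = "RGB")
  if (keep_cache)
    attr(img, "cache") <- list(w = w, noise = noise, h = h, x = x)
  img
}

#' @param want_weights Also compute weight gradients (skipped during
#'   inversion, where only the latent and noise maps move).
#' @rdname synthesize_grad
#' @export
synthesize_grad.toy_generator <- function(gen, cache, d_pixels,
                                          want_weights = TRUE) {
  wt <- gen$weights
  S <- gen$output_side
  x <- cache$x; h <- cache$h
  d_y <- d_pixels * x * (1 - x)           # logistic backprop
  d_y_vec <- as.numeric(d_y)
  d_h <- as.numeric(crossprod(wt$Phi, d_y_vec))
  d_pre <- d_h * (1 - h^2)
  d_w <- as.numeric(crossprod(wt$A, d_pre))
  d_y_spatial <- d_y[, , 1] + d_y[, , 2] + d_y[, , 3]
  d_noise <- vector("list", length(gen$noise_profile))
  d_g <- numeric(length(gen$noise_profile))
  for (i in seq_along(gen$noise_profile)) {
    r <- gen$noise_profile[i]
    bs <- block_sum(d_y_spatial, r)
    d_noise[[i]] <- wt$g[i] * bs
    d_g[i] <- sum(up_nearest(cache$noise[[i]], S) * d_y_spatial)
  }
  out <- list(d_w = d_w, d_noise = d_noise)
  if (want_weights)
    out$d_weights <- list(A = d_pre %o% cache$w, b = d_pre,
                          Phi = d_y_vec %o% h, b_img = d_y_vec, g = d_g)
  out
}

#' Save / load generator weights
#'
#' Backends persist their own weights reproducibly; the toy backend uses a
#' plain RDS checkpoint.
#'
#' @param gen A `toy_generator`.
#' @param path Checkpoint path.
#' @return `path` (save) or the restored generator (load).
#' @export
save_generator <- function(gen, path) { saveRDS(gen, path); invisible(path) }

#' @rdname save_generator
#' @export
load_generator <- function(path) readRDS(path)
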