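#' Face inversion (latent projection)
#'
#' Inversion (projection) finds the latent vector and noise maps whose
#' synthesis best matches a target face.  Starting from the mean intermediate
#' latent, the image term (perceptual distance between target and synthesis)
#' plus `alpha` times a noise-randomness regularizer is minimized by
#' adaptive-moment gradient steps on the latent and all noise maps.  The
#' regularizer penalizes lag-1 spatial autocorrelation of every noise map at
#' every dyadic downsampling, keeping the maps noise-like so facial detail
#' cannot leak into them.
#'
#' @name inversion
#' @keywords internal
NULL

#' Noise-randomness regularizer
#'
#' For each noise map, a pyramid of successive 2x mean-pooled versions is
#' built down to 8x8.  At every pyramid level of side `r`, the squared
#' normalized lag-1 autocorrelations are accumulated:
#' `(sum(n(x,y) n(x-1,y)) / r^2)^2 + (sum(n(x,y) n(x,y-1)) / r^2)^2`, with
#' out-of-range neighbours skipped.  The total over maps and levels is
#' returned, unscaled.
#'
#' @param noise_maps List of square numeric matrices.
#' @return Nonnegative scalar.
#' @export
noise_regularizer <- function(noise_maps) {
  tot <- 0
  for (n in noise_maps) {
    m <- n
    repeat {
      r <- nrow(m)
      a_h <- sum(m[-1, , drop = FALSE] * m[-r, , drop = FALSE]) / r^2
      a_v <- sum(m[, -1, drop = FALSE] * m[, -r, drop = FALSE]) / r^2
      tot <- tot + a_h^2 + a_v^2
      if (r <= 8) break
      m <- block_sum(m, r / 2) / 4
    }
  }
  tot
}

# analytic gradient of noise_regularizer w.r.t. each map
noise_regularizer_grad <- function(noise_maps) {
  lapply(noise_maps, function(n) {
    levels <- list(n)
    while (nrow(levels[[length(levels)]]) > 8) {
      m <- levels[[length(levels)]]
      levels[[length(levels) + 1]] <- block_sum(m, nrow(m) / 2) / 4
    }
    g_top <- NULL
    for (j in rev(seq_along(levels))) {
      m <- levels[[j]]; r <- nrow(m)
      a_h <- sum(m[-1, , drop = FALSE] * m[-r, , drop = FALSE]) / r^2
      a_v <- sum(m[, -1, drop = FALSE] * m[, -r, drop = FALSE]) / r^2
      g <- matrix(0, r, r)
      g[-1, ] <- g[-1, ] + m[-r, , drop = FALSE]
      g[-r, ] <- g[-r, ] + m[-1, , drop = FALSE]
      g <- g * (2 * a_h / r^2)
      g2 <- matrix(0, r, r)
      g2[, -1] <- g2[, -1] + m[, -r, drop = FALSE]
      g2[, -r] <- g2[, -r] + m[, -1, drop = FALSE]
      g <- g + g2 * (2 * a_v / r^2)
      if (!is.null(g_top)) g <- g + up_nearest(g_top, r) / 4
      g_top <- g
    }
    g_top
  })
}

#' Inversion configuration
#'
#' Defaults follow the production face-inversion recipe: 450 iterations,
#' regularizer scale `alpha = 1e5`, mean latent estimated from 10,000
#' samples, adaptive-moment optimizer with a ramped cosine learning-rate
#' schedule.
#'
#' @param iterations Gradient-step budget.
#' @param lr Base learning rate.
#' @param alpha Noise-regularizer scale.
#' @param mean_latent_samples Samples for the mean-latent initialization.
#' @param seed Integer seed (initialization and noise draws).
#' @param optimize_noise Optimize the noise maps as well as the latent.
#' @param early_stop Stop early when the image loss improves less than
#'   `early_stop_tol` over `early_stop_window` iterations.
#' @param early_stop_tol,early_stop_window Early-stop parameters.
#' @param lr_rampup,lr_rampdown Warm-up / cosine ramp-down fractions of the
#'   schedule.
#' @return A list of class `inversion_config`.
#' @export
inversion_config <- function(iterations = 450, lr = 0.05, alpha = 1e5,
                             mean_latent_samples = 10000, seed = 1,
                             optimize_noise = TRUE,
                             early_stop = FALSE, early_stop_tol = 1e-5,
                             early_stop_window = 25,
                             lr_rampup = 0.05, lr_rampdown = 0.25) {
  structure(as.list(environment()), class = "inversion_config")
}

# --- adaptive-moment optimizer (per-parameter state) -----------------------
adam_new <- function(template) list(m = template * 0, v = template * 0, t = 0)
adam_step <- function(st, grad, lr, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mh <- st$m / (1 - beta1^st$t)
  vh <- st$v / (1 - beta2^st$t)
  st$delta <- lr * mh / (sqrt(vh) + eps)
  st
}

lr_schedule <- function(i, n, base, rampup, rampdown) {
  t <- i / max(n, 1)
  f <- min(1, (1 - t) / rampdown)
  f <- 0.5 - 0.5 * cos(f * pi)
  base * f * min(1, t / rampup + 1e-12)
}

#' Invert a face into a generator's latent space
#'
#' @param gen A generator backend (e.g. [toy_generator()]).
#' @param target An RGB [image_grid()] with side `gen$output_side`.
#' @param backend A `perceptual_backend` for the image term.
#' @param cfg An [inversion_config()].
#' @return A `latent_state`: fields `w`, `noise_maps`, `step`, `loss_trace`
#'   (tibble of iteration, image_loss, reg_loss), `image` (final synthesis)
#'   and `init_image_loss`.
#' @export
invert <- function(gen, target, backend = randconv_backend(),
                   cfg = inversion_config()) {
  stopifnot(inherits(target, "image_grid"))
  if (!all(dim(target$pixels)[1:2] == gen$output_side))
    stop("target shape does not match the generator output side")
  tpx <- convert_range(target, "unit")$pixels
  fwd_t <- pb_forward(backend, tpx)
  w <- mean_latent(gen, cfg$mean_latent_samples, seed = cfg$seed)
  noise <- init_noise(gen, seed = cfg$seed + 1L)
  st_w <- adam_new(w)
  st_n <- lapply(noise, adam_new)
  trace <- vector("list", cfg$iterations)
  init_loss <- NULL
  i <- 0
  while (i < cfg$iterations) {
    i <- i + 1
    x <- synthesize(gen, w, noise, keep_cache = TRUE)
    res <- perceptual_distance_grad(backend, x$pixels, fwd_t)
    reg <- noise_regularizer(noise)
    loss <- res$distance + cfg$alpha * reg
    if (!is.finite(loss))
      stop("divergence: non-finite loss at iteration ", i)
    if (is.null(init_loss)) init_loss <- res$distance
    trace[[i]] <- c(res$distance, reg)
    sg <- synthesize_grad(gen, attr(x, "cache"), res$grad,
                          want_weights = FALSE)
    lr <- lr_schedule(i, cfg$iterations, cfg$lr, cfg$lr_rampup, cfg$lr_rampdown)
    st_w <- adam_step(st_w, sg$d_w, lr)
    w <- w - st_w$delta
    if (cfg$optimize_noise) {
      rg <- noise_regularizer_grad(noise)
      for (k in seq_along(noise)) {
        gk <- sg$d_noise[[k]] + cfg$alpha * rg[[k]]
        st_n[[k]] <- adam_step(st_n[[k]], gk, lr)
        noise[[k]] <- noise[[k]] - st_n[[k]]$delta
      }
    }
    if (cfg$early_stop && i > cfg$early_stop_window) {
      past <- trace[[i - cfg$early_stop_window]][1]
      if (past - res$distance < cfg$early_stop_tol) break
    }
  }
  trace <- trace[seq_len(i)]
  tr <- tibble::tibble(
    iteration = seq_len(length(trace)),
    image_loss = vapply(trace, `[`, 0, 1),
    reg_loss = vapply(trace, `[`, 0, 2))
  structure(list(w = w, noise_maps = noise, step = nrow(tr),
                 loss_trace = tr,
                 image = synthesize(gen, w, noise),
                 init_image_loss = if (is.null(init_loss)) NA_real_ else init_loss,
                 config = cfg),
            class = "latent_state")
}

#' @export
print.latent_state <- function(x, ...) {
  last <- if (x$step > 0) x$loss_trace$image_loss[x$step] else NA
  cat(sprintf("<latent_state: %d steps, image loss %.4g (init %.4g)>\n",
              x$step, last, x$init_image_loss))
  invisible(x)
}
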