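#' Generator model adaptation
#'
#' Projection alone leaves identity detail on the table: the generator's
#' latent space cannot represent every individual face.  Adaptation briefly
#' fine-tunes the generator *weights* -- with the inverted latent and its
#' noise maps frozen -- to minimize the sum of the perceptual distance and
#' the mean squared pixel difference between the original face and the
#' synthesis.  Stopped early (the production default is 50 iterations) the
#' adapted generator recovers identity detail while the anomaly, absent from
#' the latent space, stays suppressed; run much longer it starts
#' reconstructing the anomaly itself, which defeats normalization.
#'
#' @name adaptation
#' @keywords internal
NULL

#' Adaptation loss
#'
#' Perceptual distance plus mean squared pixel difference between the
#' original and synthesized images, both in unit range.
#'
#' @param x_org,x_norm [image_grid()]s of identical shape.
#' @param backend A `perceptual_backend`.
#' @return Nonnegative scalar, 0 iff the two images agree.
#' @export
adaptation_loss <- function(x_org, x_norm, backend = randconv_backend()) {
  stop_if_shape_mismatch(x_org, x_norm)
  a <- convert_range(x_org, "unit")$pixels
  b <- convert_range(x_norm, "unit")$pixels
  perceptual_distance(backend, x_org, x_norm) + mean((a - b)^2)
}

#' Adaptation configuration
#'
#' Weight updates use the same adaptive-moment optimizer family as
#' inversion, with a tenth of the inversion step size: fine-tuning should
#' nudge the generator, not retrain it.
#'
#' @param iterations Weight-update budget (production default 50).
#' @param lr Learning rate for the weight updates.
#' @param snapshots Integer iterations at which to keep synthesized images.
#' @param seed Integer seed (unused by the deterministic updates; kept for
#'   config completeness).
#' @return A list of class `adaptation_config`.
#' @export
adaptation_config <- function(iterations = 50, lr = 0.005,
                              snapshots = integer(), seed = 1) {
  structure(as.list(environment()), class = "adaptation_config")
}

#' Adapt generator weights to a target face
#'
#' Holds the inverted latent and noise maps fixed and gradient-updates a
#' *copy* of the generator's weights to minimize [adaptation_loss()]; the
#' generator passed in is never modified.
#'
#' @param gen A generator backend.
#' @param x_org Target RGB [image_grid()], side `gen$output_side`.
#' @param latent A `latent_state` from [invert()] on the same generator.
#' @param backend A `perceptual_backend`.
#' @param cfg An [adaptation_config()].
#' @return An `adaptation_result`: `generator` (adapted copy), `image`
#'   (x_norm), `loss_trace` (tibble of iteration, perceptual, pixel_l2),
#'   `snapshots` (named list of image grids).
#' @export
adapt <- function(gen, x_org, latent, backend = randconv_backend(),
                  cfg = adaptation_config()) {
  stopifnot(inherits(latent, "latent_state"))
  if (length(latent$w) != gen$latent_dim ||
      !all(vapply(latent$noise_maps, nrow, 1L) == gen$noise_profile))
    stop("latent state does not match the generator profile")
  if (!all(dim(x_org$pixels)[1:2] == gen$output_side))
    stop("target shape does not match the generator output side")
  tpx <- convert_range(x_org, "unit")$pixels
  fwd_t <- pb_forward(backend, tpx)
  gen2 <- gen                       # adaptation operates on a copy
  w <- latent$w; noise <- latent$noise_maps
  st <- lapply(gen2$weights, adam_new)
  trace <- vector("list", cfg$iterations)
  snaps <- list()
  npix <- length(tpx)
  for (i in seq_len(cfg$iterations)) {
    x <- synthesize(gen2, w, noise, keep_cache = TRUE)
    res <- perceptual_distance_grad(backend, x$pixels, fwd_t)
    diff <- x$pixels - tpx
    l2 <- mean(diff^2)
    loss <- res$distance + l2
    if (!is.finite(loss)) stop("divergence: non-finite loss at iteration ", i)
    trace[[i]] <- c(res$distance, l2)
    d_px <- res$grad + 2 * diff / npix
    sg <- synthesize_grad(gen2, attr(x, "cache"), d_px)
    for (nm in names(gen2$weights)) {
      st[[nm]] <- adam_step(st[[nm]], sg$d_weights[[nm]], cfg$lr)
      gen2$weights[[nm]] <- gen2$weights[[nm]] - st[[nm]]$delta
    }
    if (i %in% cfg$snapshots)
      snaps[[as.character(i)]] <- synthesize(gen2, w, noise)
  }
  tr <- tibble::tibble(
    iteration = seq_len(cfg$iterations),
    perceptual = vapply(trace, `[`, 0, 1),
    pixel_l2 = vapply(trace, `[`, 0, 2))
  structure(list(generator = gen2, image = synthesize(gen2, w, noise),
                 loss_trace = tr, snapshots = snaps, config = cfg),
            class = "adaptation_result")
}

#' @export
print.adaptation_result <- function(x, ...) {
  n <- nrow(x$loss_trace)
  cat(sprintf("<adaptation_result: %d steps, final pixel L2 %.4g>\n",
              n, if (n > 0) x$loss_trace$pixel_l2[n] else NA))
  invisible(x)
}
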