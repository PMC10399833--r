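#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an inversion trace
#'
#' One row per optimization step with the image (perceptual) loss and the
#' unscaled noise-regularizer value.
#'
#' @param x A `latent_state`.
#' @param ... Unused.
#' @return A tibble `iteration`, `image_loss`, `reg_loss`.
#' @export
tidy.latent_state <- function(x, ...) x$loss_trace

#' @rdname tidy.latent_state
#' @export
glance.latent_state <- function(x, ...) {
  tibble::tibble(
    steps = x$step,
    init_image_loss = x$init_image_loss,
    final_image_loss = if (x$step > 0) x$loss_trace$image_loss[x$step] else NA_real_,
    final_reg_loss = if (x$step > 0) x$loss_trace$reg_loss[x$step] else NA_real_)
}

#' Tidy an adaptation trace
#'
#' @param x An `adaptation_result`.
#' @param ... Unused.
#' @return A tibble `iteration`, `perceptual`, `pixel_l2`.
#' @export
tidy.adaptation_result <- function(x, ...) x$loss_trace

#' @rdname tidy.adaptation_result
#' @export
glance.adaptation_result <- function(x, ...) {
  n <- nrow(x$loss_trace)
  tibble::tibble(
    steps = n,
    final_perceptual = if (n > 0) x$loss_trace$perceptual[n] else NA_real_,
    final_pixel_l2 = if (n > 0) x$loss_trace$pixel_l2[n] else NA_real_)
}

#' Tidy an ablation grid
#'
#' @param x An `ablation_result`.
#' @param ... Unused.
#' @return The long cell tibble (`arm`, `method`, `variant`, `mask_kind`,
#'   `r`, `n`).
#' @export
tidy.ablation_result <- function(x, ...) x$cells

#' @rdname tidy.ablation_result
#' @export
glance.ablation_result <- function(x, ...) {
  best <- x$cells[which.max(x$cells$r), ]
  tibble::tibble(n_cells = nrow(x$cells), best_r = best$r,
                 best_method = best$method, best_variant = best$variant,
                 best_mask = best$mask_kind, best_arm = best$arm)
}

#' Tidy an anomaly score
#' @param x An `anomaly_score`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.anomaly_score <- function(x, ...) {
  tibble::tibble(raw_energy = x$raw_energy, score = x$score,
                 n_mask = x$n_mask, mask_kind = x$mask_kind,
                 method = x$method,
                 ycbcr = x$flags$ycbcr_applied,
                 erosion = x$flags$erosion_applied)
}
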