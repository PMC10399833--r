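#' Layered perceptual distance
#'
#' The perceptual distance between two images is a layered feature metric:
#' for every feature layer, channel features are unit-normalized at each
#' spatial position, scaled by fixed per-channel weights, and the squared
#' differences are averaged over positions and summed over layers.  The
#' backend supplying the feature layers is pluggable: production systems use
#' a pretrained deep feature extractor; this package ships a seeded
#' random-convolution extractor (no downloads, fully deterministic) and a
#' degenerate raw-pixel backend whose distance reduces to mean squared error.
#'
#' @name perceptual
#' @keywords internal
NULL

# ---- minimal conv machinery (zero-padded "same" convolution) --------------

.conv_idx_cache <- new.env(parent = emptyenv())

# linear-index matrix mapping padded input to im2col layout, cached
conv_idx <- function(H, W, k, ci) {
  key <- paste(H, W, k, ci, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- (k - 1) %/% 2
  Hp <- H + 2 * p; Wp <- W + 2 * p
  r <- rep(seq_len(H), W); c_ <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, k * k * ci)
  col <- 1L
  for (ch in seq_len(ci)) for (dc in 0:(k - 1)) for (dr in 0:(k - 1)) {
    idx[, col] <- (r + dr) + (c_ + dc - 1L) * Hp + (ch - 1L) * Hp * Wp
    col <- col + 1L
  }
  .conv_idx_cache[[key]] <- idx
  idx
}

conv2d <- function(x, filt) {
  k <- dim(filt)[1]; ci <- dim(filt)[3]; co <- dim(filt)[4]
  H <- dim(x)[1]; W <- dim(x)[2]
  p <- (k - 1) %/% 2
  xp <- array(0, c(H + 2 * p, W + 2 * p, ci))
  xp[p + seq_len(H), p + seq_len(W), ] <- x
  X <- matrix(xp[conv_idx(H, W, k, ci)], H * W)
  array(X %*% matrix(filt, k * k * ci, co), c(H, W, co))
}

# gradient w.r.t. the conv input: correlation with the flipped filters
conv2d_back <- function(d_out, filt) {
  k <- dim(filt)[1]
  ff <- aperm(filt[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  conv2d(d_out, ff)
}

meanpool2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  out <- array(0, c(H / 2, W / 2, C))
  for (k in seq_len(C)) out[, , k] <- block_sum(x[, , k], H / 2) / 4
  out
}

meanpool2_back <- function(d, H) {
  C <- dim(d)[3]
  out <- array(0, c(H, H, C))
  for (k in seq_len(C)) out[, , k] <- up_nearest(d[, , k], H) / 4
  out
}

# ---- backend constructors -------------------------------------------------

new_perceptual_backend <- function(name, layers, scale, shift, normalize,
                                   eps = 1e-10) {
  structure(list(name = name, layers = layers, scale = scale, shift = shift,
                 normalize = normalize, eps = eps),
            class = "perceptual_backend")
}

#' @export
print.perceptual_backend <- function(x, ...) {
  cat(sprintf("<perceptual_backend '%s': %d layer(s)%s>\n", x$name,
              length(x$layers), if (x$normalize) ", unit-normalized" else ""))
  invisible(x)
}

#' Raw-pixel (degenerate) perceptual backend
#'
#' A single identity feature layer with uniform weights and no channel
#' normalization; its distance equals the mean squared pixel difference.
#' Useful as an analytic oracle and for pixel-level objectives.
#'
#' @return A `perceptual_backend`.
#' @export
pixel_backend <- function() {
  new_perceptual_backend(
    "pixel",
    layers = list(list(kind = "identity", w = rep(1 / sqrt(3), 3))),
    scale = 1, shift = 0, normalize = FALSE)
}

#' Seeded random-convolution perceptual backend
#'
#' A fixed-weight feature extractor: an identity tap on the (centered)
#' pixels, a 3x3 random convolution with `tanh` activation, and a second
#' convolution on the 2x mean-pooled features.  Filters and channel weights
#' are drawn once from `seed`; the backend never changes afterwards, so all
#' distances are deterministic and no pretrained weights are required.
#'
#' @param seed Integer seed for the filter bank.
#' @param channels Feature channels per conv layer (default 8).
#' @return A `perceptual_backend` with a spatial map (see [perceptual_map()]).
#' @export
randconv_backend <- function(seed = 7, channels = 8) {
  rng <- rng_state(seed); on.exit(restore_rng(rng))
  set.seed(seed)
  mkfilt <- function(ci, co) array(stats::rnorm(9 * ci * co,
                                                sd = 1.2 / sqrt(9 * ci)),
                                   c(3, 3, ci, co))
  mkw <- function(co) stats::runif(co, 0.5, 1.5) / sqrt(co)
  layers <- list(
    list(kind = "identity", w = mkw(3)),
    list(kind = "conv", pool = FALSE, filt = mkfilt(3, channels),
         w = mkw(channels)),
    list(kind = "conv", pool = TRUE, filt = mkfilt(channels, channels),
         w = mkw(channels)))
  new_perceptual_backend(paste0("randconv-", seed), layers,
                         scale = 2, shift = -0.5, normalize = TRUE)
}

# ---- forward / backward ---------------------------------------------------

# forward pass; per layer keeps the raw feature array, the normalized
# features as an (H*W) x C matrix, the inverse-norm vector, and the chain
# state needed for backprop
pb_forward <- function(pb, px) {
  cur <- (px + pb$shift) * pb$scale
  n_l <- length(pb$layers)
  feats <- hats <- norms <- states <- dims <- vector("list", n_l)
  for (i in seq_len(n_l)) {
    ly <- pb$layers[[i]]
    if (ly$kind == "identity") {
      F_ <- cur
    } else {
      inp <- if (isTRUE(ly$pool)) meanpool2(cur) else cur
      states[[i]] <- dim(cur)[1]          # side before pooling
      F_ <- tanh(conv2d(inp, ly$filt))
      cur <- F_
    }
    d <- dim(F_)
    Fm <- matrix(F_, d[1] * d[2], d[3])
    feats[[i]] <- F_
    dims[[i]] <- d
    if (pb$normalize) {
      nrm <- sqrt(.rowSums(Fm * Fm, nrow(Fm), ncol(Fm)) + pb$eps)
      hats[[i]] <- Fm / nrm
      norms[[i]] <- nrm
    } else {
      hats[[i]] <- Fm
    }
  }
  list(feats = feats, hats = hats, norms = norms, states = states,
       dims = dims)
}

# per-layer mean squared weighted difference and (optionally) dL/dx
pb_compare <- function(pb, fwd_x, fwd_y, want_grad = FALSE,
                       want_map = FALSE) {
  n_l <- length(pb$layers)
  dl <- numeric(n_l)
  maps <- if (want_map) vector("list", n_l)
  d_hats <- if (want_grad) vector("list", n_l)
  for (i in seq_len(n_l)) {
    w <- pb$layers[[i]]$w
    d <- fwd_x$hats[[i]] - fwd_y$hats[[i]]
    m <- as.numeric((d * d) %*% w^2)
    dl[i] <- mean(m)
    if (want_map) maps[[i]] <- matrix(m, fwd_x$dims[[i]][1])
    if (want_grad)
      d_hats[[i]] <- d * rep(2 * w^2, each = nrow(d)) / nrow(d)
  }
  out <- list(distance = sum(dl), per_layer = dl)
  if (want_map) out$maps <- maps
  if (!want_grad) return(out)
  # backprop tap gradients through the layer chain to the input
  d_taps <- vector("list", n_l)
  for (i in seq_len(n_l)) {
    g <- d_hats[[i]]
    if (pb$normalize) {
      hat <- fwd_x$hats[[i]]; nrm <- fwd_x$norms[[i]]
      dot <- .rowSums(g * hat, nrow(g), ncol(g))
      g <- (g - hat * dot) / nrm
    }
    d_taps[[i]] <- array(g, fwd_x$dims[[i]])
  }
  d_cur <- NULL
  for (i in rev(seq_len(n_l))) {
    ly <- pb$layers[[i]]
    d_cur <- if (is.null(d_cur)) d_taps[[i]] else d_cur + d_taps[[i]]
    if (ly$kind == "conv") {
      F_ <- fwd_x$feats[[i]]
      d_pre <- d_cur * (1 - F_ * F_)
      d_inp <- conv2d_back(d_pre, ly$filt)
      if (isTRUE(ly$pool)) d_inp <- meanpool2_back(d_inp, fwd_x$states[[i]])
      d_cur <- d_inp
    }
  }
  out$grad <- d_cur * pb$scale
  out
}

#' Perceptual distance between two images
#'
#' Layered weighted feature distance (see the package perceptual-distance
#' description): per layer, unit-normalized channel features are weighted,
#' squared differences are averaged over spatial positions, and layer terms
#' are summed.
#'
#' @param backend A `perceptual_backend`.
#' @param x,y [image_grid()]s of identical shape.
#' @return Nonnegative scalar; 0 iff the feature stacks agree.
#' @export
perceptual_distance <- function(backend, x, y) {
  stop_if_shape_mismatch(x, y)
  px <- convert_range(x, "unit")$pixels
  py <- convert_range(y, "unit")$pixels
  pb_compare(backend, pb_forward(backend, px), pb_forward(backend, py))$distance
}

# internal: distance + gradient w.r.t. x's pixels, with y's features cached
perceptual_distance_grad <- function(backend, px, fwd_y) {
  fwd_x <- pb_forward(backend, px)
  pb_compare(backend, fwd_x, fwd_y, want_grad = TRUE)
}
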