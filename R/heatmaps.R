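#' Construct a heatmap
#'
#' A single-channel nonnegative difference raster aligned to the source
#' images, with provenance flags recording how it was produced.
#'
#' @param values Nonnegative H x W numeric matrix.
#' @param method One of `"pse"`, `"ssim"`, `"perceptual"`.
#' @param ycbcr_applied,erosion_applied Provenance flags.
#' @return An object of class `heatmap`.
#' @export
heatmap <- function(values, method = c("pse", "ssim", "perceptual"),
                    ycbcr_applied = FALSE, erosion_applied = FALSE) {
  method <- match.arg(method)
  values <- as.matrix(values)
  if (min(values) < -1e-9) stop("heatmap values must be nonnegative")
  values[values < 0] <- 0
  structure(list(values = values, method = method,
                 flags = list(ycbcr_applied = ycbcr_applied,
                              erosion_applied = erosion_applied)),
            class = "heatmap")
}

#' @export
print.heatmap <- function(x, ...) {
  cat(sprintf("<heatmap %s %dx%d%s%s, max %.4g>\n", x$method,
              nrow(x$values), ncol(x$values),
              if (x$flags$ycbcr_applied) " +ycbcr" else "",
              if (x$flags$erosion_applied) " +erosion" else "",
              max(x$values)))
  invisible(x)
}

#' RGB to YCbCr color transformation
#'
#' Applies the BT.601 affine transform: with unit-range gamma-corrected
#' R'G'B' inputs,
#' `Y'  = 16  +  65.481 R' + 128.553 G' + 24.966 B'`,
#' `Cb  = 128 -  37.797 R' -  74.203 G' + 112    B'`,
#' `Cr  = 128 + 112     R' -  93.786 G' - 18.214 B'`.
#' Achromatic inputs map to Cb = Cr = 128 exactly.  Output is byte-range
#' with colorspace tag `"YCbCr"`.
#'
#' @param img An RGB [image_grid()] (any range tag; converted internally).
#' @return A byte-range YCbCr [image_grid()].
#' @export
rgb_to_ycbcr <- function(img) {
  stopifnot(inherits(img, "image_grid"))
  if (img$colorspace != "RGB") stop("rgb_to_ycbcr requires an RGB image")
  u <- convert_range(img, "unit")$pixels
  R <- u[, , 1]; G <- u[, , 2]; B <- u[, , 3]
  out <- array(0, dim(u))
  out[, , 1] <- 16 + 65.481 * R + 128.553 * G + 24.966 * B
  out[, , 2] <- 128 - 37.797 * R - 74.203 * G + 112 * B
  out[, , 3] <- 128 + 112 * R - 93.786 * G - 18.214 * B
  image_grid(out, range = "byte", colorspace = "YCbCr")
}

#' Pixelwise squared-error heatmap
#'
#' The element-wise squared difference `(x_org - x_norm) * (x_org - x_norm)`;
#' multichannel inputs are reduced by summing squared differences over
#' channels (or use `channels` to restrict, e.g. to the luma channel).
#'
#' @param x_org,x_norm [image_grid()]s of identical shape and colorspace.
#' @param channels Integer channel subset (default: all).
#' @return A [heatmap()] with method `"pse"`.
#' @export
pse_map <- function(x_org, x_norm, channels = NULL) {
  stop_if_shape_mismatch(x_org, x_norm)
  if (x_org$colorspace != x_norm$colorspace || x_org$range != x_norm$range)
    stop("colorspace/range mismatch between images")
  if (is.null(channels)) channels <- seq_len(dim(x_org$pixels)[3])
  d2 <- (x_org$pixels[, , channels, drop = FALSE] -
         x_norm$pixels[, , channels, drop = FALSE])^2
  heatmap(apply(d2, c(1, 2), sum), method = "pse",
          ycbcr_applied = x_org$colorspace == "YCbCr")
}

# sliding box sum via integral image; in-bounds (shrinking) windows at edges
box_stats <- function(m, half) {
  H <- nrow(m); W <- ncol(m)
  S <- matrix(0, H + 1, W + 1)
  S[-1, -1] <- apply(apply(m, 2, cumsum), 1, cumsum) |> t()
  r0 <- pmax(0:(H - 1) - half, 0); r1 <- pmin(0:(H - 1) + half, H - 1)
  c0 <- pmax(0:(W - 1) - half, 0); c1 <- pmin(0:(W - 1) + half, W - 1)
  sums <- S[r1 + 2, c1 + 2] - S[r0 + 1, c1 + 2] - S[r1 + 2, c0 + 1] +
    S[r0 + 1, c0 + 1]
  counts <- outer(r1 - r0 + 1, c1 - c0 + 1)
  list(sum = sums, n = counts)
}

#' Structural-similarity dissimilarity heatmap
#'
#' Windowed SSIM
#' `((2 mu_x mu_y + c1)(2 sigma_xy + c2)) /
#'  ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`
#' computed per pixel over an odd square window (in-bounds windows at the
#' edges), averaged over channels; the heatmap is `1 - SSIM`, clipped at 0.
#' Stabilizers default to `c1 = (0.01 L)^2`, `c2 = (0.03 L)^2` with `L` the
#' dynamic range of the inputs' range tag.
#'
#' @param x_org,x_norm [image_grid()]s of identical shape and range.
#' @param window Odd window side (default 7).
#' @param c1,c2 Stabilizers; `NULL` for the defaults above.
#' @return A [heatmap()] with method `"ssim"`; values in 0..2.
#' @export
ssim_map <- function(x_org, x_norm, window = 7, c1 = NULL, c2 = NULL) {
  stop_if_shape_mismatch(x_org, x_norm)
  if (x_org$range != x_norm$range) stop("range mismatch between images")
  d <- dim(x_org$pixels)
  if (window %% 2 != 1) stop("SSIM window must be odd")
  if (window > min(d[1:2])) stop("SSIM window larger than the image")
  L <- if (x_org$range == "unit") 1 else 255
  if (is.null(c1)) c1 <- (0.01 * L)^2
  if (is.null(c2)) c2 <- (0.03 * L)^2
  half <- (window - 1) %/% 2
  acc <- matrix(0, d[1], d[2])
  for (k in seq_len(d[3])) {
    x <- x_org$pixels[, , k]; y <- x_norm$pixels[, , k]
    n <- box_stats(x, half)$n
    mx <- box_stats(x, half)$sum / n
    my <- box_stats(y, half)$sum / n
    sxx <- box_stats(x * x, half)$sum / n - mx^2
    syy <- box_stats(y * y, half)$sum / n - my^2
    sxy <- box_stats(x * y, half)$sum / n - mx * my
    ssim <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
      ((mx^2 + my^2 + c1) * (sxx + syy + c2))
    acc <- acc + ssim
  }
  heatmap(pmax(1 - acc / d[3], 0), method = "ssim",
          ycbcr_applied = x_org$colorspace == "YCbCr")
}

#' Perceptual difference heatmap
#'
#' Per-position weighted squared feature differences of every backend layer,
#' upsampled to image resolution and summed; the spatial mean of the map
#' equals [perceptual_distance()] for integer-factor layer grids.
#'
#' @param backend A `perceptual_backend` (must expose feature layers; all
#'   shipped backends do).
#' @param x_org,x_norm [image_grid()]s of identical shape.
#' @return A [heatmap()] with method `"perceptual"`.
#' @export
perceptual_map <- function(backend, x_org, x_norm) {
  stop_if_shape_mismatch(x_org, x_norm)
  px <- convert_range(x_org, "unit")$pixels
  py <- convert_range(x_norm, "unit")$pixels
  res <- pb_compare(backend, pb_forward(backend, px),
                    pb_forward(backend, py), want_map = TRUE)
  H <- dim(px)[1]
  acc <- matrix(0, H, dim(px)[2])
  for (m in res$maps) {
    if (nrow(m) != H) {
      if (H %% nrow(m) != 0)
        stop("unsupported backend: layer grid is not an integer factor of the image")
      m <- up_nearest(m, H)
    }
    acc <- acc + m
  }
  heatmap(acc, method = "perceptual",
          ycbcr_applied = x_org$colorspace == "YCbCr")
}

#' Morphological erosion (3x3 minimum filter)
#'
#' Each output pixel is the minimum over its 3x3 neighbourhood, applied
#' independently to every channel; edge pixels use their in-bounds
#' neighbourhood.  Erosion never increases any pixel value.
#'
#' @param img An [image_grid()] (any colorspace / channel count).
#' @return An [image_grid()] of identical shape, eroded.
#' @export
erode <- function(img) {
  stopifnot(inherits(img, "image_grid"))
  px <- img$pixels
  H <- dim(px)[1]; W <- dim(px)[2]
  ri <- function(s) pmin(pmax(seq_len(H) + s, 1L), H)
  ci <- function(s) pmin(pmax(seq_len(W) + s, 1L), W)
  for (k in seq_len(dim(px)[3])) {
    ch <- px[, , k]
    out <- ch
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      sh <- ch[ri(dr), ci(dc)]
      # clamp duplicates edge pixels, which exactly reproduces the
      # in-bounds-neighbourhood rule for the min filter
      out <- pmin(out, sh)
    }
    px[, , k] <- out
  }
  image_grid(px, range = img$range, colorspace = img$colorspace)
}

#' Compute a difference heatmap with optional pre-processing
#'
#' The ablation-facing entry point: optionally transforms both images to
#' YCbCr, optionally erodes both images (erosion acts on the images, not on
#' the heatmap, unless `erode_target = "heatmap"`), then computes the
#' requested difference map.
#'
#' @param x_org,x_norm RGB [image_grid()]s of identical shape.
#' @param method `"pse"`, `"ssim"` or `"perceptual"`.
#' @param ycbcr Apply the YCbCr transform first.
#' @param erosion Apply 3x3 erosion.
#' @param erode_target `"images"` (default) or `"heatmap"`.
#' @param backend Perceptual backend (method `"perceptual"` only).
#' @param range Working range for the difference stage (default `"byte"`).
#' @return A [heatmap()].
#' @export
compute_heatmap <- function(x_org, x_norm,
                            method = c("pse", "ssim", "perceptual"),
                            ycbcr = FALSE, erosion = FALSE,
                            erode_target = c("images", "heatmap"),
                            backend = NULL, range = "byte") {
  method <- match.arg(method)
  erode_target <- match.arg(erode_target)
  a <- convert_range(x_org, range); b <- convert_range(x_norm, range)
  if (ycbcr) {
    a <- rgb_to_ycbcr(a); b <- rgb_to_ycbcr(b)
    a <- convert_range(a, range); b <- convert_range(b, range)
  }
  if (erosion && erode_target == "images") {
    a <- erode(a); b <- erode(b)
  }
  hm <- switch(method,
    pse = pse_map(a, b),
    ssim = ssim_map(a, b),
    perceptual = {
      if (is.null(backend)) backend <- randconv_backend()
      perceptual_map(backend, a, b)
    })
  if (erosion && erode_target == "heatmap") {
    # heatmap values have no fixed range; apply the min filter directly
    v <- hm$values
    H <- nrow(v); W <- ncol(v)
    out <- v
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      out <- pmin(out, v[pmin(pmax(seq_len(H) + dr, 1L), H),
                         pmin(pmax(seq_len(W) + dc, 1L), W)])
    }
    hm$values <- out
  }
  hm$flags$ycbcr_applied <- ycbcr
  hm$flags$erosion_applied <- erosion
  hm
}
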