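#' Face canonicalization
#'
#' The generator expects faces in a fixed canonical frame: roughly 60% face /
#' 40% background, horizontal eyes, 100 px between the eye centers, and a
#' square crop (1024 px for the full-scale face generator).  The functions
#' documented under this topic take an arbitrary frontal photograph to that
#' frame; [preprocess_face()] chains them in the canonical order.
#'
#' @name preprocess
#' @keywords internal
NULL

#' Construct a face bounding box
#'
#' @param top,left 0-based pixel coordinates of the top-left corner.
#' @param height,width Box extent in pixels (`> 1`).
#' @return An object of class `face_box`.
#' @export
face_box <- function(top, left, height, width) {
  if (height <= 1 || width <= 1)
    stop("invalid face box: degenerate extent ", height, "x", width)
  structure(list(top = as.numeric(top), left = as.numeric(left),
                 height = as.numeric(height), width = as.numeric(width)),
            class = "face_box")
}

check_box_inside <- function(box, img) {
  d <- dim(img$pixels)
  if (box$top < 0 || box$left < 0 ||
      box$top + box$height > d[1] || box$left + box$width > d[2])
    stop("face box extends outside the image")
  invisible(TRUE)
}

#' A detector backend from explicit functions
#'
#' Face/landmark detection is pluggable: a backend is any pair of
#' deterministic functions `detect_face(img) -> face_box` and
#' `detect_landmarks(img, box) -> landmark_set`.  Production deployments wrap
#' a conventional cascade face detector plus a 68-point landmark predictor;
#' tests and fixtures inject ground truth via [fixture_detector()].
#'
#' @param detect_face Function `img -> face_box`.
#' @param detect_landmarks Function `(img, box) -> landmark_set`.
#' @return An object of class `detector_backend`.
#' @export
detector_backend <- function(detect_face, detect_landmarks) {
  structure(list(detect_face = detect_face,
                 detect_landmarks = detect_landmarks),
            class = "detector_backend")
}

#' Ground-truth detector backend
#'
#' Wraps known landmarks (e.g. from a synthetic fixture) as a
#' [detector_backend()]; the face box is derived from the landmark extent.
#'
#' @param lm A [landmark_set()].
#' @return A [detector_backend()].
#' @export
fixture_detector <- function(lm) {
  detector_backend(
    detect_face = function(img) landmark_face_box(lm, dim(img$pixels)[1:2]),
    detect_landmarks = function(img, box) lm
  )
}

#' Face box implied by a landmark set
#'
#' The 68-point scheme has no forehead points, so the box is the landmark
#' bounding box extended upward by 60% of the inter-ocular distance (a
#' conventional forehead allowance), clipped to the frame.
#'
#' @param lm A [landmark_set()].
#' @param frame_dim Optional `c(H, W)` to clip against.
#' @return A [face_box()].
#' @export
landmark_face_box <- function(lm, frame_dim = NULL) {
  p <- lm$points
  top <- min(p[, 1]) - 0.6 * eye_distance(lm)
  bottom <- max(p[, 1])
  left <- min(p[, 2]); right <- max(p[, 2])
  if (!is.null(frame_dim)) {
    top <- max(top, 0); left <- max(left, 0)
    bottom <- min(bottom, frame_dim[1] - 1)
    right <- min(right, frame_dim[2] - 1)
  }
  face_box(top, left, bottom - top + 1, right - left + 1)
}

# ---- low-level raster ops -------------------------------------------------

# reflect continuous 0-based coordinates into [0, n-1] (symmetric about the
# edge pixels, period 2(n-1))
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(0, length(x)))
  p <- 2 * (n - 1)
  x <- abs(x) %% p
  ifelse(x > (n - 1), p - x, x)
}

# bilinear sample of one channel at continuous 0-based (r, c) grids
# (matrices of equal shape); out-of-range coordinates are reflected
bilinear_sample <- function(ch, r, c) {
  H <- nrow(ch); W <- ncol(ch)
  out_rows <- nrow(r)
  r <- reflect_coord(as.numeric(r), H); c <- reflect_coord(as.numeric(c), W)
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  i00 <- cbind(r0 + 1, c0 + 1); i01 <- cbind(r0 + 1, c1 + 1)
  i10 <- cbind(r1 + 1, c0 + 1); i11 <- cbind(r1 + 1, c1 + 1)
  v <- ch[i00] * (1 - fr) * (1 - fc) + ch[i01] * (1 - fr) * fc +
       ch[i10] * fr * (1 - fc) + ch[i11] * fr * fc
  matrix(v, nrow = out_rows)
}

# warp an image with an affine *inverse* map: input_coord = A %*% out + b,
# coords 0-based (row, col); out_dim = c(H', W')
warp_affine <- function(img, A, b, out_dim) {
  Ho <- out_dim[1]; Wo <- out_dim[2]
  ro <- matrix(rep(0:(Ho - 1), Wo), nrow = Ho)
  co <- matrix(rep(0:(Wo - 1), each = Ho), nrow = Ho)
  ri <- A[1, 1] * ro + A[1, 2] * co + b[1]
  ci <- A[2, 1] * ro + A[2, 2] * co + b[2]
  px <- array(0, c(Ho, Wo, dim(img$pixels)[3]))
  for (k in seq_len(dim(img$pixels)[3]))
    px[, , k] <- bilinear_sample(img$pixels[, , k], ri, ci)
  lim <- if (img$range == "unit") 1 else 255
  image_grid(pmin(pmax(px, 0), lim), range = img$range,
             colorspace = img$colorspace)
}

# separable Gaussian blur of a matrix, replicate-padded edges
gauss_blur_mat <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  H <- nrow(m); W <- ncol(m)
  out <- matrix(0, H, W)
  for (j in seq_along(k)) {     # rows
    idx <- pmin(pmax(seq_len(H) + (j - half - 1L), 1L), H)
    out <- out + k[j] * m[idx, , drop = FALSE]
  }
  m2 <- out; out <- matrix(0, H, W)
  for (j in seq_along(k)) {     # cols
    idx <- pmin(pmax(seq_len(W) + (j - half - 1L), 1L), W)
    out <- out + k[j] * m2[, idx, drop = FALSE]
  }
  out
}

gauss_blur_img <- function(img, sigma) {
  px <- img$pixels
  for (k in seq_len(dim(px)[3])) px[, , k] <- gauss_blur_mat(px[, , k], sigma)
  image_grid(px, range = img$range, colorspace = img$colorspace)
}

# ---- preprocessing stages -------------------------------------------------

#' Composite a sharp face over a blurred background
#'
#' Builds a foreground mask from the face box, Gaussian-smooths it to a 0-1
#' weight map (re-clamping the box interior to 1 so face pixels pass through
#' unchanged), and composites the original image over a blurred copy.
#'
#' @param img An [image_grid()].
#' @param box A [face_box()].
#' @param sigma Gaussian standard deviation, pixels (`> 0`).
#' @return An [image_grid()] of the same shape.
#' @export
blur_background <- function(img, box, sigma) {
  stopifnot(inherits(img, "image_grid"), sigma > 0)
  check_box_inside(box, img)
  d <- dim(img$pixels)
  r0 <- round(box$top); c0 <- round(box$left)
  r1 <- min(r0 + round(box$height) - 1, d[1] - 1)
  c1 <- min(c0 + round(box$width) - 1, d[2] - 1)
  mask <- matrix(0, d[1], d[2])
  mask[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)] <- 1
  if (all(mask == 1)) return(img)
  w <- gauss_blur_mat(mask, sigma)
  w[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)] <- 1
  bg <- gauss_blur_img(img, sigma)$pixels
  px <- img$pixels
  for (k in seq_len(d[3]))
    px[, , k] <- w * img$pixels[, , k] + (1 - w) * bg[, , k]
  image_grid(px, range = img$range, colorspace = img$colorspace)
}

#' Adjust the face-to-background area ratio
#'
#' Brings the face-box share of the frame to `target_face_fraction` (the
#' 60/40 face/background convention of the generator's training corpus).
#' An over-large face is given more background by surrounding the frame with
#' its 8 horizontally/vertically flipped replicates, cropping the enlarged
#' canvas to the target area, and blurring the added margin; an over-small
#' face has background margin cropped away symmetrically.  Fractions already
#' within 5% of the target are left untouched.
#'
#' @param img An [image_grid()].
#' @param box A [face_box()].
#' @param target_face_fraction Target face-box area / frame area, in (0, 1).
#' @param blur_sigma Gaussian sigma for the added-margin blur; `0` disables
#'   blurring (useful for inspecting the raw mirrored margin).
#' @return An [image_grid()]; attribute `"offset"` gives the (row, col)
#'   translation that maps old coordinates to new ones.
#' @export
adjust_background <- function(img, box, target_face_fraction = 0.6,
                              blur_sigma = 3) {
  stopifnot(inherits(img, "image_grid"),
            target_face_fraction > 0, target_face_fraction < 1)
  check_box_inside(box, img)
  d <- dim(img$pixels)
  H <- d[1]; W <- d[2]
  frac <- (box$height * box$width) / (H * W)
  out <- img
  offset <- c(0, 0)
  if (abs(frac - target_face_fraction) / target_face_fraction > 0.05) {
    area_needed <- box$height * box$width / target_face_fraction
    sfac <- sqrt(area_needed / (H * W))
    Hn <- round(H * sfac); Wn <- round(W * sfac)
    if (frac > target_face_fraction) {
      # mirror-pad: 3x3 tiling of flipped replicates, then take the
      # centered Hn x Wn window
      pr <- Hn - H; pc <- Wn - W
      pt <- floor(pr / 2); pl <- floor(pc / 2)
      px <- img$pixels
      big <- array(0, c(3 * H, 3 * W, d[3]))
      for (k in seq_len(d[3])) {
        ch <- px[, , k]
        chv <- ch[H:1, ]; chh <- ch[, W:1]; chvh <- ch[H:1, W:1]
        big[, , k] <- rbind(
          cbind(chvh, chv, chvh),
          cbind(chh,  ch,  chh),
          cbind(chvh, chv, chvh))
      }
      rows <- (H - pt + 1):(H - pt + Hn)
      cols <- (W - pl + 1):(W - pl + Wn)
      out <- image_grid(big[rows, cols, , drop = FALSE],
                        range = img$range, colorspace = img$colorspace)
      offset <- c(pt, pl)
      if (blur_sigma > 0) {
        face_reg <- face_box(pt, pl, H, W)   # original frame stays sharp
        out <- blur_background(out, face_reg, blur_sigma)
      }
    } else {
      # crop symmetric background margin, never into the face box
      ct <- floor((H - Hn) / 2); cl <- floor((W - Wn) / 2)
      ct <- min(ct, floor(box$top))
      cl <- min(cl, floor(box$left))
      ct <- max(ct, 0); cl <- max(cl, 0)
      rb <- min(ct + Hn, H); cb <- min(cl + Wn, W)
      rb <- max(rb, ceiling(box$top + box$height))
      cb <- max(cb, ceiling(box$left + box$width))
      out <- image_grid(img$pixels[(ct + 1):rb, (cl + 1):cb, , drop = FALSE],
                        range = img$range, colorspace = img$colorspace)
      offset <- c(-ct, -cl)
    }
  }
  attr(out, "offset") <- offset
  out
}

#' Rotate so the eye centers are horizontal
#'
#' Rotates the image about the midpoint of the two eye centers so that the
#' inter-ocular segment has zero row difference, transforming the landmarks
#' consistently.  Rotations below 0.01 degrees are skipped (the image is
#' already aligned; resampling would only add interpolation noise).
#'
#' @param img An [image_grid()].
#' @param lm A [landmark_set()] for `img`.
#' @return `list(image =, landmarks =, angle =)` with `angle` the applied
#'   rotation in radians.
#' @export
align_eyes <- function(img, lm) {
  ec <- eye_centers(lm)
  dv <- ec[2, ] - ec[1, ]
  if (sqrt(sum(dv^2)) < 1e-9) stop("degenerate geometry: coincident eye centers")
  theta <- atan2(dv[1], dv[2])   # angle of eye segment vs horizontal
  if (abs(theta) < 0.01 * pi / 180)
    return(list(image = img, landmarks = lm, angle = 0))
  p0 <- colMeans(ec)
  ct <- cos(theta); st <- sin(theta)
  # forward map (applied to landmarks): r' = ct*r - st*c ; c' = st*r + ct*c
  Rf <- matrix(c(ct, st, -st, ct), 2, 2)        # column-major
  pts <- sweep(lm$points, 2, p0)
  pts_new <- t(Rf %*% t(pts)) + matrix(p0, nrow(pts), 2, byrow = TRUE)
  # inverse map for resampling
  Ri <- t(Rf)
  b <- p0 - Ri %*% p0
  out <- warp_affine(img, Ri, as.numeric(b), dim(img$pixels)[1:2])
  list(image = out, landmarks = landmark_set(pts_new), angle = theta)
}

#' Scale so the inter-ocular distance hits a target
#'
#' Isotropic rescale (about the image origin) taking the eye-center distance
#' to `target_distance` pixels; scale factors within 0.1% of 1 are skipped.
#'
#' @param img An [image_grid()].
#' @param lm A [landmark_set()] for `img`.
#' @param target_distance Desired eye-center distance, pixels (default 100).
#' @return `list(image =, landmarks =, scale =)`.
#' @export
scale_to_interocular <- function(img, lm, target_distance = 100) {
  d <- eye_distance(lm)
  if (d < 1e-9) stop("degenerate geometry: zero eye distance")
  s <- target_distance / d
  if (abs(s - 1) < 1e-3)
    return(list(image = img, landmarks = lm, scale = 1))
  out_dim <- pmax(round(dim(img$pixels)[1:2] * s), 2L)
  A <- diag(2) / s
  out <- warp_affine(img, A, c(0, 0), out_dim)
  list(image = out, landmarks = landmark_set(lm$points * s), scale = s)
}

#' Crop the canonical square window around the face
#'
#' Extracts a `side` x `side` window whose center is the eye midpoint
#' shifted down by `center_drop * side` rows (faces sit slightly below the
#' eye line in the canonical frame).  The window is reflection-padded where
#' it overruns the canvas, so cropping always succeeds.
#'
#' @param img An [image_grid()].
#' @param lm A [landmark_set()] for `img`.
#' @param side Output side, pixels (default 1024).
#' @param center_drop Vertical offset of the crop center below the eye
#'   midpoint, as a fraction of `side` (default 0.05).
#' @return `list(image =, landmarks =, origin =)` with `origin` the (row,
#'   col) of the window's top-left corner in input coordinates.
#' @export
crop_canonical <- function(img, lm, side = 1024, center_drop = 0.05) {
  ec <- colMeans(eye_centers(lm))
  center <- c(ec[1] + center_drop * side, ec[2])
  top <- round(center[1] - (side - 1) / 2)
  left <- round(center[2] - (side - 1) / 2)
  H <- dim(img$pixels)[1]; W <- dim(img$pixels)[2]
  ridx <- reflect_coord(top:(top + side - 1), H) + 1
  cidx <- reflect_coord(left:(left + side - 1), W) + 1
  px <- img$pixels[ridx, cidx, , drop = FALSE]
  out <- image_grid(px, range = img$range, colorspace = img$colorspace)
  list(image = out,
       landmarks = landmark_set(sweep(lm$points, 2, c(top, left))),
       origin = c(top, left))
}

#' Full face canonicalization
#'
#' Runs background adjustment, background blur, eye alignment, inter-ocular
#' scaling and the canonical crop in that order, tracking landmarks through
#' every stage.
#'
#' @param img An RGB [image_grid()].
#' @param lm A [landmark_set()]; if `NULL`, obtained from `detector`.
#' @param detector Optional [detector_backend()] used when `lm` is `NULL`.
#' @param face_fraction Target face-box area fraction (default 0.6).
#' @param eye_dist Target inter-ocular distance, pixels (default 100).
#' @param side Canonical crop side, pixels (default 1024).
#' @param center_drop Crop-center drop fraction, see [crop_canonical()].
#' @param blur_sigma Background blur sigma, pixels.
#' @return `list(image =, landmarks =, meta =)`; `meta` is a one-row tibble
#'   with the applied rotation angle (radians), scale factor, crop origin
#'   and final face fraction.
#' @export
preprocess_face <- function(img, lm = NULL, detector = NULL,
                            face_fraction = 0.6, eye_dist = 100,
                            side = 1024, center_drop = 0.05,
                            blur_sigma = 3) {
  if (is.null(lm)) {
    if (is.null(detector)) stop("either landmarks or a detector is required")
    box <- detector$detect_face(img)
    lm <- detector$detect_landmarks(img, box)
  } else {
    box <- landmark_face_box(lm, dim(img$pixels)[1:2])
  }
  adj <- adjust_background(img, box, face_fraction, blur_sigma)
  off <- attr(adj, "offset")
  lm1 <- landmark_set(sweep(lm$points, 2, -off))
  al <- align_eyes(adj, lm1)
  sc <- scale_to_interocular(al$image, al$landmarks, eye_dist)
  cr <- crop_canonical(sc$image, sc$landmarks, side, center_drop)
  box_f <- landmark_face_box(cr$landmarks, c(side, side))
  meta <- tibble::tibble(
    angle = al$angle, scale = sc$scale,
    origin_row = cr$origin[1], origin_col = cr$origin[2],
    face_fraction = box_f$height * box_f$width / (side * side),
    eye_distance = eye_distance(cr$landmarks))
  list(image = cr$image, landmarks = cr$landmarks, meta = meta)
}
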