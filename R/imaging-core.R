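#' Construct an image grid
#'
#' The common raster currency of the package: an H x W x C numeric array with
#' an explicit value-range tag and colorspace.  All pipeline stages pass
#' `image_grid` objects so that range conversions are always explicit.
#'
#' @param pixels Numeric array, `H x W x C` (or an `H x W` matrix, promoted to
#'   one gray channel).  Rows index image rows from the top; the origin is the
#'   top-left pixel at (1, 1).
#' @param range One of `"unit"` (values in 0..1) or `"byte"` (0..255).
#' @param colorspace One of `"RGB"`, `"YCbCr"`, `"gray"`.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(pixels, range = c("unit", "byte"),
                       colorspace = c("RGB", "YCbCr", "gray")) {
  range <- match.arg(range)
  colorspace <- match.arg(colorspace)
  if (is.matrix(pixels)) pixels <- array(pixels, c(dim(pixels), 1L))
  stopifnot(is.array(pixels), length(dim(pixels)) == 3L)
  nc <- dim(pixels)[3]
  if (colorspace == "gray" && nc != 1L)
    stop("gray images must have exactly 1 channel, got ", nc)
  if (colorspace != "gray" && nc != 3L)
    stop(colorspace, " images must have exactly 3 channels, got ", nc)
  lim <- if (range == "unit") c(0, 1) else c(0, 255)
  tol <- 1e-6 * max(1, lim[2])
  rng <- range(pixels)
  if (rng[1] < lim[1] - tol || rng[2] > lim[2] + tol)
    stop(sprintf("pixel values [%g, %g] outside declared %s range",
                 rng[1], rng[2], range))
  structure(list(pixels = pixels, range = range, colorspace = colorspace),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_grid %dx%dx%d %s %s-range>\n",
              d[1], d[2], d[3], x$colorspace, x$range))
  invisible(x)
}

#' @export
dim.image_grid <- function(x) dim(x$pixels)

img_side <- function(img) dim(img$pixels)[1:2]

#' Convert the value range of an image
#'
#' Linear rescale between the unit (0..1) and byte (0..255) conventions.
#' Converting to the current tag is the identity.
#'
#' @param img An [image_grid()].
#' @param target `"unit"` or `"byte"`.
#' @return An [image_grid()] with the requested range tag.
#' @export
convert_range <- function(img, target = c("unit", "byte")) {
  target <- match.arg(target)
  stopifnot(inherits(img, "image_grid"))
  if (img$range == target) return(img)
  f <- if (target == "byte") 255 else 1 / 255
  image_grid(img$pixels * f, range = target, colorspace = img$colorspace)
}

#' Read an image file into an image grid
#'
#' Reads PNG (via the \pkg{png} package) or JPEG (via \pkg{EBImage}, when
#' installed) into an RGB `image_grid` with the byte range tag.  Grayscale
#' files are expanded to three identical channels; alpha channels are
#' rejected.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An RGB [image_grid()], `range = "byte"`.
#' @export
load_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = tryCatch(png::readPNG(path),
                   error = function(e) stop("failed to decode PNG '", path,
                                            "': ", conditionMessage(e))),
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("JPEG decoding requires the EBImage package")
      im <- tryCatch(EBImage::readImage(path),
                     error = function(e) stop("failed to decode JPEG '", path,
                                              "': ", conditionMessage(e)))
      a <- EBImage::imageData(im)
      # EBImage stores x (col) first; transpose to row-major
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
    },
    stop("unsupported image format '.", ext, "' for ", path)
  )
  if (is.matrix(px)) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L)
    stop("alpha channels are not supported: ", path)
  if (dim(px)[3] != 3L)
    stop("unsupported channel count ", dim(px)[3], " in ", path)
  image_grid(px * 255, range = "byte", colorspace = "RGB")
}

#' Write an image grid to a PNG file
#'
#' Lossless 8-bit PNG output; the round trip `load_image(save_image(x))` is
#' exact for byte-range images with integer values.
#'
#' @param img An RGB or gray [image_grid()].
#' @param path Output path ending in `.png`.
#' @return `path`, invisibly.
#' @export
save_image <- function(img, path) {
  stopifnot(inherits(img, "image_grid"))
  u <- convert_range(img, "unit")$pixels
  u <- pmin(pmax(u, 0), 1)
  if (dim(u)[3] == 1L) u <- u[, , 1]
  png::writePNG(u, target = path)
  invisible(path)
}

#' Construct a 68-point facial landmark set
#'
#' Landmarks follow the standard 68-point annotation scheme: 1-17 jaw,
#' 18-27 brows, 28-36 nose, 37-42 left eye, 43-48 right eye, 49-68 mouth
#' (49-60 outer, 61-68 inner).  Coordinates are (row, col) in pixel units,
#' 0-based, origin top-left.
#'
#' @param points A 68 x 2 numeric matrix of (row, col) coordinates.
#' @return An object of class `landmark_set`.
#' @export
landmark_set <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 2L)
    stop("a landmark set must be a 68 x 2 (row, col) matrix")
  storage.mode(points) <- "double"
  colnames(points) <- c("row", "col")
  structure(list(points = points), class = "landmark_set")
}

#' @export
print.landmark_set <- function(x, ...) {
  ec <- eye_centers(x)
  cat(sprintf("<landmark_set 68 pts, eyes (%.1f,%.1f)/(%.1f,%.1f)>\n",
              ec[1, 1], ec[1, 2], ec[2, 1], ec[2, 2]))
  invisible(x)
}

# index subsets of the 68-point scheme (1-based row indices)
LM_JAW   <- 1:17
LM_BROWS <- 18:27
LM_NOSE  <- 28:36
LM_EYE_L <- 37:42
LM_EYE_R <- 43:48
LM_MOUTH_OUT <- 49:60
LM_MOUTH_IN  <- 61:68

#' Eye centers of a landmark set
#'
#' Each eye center is the centroid of that eye's six landmarks.
#'
#' @param lm A [landmark_set()].
#' @return A 2 x 2 matrix; row 1 the left eye, row 2 the right eye,
#'   columns (row, col).
#' @export
eye_centers <- function(lm) {
  stopifnot(inherits(lm, "landmark_set"))
  rbind(colMeans(lm$points[LM_EYE_L, , drop = FALSE]),
        colMeans(lm$points[LM_EYE_R, , drop = FALSE]))
}

#' Inter-ocular distance
#' @param lm A [landmark_set()].
#' @return Euclidean distance between the two eye centers, in pixels.
#' @export
eye_distance <- function(lm) {
  ec <- eye_centers(lm)
  sqrt(sum((ec[1, ] - ec[2, ])^2))
}

#' Read landmarks from a two-column CSV
#'
#' Accepts a headerless (or `row,col`-headed) 68-row CSV of (row, col)
#' pixel coordinates, the interchange format used when no detector backend
#' is attached.
#'
#' @param path CSV path.
#' @return A [landmark_set()].
#' @export
load_landmarks <- function(path) {
  df <- utils::read.csv(path, header = FALSE, comment.char = "#")
  if (is.character(df[[1]]) || is.factor(df[[1]]))
    df <- utils::read.csv(path, header = TRUE)
  landmark_set(as.matrix(df[, 1:2]))
}

#' Write landmarks to CSV
#' @param lm A [landmark_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
save_landmarks <- function(lm, path) {
  utils::write.csv(as.data.frame(lm$points), path, row.names = FALSE)
  invisible(path)
}

#' Construct a binary region mask
#'
#' @param mask Logical (or 0/1) H x W matrix; must contain at least one
#'   `TRUE` pixel.
#' @param region_kind One of `"oral_nasal"`, `"face_excluding_eyes"`,
#'   `"custom"`.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(mask,
                        region_kind = c("custom", "oral_nasal",
                                        "face_excluding_eyes")) {
  region_kind <- match.arg(region_kind)
  mask <- as.matrix(mask)
  storage.mode(mask) <- "logical"
  if (!any(mask)) stop("degenerate region mask: no pixels set")
  structure(list(mask = mask, region_kind = region_kind),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask %s: %d / %d px>\n", x$region_kind,
              sum(x$mask), length(x$mask)))
  invisible(x)
}

stop_if_shape_mismatch <- function(a, b, what = "images") {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop("shape mismatch between ", what, ": ",
         paste(dim(a$pixels), collapse = "x"), " vs ",
         paste(dim(b$pixels), collapse = "x"))
  invisible(TRUE)
}
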