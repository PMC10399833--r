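#' Masked negative-log anomaly scoring
#'
#' The severity score is the negative log of the masked heatmap energy:
#' `S = -log(||M * D||_F / N)` with `M` a landmark-derived region mask, `D`
#' the difference heatmap and `N` the number of mask pixels.  Higher masked
#' energy means a larger original-vs-normalized difference, hence a *lower*
#' score -- aligned with the human 1 (least normal) to 7 (most normal)
#' rating scale.  The log resembles the saturating sensitivity of human
#' appraisal: small anomalies move the score a lot, large ones progressively
#' less.
#'
#' @name scoring
#' @keywords internal
NULL

# convex hull of (row, col) points as an edge list with outward unit normals
hull_edges <- function(pts) {
  idx <- grDevices::chull(pts[, 2], pts[, 1])
  hp <- pts[idx, , drop = FALSE]
  ctr <- colMeans(hp)
  n <- nrow(hp)
  v0 <- hp
  v1 <- hp[c(2:n, 1), , drop = FALSE]
  e <- v1 - v0
  nrm <- cbind(-e[, 2], e[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, 1e-12)
  out <- rowSums((matrix(ctr, n, 2, byrow = TRUE) - v0) * nrm) > 0
  nrm[out, ] <- -nrm[out, , drop = FALSE]
  list(v = v0, n = nrm)
}

# membership of grid pixels in a hull dilated by `margin` (edge offset)
hull_mask <- function(pts, side, margin) {
  he <- hull_edges(pts)
  rr <- matrix(rep(0:(side - 1), side), side)
  cc <- matrix(rep(0:(side - 1), each = side), side)
  inside <- matrix(TRUE, side, side)
  for (i in seq_len(nrow(he$v))) {
    d <- (rr - he$v[i, 1]) * he$n[i, 1] + (cc - he$v[i, 2]) * he$n[i, 2]
    inside <- inside & (d <= margin)
  }
  inside
}

#' Build a scoring mask from landmarks
#'
#' `oral_nasal`: filled convex hull of the nose and outer-mouth landmarks,
#' dilated by `margin_frac * side`.  `face_excluding_eyes`: filled hull of
#' the jaw and brow landmarks minus the dilated hulls of the two eyes.
#'
#' @param lm A [landmark_set()] in the `side` x `side` frame.
#' @param kind `"oral_nasal"` or `"face_excluding_eyes"`.
#' @param side Frame side, pixels.
#' @param margin_frac Hull dilation margin as a fraction of `side`
#'   (default 0.04).
#' @return A [region_mask()].
#' @export
build_mask <- function(lm, kind = c("oral_nasal", "face_excluding_eyes"),
                       side, margin_frac = 0.04) {
  kind <- match.arg(kind)
  p <- lm$points
  margin <- margin_frac * side
  if (kind == "oral_nasal") {
    m <- hull_mask(p[c(LM_NOSE, LM_MOUTH_OUT), , drop = FALSE], side, margin)
  } else {
    m <- hull_mask(p[c(LM_JAW, LM_BROWS), , drop = FALSE], side, margin)
    m <- m & !hull_mask(p[LM_EYE_L, , drop = FALSE], side, margin)
    m <- m & !hull_mask(p[LM_EYE_R, , drop = FALSE], side, margin)
  }
  if (!any(m)) stop("degenerate mask: no pixels selected")
  region_mask(m, kind)
}

#' Anomaly severity score of a masked heatmap
#'
#' @param heat A [heatmap()].
#' @param mask A [region_mask()] of the same shape.
#' @param energy `"frobenius"` (root-sum-square, the reference definition)
#'   or `"mean"` (plain masked mean).
#' @return An `anomaly_score`: fields `raw_energy`, `score`
#'   (`-log(raw_energy)`; `+Inf` with `perfect = TRUE` when the masked
#'   heatmap is identically zero), `n_mask`, `mask_kind`, `method`, `flags`.
#' @export
anomaly_score <- function(heat, mask, energy = c("frobenius", "mean")) {
  energy <- match.arg(energy)
  stopifnot(inherits(heat, "heatmap"), inherits(mask, "region_mask"))
  if (!identical(dim(heat$values), dim(mask$mask)))
    stop("heatmap and mask shapes differ")
  v <- heat$values[mask$mask]
  N <- length(v)
  raw <- if (energy == "frobenius") sqrt(sum(v^2)) / N else sum(v) / N
  structure(list(
    raw_energy = raw,
    score = if (raw > 0) -log(raw) else Inf,
    perfect = raw == 0,
    n_mask = N, mask_kind = mask$region_kind,
    method = heat$method, flags = heat$flags),
    class = "anomaly_score")
}

#' @export
print.anomaly_score <- function(x, ...) {
  cat(sprintf("<anomaly_score %s/%s: S = %.4f (energy %.4g over %d px)>\n",
              x$method, x$mask_kind, x$score, x$raw_energy, x$n_mask))
  invisible(x)
}

#' Linearly scale scores onto an interval
#'
#' Order-preserving affine map of finite scores onto `interval` (default
#' 1..7, the human rating scale); used only for comparable visualization --
#' Pearson correlation is invariant to it.
#'
#' @param scores Numeric vector (`>= 2` finite values).
#' @param interval Target interval, length 2.
#' @return Numeric vector of scaled scores.
#' @export
scale_scores <- function(scores, interval = c(1, 7)) {
  fin <- is.finite(scores)
  if (sum(fin) < 2) stop("need at least 2 finite scores to scale")
  lo <- min(scores[fin]); hi <- max(scores[fin])
  if (hi - lo < 1e-12) {
    warning("all scores identical; returning the interval midpoint")
    out <- rep(mean(interval), length(scores))
    out[!fin] <- scores[!fin]
    return(out)
  }
  out <- interval[1] + (scores - lo) / (hi - lo) * diff(interval)
  out
}

#' Validate a human rating table
#'
#' @param df Data frame with columns `image_id`, `rater_id`, `rating`
#'   (integers 1..7).
#' @return A tibble of class `rating_table`.
#' @export
rating_table <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("image_id", "rater_id", "rating") %in% names(df)))
  if (!all(df$rating %in% 1:7))
    stop("ratings must be integers on the 1..7 scale")
  class(df) <- c("rating_table", class(df))
  df
}

#' Aggregate human ratings per image
#'
#' Drops images with fewer than `min_ratings` individual ratings (the study
#' convention is a minimum of 20) and averages the rest.
#'
#' @param table A [rating_table()] (or coercible data frame).
#' @param min_ratings Minimum ratings per retained image (default 20).
#' @return Tibble with `image_id`, `n_ratings`, `mean_rating`.
#' @export
aggregate_ratings <- function(table, min_ratings = 20) {
  stopifnot(min_ratings >= 1)
  df <- rating_table(table)
  out <- df |>
    dplyr::group_by(.data$image_id) |>
    dplyr::summarise(n_ratings = dplyr::n(),
                     mean_rating = mean(.data$rating), .groups = "drop") |>
    dplyr::filter(.data$n_ratings >= min_ratings)
  if (nrow(out) == 0)
    stop("no image received at least ", min_ratings, " ratings")
  out
}

#' Pearson correlation
#'
#' The plain product-moment correlation
#' `sum((x - mean(x)) (y - mean(y))) / sqrt(sum((x - mean(x))^2) sum((y - mean(y))^2))`,
#' the package's machine-vs-human agreement statistic.
#'
#' @param x,y Numeric vectors of equal length `>= 3` with nonzero variance.
#' @return Correlation in -1..1.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3) stop("need at least 3 pairs")
  dx <- x - mean(x); dy <- y - mean(y)
  sx <- sum(dx^2); sy <- sum(dy^2)
  if (sx < 1e-24 || sy < 1e-24)
    stop("undefined correlation: zero variance")
  sum(dx * dy) / sqrt(sx * sy)
}

#' Correlate machine scores with human ratings
#'
#' Joins per-image machine scores with aggregated human ratings and reports
#' their Pearson correlation.
#'
#' @param scores Tibble with `image_id` and `score`.
#' @param ratings A [rating_table()] (raw per-rater rows).
#' @param min_ratings Minimum ratings per image (default 20).
#' @return `list(r =, n =, data =)`; `data` holds the joined tibble.
#' @export
evaluate_scores <- function(scores, ratings, min_ratings = 20) {
  agg <- aggregate_ratings(ratings, min_ratings)
  joined <- dplyr::inner_join(tibble::as_tibble(scores), agg, by = "image_id")
  joined <- dplyr::filter(joined, is.finite(.data$score))
  list(r = pearson(joined$score, joined$mean_rating), n = nrow(joined),
       data = joined)
}
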