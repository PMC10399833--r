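#' Pipeline run configuration
#'
#' Bundles every stage parameter.  The defaults reproduce the reference
#' production settings: 60% face fraction, 100 px inter-ocular distance,
#' 1024 px canonical crop, 450 inversion iterations with regularizer scale
#' 1e5, 50 adaptation iterations, PSE heatmaps with YCbCr transform and
#' erosion, oral/nasal mask, minimum 20 ratings per image.  Desk-scale runs
#' override the geometry and iteration budget to match the toy generator
#' (see [toy_run_config()]).
#'
#' @param face_fraction Target face-box area fraction.
#' @param eye_distance Canonical inter-ocular distance, px.
#' @param crop_side Canonical crop side, px (must equal the generator's
#'   output side when the full pipeline is run).
#' @param center_drop Crop-center drop fraction.
#' @param inversion_iters,alpha,inversion_lr Inversion budget, regularizer
#'   scale, learning rate.
#' @param mean_latent_samples Samples for the mean-latent initialization.
#' @param adaptation_iters,adaptation_lr Adaptation budget and learning rate.
#' @param heatmap_method `"pse"`, `"ssim"` or `"perceptual"`.
#' @param ycbcr,erosion Heatmap pre-processing flags.
#' @param erode_target `"images"` or `"heatmap"`.
#' @param heatmap_range Working range for the difference stage (`"byte"`).
#' @param mask_kind `"oral_nasal"` or `"face_excluding_eyes"`.
#' @param energy `"frobenius"` or `"mean"` masked-energy definition.
#' @param min_ratings Minimum human ratings per image.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(face_fraction = 0.6, eye_distance = 100,
                       crop_side = 1024, center_drop = 0.05,
                       inversion_iters = 450, alpha = 1e5,
                       inversion_lr = 0.05, mean_latent_samples = 10000,
                       adaptation_iters = 50, adaptation_lr = 0.005,
                       heatmap_method = "pse", ycbcr = TRUE, erosion = TRUE,
                       erode_target = "images", heatmap_range = "byte",
                       mask_kind = "oral_nasal", energy = "frobenius",
                       min_ratings = 20, seed = 1) {
  structure(as.list(environment()), class = "run_config")
}

#' Desk-scale configuration for the toy generator
#'
#' The toy generator synthesizes 64 px faces, so the canonical geometry and
#' iteration budgets are scaled down accordingly (inter-ocular distance
#' matching the fixture faces' construction, shorter optimization because
#' the toy latent space is 16-dimensional).  All method parameters
#' (regularizer scale, heatmap flags, mask, energy) keep their defaults.
#'
#' @param ... Overrides passed to [run_config()].
#' @return A `run_config`.
#' @export
toy_run_config <- function(...) {
  defaults <- list(crop_side = 64, eye_distance = 22.4, center_drop = 0.1,
                   inversion_iters = 100, adaptation_iters = 20,
                   adaptation_lr = 5e-4, mean_latent_samples = 2000)
  args <- utils::modifyList(defaults, list(...))
  do.call(run_config, args)
}

#' Save / load a run configuration
#'
#' Plain JSON round trip; `load_config(save_config(cfg))` reproduces the
#' configuration exactly.
#'
#' @param cfg A [run_config()].
#' @param path JSON path.
#' @return `path` (save) or the restored `run_config` (load).
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  do.call(run_config, jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Normalize one canonical face
#'
#' Inversion plus (optionally) adaptation, returning the normalized face and
#' the intermediate states.
#'
#' @param x_canon Canonical RGB [image_grid()] with side `gen$output_side`.
#' @param gen Generator backend.
#' @param backend Perceptual backend.
#' @param cfg A [run_config()].
#' @return `list(x_norm =, x_norm_noadapt =, latent =, adaptation =)`.
#' @export
normalize_face <- function(x_canon, gen, backend = randconv_backend(),
                           cfg = toy_run_config()) {
  inv <- invert(gen, x_canon, backend,
                inversion_config(iterations = cfg$inversion_iters,
                                 lr = cfg$inversion_lr, alpha = cfg$alpha,
                                 mean_latent_samples = cfg$mean_latent_samples,
                                 seed = cfg$seed))
  ad <- NULL
  x_norm <- inv$image
  if (cfg$adaptation_iters > 0) {
    ad <- adapt(gen, x_canon, inv, backend,
                adaptation_config(iterations = cfg$adaptation_iters,
                                  lr = cfg$adaptation_lr, seed = cfg$seed))
    x_norm <- ad$image
  }
  list(x_norm = x_norm, x_norm_noadapt = inv$image, latent = inv,
       adaptation = ad)
}

score_one <- function(x_canon, x_norm, lm_canon, cfg, backend) {
  hm <- compute_heatmap(x_canon, x_norm, method = cfg$heatmap_method,
                        ycbcr = cfg$ycbcr, erosion = cfg$erosion,
                        erode_target = cfg$erode_target,
                        backend = backend, range = cfg$heatmap_range)
  mask <- build_mask(lm_canon, cfg$mask_kind, cfg$crop_side)
  anomaly_score(hm, mask, energy = cfg$energy)
}

#' Run the full scoring pipeline over a batch of faces
#'
#' Executes, per face: canonicalization, inversion, adaptation, heatmap
#' generation (with the configured color transform and erosion), masking and
#' scoring.  Per-image failures are warned about and skipped.
#'
#' @param faces Tibble with columns `image_id`, list-columns `x_org`
#'   ([image_grid()]s) and `landmarks` ([landmark_set()]s) -- the layout
#'   produced by [fixture_faces()].
#' @param gen Generator backend whose output side equals `cfg$crop_side`.
#' @param backend Perceptual backend.
#' @param cfg A [run_config()].
#' @param keep_images Keep canonical/normalized images and heatmaps in the
#'   result (default `FALSE` to bound memory).
#' @return `list(scores =, artifacts =, meta =)`: `scores` is a tibble with
#'   `image_id`, `raw_energy`, `score`, `scaled_score`, `method`,
#'   `mask_kind`, `elapsed`; `meta` records the config echo, seed and
#'   failures.
#' @export
run_pipeline <- function(faces, gen, backend = randconv_backend(),
                         cfg = toy_run_config(), keep_images = FALSE) {
  if (gen$output_side != cfg$crop_side)
    stop("config crop_side (", cfg$crop_side,
         ") must equal the generator output side (", gen$output_side, ")")
  empty <- tibble::tibble(image_id = character(), raw_energy = numeric(),
                          score = numeric(), scaled_score = numeric(),
                          method = character(), mask_kind = character(),
                          elapsed = numeric())
  if (nrow(faces) == 0)
    return(list(scores = empty, artifacts = list(),
                meta = list(config = cfg, failures = character())))
  failures <- character()
  artifacts <- list()
  rows <- vector("list", nrow(faces))
  for (i in seq_len(nrow(faces))) {
    id <- faces$image_id[i]
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      pre <- preprocess_face(faces$x_org[[i]], faces$landmarks[[i]],
                             face_fraction = cfg$face_fraction,
                             eye_dist = cfg$eye_distance,
                             side = cfg$crop_side,
                             center_drop = cfg$center_drop)
      nm <- normalize_face(pre$image, gen, backend, cfg)
      sc <- score_one(pre$image, nm$x_norm, pre$landmarks, cfg, backend)
      if (keep_images)
        artifacts[[id]] <- list(x_canon = pre$image, x_norm = nm$x_norm,
                                latent = nm$latent)
      tibble::tibble(image_id = id, raw_energy = sc$raw_energy,
                     score = sc$score, scaled_score = NA_real_,
                     method = sc$method, mask_kind = sc$mask_kind,
                     elapsed = proc.time()[["elapsed"]] - t0)
    }, error = function(e) {
      warning("image '", id, "' failed: ", conditionMessage(e))
      failures <<- c(failures, id)
      NULL
    })
    rows[[i]] <- res
  }
  scores <- dplyr::bind_rows(c(list(empty), rows))
  if (sum(is.finite(scores$score)) >= 2)
    scores$scaled_score <- scale_scores(scores$score)
  list(scores = scores, artifacts = artifacts,
       meta = list(config = cfg, seed = cfg$seed, failures = failures))
}

#' Heatmap-method x processing x mask ablation grid
#'
#' Normalizes each face once per arm (with and, optionally, without
#' adaptation) and evaluates every combination of heatmap method (PSE,
#' SSIM, perceptual), processing variant (base, +YCbCr, +erosion, +both)
#' and mask kind (oral/nasal, entire face excluding eyes) against human
#' ratings: 24 Pearson-r cells per arm.
#'
#' @param faces As for [run_pipeline()].
#' @param ratings A [rating_table()] covering `faces$image_id`.
#' @param gen,backend,cfg As for [run_pipeline()].
#' @param arms Character subset of `c("adaptation", "no_adaptation")`.
#' @return An `ablation_result`: tibble `cells` with `arm`, `method`,
#'   `variant`, `mask_kind`, `r`, `n`, plus the per-image `scores` tibble.
#' @export
run_ablation <- function(faces, ratings, gen,
                         backend = randconv_backend(),
                         cfg = toy_run_config(),
                         arms = c("adaptation", "no_adaptation")) {
  arms <- match.arg(arms, several.ok = TRUE)
  agg <- aggregate_ratings(ratings, cfg$min_ratings)
  norm <- vector("list", nrow(faces))
  for (i in seq_len(nrow(faces))) {
    pre <- preprocess_face(faces$x_org[[i]], faces$landmarks[[i]],
                           face_fraction = cfg$face_fraction,
                           eye_dist = cfg$eye_distance,
                           side = cfg$crop_side, center_drop = cfg$center_drop)
    nm <- normalize_face(pre$image, gen, backend, cfg)
    norm[[i]] <- list(id = faces$image_id[i], pre = pre, nm = nm)
  }
  grid <- tidyr::expand_grid(
    arm = arms,
    method = c("pse", "ssim", "perceptual"),
    variant = c("base", "ycbcr", "erosion", "both"),
    mask_kind = c("oral_nasal", "face_excluding_eyes"))
  all_scores <- list()
  cells <- purrr::pmap_dfr(grid, function(arm, method, variant, mask_kind) {
    cfg_i <- cfg
    cfg_i$heatmap_method <- method
    cfg_i$ycbcr <- variant %in% c("ycbcr", "both")
    cfg_i$erosion <- variant %in% c("erosion", "both")
    cfg_i$mask_kind <- mask_kind
    sc <- purrr::map_dfr(norm, function(nd) {
      x_norm <- if (arm == "adaptation") nd$nm$x_norm else nd$nm$x_norm_noadapt
      s <- score_one(nd$pre$image, x_norm, nd$pre$landmarks, cfg_i, backend)
      tibble::tibble(image_id = nd$id, score = s$score)
    })
    all_scores[[paste(arm, method, variant, mask_kind, sep = "_")]] <<- sc
    ev <- evaluate_scores(sc, ratings, cfg$min_ratings)
    tibble::tibble(arm = arm, method = method, variant = variant,
                   mask_kind = mask_kind, r = ev$r, n = ev$n)
  })
  structure(list(cells = cells, scores = all_scores, config = cfg),
            class = "ablation_result")
}

#' @export
print.ablation_result <- function(x, ...) {
  cat("<ablation_result: ", nrow(x$cells), " cells>\n", sep = "")
  print(ablation_table(x))
  invisible(x)
}

#' Ablation grid in the standard wide layout
#'
#' One row per (arm, method), processing variants as columns, grouped by
#' mask kind; correlations are shown as percentages.
#'
#' @param ab An `ablation_result`.
#' @return A wide tibble.
#' @export
ablation_table <- function(ab) {
  ab$cells |>
    dplyr::mutate(r_pct = round(100 * .data$r, 1),
                  col = paste(.data$mask_kind, .data$variant, sep = ".")) |>
    dplyr::select("arm", "method", "col", "r_pct") |>
    tidyr::pivot_wider(names_from = "col", values_from = "r_pct")
}
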