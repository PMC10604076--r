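#' Configuration of a synthetic multimodal well scene
#'
#' Describes the geometry, optics and dose-response of a simulated well of
#' droplet-templating amphiphilic particles, as imaged by a low-magnification
#' multimodal reader. Defaults emulate the study conditions: a 3280 x 2464 px
#' sensor read at 10-bit depth, ~150 particles of ~300 um diameter
#' (concentric droplet / PEG ring / outer shell at 90 / 130 / 150 um radius),
#' a four-frame exposure bracket of 100/500/1000/2000 ms, and per-particle
#' fluorescence drawn from a log-normal dose-response.
#'
#' @param image_height_px,image_width_px image dimensions in pixels.
#' @param pixel_scale micrometres per pixel. The default 5.6 corresponds to a
#'   1.12 um sensor pitch behind ~0.2x magnification, so a 300 um particle
#'   spans ~54 px.
#' @param n_particles number of particles seeded in the well.
#' @param r_droplet_um,r_peg_um,r_outer_um concentric radii (droplet core,
#'   PEG ring outer edge, particle outer shell), micrometres; must increase.
#' @param min_center_spacing_px minimum pairwise centre distance; default
#'   2.2x the outer radius in pixels so particles never touch.
#' @param edge_margin_px placement keep-out from the image border (the border
#'   clearance is this margin plus the outer radius).
#' @param edge_particles number of additional particles deliberately placed
#'   so their outer circle crosses the image border (for testing edge
#'   exclusion); default 0.
#' @param concentration analyte concentration in ng/mL.
#' @param dose_slope,dose_intercept,dose_saturation linear-with-saturation
#'   dose-response in radiance units: mean droplet radiance =
#'   `min(dose_intercept + dose_slope * concentration, dose_saturation)`.
#' @param particle_cv coefficient of variation of per-particle radiance
#'   (log-normal dispersion).
#' @param peg_enrichment multiplicative radiance factor (>= 1) of the PEG
#'   ring relative to the droplet core, reflecting accumulation of the
#'   fluorescent product in the PEG region.
#' @param background_level background radiance added everywhere.
#' @param noise_sd per-frame additive Gaussian read noise, in sensor counts.
#' @param gain sensor counts per unit radiance per millisecond.
#' @param aberration_coeffs named list of per-modality second-order radial
#'   coefficients `c(a1, a2)` (see [aberration_model()]); fluorescence is the
#'   reference channel and defaults to no distortion.
#' @param shift_bf,shift_df rigid (row, col) pixel offsets of the
#'   bright-field and dark-field images relative to the fluorescence frame.
#' @param exposure_times_ms strictly increasing positive exposure times.
#' @param bit_depth sensor bit depth; saturation level is `2^bit_depth - 1`.
#' @param quantize round simulated frames to integer counts (TRUE mimics the
#'   sensor; FALSE yields the exact exposure-scaled radiance clips used by
#'   noiseless oracles).
#' @param seed integer seed; all scene randomness derives from it.
#' @return an object of class `scene_config`.
#' @seealso [sample_scene()], [render_modalities()]
#' @export
scene_config <- function(image_height_px = 2464, image_width_px = 3280,
                         pixel_scale = 5.6, n_particles = 150,
                         r_droplet_um = 90, r_peg_um = 130, r_outer_um = 150,
                         min_center_spacing_px = NULL, edge_margin_px = 20,
                         edge_particles = 0,
                         concentration = 0, dose_slope = 4000,
                         dose_intercept = 100, dose_saturation = 8000,
                         particle_cv = 0.25, peg_enrichment = 2,
                         background_level = 20, noise_sd = 2, gain = 1e-3,
                         aberration_coeffs = list(
                           fluorescence = c(0, 0),
                           bright_field = c(5e-6, 2e-9),
                           dark_field = c(8e-6, 3e-9)),
                         shift_bf = c(4, -3), shift_df = c(-2, 5),
                         exposure_times_ms = c(100, 500, 1000, 2000),
                         bit_depth = 10, quantize = TRUE, seed = 1L) {
  r_outer_px <- r_outer_um / pixel_scale
  if (is.null(min_center_spacing_px)) min_center_spacing_px <- 2.2 * r_outer_px
  cfg <- list(
    image_height_px = as.integer(image_height_px),
    image_width_px = as.integer(image_width_px),
    pixel_scale = pixel_scale, n_particles = as.integer(n_particles),
    r_droplet_um = r_droplet_um, r_peg_um = r_peg_um, r_outer_um = r_outer_um,
    min_center_spacing_px = min_center_spacing_px,
    edge_margin_px = as.integer(edge_margin_px),
    edge_particles = as.integer(edge_particles),
    concentration = concentration, dose_slope = dose_slope,
    dose_intercept = dose_intercept, dose_saturation = dose_saturation,
    particle_cv = particle_cv, peg_enrichment = peg_enrichment,
    background_level = background_level, noise_sd = noise_sd, gain = gain,
    aberration_coeffs = aberration_coeffs,
    shift_bf = shift_bf, shift_df = shift_df,
    exposure_times_ms = exposure_times_ms,
    bit_depth = as.integer(bit_depth), quantize = isTRUE(quantize),
    seed = as.integer(seed))
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(
    cfg$image_height_px >= 16, cfg$image_width_px >= 16,
    cfg$pixel_scale > 0, cfg$n_particles >= 1,
    cfg$r_droplet_um > 0, cfg$r_droplet_um < cfg$r_peg_um,
    cfg$r_peg_um < cfg$r_outer_um,
    cfg$min_center_spacing_px >= 0, cfg$edge_margin_px >= 0,
    cfg$edge_particles >= 0,
    cfg$concentration >= 0, cfg$particle_cv >= 0, cfg$peg_enrichment >= 1,
    cfg$background_level >= 0, cfg$noise_sd >= 0, cfg$gain > 0,
    all(cfg$exposure_times_ms > 0),
    all(diff(cfg$exposure_times_ms) > 0),
    cfg$bit_depth >= 1)
  invisible(cfg)
}

#' Saturation level of a scene or stack configuration
#' @param bit_depth integer bit depth.
#' @return `2^bit_depth - 1`.
#' @export
saturation_level <- function(bit_depth) 2^bit_depth - 1

# Radii (droplet, peg, outer) in pixels for a config.
scene_radii_px <- function(cfg) {
  c(droplet = cfg$r_droplet_um, peg = cfg$r_peg_um, outer = cfg$r_outer_um) /
    cfg$pixel_scale
}

# Mean of the linear-with-saturation dose-response.
dose_response_mean <- function(concentration, dose_params) {
  min(dose_params$intercept + dose_params$slope * concentration,
      dose_params$saturation)
}

#' Draw a per-particle intensity population from the dose-response
#'
#' Samples `n` per-particle fluorescence intensities at a given analyte
#' concentration: log-normal with mean
#' `min(dose_intercept + dose_slope * concentration, dose_saturation)` and
#' coefficient of variation `cv`. A CV of zero returns the mean exactly; a
#' mean of zero returns zeros.
#'
#' @param concentration analyte concentration, ng/mL.
#' @param n population size (the study typically measured ~80 particles per
#'   sample).
#' @param dose_params list with `intercept`, `slope`, `saturation`.
#' @param cv coefficient of variation (sd/mean) of the population.
#' @param seed integer seed.
#' @return numeric vector of length `n`.
#' @export
sample_intensity_population <- function(concentration, n,
                                        dose_params = list(intercept = 100,
                                                           slope = 4000,
                                                           saturation = 8000),
                                        cv = 0.25, seed = 1L) {
  if (!is_count(n)) stop("n must be a positive integer")
  stopifnot(concentration >= 0, cv >= 0)
  m <- dose_response_mean(concentration, dose_params)
  if (m < 0) stop("dose-response mean is negative")
  if (m == 0) return(rep(0, n))
  if (cv == 0) return(rep(m, n))
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  with_local_seed(seed, stats::rlnorm(n, meanlog, sdlog))
}

#' Sample the ground-truth geometry and radiance of a synthetic well
#'
#' Places particles by rejection sampling with a minimum centre spacing and
#' an edge keep-out, draws per-particle droplet radiance from the
#' dose-response log-normal, and builds a pixel label map. The result is the
#' ground truth against which every downstream detection and quantification
#' stage can be scored.
#'
#' @param config a [scene_config()].
#' @param max_attempts_per_particle rejection-sampling budget before the
#'   configuration is declared over-packed.
#' @return an object of class `scene_truth` with elements
#'   * `centers`: n x 2 matrix of (row, col) particle centres, 1-based;
#'   * `radii_px`: n x 3 matrix of (droplet, peg, outer) radii in pixels;
#'   * `true_radiance`: n x 3 matrix of mean radiance for the droplet ROI,
#'     PEG ROI and (area-weighted) combined ROI;
#'   * `label_map`: integer matrix, 0 = background, i = particle i
#'     (pixels within the outer radius);
#'   * `shortfall`: TRUE if fewer than the requested particles were placed.
#' @export
sample_scene <- function(config, max_attempts_per_particle = 200) {
  validate_scene_config(config)
  radii <- scene_radii_px(config)
  nr <- config$image_height_px; nc <- config$image_width_px
  clear <- config$edge_margin_px + radii["outer"]
  if (2 * clear >= min(nr, nc) && config$n_particles > 0)
    stop("well too small to hold any particle at the requested margins")

  n_req <- config$n_particles
  with_local_seed(derive_seed(config$seed, 1L), {
    centers <- matrix(NA_real_, n_req + config$edge_particles, 2)
    placed <- 0L
    attempts <- 0L
    max_attempts <- max_attempts_per_particle * n_req
    while (placed < n_req && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- c(stats::runif(1, clear, nr - clear),
                stats::runif(1, clear, nc - clear))
      if (placed == 0L ||
          min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= config$min_center_spacing_px) {
        placed <- placed + 1L
        centers[placed, ] <- cand
      }
    }
    shortfall <- placed < n_req
    if (shortfall)
      warning(sprintf(
        "placed %d of %d particles: configuration is over-packed", placed,
        n_req))
    # Deliberate edge-touchers: centre at half the outer radius from a border.
    n_edge <- 0L
    while (n_edge < config$edge_particles) {
      side <- sample(4L, 1)
      d <- radii["outer"] / 2
      cand <- switch(side,
        c(d, stats::runif(1, clear, nc - clear)),
        c(nr - d, stats::runif(1, clear, nc - clear)),
        c(stats::runif(1, clear, nr - clear), d),
        c(stats::runif(1, clear, nr - clear), nc - d))
      if (min(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) -
                            cand)^2))) >= config$min_center_spacing_px) {
        placed <- placed + 1L
        n_edge <- n_edge + 1L
        centers[placed, ] <- cand
      }
    }
    centers <- centers[seq_len(placed), , drop = FALSE]
    n <- nrow(centers)

    dose_params <- list(intercept = config$dose_intercept,
                        slope = config$dose_slope,
                        saturation = config$dose_saturation)
    droplet_rad <- sample_intensity_population(
      config$concentration, n, dose_params, config$particle_cv,
      seed = derive_seed(config$seed, 2L))
    peg_rad <- config$peg_enrichment * droplet_rad
    a_d <- radii["droplet"]^2
    a_p <- radii["peg"]^2 - radii["droplet"]^2
    combined_rad <- (a_d * droplet_rad + a_p * peg_rad) / (a_d + a_p)

    label_map <- matrix(0L, nr, nc)
    for (i in seq_len(n)) {
      px <- disc_pixels(centers[i, ], radii["outer"], nr, nc)
      label_map[px] <- i
    }

    truth <- list(
      centers = centers,
      radii_px = matrix(radii, n, 3, byrow = TRUE,
                        dimnames = list(NULL, c("droplet", "peg", "outer"))),
      true_radiance = cbind(droplet = droplet_rad, peg = peg_rad,
                            combined = combined_rad),
      label_map = label_map,
      shortfall = shortfall)
    class(truth) <- "scene_truth"
    truth
  })
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("scene_truth: %d particles on a %d x %d px well%s\n",
              nrow(x$centers), nrow(x$label_map), ncol(x$label_map),
              if (isTRUE(x$shortfall)) " (placement shortfall)" else ""))
  cat(sprintf("  radii (droplet/peg/outer): %.1f / %.1f / %.1f px\n",
              x$radii_px[1, 1], x$radii_px[1, 2], x$radii_px[1, 3]))
  cat(sprintf("  droplet radiance: mean %.1f, sd %.1f\n",
              mean(x$true_radiance[, "droplet"]),
              stats::sd(x$true_radiance[, "droplet"])))
  invisible(x)
}

# Linear pixel indices of the disc of radius r around center (row, col).
disc_pixels <- function(center, r, nr, nc) {
  r0 <- max(1L, floor(center[1] - r)); r1 <- min(nr, ceiling(center[1] + r))
  c0 <- max(1L, floor(center[2] - r)); c1 <- min(nc, ceiling(center[2] + r))
  if (r0 > r1 || c0 > c1) return(integer(0))
  rows <- r0:r1; cols <- c0:c1
  dr <- rows - center[1]; dc <- cols - center[2]
  inside <- outer(dr^2, dc^2, "+") <= r^2
  idx <- which(inside)
  ((idx - 1L) %/% length(rows) + c0 - 1L) * nr +
    ((idx - 1L) %% length(rows) + r0)
}

# Ideal (unwarped, unshifted) fluorescence radiance map of a scene.
scene_radiance_map <- function(truth, config) {
  nr <- config$image_height_px; nc <- config$image_width_px
  rad <- matrix(config$background_level, nr, nc)
  for (i in seq_len(nrow(truth$centers))) {
    ctr <- truth$centers[i, ]
    peg_px <- disc_pixels(ctr, truth$radii_px[i, "peg"], nr, nc)
    dro_px <- disc_pixels(ctr, truth$radii_px[i, "droplet"], nr, nc)
    rad[peg_px] <- config$background_level + truth$true_radiance[i, "peg"]
    rad[dro_px] <- config$background_level + truth$true_radiance[i, "droplet"]
  }
  rad
}

# Ideal bright-field / dark-field images (10-bit scale, before warp/noise).
scene_bf_ideal <- function(truth, config) {
  sat <- saturation_level(config$bit_depth)
  nr <- config$image_height_px; nc <- config$image_width_px
  img <- matrix(0.70 * sat, nr, nc)
  band <- max(1.5, truth$radii_px[1, "outer"] * 0.2)
  for (i in seq_len(nrow(truth$centers))) {
    ctr <- truth$centers[i, ]
    outer_px <- disc_pixels(ctr, truth$radii_px[i, "outer"], nr, nc)
    inner_px <- disc_pixels(ctr, truth$radii_px[i, "outer"] - band, nr, nc)
    peg_px <- disc_pixels(ctr, truth$radii_px[i, "peg"], nr, nc)
    core_px <- disc_pixels(ctr, truth$radii_px[i, "peg"] - band / 2, nr, nc)
    img[outer_px] <- 0.25 * sat           # dark particle boundary ring
    img[inner_px] <- 0.62 * sat           # slightly dimmed PPG shell
    img[peg_px] <- 0.45 * sat             # PEG/shell interface also visible
    img[core_px] <- 0.60 * sat            # droplet interior
  }
  img
}

scene_df_ideal <- function(truth, config) {
  sat <- saturation_level(config$bit_depth)
  nr <- config$image_height_px; nc <- config$image_width_px
  img <- matrix(0.03 * sat, nr, nc)
  for (i in seq_len(nrow(truth$centers))) {
    ctr <- truth$centers[i, ]
    peg_px <- disc_pixels(ctr, truth$radii_px[i, "peg"], nr, nc)
    dro_px <- disc_pixels(ctr, truth$radii_px[i, "droplet"], nr, nc)
    img[peg_px] <- 0.60 * sat             # PEG ring scatters side light
    img[dro_px] <- 0.10 * sat             # droplet core stays dark
  }
  img
}

# Add read noise, quantize and clip to the sensor range.
sensorize <- function(img, config, stream) {
  sat <- saturation_level(config$bit_depth)
  if (config$noise_sd > 0)
    img <- img + with_local_seed(
      derive_seed(config$seed, stream),
      matrix(stats::rnorm(length(img), 0, config$noise_sd),
             nrow(img), ncol(img)))
  if (config$quantize) img <- round(img)
  pmin(pmax(img, 0), sat)
}

#' Render the three imaging modalities of a synthetic well
#'
#' Renders the exposure-bracketed fluorescence stack plus one bright-field
#' and one dark-field image from a scene ground truth. Fluorescence frames
#' are `clip(radiance * exposure * gain + noise, 0, 2^bit_depth - 1)` of the
#' ideal radiance map (background plus droplet radiance over the droplet
#' disc and `peg_enrichment` times that over the PEG ring). Bright-field is a
#' bright background with darkened particle boundaries; dark-field is a dark
#' background with bright PEG rings. Bright- and dark-field carry the
#' configured rigid shifts and second-order radial chromatic-aberration
#' warps relative to the fluorescence frame.
#'
#' @param truth a [sample_scene()] result consistent with `config`.
#' @param config the [scene_config()] used to build `truth`.
#' @return a list with elements `fluorescence` (an [ldr_stack()]),
#'   `bright_field`, `dark_field` (matrices on the sensor scale) and
#'   `radiance` (the ideal ground-truth radiance map, for oracles).
#' @export
render_modalities <- function(truth, config) {
  validate_scene_config(config)
  stopifnot(inherits(truth, "scene_truth"))
  sat <- saturation_level(config$bit_depth)

  rad <- scene_radiance_map(truth, config)
  frames <- lapply(seq_along(config$exposure_times_ms), function(i) {
    sensorize(rad * config$exposure_times_ms[i] * config$gain, config,
              stream = 100L + i)
  })
  stack <- ldr_stack(frames, config$exposure_times_ms, sat)

  warp_modality <- function(img, coeffs, shift, stream) {
    model <- aberration_model(coeffs = coeffs,
                              center = (dim(img) + 1) / 2)
    if (any(coeffs != 0)) img <- apply_aberration(img, model)
    if (any(shift != 0)) img <- translate_image(img, shift)
    sensorize(img, config, stream)
  }
  bf <- warp_modality(scene_bf_ideal(truth, config),
                      config$aberration_coeffs$bright_field,
                      config$shift_bf, 201L)
  df <- warp_modality(scene_df_ideal(truth, config),
                      config$aberration_coeffs$dark_field,
                      config$shift_df, 202L)

  list(fluorescence = stack, bright_field = bf, dark_field = df,
       radiance = rad)
}
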