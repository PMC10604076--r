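# Shared fixture builders. Small wells keep unit tests fast; the "standard
# test well" is the half-resolution geometry used for detection studies
# (1640 x 1232 px at 11.2 um/px, ~150 particles of ~27 px diameter).

small_scene_config <- function(seed = 7, n_particles = 10,
                               concentration = 0.1, ...) {
  scene_config(image_height_px = 420, image_width_px = 520,
               pixel_scale = 11.2, n_particles = n_particles,
               concentration = concentration, seed = seed, ...)
}

# Noiseless, unquantized variant for exact oracles.
noiseless_scene_config <- function(seed = 7, ...) {
  small_scene_config(seed = seed, noise_sd = 0, quantize = FALSE, ...)
}

test_well_config <- function(seed = 1, concentration = 0.1, ...) {
  scene_config(image_height_px = 1232, image_width_px = 1640,
               pixel_scale = 11.2, concentration = concentration,
               seed = seed, ...)
}

small_detection_config <- function(...) {
  detection_config(expected_radius_px = 150 / 11.2, ...)
}

# Rendered small scene cached per (seed, options) within a test run.
.scene_cache <- new.env(parent = emptyenv())
rendered_scene <- function(cfg) {
  key <- paste(cfg$seed, cfg$noise_sd, cfg$quantize, cfg$n_particles,
               cfg$concentration, cfg$image_height_px, cfg$image_width_px,
               paste(unlist(cfg$aberration_coeffs), collapse = "_"),
               paste(cfg$shift_bf, cfg$shift_df, collapse = "_"), sep = "|")
  if (is.null(.scene_cache[[key]])) {
    truth <- sample_scene(cfg)
    .scene_cache[[key]] <- list(truth = truth,
                                images = render_modalities(truth, cfg),
                                config = cfg)
  }
  .scene_cache[[key]]
}

# Build a detection mask from filled discs placed at given centres.
disc_mask <- function(centers, radius, nr, nc, modality = "fluorescence") {
  lab <- matrix(0L, nr, nc)
  for (i in seq_len(nrow(centers))) {
    rr <- outer((seq_len(nr) - centers[i, 1])^2,
                (seq_len(nc) - centers[i, 2])^2, "+")
    lab[rr <= radius^2] <- i
  }
  detection_mask(lab, swarmreader:::region_features(lab, modality))
}

# Circularly roll a matrix by (dr, dc) (content moves down/right).
roll_matrix <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  m[((seq_len(nr) - 1 - dr) %% nr) + 1, ((seq_len(nc) - 1 - dc) %% nc) + 1]
}
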