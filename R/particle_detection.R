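#' Particle-detection configuration
#'
#' Parameters of the per-modality Canny-based segmenter and of the
#' false-positive filters. Area bounds default to 0.25x and 2.25x the
#' expected particle disc area implied by `expected_radius_px`, tying them
#' to the ~300 um particle size at the reader's ~0.2x magnification.
#'
#' @param expected_radius_px expected particle outer radius in pixels; used
#'   only to derive default area bounds.
#' @param canny_low,canny_high hysteresis thresholds as fractions of the
#'   maximum gradient magnitude of the preprocessed image.
#' @param dilation_radius_px radius of the disc used to dilate Canny edges
#'   before hole filling (the mask is eroded back afterwards, i.e. a
#'   morphological closing).
#' @param area_min_px,area_max_px region area bounds in pixels.
#' @param eccentricity_max maximum ellipse eccentricity (0 = circle).
#' @param convexity_min minimum convexity (region area / convex hull area).
#' @param edge_margin_px regions whose bounding box enters this border
#'   margin are excluded (particles near the well edge).
#' @param overlap_max candidate pairs whose equivalent-disc overlap exceeds
#'   this fraction of the smaller disc are both removed.
#' @param clahe_clip,clahe_tile contrast-limited adaptive histogram
#'   equalization clip limit and tile count per axis.
#' @param bilateral_sigma_spatial,bilateral_sigma_range bilateral filter
#'   scales (pixels; intensity fraction of full scale).
#' @return object of class `detection_config`.
#' @export
detection_config <- function(expected_radius_px = 150 / 5.6,
                             canny_low = 0.04, canny_high = 0.12,
                             dilation_radius_px = 2,
                             area_min_px = NULL, area_max_px = NULL,
                             eccentricity_max = 0.8, convexity_min = 0.85,
                             edge_margin_px = 10, overlap_max = 0.2,
                             clahe_clip = 2, clahe_tile = 8,
                             bilateral_sigma_spatial = 2,
                             bilateral_sigma_range = 0.1) {
  disc <- pi * expected_radius_px^2
  if (is.null(area_min_px)) area_min_px <- 0.25 * disc
  if (is.null(area_max_px)) area_max_px <- 2.25 * disc
  cfg <- list(expected_radius_px = expected_radius_px,
              canny_low = canny_low, canny_high = canny_high,
              dilation_radius_px = as.integer(dilation_radius_px),
              area_min_px = area_min_px, area_max_px = area_max_px,
              eccentricity_max = eccentricity_max,
              convexity_min = convexity_min,
              edge_margin_px = as.integer(edge_margin_px),
              overlap_max = overlap_max,
              clahe_clip = clahe_clip, clahe_tile = as.integer(clahe_tile),
              bilateral_sigma_spatial = bilateral_sigma_spatial,
              bilateral_sigma_range = bilateral_sigma_range)
  stopifnot(cfg$canny_low < cfg$canny_high, cfg$canny_low > 0,
            cfg$area_min_px < cfg$area_max_px,
            cfg$eccentricity_max >= 0, cfg$eccentricity_max < 1,
            cfg$convexity_min > 0, cfg$convexity_min <= 1,
            cfg$dilation_radius_px >= 1, cfg$edge_margin_px >= 0,
            cfg$overlap_max >= 0)
  class(cfg) <- "detection_config"
  cfg
}

#' Labelled particle-detection mask
#'
#' @param label_image integer matrix; 0 = background, labels contiguous
#'   from 1.
#' @param regions data frame with one row per region: `label`,
#'   `centroid_row`, `centroid_col`, `area_px`, `eccentricity`, `convexity`,
#'   `modalities` (comma-separated provenance).
#' @return object of class `detection_mask`.
#' @export
detection_mask <- function(label_image, regions) {
  stopifnot(is.matrix(label_image), is.data.frame(regions))
  labs <- sort(unique(as.integer(label_image[label_image > 0])))
  if (length(labs) && !identical(labs, seq_along(labs)))
    stop("labels must be contiguous from 1")
  if (length(labs) != nrow(regions))
    stop("regions table inconsistent with label image")
  structure(list(label_image = label_image, regions = regions),
            class = "detection_mask")
}

#' @export
print.detection_mask <- function(x, ...) {
  cat(sprintf("detection_mask: %d regions on %d x %d px\n",
              nrow(x$regions), nrow(x$label_image), ncol(x$label_image)))
  if (nrow(x$regions))
    cat(sprintf("  area %.0f-%.0f px, median eccentricity %.2f, median convexity %.2f\n",
                min(x$regions$area_px), max(x$regions$area_px),
                stats::median(x$regions$eccentricity),
                stats::median(x$regions$convexity)))
  invisible(x)
}

#' Pixel (linear) indices belonging to one region of a mask
#' @param mask a [detection_mask()].
#' @param label region label.
#' @return integer vector of linear indices into the label image.
#' @export
region_pixels <- function(mask, label) which(mask$label_image == label)

empty_regions <- function() {
  data.frame(label = integer(0), centroid_row = numeric(0),
             centroid_col = numeric(0), area_px = integer(0),
             eccentricity = numeric(0), convexity = numeric(0),
             modalities = character(0), stringsAsFactors = FALSE)
}

# Shift a matrix by (dr, dc) filling vacated cells with `fill`.
mat_shift <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

# Canny edge detector: Sobel gradients, non-maximum suppression along the
# quantized gradient direction, double-threshold hysteresis (thresholds as
# fractions of the maximum gradient magnitude), linking via connected
# components.
canny_edges <- function(image, low_frac, high_frac) {
  g <- sobel_gradients(image)
  mag <- g$mag
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nrow(mag), ncol(mag)))
  ang <- atan2(g$gy, g$gx)          # gx: along rows, gy: along cols
  ang[ang < 0] <- ang[ang < 0] + pi
  bin <- floor((ang + pi / 8) / (pi / 4)) %% 4  # 0:row 1:diag 2:col 3:anti
  dirs <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))
  nms <- matrix(FALSE, nrow(mag), ncol(mag))
  for (b in 0:3) {
    d <- dirs[[b + 1]]
    keep <- mag >= mat_shift(mag, d[1], d[2]) &
            mag >= mat_shift(mag, -d[1], -d[2])
    nms <- nms | (bin == b & keep)
  }
  weak <- nms & (mag >= low_frac * mx)
  strong <- nms & (mag >= high_frac * mx)
  if (!any(strong)) return(matrix(FALSE, nrow(mag), ncol(mag)))
  lab <- EBImage::bwlabel(weak)
  keep_labs <- unique(lab[strong])
  matrix(lab %in% keep_labs[keep_labs > 0] & weak, nrow(mag), ncol(mag))
}

#' Contrast-enhance and denoise an image before edge detection
#'
#' Rescales to `[0, 1]`, applies contrast-limited adaptive histogram
#' equalization, then an edge-preserving bilateral filter, and rescales the
#' result to `[0, 1]`. Constant images pass through unchanged (as zeros):
#' no spurious contrast is created.
#'
#' @param image 2-D numeric matrix.
#' @param config a [detection_config()].
#' @return matrix in `[0, 1]`, same shape.
#' @export
preprocess <- function(image, config = detection_config()) {
  stopifnot(is.matrix(image))
  if (any(!is.finite(image))) stop("image contains non-finite pixels")
  x <- rescale01(image)
  if (max(x) == 0) return(x)
  # clahe requires dimensions divisible by the tile grid: pad by edge
  # replication, equalize, crop back
  nr <- nrow(x); nc <- ncol(x)
  tile <- config$clahe_tile
  pr <- (tile - nr %% tile) %% tile
  pc <- (tile - nc %% tile) %% tile
  xp <- x[c(seq_len(nr), rep(nr, pr)), c(seq_len(nc), rep(nc, pc))]
  xp <- as.matrix(EBImage::clahe(xp, nx = tile, ny = tile,
                                 limit = config$clahe_clip))
  x <- xp[seq_len(nr), seq_len(nc)]
  x <- bilateral_filter_cpp(x, config$bilateral_sigma_spatial,
                            config$bilateral_sigma_range,
                            radius = as.integer(
                              ceiling(2 * config$bilateral_sigma_spatial)))
  rescale01(x)
}

# Features of every label in a label image, plus per-region pixel lists.
region_features <- function(label_image, modality = "") {
  idx <- which(label_image > 0)
  if (!length(idx)) return(empty_regions())
  labs <- as.integer(label_image[idx])
  nr <- nrow(label_image)
  rows <- (idx - 1L) %% nr + 1L
  cols <- (idx - 1L) %/% nr + 1L
  area <- as.integer(rowsum(rep(1L, length(labs)), labs))
  ulab <- sort(unique(labs))
  cr <- rowsum(rows, labs)[, 1] / area
  cc <- rowsum(cols, labs)[, 1] / area
  # central second moments -> ellipse eccentricity
  dr <- rows - cr[match(labs, ulab)]
  dc <- cols - cc[match(labs, ulab)]
  mu20 <- rowsum(dr^2, labs)[, 1] / area
  mu02 <- rowsum(dc^2, labs)[, 1] / area
  mu11 <- rowsum(dr * dc, labs)[, 1] / area
  comm <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  l1 <- (mu20 + mu02) / 2 + comm
  l2 <- (mu20 + mu02) / 2 - comm
  ecc <- ifelse(l1 > 1e-12, sqrt(pmax(0, 1 - l2 / l1)), 0)
  conv <- vapply(split(seq_along(labs), labs), function(ii) {
    convexity_of(rows[ii], cols[ii])
  }, numeric(1))
  data.frame(label = ulab, centroid_row = as.numeric(cr),
             centroid_col = as.numeric(cc), area_px = area,
             eccentricity = as.numeric(ecc), convexity = as.numeric(conv),
             modalities = modality, stringsAsFactors = FALSE)
}

# Convexity = pixel area / lattice-point count of the convex hull
# (interior + boundary lattice points via the shoelace formula and Pick's
# theorem), capped at 1.
convexity_of <- function(rows, cols) {
  n <- length(rows)
  if (n <= 3) return(1)
  pts <- cbind(rows, cols)
  h <- grDevices::chull(pts)
  hp <- pts[h, , drop = FALSE]
  k <- nrow(hp)
  if (k < 3) return(1)
  nxt <- c(2:k, 1)
  area_hull <- abs(sum(hp[, 1] * hp[nxt, 2] - hp[nxt, 1] * hp[, 2])) / 2
  boundary <- sum(mapply(function(i, j) {
    d <- abs(hp[i, ] - hp[j, ])
    max(1, gcd2(d[1], d[2]))
  }, seq_len(k), nxt))
  hull_px <- area_hull + boundary / 2 + 1
  min(1, n / hull_px)
}

gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

#' Detect candidate particle regions in one modality
#'
#' Runs the Canny detector on a preprocessed image, dilates the edges,
#' fills holes, erodes back (morphological closing) and labels connected
#' components. No false-positive filtering is applied here; see
#' [filter_regions()].
#'
#' @param image preprocessed (see [preprocess()]) or raw 2-D image; raw
#'   images are preprocessed internally.
#' @param config a [detection_config()].
#' @param modality provenance tag recorded on each region
#'   (`"bright_field"`, `"dark_field"` or `"fluorescence"`).
#' @param preprocessed set TRUE if `image` already went through
#'   [preprocess()].
#' @return a [detection_mask()] of unfiltered candidates.
#' @export
detect_modality <- function(image, config = detection_config(),
                            modality = "fluorescence",
                            preprocessed = FALSE) {
  x <- if (preprocessed) image else preprocess(image, config)
  edges <- canny_edges(x, config$canny_low, config$canny_high)
  if (!any(edges)) {
    return(detection_mask(matrix(0L, nrow(x), ncol(x)), empty_regions()))
  }
  brush <- EBImage::makeBrush(2L * config$dilation_radius_px + 1L, "disc")
  m <- EBImage::dilate(edges * 1, brush)
  m <- EBImage::fillHull(m)
  m <- EBImage::erode(m, brush)
  lab <- as.matrix(EBImage::bwlabel(m))
  storage.mode(lab) <- "integer"
  detection_mask(lab, region_features(lab, modality))
}

# Area of the intersection of two discs over the area of the smaller disc.
disc_overlap_fraction <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c1 - c2)^2))
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) return(1)
  # circular lens area
  p1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  p2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  p3 <- 0.5 * sqrt(pmax(0, (-d + r1 + r2) * (d + r1 - r2) *
                           (d - r1 + r2) * (d + r1 + r2)))
  (p1 + p2 - p3) / (pi * min(r1, r2)^2)
}

# Relabel a mask contiguously, keeping only `keep` labels.
subset_mask <- function(mask, keep) {
  reg <- mask$regions[mask$regions$label %in% keep, , drop = FALSE]
  lab <- mask$label_image
  new <- integer(max(lab, 1L))
  new[reg$label] <- seq_len(nrow(reg))
  out <- matrix(0L, nrow(lab), ncol(lab))
  nz <- lab > 0
  out[nz] <- new[lab[nz]]
  reg$label <- seq_len(nrow(reg))
  rownames(reg) <- NULL
  detection_mask(out, reg)
}

#' Filter false-positive candidate regions
#'
#' Removes regions with area outside `[area_min_px, area_max_px]`,
#' eccentricity above `eccentricity_max` or convexity below
#' `convexity_min`; regions whose bounding box enters the `edge_margin_px`
#' border (particles near the well edge); and both members of any candidate
#' pair whose equivalent discs overlap by more than `overlap_max` of the
#' smaller disc (overlapping particles). Surviving regions are relabelled
#' contiguously. The operation is idempotent.
#'
#' @param mask a [detection_mask()].
#' @param config a [detection_config()].
#' @return filtered [detection_mask()].
#' @export
filter_regions <- function(mask, config = detection_config()) {
  reg <- mask$regions
  if (!nrow(reg)) return(mask)
  keep <- reg$area_px >= config$area_min_px &
          reg$area_px <= config$area_max_px &
          reg$eccentricity <= config$eccentricity_max &
          reg$convexity >= config$convexity_min

  # edge exclusion on the bounding box
  nr <- nrow(mask$label_image); nc <- ncol(mask$label_image)
  m <- config$edge_margin_px
  if (m > 0 && any(keep)) {
    for (i in which(keep)) {
      px <- which(mask$label_image == reg$label[i])
      rows <- (px - 1L) %% nr + 1L
      cols <- (px - 1L) %/% nr + 1L
      if (min(rows) <= m || max(rows) > nr - m ||
          min(cols) <= m || max(cols) > nc - m)
        keep[i] <- FALSE
    }
  }

  # mutual overlap exclusion among survivors
  surv <- which(keep)
  if (length(surv) > 1) {
    r_eq <- sqrt(reg$area_px / pi)
    drop <- rep(FALSE, length(surv))
    for (a in seq_along(surv)) {
      for (b in seq_along(surv)) {
        if (b <= a) next
        i <- surv[a]; j <- surv[b]
        ov <- disc_overlap_fraction(
          c(reg$centroid_row[i], reg$centroid_col[i]), r_eq[i],
          c(reg$centroid_row[j], reg$centroid_col[j]), r_eq[j])
        if (ov > config$overlap_max) drop[a] <- drop[b] <- TRUE
      }
    }
    keep[surv[drop]] <- FALSE
  }
  subset_mask(mask, reg$label[keep])
}

#' Fuse per-modality detection masks
#'
#' Combines the bright-field, dark-field and fluorescence masks by pixelwise
#' OR, relabels connected components, applies the convexity constraint
#' (fused blobs formed by different particles' discs fail it; slightly
#' offset detections of the same particle pass) and records, for each fused
#' region, which modalities contributed pixels to it.
#'
#' @param m_bf,m_df,m_fl per-modality [detection_mask()]s in the same
#'   registered coordinate frame; any of them may be NULL (e.g. a missing
#'   modality), in which case fusion proceeds over the remainder with a
#'   warning.
#' @param config a [detection_config()].
#' @return fused [detection_mask()] with modality provenance.
#' @export
fuse_masks <- function(m_bf, m_df, m_fl, config = detection_config()) {
  inputs <- list(bright_field = m_bf, dark_field = m_df, fluorescence = m_fl)
  miss <- names(inputs)[vapply(inputs, is.null, TRUE)]
  if (length(miss)) {
    warning("fusing without modalities: ", paste(miss, collapse = ", "))
    inputs <- inputs[!names(inputs) %in% miss]
  }
  if (!length(inputs)) stop("no masks to fuse")
  d <- dim(inputs[[1]]$label_image)
  for (m in inputs)
    if (!identical(dim(m$label_image), d)) stop("mask shape mismatch")
  ored <- Reduce(`|`, lapply(inputs, function(m) m$label_image > 0))
  lab <- as.matrix(EBImage::bwlabel(ored * 1))
  storage.mode(lab) <- "integer"
  reg <- region_features(lab)
  if (nrow(reg)) {
    prov <- vapply(reg$label, function(l) {
      px <- which(lab == l)
      paste(names(inputs)[vapply(inputs, function(m)
        any(m$label_image[px] > 0), TRUE)], collapse = ",")
    }, character(1))
    reg$modalities <- prov
  }
  fused <- detection_mask(lab, reg)
  subset_mask(fused, reg$label[reg$convexity >= config$convexity_min])
}

#' Score a detection mask against scene ground truth
#'
#' A detected region matches a true particle when its centroid lies within
#' that particle's outer radius; matching is one-to-one and greedy by
#' distance. Recall is matched / true particles, precision is matched /
#' detected regions. An empty mask yields recall 0 and precision reported
#' as 0 with `precision_defined = FALSE`.
#'
#' @param mask a [detection_mask()] in the truth's coordinate frame.
#' @param truth a [sample_scene()] ground truth.
#' @return list with `recall`, `precision`, `n_matched`, `n_true`,
#'   `n_detected`, `matches` (detected label per true particle, NA if
#'   unmatched) and `precision_defined`.
#' @export
evaluate_detection <- function(mask, truth) {
  n_true <- nrow(truth$centers)
  reg <- mask$regions
  n_det <- nrow(reg)
  if (n_det == 0)
    return(list(recall = 0, precision = 0, n_matched = 0L, n_true = n_true,
                n_detected = 0L, matches = rep(NA_integer_, n_true),
                precision_defined = FALSE))
  d <- outer(truth$centers[, 1], reg$centroid_row, "-")^2 +
       outer(truth$centers[, 2], reg$centroid_col, "-")^2
  d <- sqrt(d)
  d[d > truth$radii_px[, "outer"]] <- Inf   # recycled per true particle row
  matches <- rep(NA_integer_, n_true)
  used <- rep(FALSE, n_det)
  ord <- order(d)
  for (k in ord) {
    if (!is.finite(d[k])) break
    i <- (k - 1L) %% n_true + 1L
    j <- (k - 1L) %/% n_true + 1L
    if (is.na(matches[i]) && !used[j]) {
      matches[i] <- reg$label[j]
      used[j] <- TRUE
    }
  }
  n_m <- sum(!is.na(matches))
  list(recall = n_m / n_true, precision = n_m / n_det,
       n_matched = n_m, n_true = n_true, n_detected = n_det,
       matches = matches, precision_defined = TRUE)
}
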