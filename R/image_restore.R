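#' Exposure-bracketed low-dynamic-range image stack
#'
#' @param frames list of same-shaped non-negative numeric matrices (sensor
#'   counts).
#' @param exposure_times positive exposure times (ms), one per frame.
#' @param saturation_value sensor saturation level (`2^bit_depth - 1`).
#' @param valid optional list of logical matrices flagging pixels actually
#'   observed in each frame (FALSE marks e.g. out-of-frame pixels introduced
#'   by registration).
#' @return an object of class `ldr_stack`.
#' @export
ldr_stack <- function(frames, exposure_times, saturation_value,
                      valid = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1,
            length(frames) == length(exposure_times),
            all(exposure_times > 0),
            is_number(saturation_value), saturation_value > 0)
  d <- dim(frames[[1]])
  for (f in frames) {
    stopifnot(is.matrix(f), identical(dim(f), d))
    if (min(f) < 0 || max(f) > saturation_value + 1e-6)
      stop("frame values must lie in [0, saturation_value]")
  }
  if (!is.null(valid))
    stopifnot(length(valid) == length(frames),
              all(vapply(valid, function(v) identical(dim(v), d), TRUE)))
  structure(list(frames = frames, exposure_times = exposure_times,
                 saturation_value = saturation_value, valid = valid),
            class = "ldr_stack")
}

#' @export
print.ldr_stack <- function(x, ...) {
  cat(sprintf("ldr_stack: %d frames of %d x %d px, exposures [%s] ms, sat %d\n",
              length(x$frames), nrow(x$frames[[1]]), ncol(x$frames[[1]]),
              paste(x$exposure_times, collapse = ", "),
              round(x$saturation_value)))
  invisible(x)
}

#' High-dynamic-range radiance image
#'
#' @param radiance non-negative numeric matrix of relative radiance.
#' @param valid_mask logical matrix; TRUE where at least one usable (below
#'   saturation) observation contributed.
#' @return object of class `hdr_image`.
#' @export
hdr_image <- function(radiance, valid_mask) {
  stopifnot(is.matrix(radiance), is.matrix(valid_mask),
            identical(dim(radiance), dim(valid_mask)))
  if (any(!is.finite(radiance[valid_mask])) ||
      any(radiance[valid_mask] < 0))
    stop("radiance must be finite and non-negative where valid")
  structure(list(radiance = radiance, valid_mask = valid_mask),
            class = "hdr_image")
}

#' @export
print.hdr_image <- function(x, ...) {
  cat(sprintf("hdr_image: %d x %d px, radiance range [%.4g, %.4g], %.1f%% valid\n",
              nrow(x$radiance), ncol(x$radiance), min(x$radiance),
              max(x$radiance), 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Estimate the rigid shift between two images by phase correlation
#'
#' Computes the normalized cross-power spectrum of the two images and locates
#' its inverse-FFT peak. The returned shift is the displacement of `moving`
#' relative to `reference` (a pure circular shift of the reference by
#' `(dr, dc)` is recovered as `(dr, dc)`); `translate_image(moving, -shift)`
#' brings `moving` into the reference frame. Sub-pixel refinement uses a
#' parabolic fit around the correlation peak, so exact integer shifts on
#' noiseless input are returned exactly.
#'
#' @param reference,moving same-shaped numeric matrices.
#' @param subpixel logical; refine the integer peak parabolically.
#' @param lowpass_sigma optional spatial sigma (pixels) of a Gaussian
#'   low-pass applied to the whitened cross-power spectrum (band-limited
#'   phase correlation). Useful for cross-modality registration, where thin
#'   rings of slightly different radii otherwise produce spurious tangency
#'   peaks; NULL (default) keeps the classic fully-whitened form, which
#'   recovers integer shifts exactly on noiseless input.
#' @return named numeric vector `c(d_row, d_col)`.
#' @export
phase_correlate <- function(reference, moving, subpixel = TRUE,
                            lowpass_sigma = NULL) {
  stopifnot(is.matrix(reference), is.matrix(moving),
            identical(dim(reference), dim(moving)))
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0)
    stop("constant image has no spectral content; cannot register")
  f1 <- stats::fft(reference)
  f2 <- stats::fft(moving)
  cp <- f1 * Conj(f2)
  cp <- cp / pmax(Mod(cp), .Machine$double.eps)
  if (!is.null(lowpass_sigma)) {
    n <- dim(cp)
    u <- c(0:(n[1] %/% 2), -rev(seq_len(n[1] - n[1] %/% 2 - 1))) / n[1]
    v <- c(0:(n[2] %/% 2), -rev(seq_len(n[2] - n[2] %/% 2 - 1))) / n[2]
    cp <- cp * exp(-2 * pi^2 * lowpass_sigma^2 * outer(u^2, v^2, "+"))
  }
  corr <- Re(stats::fft(cp, inverse = TRUE))
  pk <- arrayInd(which.max(corr), dim(corr))
  n <- dim(corr)

  refine <- function(axis) {
    i <- pk[axis]
    at <- function(k) {
      idx <- pk
      idx[axis] <- ((k - 1) %% n[axis]) + 1
      corr[idx[1], idx[2]]
    }
    c0 <- at(i); cm <- at(i - 1); cp1 <- at(i + 1)
    denom <- cm - 2 * c0 + cp1
    off <- if (subpixel && denom < 0) 0.5 * (cm - cp1) / denom else 0
    max(min(off, 0.5), -0.5)
  }
  d <- (pk - 1) + c(refine(1), refine(2))
  # peak sits at -shift modulo the image size: wrap, then negate
  d <- ifelse(d > n / 2, d - n, d)
  c(d_row = -d[1], d_col = -d[2])
}

#' Register an exposure bracket to its first frame
#'
#' Aligns every frame of the stack to the first via [phase_correlate()] and
#' resamples with bilinear interpolation. Pixels translated in from outside
#' the frame are edge-replicated and flagged invalid rather than treated as
#' observations.
#'
#' @param stack an [ldr_stack()] with at least 2 frames.
#' @return an `ldr_stack` whose frames are aligned to the first; the applied
#'   corrections (negated estimated shifts) are recorded in the `shifts`
#'   attribute as a frames x 2 matrix.
#' @export
register_stack <- function(stack) {
  stopifnot(inherits(stack, "ldr_stack"), length(stack$frames) >= 2)
  ref <- stack$frames[[1]]
  nr <- nrow(ref); nc <- ncol(ref)
  shifts <- matrix(0, length(stack$frames), 2,
                   dimnames = list(NULL, c("d_row", "d_col")))
  frames <- stack$frames
  valid <- lapply(stack$frames, function(f) matrix(TRUE, nr, nc))
  for (i in seq_along(frames)[-1]) {
    s <- phase_correlate(ref, frames[[i]])
    # snap near-integer estimates so pure integer shifts resample losslessly
    if (max(abs(s - round(s))) < 0.1) s <- round(s)
    if (any(abs(s) > 1e-3)) {
      frames[[i]] <- pmin(translate_image(frames[[i]], -s),
                          stack$saturation_value)
      v <- matrix(TRUE, nr, nc)
      if (s[1] > 0) v[seq_len(min(nr, ceiling(s[1]))), ] <- FALSE
      if (s[1] < 0) v[nr + 1 - seq_len(min(nr, ceiling(-s[1]))), ] <- FALSE
      if (s[2] > 0) v[, seq_len(min(nc, ceiling(s[2])))] <- FALSE
      if (s[2] < 0) v[, nc + 1 - seq_len(min(nc, ceiling(-s[2])))] <- FALSE
      valid[[i]] <- v
    }
    shifts[i, ] <- -s
  }
  out <- ldr_stack(frames, stack$exposure_times, stack$saturation_value,
                   valid = valid)
  attr(out, "shifts") <- shifts
  out
}

#' Synthesize an HDR radiance image from a registered exposure bracket
#'
#' Per-pixel radiance is the Gaussian-weighted mean of the per-frame
#' estimates `z_i / t_i`:
#' \deqn{L = \sum_i w(z_i) z_i / t_i \; / \; \sum_i w(z_i)}
#' with `w` a Gaussian centred at half the saturation level (sigma = a
#' quarter of it), floored at a small epsilon, so near-zero and
#' near-saturated counts contribute little. Saturated observations
#' (`z >= saturation`) receive zero weight; pixels saturated in every frame
#' fall back to the shortest exposure's (clipped, hence lower-bound)
#' estimate and are flagged invalid in `valid_mask`.
#'
#' @param stack a registered [ldr_stack()].
#' @param weight_floor weight floor for unsaturated observations.
#' @return an [hdr_image()].
#' @export
synthesize_hdr <- function(stack, weight_floor = 1e-6) {
  stopifnot(inherits(stack, "ldr_stack"))
  if (length(stack$frames) == 0) stop("empty stack")
  sat <- stack$saturation_value
  mid <- sat / 2
  sig <- sat / 4
  num <- 0; den <- 0
  n_usable <- 0L
  for (i in seq_along(stack$frames)) {
    z <- stack$frames[[i]]
    usable <- z < sat
    if (!is.null(stack$valid)) usable <- usable & stack$valid[[i]]
    w <- pmax(exp(-((z - mid)^2) / (2 * sig^2)), weight_floor)
    w[!usable] <- 0
    num <- num + w * z / stack$exposure_times[i]
    den <- den + w
    n_usable <- n_usable + usable
  }
  valid <- n_usable >= 1L
  radiance <- matrix(0, nrow(num), ncol(num))
  radiance[valid] <- num[valid] / den[valid]
  if (any(!valid))  # all-saturated: lower-bound estimate from shortest frame
    radiance[!valid] <- stack$frames[[1]][!valid] / stack$exposure_times[1]
  hdr_image(radiance, valid)
}

#' Second-order radial aberration model
#'
#' Maps an ideal radius `r` (pixels from the distortion centre) to the
#' distorted radius `r*(1 + a1*r + a2*r^2)`. Used to model per-channel
#' chromatic distortion; [correct_aberration()] applies the numerically
#' inverted map.
#'
#' @param coeffs numeric `c(a1, a2)`.
#' @param center `(row, col)` of the distortion centre.
#' @return object of class `aberration_model`.
#' @export
aberration_model <- function(coeffs = c(0, 0), center) {
  stopifnot(length(coeffs) == 2, all(is.finite(coeffs)),
            length(center) == 2, all(is.finite(center)))
  structure(list(coeffs = as.numeric(coeffs), center = as.numeric(center)),
            class = "aberration_model")
}

aberration_forward <- function(model, r) {
  r * (1 + model$coeffs[1] * r + model$coeffs[2] * r^2)
}

check_monotone <- function(model, rmax) {
  r <- seq(0, rmax, length.out = 512)
  if (any(diff(aberration_forward(model, r)) <= 0))
    stop("aberration model is not monotone over the image radius range")
  invisible(TRUE)
}

radial_resample <- function(image, model, radius_map) {
  nr <- nrow(image); nc <- ncol(image)
  rr <- rep(seq_len(nr), times = nc) - model$center[1]
  cc <- rep(seq_len(nc), each = nr) - model$center[2]
  r <- sqrt(rr^2 + cc^2)
  scale <- ifelse(r > 0, radius_map(r) / r, 1)
  matrix(bilinear_sample(image, model$center[1] + rr * scale,
                         model$center[2] + cc * scale), nr, nc)
}

#' Apply a radial aberration warp (forward model)
#'
#' Distorts an ideal image with the model's radial map: content at ideal
#' radius `r` appears at the radius whose forward image is `r`. Round-trips
#' with [correct_aberration()].
#'
#' @param image numeric matrix.
#' @param model an [aberration_model()].
#' @return warped matrix, same shape.
#' @export
apply_aberration <- function(image, model) {
  rmax <- sqrt(sum((dim(image))^2))
  check_monotone(model, rmax)
  radial_resample(image, model, function(r) aberration_forward(model, r))
}

#' Correct a radial aberration (numerical inverse)
#'
#' Applies the inverse of the model's radial map, computed numerically on a
#' radius grid and interpolated, so that
#' `correct_aberration(apply_aberration(x, m), m)` recovers `x` up to
#' interpolation error.
#'
#' @inheritParams apply_aberration
#' @return corrected matrix, same shape.
#' @export
correct_aberration <- function(image, model) {
  if (all(model$coeffs == 0)) return(image)
  rmax <- sqrt(sum((dim(image))^2))
  check_monotone(model, rmax)
  grid <- seq(0, rmax * 1.05, length.out = 2048)
  fwd <- aberration_forward(model, grid)
  inv <- stats::approxfun(fwd, grid, rule = 2)
  radial_resample(image, model, inv)
}

#' Register a bright- or dark-field image to the HDR reference frame
#'
#' Because the modalities are contrast-inverted relative to one another
#' (dark particles on a bright background versus bright discs on a dark
#' background), phase correlation is run on Sobel gradient magnitudes, which
#' peak at particle boundaries in every modality; a band-limited
#' (low-passed) cross-power spectrum suppresses the tangency ambiguity of
#' thin boundary rings whose radii differ between modalities.
#'
#' @param image numeric matrix (aberration-corrected bright/dark-field).
#' @param reference an [hdr_image()] or numeric matrix.
#' @param lowpass_sigma band limit passed to [phase_correlate()].
#' @return list with `image` (resampled into the reference frame) and
#'   `shift` (the estimated displacement of `image` relative to the
#'   reference).
#' @export
register_to_reference <- function(image, reference, lowpass_sigma = 3) {
  ref <- if (inherits(reference, "hdr_image")) reference$radiance
         else reference
  stopifnot(identical(dim(image), dim(ref)))
  s <- phase_correlate(sobel_gradients(rescale01(ref))$mag,
                       sobel_gradients(rescale01(image))$mag,
                       lowpass_sigma = lowpass_sigma)
  aligned <- if (any(abs(s) > 1e-3)) translate_image(image, -s) else image
  list(image = aligned, shift = s)
}
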