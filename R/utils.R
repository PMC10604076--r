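#' @useDynLib swarmreader, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Run code under a temporary RNG state so package functions never disturb the
# caller's random stream. seed must be a single finite integer-valued number.
with_local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic substream seed derived from a base seed and a stream index;
# kept strictly below 2^31 so it is always a valid R integer seed.
derive_seed <- function(seed, stream) {
  ((as.double(seed) %% 2147483647) * 48271 + as.double(stream)) %% 2147483647
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

#' Bilinearly sample an image at real-valued coordinates
#'
#' Out-of-range coordinates are clamped to the image border (edge
#' replication), matching the pipeline's convention that border content is
#' excluded later by the detection edge margin.
#'
#' @param img numeric matrix.
#' @param row,col equal-length numeric vectors of 1-based sampling
#'   coordinates.
#' @return numeric vector of sampled values.
#' @keywords internal
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img); nc <- ncol(img)
  row <- pmin(pmax(row, 1), nr)
  col <- pmin(pmax(col, 1), nc)
  r0 <- pmin(floor(row), nr - 1L); c0 <- pmin(floor(col), nc - 1L)
  fr <- row - r0; fc <- col - c0
  i00 <- (c0 - 1) * nr + r0
  v00 <- img[i00];      v10 <- img[i00 + 1]
  v01 <- img[i00 + nr]; v11 <- img[i00 + nr + 1]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Resample an image under a rigid translation: output(p) = input(p - shift).
# Edge-replicated; shift = c(d_row, d_col) moves content down/right.
translate_image <- function(img, shift) {
  nr <- nrow(img); nc <- ncol(img)
  rc <- rep(seq_len(nr), times = nc) - shift[1]
  cc <- rep(seq_len(nc), each = nr) - shift[2]
  matrix(bilinear_sample(img, rc, cc), nr, nc)
}

# Sobel gradient magnitude (used for cross-modality registration and Canny).
sobel_gradients <- function(img) {
  kx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/drow
  ky <- t(kx)
  gx <- as.matrix(EBImage::filter2(img, kx, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(img, ky, boundary = "replicate"))
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# Rescale a matrix to [0, 1]; constant input maps to all zeros.
rescale01 <- function(img) {
  rng <- range(img)
  if (!all(is.finite(rng))) stop("image contains non-finite pixels")
  if (rng[2] == rng[1]) return(matrix(0, nrow(img), ncol(img)))
  (img - rng[1]) / (rng[2] - rng[1])
}
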