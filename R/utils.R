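#' @useDynLib semfocus, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm rpois runif sd lm coef cor fft
#' @importFrom utils head write.csv read.csv
NULL

# Run expr with a temporarily fixed RNG state; the caller's stream is
# untouched. All stochastic operations in the package route through this so
# that a seed argument gives bit-identical results regardless of ambient
# RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream derivation: one root seed fans out into
# per-stage / per-item seeds, all below 2^31.
derive_seed <- function(seed, ...) {
  ix <- c(...)
  s <- as.double(seed) %% 2147483629
  for (i in ix) s <- (s * 48271 + as.double(i) * 1299721 + 12345) %% 2147483629
  as.integer(s) + 1L
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("non-finite %s", what), call. = FALSE)
}

#' Write a raster to an 8-bit grayscale TIFF file
#'
#' @param raster numeric matrix with gray values in `[0, 255]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  stopifnot(is.matrix(raster))
  tiff::writeTIFF(raster / 255, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read an 8-bit grayscale TIFF file into a raster matrix
#'
#' @param path TIFF file path.
#' @return numeric matrix with gray values in `[0, 255]`.
#' @export
read_raster <- function(path) {
  x <- tiff::readTIFF(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  round(x * 255)
}

# Global structural-similarity index between two rasters on the 0-255 scale
# (single-window variant: image-wide means, variances and covariance).

#' Structural similarity between two rasters
#'
#' Computes the single-window structural similarity index (SSIM) between two
#' gray-level images on the 0-255 dynamic range. Used as an image-based
#' cross-check that smaller focus-parameter residuals correspond to images
#' closer to the in-focus render.
#'
#' @param a,b numeric matrices of equal shape, gray levels in `[0, 255]`.
#' @return a scalar in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  L <- 255
  c1 <- (0.01 * L)^2
  c2 <- (0.03 * L)^2
  mu_a <- mean(a); mu_b <- mean(b)
  va <- stats::var(as.vector(a)); vb <- stats::var(as.vector(b))
  cab <- stats::cov(as.vector(a), as.vector(b))
  ((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
    ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2))
}
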