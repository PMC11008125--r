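#' @useDynLib sicklekin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rlnorm rexp median quantile sd var dist
#' @importFrom grDevices chull contourLines png dev.off
#' @importFrom graphics pairs
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All package randomness funnels through this.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a global seed by a fixed offset, kept within the
# 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset) %% 2147483647)
}

# Min-max rescale to [0, 1]; constant input maps to all zeros.
rescale01 <- function(x) {
  r <- range(x)
  if (r[2] - r[1] <= .Machine$double.eps) return(array(0, dim = dim(x)))
  (x - r[1]) / (r[2] - r[1])
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Band-limited (smoothed, standardized) white noise field, the texture
# primitive for the "coarse texture" of sickled cells.
smooth_noise <- function(nx, ny, sigma = 1.5) {
  z <- matrix(rnorm(nx * ny), nx, ny)
  zs <- EBImage::gblur(EBImage::Image(z), sigma = sigma)
  zs <- EBImage::imageData(zs)
  (zs - mean(zs)) / max(sd(zs), 1e-12)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
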