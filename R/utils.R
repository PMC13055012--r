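#' Internal numerical helpers
#'
#' Small shared primitives: matrix flattening between 4D volumes and
#' voxel-by-time matrices, band-limited noise synthesis, and a trapezoid
#' integral wrapper.
#'
#' @name multiecho-utils
#' @keywords internal
NULL

# 4D array (X,Y,Z,T) -> V x T matrix for voxels where mask is TRUE
vox_by_time <- function(vol4d, mask = NULL) {
  d <- dim(vol4d)
  stopifnot(length(d) == 4L)
  m <- matrix(vol4d, nrow = prod(d[1:3]), ncol = d[4])
  if (is.null(mask)) return(m)
  m[as.vector(mask), , drop = FALSE]
}

# inverse of vox_by_time: place V x T rows back into a 4D array
time_to_vox <- function(mat, mask, dims, fill = 0) {
  out <- array(fill, dim = c(dims, ncol(mat)))
  flat <- matrix(out, nrow = prod(dims), ncol = ncol(mat))
  flat[as.vector(mask), ] <- mat
  array(flat, dim = c(dims, ncol(mat)))
}

# place a per-voxel vector back into a 3D array
vec_to_vol <- function(x, mask, dims, fill = NA_real_) {
  out <- array(fill, dim = dims)
  out[as.vector(mask)] <- x
  out
}

#' @noRd
trapz_unit <- function(y) {
  if (length(y) < 2L) return(0)
  pracma::trapz(seq_along(y), y)
}

# Band-limited Gaussian noise via FFT masking; unit SD, zero mean.
# Frequencies in Hz; tr in seconds. Deterministic under the caller's RNG.
band_limited_noise <- function(n, tr, f_lo = 0.01, f_hi = 0.1) {
  x <- rnorm(n)
  xf <- fft(x)
  freqs <- (seq_len(n) - 1) / (n * tr)
  freqs <- pmin(freqs, 1 / tr - freqs)  # two-sided spectrum folding
  keep <- freqs >= f_lo & freqs <= f_hi
  keep[1] <- FALSE
  xf[!keep] <- 0 + 0i
  y <- Re(fft(xf, inverse = TRUE)) / n
  s <- sd(y)
  if (s < .Machine$double.eps) return(rep(0, n))
  as.numeric((y - mean(y)) / s)
}

# Moore-Penrose pseudoinverse via MASS
pinv <- function(m) MASS::ginv(m)

# column-standardize (zero mean, unit SD); constant columns become 0
col_standardize <- function(m) {
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  s[s < .Machine$double.eps] <- Inf
  sweep(sweep(m, 2, mu, "-"), 2, s, "/")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
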