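#' DVARS of a 4D series
#'
#' DVARS(t) is the root mean square, over in-mask voxels, of the frame-to-frame
#' signal difference: `sqrt(mean_v [X(v,t) - X(v,t-1)]^2)` for t = 2..T.
#' Reported in raw intensity units by default; with `percent = TRUE` the
#' series is first scaled to percent of the in-mask temporal mean.
#'
#' @param x 4D array (X,Y,Z,T) or a voxels-by-time matrix.
#' @param mask Logical 3D array (ignored when `x` is a matrix and mask NULL).
#' @param percent Report in percent-of-mean units instead of raw intensity.
#' @return A list: `series` (length T-1), `mean` (temporal mean),
#'   `auc` (trapezoid integral over volume index, unit spacing), and
#'   `confound` (length T with a leading 0 placeholder for the undefined
#'   first difference).
#' @export
dvars <- function(x, mask = NULL, percent = FALSE) {
  m <- if (length(dim(x)) == 4L) vox_by_time(x, mask) else {
    if (is.null(mask)) x else x[as.vector(mask), , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty mask")
  if (ncol(m) < 2L) stop("need at least 2 volumes")
  if (percent) {
    gm <- mean(rowMeans(m))
    if (gm == 0) stop("cannot scale to percent: zero mean signal")
    m <- 100 * m / gm
  }
  d <- m[, -1, drop = FALSE] - m[, -ncol(m), drop = FALSE]
  series <- sqrt(colMeans(d^2))
  list(series = series, mean = mean(series), auc = trapz_unit(series),
       confound = c(0, series))
}

#' Framewise displacement (Power convention)
#'
#' `FD(t) = sum |d trans| + radius * sum |d rot|`, backward differences, with
#' rotations in radians converted to arc length on a sphere of the given
#' radius. The first frame is 0 by convention.
#'
#' @param mp T-by-6 matrix of realignment parameters, columns
#'   rot_x/rot_y/rot_z (radians) then trans_x/trans_y/trans_z (mm).
#' @param radius Head radius in mm used to convert rotations.
#' @return Numeric vector of length T, in mm.
#' @export
framewise_displacement <- function(mp, radius = 50) {
  mp <- as.matrix(mp)
  if (ncol(mp) != 6L) stop("motion parameters must have 6 columns")
  d <- abs(diff(mp))
  fd <- radius * rowSums(d[, 1:3, drop = FALSE]) + rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' Temporal signal-to-noise ratio
#'
#' `tSNR(v) = mean_t X(v,t) / SD_t X(v,t)` with the unbiased (n-1) SD.
#' Voxels with zero temporal SD are flagged `NA` and excluded from the mean.
#'
#' @inheritParams dvars
#' @return A list: `map` (3D array when input is 4D, else vector, `NA` where
#'   undefined) and `mean` over defined in-mask voxels.
#' @export
tsnr <- function(x, mask = NULL) {
  is4d <- length(dim(x)) == 4L
  m <- if (is4d) vox_by_time(x, mask) else {
    if (is.null(mask)) x else x[as.vector(mask), , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty mask")
  if (ncol(m) < 2L) stop("need at least 2 volumes")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  v <- ifelse(s > 0, mu / s, NA_real_)
  map <- if (is4d) vec_to_vol(v, mask %||% array(TRUE, dim(x)[1:3]), dim(x)[1:3]) else v
  list(map = map, mean = mean(v, na.rm = TRUE))
}

#' Carpet matrix
#'
#' Rows are in-mask voxel time series, demeaned per row, ordered by their
#' Pearson correlation with the global (mask-mean) signal, descending. The
#' matrix backs carpet plots; no rendering is done here.
#'
#' @inheritParams dvars
#' @return Matrix of dimension (in-mask voxels) x T with attribute `order`
#'   (the voxel permutation applied).
#' @export
carpet_matrix <- function(x, mask = NULL) {
  m <- if (length(dim(x)) == 4L) vox_by_time(x, mask) else {
    if (is.null(mask)) x else x[as.vector(mask), , drop = FALSE]
  }
  if (nrow(m) == 0L) stop("empty mask")
  gs <- colMeans(m)
  r <- suppressWarnings(apply(m, 1, function(row) {
    if (sd(row) == 0 || sd(gs) == 0) 0 else cor(row, gs)
  }))
  ord <- order(r, decreasing = TRUE)
  out <- m[ord, , drop = FALSE] - rowMeans(m[ord, , drop = FALSE])
  attr(out, "order") <- ord
  out
}

#' Shannon entropy of a time series
#'
#' Histograms the series into `n_bins` equal-width bins over its observed
#' range and returns `H = -sum p_i log2 p_i` (bits), with `0 log 0 = 0`.
#' A constant series has zero entropy by convention.
#'
#' @param x Numeric vector.
#' @param n_bins Number of equal-width bins.
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(x, n_bins = 20) {
  if (length(x) < n_bins) stop("series shorter than the number of bins")
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  counts <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n_bins)
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Mean tissue confound signals
#'
#' Per-volume mean signal over each of two tissue masks (conventionally white
#' matter and CSF).
#'
#' @param x 4D array or voxels-by-time matrix over the full grid.
#' @param wm_mask,csf_mask Logical 3D arrays.
#' @return A list with numeric vectors `white_matter` and `csf`, length T.
#' @export
confound_signals <- function(x, wm_mask, csf_mask) {
  if (sum(wm_mask) == 0L || sum(csf_mask) == 0L) stop("empty mask")
  wm <- colMeans(vox_by_time(x, wm_mask))
  cs <- colMeans(vox_by_time(x, csf_mask))
  list(white_matter = wm, csf = cs)
}

#' Mean in-mask Shannon entropy of a series
#'
#' Convenience wrapper: entropy of every in-mask voxel time series, averaged.
#'
#' @inheritParams dvars
#' @param n_bins Number of histogram bins per voxel.
#' @return Mean entropy in bits over in-mask voxels.
#' @export
mean_entropy <- function(x, mask = NULL, n_bins = 20) {
  m <- if (length(dim(x)) == 4L) vox_by_time(x, mask) else x
  mean(apply(m, 1, shannon_entropy, n_bins = n_bins))
}
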