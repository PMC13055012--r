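#' Seed-based functional connectivity map
#'
#' Pearson correlation between the mean time series of a seed region and
#' every in-brain voxel.
#'
#' @param x 4D array or voxels-by-time matrix over the full grid.
#' @param seed_mask Logical 3D array defining the seed region.
#' @param brain_mask Logical 3D array of voxels to correlate (default: all).
#' @return List of class `fc_map`: `values` (r per in-brain voxel), `map`
#'   (3D array, NA outside brain), `brain_mask`.
#' @export
seed_fc_map <- function(x, seed_mask, brain_mask = NULL) {
  dims <- if (length(dim(x)) == 4L) dim(x)[1:3] else NULL
  if (sum(seed_mask) == 0L) stop("empty seed mask")
  if (is.null(brain_mask)) brain_mask <- array(TRUE, dim = dims %||% dim(seed_mask))
  seed_ts <- colMeans(vox_by_time(x, seed_mask))
  if (sd(seed_ts) == 0) stop("zero-variance seed time series")
  m <- vox_by_time(x, brain_mask)
  r <- suppressWarnings(as.vector(cor(t(m), seed_ts)))
  r[!is.finite(r)] <- 0
  structure(list(values = r,
                 map = vec_to_vol(r, brain_mask, dim(seed_mask)),
                 brain_mask = brain_mask),
            class = "fc_map")
}

#' Spatial reliability of an FC map against a template
#'
#' Pearson correlation between the voxelwise FC values and a binary network
#' template over in-brain voxels: high when connectivity concentrates where
#' the canonical network says it should.
#'
#' @param fc An [seed_fc_map()] result.
#' @param template_mask Logical/0-1 3D array of the canonical network.
#' @return Pearson r.
#' @export
spatial_reliability <- function(fc, template_mask) {
  stopifnot(inherits(fc, "fc_map"))
  tv <- as.numeric(as.vector(template_mask))[as.vector(fc$brain_mask)]
  if (sd(tv) == 0) stop("template is constant over the brain mask")
  cor(fc$values, tv)
}

#' Cronbach's alpha across network reliability scores
#'
#' `alpha = k/(k-1) * (1 - sum_i var(item_i) / var(total))`, items = network
#' columns, cases = subject rows, total = per-subject sum across items.
#'
#' @param mat Subjects x networks numeric matrix (at least 2 of each).
#' @return Cronbach's alpha.
#' @export
cronbach_alpha <- function(mat) {
  mat <- as.matrix(mat)
  k <- ncol(mat)
  if (k < 2L || nrow(mat) < 2L) stop("need at least 2 networks and 2 subjects")
  vt <- var(rowSums(mat))
  if (vt == 0) stop("zero total variance")
  k / (k - 1) * (1 - sum(apply(mat, 2, var)) / vt)
}

#' Parcelwise functional connectome
#'
#' Mean time series per parcel, then the Pearson correlation matrix
#' (diagonal 1).
#'
#' @param x 4D array or voxels-by-time matrix over the full grid.
#' @param parcel_labels Integer 3D label array; 0 = background.
#' @return Symmetric correlation matrix (parcels x parcels).
#' @export
connectome <- function(x, parcel_labels) {
  labs <- sort(unique(as.vector(parcel_labels)))
  labs <- labs[labs != 0]
  if (length(labs) < 2L) stop("need at least 2 parcels")
  nv <- length(parcel_labels)
  m <- if (length(dim(x)) == 4L) matrix(x, nv, dim(x)[4]) else x
  ts <- vapply(labs, function(l) {
    idx <- as.vector(parcel_labels) == l
    if (!any(idx)) stop("empty parcel ", l)
    colMeans(m[idx, , drop = FALSE])
  }, numeric(ncol(m)))
  r <- cor(ts)
  dimnames(r) <- list(labs, labs)
  r
}

upper_tri_vec <- function(m) m[upper.tri(m)]

#' ICC(3,1) between two edge-pattern vectors
#'
#' Two-way mixed, consistency, single-measure intraclass correlation with
#' k = 2 raters (the two patterns) and n = edges as targets:
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE)`. Consistency form, so an additive
#' offset between the patterns does not lower it.
#'
#' @param a,b Numeric vectors of equal length (at least 3), e.g.
#'   upper-triangle vectorized connectomes.
#' @return ICC(3,1).
#' @export
icc_pattern <- function(a, b) {
  n <- length(a)
  if (length(b) != n || n < 3L) stop("need two equal-length vectors, length >= 3")
  dat <- cbind(a, b)
  k <- 2
  row_means <- rowMeans(dat)
  col_means <- colMeans(dat)
  grand <- mean(dat)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((dat - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr + (k - 1) * mse == 0) stop("zero between-target variance")
  (msr - mse) / (msr + (k - 1) * mse)
}

#' Sliding-window ICC reliability curve of a connectome
#'
#' For each window length on a 5%..100% grid (5% steps, 20 points), slides a
#' window of `floor(L * T / 100)` volumes (clamped to at least `min_window`)
#' across the run with stride `max(1, floor(window/2))`, computes the
#' connectome per window, and takes the mean ICC(3,1) between each windowed
#' upper-triangle pattern and the full-data pattern. The final grid point
#' compares the full data with itself, so the curve ends at exactly 1.
#'
#' Summaries: `auc` is the trapezoid integral over the grid index (unit
#' spacing; maximum 19 for 20 points), and `mp` is the smallest grid length
#' (percent) whose curve value reaches `mp_threshold` (NA if never reached).
#'
#' @param x 4D array or voxels-by-time matrix over the full grid.
#' @param parcel_labels Integer 3D label array.
#' @param grid Window lengths as percent of T.
#' @param min_window Smallest usable window, volumes. Windows shorter than
#'   this are clamped up with a warning.
#' @param mp_threshold Pattern-similarity threshold defining MP.
#' @param single_window Use one start-anchored window per length instead of
#'   sliding (faster; less smooth).
#' @return Object of class `icc_curve`: tibble `curve` (window_pct,
#'   window_volumes, icc), scalar `auc`, `mp`.
#' @export
icc_curve <- function(x, parcel_labels, grid = seq(5, 100, by = 5),
                      min_window = 10L, mp_threshold = 0.95,
                      single_window = FALSE) {
  nv <- length(parcel_labels)
  m <- if (length(dim(x)) == 4L) matrix(x, nv, dim(x)[4]) else x
  nt <- ncol(m)
  full_vec <- upper_tri_vec(connectome(m, parcel_labels))
  clamped <- FALSE
  icc <- vapply(grid, function(L) {
    wlen <- floor(L * nt / 100)
    if (wlen < min_window) { clamped <<- TRUE; wlen <- min(min_window, nt) }
    if (wlen >= nt) return(1)
    starts <- if (single_window) 1L else
      seq.int(1L, nt - wlen + 1L, by = max(1L, floor(wlen / 2)))
    vals <- vapply(starts, function(s) {
      wv <- upper_tri_vec(connectome(m[, s:(s + wlen - 1), drop = FALSE],
                                     parcel_labels))
      icc_pattern(wv, full_vec)
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  if (clamped)
    warning("short run: sub-", min_window, "-volume windows clamped to ",
            min_window, " volumes")
  reached <- which(icc >= mp_threshold)
  structure(
    list(curve = tibble::tibble(window_pct = grid,
                                window_volumes = pmax(floor(grid * nt / 100),
                                                      pmin(min_window, nt)),
                                icc = icc),
         auc = trapz_unit(icc),
         mp = if (length(reached)) grid[reached[1]] else NA_real_,
         mp_threshold = mp_threshold),
    class = "icc_curve"
  )
}

#' @export
print.icc_curve <- function(x, ...) {
  cat(sprintf("<icc_curve> %d points, AUC = %.3f, MP = %s%%\n",
              nrow(x$curve), x$auc,
              if (is.na(x$mp)) "not reached" else format(x$mp)))
  invisible(x)
}
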