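#' Z-axis spatial concatenation of echoes
#'
#' Stacks the E echo volumes along the Z axis (slab order = ascending TE),
#' producing a single 4D volume of shape (X, Y, Z*E, T) on which one ICA
#' decomposition yields component time courses shared across echoes.
#'
#' @param me A [multi_echo_series()].
#' @return A list of class `concat_volume`: `data` (4D array), `n_echoes`,
#'   `slab_z` (Z extent of one echo), `tr`.
#' @export
zconcat <- function(me) {
  stopifnot(inherits(me, "multi_echo_series"))
  d <- me$dims
  nt <- me$n_volumes
  ne <- n_echoes(me)
  out <- array(0, dim = c(d[1], d[2], d[3] * ne, nt))
  for (e in seq_len(ne))
    out[, , ((e - 1) * d[3] + 1):(e * d[3]), ] <- me$data[[e]]
  structure(list(data = out, n_echoes = ne, slab_z = d[3], tr = me$tr),
            class = "concat_volume")
}

#' Split a concatenated volume back into echoes
#'
#' Inverse of [zconcat()]; round-trips losslessly.
#'
#' @param cv A `concat_volume`.
#' @param echo_times Echo times to attach to the rebuilt series (ms).
#' @return A [multi_echo_series()].
#' @export
split_concat <- function(cv, echo_times) {
  stopifnot(inherits(cv, "concat_volume"))
  z <- cv$slab_z
  data <- lapply(seq_len(cv$n_echoes), function(e)
    cv$data[, , ((e - 1) * z + 1):(e * z), , drop = FALSE])
  multi_echo_series(data, echo_times, cv$tr)
}

# replicate a per-slab 3D mask across echo slabs
concat_mask <- function(mask, n_echoes) {
  d <- dim(mask)
  out <- array(FALSE, dim = c(d[1], d[2], d[3] * n_echoes))
  for (e in seq_len(n_echoes))
    out[, , ((e - 1) * d[3] + 1):(e * d[3])] <- mask
  out
}

#' Split concatenated component maps per echo
#'
#' Component maps from an ICA of the Z-concatenated volume live on the
#' extended grid; this slices them into one map stack per echo. Stack 1
#' (the first, shortest-TE echo) is the stack used for spatial feature
#' extraction.
#'
#' @param ica An [ica_decompose()] result.
#' @param n_echoes Number of echo slabs in the concatenated grid.
#' @return List of E matrices, each (voxels per echo) x K, plus attribute
#'   `mask` (per-echo 3D mask) when the ICA mask splits evenly.
#' @export
split_concat_maps <- function(ica, n_echoes) {
  stopifnot(inherits(ica, "ica_result"))
  d <- ica$dims
  if (d[3] %% n_echoes != 0L)
    stop("concatenated Z extent is not divisible by the echo count")
  z <- d[3] %/% n_echoes
  full <- matrix(NA_real_, prod(d), ica$k)
  full[as.vector(ica$mask), ] <- ica$maps
  arr <- array(full, dim = c(d[1], d[2], d[3], ica$k))
  lapply(seq_len(n_echoes), function(e) {
    slab <- arr[, , ((e - 1) * z + 1):(e * z), , drop = FALSE]
    matrix(slab, nrow = prod(d[1], d[2], z), ncol = ica$k)
  })
}

# symmetric fixed-point ICA (tanh contrast) on whitened K x V data
fixed_point_ica <- function(z, max_iter = 200, tol = 1e-4) {
  k <- nrow(z)
  nv <- ncol(z)
  w <- matrix(rnorm(k * k), k, k)
  sym_decorrelate <- function(w) {
    s <- svd(w)
    s$u %*% t(s$v)
  }
  w <- sym_decorrelate(w)
  delta <- Inf
  for (i in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gprime <- rowMeans(1 - g^2)
    w_new <- g %*% t(z) / nv - diag(gprime, k) %*% w
    w_new <- sym_decorrelate(w_new)
    delta <- max(abs(abs(diag(w_new %*% t(w))) - 1))
    w <- w_new
    if (delta < tol) return(list(w = w, converged = TRUE, iter = i, delta = delta))
  }
  list(w = w, converged = FALSE, iter = max_iter, delta = delta)
}

#' Spatial ICA decomposition with automatic dimensionality
#'
#' Demeans and variance-normalizes every in-mask voxel time series, reduces
#' to K principal components, and runs symmetric fixed-point ICA (tanh
#' contrast) on the whitened spatial data, with deterministic seeding and up
#' to `max_restarts` restarts on non-convergence. When `k` is not given it is
#' chosen automatically as the number of covariance eigenvalues above the
#' Marchenko-Pastur upper edge of the noise spectrum (estimated from the
#' median eigenvalue), clipped to `[k_min, min(T - 1, k_max)]` — a
#' deterministic surrogate for Bayesian dimensionality estimation that keeps
#' only components standing out of the random-matrix noise floor.
#'
#' Mixing-matrix columns are scaled to unit variance; spatial maps are
#' Z-scored over in-mask voxels.
#'
#' @param x A `concat_volume`, 4D array, or voxels-by-time matrix.
#' @param mask Logical 3D array (NULL keeps every voxel with nonzero
#'   variance).
#' @param k Number of components; NULL for the automatic rule.
#' @param seed Integer seed making the decomposition reproducible.
#' @param mp_factor Multiplier on the Marchenko-Pastur upper edge; larger
#'   values keep fewer components.
#' @param k_min,k_max Clip range of the automatic K.
#' @param max_restarts Restarts with fresh initialization on non-convergence.
#' @return Object of class `ica_result`: `mixing` (T x K, unit-variance
#'   columns), `maps` (in-mask voxels x K, Z-scored), `k`, `mask`, `dims`,
#'   `explained_variance` (cumulative PCA variance at K), `converged`,
#'   `seed`.
#' @export
ica_decompose <- function(x, mask = NULL, k = NULL, seed = 1L,
                          mp_factor = 1, k_min = 2L, k_max = 100L,
                          max_restarts = 10L) {
  if (inherits(x, "concat_volume")) x <- x$data
  if (length(dim(x)) == 4L) {
    dims <- dim(x)[1:3]
    if (is.null(mask)) mask <- array(TRUE, dim = dims)
    xm <- vox_by_time(x, mask)
  } else {
    dims <- c(nrow(x), 1L, 1L)
    if (is.null(mask)) mask <- array(TRUE, dim = dims)
    xm <- x[as.vector(mask), , drop = FALSE]
  }
  nt <- ncol(xm)
  if (nt < 20L) stop("need at least 20 time points for ICA")
  if (nrow(xm) == 0L) stop("empty mask")

  mu <- rowMeans(xm)
  xc <- xm - mu
  s <- apply(xc, 1, sd)
  keep_var <- s > .Machine$double.eps
  xc[keep_var, ] <- xc[keep_var, , drop = FALSE] / s[keep_var]
  xc[!keep_var, ] <- 0

  # PCA over time: eigendecomposition of the T x T covariance
  cc <- crossprod(xc) / (nrow(xc) - 1)
  eg <- eigen(cc, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  ev_frac <- cumsum(ev) / sum(ev)
  rank <- sum(ev > ev[1] * 1e-9)
  if (is.null(k)) {
    # noise eigenvalues of a V x T i.i.d. matrix fall below
    # sigma^2 (1 + sqrt(T/V))^2; the median eigenvalue estimates sigma^2
    edge <- mp_factor * median(ev) * (1 + sqrt(nt / nrow(xc)))^2
    k_auto <- max(sum(ev > edge), 1L)
    k <- min(max(k_auto, k_min), min(nt - 1L, k_max))
  }
  k <- as.integer(min(max(k, 1L), nt - 1L, rank))

  # whitened spatial components: rows of z are unit-norm-scaled PC maps
  u <- eg$vectors[, seq_len(k), drop = FALSE]            # T x K temporal PCs
  sv <- sqrt(ev[seq_len(k)] * (nrow(xc) - 1))
  z <- t(xc %*% u) / sv                                  # K x V, rows orthonormal
  z <- z * sqrt(ncol(z))                                 # unit variance rows

  # restart with a fresh initialization on non-convergence, up to
  # max_restarts; abandon early once restarts stop improving the final
  # rotation increment (typical when K exceeds the non-Gaussian subspace and
  # the leftover directions are rotation-indeterminate)
  res <- NULL
  withr::with_seed(as.integer(seed), {
    for (r in seq_len(max_restarts)) {
      cand <- fixed_point_ica(z)
      if (is.null(res) || cand$delta < res$delta) res <- cand
      if (res$converged) break
      if (r >= 2L && cand$delta > 0.5 * res$delta) break
    }
  })
  if (!res$converged)
    warning("fixed-point ICA did not converge (final rotation increment ",
            signif(res$delta, 3), "); returning the best iterate")

  sources <- res$w %*% z                                 # K x V
  # mixing such that xc ~ mixing %*% sources (up to per-voxel scaling)
  mixing <- u %*% diag(sv / sqrt(ncol(z)), k) %*% t(res$w)   # T x K
  # fix signs: make each map's skew positive for reproducibility
  sk <- apply(sources, 1, function(v) mean((v - mean(v))^3))
  flip <- ifelse(sk < 0, -1, 1)
  sources <- sources * flip
  mixing <- sweep(mixing, 2, flip, "*")
  # normalize: unit-variance time courses, Z-scored maps
  tc_sd <- apply(mixing, 2, sd)
  tc_sd[tc_sd < .Machine$double.eps] <- 1
  mixing <- sweep(mixing, 2, tc_sd, "/")
  maps <- t(sources)
  maps <- col_standardize(maps)

  structure(
    list(mixing = mixing, maps = maps, k = k, mask = mask, dims = dims,
         explained_variance = ev_frac[k], converged = res$converged,
         seed = as.integer(seed)),
    class = "ica_result"
  )
}

#' @export
print.ica_result <- function(x, ...) {
  cat(sprintf("<ica_result> K = %d components, %d time points, EV %.3f%s\n",
              x$k, nrow(x$mixing), x$explained_variance,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Non-aggressive removal of noise components
#'
#' Fits the FULL mixing matrix to every voxel time series and subtracts only
#' the noise components' fitted contributions, leaving variance shared with
#' retained components in place (the partial-regression convention of
#' ICA-based denoisers).
#'
#' @param x Voxels-by-time matrix.
#' @param mixing T x K mixing matrix.
#' @param noise_idx Integer indices (1-based) of components to remove; empty
#'   returns `x` unchanged.
#' @return Denoised voxels-by-time matrix.
#' @export
nonaggressive_regress <- function(x, mixing, noise_idx) {
  if (length(noise_idx) == 0L) return(x)
  stopifnot(is.matrix(mixing), ncol(mixing) >= 1L)
  if (any(noise_idx < 1L | noise_idx > ncol(mixing)))
    stop("noise_idx outside 1..K")
  beta <- pinv(mixing) %*% t(x)                       # K x V
  x - t(mixing[, noise_idx, drop = FALSE] %*% beta[noise_idx, , drop = FALSE])
}
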