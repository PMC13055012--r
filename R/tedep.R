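#' TE-dependence (kappa) and TE-independence (rho) scores
#'
#' For each component, the per-echo regression coefficients of every voxel's
#' echo time series on the component time course are fitted, across echoes,
#' with two one-parameter models: the R2* (BOLD-like) model
#' `beta_{v,e} ~ -gamma_v * Sbar_{v,e} * TE_e` and the S0 (artifact-like)
#' model `beta_{v,e} ~ alpha_v * Sbar_{v,e}`, where `Sbar` is the mean echo
#' signal. Per-voxel F statistics of the two models are averaged with weights
#' equal to the squared component Z map over suprathreshold voxels, giving
#' kappa (TE-dependence) and rho (TE-independence). Components whose loadings
#' are all zero are flagged degenerate with kappa = rho = 0.
#'
#' Scores are invariant to rescaling a component's time course: the scale is
#' absorbed by the betas and cancels in the F ratios.
#'
#' @param me A [multi_echo_series()] (the per-echo data the combined series
#'   was built from).
#' @param mixing T x K mixing matrix from an ICA of the combined series.
#' @param maps In-mask-voxels x K component Z maps on the single-echo grid.
#' @param mask Logical 3D array of analysis voxels (same mask as the ICA).
#' @param z_thr Suprathreshold |Z| cutoff for the weighting; if no voxel of a
#'   component is suprathreshold, uniform in-mask weights are used.
#' @return A tibble of class `ted_metrics`: `component`, `kappa`, `rho`,
#'   `variance_explained`, `degenerate`.
#' @export
compute_kappa_rho <- function(me, mixing, maps, mask, z_thr = 2.3) {
  stopifnot(inherits(me, "multi_echo_series"))
  ne <- n_echoes(me)
  if (ne < 3L) stop("kappa/rho need at least 3 echoes for the F statistics")
  tes <- me$echo_times
  kk <- ncol(mixing)
  nvm <- sum(mask)
  stopifnot(nrow(maps) == nvm, ncol(maps) == kk)

  pm <- pinv(mixing)                                     # K x T
  betas <- vector("list", ne)                            # each K x V
  sbar <- matrix(0, nvm, ne)
  total_var <- 0
  for (e in seq_len(ne)) {
    x <- vox_by_time(me$data[[e]], mask)
    mu <- rowMeans(x)
    sbar[, e] <- mu
    total_var <- total_var + sum((x - mu)^2)
    betas[[e]] <- pm %*% t(x)
  }

  kappa <- rho <- varex <- numeric(kk)
  degenerate <- logical(kk)
  for (k in seq_len(kk)) {
    b <- vapply(betas, function(bm) bm[k, ], numeric(nvm))    # V x E
    sst <- rowSums(b^2)
    if (sum(sst) <= 1e-12 * max(sum(sbar^2), 1)) {
      degenerate[k] <- TRUE
      next
    }
    x_r2 <- -sbar * matrix(tes, nvm, ne, byrow = TRUE)
    x_s0 <- sbar
    f_of <- function(xmat) {
      num <- rowSums(xmat * b)
      den <- rowSums(xmat^2)
      gamma <- ifelse(den > 0, num / den, 0)
      sse <- rowSums((b - gamma * xmat)^2)
      f <- (sst - sse) / pmax(sse / (ne - 1), .Machine$double.eps)
      pmax(f, 0)
    }
    f_r2 <- f_of(x_r2)
    f_s0 <- f_of(x_s0)
    w <- maps[, k]^2
    w[abs(maps[, k]) < z_thr] <- 0
    if (sum(w) == 0) w <- rep(1, nvm)
    kappa[k] <- sum(w * f_r2) / sum(w)
    rho[k] <- sum(w * f_s0) / sum(w)
    varex[k] <- sum(b^2) * sum(mixing[, k]^2) / max(total_var, .Machine$double.eps)
  }
  varex <- varex / max(sum(varex), 1)
  structure(
    tibble::tibble(component = seq_len(kk), kappa = kappa, rho = rho,
                   variance_explained = varex, degenerate = degenerate),
    class = c("ted_metrics", class(tibble::tibble()))
  )
}

# index of the point of a descending curve farthest from its end-to-end chord
elbow_index <- function(y) {
  n <- length(y)
  if (n < 3L) return(n)
  x <- seq_len(n)
  x1 <- 1; y1 <- y[1]; x2 <- n; y2 <- y[n]
  d <- abs((y2 - y1) * x - (x2 - x1) * y + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  which.max(d)
}

# threshold = midpoint between the elbow point and its predecessor on the
# sorted curve; no elbow (NA) when the curve is short, flat, or spans less
# than a 3x dynamic range — a cluster of comparable scores has no cutoff,
# generalizing the accept-all rule for identical scores
elbow_threshold <- function(scores, min_ratio = 3) {
  s <- sort(scores, decreasing = TRUE)
  if (length(s) < 3L || max(s) == min(s)) return(NA_real_)
  if (max(s) < min_ratio * min(s)) return(NA_real_)
  i <- elbow_index(s)
  if (i <= 1L) return(NA_real_)
  (s[i - 1L] + s[i]) / 2
}

#' Accept/reject components by kappa/rho elbows
#'
#' A component is accepted when its kappa exceeds the kappa elbow threshold
#' and its rho falls below the rho elbow threshold. Each threshold is the
#' midpoint between the maximum-distance-to-chord point of the sorted score
#' curve and its predecessor. A curve with no real elbow — identical scores,
#' or a cluster spanning less than a 3x dynamic range — yields no threshold:
#' every component then passes that criterion (with all kappa equal every
#' component is accepted).
#'
#' @param metrics A [compute_kappa_rho()] tibble.
#' @return The tibble with an added `label` column ("accepted"/"rejected");
#'   degenerate components are rejected.
#' @export
classify_tedep <- function(metrics) {
  stopifnot(all(c("kappa", "rho") %in% names(metrics)))
  if (nrow(metrics) < 2L) stop("need at least 2 components")
  k_thr <- elbow_threshold(metrics$kappa)
  r_thr <- elbow_threshold(metrics$rho)
  acc_k <- if (is.na(k_thr)) rep(TRUE, nrow(metrics)) else metrics$kappa > k_thr
  acc_r <- if (is.na(r_thr)) rep(TRUE, nrow(metrics)) else metrics$rho < r_thr
  out <- metrics
  out$label <- ifelse(acc_k & acc_r & !out$degenerate, "accepted", "rejected")
  out
}

#' ME-ICA style denoising of a combined series
#'
#' Decomposes the optimally combined series with ICA, scores every component
#' for TE-dependence with [compute_kappa_rho()] (using the per-echo data),
#' classifies via [classify_tedep()], and removes rejected components from
#' the combined series with [nonaggressive_regress()].
#'
#' @param me The [multi_echo_series()] the combined series derives from.
#' @param optcom An [optimal_combine()] result.
#' @param mask Logical 3D analysis mask.
#' @param k Component count (NULL = automatic).
#' @param seed Decomposition seed.
#' @param z_thr Suprathreshold cutoff shared with the spatial features.
#' @return List of class `meica_result`: `series` (denoised `optcom_series`),
#'   `metrics` (component tibble with labels), `ica`, `rejected_idx`.
#' @export
meica_denoise <- function(me, optcom, mask, k = NULL, seed = 1L, z_thr = 2.3) {
  stopifnot(inherits(optcom, "optcom_series"))
  ica <- ica_decompose(optcom$data, mask, k = k, seed = seed)
  metrics <- compute_kappa_rho(me, ica$mixing, ica$maps, mask, z_thr = z_thr)
  metrics <- classify_tedep(metrics)
  rejected <- metrics$component[metrics$label == "rejected"]
  nv <- prod(dim(optcom$data)[1:3])
  x <- matrix(optcom$data, nv, dim(optcom$data)[4])
  xd <- nonaggressive_regress(x, ica$mixing, rejected)
  out <- optcom
  out$data <- array(xd, dim = dim(optcom$data))
  structure(list(series = out, metrics = metrics, ica = ica,
                 rejected_idx = rejected),
            class = "meica_result")
}
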