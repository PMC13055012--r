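#' Fit the voxelwise monoexponential decay model
#'
#' Models the temporal-mean multi-echo signal as `S(TE) = S0 * exp(-TE/T2*)`
#' and estimates one (S0, T2*) pair per voxel by ordinary least squares of
#' `log(mean signal)` on echo time: the slope gives `R2* = 1/T2*` and the
#' intercept `log S0`. T2* is clipped to `[floor, cap]`; voxels with any
#' nonpositive mean echo signal are excluded from `fit_mask` (and carry
#' capped/flagged values).
#'
#' @param me A [multi_echo_series()] with at least 2 echoes.
#' @param mask Logical 3D array of voxels to fit; default whole grid.
#' @param cap,floor Bounds on T2* in ms. Capping marks the voxel as
#'   degenerate (excluded from `fit_mask`) when the unclipped estimate was
#'   nonpositive or above the cap.
#' @return An object of class `decay_fit`: 3D maps `s0`, `t2s` (ms), `r2s`
#'   (1/ms), `rmse` (via [rmse_map()], filled lazily as NULL here), logical
#'   `fit_mask`, plus the `mask` and `echo_times` used.
#' @export
fit_monoexponential <- function(me, mask = NULL, cap = 300, floor = 1) {
  stopifnot(inherits(me, "multi_echo_series"))
  if (n_echoes(me) < 2L) stop("T2* fitting needs at least 2 echoes")
  tes <- me$echo_times
  if (length(unique(tes)) < 2L) stop("all echoes share one TE; decay is unidentifiable")
  dims <- me$dims
  if (is.null(mask)) mask <- array(TRUE, dim = dims)
  if (sum(mask) == 0L) stop("empty mask")

  sbar <- echo_means(me)[as.vector(mask), , drop = FALSE]     # V x E
  ok <- rowSums(sbar <= 0) == 0L
  slope <- rep(NA_real_, nrow(sbar))
  icpt <- rep(NA_real_, nrow(sbar))
  if (any(ok)) {
    y <- log(sbar[ok, , drop = FALSE])
    tc <- tes - mean(tes)
    slope[ok] <- as.vector(y %*% tc) / sum(tc^2)
    icpt[ok] <- rowMeans(y) - slope[ok] * mean(tes)
  }
  r2s_raw <- -slope
  t2s_raw <- ifelse(r2s_raw > 0, 1 / r2s_raw, Inf)
  valid <- ok & is.finite(t2s_raw) & t2s_raw > 0 & t2s_raw <= cap & t2s_raw >= floor
  t2s <- pmin(pmax(t2s_raw, floor), cap)
  t2s[!ok] <- cap
  s0 <- exp(icpt)
  s0[!ok] <- 0

  structure(
    list(
      s0 = vec_to_vol(s0, mask, dims, fill = 0),
      t2s = vec_to_vol(t2s, mask, dims, fill = cap),
      r2s = vec_to_vol(1 / t2s, mask, dims, fill = 1 / cap),
      fit_mask = vec_to_vol(valid, mask, dims, fill = FALSE) > 0,
      mask = mask, echo_times = tes, cap = cap, floor = floor
    ),
    class = "decay_fit"
  )
}

#' T2*-weighted optimal combination of echoes
#'
#' Combines echoes with the BOLD-sensitivity weights
#' `w_e(v) = TE_e * exp(-TE_e / T2*(v)) / sum_e' TE_e' * exp(-TE_e' / T2*(v))`,
#' which are nonnegative and sum to one at every voxel. Outside `fit_mask`
#' the T2* estimate is untrusted and a simple TE-weighted average
#' (`w_e` proportional to `TE_e`, the infinite-T2* limit) is used instead.
#'
#' @param me A [multi_echo_series()].
#' @param fit A [fit_monoexponential()] result on the same grid.
#' @return An object of class `optcom_series`: `data` (4D combined volume),
#'   `weights` (list of 3D per-echo weight maps), `tr`, `echo_times`.
#' @export
optimal_combine <- function(me, fit) {
  stopifnot(inherits(me, "multi_echo_series"), inherits(fit, "decay_fit"))
  if (!identical(dim(fit$t2s), as.integer(me$dims)) &&
      !identical(dim(fit$t2s), me$dims)) stop("fit grid does not match series grid")
  tes <- me$echo_times
  nv <- prod(me$dims)
  t2s <- as.vector(fit$t2s)
  w <- matrix(vapply(tes, function(te) te * exp(-te / t2s), numeric(nv)),
              nrow = nv)
  bad <- !as.vector(fit$fit_mask)
  if (any(bad)) w[bad, ] <- matrix(tes, sum(bad), length(tes), byrow = TRUE)
  norm <- rowSums(w)
  stopifnot(all(norm > 0))
  w <- w / norm
  comb <- matrix(0, nv, me$n_volumes)
  for (e in seq_along(tes))
    comb <- comb + w[, e] * matrix(me$data[[e]], nv, me$n_volumes)
  structure(
    list(data = array(comb, dim = c(me$dims, me$n_volumes)),
         weights = lapply(seq_along(tes), function(e) array(w[, e], dim = me$dims)),
         tr = me$tr, echo_times = tes),
    class = "optcom_series"
  )
}

#' @export
print.optcom_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<optcom_series> grid %s, %d volumes, TR %.3g s\n",
              paste(d[1:3], collapse = "x"), d[4], x$tr))
  invisible(x)
}

#' Root mean squared error of the decay model
#'
#' Evaluates the fitted static model `S0(v) * exp(-TE_e / T2*(v))` against
#' every observed sample and returns, per voxel,
#' `RMSE(v) = sqrt( mean over t,e of [Y(t,v,e) - S0 exp(-TE_e/T2*)]^2 )`.
#' One (S0, T2*) pair per voxel is used across the whole run, so the map is
#' invariant to permuting time points.
#'
#' @inheritParams optimal_combine
#' @return 3D RMSE map (intensity units), `NA` outside the fit mask's grid.
#' @export
rmse_map <- function(me, fit) {
  stopifnot(inherits(me, "multi_echo_series"), inherits(fit, "decay_fit"))
  tes <- me$echo_times
  nv <- prod(me$dims)
  s0 <- as.vector(fit$s0)
  r2s <- 1 / as.vector(fit$t2s)
  acc <- numeric(nv)
  for (e in seq_along(tes)) {
    pred <- s0 * exp(-tes[e] * r2s)
    resid <- matrix(me$data[[e]], nv, me$n_volumes) - pred
    acc <- acc + rowSums(resid^2)
  }
  array(sqrt(acc / (me$n_volumes * length(tes))), dim = me$dims)
}
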