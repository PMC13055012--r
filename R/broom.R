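#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a decay fit into one row per in-mask voxel
#'
#' @param x A [fit_monoexponential()] result.
#' @param ... Unused.
#' @return Tibble: `voxel` (linear index), `s0`, `t2s`, `r2s`, `valid`.
#' @export
tidy.decay_fit <- function(x, ...) {
  idx <- which(as.vector(x$mask))
  tibble::tibble(voxel = idx,
                 s0 = x$s0[idx], t2s = x$t2s[idx], r2s = x$r2s[idx],
                 valid = x$fit_mask[idx])
}

#' One-row summary of a decay fit
#'
#' @inheritParams tidy.decay_fit
#' @return Tibble: `n_voxels`, `n_valid`, `t2s_median`, `s0_median`.
#' @export
glance.decay_fit <- function(x, ...) {
  idx <- which(as.vector(x$mask))
  tibble::tibble(n_voxels = length(idx), n_valid = sum(x$fit_mask[idx]),
                 t2s_median = median(x$t2s[idx][x$fit_mask[idx]]),
                 s0_median = median(x$s0[idx][x$fit_mask[idx]]))
}

#' Tidy an ICA decomposition into one row per component
#'
#' @param x An [ica_decompose()] result.
#' @param ... Unused.
#' @return Tibble: `component`, `tc_sd`, `map_kurtosis` (excess spatial
#'   kurtosis, a non-Gaussianity indicator).
#' @export
tidy.ica_result <- function(x, ...) {
  kurt <- apply(x$maps, 2, function(v) mean((v - mean(v))^4) / var(v)^2 - 3)
  tibble::tibble(component = seq_len(x$k),
                 tc_sd = apply(x$mixing, 2, sd),
                 map_kurtosis = kurt)
}

#' One-row summary of an ICA decomposition
#'
#' @inheritParams tidy.ica_result
#' @return Tibble: `k`, `explained_variance`, `converged`.
#' @export
glance.ica_result <- function(x, ...) {
  tibble::tibble(k = x$k, explained_variance = x$explained_variance,
                 converged = x$converged)
}

#' Tidy an ICC reliability curve
#'
#' @param x An [icc_curve()] result.
#' @param ... Unused.
#' @return The curve tibble: `window_pct`, `window_volumes`, `icc`.
#' @export
tidy.icc_curve <- function(x, ...) x$curve

#' One-row summary of an ICC reliability curve
#'
#' @inheritParams tidy.icc_curve
#' @return Tibble: `auc`, `mp`, `mp_threshold`.
#' @export
glance.icc_curve <- function(x, ...) {
  tibble::tibble(auc = x$auc, mp = x$mp, mp_threshold = x$mp_threshold)
}
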