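#' Published linear-discriminant hyperplane for motion classification
#'
#' Intercept and coefficients of the pretrained LDA decision function on
#' (maxRPcorr, edgeFraction), imported verbatim as external constants from
#' the published ICA-AROMA distribution. A component is motion-like when
#' `b0 + b1 * maxRPcorr + b2 * edgeFraction > 0`.
#'
#' @format Named numeric vector of length 3: `intercept`, `max_rp_corr`,
#'   `edge_fraction`.
#' @export
aroma_hyperplane <- c(intercept = -19.9751070082159,
                      max_rp_corr = 9.95127547670627,
                      edge_fraction = 24.8333160239175)

#' Build the 36-regressor realignment model
#'
#' Columns are the 6 realignment parameters and their backward first
#' differences (12), plus those 12 shifted forward by one TR and backward by
#' one TR (36 total). Shift edges repeat the boundary value; the first
#' difference row is 0.
#'
#' @param mp T-by-6 matrix of realignment parameters.
#' @param tr Repetition time in seconds (recorded; shifts are by one frame).
#' @return T x 36 matrix of class `motion_design` with descriptive column
#'   names `p<j>_<orig|deriv>_<unshifted|fwd|bwd>`.
#' @export
build_motion_design <- function(mp, tr = NULL) {
  mp <- as.matrix(mp)
  if (ncol(mp) != 6L) stop("motion parameters must have 6 columns")
  nt <- nrow(mp)
  if (nt < 3L) stop("need at least 3 time points")
  deriv <- rbind(0, diff(mp))
  base <- cbind(mp, deriv)
  fwd <- rbind(base[1, , drop = FALSE], base[-nt, , drop = FALSE])
  bwd <- rbind(base[-1, , drop = FALSE], base[nt, , drop = FALSE])
  out <- cbind(base, fwd, bwd)
  kind <- rep(c("orig", "deriv"), each = 6)
  lab <- paste0("p", rep(1:6, 2), "_", kind)
  colnames(out) <- c(paste0(lab, "_unshifted"), paste0(lab, "_fwd"),
                     paste0(lab, "_bwd"))
  class(out) <- c("motion_design", class(out))
  attr(out, "tr") <- tr
  out
}

# correlations that treat zero-variance columns as r = 0
safe_cor <- function(a, b) {
  r <- suppressWarnings(cor(a, b))
  r[!is.finite(r)] <- 0
  r
}

# vectorized maxRPcorr for a T x K time-course matrix
max_rp_corr_multi <- function(tc, design, n_subsamples = 1000, frac = 0.9,
                              seed = 1L) {
  tc <- as.matrix(tc)
  nt <- nrow(tc)
  if (nrow(design) != nt) stop("time course and design lengths differ")
  n_keep <- round(frac * nt)
  if (n_keep < 10L) stop("subsample too short (fewer than 10 time points)")
  k <- ncol(tc)
  d2 <- design^2
  acc <- matrix(0, n_subsamples, k)
  withr::with_seed(as.integer(seed), {
    for (s in seq_len(n_subsamples)) {
      idx <- sort(sample.int(nt, n_keep))
      r1 <- abs(safe_cor(tc[idx, , drop = FALSE], design[idx, , drop = FALSE]))
      r2 <- abs(safe_cor(tc[idx, , drop = FALSE]^2, d2[idx, , drop = FALSE]))
      acc[s, ] <- pmax(apply(r1, 1, max), apply(r2, 1, max))
    }
  })
  colMeans(acc)
}

#' Maximum realignment-parameter correlation of a component
#'
#' For random subsamples of `frac` of the time points, computes the absolute
#' Pearson correlation between the component time course and each of the 36
#' realignment regressors, and between the squared time course and the 36
#' squared regressors (72 values per subsample); takes each subsample's
#' maximum and returns the mean of those maxima. Constant regressors
#' contribute r = 0.
#'
#' @param tc Component time course (length T), or a T x K matrix to score
#'   several components in one pass.
#' @param design A [build_motion_design()] matrix.
#' @param n_subsamples Number of random subsamples.
#' @param frac Fraction of time points per subsample.
#' @param seed Seed for the subsampling generator.
#' @return Numeric maxRPcorr in \[0, 1\] (vector of length K for matrix input).
#' @export
max_rp_corr <- function(tc, design, n_subsamples = 1000, frac = 0.9, seed = 1L) {
  out <- max_rp_corr_multi(as.matrix(tc), design, n_subsamples, frac, seed)
  if (is.null(dim(tc)) || ncol(as.matrix(tc)) == 1L) out[1] else out
}

#' High-frequency content of a time course
#'
#' Position, on a frequency axis normalized to 0 at 0.01 Hz and 1 at the
#' Nyquist frequency, at which the cumulative one-sided power spectrum
#' (restricted to frequencies at or above 0.01 Hz) first reaches half the
#' total power. Spiky, motion-like series score high; slow hemodynamic
#' fluctuations score low.
#'
#' @param tc Numeric time course, length at least 16.
#' @param tr Repetition time in seconds.
#' @return HFC in \[0, 1\].
#' @export
high_freq_content <- function(tc, tr) {
  nt <- length(tc)
  if (nt < 16L) stop("time course too short for a spectral estimate")
  x <- tc - mean(tc)
  spec <- Mod(fft(x))^2
  nf <- floor(nt / 2)
  freqs <- (1:nf) / (nt * tr)
  pw <- spec[2:(nf + 1)]
  nyq <- 1 / (2 * tr)
  keep <- freqs >= 0.01
  if (!any(keep) || sum(pw[keep]) == 0) return(0)
  f <- freqs[keep]
  p <- pw[keep] / sum(pw[keep])
  fpos <- (f - 0.01) / (nyq - 0.01)
  cum <- cumsum(p)
  fpos[which(cum >= 0.5)[1]]
}

#' Edge and CSF fractions of a component map
#'
#' With `W(v) = |Z(v)|` over suprathreshold voxels (`|Z| >= z_thr`):
#' `csfFraction = sum W(CSF) / sum W(total)` and
#' `edgeFraction = (sum W(edge) + sum W(out-of-brain)) / (sum W(total) - sum W(CSF))`.
#' Both are 0 when no voxel is suprathreshold. Maps are taken from the
#' first-echo slab of the concatenated decomposition.
#'
#' @param zmap Numeric 3D array or vector of component Z scores on the
#'   single-echo grid.
#' @param masks List with logical arrays `brain`, `edge`, `csf`, `out`
#'   (mutually exclusive).
#' @param z_thr Suprathreshold cutoff on |Z|.
#' @return Named numeric vector `c(edge_fraction, csf_fraction)`.
#' @export
spatial_fractions <- function(zmap, masks, z_thr = 2.3) {
  z <- as.vector(zmap)
  mb <- as.vector(masks$brain); me_ <- as.vector(masks$edge)
  mc <- as.vector(masks$csf); mo <- as.vector(masks$out)
  if (any(mb & me_) || any(mb & mc) || any(me_ & mc) ||
      any(mo & (mb | me_ | mc))) stop("masks overlap")
  w <- abs(z)
  w[is.na(w) | w < z_thr] <- 0
  tot <- sum(w)
  if (tot == 0) return(c(edge_fraction = 0, csf_fraction = 0))
  w_csf <- sum(w[mc]); w_edge <- sum(w[me_]) + sum(w[mo])
  denom <- tot - w_csf
  c(edge_fraction = if (denom > 0) w_edge / denom else 0,
    csf_fraction = w_csf / tot)
}

#' Classify components as motion or signal
#'
#' A component is labeled motion when any of three criteria fires:
#' (a) the pretrained LDA decision function on (maxRPcorr, edgeFraction)
#' ([aroma_hyperplane]) is positive; (b) HFC exceeds `hfc_thr`;
#' (c) csfFraction exceeds `csf_thr`. The rationale column records which
#' rules fired.
#'
#' @param features A data frame / tibble with columns `max_rp_corr`, `hfc`,
#'   `edge_fraction`, `csf_fraction` (one row per component).
#' @param hfc_thr,csf_thr Auxiliary thresholds.
#' @return The input as a tibble with added `label` ("motion"/"signal") and
#'   `rationale` columns.
#' @export
classify_components <- function(features, hfc_thr = 0.35, csf_thr = 0.10) {
  need <- c("max_rp_corr", "hfc", "edge_fraction", "csf_fraction")
  if (!all(need %in% names(features)))
    stop("features must contain: ", paste(need, collapse = ", "))
  f <- tibble::as_tibble(features)
  lda <- aroma_hyperplane[["intercept"]] +
    aroma_hyperplane[["max_rp_corr"]] * f$max_rp_corr +
    aroma_hyperplane[["edge_fraction"]] * f$edge_fraction
  fired <- cbind(lda = lda > 0, hfc = f$hfc > hfc_thr, csf = f$csf_fraction > csf_thr)
  f$label <- ifelse(rowSums(fired) > 0, "motion", "signal")
  f$rationale <- apply(fired, 1, function(r) {
    if (!any(r)) "none" else paste(c("lda", "hfc", "csf")[r], collapse = "+")
  })
  f
}

#' Early ICA-based denoising of a multi-echo series (preICA stage)
#'
#' Pipeline: Z-concatenate the echoes, decompose with [ica_decompose()],
#' compute the four component features (maxRPcorr and HFC on the shared time
#' courses; edge and CSF fractions on the first-echo Z-score maps), classify
#' with [classify_components()], and remove motion-labeled components from
#' every echo by [nonaggressive_regress()] with the SAME component set.
#'
#' @param me A [multi_echo_series()].
#' @param motion_params T x 6 realignment parameters.
#' @param masks List of logical arrays `brain`, `edge`, `csf`, `out`.
#' @param k Component count (NULL = automatic).
#' @param seed Seed for the decomposition and subsampling.
#' @param z_thr Suprathreshold |Z| cutoff for spatial features.
#' @param hfc_thr,csf_thr Classifier thresholds.
#' @param n_subsamples maxRPcorr subsampling schedule.
#' @return List of class `preica_result`: `series` (denoised
#'   [multi_echo_series()]), `report` (per-component feature tibble with
#'   labels and rationale), `ica` (the decomposition), `motion_idx`.
#' @export
preica_denoise <- function(me, motion_params, masks, k = NULL, seed = 1L,
                           z_thr = 2.3, hfc_thr = 0.35, csf_thr = 0.10,
                           n_subsamples = 1000) {
  stopifnot(inherits(me, "multi_echo_series"))
  head_mask <- masks$brain | masks$edge | masks$csf
  cv <- zconcat(me)
  cmask <- concat_mask(head_mask, n_echoes(me))
  ica <- ica_decompose(cv$data, cmask, k = k, seed = seed)

  design <- build_motion_design(motion_params, me$tr)
  mrp <- max_rp_corr_multi(ica$mixing, design, n_subsamples = n_subsamples,
                           seed = seed)
  hfc <- apply(ica$mixing, 2, high_freq_content, tr = me$tr)
  echo_maps <- split_concat_maps(ica, n_echoes(me))
  first_maps <- echo_maps[[1]]
  fr <- t(apply(first_maps, 2, spatial_fractions, masks = masks, z_thr = z_thr))

  feats <- tibble::tibble(
    component = seq_len(ica$k),
    max_rp_corr = mrp, hfc = hfc,
    edge_fraction = fr[, "edge_fraction"],
    csf_fraction = fr[, "csf_fraction"]
  )
  report <- classify_components(feats, hfc_thr = hfc_thr, csf_thr = csf_thr)
  motion_idx <- report$component[report$label == "motion"]

  nv <- prod(me$dims)
  cleaned <- lapply(me$data, function(a) {
    x <- matrix(a, nv, me$n_volumes)
    xd <- nonaggressive_regress(x, ica$mixing, motion_idx)
    array(xd, dim = c(me$dims, me$n_volumes))
  })
  structure(
    list(series = multi_echo_series(cleaned, me$echo_times, me$tr),
         report = report, ica = ica, motion_idx = motion_idx),
    class = "preica_result"
  )
}
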