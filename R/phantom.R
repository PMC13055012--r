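#' Specification of a synthetic multi-echo phantom
#'
#' Bundles every tunable of the synthetic run generator. Defaults mirror a
#' common 3T 4-echo resting-state acquisition (TEs 12/28/44/60 ms, TR 2.47 s)
#' at a desk-scale grid so that a full run generates and processes in seconds.
#'
#' The generated signal follows the monoexponential decay model
#' `S = S0 * exp(-TE * (R2* + dR2*(v,t))) * (1 + m(v,t)) + csf + drift + noise`
#' where `dR2*` carries band-limited (0.01-0.1 Hz) BOLD fluctuations in
#' network-shaped regions, `m` is a TE-independent multiplicative motion
#' artifact locked to the generated realignment parameters and concentrated at
#' the brain edge, `csf` is an additive fluctuation confined to a central CSF
#' compartment, `drift` is a slow linear trend, and `noise` is i.i.d. Gaussian
#' thermal noise per echo.
#'
#' @param grid_shape Integer vector of 3 positive extents (voxels). Each axis
#'   must be at least 5 so a 1-voxel edge shell exists.
#' @param n_volumes Number of time points T.
#' @param tr Repetition time, seconds.
#' @param echo_times Strictly increasing positive echo times, milliseconds.
#' @param s0_range Range of baseline intensity S0 inside the head.
#' @param t2s_range Range of tissue T2* (ms), within (0, 500].
#' @param n_networks Number of disjoint spherical BOLD networks.
#' @param bold_amplitude SD of the dR2* fluctuation (1/ms). The default
#'   0.0007/ms corresponds to roughly a 2% BOLD signal change at TE = 30 ms.
#' @param motion_amplitude Fractional amplitude of the TE-independent motion
#'   artifact at the brain edge.
#' @param csf_noise_sd SD of the additive CSF fluctuation, intensity units.
#' @param thermal_sd SD of i.i.d. Gaussian thermal noise, intensity units.
#' @param drift_coeff Peak-to-peak linear drift as a fraction of baseline
#'   signal per run.
#' @param seed Integer seed; identical spec + seed gives bit-identical output.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 12L),
                         n_volumes = 120L,
                         tr = 2.47,
                         echo_times = c(12, 28, 44, 60),
                         s0_range = c(800, 1200),
                         t2s_range = c(20, 60),
                         n_networks = 6L,
                         bold_amplitude = 7e-4,
                         motion_amplitude = 0.03,
                         csf_noise_sd = 15,
                         thermal_sd = 10,
                         drift_coeff = 0.01,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0L))
  if (any(grid_shape < 5L))
    stop("grid too small for an edge shell: need at least 5 voxels per axis")
  if (any(echo_times <= 0) || is.unsorted(echo_times, strictly = TRUE))
    stop("echo_times must be positive and strictly increasing")
  if (t2s_range[1] <= 0 || t2s_range[2] > 500)
    stop("t2s_range must lie within (0, 500] ms")
  sds <- c(csf_noise_sd, thermal_sd)
  if (any(sds < 0) || bold_amplitude < 0 || motion_amplitude < 0 || drift_coeff < 0)
    stop("amplitudes and SDs must be nonnegative")
  structure(
    list(grid_shape = grid_shape, n_volumes = as.integer(n_volumes), tr = tr,
         echo_times = as.numeric(echo_times), s0_range = s0_range,
         t2s_range = t2s_range, n_networks = as.integer(n_networks),
         bold_amplitude = bold_amplitude, motion_amplitude = motion_amplitude,
         csf_noise_sd = csf_noise_sd, thermal_sd = thermal_sd,
         drift_coeff = drift_coeff, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# 1-voxel morphological erosion with 6-connectivity
erode_mask <- function(mask) {
  d <- dim(mask)
  out <- mask
  shift <- function(m, ax, by) {
    r <- array(FALSE, dim = d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- (1 + by):d[ax]; idx_src[[ax]] <- 1:(d[ax] - by) }
    else { idx_dst[[ax]] <- 1:(d[ax] + by); idx_src[[ax]] <- (1 - by):d[ax] }
    r[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <- m[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    r
  }
  for (ax in 1:3) for (by in c(-1L, 1L)) out <- out & shift(mask, ax, by)
  out
}

ellipsoid_mask <- function(dims, center, semi) {
  g <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]), z = seq_len(dims[3]))
  v <- ((g$x - center[1]) / semi[1])^2 + ((g$y - center[2]) / semi[2])^2 +
    ((g$z - center[3]) / semi[3])^2
  array(v <= 1, dim = dims)
}

# realignment parameters: smooth random walk plus abrupt head jerks whose
# dominant axis is z-translation, so framewise displacement is spike-locked
generate_motion_params <- function(n, tr) {
  walk_sd <- c(rep(2e-4, 3), rep(0.02, 3))  # rot rad, trans mm per step
  mp <- vapply(walk_sd, function(s) cumsum(rnorm(n, 0, s)), numeric(n))
  n_spikes <- max(3L, round(n / 40))
  at <- sort(sample(5:(n - 2), n_spikes))
  for (t0 in at) {
    jump <- runif(1, 0.4, 0.9)
    mp[t0:n, 6] <- mp[t0:n, 6] + jump                      # trans_z step
    other <- sample(c(1:5), 2)
    for (j in other) {
      sc <- if (j <= 3) 0.002 else 0.1
      mp[t0:n, j] <- mp[t0:n, j] + sc * jump * sample(c(-1, 1), 1)
    }
  }
  colnames(mp) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  mp
}

#' Generate a synthetic multi-echo run with full ground truth
#'
#' Builds an ellipsoidal head with brain, 1-voxel edge shell, central CSF, and
#' out-of-brain compartments; draws voxelwise S0 and T2* maps; injects
#' network BOLD fluctuations (TE-dependent, via dR2*), a TE-independent
#' edge-localized motion artifact locked to generated realignment parameters,
#' CSF fluctuations, slow drift, and thermal noise, per the signal model
#' documented in [phantom_spec()].
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `series` (a [multi_echo_series()]) and `truth`
#'   (ground truth: `s0_map`, `t2s_map`, `masks` (brain/edge/csf/out),
#'   `network_labels`, `motion_params`, `fd`, `component_truth` — one record
#'   per injected component with time course, spatial map and class in
#'   bold/motion/csf/drift — and `clean_series`, the noise-free BOLD-only
#'   series).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  withr::with_seed(spec$seed, generate_phantom_impl(spec))
}

generate_phantom_impl <- function(spec) {
  dims <- spec$grid_shape
  nt <- spec$n_volumes
  tes <- spec$echo_times
  ne <- length(tes)
  nv <- prod(dims)

  center <- (dims + 1) / 2
  head_mask <- ellipsoid_mask(dims, center, 0.42 * dims)
  interior <- erode_mask(head_mask)
  edge <- head_mask & !interior
  csf <- ellipsoid_mask(dims, center, pmax(0.12 * dims, 1.6)) & interior
  brain <- interior & !csf
  out <- !head_mask
  masks <- list(brain = brain, edge = edge, csf = csf, out = out)

  s0_map <- array(0, dim = dims)
  in_head <- as.vector(head_mask)
  s0_map[in_head] <- runif(sum(in_head), spec$s0_range[1], spec$s0_range[2])
  t2s_map <- array(30, dim = dims)
  tissue <- as.vector(brain | edge)
  t2s_map[tissue] <- runif(sum(tissue), spec$t2s_range[1], spec$t2s_range[2])
  t2s_map[as.vector(csf)] <- runif(sum(csf), 100, 200)

  # disjoint spherical networks in the brain interior; greedy scan over a
  # shuffled candidate list guarantees placement whenever it is feasible
  radius <- max(2, round(min(dims) / 4))
  cand <- which(as.vector(brain), arr.ind = FALSE)
  coords <- arrayInd(cand, dims)
  deep <- coords[apply(coords, 1, function(p) {
    all(p > radius) && all(p <= dims - radius)
  }), , drop = FALSE]
  centers <- matrix(NA_real_, 0, 3)
  if (spec$n_networks > 0) {
    if (nrow(deep) == 0)
      stop("could not place ", spec$n_networks, " disjoint networks on this grid")
    for (p_i in sample.int(nrow(deep))) {
      p <- deep[p_i, ]
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, p)^2))) > 2 * radius) {
        centers <- rbind(centers, p)
        if (nrow(centers) == spec$n_networks) break
      }
    }
    if (nrow(centers) < spec$n_networks)
      stop("could not place ", spec$n_networks, " disjoint networks on this grid")
  }

  grid_xyz <- arrayInd(seq_len(nv), dims)
  network_labels <- array(0L, dim = dims)
  net_profiles <- matrix(0, nrow = nv, ncol = spec$n_networks)
  for (k in seq_len(spec$n_networks)) {
    d2 <- rowSums(sweep(grid_xyz, 2, centers[k, ])^2)
    inside <- d2 <= radius^2 & as.vector(brain)
    prof <- exp(-d2 / (2 * (radius / 1.5)^2))
    prof[!inside] <- 0
    net_profiles[, k] <- prof
    network_labels[inside] <- k
  }

  net_tc <- vapply(seq_len(spec$n_networks),
                   function(k) band_limited_noise(nt, spec$tr, 0.01, 0.1),
                   numeric(nt))

  mp <- generate_motion_params(nt, spec$tr)
  fd <- framewise_displacement(mp)
  f <- if (max(fd) > 0) fd / max(fd) else fd
  mtc_raw <- f + f^2
  motion_tc <- as.numeric(scale(mtc_raw))
  # heterogeneous voxelwise gain: rim voxels gain or lose signal with head
  # displacement depending on the local spatial gradient, so the artifact map
  # has a wide amplitude distribution over the shell rather than a flat one
  motion_profile <- array(0, dim = dims)
  motion_profile[as.vector(edge)] <- rnorm(sum(edge))
  motion_profile[as.vector(csf)] <- 0.5 * rnorm(sum(csf))

  csf_tc <- band_limited_noise(nt, spec$tr, 0.01, 0.15)
  csf_profile <- array(0, dim = dims)
  csf_profile[as.vector(csf)] <- rnorm(sum(csf))

  drift_tc <- as.numeric(scale(seq_len(nt)))
  ramp <- seq(-0.5, 0.5, length.out = nt)

  r2s <- 1 / as.vector(t2s_map)
  dR2 <- spec$bold_amplitude * (net_profiles %*% t(net_tc))     # V x T
  mvt <- spec$motion_amplitude * outer(as.vector(motion_profile), motion_tc)
  csf_term <- spec$csf_noise_sd * outer(as.vector(csf_profile), csf_tc)

  s0v <- as.vector(s0_map)
  clean <- vector("list", ne)
  noisy <- vector("list", ne)
  for (e in seq_len(ne)) {
    base <- s0v * exp(-tes[e] * r2s)                            # V
    sig <- base * exp(-tes[e] * dR2)                            # V x T (BOLD only)
    clean[[e]] <- array(sig, dim = c(dims, nt))
    full <- sig * (1 + mvt) + csf_term +
      spec$drift_coeff * outer(base, ramp)
    if (spec$thermal_sd > 0)
      full <- full + matrix(rnorm(nv * nt, 0, spec$thermal_sd), nv, nt)
    noisy[[e]] <- array(full, dim = c(dims, nt))
  }

  component_truth <- c(
    lapply(seq_len(spec$n_networks), function(k) {
      list(class = "bold", time_course = net_tc[, k],
           map = array(net_profiles[, k], dim = dims))
    }),
    list(list(class = "motion", time_course = motion_tc, map = motion_profile),
         list(class = "csf", time_course = csf_tc, map = csf_profile),
         list(class = "drift", time_course = drift_tc,
              map = array(as.numeric(head_mask), dim = dims)))
  )

  series <- multi_echo_series(noisy, tes, spec$tr)
  truth <- list(
    s0_map = s0_map, t2s_map = t2s_map, masks = masks,
    network_labels = network_labels, motion_params = mp, fd = fd,
    component_truth = component_truth,
    clean_series = multi_echo_series(clean, tes, spec$tr)
  )
  list(series = series, truth = truth)
}
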