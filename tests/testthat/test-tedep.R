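# build a small 3-echo series carrying one planted component whose per-echo
# loadings follow either the R2* (BOLD-like) or S0 (artifact-like) model
planted_tedep_series <- function(kind = c("r2s", "s0"), seed = 1,
                                 dims = c(8, 8, 4), nt = 60) {
  kind <- match.arg(kind)
  tes <- c(15, 35, 55)
  withr::with_seed(seed, {
    nv <- prod(dims)
    s0 <- runif(nv, 800, 1200)
    t2s <- runif(nv, 25, 55)
    tc <- multiecho:::band_limited_noise(nt, 2, 0.01, 0.1)
    support <- rep(FALSE, nv)
    support[sample(nv, 60)] <- TRUE
    amp <- runif(nv, 0.5, 1.5) * support
    data <- lapply(tes, function(te) {
      base <- s0 * exp(-te / t2s)
      load <- if (kind == "r2s") 1e-3 * base * te * amp else 0.02 * base * amp
      a <- outer(base, rep(1, nt)) + outer(load, tc) +
        matrix(rnorm(nv * nt, 0, 0.5), nv, nt)
      array(a, dim = c(dims, nt))
    })
    list(me = multi_echo_series(data, tes, 2), tc = tc, support = support,
         dims = dims, nt = nt)
  })
}

ted_metrics_for <- function(pl) {
  mask <- array(TRUE, pl$dims)
  mixing <- cbind(pl$tc / sd(pl$tc))
  zmap <- matrix(0, prod(pl$dims), 1)
  zmap[pl$support, 1] <- 5
  compute_kappa_rho(pl$me, mixing, zmap, mask)
}

test_that("kappa dominates for a TE-dependent planted component", {
  m <- ted_metrics_for(planted_tedep_series("r2s"))
  expect_gte(m$kappa[1] / max(m$rho[1], 1e-12), 5)
})

test_that("rho dominates for a TE-independent planted component", {
  m <- ted_metrics_for(planted_tedep_series("s0"))
  expect_gte(m$rho[1] / max(m$kappa[1], 1e-12), 5)
})

test_that("all-zero loadings give a degenerate zero-score component", {
  pl <- planted_tedep_series("r2s")
  mask <- array(TRUE, pl$dims)
  # a time course orthogonal to the data's temporal span contributes nothing
  flat <- lapply(seq_len(3), function(e)
    array(1000, dim = c(pl$dims, pl$nt)))
  me_flat <- multi_echo_series(flat, pl$me$echo_times, 2)
  mixing <- cbind(pl$tc / sd(pl$tc))
  zmap <- matrix(1, prod(pl$dims), 1)
  m <- compute_kappa_rho(me_flat, mixing, zmap, mask)
  expect_true(m$degenerate[1])
  expect_equal(m$kappa[1], 0)
  expect_equal(m$rho[1], 0)
})

test_that("kappa and rho are invariant to rescaling the time course", {
  pl <- planted_tedep_series("r2s")
  mask <- array(TRUE, pl$dims)
  zmap <- matrix(0, prod(pl$dims), 1)
  zmap[pl$support, 1] <- 5
  m1 <- compute_kappa_rho(pl$me, cbind(pl$tc), zmap, mask)
  m2 <- compute_kappa_rho(pl$me, cbind(10 * pl$tc), zmap, mask)
  expect_equal(m1$kappa, m2$kappa, tolerance = 1e-9)
  expect_equal(m1$rho, m2$rho, tolerance = 1e-9)
})

# exhaustive chord-distance elbow oracle on a sorted descending curve
elbow_oracle <- function(y) {
  s <- sort(y, decreasing = TRUE)
  n <- length(s)
  d <- vapply(seq_len(n), function(i) {
    num <- abs((s[n] - s[1]) * i - (n - 1) * s[i] + n * s[1] - s[n] * 1)
    num / sqrt((s[n] - s[1])^2 + (n - 1)^2)
  }, numeric(1))
  which.max(d)
}

test_that("elbow classification matches the exhaustive chord-distance oracle", {
  kappa <- c(100, 95, 5, 4)
  rho <- c(0.5, 0.4, 0.3, 0.2)
  m <- tibble::tibble(component = 1:4, kappa = kappa, rho = rho,
                      variance_explained = rep(0.25, 4),
                      degenerate = rep(FALSE, 4))
  out <- classify_tedep(m)
  i <- elbow_oracle(kappa)
  expect_equal(i, 3L)  # the oracle puts the kappa elbow at the 3rd sorted point
  expect_equal(out$label, c("accepted", "accepted", "rejected", "rejected"))

  # all-equal kappa: accept everything
  m2 <- m; m2$kappa <- rep(10, 4); m2$rho <- rep(0.1, 4)
  expect_true(all(classify_tedep(m2)$label == "accepted"))

  # a single dominating rho outlier is rejected
  m3 <- tibble::tibble(component = 1:5, kappa = c(50, 48, 46, 44, 42),
                       rho = c(80, 1, 1.2, 0.9, 1.1),
                       variance_explained = rep(0.2, 5),
                       degenerate = rep(FALSE, 5))
  out3 <- classify_tedep(m3)
  expect_equal(out3$label[1], "rejected")
  expect_true(all(out3$label[-1] == "accepted"))
})

test_that("ME-ICA denoising keeps BOLD and removes an S0-type artifact", {
  # BOLD-only phantom: the network signal survives
  spec <- small_spec(motion_amplitude = 0, csf_noise_sd = 0, drift_coeff = 0,
                     thermal_sd = 2)
  ph <- generate_phantom(spec)
  head_mask <- with(ph$truth$masks, brain | edge | csf)
  fit <- fit_monoexponential(ph$series, head_mask)
  oc <- optimal_combine(ph$series, fit)
  md <- suppressWarnings(meica_denoise(ph$series, oc, head_mask, seed = 1))
  expect_equal(dim(md$series$data), dim(oc$data))
  classes <- vapply(ph$truth$component_truth, `[[`, character(1), "class")
  for (i in which(classes == "bold")) {
    ct <- ph$truth$component_truth[[i]]
    netmask <- ct$map > 0.5
    before <- colMeans(multiecho:::vox_by_time(oc$data, netmask))
    after <- colMeans(multiecho:::vox_by_time(md$series$data, netmask))
    expect_gte(abs(cor(after, ct$time_course)), 0.9)
    expect_gte(var(after) / var(before), 0.5)
  }

  # strong TE-independent (S0-like) motion artifact: its time course goes
  spec2 <- small_spec(seed = 2, motion_amplitude = 0.08, thermal_sd = 2)
  ph2 <- generate_phantom(spec2)
  head2 <- with(ph2$truth$masks, brain | edge | csf)
  fit2 <- fit_monoexponential(ph2$series, head2)
  oc2 <- optimal_combine(ph2$series, fit2)
  md2 <- suppressWarnings(meica_denoise(ph2$series, oc2, head2, seed = 2))
  classes2 <- vapply(ph2$truth$component_truth, `[[`, character(1), "class")
  mt <- ph2$truth$component_truth[[which(classes2 == "motion")]]
  edge_w <- abs(mt$map) > 0.5
  before <- colMeans(multiecho:::vox_by_time(oc2$data, edge_w))
  after <- colMeans(multiecho:::vox_by_time(md2$series$data, edge_w))
  expect_gte(abs(cor(before, mt$time_course)), 0.5)
  expect_lte(abs(cor(after, mt$time_course)), 0.3)
})
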