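# independent grid-search nonlinear least-squares oracle over (S0, T2*):
# for each candidate T2*, the optimal S0 is closed-form, so a dense 1-D grid
# suffices; used only to validate the log-linear estimator
nls_oracle_t2s <- function(sbar, tes, t2s_grid = seq(1, 300, by = 0.25)) {
  best <- c(Inf, NA, NA)
  for (t2s in t2s_grid) {
    x <- exp(-tes / t2s)
    s0 <- sum(sbar * x) / sum(x^2)
    sse <- sum((sbar - s0 * x)^2)
    if (sse < best[1]) best <- c(sse, s0, t2s)
  }
  c(s0 = best[2], t2s = best[3])
}

toy_series <- function(values_by_echo, tes, tr = 2, dims = c(1, 1, 1)) {
  nt <- length(values_by_echo[[1]]) / prod(dims)
  multi_echo_series(lapply(values_by_echo, function(v)
    array(v, dim = c(dims, nt))), tes, tr)
}

test_that("exact monoexponential data is recovered exactly", {
  tes <- c(12, 28, 44, 60)
  vals <- lapply(tes, function(te) rep(100 * exp(-te / 30), 5))
  me <- toy_series(vals, tes)
  fit <- fit_monoexponential(me)
  expect_equal(as.vector(fit$s0), 100, tolerance = 1e-10)
  expect_equal(as.vector(fit$t2s), 30, tolerance = 1e-10)
  expect_true(all(fit$fit_mask))
})

test_that("constant signal across echoes is capped and flagged", {
  tes <- c(12, 28, 44, 60)
  me <- toy_series(lapply(tes, function(te) rep(50, 5)), tes)
  fit <- fit_monoexponential(me, cap = 300)
  expect_equal(as.vector(fit$t2s), 300)
  expect_false(any(fit$fit_mask))
})

test_that("log-linear fit tracks truth and the grid-search NLS oracle under noise", {
  ph <- generate_phantom(phantom_spec(n_networks = 0, bold_amplitude = 0,
                                      motion_amplitude = 0, csf_noise_sd = 0,
                                      drift_coeff = 0, thermal_sd = 37,
                                      seed = 11))
  brain <- ph$truth$masks$brain
  fit <- fit_monoexponential(ph$series, brain)
  truth_t2s <- ph$truth$t2s_map[brain]
  est_t2s <- fit$t2s[brain]
  rel_err <- abs(est_t2s - truth_t2s) / truth_t2s
  expect_lt(median(rel_err), 0.05)

  # against the independent NLS oracle on 100 random voxels
  sbar_all <- multiecho:::echo_means(ph$series)[as.vector(brain), ]
  set.seed(42)
  idx <- sample(nrow(sbar_all), 100)
  oracle <- t(apply(sbar_all[idx, ], 1, nls_oracle_t2s, tes = ph$series$echo_times))
  rel_vs_oracle <- abs(est_t2s[idx] - oracle[, "t2s"]) / oracle[, "t2s"]
  expect_lte(median(rel_vs_oracle), 0.05)
})

test_that("combination weights are normalized and match hand arithmetic", {
  ph <- small_phantom()
  head_mask <- with(ph$truth$masks, brain | edge | csf)
  fit <- fit_monoexponential(ph$series, head_mask)
  oc <- optimal_combine(ph$series, fit)
  wsum <- Reduce(`+`, oc$weights)
  expect_lt(max(abs(wsum - 1)), 1e-12)
  expect_true(all(vapply(oc$weights, function(w) all(w >= 0), logical(1))))

  # 2-echo toy: TE 10/30 ms, T2* = 20 ms; weights from the formula by hand
  tes <- c(10, 30)
  me2 <- toy_series(lapply(tes, function(te) rep(100 * exp(-te / 20), 4)), tes)
  fit2 <- fit_monoexponential(me2)
  oc2 <- optimal_combine(me2, fit2)
  w1_hand <- 10 * exp(-10 / 20) / (10 * exp(-10 / 20) + 30 * exp(-30 / 20))
  expect_equal(as.vector(oc2$weights[[1]]), w1_hand, tolerance = 1e-10)
  expect_equal(as.vector(oc2$weights[[2]]), 1 - w1_hand, tolerance = 1e-10)

  # T2* -> infinity limit: weights proportional to TE
  fit_inf <- fit
  fit_inf$t2s <- array(1e12, dim = dim(fit$t2s))
  fit_inf$fit_mask <- array(TRUE, dim = dim(fit$t2s))
  oc_inf <- optimal_combine(ph$series, fit_inf)
  tes4 <- ph$series$echo_times
  for (e in 1:4)
    expect_equal(as.vector(oc_inf$weights[[e]]),
                 rep(tes4[e] / sum(tes4), length(oc_inf$weights[[e]])),
                 tolerance = 1e-6)
})

test_that("RMSE is zero on noise-free data and matches the hand-worked toy", {
  spec <- small_spec(bold_amplitude = 0, motion_amplitude = 0, thermal_sd = 0,
                     csf_noise_sd = 0, drift_coeff = 0)
  ph <- generate_phantom(spec)
  head_mask <- with(ph$truth$masks, brain | edge | csf)
  fit <- fit_monoexponential(ph$series, head_mask)
  rm <- rmse_map(ph$series, fit)
  base <- ph$truth$s0_map[head_mask]
  expect_lt(max(rm[head_mask] / base), 1e-8)

  # 2 echoes x 2 time points, S0 = 100, T2* = 30 ms, TE 12/28 ms,
  # observations {68, 66} and {40, 39}; hand arithmetic oracle
  me <- toy_series(list(c(68, 66), c(40, 39)), c(12, 28))
  fit_toy <- structure(list(
    s0 = array(100, dim = c(1, 1, 1)), t2s = array(30, dim = c(1, 1, 1)),
    r2s = array(1 / 30, dim = c(1, 1, 1)),
    fit_mask = array(TRUE, dim = c(1, 1, 1)),
    mask = array(TRUE, dim = c(1, 1, 1)), echo_times = c(12, 28)
  ), class = "decay_fit")
  pred1 <- 100 * exp(-12 / 30); pred2 <- 100 * exp(-28 / 30)
  hand <- sqrt(((68 - pred1)^2 + (66 - pred1)^2 +
                  (40 - pred2)^2 + (39 - pred2)^2) / 4)
  expect_equal(as.vector(rmse_map(me, fit_toy)), hand, tolerance = 1e-12)
  expect_equal(hand, 0.8006, tolerance = 1e-4)
})

test_that("RMSE is invariant to permuting time points and tracks added noise", {
  ph <- small_phantom()
  head_mask <- with(ph$truth$masks, brain | edge | csf)
  fit <- fit_monoexponential(ph$series, head_mask)
  r1 <- rmse_map(ph$series, fit)
  perm <- rev(seq_len(ph$series$n_volumes))
  me_perm <- multi_echo_series(lapply(ph$series$data, function(a)
    a[, , , perm, drop = FALSE]), ph$series$echo_times, ph$series$tr)
  fit_perm <- fit_monoexponential(me_perm, head_mask)
  expect_equal(rmse_map(me_perm, fit_perm), r1, tolerance = 1e-10)

  # pure additive N(0, sigma) on noise-free data: spatial median RMSE ~ sigma
  sigma <- 5
  spec0 <- small_spec(seed = 9, bold_amplitude = 0, motion_amplitude = 0,
                      thermal_sd = 0, csf_noise_sd = 0, drift_coeff = 0)
  ph0 <- generate_phantom(spec0)
  set.seed(99)
  noisy <- lapply(ph0$series$data, function(a)
    a + array(rnorm(length(a), 0, sigma), dim = dim(a)))
  me_n <- multi_echo_series(noisy, ph0$series$echo_times, ph0$series$tr)
  head0 <- with(ph0$truth$masks, brain | edge | csf)
  fit_n <- fit_monoexponential(me_n, head0)
  rm_n <- rmse_map(me_n, fit_n)
  expect_lt(abs(median(rm_n[head0]) - sigma) / sigma, 0.05)
})
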