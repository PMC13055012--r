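test_that("motion design has 36 labeled columns with the shift structure", {
  withr::with_seed(1, mp <- matrix(rnorm(50 * 6), 50, 6))
  d <- build_motion_design(mp, tr = 2)
  expect_equal(ncol(d), 36)
  expect_equal(sum(grepl("_orig_", colnames(d))), 18)
  expect_equal(sum(grepl("_deriv_", colnames(d))), 18)
  # derivative columns are backward first differences with a leading 0
  expect_equal(unname(d[, "p1_deriv_unshifted"]), c(0, diff(mp[, 1])))
  # backward-shifted column j at t equals the unshifted column at t + 1
  for (t in 2:48)
    expect_equal(unname(d[t, "p3_orig_bwd"]), unname(d[t + 1, "p3_orig_unshifted"]))
  # forward-shifted column at t equals unshifted at t - 1
  for (t in 2:49)
    expect_equal(unname(d[t, "p3_orig_fwd"]), unname(d[t - 1, "p3_orig_unshifted"]))
  # zero motion propagates to an all-zero design
  expect_true(all(build_motion_design(matrix(0, 20, 6), tr = 2) == 0))
  expect_error(build_motion_design(matrix(0, 2, 6), 2), "at least 3")
})

test_that("maxRPcorr is near 1 for a regressor copy and subsamples 72 correlations", {
  withr::with_seed(2, mp <- matrix(cumsum(rnorm(100 * 6, 0, 0.1)), 100, 6))
  d <- build_motion_design(mp, tr = 2)
  v <- max_rp_corr(d[, 1], d, n_subsamples = 200, seed = 1)
  expect_gte(v, 0.999)
  # the correlation families: 36 plain + 36 squared regressors
  expect_equal(2L * ncol(d), 72L)
})

test_that("maxRPcorr of independent noise stays low", {
  withr::with_seed(3, mp <- matrix(cumsum(rnorm(200 * 6, 0, 0.1)), 200, 6))
  d <- build_motion_design(mp, tr = 2)
  vals <- vapply(1:20, function(s) {
    c <- withr::with_seed(100 + s, rnorm(200))
    max_rp_corr(c, d, n_subsamples = 100, seed = s)
  }, numeric(1))
  expect_gte(mean(vals < 0.5), 0.95)
})

test_that("high-frequency content separates slow from fast series", {
  tr <- 1
  nt <- 300
  t <- seq_len(nt)
  hi <- sin(2 * pi * 0.95 * (1 / (2 * tr)) * t * tr)
  expect_gte(high_freq_content(hi, tr), 0.9)
  lo <- sin(2 * pi * 0.015 * t * tr)
  expect_lte(high_freq_content(lo, tr), 0.1)
  wn <- withr::with_seed(5, rnorm(1000))
  expect_lt(abs(high_freq_content(wn, tr) - 0.5), 0.05)
  expect_error(high_freq_content(rnorm(8), tr), "short")
})

test_that("edge and CSF fractions follow the suprathreshold mass", {
  dims <- c(6, 6, 4)
  masks <- list(brain = array(FALSE, dims), edge = array(FALSE, dims),
                csf = array(FALSE, dims), out = array(FALSE, dims))
  masks$edge[1, , ] <- TRUE
  masks$csf[3, 3, ] <- TRUE
  masks$out[6, , ] <- TRUE
  masks$brain <- !(masks$edge | masks$csf | masks$out)

  z <- array(0, dims)
  z[1, 1, 1] <- 5                        # edge mass only
  expect_equal(spatial_fractions(z, masks),
               c(edge_fraction = 1, csf_fraction = 0))
  z2 <- array(0, dims)
  z2[3, 3, 1] <- -4                      # CSF mass only (sign ignored)
  expect_equal(unname(spatial_fractions(z2, masks)["csf_fraction"]), 1)
  # |Z| mass 30 in edge, 70 in interior brain, 0 in CSF -> edge fraction 0.3
  z3 <- array(0, dims)
  z3[1, 1:2, 1] <- c(10, 20)
  z3[2, 1:2, 1] <- c(30, 40)
  expect_equal(unname(spatial_fractions(z3, masks)["edge_fraction"]), 0.3)
  # below-threshold mass does not count
  z4 <- array(1.0, dims)
  expect_equal(spatial_fractions(z4, masks),
               c(edge_fraction = 0, csf_fraction = 0))
  # overlapping masks are rejected
  bad <- masks; bad$csf[1, 1, 1] <- TRUE
  expect_error(spatial_fractions(z, bad), "overlap")
})

test_that("classification rules fire as documented and are monotone in HFC", {
  f <- tibble::tibble(
    max_rp_corr = c(0.99, 0.05, 0),
    edge_fraction = c(0.95, 0.02, 0),
    hfc = c(0.10, 0.05, 1.0),
    csf_fraction = c(0, 0, 0)
  )
  out <- classify_components(f)
  # rule (a): hyperplane evaluated independently
  lda1 <- -19.9751070082159 + 9.95127547670627 * 0.99 + 24.8333160239175 * 0.95
  expect_gt(lda1, 0)
  expect_equal(out$label, c("motion", "signal", "motion"))
  expect_match(out$rationale[1], "lda")
  expect_match(out$rationale[3], "hfc")

  # monotonicity: raising HFC never flips motion -> signal
  withr::with_seed(6, {
    base <- tibble::tibble(max_rp_corr = runif(50), edge_fraction = runif(50),
                           hfc = runif(50), csf_fraction = runif(50, 0, 0.3))
  })
  l0 <- classify_components(base)$label
  up <- base; up$hfc <- pmin(up$hfc + 0.3, 1)
  l1 <- classify_components(up)$label
  expect_false(any(l0 == "motion" & l1 == "signal"))
})

test_that("preICA leaves a clean BOLD-only phantom essentially untouched", {
  spec <- small_spec(motion_amplitude = 0, csf_noise_sd = 0, thermal_sd = 0,
                     drift_coeff = 0)
  ph <- generate_phantom(spec)
  pre <- suppressWarnings(
    preica_denoise(ph$series, ph$truth$motion_params, ph$truth$masks,
                   seed = 1, n_subsamples = 200))
  head_mask <- with(ph$truth$masks, brain | edge | csf)
  var_before <- sum(vapply(ph$series$data, function(a) {
    m <- multiecho:::vox_by_time(a, head_mask); sum((m - rowMeans(m))^2)
  }, numeric(1)))
  var_after <- sum(vapply(pre$series$data, function(a) {
    m <- multiecho:::vox_by_time(a, head_mask); sum((m - rowMeans(m))^2)
  }, numeric(1)))
  expect_gte(var_after, 0.9 * var_before)
  expect_equal(dim(pre$series$data[[1]]), dim(ph$series$data[[1]]))
})

test_that("a strong injected motion artifact is captured by a motion-labeled component", {
  r <- study_run(1)
  expect_gte(r$motion_r, 0.8)
  expect_equal(r$motion_label, "motion")
})

test_that("all four features stay in [0, 1] on phantom decompositions", {
  ph <- small_phantom(seed = 3)
  pre <- suppressWarnings(
    preica_denoise(ph$series, ph$truth$motion_params, ph$truth$masks,
                   seed = 3, n_subsamples = 100))
  rep <- pre$report
  for (colname in c("max_rp_corr", "hfc", "edge_fraction", "csf_fraction")) {
    expect_true(all(rep[[colname]] >= 0 & rep[[colname]] <= 1),
                info = colname)
  }
  expect_true(all(rep$label %in% c("motion", "signal")))
})
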