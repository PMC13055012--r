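# shared fixtures, all generated in code; heavy multi-seed runs are cached
# so several test files can reuse them within one session

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# compact phantom for module-level tests
small_spec <- function(seed = 1, ...) {
  phantom_spec(grid_shape = c(18, 18, 10), n_volumes = 60, n_networks = 4,
               seed = seed, ...)
}

small_phantom <- function(seed = 1, ...) {
  cached(paste0("small_phantom_", seed, "_", paste(c(...), collapse = "_")),
         generate_phantom(small_spec(seed, ...)))
}

default_phantom <- function(seed = 1) {
  cached(paste0("default_phantom_", seed),
         generate_phantom(phantom_spec(seed = seed)))
}

# one full study run at the default (study-condition) phantom scale:
# all four variants, QC, decay RMSE, ICC reliability, and the classification
# outcome for the planted components; only compact summaries are kept
study_run <- function(seed) {
  cached(paste0("study_run_", seed), {
    ph <- generate_phantom(phantom_spec(seed = seed))
    me <- ph$series
    truth <- ph$truth
    res <- suppressWarnings(
      process_variants(me, truth$motion_params, truth$masks, seed = seed,
                       detail = TRUE)
    )
    pre <- attr(res, "preica")
    classes <- vapply(truth$component_truth, `[[`, character(1), "class")
    match_label <- function(tc) {
      r <- abs(cor(pre$ica$mixing, tc))
      k <- which.max(r)
      list(label = pre$report$label[k], r = max(r))
    }
    motion_truth <- truth$component_truth[[which(classes == "motion")]]
    motion_match <- match_label(motion_truth$time_course)
    bold_matches <- lapply(which(classes == "bold"), function(i)
      match_label(truth$component_truth[[i]]$time_course))
    summaries <- lapply(res, function(r) {
      ic <- suppressWarnings(icc_curve(r$data, truth$network_labels))
      tibble::tibble(dvars = r$qc$dvars_mean, tsnr = r$qc$tsnr_mean,
                     rmse = r$rmse_mean, entropy = r$qc$entropy_mean,
                     icc_auc = ic$auc, icc_mp = ic$mp)
    })
    list(summaries = summaries,
         motion_label = motion_match$label, motion_r = motion_match$r,
         bold_labels = vapply(bold_matches, `[[`, character(1), "label"))
  })
}

study_seeds <- 1:10

study_metric <- function(variant, metric) {
  vapply(study_seeds, function(s) study_run(s)$summaries[[variant]][[metric]],
         numeric(1))
}

# one-sided sign test: P(#successes >= x | p = 0.5)
sign_test_p <- function(successes, n) {
  stats::binom.test(successes, n, p = 0.5, alternative = "greater")$p.value
}
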