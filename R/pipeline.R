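#' QC summary of a 4D series
#'
#' DVARS (mean and trapezoid AUC), mean tSNR, and mean in-mask Shannon
#' entropy, as one tibble row.
#'
#' @param data 4D array.
#' @param mask Logical 3D analysis mask.
#' @param n_bins Entropy histogram bins.
#' @return One-row tibble: `dvars_mean`, `dvars_auc`, `tsnr_mean`,
#'   `entropy_mean`.
#' @export
qc_summary <- function(data, mask, n_bins = 20) {
  dv <- dvars(data, mask)
  ts <- tsnr(data, mask)
  tibble::tibble(dvars_mean = dv$mean, dvars_auc = dv$auc,
                 tsnr_mean = ts$mean,
                 entropy_mean = mean_entropy(data, mask, n_bins = n_bins))
}

pipeline_variants <- c("optcom", "pOptcom", "MEICA", "pMEICA")

#' Run the four denoising paths in memory
#'
#' Produces any subset of the four output series from one multi-echo run:
#' `optcom` (T2*-weighted combination), `pOptcom` (preICA denoising before
#' combination), `MEICA` (TE-dependence denoising of the combined series),
#' `pMEICA` (preICA, then combination, then TE-dependence denoising). The
#' optcom path involves no randomness, so its output is identical whichever
#' other variants are enabled; ICA stages use seeds derived deterministically
#' from `seed`.
#'
#' @param me A [multi_echo_series()].
#' @param motion_params T x 6 realignment parameters.
#' @param masks Named list of logical arrays `brain`, `edge`, `csf`, `out`.
#' @param variants Subset of `r paste(pipeline_variants, collapse = ", ")`.
#' @param seed Base seed for the ICA stages.
#' @param k Component count passed to the decompositions (NULL = automatic).
#' @param z_thr,hfc_thr,csf_thr,n_subsamples Classifier settings, see
#'   [preica_denoise()].
#' @param detail Attach the full `preica_result` as attribute `"preica"` of
#'   the returned list (used for component-level inspection).
#' @return Named list, one entry per variant: `data` (4D array), `fit` (the
#'   decay fit behind the combination), `rmse_mean` (mean in-brain decay
#'   RMSE of the per-echo data the variant combines), `qc` (a [qc_summary()]
#'   row), plus `preica` and/or `meica` reports where those stages ran.
#' @export
process_variants <- function(me, motion_params, masks,
                             variants = pipeline_variants, seed = 1L,
                             k = NULL, z_thr = 2.3, hfc_thr = 0.35,
                             csf_thr = 0.10, n_subsamples = 1000,
                             detail = FALSE) {
  variants <- match.arg(variants, pipeline_variants, several.ok = TRUE)
  head_mask <- masks$brain | masks$edge | masks$csf
  brain <- masks$brain
  out <- list()

  need_pre <- any(c("pOptcom", "pMEICA") %in% variants)
  pre <- NULL
  if (need_pre)
    pre <- preica_denoise(me, motion_params, masks, k = k, seed = seed,
                          z_thr = z_thr, hfc_thr = hfc_thr, csf_thr = csf_thr,
                          n_subsamples = n_subsamples)

  mk_combined <- function(series) {
    fit <- fit_monoexponential(series, head_mask)
    list(fit = fit, oc = optimal_combine(series, fit),
         rmse = rmse_map(series, fit))
  }
  raw <- if (any(c("optcom", "MEICA") %in% variants)) mk_combined(me) else NULL
  prc <- if (need_pre) mk_combined(pre$series) else NULL

  pack <- function(data, fit, rmse, extra = list()) {
    c(list(data = data, fit = fit,
           rmse_mean = mean(rmse[brain], na.rm = TRUE),
           qc = qc_summary(data, brain)), extra)
  }
  if ("optcom" %in% variants)
    out$optcom <- pack(raw$oc$data, raw$fit, raw$rmse)
  if ("pOptcom" %in% variants)
    out$pOptcom <- pack(prc$oc$data, prc$fit, prc$rmse,
                        list(preica = pre$report))
  if ("MEICA" %in% variants) {
    md <- meica_denoise(me, raw$oc, head_mask, k = k, seed = seed + 1L,
                        z_thr = z_thr)
    out$MEICA <- pack(md$series$data, raw$fit, raw$rmse,
                      list(meica = md$metrics))
  }
  if ("pMEICA" %in% variants) {
    md <- meica_denoise(pre$series, prc$oc, head_mask, k = k,
                        seed = seed + 2L, z_thr = z_thr)
    out$pMEICA <- pack(md$series$data, prc$fit, prc$rmse,
                       list(preica = pre$report, meica = md$metrics))
  }
  if (detail && !is.null(pre)) attr(out, "preica") <- pre
  out
}

#' Pipeline configuration
#'
#' Flat record of every path and parameter one end-to-end run needs; printed
#' into the output manifest for provenance.
#'
#' @param bids_dir,out_dir Input and output directories.
#' @param subject,task BIDS entities.
#' @param variants Which of the four outputs to produce.
#' @param atlas Optional integer-label NIfTI path (or 3D array) for
#'   reliability metrics.
#' @param seed Base seed.
#' @param k,z_thr,hfc_thr,csf_thr,n_subsamples Stage parameters.
#' @param entropy_bins Histogram bins for the entropy QC metric.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(bids_dir, out_dir, subject = "sub-01",
                            task = "rest", variants = pipeline_variants,
                            atlas = NULL, seed = 1L, k = NULL, z_thr = 2.3,
                            hfc_thr = 0.35, csf_thr = 0.10,
                            n_subsamples = 1000, entropy_bins = 20) {
  if (length(variants) == 0L) stop("at least one variant must be enabled")
  variants <- match.arg(variants, pipeline_variants, several.ok = TRUE)
  structure(
    list(bids_dir = bids_dir, out_dir = out_dir, subject = subject,
         task = task, variants = variants, atlas = atlas,
         seed = as.integer(seed), k = k, z_thr = z_thr, hfc_thr = hfc_thr,
         csf_thr = csf_thr, n_subsamples = n_subsamples,
         entropy_bins = entropy_bins),
    class = "pipeline_config"
  )
}

#' Run the pipeline end to end on a BIDS-lite directory
#'
#' Discovers the run, loads it, produces every enabled variant with
#' [process_variants()], writes each denoised series with its confound
#' table, component reports, a QC summary JSON, and (when an atlas is given)
#' reliability metrics, and records the configuration in a JSON manifest.
#'
#' @param config A [pipeline_config()].
#' @return Tibble manifest of written files: `variant`, `kind`, `path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  layout <- discover_run(config$bids_dir, config$subject, config$task)
  run <- load_run(layout)
  me <- run$series
  masks <- run$masks[c("brain", "edge", "csf", "out")]
  if (any(vapply(masks, is.null, logical(1))))
    stop("run must provide brain/edge/csf/out masks")
  if (is.null(run$motion_params)) stop("run lacks a motion parameter TSV")

  res <- process_variants(me, run$motion_params, masks,
                          variants = config$variants, seed = config$seed,
                          k = config$k, z_thr = config$z_thr,
                          hfc_thr = config$hfc_thr, csf_thr = config$csf_thr,
                          n_subsamples = config$n_subsamples)

  atlas <- config$atlas
  if (is.character(atlas)) atlas <- array(as.integer(read_volume(atlas) + 0.5),
                                          dim = layout$dims)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  add <- function(variant, kind, path)
    rows[[length(rows) + 1]] <<- tibble::tibble(variant = variant, kind = kind,
                                                path = path)
  for (v in names(res)) {
    r <- res[[v]]
    cs <- confound_signals(r$data, masks$brain, masks$csf)
    dv <- dvars(r$data, masks$brain)
    conf <- confound_table(run$motion_params, dv$confound,
                           csf = cs$csf, white_matter = cs$white_matter)
    paths <- write_outputs(r$data, conf, config$out_dir, variant = v,
                           subject = config$subject, task = config$task,
                           tr = me$tr)
    add(v, "bold", paths["bold"]); add(v, "confounds", paths["confounds"])
    qc_path <- file.path(config$out_dir,
                         sprintf("%s_task-%s_desc-%s_qc.json",
                                 config$subject, config$task, v))
    qc <- as.list(r$qc)
    qc$rmse_mean <- r$rmse_mean
    if (!is.null(atlas)) {
      ic <- icc_curve(r$data, atlas)
      qc$icc_auc <- ic$auc
      qc$icc_mp <- ic$mp
    }
    jsonlite::write_json(qc, qc_path, auto_unbox = TRUE, digits = NA)
    add(v, "qc", qc_path)
    for (tab in intersect(c("preica", "meica"), names(r))) {
      p <- file.path(config$out_dir,
                     sprintf("%s_task-%s_desc-%s_%s.tsv",
                             config$subject, config$task, v, tab))
      write.table(as.data.frame(r[[tab]]), p, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      add(v, tab, p)
    }
  }
  manifest_path <- file.path(config$out_dir, "manifest.json")
  cfg <- config
  cfg$atlas <- if (is.null(config$atlas)) NULL else "provided"
  jsonlite::write_json(
    list(package_version = as.character(utils::packageVersion("multiecho")),
         config = unclass(cfg)),
    manifest_path, auto_unbox = TRUE, digits = NA, null = "null")
  add("all", "manifest", manifest_path)
  dplyr::bind_rows(rows)
}

#' Simulate a phantom run onto disk
#'
#' Thin wrapper: generate a phantom and write it as a BIDS-lite directory
#' that [discover_run()] accepts.
#'
#' @param out_dir Destination directory.
#' @param spec A [phantom_spec()]; defaults used when NULL.
#' @param subject,task BIDS entities.
#' @return The [write_phantom_bids()] manifest tibble.
#' @export
simulate_run <- function(out_dir, spec = NULL, subject = "sub-01",
                         task = "rest") {
  spec <- spec %||% phantom_spec()
  ph <- generate_phantom(spec)
  write_phantom_bids(ph, out_dir, subject = subject, task = task)
}
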