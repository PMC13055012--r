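#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file (.nii or .nii.gz).
#' @return Numeric array with attribute `pixdim` preserved by RNifti.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  attr(a, "pixdim") <- RNifti::pixdim(img)
  a
}

#' Write an array as NIfTI
#'
#' @param x Numeric/logical array (3D or 4D).
#' @param path Destination (.nii.gz recommended).
#' @param tr Repetition time in seconds for 4D volumes (stored in pixdim).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, tr = NULL) {
  a <- array(as.numeric(x), dim = dim(x))
  img <- RNifti::asNifti(a)
  if (!is.null(tr) && length(dim(a)) == 4L) {
    pd <- RNifti::pixdim(img)
    pd[4] <- tr
    RNifti::pixdim(img) <- pd
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_mask <- function(path) {
  a <- read_volume(path)
  vals <- unique(as.vector(a))
  if (any(!vals %in% c(0, 1))) {
    warning("mask ", basename(path), " is not strictly binary; nonzero treated as 1")
  }
  array(a != 0, dim = dim(a))
}

#' Write a synthetic phantom as a BIDS-lite directory
#'
#' One gzipped NIfTI per echo (`echo-<n>_bold`) with a JSON sidecar carrying
#' `EchoTime` in seconds (BIDS convention; converted from the internal ms)
#' and `RepetitionTime`; realignment parameters as a 6-column TSV; masks,
#' ground-truth S0/T2* maps and network labels as NIfTI.
#'
#' @param phantom A [generate_phantom()] result.
#' @param out_dir Output directory (created if needed).
#' @param subject,task BIDS entities used in file names.
#' @return Tibble manifest: `path`, `kind`.
#' @export
write_phantom_bids <- function(phantom, out_dir, subject = "sub-01",
                               task = "rest") {
  me <- phantom$series
  truth <- phantom$truth
  func <- file.path(out_dir, subject, "func")
  dir.create(func, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(func, sprintf("%s_task-%s", subject, task))
  paths <- character(0); kinds <- character(0)
  add <- function(p, k) { paths <<- c(paths, p); kinds <<- c(kinds, k) }

  for (e in seq_len(n_echoes(me))) {
    bold <- sprintf("%s_echo-%d_bold.nii.gz", stem, e)
    write_volume(me$data[[e]], bold, tr = me$tr)
    side <- sprintf("%s_echo-%d_bold.json", stem, e)
    jsonlite::write_json(
      list(EchoTime = me$echo_times[e] / 1000, RepetitionTime = me$tr),
      side, auto_unbox = TRUE, digits = NA)
    add(bold, "bold"); add(side, "sidecar")
  }
  mp_path <- sprintf("%s_motion.tsv", stem)
  write.table(truth$motion_params, mp_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  add(mp_path, "motion")
  for (nm in names(truth$masks)) {
    p <- sprintf("%s_desc-%s_mask.nii.gz", stem, nm)
    write_volume(truth$masks[[nm]], p)
    add(p, paste0("mask_", nm))
  }
  p <- sprintf("%s_desc-S0map.nii.gz", stem)
  write_volume(truth$s0_map, p); add(p, "s0_map")
  p <- sprintf("%s_desc-T2starmap.nii.gz", stem)
  write_volume(truth$t2s_map, p); add(p, "t2s_map")
  p <- sprintf("%s_desc-networks_dseg.nii.gz", stem)
  write_volume(truth$network_labels, p); add(p, "networks")
  tibble::tibble(path = paths, kind = kinds)
}

#' Discover a multi-echo run in a BIDS-lite directory
#'
#' Locates the `echo-<n>_bold` NIfTI files of one subject/task, reads echo
#' times from the JSON sidecars (seconds, converted to ms internally), the
#' repetition time, motion parameters, and any masks written alongside.
#' Echoes are returned TE-ascending regardless of on-disk order.
#'
#' @param bids_dir Root directory.
#' @param subject,task BIDS entities.
#' @return List of class `run_layout`: `subject`, `echo_paths`, `echo_times`
#'   (ms), `tr` (s), `motion_path`, `mask_paths` (named), `dims`.
#' @export
discover_run <- function(bids_dir, subject = "sub-01", task = "rest") {
  func <- file.path(bids_dir, subject, "func")
  if (!dir.exists(func)) stop("no func directory for ", subject, " under ", bids_dir)
  bolds <- list.files(func, pattern = sprintf("%s_task-%s_echo-[0-9]+_bold\\.nii(\\.gz)?$",
                                              subject, task),
                      full.names = TRUE)
  if (length(bolds) < 2L) stop("insufficient echoes: found ", length(bolds))
  idx <- as.integer(sub(".*echo-([0-9]+)_bold.*", "\\1", basename(bolds)))
  if (!setequal(idx, seq_along(idx)))
    stop("echo indices must be contiguous from 1; got ", paste(sort(idx), collapse = ","))
  if (length(bolds) < 3L) warning("fewer than 3 echoes; T2* fits will be exact-fit only")
  tes <- numeric(length(bolds)); tr <- NA_real_
  for (i in seq_along(bolds)) {
    side <- sub("\\.nii(\\.gz)?$", ".json", bolds[i])
    if (!file.exists(side)) stop("missing sidecar for ", basename(bolds[i]))
    meta <- jsonlite::read_json(side)
    if (is.null(meta$EchoTime)) stop("sidecar lacks EchoTime: ", basename(side))
    tes[i] <- as.numeric(meta$EchoTime) * 1000
    if (!is.null(meta$RepetitionTime)) tr <- as.numeric(meta$RepetitionTime)
  }
  ord <- order(idx)
  bolds <- bolds[ord]; tes <- tes[ord]
  if (is.unsorted(tes, strictly = TRUE))
    stop("echo times are not strictly ascending with echo index")
  hdr <- RNifti::niftiHeader(bolds[1])
  dims <- hdr$dim[2:4]
  for (b in bolds[-1]) {
    h <- RNifti::niftiHeader(b)
    if (!identical(h$dim[2:5], hdr$dim[2:5]))
      stop("echo volumes disagree in shape: ", basename(b))
  }
  stem <- file.path(func, sprintf("%s_task-%s", subject, task))
  motion <- sprintf("%s_motion.tsv", stem)
  masks <- list.files(func, pattern = sprintf("%s_task-%s_desc-.*_mask\\.nii(\\.gz)?$",
                                              subject, task), full.names = TRUE)
  names(masks) <- sub(".*desc-([a-zA-Z0-9]+)_mask.*", "\\1", basename(masks))
  structure(
    list(subject = subject, task = task, echo_paths = bolds, echo_times = tes,
         tr = tr, motion_path = if (file.exists(motion)) motion else NULL,
         mask_paths = as.list(masks), dims = dims),
    class = "run_layout"
  )
}

#' Load the series and ancillaries described by a run layout
#'
#' @param layout A [discover_run()] result.
#' @return List: `series` ([multi_echo_series()]), `motion_params` (matrix or
#'   NULL), `masks` (named list of logical arrays).
#' @export
load_run <- function(layout) {
  stopifnot(inherits(layout, "run_layout"))
  data <- lapply(layout$echo_paths, function(p) {
    a <- read_volume(p)
    array(a, dim = dim(a))
  })
  mp <- NULL
  if (!is.null(layout$motion_path))
    mp <- as.matrix(read.table(layout$motion_path, header = TRUE, sep = "\t"))
  masks <- lapply(layout$mask_paths, read_mask)
  list(series = multi_echo_series(data, layout$echo_times, layout$tr),
       motion_params = mp, masks = masks)
}

confound_colnames <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y",
                       "rot_z", "framewise_displacement", "dvars", "csf",
                       "white_matter")

#' Assemble the per-volume confound table
#'
#' Columns in fixed order: the six realignment parameters, framewise
#' displacement, DVARS, and mean CSF / white-matter signals. The first FD
#' and DVARS entries are 0 (the backward difference is undefined there).
#'
#' @param motion_params T x 6 matrix (rot then trans columns, as stored).
#' @param dvars_confound Length-T DVARS vector with leading 0.
#' @param csf,white_matter Length-T mean tissue signals.
#' @return Tibble with `r confound_colnames` columns.
#' @export
confound_table <- function(motion_params, dvars_confound, csf, white_matter) {
  mp <- as.matrix(motion_params)
  fd <- framewise_displacement(mp)
  tibble::tibble(
    trans_x = mp[, "trans_x"], trans_y = mp[, "trans_y"], trans_z = mp[, "trans_z"],
    rot_x = mp[, "rot_x"], rot_y = mp[, "rot_y"], rot_z = mp[, "rot_z"],
    framewise_displacement = fd, dvars = dvars_confound,
    csf = csf, white_matter = white_matter
  )
}

#' Write a denoised series and its confounds
#'
#' Writes `desc-<variant>_bold.nii.gz` plus a `desc-<variant>_confounds.tsv`
#' next to it.
#'
#' @param data 4D array to write.
#' @param confounds A [confound_table()] tibble.
#' @param out_dir Output directory.
#' @param subject,task BIDS entities.
#' @param variant One of "optcom", "pOptcom", "MEICA", "pMEICA".
#' @param tr Repetition time, seconds.
#' @return Named character vector with `bold` and `confounds` paths.
#' @export
write_outputs <- function(data, confounds, out_dir, variant,
                          subject = "sub-01", task = "rest", tr = NULL) {
  variant <- match.arg(variant, c("optcom", "pOptcom", "MEICA", "pMEICA"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(out_dir, sprintf("%s_task-%s_desc-%s", subject, task, variant))
  bold <- paste0(stem, "_bold.nii.gz")
  write_volume(data, bold, tr = tr)
  conf <- paste0(stem, "_confounds.tsv")
  write.table(as.data.frame(confounds), conf, sep = "\t", quote = FALSE,
              row.names = FALSE)
  c(bold = bold, confounds = conf)
}
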