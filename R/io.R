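# NIfTI, config and provenance I/O. All volumes travel as plain R arrays;
# RNifti handles the on-disk format.

#' Write a volume to NIfTI
#'
#' @param vol numeric or logical 3D/4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxel_size_mm voxel dimensions in mm.
#' @param description short free-text tag stored in the header.
#' @return the path, invisibly.
#' @export
write_nifti_volume <- function(vol, path, voxel_size_mm = c(1, 1, 1),
                               description = NULL) {
  if (is.logical(vol)) vol <- array(as.numeric(vol), dim = dim(vol))
  img <- RNifti::asNifti(vol)
  nd <- length(dim(vol))
  RNifti::pixdim(img) <- c(voxel_size_mm, rep(1, nd - 3))
  if (!is.null(description))
    img <- RNifti::asNifti(img, list(descrip = substr(description, 1, 79)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI volume as a plain array
#'
#' @param path NIfTI file path.
#' @return numeric array with attribute `voxel_size_mm`.
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  out <- array(as.numeric(img), dim = dim(img))
  attr(out, "voxel_size_mm") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  out
}

#' Write a simulated acquisition to disk
#'
#' One 4D magnitude and one 4D phase NIfTI per coil per repeat (echo as the
#' 4th dimension), the configuration as YAML, and ground-truth maps when
#' supplied.
#'
#' @param data a [multi_coil_echo_data()].
#' @param dir output directory (created if needed).
#' @param spec optional [phantom_spec()] written into the config.
#' @param truth optional [build_phantom()] result; maps are written under
#'   `ground_truth/`.
#' @return `dir`, invisibly.
#' @export
write_simulated_dataset <- function(data, dir, spec = NULL, truth = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vox <- data$params$voxel_size_mm
  for (r in seq_len(data$n_repeats)) {
    for (c_i in seq_len(data$n_coils)) {
      vol <- data$data[, , , , c_i, r, drop = TRUE]
      dim(vol) <- c(data$grid_shape, data$n_echoes)
      base <- sprintf("coil%02d_rep%d", c_i, r)
      write_nifti_volume(Mod(vol), file.path(dir, paste0(base, "_mag.nii.gz")), vox)
      write_nifti_volume(Arg(vol), file.path(dir, paste0(base, "_phase.nii.gz")), vox)
    }
  }
  cfg <- list(acquisition = unclass(data$params))
  if (!is.null(spec)) cfg$phantom <- unclass(spec)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  if (!is.null(truth)) {
    gt <- file.path(dir, "ground_truth")
    dir.create(gt, showWarnings = FALSE)
    write_nifti_volume(truth$chi_ppb, file.path(gt, "chi_ppb.nii.gz"), vox)
    write_nifti_volume(truth$r2s_per_s, file.path(gt, "r2star_s-1.nii.gz"), vox)
    write_nifti_volume(truth$m0, file.path(gt, "m0.nii.gz"), vox)
    write_nifti_volume(truth$labels, file.path(gt, "labels.nii.gz"), vox)
    write_nifti_volume(truth$brain_mask, file.path(gt, "brain_mask.nii.gz"), vox)
  }
  invisible(dir)
}

#' Read a simulated acquisition from disk
#'
#' Inverse of [write_simulated_dataset()].
#'
#' @param dir dataset directory.
#' @return a [multi_coil_echo_data()].
#' @export
read_simulated_dataset <- function(dir) {
  cfg <- yaml::read_yaml(file.path(dir, "config.yaml"))
  params <- do.call(acquisition_params, cfg$acquisition)
  mags <- sort(list.files(dir, pattern = "^coil[0-9]+_rep[0-9]+_mag\\.nii(\\.gz)?$"))
  if (length(mags) == 0) stop("no coil volumes found in ", dir)
  ids <- regmatches(mags, regexec("coil([0-9]+)_rep([0-9]+)", mags))
  coils <- vapply(ids, function(x) as.integer(x[2]), 1L)
  reps <- vapply(ids, function(x) as.integer(x[3]), 1L)
  n_coils <- max(coils)
  n_reps <- max(reps)
  first <- read_nifti_volume(file.path(dir, mags[1]))
  shape <- dim(first)[1:3]
  ne <- dim(first)[4]
  data <- array(0i, dim = c(shape, ne, n_coils, n_reps))
  for (i in seq_along(mags)) {
    mag <- read_nifti_volume(file.path(dir, mags[i]))
    ph <- read_nifti_volume(file.path(dir, sub("_mag", "_phase", mags[i])))
    data[, , , , coils[i], reps[i]] <- mag * exp(1i * ph)
  }
  multi_coil_echo_data(data, params)
}

# JSON provenance sidecar written next to each pipeline artifact set.
write_provenance <- function(path, stage, params, seed = NULL) {
  payload <- list(
    stage = stage,
    package = "pmqsm",
    version = as.character(utils::packageVersion("pmqsm")),
    seed = seed,
    parameters = params,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
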