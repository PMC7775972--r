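#' Default pipeline configuration
#'
#' Returns the full configuration list understood by [run_pipeline()], with
#' every stage's tunable parameters at its documented default. Supplied
#' values override defaults by name.
#'
#' @param ... named overrides, e.g. `inversion = list(method = "tkd")`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    output_dir = NULL,
    seed = 1L,
    acquisition = list(),
    simulate = NULL,          # phantom_spec arguments, or NULL
    input_dir = NULL,         # alternatively, a write_simulated_dataset dir
    truncate_slice_factor = NULL,
    combine = list(weighting = "weighted"),
    mask = list(threshold_frac = 0.1),
    phi0 = list(threshold_rad = 1.0),
    fit = list(max_iter = 50, tol = 1e-10),
    vsharp = list(max_kernel_mm = 12, reg_param = 0.02),
    inversion = list(method = "star", threshold = 0.2,
                     strong_percentile = 99.5,
                     strong_pass_threshold = 0.05,
                     residual_threshold = 0.3),
    r2star = list(assess_drift = TRUE, r2s_floor_per_s = 1),
    rois = NULL,              # named list of logical volumes or NIfTI paths
    keep_intermediates = TRUE
  )
  over <- list(...)
  for (nm in names(over)) {
    if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  structure(cfg, class = c("pipeline_config", "list"))
}

stage_log <- function(...) message("[pmqsm] ", ...)

#' Run the full QSM + R2* processing pipeline
#'
#' Orchestrates all stages from raw multi-coil echoes (simulated in-memory
#' or read from disk) to referenced susceptibility maps, R2* maps, drift
#' diagnostics and ROI statistics:
#' optional k-space slice truncation; per repeat: echo alignment, coil
#' combination, mask generation, readout phase-gradient removal, two-echo
#' initialization, nonlinear field fit, phi0 mask refinement; then repeat
#' alignment, field averaging, v-SHARP background removal, dipole inversion
#' and whole-brain referencing; in parallel, repeat-averaged magnitudes feed
#' the R2* fit and the per-repeat T2* drift report; finally ROI summaries.
#' Each stage writes intermediates plus a JSON provenance sidecar when an
#' output directory is configured.
#'
#' @param config a [pipeline_config()] (or plain list with the same fields).
#' @return invisibly, a list with `chi` (referenced `susceptibility_map`),
#'   `r2star` (`r2star_fit_result`), `field` (averaged `field_map_result`
#'   with drift diagnostic), `t2star_drift` (`drift_report` or NULL),
#'   `repeat_shifts`, `echo_shifts`, `roi_stats` (data frame or NULL),
#'   `mask` (refined `brain_mask`), `output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else do.call(pipeline_config, config)
  params <- do.call(acquisition_params, cfg$acquisition)
  out_dir <- cfg$output_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  save_vol <- function(vol, name, desc = NULL) {
    if (!is.null(out_dir) && isTRUE(cfg$keep_intermediates))
      write_nifti_volume(vol, file.path(out_dir, name), params$voxel_size_mm, desc)
  }

  # --- input -----------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    stage_log("simulating acquisition")
    spec <- do.call(phantom_spec, modifyList(cfg$simulate,
                                             list(seed = cfg$seed)))
    truth <- build_phantom(spec, params)
    data <- simulate_acquisition(truth, spec, params, seed = cfg$seed)
  } else if (!is.null(cfg$input_dir)) {
    stage_log("reading dataset from ", cfg$input_dir)
    data <- read_simulated_dataset(cfg$input_dir)
    params <- data$params
    truth <- NULL
  } else stop("config must provide either `simulate` or `input_dir`")

  if (!is.null(cfg$truncate_slice_factor) && cfg$truncate_slice_factor > 1) {
    stage_log("truncating k-space along the slice axis (factor ",
              cfg$truncate_slice_factor, ")")
    data <- truncate_kspace_slice(data, cfg$truncate_slice_factor)
    params <- data$params
  }

  # --- per-repeat pre-processing and field fitting ---------------------
  n_rep <- data$n_repeats
  series_list <- vector("list", n_rep)
  echo_shifts <- matrix(0, n_rep, data$n_echoes)
  for (r in seq_len(n_rep)) {
    stage_log("repeat ", r, ": echo alignment + coil combination")
    al <- align_echoes_first_to_rest(data, r)
    echo_shifts[r, ] <- al$shifts_voxels
    series_list[[r]] <- combine_coils(data, r, echo_shifts = al$shifts_voxels,
                                      weighting = cfg$combine$weighting)
  }

  stage_log("aligning repeats to echo 2 of repeat 1")
  ar <- align_repeats(series_list)
  series_list <- ar$aligned

  fields <- vector("list", n_rep)
  refined <- NULL
  for (r in seq_len(n_rep)) {
    stage_log("repeat ", r, ": mask, readout gradient removal, field fit")
    s <- series_list[[r]]
    mask0 <- generate_mask(s$magnitude[, , , 1], cfg$mask$threshold_frac)
    s <- remove_readout_phase_gradient(s, mask0, params)
    series_list[[r]] <- s
    init <- initialize_field_fit(s, mask0)
    fit <- fit_field_nonlinear(s, mask0, init,
                               max_iter = cfg$fit$max_iter, tol = cfg$fit$tol)
    refined_r <- refine_mask_phi0(fit, cfg$phi0$threshold_rad)
    fit$mask <- refined_r$mask
    fields[[r]] <- fit
    if (r == 1) refined <- refined_r
  }

  stage_log("averaging per-repeat field maps")
  field_avg <- average_repeat_fields(fields)
  save_vol(field_avg$delta_f_hz, "delta_f_hz.nii.gz", "mean frequency offset")
  if (!is.null(out_dir)) {
    write.csv(field_avg$drift, file.path(out_dir, "drift_diagnostics.csv"),
              row.names = FALSE)
    shifts_df <- data.frame(repeat_index = seq_len(n_rep),
                            dx = ar$shifts[, 1], dy = ar$shifts[, 2],
                            dz = ar$shifts[, 3])
    write.csv(shifts_df, file.path(out_dir, "repeat_shifts_voxels.csv"),
              row.names = FALSE)
  }

  # --- QSM branch ------------------------------------------------------
  stage_log("v-SHARP background removal")
  vs <- vsharp_background_removal(field_avg, field_avg$mask,
                                  max_kernel_mm = cfg$vsharp$max_kernel_mm,
                                  reg_param = cfg$vsharp$reg_param,
                                  voxel_size_mm = params$voxel_size_mm)
  save_vol(vs$local_field_hz, "local_field_hz.nii.gz", "v-SHARP local field")

  stage_log("dipole inversion (", cfg$inversion$method, ")")
  kern <- make_dipole_kernel(dim(vs$local_field_hz), params$voxel_size_mm,
                             params$b0_direction)
  chi <- if (identical(cfg$inversion$method, "tkd")) {
    tkd_inversion(vs$local_field_hz, kern, params,
                  threshold = cfg$inversion$threshold, mask = vs$eroded_mask)
  } else {
    streak_reduced_inversion(
      vs$local_field_hz, kern, params,
      threshold = cfg$inversion$threshold,
      strong_percentile = cfg$inversion$strong_percentile,
      strong_pass_threshold = cfg$inversion$strong_pass_threshold,
      residual_threshold = cfg$inversion$residual_threshold,
      mask = vs$eroded_mask)
  }
  chi <- reference_susceptibility(chi, vs$eroded_mask)
  save_vol(chi$chi_ppb, "chi_ppb.nii.gz",
           paste0("chi [ppb], ", chi$method, ", whole-brain-mean-zero"))

  # --- R2* branch ------------------------------------------------------
  stage_log("R2* fitting on repeat-averaged magnitudes")
  mag_avg <- series_list[[1]]$magnitude
  if (n_rep > 1) {
    for (r in 2:n_rep) mag_avg <- mag_avg + series_list[[r]]$magnitude
    mag_avg <- mag_avg / n_rep
  }
  r2fit <- fit_r2star(mag_avg, params, refined)
  save_vol(r2fit$r2star_per_s, "r2star_s-1.nii.gz", "R2* [1/s]")
  save_vol(r2fit$m0, "m0.nii.gz", "M0")
  save_vol(r2fit$noise_floor, "noise_floor.nii.gz", "noise floor")

  t2drift <- NULL
  if (isTRUE(cfg$r2star$assess_drift) && n_rep >= 2) {
    stage_log("assessing inter-repeat T2* drift")
    mags_per_rep <- lapply(series_list, `[[`, "magnitude")
    t2drift <- assess_t2star_drift(mags_per_rep, params, refined,
                                   r2s_floor_per_s = cfg$r2star$r2s_floor_per_s)
    if (!is.null(out_dir))
      write.csv(as.data.frame(t2drift),
                file.path(out_dir, "t2star_drift.csv"), row.names = FALSE)
  }

  # --- ROI statistics --------------------------------------------------
  roi_stats <- NULL
  if (!is.null(cfg$rois)) {
    stage_log("ROI summaries")
    rows <- list()
    for (nm in names(cfg$rois)) {
      roi <- cfg$rois[[nm]]
      if (is.character(roi)) roi <- read_nifti_volume(roi) > 0.5
      sc <- roi_summary(chi$chi_ppb, roi)
      sr <- roi_summary(r2fit$r2star_per_s, roi)
      rows[[nm]] <- data.frame(roi = nm, mean_chi_ppb = sc$mean,
                               mean_r2star_per_s = sr$mean,
                               n_voxels = sc$n_voxels,
                               n_outliers_chi = sc$n_outliers,
                               n_outliers_r2star = sr$n_outliers)
    }
    roi_stats <- do.call(rbind, rows)
    if (!is.null(out_dir))
      write.csv(roi_stats, file.path(out_dir, "roi_stats.csv"),
                row.names = FALSE)
  }

  if (!is.null(out_dir))
    write_provenance(file.path(out_dir, "provenance.json"), "run_pipeline",
                     unclass(cfg)[setdiff(names(cfg), "rois")],
                     seed = cfg$seed)
  stage_log("done")
  invisible(list(chi = chi, r2star = r2fit, field = field_avg,
                 t2star_drift = t2drift, repeat_shifts = ar$shifts,
                 echo_shifts = echo_shifts, roi_stats = roi_stats,
                 mask = refined, truth = if (exists("truth")) truth else NULL,
                 output_dir = out_dir))
}
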