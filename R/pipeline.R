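# Whole-study orchestration: a validated configuration object, a
# per-session driver running pre-processing -> registration -> modality
# pipelines -> matrices, and a JSON run manifest with checksums so
# deterministic stages can be verified to reproduce bit-identically.

default_config <- function() {
  list(
    output_dir = "murimap-out",
    seed = 1L,
    session = "session1",
    inputs = list(
      t2 = NULL, t2_orientation = "RAS",
      template = NULL, labels = NULL, ontology = NULL,
      dwi = NULL, bval = NULL, bvec = NULL, dwi_orientation = "RAS",
      bold = NULL, bold_orientation = "RAS",
      physio = NULL, physio_triggers = NULL, physio_rate_hz = NULL
    ),
    stages = list(
      bias_correction = TRUE,
      registration = TRUE,
      dti = TRUE,
      fmri = TRUE
    ),
    parameters = list(
      n_classes = 3L, mask_radius_mm = 5,
      affine_dof = 6L, levels = 3L, grid_spacing_mm = 2.5,
      jacobian_penalty = 0.3, nonlinear_max_iter = 50L,
      collapse_sigma_mm = 0.45,
      step_mm = 0.5, angle_deg = 55, min_len_mm = 0.5, max_len_mm = 12,
      fiber_cap = 1e6, fa_stop = 0.2,
      fwhm_mm = 3.0, highpass_hz = 0.01,
      slice_timing = FALSE, slice_order = NULL,
      regress_respiration = FALSE
    )
  )
}

check_known_keys <- function(user, ref, path = "") {
  for (k in names(user)) {
    if (!k %in% names(ref)) {
      stop("unknown config key: ", paste0(path, k))
    }
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(user[[k]])) {
      check_known_keys(user[[k]], ref[[k]], paste0(path, k, "$"))
    }
  }
}

#' Build a pipeline configuration
#'
#' Merges user settings over the documented defaults; unknown keys are
#' rejected. A configuration can also be loaded from a YAML file with
#' [read_pipeline_config()].
#'
#' @param ... named top-level entries (`output_dir`, `seed`, `session`,
#'   `inputs`, `stages`, `parameters`); nested lists are merged key-wise.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  user <- list(...)
  ref <- default_config()
  check_known_keys(user, ref)
  cfg <- modifyList(ref, user)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

as_input_volume <- function(x, orientation, modality) {
  if (is.null(x)) return(NULL)
  v <- if (is.character(x)) read_nifti_volume(x, modality = modality) else x
  stopifnot(inherits(v, "mri_volume"))
  if (orientation != "RAS") v <- reorient_to_ras(v, orientation) else v
}

#' Run the full processing pipeline for one session
#'
#' Executes, as configured: re-orientation, bias-field correction and
#' brain masking of the anatomical scan; template-to-anatomy registration
#' (affine + non-linear, estimated once per session); affine-only
#' transfer to the diffusion and BOLD spaces reusing the session's
#' non-linear field; the diffusion pipeline (slice-wise motion
#' correction, tensor fit, FA/MD/RD/AD maps, deterministic tractography,
#' structural connectivity); and the BOLD pipeline (motion correction,
#' optional slice timing, in-plane smoothing, temporal high-pass,
#' regional extraction, respiration regressor, functional connectivity).
#' Every artifact is written under `output_dir` and recorded, with its
#' MD5 checksum and the full parameter set, in `manifest.json`;
#' re-running with unchanged inputs reproduces the checksums of all
#' deterministic stages.
#'
#' @param config a [pipeline_config()]. Volumes may be given as NIfTI
#'   paths or in-memory [mri_volume()] objects.
#' @return The run manifest (list), invisibly the same as written to
#'   `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  cfg <- config
  p <- cfg$parameters
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$output_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  t_start <- Sys.time()
  logmsg <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), "  ", ...)
    writeLines(msg, log_con)
  }
  artifacts <- list()
  add_artifact <- function(tag, path) {
    artifacts[[tag]] <<- list(path = path,
                              md5 = unname(tools::md5sum(path)))
  }
  want_dti <- cfg$stages$dti && !is.null(cfg$inputs$dwi)
  want_fmri <- cfg$stages$fmri && !is.null(cfg$inputs$bold)
  want_reg <- cfg$stages$registration
  if (want_reg && (want_dti || want_fmri) && is.null(cfg$inputs$t2)) {
    stop("an anatomical reference (T2) acquired in the same session is ",
         "required to register DTI/fMRI data; supply inputs$t2 or disable ",
         "the registration stage")
  }
  logmsg("pipeline start, session '", cfg$session, "'")

  t2 <- as_input_volume(cfg$inputs$t2, cfg$inputs$t2_orientation, "t2")
  template <- as_input_volume(cfg$inputs$template, "RAS", "t2")
  labels <- cfg$inputs$labels
  if (is.character(labels)) labels <- read_nifti_volume(labels, "label")
  if (!is.null(labels)) labels <- label_volume(labels)

  brain_mask <- NULL
  chain_t2 <- NULL
  t2_affine <- NULL
  t2_nl <- NULL
  if (!is.null(t2)) {
    if (cfg$stages$bias_correction) {
      pre_mask <- estimate_brain_mask(t2, p$mask_radius_mm)
      model <- mico_fit(t2, pre_mask, n_classes = p$n_classes)
      t2 <- mico_correct(t2, model)
      bias_path <- file.path(cfg$output_dir, "t2_bias.nii.gz")
      write_nifti_volume(model$bias, bias_path)
      add_artifact("t2_bias", bias_path)
      logmsg("bias correction done (", length(model$energy), " iterations)")
    }
    brain_mask <- estimate_brain_mask(t2, p$mask_radius_mm)
    t2_masked <- apply_mask(t2, brain_mask)
    t2_path <- file.path(cfg$output_dir, "t2_preprocessed.nii.gz")
    write_nifti_volume(t2_masked, t2_path)
    add_artifact("t2_preprocessed", t2_path)
    if (want_reg && !is.null(template)) {
      t2_affine <- register_affine(t2_masked, template, dof = p$affine_dof,
                                   levels = p$levels, session = cfg$session)
      pre <- apply_chain(t2_affine, template, t2_masked)
      t2_nl <- register_nonlinear(t2_masked, pre,
                                  grid_spacing = p$grid_spacing_mm,
                                  penalty = p$jacobian_penalty,
                                  max_iter = p$nonlinear_max_iter,
                                  session = cfg$session)
      chain_t2 <- build_session_chain(
        t2_affine, t2_nl,
        affine_transform(session = cfg$session))
      chain_path <- file.path(cfg$output_dir, "chain_t2.json")
      save_transform(chain_t2, chain_path)
      add_artifact("chain_t2", chain_path)
      logmsg("T2 registration done (metric ",
             signif(attr(t2_affine, "metric_final"), 4), ")")
    }
  }

  labels_for <- function(target_vol, modality_affine) {
    if (is.null(labels)) return(NULL)
    if (want_reg && !is.null(chain_t2)) {
      chain <- build_session_chain(t2_affine, t2_nl, modality_affine)
      apply_chain(chain, labels, target_vol)
    } else {
      labels   # assumed already in the modality space
    }
  }

  if (want_dti) {
    dwi <- as_input_volume(cfg$inputs$dwi, cfg$inputs$dwi_orientation, "dwi")
    scheme <- if (inherits(cfg$inputs$bval, "gradient_scheme")) cfg$inputs$bval
      else read_gradient_scheme(cfg$inputs$bval, cfg$inputs$bvec)
    mc <- motion_correct_slicewise(dwi)
    dwi <- mc$corrected
    collapsed <- collapse_4d(dwi, p$collapse_sigma_mm)
    mod_affine <- affine_transform(session = cfg$session)
    if (want_reg && !is.null(t2)) {
      mod_affine <- register_affine(collapsed, t2, dof = p$affine_dof,
                                    levels = max(p$levels - 1L, 1L),
                                    session = cfg$session)
    }
    dwi_mask <- estimate_brain_mask(collapsed, p$mask_radius_mm)
    tf <- fit_tensor(dwi, scheme, dwi_mask)
    maps <- scalar_maps(tf)
    for (nm in names(maps)) {
      path <- file.path(cfg$output_dir, paste0("dti_", nm, ".nii.gz"))
      write_nifti_volume(maps[[nm]], path)
      add_artifact(paste0("dti_", nm), path)
    }
    fibers <- track_deterministic(tf, dwi_mask, step_mm = p$step_mm,
                                  angle_deg = p$angle_deg,
                                  min_len_mm = p$min_len_mm,
                                  max_len_mm = p$max_len_mm,
                                  fiber_cap = p$fiber_cap,
                                  fa_stop = p$fa_stop, seed = cfg$seed)
    trk_path <- file.path(cfg$output_dir, "fibers.trk")
    write_trk(fibers, trk_path)
    add_artifact("fibers_trk", trk_path)
    lab_dwi <- labels_for(collapsed, mod_affine)
    if (!is.null(lab_dwi)) {
      sc <- structural_connectivity(fibers, lab_dwi)
      sc_path <- file.path(cfg$output_dir, "structural_connectivity.csv")
      write_connectivity_csv(sc, sc_path)
      add_artifact("structural_connectivity", sc_path)
    }
    logmsg("DTI done: ", length(fibers$n_points), " fibers")
  }

  if (want_fmri) {
    bold <- as_input_volume(cfg$inputs$bold, cfg$inputs$bold_orientation, "bold")
    mc <- motion_correct_slicewise(bold)
    bold <- mc$corrected
    if (isTRUE(p$slice_timing)) {
      ord <- p$slice_order
      if (is.null(ord)) ord <- seq_len(dim(bold$data)[3])
      bold <- slice_timing_correct(bold, ord)
    }
    bold <- smooth_inplane(bold, p$fwhm_mm)
    bold <- highpass_temporal(bold, p$highpass_hz)
    collapsed_b <- collapse_4d(bold, p$collapse_sigma_mm)
    mod_affine <- affine_transform(session = cfg$session)
    if (want_reg && !is.null(t2)) {
      mod_affine <- register_affine(collapsed_b, t2, dof = p$affine_dof,
                                    levels = max(p$levels - 1L, 1L),
                                    session = cfg$session)
    }
    lab_bold <- labels_for(collapsed_b, mod_affine)
    if (!is.null(lab_bold)) {
      ts <- extract_regional_timeseries(bold, lab_bold)
      nuis <- NULL
      if (!is.null(cfg$inputs$physio)) {
        tr <- cfg$inputs$physio
        if (!inherits(tr, "physio_trace")) {
          tr <- read_physio_trace(tr, cfg$inputs$physio_triggers,
                                  cfg$inputs$physio_rate_hz)
        }
        reg <- respiration_regressor(tr, ncol(ts$series))
        reg_path <- file.path(cfg$output_dir, "respiration_regressor.tsv")
        utils::write.table(data.frame(volume = seq_along(reg), rate_hz = reg),
                           reg_path, sep = "\t", row.names = FALSE, quote = FALSE)
        add_artifact("respiration_regressor", reg_path)
        if (isTRUE(p$regress_respiration)) nuis <- as.numeric(reg)
      }
      ts_path <- file.path(cfg$output_dir, "regional_timeseries.tsv")
      write_regional_tsv(ts, ts_path)
      add_artifact("regional_timeseries", ts_path)
      fc <- functional_connectivity(ts, nuisance = nuis)
      fc_path <- file.path(cfg$output_dir, "functional_connectivity.csv")
      write_connectivity_csv(fc, fc_path)
      add_artifact("functional_connectivity", fc_path)
    }
    logmsg("fMRI done")
  }

  manifest <- list(
    session = cfg$session,
    seed = cfg$seed,
    parameters = p,
    stages = cfg$stages,
    artifacts = artifacts,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs"))
  )
  man_path <- file.path(cfg$output_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  logmsg("pipeline finished")
  invisible(manifest)
}
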