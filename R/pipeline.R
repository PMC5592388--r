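#' Pipeline configuration
#'
#' Bundles every stage's parameters with the input/output paths. All
#' defaults follow the published workflow where it states a value: Frangi
#' `beta = 0.5`, `c = 20` for both channels, vein probability threshold
#' 0.60, artery threshold 0.75, in-plane dilation 2 voxels, 16 mm sliding
#' mIP.
#'
#' @param swi,mra,brain_mask,transform input file paths (NIfTI volumes; the
#'   transform is a 4x4 text matrix). `brain_mask` and `transform` may be
#'   `NULL`: the brain mask then falls back to [fallback_brain_mask] and
#'   the transform is estimated by [estimate_rigid].
#' @param out_dir output directory.
#' @param m1_slice 1-based SWI slice index of the M1 plane.
#' @param frangi_swi,frangi_mra [frangi_params] for the dark (SWI) and
#'   bright (MRA) channels.
#' @param masking a [masking_params].
#' @param projection a [projection_params].
#' @param registration a [registration_config].
#' @param ignore_qc proceed even if registration QC fails.
#' @param seed integer seed echoed into reports (the pipeline itself is
#'   deterministic; the seed governs phantom generation).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(swi = NULL, mra = NULL, brain_mask = NULL,
                            transform = NULL, out_dir = ".", m1_slice = 8L,
                            frangi_swi = frangi_params(polarity = "dark"),
                            frangi_mra = frangi_params(polarity = "bright"),
                            masking = masking_params(),
                            projection = projection_params(),
                            registration = registration_config(),
                            ignore_qc = FALSE, seed = 1L) {
  structure(list(swi = swi, mra = mra, brain_mask = brain_mask,
                 transform = transform, out_dir = out_dir,
                 m1_slice = as.integer(m1_slice), frangi_swi = frangi_swi,
                 frangi_mra = frangi_mra, masking = masking,
                 projection = projection, registration = registration,
                 ignore_qc = isTRUE(ignore_qc), seed = as.integer(seed)),
            class = "pipeline_config")
}

config_to_list <- function(config) {
  lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
}

#' Write / read a pipeline configuration as YAML
#' @param config a [pipeline_config].
#' @param path file path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  fr <- function(x, pol) {
    if (is.null(x)) return(frangi_params(polarity = pol))
    frangi_params(beta = x$beta, c = x$c, scales = unlist(x$scales),
                  polarity = x$polarity %||% pol)
  }
  pipeline_config(
    swi = raw$swi, mra = raw$mra, brain_mask = raw$brain_mask,
    transform = raw$transform, out_dir = raw$out_dir %||% ".",
    m1_slice = raw$m1_slice %||% 8L,
    frangi_swi = fr(raw$frangi_swi, "dark"),
    frangi_mra = fr(raw$frangi_mra, "bright"),
    masking = if (is.null(raw$masking)) masking_params() else
      masking_params(raw$masking$artery_threshold,
                     raw$masking$dilation_radius,
                     raw$masking$vein_threshold),
    projection = if (is.null(raw$projection)) projection_params() else
      projection_params(raw$projection$thickness, raw$projection$axis,
                        raw$projection$fill_quantile),
    registration = if (is.null(raw$registration)) registration_config() else
      registration_config(raw$registration$bins, raw$registration$levels,
                          raw$registration$tol, raw$registration$max_iter),
    ignore_qc = isTRUE(raw$ignore_qc), seed = raw$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[swiven] ", fmt), ...))
}

#' Uncorrected NVVV from an SWI volume
#'
#' Sliding mIP, dark-polarity Frangi segmentation, NVVV above the M1
#' plane — arteries included, hence "uncorrected".
#'
#' @param swi the SWI [intensity_volume].
#' @param brain a [binary_mask]; `NULL` invokes [fallback_brain_mask].
#' @param m1_slice 1-based M1 slice index.
#' @param frangi dark-polarity [frangi_params].
#' @param projection a [projection_params].
#' @param vein_threshold strict vein probability threshold (default 0.60).
#' @param verbose log stage summaries via `message()`.
#' @return List with `mip`, `vein_mask`, `brain`, `unvvv`, voxel counts.
#' @export
nvvv_uncorrected <- function(swi, brain = NULL, m1_slice = 8L,
                             frangi = frangi_params(polarity = "dark"),
                             projection = projection_params(),
                             vein_threshold = 0.60, verbose = FALSE) {
  if (is.null(brain)) {
    brain <- fallback_brain_mask(swi)
    stage_log(verbose, "fallback brain mask: %d voxels", sum(brain$values))
  }
  mip <- sliding_mip(swi, projection, brain)
  veins <- segment_veins(mip, brain, frangi, vein_threshold)
  stage_log(verbose, "uncorrected vein mask: %d voxels", sum(veins$values))
  unvvv <- compute_nvvv(veins, brain, m1_slice)
  sl <- (m1_slice + 1L):swi$grid$shape[3]
  list(mip = mip, vein_mask = veins, brain = brain, unvvv = unvvv,
       vein_count = sum(veins$values[, , sl]),
       brain_count = sum(brain$values[, , sl]))
}

#' Full arterial-decontamination pipeline
#'
#' The complete workflow: rigid NMI registration of the MRA to the SWI
#' (skipped when a transform is supplied), dilated arterial mask on the
#' SWI grid, uncorrected and arterial-masked sliding mIPs, dark-vessel
#' segmentation of both, uNVVV / cNVVV above the M1 plane and the
#' contamination fraction.
#'
#' @param swi,mra [intensity_volume]s.
#' @param brain optional [binary_mask] on the SWI grid.
#' @param transform optional precomputed [rigid_transform] (MRA world to
#'   SWI world); `NULL` estimates it.
#' @param config a [pipeline_config] providing all stage parameters.
#' @param verbose log stage summaries.
#' @return List with the [nvvv_report] (`report`) and all intermediates:
#'   `mip`, `mip_corrected`, `artery_mask`, `vein_mask_uncorrected`,
#'   `vein_mask_corrected`, `brain`, `transform`, `qc`.
#' @export
swi_correct <- function(swi, mra, brain = NULL, transform = NULL,
                        config = pipeline_config(), verbose = FALSE) {
  stopifnot(inherits(swi, "intensity_volume"), inherits(mra, "intensity_volume"))
  if (is.null(brain)) {
    brain <- fallback_brain_mask(swi)
    stage_log(verbose, "fallback brain mask: %d voxels", sum(brain$values))
  }
  estimated <- is.null(transform)
  if (estimated) {
    transform <- estimate_rigid(mra, swi, config$registration)
    stage_log(verbose, "estimated transform: NMI %.4f",
              attr(transform, "nmi"))
  }
  qc <- registration_qc(mra, swi, transform, config$registration$bins)
  stage_log(verbose, "registration QC: NMI %.4f -> %.4f (%s)",
            qc$nmi_before, qc$nmi_after, if (qc$pass) "pass" else "FAIL")
  if (!qc$pass && !config$ignore_qc) {
    stop(sprintf(paste0("registration QC failed (NMI before %.4f, after ",
                        "%.4f); supply a transform or set ignore_qc"),
                 qc$nmi_before, qc$nmi_after))
  }
  artery <- build_arterial_mask(mra, swi$grid, transform, config$masking,
                                config$frangi_mra)
  stage_log(verbose, "arterial mask on SWI grid: %d voxels",
            sum(artery$values))

  unc <- nvvv_uncorrected(swi, brain, config$m1_slice, config$frangi_swi,
                          config$projection, config$masking$vein_threshold,
                          verbose = verbose)
  mip_c <- masked_sliding_mip(swi, artery, config$projection, brain)
  veins_c <- segment_veins(mip_c, brain, config$frangi_swi,
                           config$masking$vein_threshold)
  stage_log(verbose, "corrected vein mask: %d voxels", sum(veins_c$values))
  cnvvv <- compute_nvvv(veins_c, brain, config$m1_slice)
  sl <- (config$m1_slice + 1L):swi$grid$shape[3]

  report <- nvvv_report(
    unvvv = unc$unvvv, cnvvv = cnvvv,
    vein_count_uncorrected = unc$vein_count,
    vein_count_corrected = sum(veins_c$values[, , sl]),
    brain_count = unc$brain_count, m1_slice = config$m1_slice,
    params = list(
      frangi_swi = unclass(config$frangi_swi),
      frangi_mra = unclass(config$frangi_mra),
      masking = unclass(config$masking),
      projection = unclass(config$projection),
      registration = unclass(config$registration),
      transform_estimated = estimated,
      transform_matrix = rigid_matrix(transform),
      seed = config$seed),
    qc = qc[c("nmi_before", "nmi_after", "pass")])
  if (is.finite(cnvvv) && cnvvv > unc$unvvv) {
    warning(sprintf("cNVVV (%.5f) exceeds uNVVV (%.5f)", cnvvv, unc$unvvv))
  }
  list(report = report, mip = unc$mip, mip_corrected = mip_c,
       artery_mask = artery, vein_mask_uncorrected = unc$vein_mask,
       vein_mask_corrected = veins_c, brain = unc$brain,
       transform = transform, qc = qc)
}

load_pipeline_inputs <- function(config) {
  if (is.null(config$swi)) stop("config$swi (SWI NIfTI path) is required")
  swi <- read_volume(config$swi)
  brain <- if (!is.null(config$brain_mask)) read_mask(config$brain_mask)
  list(swi = swi, brain = brain)
}

#' Run the uncorrected analysis from a configuration (file in, files out)
#'
#' @param config a [pipeline_config] with `swi` (and optionally
#'   `brain_mask`) paths set.
#' @param verbose log stage summaries.
#' @return The output directory, invisibly; writes `mip.nii.gz`,
#'   `vein_mask_uncorrected.nii.gz`, `brain_mask_used.nii.gz`,
#'   `report.json` and `config_used.yaml` under `config$out_dir`.
#' @export
run_uncorrected <- function(config, verbose = TRUE) {
  inp <- load_pipeline_inputs(config)
  res <- nvvv_uncorrected(inp$swi, inp$brain, config$m1_slice,
                          config$frangi_swi, config$projection,
                          config$masking$vein_threshold, verbose = verbose)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_volume(res$mip, file.path(config$out_dir, "mip.nii.gz"))
  write_volume(res$vein_mask,
               file.path(config$out_dir, "vein_mask_uncorrected.nii.gz"))
  write_volume(res$brain, file.path(config$out_dir, "brain_mask_used.nii.gz"))
  report <- nvvv_report(unvvv = res$unvvv,
                        vein_count_uncorrected = res$vein_count,
                        brain_count = res$brain_count,
                        m1_slice = config$m1_slice,
                        params = list(frangi_swi = unclass(config$frangi_swi),
                                      projection = unclass(config$projection),
                                      vein_threshold =
                                        config$masking$vein_threshold,
                                      seed = config$seed))
  write_nvvv_report(report, file.path(config$out_dir, "report.json"))
  write_config(config, file.path(config$out_dir, "config_used.yaml"))
  invisible(config$out_dir)
}

#' Run the full corrected pipeline from a configuration (files in, files out)
#'
#' @param config a [pipeline_config] with `swi` and `mra` paths set
#'   (optionally `brain_mask` and `transform`).
#' @param verbose log stage summaries.
#' @return The output directory, invisibly; writes the corrected and
#'   uncorrected mIPs, arterial and vein masks, the transform actually
#'   used, `report.json` and `config_used.yaml`.
#' @export
run_corrected <- function(config, verbose = TRUE) {
  inp <- load_pipeline_inputs(config)
  if (is.null(config$mra)) stop("config$mra (TOF MRA NIfTI path) is required")
  mra <- read_volume(config$mra)
  transform <- if (!is.null(config$transform)) read_transform(config$transform)
  res <- swi_correct(inp$swi, mra, inp$brain, transform, config,
                     verbose = verbose)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_volume(res$mip, file.path(out, "mip_uncorrected.nii.gz"))
  write_volume(res$mip_corrected, file.path(out, "mip_corrected.nii.gz"))
  write_volume(res$artery_mask, file.path(out, "artery_mask.nii.gz"))
  write_volume(res$vein_mask_uncorrected,
               file.path(out, "vein_mask_uncorrected.nii.gz"))
  write_volume(res$vein_mask_corrected,
               file.path(out, "vein_mask_corrected.nii.gz"))
  write_volume(res$brain, file.path(out, "brain_mask_used.nii.gz"))
  write_transform(res$transform, file.path(out, "transform_used.txt"))
  write_nvvv_report(res$report, file.path(out, "report.json"))
  write_config(config, file.path(out, "config_used.yaml"))
  invisible(out)
}
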