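#' Pipeline configuration
#'
#' Assembles and validates the configuration driving [run_pipeline()].
#' Inputs may be given as file paths (`dynamic`, `timing`, `labels_path` +
#' `label_names`) or as in-memory objects (`image`, `labels`).
#'
#' @param dynamic,timing paths to the 4D NIfTI and its timing sidecar.
#' @param labels_path path to the integer-label NIfTI.
#' @param label_names named list/vector mapping region name to label value.
#' @param image,labels in-memory [dynamic_image()] / [label_volume()]
#'   alternatives to the paths above.
#' @param scan_id identifier used in the report.
#' @param target_regions regions to quantify (default: all non-reference
#'   named regions).
#' @param ref_region reference region (default `"cerebellum"`).
#' @param t_star Patlak equilibrium time, minutes (default 20).
#' @param suvr_window SUVr window, minutes (default `c(60, 75)`).
#' @param motion_correct run frame-to-frame realignment (default TRUE).
#' @param reference_frame `"auto"` (mid-time nearest 15 min) or an index.
#' @param spike_threshold mm (default 5), `max_fd_limit` mm (default 8),
#'   `fd_radius` mm (default 50): motion QC parameters.
#' @param max_fd_limit,fd_radius see above.
#' @param decay_correct apply decay correction if the input is not already
#'   corrected (default TRUE; a no-op on corrected input).
#' @param half_life isotope half-life, minutes (default 109.77, F-18).
#' @param voxelwise compute Ki/intercept parametric maps (default TRUE).
#' @param tv_weight TV denoising weight (`NULL` = robust default; `0`
#'   disables), `tv_max_iter`, `tv_tol`: see [tv_denoise()].
#' @param tv_max_iter,tv_tol see above.
#' @param out_dir if non-`NULL`, artifacts (static image, parametric maps,
#'   regional CSV, QC and report JSON) are written there.
#' @param seed integer recorded in provenance (the quantification itself is
#'   deterministic).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(dynamic = NULL, timing = NULL, labels_path = NULL,
                            label_names = NULL, image = NULL, labels = NULL,
                            scan_id = "scan", target_regions = NULL,
                            ref_region = "cerebellum", t_star = 20,
                            suvr_window = c(60, 75), motion_correct = TRUE,
                            reference_frame = "auto", spike_threshold = 5,
                            max_fd_limit = 8, fd_radius = 50,
                            decay_correct = TRUE, half_life = 109.77,
                            voxelwise = TRUE, tv_weight = NULL,
                            tv_max_iter = 200, tv_tol = 2e-4,
                            out_dir = NULL, seed = 1L) {
  if (is.null(image) && is.null(dynamic))
    stop("config needs either 'image' or a 'dynamic' path", call. = FALSE)
  if (is.null(labels) && is.null(labels_path))
    stop("config needs either 'labels' or a 'labels_path'", call. = FALSE)
  if (!is.null(labels_path) && is.null(label_names))
    stop("'label_names' is required with 'labels_path'", call. = FALSE)
  structure(list(dynamic = dynamic, timing = timing,
                 labels_path = labels_path, label_names = label_names,
                 image = image, labels = labels, scan_id = scan_id,
                 target_regions = target_regions, ref_region = ref_region,
                 t_star = t_star, suvr_window = suvr_window,
                 motion_correct = motion_correct,
                 reference_frame = reference_frame,
                 spike_threshold = spike_threshold,
                 max_fd_limit = max_fd_limit, fd_radius = fd_radius,
                 decay_correct = decay_correct, half_life = half_life,
                 voxelwise = voxelwise, tv_weight = tv_weight,
                 tv_max_iter = tv_max_iter, tv_tol = tv_tol,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Fingerprint of the analysis-relevant configuration: identical iff every
# parameter that can change the numbers is identical. Input paths identify
# the data; presentation fields (scan_id, out_dir) are excluded.
config_hash <- function(config) {
  relevant <- config[c("dynamic", "timing", "labels_path", "label_names",
                       "target_regions", "ref_region", "t_star",
                       "suvr_window", "motion_correct", "reference_frame",
                       "spike_threshold", "max_fd_limit", "fd_radius",
                       "decay_correct", "half_life", "voxelwise", "tv_weight",
                       "tv_max_iter", "tv_tol", "seed")]
  fnv1a32(jsonlite::toJSON(relevant, auto_unbox = TRUE, digits = NA,
                           null = "null"))
}

#' Run the full FDOPA quantification pipeline on one scan
#'
#' Stages, in order: load (+ decay correction if requested and needed),
#' frame-to-frame rigid realignment to the 15-min reference frame, motion QC
#' (framewise displacement, spike count at the 5 mm threshold, pass/fail at
#' the 8 mm max-displacement limit), static summation image, regional TAC
#' extraction, region-wise reference-Patlak Ki(cer) and SUVr, and optionally
#' TV-denoised voxelwise Ki parametric maps. A stage failure is captured in
#' the report's `status`/`errors` fields rather than thrown.
#'
#' @param config a [pipeline_config()] (or plain list of the same fields).
#' @return A `scan_report` list: `scan_id`, `status` (`"ok"`/`"error"`),
#'   `errors`, `qc`, `kinetics` (regional table + SUVr), `voxelwise` summary,
#'   and `provenance` (package version, config hash, seed, timestamp).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- do.call(pipeline_config, config)
  report <- list(schema_version = report_schema_version(),
                 scan_id = config$scan_id, status = "ok",
                 errors = character(0))
  report$provenance <- list(
    software = "fdopapet",
    version = as.character(utils::packageVersion("fdopapet")),
    config_hash = config_hash(config), seed = config$seed,
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))

  result <- tryCatch({
    img <- if (!is.null(config$image)) config$image
           else read_dynamic(config$dynamic, config$timing)
    labels <- if (!is.null(config$labels)) config$labels else {
      lab_arr <- as.array(RNifti::readNifti(config$labels_path))
      storage.mode(lab_arr) <- "integer"
      label_volume(lab_arr, unlist(config$label_names))
    }
    if (config$decay_correct && !img$decay_corrected)
      img <- decay_correct(img, config$half_life)

    transforms <- NULL
    realign_warnings <- character(0)
    if (config$motion_correct) {
      ra <- realign_frames(img, reference = config$reference_frame)
      img <- ra$image
      transforms <- ra$transforms
      realign_warnings <- ra$warnings
      fd <- framewise_displacement(ra$transforms, radius = config$fd_radius)
      qc <- detect_spikes(fd, threshold = config$spike_threshold)
      gate <- qc_motion(qc, max_fd_limit = config$max_fd_limit)
      report$qc <- list(reference_frame = ra$reference, fd = qc$fd,
                        total_motion_mm = qc$total_motion,
                        max_fd_mm = qc$max_fd, n_spikes = qc$n_spikes,
                        flagged = qc$flagged, pass = gate$pass,
                        reasons = gate$reasons,
                        low_signal_frames = ra$low_signal,
                        warnings = realign_warnings)
    }

    static <- sum_frames(img)

    regions <- config$target_regions
    if (is.null(regions))
      regions <- setdiff(names(labels$names), config$ref_region)
    ref_tac <- extract_tac(img, labels, config$ref_region)
    regional <- do.call(rbind, lapply(regions, function(rg) {
      tgt <- extract_tac(img, labels, rg)
      fit <- patlak_fit(patlak_transform(tgt, ref_tac),
                        t_star = config$t_star, region = rg)
      sv <- suvr(img, labels, rg, config$ref_region,
                 window = config$suvr_window)
      data.frame(region = rg, ki_per_min = fit$ki, intercept = fit$intercept,
                 r2 = fit$r_squared, suvr = sv$suvr)
    }))
    report$kinetics <- list(ref_region = config$ref_region,
                            t_star = config$t_star,
                            suvr_window = config$suvr_window,
                            regional = regional)

    pmap <- NULL
    if (config$voxelwise) {
      brain <- labels$labels > 0L
      tv_cfg <- if (!is.null(config$tv_weight) && config$tv_weight == 0) NULL
                else list(weight = config$tv_weight,
                          max_iter = config$tv_max_iter, tol = config$tv_tol)
      pmap <- patlak_voxelwise(img, ref_tac, brain, t_star = config$t_star,
                               tv = tv_cfg)
      report$voxelwise <- list(
        n_voxels = sum(brain),
        regional_mean_ki = stats::setNames(lapply(regions, function(rg) {
          v <- pmap$ki_map[labels$labels == labels$names[[rg]]]
          mean(v, na.rm = TRUE)
        }), regions))
    }

    if (!is.null(config$out_dir)) {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      write_volume(static, img$voxel_size,
                   file.path(config$out_dir, "static.nii.gz"))
      utils::write.csv(regional,
                       file.path(config$out_dir, "regional.csv"),
                       row.names = FALSE)
      if (!is.null(pmap)) {
        write_volume(pmap$ki_map, img$voxel_size,
                     file.path(config$out_dir, "ki.nii.gz"))
        write_volume(pmap$intercept_map, img$voxel_size,
                     file.path(config$out_dir, "intercept.nii.gz"))
      }
    }
    list(report = report, image = img, static = static, pmap = pmap,
         transforms = transforms)
  }, error = function(e) {
    report$status <- "error"
    report$errors <- conditionMessage(e)
    list(report = report)
  })

  report <- result$report
  class(report) <- "scan_report"
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(report, file.path(config$out_dir, "report.json"))
  }
  attr(report, "artifacts") <- result[setdiff(names(result), "report")]
  report
}

report_schema_version <- function() "1.0"

#' Serialize / restore a scan report
#'
#' Reports round-trip losslessly through JSON: `write_report()` then
#' `read_report()` reproduces the report (data-frame blocks included).
#'
#' @param report a `scan_report`.
#' @param path JSON path.
#' @export
write_report <- function(report, path) {
  r <- unclass(report)
  attr(r, "artifacts") <- NULL
  jsonlite::write_json(r, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(r$kinetics$regional))
    r$kinetics$regional <- as.data.frame(r$kinetics$regional)
  class(r) <- "scan_report"
  r
}

#' Validate a scan report against the packaged schema
#'
#' Checks the report against the JSON schema shipped in
#' `inst/extdata/report-schema.json` (required fields, types of the scalar
#' fields). Returns `TRUE` invisibly or throws with the list of violations.
#'
#' @param report a `scan_report` or path to a report JSON.
#' @export
validate_report <- function(report) {
  if (is.character(report)) report <- read_report(report)
  schema <- jsonlite::read_json(system.file("extdata", "report-schema.json",
                                            package = "fdopapet"),
                                simplifyVector = TRUE)
  problems <- character(0)
  for (f in schema$required)
    if (is.null(report[[f]])) problems <- c(problems, paste0("missing: ", f))
  for (f in schema$provenance_required)
    if (is.null(report$provenance[[f]]))
      problems <- c(problems, paste0("missing: provenance.", f))
  if (!is.null(report$schema_version) &&
      !identical(as.character(report$schema_version), schema$schema_version))
    problems <- c(problems, "schema_version mismatch")
  if (length(problems) > 0)
    stop("report does not validate: ", paste(problems, collapse = "; "),
         call. = FALSE)
  invisible(TRUE)
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("Scan report '%s' [%s]\n", x$scan_id, x$status))
  if (!is.null(x$qc))
    cat(sprintf("  QC: max FD %.2f mm, %d spike(s), %s\n", x$qc$max_fd_mm,
                x$qc$n_spikes, if (isTRUE(x$qc$pass)) "pass" else "FAIL"))
  if (!is.null(x$kinetics$regional)) {
    cat("  Kinetics:\n")
    print(x$kinetics$regional, row.names = FALSE)
  }
  invisible(x)
}

#' Generate a phantom scan on disk from a JSON spec
#'
#' Reads a phantom specification from JSON (fields mirroring
#' [phantom_spec()]: `dim`, `voxel_size`, `frame_durations_sec`,
#' `noise_sigma0`, `seed`, optional `motion` as per-frame 6-vectors and
#' `regions` with `center`/`semiaxes`/`K1`/`k2`/`k3`), builds the phantom
#' and writes the NIfTI + sidecar + labels + ground truth via
#' [write_phantom()]. A spec without a seed is refused.
#'
#' @param spec_path JSON path, or a [phantom_spec()] directly.
#' @param out_dir output directory.
#' @return Invisibly, the output directory.
#' @export
simulate_scan <- function(spec_path, out_dir) {
  spec <- if (inherits(spec_path, "phantom_spec")) spec_path
          else phantom_spec_from_json(spec_path)
  write_phantom(build_phantom(spec), out_dir)
}

phantom_spec_from_json <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(js$seed))
    stop("phantom spec must declare a seed", call. = FALSE)
  args <- list(seed = js$seed)
  if (!is.null(js$dim)) args$dim3 <- js$dim
  if (!is.null(js$voxel_size)) args$voxel_size <- js$voxel_size
  if (!is.null(js$frame_durations_sec))
    args$schedule <- frame_schedule_from_durations(js$frame_durations_sec)
  if (!is.null(js$noise_sigma0)) args$noise_sigma0 <- js$noise_sigma0
  if (!is.null(js$plasma_peak)) args$plasma_peak <- js$plasma_peak
  if (!is.null(js$plasma_scale)) args$plasma_scale <- js$plasma_scale
  if (!is.null(js$regions)) {
    args$regions <- lapply(js$regions, function(r)
      list(center = r$center, semiaxes = r$semiaxes,
           params = kinetic_parameters(r$K1, r$k2,
                                       if (is.null(r$k3)) 0 else r$k3)))
  }
  if (!is.null(js$motion)) {
    args$motion <- lapply(seq_len(nrow(js$motion)), function(i)
      rigid_transform(js$motion[i, 1:3], js$motion[i, 4:6]))
  }
  do.call(phantom_spec, args)
}
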