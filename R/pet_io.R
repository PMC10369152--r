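#' Dynamic PET image container
#'
#' Bundles a 4D activity array (x, y, z, frame; kBq/mL), the voxel geometry,
#' the [frame_schedule()] and a decay-correction flag. All temporal fields are
#' minutes from injection.
#'
#' @param data 4D numeric array, frame axis last.
#' @param voxel_size voxel edge lengths in mm (length-3).
#' @param schedule a [frame_schedule()] whose length matches the frame axis.
#' @param decay_corrected logical; whether activities are referenced to
#'   injection time.
#' @param units activity unit label (default `"kBq/mL"`).
#' @return A `dynamic_image` object.
#' @export
dynamic_image <- function(data, voxel_size, schedule, decay_corrected = FALSE,
                          units = "kBq/mL") {
  if (length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, frame)", call. = FALSE)
  if (!inherits(schedule, "frame_schedule"))
    stop("'schedule' must be a frame_schedule", call. = FALSE)
  if (dim(data)[4] != nrow(schedule))
    stop(sprintf("frame axis length (%d) does not match schedule (%d frames)",
                 dim(data)[4], nrow(schedule)), call. = FALSE)
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be three positive lengths in mm", call. = FALSE)
  if (!all(is.finite(data)))
    stop("activity values must be finite", call. = FALSE)
  structure(list(data = data, voxel_size = voxel_size, schedule = schedule,
                 decay_corrected = isTRUE(decay_corrected), units = units),
            class = "dynamic_image")
}

#' @export
print.dynamic_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "Dynamic PET image: %dx%dx%d voxels x %d frames, %.3gx%.3gx%.3g mm\n",
    d[1], d[2], d[3], d[4], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  cat(sprintf("  %.1f min scan, decay-corrected: %s, units: %s\n",
              scan_duration(x$schedule), x$decay_corrected, x$units))
  invisible(x)
}

#' Integer-label region volume
#'
#' @param labels 3D integer array; 0 is background.
#' @param names named integer vector mapping region name -> label value,
#'   e.g. `c(whole_striatum = 1, cerebellum = 2)`. Every named label must
#'   occur in the grid.
#' @return A `label_volume` object.
#' @export
label_volume <- function(labels, names) {
  if (length(dim(labels)) != 3L)
    stop("'labels' must be a 3D array", call. = FALSE)
  if (is.null(base::names(names)) || any(base::names(names) == ""))
    stop("'names' must be a fully named integer vector", call. = FALSE)
  present <- unique(as.vector(labels))
  missing <- setdiff(as.integer(names), present)
  if (length(missing) > 0)
    stop(sprintf("labels not present in grid: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (any(as.integer(names) == 0L))
    stop("label 0 is reserved for background", call. = FALSE)
  structure(list(labels = labels, names = vapply(names, as.integer, 0L)),
            class = "label_volume")
}

#' Read a 4D dynamic PET volume with its frame-timing sidecar
#'
#' Reads a NIfTI-1 image and a JSON sidecar with PET-BIDS style fields
#' `FrameTimesStart` and `FrameDuration` (both in seconds), returning a
#' [dynamic_image()] with the schedule converted to minutes.
#'
#' @param image_path path to a `.nii`/`.nii.gz` 4D volume.
#' @param timing_path path to the JSON sidecar; defaults to the image path
#'   with its extension replaced by `.json`.
#' @return A [dynamic_image()].
#' @export
read_dynamic <- function(image_path, timing_path = NULL) {
  if (is.null(timing_path))
    timing_path <- sub("\\.nii(\\.gz)?$", ".json", image_path)
  img <- RNifti::readNifti(image_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4L)
    stop("expected a 4D dynamic volume", call. = FALSE)
  side <- jsonlite::read_json(timing_path, simplifyVector = TRUE)
  if (is.null(side$FrameTimesStart) || is.null(side$FrameDuration))
    stop("timing sidecar must contain FrameTimesStart and FrameDuration",
         call. = FALSE)
  fts <- as.numeric(side$FrameTimesStart)
  fdur <- as.numeric(side$FrameDuration)
  if (length(fdur) == 1L) fdur <- rep(fdur, length(fts))
  if (length(fts) != length(fdur))
    stop("FrameTimesStart and FrameDuration lengths differ", call. = FALSE)
  if (length(fts) != dim(arr)[4])
    stop(sprintf("sidecar describes %d frames but image has %d",
                 length(fts), dim(arr)[4]), call. = FALSE)
  sch <- frame_schedule(start = fts / 60, duration = fdur / 60)
  vox <- RNifti::pixdim(img)[1:3]
  dec <- isTRUE(side$DecayCorrected) ||
    identical(side$ImageDecayCorrected, TRUE)
  dynamic_image(arr, vox, sch, decay_corrected = dec,
                units = if (!is.null(side$Units)) side$Units else "kBq/mL")
}

#' Write a dynamic image and its timing sidecar
#'
#' Inverse of [read_dynamic()]: writes the 4D NIfTI volume and a JSON sidecar
#' with `FrameTimesStart`/`FrameDuration` in seconds.
#'
#' @param img a [dynamic_image()].
#' @param image_path output `.nii`/`.nii.gz` path.
#' @param timing_path output JSON path (default: image path with `.json`).
#' @param extra named list merged into the sidecar (e.g. `TracerName`).
#' @return Invisibly, the image path.
#' @export
write_dynamic <- function(img, image_path, timing_path = NULL, extra = list()) {
  stopifnot(inherits(img, "dynamic_image"))
  if (is.null(timing_path))
    timing_path <- sub("\\.nii(\\.gz)?$", ".json", image_path)
  nim <- RNifti::asNifti(img$data)
  RNifti::pixdim(nim) <- c(img$voxel_size, 1)
  RNifti::writeNifti(nim, image_path)
  side <- c(list(FrameTimesStart = img$schedule$start * 60,
                 FrameDuration = img$schedule$duration * 60,
                 DecayCorrected = img$decay_corrected,
                 Units = img$units), extra)
  jsonlite::write_json(side, timing_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(image_path)
}

#' Write a 3D volume (labels, static or parametric image) as NIfTI
#' @param vol 3D array.
#' @param voxel_size mm triple.
#' @param path output path.
#' @export
write_volume <- function(vol, voxel_size, path) {
  nim <- RNifti::asNifti(vol)
  RNifti::pixdim(nim) <- voxel_size
  RNifti::writeNifti(nim, path)
  invisible(path)
}

#' Correct a dynamic image for radioisotope decay
#'
#' Rescales each frame to injection time (t = 0) by the factor
#' `2^(mid / half_life)`, using the frame mid-time. Refuses input that is
#' already decay-corrected.
#'
#' @param img a [dynamic_image()] with `decay_corrected = FALSE`.
#' @param half_life isotope half-life in minutes (default fluorine-18,
#'   109.77 min).
#' @return The corrected [dynamic_image()] with `decay_corrected = TRUE`.
#' @export
decay_correct <- function(img, half_life = 109.77) {
  stopifnot(inherits(img, "dynamic_image"))
  if (img$decay_corrected)
    stop("image is already decay-corrected; refusing to correct twice",
         call. = FALSE)
  if (!is.finite(half_life) || half_life <= 0) {
    if (is.infinite(half_life) && half_life > 0) {
      img$decay_corrected <- TRUE
      return(img)
    }
    stop("'half_life' must be positive", call. = FALSE)
  }
  fac <- 2^(img$schedule$mid / half_life)
  for (f in seq_along(fac)) img$data[, , , f] <- img$data[, , , f] * fac[f]
  img$decay_corrected <- TRUE
  img
}

#' Duration-weighted sum of frames over a time window
#'
#' Sums `duration * frame` over all frames whose mid-time falls inside the
#' window, producing the static summation image used as the registration /
#' coregistration target.
#'
#' @param img a [dynamic_image()].
#' @param window numeric length-2 `(t0, t1)` in minutes, or `NULL` for the
#'   whole scan. Frame membership is decided by mid-time
#'   (`t0 <= mid <= t1`).
#' @return 3D array with attribute `window`.
#' @export
sum_frames <- function(img, window = NULL) {
  stopifnot(inherits(img, "dynamic_image"))
  mid <- img$schedule$mid
  if (is.null(window)) {
    sel <- seq_along(mid)
    window <- c(img$schedule$start[1], scan_duration(img$schedule))
  } else {
    if (length(window) != 2L || window[2] <= window[1])
      stop("'window' must be (t0, t1) with t1 > t0", call. = FALSE)
    sel <- which(mid >= window[1] & mid <= window[2])
    if (length(sel) == 0L)
      stop("window contains no frame mid-times", call. = FALSE)
  }
  d <- dim(img$data)[1:3]
  out <- array(0, d)
  for (f in sel)
    out <- out + img$schedule$duration[f] * array(img$data[, , , f], d)
  attr(out, "window") <- window
  out
}

#' Extract a regional time-activity curve
#'
#' Per-frame mean activity over the voxels carrying the region's label.
#'
#' @param img a [dynamic_image()].
#' @param labels a [label_volume()] on the same grid.
#' @param region region name present in `labels$names`.
#' @return A `tac` data frame with columns `mid` (minutes) and `value`
#'   (activity), and attribute `region`.
#' @export
extract_tac <- function(img, labels, region) {
  stopifnot(inherits(img, "dynamic_image"), inherits(labels, "label_volume"))
  if (!all(dim(labels$labels) == dim(img$data)[1:3]))
    stop("label grid does not match image grid", call. = FALSE)
  if (!region %in% names(labels$names))
    stop(sprintf("unknown region '%s'", region), call. = FALSE)
  idx <- which(labels$labels == labels$names[[region]])
  if (length(idx) == 0L)
    stop(sprintf("region '%s' is empty", region), call. = FALSE)
  nf <- dim(img$data)[4]
  nvox <- prod(dim(img$data)[1:3])
  m <- matrix(img$data, nrow = nvox, ncol = nf)
  tac(mid = img$schedule$mid, value = colMeans(m[idx, , drop = FALSE]),
      region = region)
}

#' Construct a time-activity curve
#' @param mid frame mid-times, minutes, strictly increasing.
#' @param value activity values, same length.
#' @param region region name label.
#' @export
tac <- function(mid, value, region = "unknown") {
  if (length(mid) != length(value))
    stop("'mid' and 'value' must have the same length", call. = FALSE)
  if (any(diff(mid) <= 0))
    stop("'mid' must be strictly increasing", call. = FALSE)
  out <- data.frame(mid = as.numeric(mid), value = as.numeric(value))
  attr(out, "region") <- region
  class(out) <- c("tac", "data.frame")
  out
}

#' Export regional TACs to CSV
#'
#' Writes `region, frame, mid_min, activity` rows for one or more TACs.
#' @param tacs a `tac` or list of them.
#' @param path output CSV path.
#' @export
write_tac_csv <- function(tacs, path) {
  if (inherits(tacs, "tac")) tacs <- list(tacs)
  rows <- do.call(rbind, lapply(tacs, function(tc) {
    data.frame(region = attr(tc, "region"), frame = seq_len(nrow(tc)),
               mid_min = tc$mid, activity = tc$value)
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
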