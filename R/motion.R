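#' Frame-to-frame rigid realignment of a dynamic PET series
#'
#' Estimates a 6-DOF rigid transform per frame by minimizing the mean squared
#' intensity difference to a reference frame, then resamples each frame
#' (trilinear). The reference defaults to the frame whose mid-time is nearest
#' 15 minutes — the usual trade-off between count statistics and tracer
#' distribution for bolus FDOPA. Estimation is multi-resolution: a coarse
#' pass on an 8 mm-FWHM-smoothed, half-resolution grid seeds a full-grid
#' Nelder-Mead refinement.
#'
#' Frames whose total signal is negligible relative to the reference (early
#' pre-arrival frames) cannot drive the cost function; they receive identity
#' transforms and are listed in the `low_signal` attribute. Non-converged
#' optimizations fall back to the best coarse estimate and are recorded in
#' `warnings`.
#'
#' @details
#' Several numerical details matter at PET voxel sizes and frame-to-frame
#' contrast levels:
#' \itemize{
#' \item The coarse pass (Nelder-Mead on an 8 mm-smoothed half-resolution
#'   grid, scale-free cosine cost) only seeds Levenberg-Marquardt
#'   refinements of the full residual vector, which are far more reliable
#'   than a simplex in the 6-D rigid space.
#' \item Trilinear interpolation acts as a small pose-dependent blur; if the
#'   cost compared interpolated moving samples against never-interpolated
#'   reference voxels, grid-aligned poses would look spuriously sharp and
#'   attract the optimizer. All costs therefore evaluate both images at a
#'   fixed set of sub-voxel jittered sample points, so both are interpolated
#'   with statistically identical blur at every candidate pose.
#' \item Tracer kinetics change the regional contrast across frames
#'   (striatal uptake grows while the reference washes out), which shifts
#'   the optimum of any single-reference intensity cost by up to ~0.3 mm /
#'   1 degree even without noise. A contrast-immune detector first fits the
#'   frame against the two-image basis spanned by the reference and an
#'   early-transit frame (the temporal contrast space of the tracer is
#'   essentially two-dimensional); if the detected pose is negligible it is
#'   accepted as is. Otherwise the pose is re-estimated by LM with a fixed
#'   intensity scale — more precise under noise once real motion exists —
#'   started from both the coarse seed and zero, keeping the better fit
#'   (preferring the smaller motion on near-ties).
#' }
#'
#' @param img a [dynamic_image()] with at least 2 frames.
#' @param reference frame index, or `"auto"` (mid-time nearest 15 min).
#' @param coarse_fwhm smoothing (mm) for the coarse pass (default 8).
#' @param fine_fwhm smoothing (mm) for the full-grid refinement (default 5;
#'   smoothing regularizes the cost surface against reconstruction noise).
#' @param maxit_coarse,maxit_fine iteration caps for the two passes.
#' @param frames indices of frames to estimate (default all); frames outside
#'   the subset keep identity transforms. Useful for targeted experiments.
#' @return A list: `image` (realigned [dynamic_image()]), `transforms`
#'   (list of [rigid_transform()], identity for the reference), `reference`
#'   (index), `low_signal`, `warnings`.
#' @export
realign_frames <- function(img, reference = "auto", coarse_fwhm = 8,
                           fine_fwhm = 5, maxit_coarse = 150,
                           maxit_fine = 100, frames = NULL) {
  stopifnot(inherits(img, "dynamic_image"))
  nf <- dim(img$data)[4]
  if (nf < 2L) stop("need at least 2 frames to realign", call. = FALSE)
  if (identical(reference, "auto"))
    reference <- which.min(abs(img$schedule$mid - 15))
  reference <- as.integer(reference)
  ref_vol <- img$data[, , , reference]
  if (max(abs(ref_vol)) == 0)
    stop("reference frame has no signal", call. = FALSE)

  d <- dim(img$data)[1:3]
  vox <- img$voxel_size
  ref_coarse_full <- gauss_smooth3d(ref_vol, coarse_fwhm, vox)
  ref_coarse <- downsample2(ref_coarse_full)
  vox_coarse <- vox * 2
  grid_coarse <- centred_grid_mm(dim(ref_coarse), vox_coarse)
  ref_fine <- gauss_smooth3d(ref_vol, fine_fwhm, vox)
  # fine cost on jittered sample points within the smoothed-reference
  # support: both images are interpolated identically at every pose
  support <- which(ref_coarse_full > 0.02 * max(ref_coarse_full))
  grid_full <- centred_grid_mm(d, vox)
  jitter <- with_seed(7137L, matrix(stats::runif(length(support) * 3,
                                                 -0.5, 0.5), ncol = 3))
  pts_fine <- grid_full[support, , drop = FALSE] +
    jitter %*% diag(vox, nrow = 3)
  ref_fine_vals <- sample_transformed(ref_fine, rigid_transform(), vox,
                                      pts_fine)
  # contrast basis: reference + an early-transit frame (if one with signal
  # exists) span the tracer's temporal contrast space. A second-choice
  # early frame provides the basis when the first is itself the frame being
  # registered (a frame must never sit in its own basis).
  basis_frame <- function(idx) {
    sample_transformed(gauss_smooth3d(img$data[, , , idx], fine_fwhm, vox),
                       rigid_transform(), vox, pts_fine)
  }
  usable_early <- which(img$schedule$mid <= 15 &
                          seq_len(nf) != reference &
                          apply(img$data, 4, function(v) mean(v^2)) >
                            1e-4 * mean(ref_vol^2))
  early_order <- usable_early[order(abs(img$schedule$mid[usable_early] - 2.5))]
  qr_basis_for <- function(f) {
    cand <- setdiff(early_order, f)
    if (length(cand) == 0) return(qr(cbind(ref_fine_vals)))
    qr(cbind(ref_fine_vals, basis_frame(cand[1])))
  }
  qr_basis_main <- qr_basis_for(-1L)
  parscale <- c(1, 1, 1, 0.02, 0.02, 0.02)

  transforms <- vector("list", nf)
  low_signal <- integer(0)
  warn <- character(0)
  ref_energy <- mean(ref_vol^2)

  if (is.null(frames)) frames <- seq_len(nf)
  for (f in seq_len(nf)) {
    if (f == reference || !(f %in% frames)) {
      transforms[[f]] <- rigid_transform()
      next
    }
    mov <- img$data[, , , f]
    if (mean(mov^2) < 1e-4 * ref_energy) {
      transforms[[f]] <- rigid_transform()
      low_signal <- c(low_signal, f)
      next
    }
    mov_coarse <- downsample2(gauss_smooth3d(mov, coarse_fwhm, vox))
    # coarse cost allows a free global intensity scale (cosine form):
    # frames differ in overall activity, which would otherwise bias the pose
    cost_coarse <- function(p) {
      m <- sample_transformed(mov_coarse, rigid_transform(p[1:3], p[4:6]),
                              vox_coarse, grid_coarse)
      1 - sum(m * ref_coarse)^2 / (sum(m * m) * sum(ref_coarse^2))
    }
    oc <- stats::optim(rep(0, 6), cost_coarse, method = "Nelder-Mead",
                       control = list(maxit = maxit_coarse,
                                      parscale = parscale, reltol = 1e-9))
    mov_fine <- gauss_smooth3d(mov, fine_fwhm, vox)
    mag <- function(p) sqrt(sum(p[1:3]^2)) + 50 * sqrt(sum(p[4:6]^2))
    # stage 1 — contrast-immune detector: residual orthogonal to the
    # temporal contrast basis; exact for a motion-free frame regardless of
    # its regional contrast
    qb <- if (f %in% early_order && length(early_order) > 0 &&
              f == early_order[1]) qr_basis_for(f) else qr_basis_main
    proj <- minpack.lm::nls.lm(oc$par / parscale, fn = function(q) {
      p <- q * parscale
      qr.resid(qb,
               sample_transformed(mov_fine, rigid_transform(p[1:3], p[4:6]),
                                  vox, pts_fine))
    }, control = minpack.lm::nls.lm.control(maxiter = maxit_fine))
    p_proj <- proj$par * parscale
    if (mag(p_proj) < 0.5) {
      transforms[[f]] <- rigid_transform(p_proj[1:3], p_proj[4:6])
      next
    }
    # stage 2 — real motion detected: LM with the intensity scale estimated
    # at the starting pose and held fixed (a free scale inside the
    # refinement lets pose and scale trade off against the frame's evolving
    # contrast). Run from both the coarse seed and zero: the coarse pass
    # can park in a contrast-drift minimum, while the zero start can miss
    # large motion; keep the better fit, preferring smaller motion on
    # near-ties.
    refine <- function(init) {
      m0 <- sample_transformed(mov_fine,
                               rigid_transform(init[1:3], init[4:6]),
                               vox, pts_fine)
      a0 <- sum(m0 * ref_fine_vals) / sum(m0 * m0)
      of <- minpack.lm::nls.lm(init / parscale, fn = function(q) {
        p <- q * parscale
        a0 * sample_transformed(mov_fine, rigid_transform(p[1:3], p[4:6]),
                                vox, pts_fine) - ref_fine_vals
      }, control = minpack.lm::nls.lm.control(maxiter = maxit_fine))
      list(par = of$par * parscale, info = of$info)
    }
    scale_free_cost <- function(p) {
      m <- sample_transformed(mov_fine, rigid_transform(p[1:3], p[4:6]), vox,
                              pts_fine)
      1 - sum(m * ref_fine_vals)^2 / (sum(m * m) * sum(ref_fine_vals^2))
    }
    r1 <- refine(oc$par)
    r2 <- if (mag(oc$par) > 0.25) refine(rep(0, 6)) else r1
    c1 <- scale_free_cost(r1$par)
    c2 <- scale_free_cost(r2$par)
    pick <- if (abs(c1 - c2) <= 0.02 * max(c1, c2)) {
      if (mag(r1$par) <= mag(r2$par)) r1 else r2
    } else if (c1 < c2) r1 else r2
    if (pick$info == 0 || pick$info == 5)
      warn <- c(warn, sprintf("frame %d: optimizer did not fully converge", f))
    transforms[[f]] <- rigid_transform(pick$par[1:3], pick$par[4:6])
  }

  out <- apply_transforms(img, transforms)
  list(image = out, transforms = transforms, reference = reference,
       low_signal = low_signal, warnings = warn)
}

#' Apply previously estimated transforms to a dynamic series
#'
#' Resamples each frame of `other` under the corresponding transform — the
#' mechanism by which motion estimated on the non-attenuation-corrected
#' series is applied to the attenuation-corrected one.
#'
#' @param other a [dynamic_image()].
#' @param transforms list of [rigid_transform()], one per frame.
#' @return The resampled [dynamic_image()].
#' @export
apply_transforms <- function(other, transforms) {
  stopifnot(inherits(other, "dynamic_image"))
  nf <- dim(other$data)[4]
  if (length(transforms) != nf)
    stop(sprintf("need %d transforms, got %d", nf, length(transforms)),
         call. = FALSE)
  inject_motion(other, transforms)
}

#' Framewise displacement from rigid transform parameters
#'
#' Scalar between-frame head movement:
#' `fd[i] = ||t[i+1] - t[i]|| + radius * ||theta[i+1] - theta[i]||`,
#' combining the translation step (mm) with the rotation step converted to
#' arc length on a head-sized sphere.
#'
#' @param transforms list of [rigid_transform()] (>= 2).
#' @param radius sphere radius in mm (default 50, head-radius convention).
#' @param mode `"consecutive"` (default) differences adjacent frames;
#'   `"to_reference"` measures each frame's displacement from the aligned
#'   (identity) pose instead.
#' @return Numeric vector: length `length(transforms) - 1` for
#'   `"consecutive"`, `length(transforms)` for `"to_reference"`.
#' @export
framewise_displacement <- function(transforms, radius = 50,
                                   mode = c("consecutive", "to_reference")) {
  mode <- match.arg(mode)
  if (length(transforms) < 2L)
    stop("need at least two transforms", call. = FALSE)
  p <- do.call(rbind, lapply(transforms, as.numeric))
  dp <- if (mode == "consecutive") diff(p) else p
  sqrt(rowSums(dp[, 1:3, drop = FALSE]^2)) +
    radius * sqrt(rowSums(dp[, 4:6, drop = FALSE]^2))
}

#' Motion spike detection
#'
#' Counts between-frame displacements strictly exceeding the threshold
#' (default 5 mm — the minimal spatial resolution detectable with standard
#' clinical PET scanners). One or more spikes flags the scan for potential
#' attenuation-map misalignment.
#'
#' @param fd non-negative framewise-displacement series.
#' @param threshold mm (default 5).
#' @return A `motion_qc` object: `fd`, `total_motion` (sum), `max_fd`,
#'   `n_spikes`, `flagged`, `threshold`.
#' @export
detect_spikes <- function(fd, threshold = 5) {
  fd <- as.numeric(fd)
  if (any(fd < 0)) stop("framewise displacement must be >= 0", call. = FALSE)
  n_spikes <- sum(fd > threshold)
  structure(list(fd = fd, total_motion = sum(fd), max_fd = max(fd),
                 n_spikes = n_spikes, flagged = n_spikes >= 1L,
                 threshold = threshold),
            class = "motion_qc")
}

#' @export
print.motion_qc <- function(x, ...) {
  cat(sprintf(
    "Motion QC: total %.2f mm, max step %.2f mm, %d spike(s) > %.1f mm%s\n",
    x$total_motion, x$max_fd, x$n_spikes, x$threshold,
    if (x$flagged) " [FLAGGED]" else ""))
  invisible(x)
}

#' Scan-level motion pass/fail decision
#'
#' Applies the archive QC criterion: a scan fails when its maximum
#' between-frame displacement reaches the limit (default 8 mm; passing
#' requires `max_fd < 8`).
#'
#' @param qc a `motion_qc` from [detect_spikes()].
#' @param max_fd_limit mm (default 8).
#' @return A list: `pass` (logical), `max_fd`, `limit`, `reasons`
#'   (character, empty on pass).
#' @export
qc_motion <- function(qc, max_fd_limit = 8) {
  stopifnot(inherits(qc, "motion_qc"))
  reasons <- character(0)
  if (qc$max_fd >= max_fd_limit)
    reasons <- c(reasons, sprintf(
      "max between-frame displacement %.2f mm >= %.1f mm limit",
      qc$max_fd, max_fd_limit))
  list(pass = length(reasons) == 0L, max_fd = qc$max_fd,
       limit = max_fd_limit, reasons = reasons)
}
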