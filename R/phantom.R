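#' Kinetic rate constants for an irreversible two-tissue compartment model
#'
#' `K1` (mL/g/min) is the plasma-to-tissue clearance, `k2` (1/min) the efflux
#' back to plasma, and `k3` (1/min) the trapping (decarboxylation) rate. The
#' implied net uptake (plasma-input Patlak slope) is
#' `Ki = K1 * k3 / (k2 + k3)`; a reference region has `k3 = 0` and hence
#' `Ki = 0`.
#'
#' @param K1,k2,k3 non-negative rate constants.
#' @return A `kinetic_parameters` object with derived field `Ki`.
#' @export
kinetic_parameters <- function(K1, k2, k3 = 0) {
  if (any(c(K1, k2, k3) < 0)) stop("rate constants must be >= 0", call. = FALSE)
  ki <- if (k2 + k3 > 0) K1 * k3 / (k2 + k3) else 0
  structure(list(K1 = K1, k2 = k2, k3 = k3, Ki = ki),
            class = "kinetic_parameters")
}

# Solve k3 giving a requested plasma-input Ki for fixed K1, k2.
k3_for_ki <- function(K1, k2, ki) {
  if (ki <= 0) return(0)
  if (ki >= K1) stop("target Ki must be < K1", call. = FALSE)
  ki * k2 / (K1 - ki)
}

# Feng (model 2) bolus shape: (A1*t - A2 - A3) e^{l1 t} + A2 e^{l2 t} +
# A3 e^{l3 t}, zero before injection. Canonical coefficients; the public
# input_function() rescales time and amplitude to the requested peak.
feng_canonical <- function(t) {
  A1 <- 851.1225; A2 <- 21.8798; A3 <- 20.8113
  l1 <- -4.133859; l2 <- -0.1190996; l3 <- -0.01043449
  v <- (A1 * t - A2 - A3) * exp(l1 * t) + A2 * exp(l2 * t) + A3 * exp(l3 * t)
  v[t <= 0] <- 0
  pmax(v, 0)
}

#' Synthetic metabolite-free plasma input function
#'
#' A Feng-type bolus: fast rise from zero at injection followed by
#' tri-exponential washout. The peak is placed at `peak_time` by delaying the
#' canonical curve (which preserves the physiological washout rates); when
#' `peak_time` precedes the canonical peak the time axis is compressed
#' instead. Amplitude is rescaled so the maximum equals `scale`.
#'
#' @param schedule a [frame_schedule()]; the input is sampled at frame
#'   mid-times (a dense evaluator is attached for ODE integration).
#' @param peak_time minutes; must lie inside the scan.
#' @param scale peak plasma activity (kBq/mL); `0` gives the all-zero curve,
#'   negative values are an error.
#' @return A `plasma_input` object: a `tac` with extra attribute `fun`, a
#'   vectorized evaluator Cp(t) usable on any time grid.
#' @export
input_function <- function(schedule, peak_time = 1.0, scale = 25) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (scale < 0) stop("'scale' must be non-negative", call. = FALSE)
  if (peak_time <= 0 || peak_time > scan_duration(schedule))
    stop("'peak_time' must lie within the scan", call. = FALSE)
  tg <- seq(0, 10, by = 1e-3)
  cg <- feng_canonical(tg)
  t_peak0 <- tg[which.max(cg)]
  peak0 <- max(cg)
  amp <- if (scale > 0) scale / peak0 else 0
  if (peak_time >= t_peak0) {
    shift <- peak_time - t_peak0
    fun <- function(t) amp * feng_canonical(t - shift)
  } else {
    a <- t_peak0 / peak_time
    fun <- function(t) amp * feng_canonical(a * t)
  }
  out <- tac(mid = schedule$mid, value = fun(schedule$mid), region = "plasma")
  attr(out, "fun") <- fun
  class(out) <- c("plasma_input", class(out))
  out
}

plasma_fun <- function(plasma) {
  f <- attr(plasma, "fun")
  if (!is.null(f)) return(f)
  if (is.function(plasma)) return(plasma)
  stats::approxfun(c(0, plasma$mid), c(0, plasma$value), rule = 2)
}

#' Simulate a tissue time-activity curve from compartmental kinetics
#'
#' Integrates the irreversible two-tissue system
#' `dC1/dt = K1 Cp - (k2 + k3) C1`, `dC2/dt = k3 C1` (one-tissue when
#' `k3 = 0`) and returns `C1 + C2` sampled at the schedule's frame mid-times.
#'
#' @param params a [kinetic_parameters()].
#' @param plasma a `plasma_input` (or plain function of minutes).
#' @param schedule a [frame_schedule()].
#' @param region region name attached to the returned TAC.
#' @return A `tac` of total tissue activity.
#' @export
simulate_tissue_tac <- function(params, plasma, schedule, region = "tissue") {
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(schedule, "frame_schedule"))
  cp <- plasma_fun(plasma)
  if (params$K1 == 0)
    return(tac(schedule$mid, rep(0, nrow(schedule)), region = region))
  deriv <- function(t, y, p) {
    list(c(p$K1 * cp(t) - (p$k2 + p$k3) * y[1], p$k3 * y[1]))
  }
  times <- c(0, schedule$mid)
  sol <- deSolve::lsoda(y = c(C1 = 0, C2 = 0), times = times, func = deriv,
                        parms = params, rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed: ", paste(attr(sol, "istate"), collapse = " "),
         call. = FALSE)
  tot <- sol[-1, "C1"] + sol[-1, "C2"]
  tac(schedule$mid, tot, region = region)
}

#' Construct a target TAC with an exactly linear Patlak plot
#'
#' Given a reference TAC, builds `C_T(t) = C_ref(t) * (intercept + Ki * x(t))`
#' where `x(t)` is the Patlak abscissa (cumulative trapezoidal integral of the
#' reference over its instantaneous value, with an implicit zero at
#' injection). By construction the reference-input Patlak plot of the result
#' is a perfect line with slope `Ki` at every usable point.
#'
#' @param ref a `tac` (reference region), positive after t = 0.
#' @param ki slope (1/min).
#' @param intercept dimensionless intercept.
#' @return A `tac`.
#' @export
patlak_consistent_tac <- function(ref, ki, intercept) {
  stopifnot(inherits(ref, "tac"))
  cum <- cumtrapz0(ref$mid, ref$value)
  x <- ifelse(ref$value > 0, cum / ref$value, 0)
  tac(ref$mid, ref$value * (intercept + ki * x), region = "patlak_consistent")
}

#' Phantom specification
#'
#' Describes a desk-scale digital FDOPA phantom: grid geometry, ellipsoidal
#' region layout, per-region kinetics, acquisition schedule, noise level and
#' optional per-frame rigid motion. The defaults emulate a 95-min bolus FDOPA
#' scan with striatal net uptake Ki(cer) near 0.0137 1/min, a cerebellar
#' reference with no trapping, and an occipital-like low-uptake background.
#'
#' @param dim3 grid dimensions (default `c(32, 32, 24)`).
#' @param voxel_size mm triple (default 4 mm isotropic).
#' @param schedule a [frame_schedule()] (default [frame_schedule_fdopa()]).
#' @param regions named list of region specs, each
#'   `list(center, semiaxes, params)` with `center`/`semiaxes` in voxel
#'   units and `params` a [kinetic_parameters()]. Regions must not overlap.
#' @param noise_sigma0 noise scale: per-frame Gaussian sd is
#'   `noise_sigma0 * sqrt(mean_activity / duration)` (shorter, hotter frames
#'   are noisier, a proxy for reconstruction noise). 0 disables noise. The
#'   default 0.35 corresponds to clinical 2 mm-grid reconstruction noise
#'   volume-averaged onto the phantom's 4 mm voxels (1/sqrt(8) of the unit
#'   scale).
#' @param motion `NULL`, or a list of [rigid_transform()] (one per frame)
#'   injected into the generated dynamic.
#' @param plasma_peak,plasma_scale input-function peak time (min) and peak
#'   amplitude (kBq/mL).
#' @param seed integer seed; mandatory (used for every stochastic path).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(dim3 = c(32, 32, 24), voxel_size = c(4, 4, 4),
                         schedule = frame_schedule_fdopa(),
                         regions = default_phantom_regions(),
                         noise_sigma0 = 0.35, motion = NULL,
                         plasma_peak = 1.0, plasma_scale = 25,
                         seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("'seed' is mandatory in a phantom spec", call. = FALSE)
  stopifnot(inherits(schedule, "frame_schedule"))
  if (!is.null(motion) && length(motion) != nrow(schedule))
    stop("'motion' must supply one transform per frame", call. = FALSE)
  structure(list(dim3 = as.integer(dim3), voxel_size = as.numeric(voxel_size),
                 schedule = schedule, regions = regions,
                 noise_sigma0 = noise_sigma0, motion = motion,
                 plasma_peak = plasma_peak, plasma_scale = plasma_scale,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default phantom region layout and kinetics
#'
#' Ellipsoidal regions on the default 32 x 32 x 24 grid (4 mm voxels): a
#' bilateral striatum (two lateral lobes sharing one label; trapping tuned to
#' a reference-normalized Patlak slope of 0.0137 1/min), a cerebellar
#' reference (`k3 = 0`, `K1/k2 = 1` so the reference-normalized Patlak slope
#' equals the plasma-input Ki), and a large occipital-like background shell
#' tuned to Ki = 0.0005 1/min with efflux matched to the reference so
#' equilibration transients cancel. The bilateral layout breaks the
#' phantom's mirror symmetries, making all six rigid degrees of freedom
#' identifiable for realignment experiments.
#' @export
default_phantom_regions <- function() {
  list(
    whole_striatum = list(center = rbind(c(10.5, 19, 13), c(20.5, 19, 13)),
                          semiaxes = rbind(c(2.8, 4, 3), c(2.8, 4, 3)),
                          params = kinetic_parameters(
                            K1 = 0.05, k2 = 0.04,
                            k3 = k3_for_ki(0.05, 0.04, 0.0137))),
    cerebellum = list(center = c(15.5, 7, 6), semiaxes = c(7, 4.5, 3.5),
                      params = kinetic_parameters(K1 = 0.06, k2 = 0.06,
                                                  k3 = 0)),
    background = list(center = c(15.5, 15.5, 13), semiaxes = c(13, 13, 9),
                      params = kinetic_parameters(
                        K1 = 0.054, k2 = 0.06,
                        k3 = k3_for_ki(0.054, 0.06, 0.0005)))
  )
}

# Ellipsoid membership mask; center/semiaxes may be matrices (one row per
# lobe), giving the union of the lobes under a single label.
ellipsoid_mask <- function(dim3, center, semiaxes) {
  if (is.null(dim(center))) center <- matrix(center, nrow = 1)
  if (is.null(dim(semiaxes))) semiaxes <- matrix(semiaxes, nrow = 1)
  out <- array(FALSE, dim3)
  for (l in seq_len(nrow(center))) {
    i <- (seq_len(dim3[1]) - center[l, 1]) / semiaxes[l, 1]
    j <- (seq_len(dim3[2]) - center[l, 2]) / semiaxes[l, 2]
    k <- (seq_len(dim3[3]) - center[l, 3]) / semiaxes[l, 3]
    out <- out | (outer(outer(i^2, j^2, `+`), k^2, `+`) <= 1)
  }
  out
}

# Index coordinates (1-based, x-fastest vector order) of every voxel centre
# after mapping through a rigid transform acting on centred mm coordinates.
transformed_index_coords <- function(dim3, voxel, tf) {
  grid <- centred_grid_mm(dim3, voxel)
  m <- transform_matrix(tf)
  src <- grid %*% t(m[1:3, 1:3])
  ctr <- (dim3 - 1) / 2
  list(ix = (src[, 1] + m[1, 4]) / voxel[1] + ctr[1] + 1,
       iy = (src[, 2] + m[2, 4]) / voxel[2] + ctr[2] + 1,
       iz = (src[, 3] + m[3, 4]) / voxel[3] + ctr[3] + 1,
       rot = m[1:3, 1:3])
}

# Anti-aliased (partial-volume) rasterization of an ellipsoid union under a
# rigid transform: returns the per-voxel inside fraction, estimated by 3^3
# supersampling of voxels near the boundary. Analytic rasterization keeps
# moved frames sharp (a moved head produces a sharp image), avoiding the
# interpolation blur that image-space resampling would bake into the data.
ellipsoid_fraction <- function(dim3, voxel, center, semiaxes, tf,
                               coords = NULL) {
  if (is.null(dim(center))) center <- matrix(center, nrow = 1)
  if (is.null(dim(semiaxes))) semiaxes <- matrix(semiaxes, nrow = 1)
  if (is.null(coords)) coords <- transformed_index_coords(dim3, voxel, tf)
  nvox <- prod(dim3)
  frac <- numeric(nvox)
  offs <- as.matrix(expand.grid(e1 = c(-1, 0, 1) / 3, e2 = c(-1, 0, 1) / 3,
                                e3 = c(-1, 0, 1) / 3))
  for (l in seq_len(nrow(center))) {
    rho2 <- ((coords$ix - center[l, 1]) / semiaxes[l, 1])^2 +
      ((coords$iy - center[l, 2]) / semiaxes[l, 2])^2 +
      ((coords$iz - center[l, 3]) / semiaxes[l, 3])^2
    # band of voxels whose supersamples could straddle the surface
    band <- 1.2 / min(semiaxes[l, ])
    inner <- rho2 <= (1 - band)^2
    edge <- which(!inner & rho2 <= (1 + band)^2)
    lf <- as.numeric(inner)
    if (length(edge) > 0) {
      acc <- numeric(length(edge))
      for (o in seq_len(nrow(offs))) {
        # offset in output-voxel mm, rotated into source index space
        d_mm <- coords$rot %*% (offs[o, ] * voxel)
        sx <- coords$ix[edge] + d_mm[1] / voxel[1] - center[l, 1]
        sy <- coords$iy[edge] + d_mm[2] / voxel[2] - center[l, 2]
        sz <- coords$iz[edge] + d_mm[3] / voxel[3] - center[l, 3]
        acc <- acc + as.numeric((sx / semiaxes[l, 1])^2 +
                                  (sy / semiaxes[l, 2])^2 +
                                  (sz / semiaxes[l, 3])^2 <= 1)
      }
      lf[edge] <- acc / nrow(offs)
    }
    frac <- pmax(frac, lf)
  }
  array(frac, dim3)
}

#' Build a dynamic phantom with known ground truth
#'
#' Generates region geometry from the spec, simulates one noiseless
#' compartmental TAC per region, paints the TACs into a 4D dynamic, then
#' applies per-frame rigid motion (if any) and frame-duration-dependent
#' Gaussian noise. Later/smaller regions are carved out of larger ones, so
#' the default background shell surrounds the striatum and cerebellum
#' without overlap. Region labels mark voxels fully interior to a region;
#' boundary voxels carry partial-volume mixtures from the anti-aliased
#' rasterization. Motion is applied analytically — each moved frame is
#' rasterized at its transformed pose — so moved frames stay sharp, exactly
#' as a moved head would appear to the scanner. Fully deterministic under
#' the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `image` ([dynamic_image()]), `labels`
#'   ([label_volume()]), and `truth`: per-region `kinetic_parameters`, their
#'   plasma-input `Ki`, `ki_cer` (reference-normalized slope
#'   `Ki * k2_ref / K1_ref`), the noiseless regional TACs, the injected
#'   motion 6-vectors, and the seed.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dim3
  vox <- spec$voxel_size
  nf <- nrow(spec$schedule)
  nr <- length(spec$regions)
  plasma <- input_function(spec$schedule, spec$plasma_peak, spec$plasma_scale)
  region_names <- names(spec$regions)

  # paint order: larger regions first, so smaller ones carve them out
  sizes <- vapply(spec$regions, function(r)
    sum(ellipsoid_mask(d, r$center, r$semiaxes)), 0)
  paint <- order(sizes, decreasing = TRUE)

  # per-region partial-volume weights at a given pose
  region_weights <- function(tf) {
    coords <- transformed_index_coords(d, vox, tf)
    fr <- lapply(spec$regions, function(r)
      ellipsoid_fraction(d, vox, r$center, r$semiaxes, tf, coords = coords))
    w <- vector("list", nr)
    remaining <- array(1, d)
    for (r in rev(paint)) {       # smallest first: full claim, then shadow
      w[[r]] <- fr[[r]] * remaining
      remaining <- remaining * (1 - fr[[r]])
    }
    w
  }

  w_id <- region_weights(rigid_transform())
  lab <- array(0L, d)
  for (r in paint) lab[w_id[[r]] >= 0.999] <- r
  for (r in seq_len(nr)) {
    if (!any(lab == r))
      stop(sprintf("region '%s' is fully covered by other regions",
                   region_names[r]), call. = FALSE)
  }

  ref_pars <- NULL
  tacs <- list()
  tacmat <- matrix(0, nr, nf)
  for (r in seq_len(nr)) {
    pars <- spec$regions[[r]]$params
    tc <- simulate_tissue_tac(pars, plasma, spec$schedule,
                              region = region_names[r])
    tacs[[region_names[r]]] <- tc
    tacmat[r, ] <- tc$value
    if (region_names[r] == "cerebellum") ref_pars <- pars
  }

  data <- array(0, c(d, nf))
  nv <- prod(d)
  if (is.null(spec$motion)) {
    wmat <- vapply(w_id, as.vector, numeric(nv))      # nv x nr
    data <- array(wmat %*% tacmat, c(d, nf))
  } else {
    for (f in seq_len(nf)) {
      tf <- spec$motion[[f]]
      wf <- if (is_identity_transform(tf)) w_id else region_weights(tf)
      frame <- numeric(nv)
      for (r in seq_len(nr)) frame <- frame + as.vector(wf[[r]]) * tacmat[r, f]
      data[, , , f] <- frame
    }
  }

  img <- dynamic_image(data, spec$voxel_size, spec$schedule,
                       decay_corrected = TRUE)

  if (spec$noise_sigma0 > 0) {
    # per-frame sd from the mean tissue activity and the frame duration
    # (shorter, hotter frames are noisier); noise spans the whole grid as
    # reconstruction noise does, so it is independent of head pose
    tissue_vox <- sum(vapply(w_id, sum, 0))
    mu_f <- as.vector(vapply(w_id, sum, 0) %*% tacmat) / tissue_vox
    img$data <- with_seed(spec$seed, {
      dd <- img$data
      for (f in seq_len(nf)) {
        sdev <- spec$noise_sigma0 * sqrt(max(mu_f[f], 0) /
                                           spec$schedule$duration[f])
        if (sdev > 0)
          dd[, , , f] <- dd[, , , f] + stats::rnorm(nv, 0, sdev)
      }
      dd
    })
  }

  ref_clearance <- if (!is.null(ref_pars) && ref_pars$K1 > 0)
    ref_pars$K1 / ref_pars$k2 else NA_real_
  truth <- list(
    regions = stats::setNames(lapply(seq_along(spec$regions), function(r) {
      p <- spec$regions[[r]]$params
      list(params = p, Ki_true = p$Ki,
           ki_cer = if (is.finite(ref_clearance)) p$Ki / ref_clearance
                    else NA_real_)
    }), region_names),
    tacs = tacs, plasma = plasma,
    motion = spec$motion, seed = spec$seed)

  labels <- label_volume(lab, stats::setNames(seq_along(region_names),
                                              region_names))
  list(image = img, labels = labels, truth = truth)
}

#' Apply per-frame rigid motion to a dynamic image
#'
#' Resamples each frame under its rigid transform (trilinear interpolation,
#' pull-back convention: output voxel `v` takes the value at `R v + t`).
#' Identity transforms leave frames untouched; integer-voxel translations are
#' exact inside the field of view.
#'
#' @param img a [dynamic_image()].
#' @param transforms list of [rigid_transform()], one per frame.
#' @return The moved [dynamic_image()].
#' @export
inject_motion <- function(img, transforms) {
  stopifnot(inherits(img, "dynamic_image"))
  nf <- dim(img$data)[4]
  if (length(transforms) != nf)
    stop(sprintf("need %d transforms, got %d", nf, length(transforms)),
         call. = FALSE)
  d <- dim(img$data)[1:3]
  grid <- centred_grid_mm(d, img$voxel_size)
  for (f in seq_len(nf)) {
    tf <- transforms[[f]]
    if (is_identity_transform(tf)) next
    img$data[, , , f] <- resample_volume(img$data[, , , f], tf,
                                         img$voxel_size, grid = grid)
  }
  img
}

#' Write a phantom to disk in the package's NIfTI + JSON dialect
#'
#' Emits `dynamic.nii.gz` + `dynamic.json` (readable by [read_dynamic()]),
#' `labels.nii.gz`, and `ground_truth.json` with per-region kinetics,
#' Ki values, injected motion 6-vectors and the seed.
#'
#' @param phantom result of [build_phantom()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the output directory.
#' @export
write_phantom <- function(phantom, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_dynamic(phantom$image, file.path(out_dir, "dynamic.nii.gz"),
                extra = list(TracerName = "FDOPA"))
  write_volume(phantom$labels$labels, phantom$image$voxel_size,
               file.path(out_dir, "labels.nii.gz"))
  jsonlite::write_json(list(
    label_names = as.list(phantom$labels$names),
    regions = lapply(phantom$truth$regions, function(r)
      list(K1 = r$params$K1, k2 = r$params$k2, k3 = r$params$k3,
           Ki_true = r$Ki_true, ki_cer = r$ki_cer)),
    motion = if (is.null(phantom$truth$motion)) NULL else
      lapply(phantom$truth$motion, function(tf) as.numeric(tf)),
    seed = phantom$truth$seed
  ), file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA,
  pretty = TRUE)
  invisible(out_dir)
}
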