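#' Patlak transformation of a target/reference TAC pair
#'
#' Computes the reference-input Patlak coordinates
#' `x(t) = int_0^t C_ref dtau / C_ref(t)` (normalized time, minutes) and
#' `y(t) = C_T(t) / C_ref(t)` on the shared frame mid-times. The integral is
#' trapezoidal with an implicit (0, 0) sample at injection. Points where the
#' reference is at or below `eps_frac * max(C_ref)` are dropped and counted.
#'
#' @param target,ref `tac` objects on identical mid-times.
#' @param eps_frac positivity guard for the reference (default 1e-6).
#' @return A `patlak_points` data frame with columns `mid`, `x`, `y` and
#'   attribute `n_dropped`.
#' @export
patlak_transform <- function(target, ref, eps_frac = 1e-6) {
  stopifnot(inherits(target, "tac"), inherits(ref, "tac"))
  if (nrow(target) != nrow(ref) || any(abs(target$mid - ref$mid) > 1e-9))
    stop("target and reference TACs must share mid-times", call. = FALSE)
  eps <- eps_frac * max(ref$value)
  cum <- cumtrapz0(ref$mid, ref$value)
  keep <- ref$value > eps
  if (!any(keep))
    stop("all Patlak points dropped: reference has no positive activity",
         call. = FALSE)
  out <- data.frame(mid = ref$mid[keep], x = cum[keep] / ref$value[keep],
                    y = target$value[keep] / ref$value[keep])
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("patlak_points", "data.frame")
  out
}

#' Patlak graphical fit
#'
#' Ordinary least squares on the Patlak points with mid-time at or beyond
#' the equilibrium time `t_star` (default 20 minutes). The slope is Ki(cer)
#' (1/min), the net influx rate constant used as a proxy of dopamine
#' synthesis capacity; negative slopes are retained.
#'
#' @param points a `patlak_points` data frame from [patlak_transform()].
#' @param t_star minutes; points with `mid >= t_star` are fitted (>= 3
#'   required).
#' @param region region name carried into the result.
#' @return A `patlak_result`: `ki`, `intercept`, `t_star`, `n_points`,
#'   `r_squared`, `region`.
#' @export
patlak_fit <- function(points, t_star = 20, region = "unknown") {
  stopifnot(inherits(points, "patlak_points"))
  sel <- points$mid >= t_star
  if (sum(sel) < 3L)
    stop(sprintf("need >= 3 Patlak points with mid >= %.1f min (have %d)",
                 t_star, sum(sel)), call. = FALSE)
  fit <- stats::lm(y ~ x, data = points[sel, ])
  co <- stats::coef(fit)
  tss <- sum((points$y[sel] - mean(points$y[sel]))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else 1
  structure(list(ki = unname(co[2]), intercept = unname(co[1]),
                 t_star = t_star, n_points = sum(sel), r_squared = r2,
                 region = region),
            class = "patlak_result")
}

#' @export
print.patlak_result <- function(x, ...) {
  cat(sprintf(
    "Patlak fit [%s]: Ki = %.5f 1/min, intercept = %.4f, R^2 = %.4f (%d points, t* = %g min)\n",
    x$region, x$ki, x$intercept, x$r_squared, x$n_points, x$t_star))
  invisible(x)
}

#' Region-wise Patlak quantification
#'
#' Convenience wrapper: extracts the target and reference TACs from a label
#' volume and runs [patlak_transform()] + [patlak_fit()].
#'
#' @param img a realigned [dynamic_image()].
#' @param labels a [label_volume()].
#' @param region target region name.
#' @param ref_region reference region name (default `"cerebellum"`).
#' @param t_star minutes (default 20).
#' @return A `patlak_result`.
#' @export
patlak_region <- function(img, labels, region, ref_region = "cerebellum",
                          t_star = 20) {
  target <- extract_tac(img, labels, region)
  ref <- extract_tac(img, labels, ref_region)
  patlak_fit(patlak_transform(target, ref), t_star = t_star, region = region)
}

#' Voxelwise Patlak parametric maps
#'
#' Per-frame TV denoising (optional) followed by a closed-form voxelwise
#' Patlak OLS against a shared reference design: because every voxel shares
#' the same abscissa `x(t)`, the slope and intercept reduce to vectorized
#' moment expressions over the frame axis. Voxels with no signal (all frames
#' zero) or non-finite ratios get `NA`.
#'
#' @param img a realigned [dynamic_image()].
#' @param ref reference-region `tac` (e.g. cerebellum).
#' @param brain_mask logical 3D array of voxels to fit.
#' @param t_star minutes (default 20).
#' @param tv `NULL` to skip denoising, or a list with entries `weight`,
#'   `max_iter`, `tol` passed to [tv_denoise()] per frame.
#' @param weight_frames if `TRUE`, the per-voxel OLS weights each late
#'   frame by its duration (longer frames carry better counts); default
#'   `FALSE`, matching the unweighted region-wise estimator.
#' @return A `parametric_map`: `ki_map`, `intercept_map`, `r2_map`, `mask`,
#'   `voxel_size`.
#' @export
patlak_voxelwise <- function(img, ref, brain_mask, t_star = 20, tv = NULL,
                             weight_frames = FALSE) {
  stopifnot(inherits(img, "dynamic_image"), inherits(ref, "tac"))
  d <- dim(img$data)[1:3]
  if (!all(dim(brain_mask) == d))
    stop("brain mask does not match image grid", call. = FALSE)
  if (!any(brain_mask)) stop("brain mask is empty", call. = FALSE)
  nf <- dim(img$data)[4]

  data <- img$data
  if (!is.null(tv)) {
    w <- tv$weight
    for (f in seq_len(nf)) {
      data[, , , f] <- tv_denoise(data[, , , f], weight = w,
                                  max_iter = if (is.null(tv$max_iter)) 200
                                             else tv$max_iter,
                                  tol = if (is.null(tv$tol)) 2e-4 else tv$tol)
    }
  }

  eps <- 1e-6 * max(ref$value)
  cum <- cumtrapz0(ref$mid, ref$value)
  keep <- ref$value > eps & ref$mid >= t_star
  if (sum(keep) < 3L)
    stop("fewer than 3 usable late frames for the voxelwise fit",
         call. = FALSE)
  x <- cum[keep] / ref$value[keep]

  vox_idx <- which(brain_mask)
  nvox <- prod(d)
  m <- matrix(data, nrow = nvox, ncol = nf)[vox_idx, keep, drop = FALSE]
  y <- sweep(m, 2, ref$value[keep], `/`)

  w <- if (weight_frames) img$schedule$duration[keep] else rep(1, sum(keep))
  w <- w / sum(w)
  xbar <- sum(w * x)
  xc <- x - xbar
  sxx <- sum(w * xc^2)
  ybar <- as.vector(y %*% w)
  slope <- as.vector(y %*% (w * xc)) / sxx
  intercept <- ybar - slope * xbar
  fitted_ss <- slope^2 * sxx
  tot_ss <- as.vector(sweep(y, 1, ybar)^2 %*% w)
  r2 <- ifelse(tot_ss > 0, fitted_ss / tot_ss, NA_real_)

  dead <- rowSums(abs(m)) == 0 | !is.finite(slope)
  slope[dead] <- NA_real_
  intercept[dead] <- NA_real_
  r2[dead] <- NA_real_

  ki_map <- array(NA_real_, d); ki_map[vox_idx] <- slope
  int_map <- array(NA_real_, d); int_map[vox_idx] <- intercept
  r2_map <- array(NA_real_, d); r2_map[vox_idx] <- r2
  structure(list(ki_map = ki_map, intercept_map = int_map, r2_map = r2_map,
                 mask = brain_mask, voxel_size = img$voxel_size,
                 t_star = t_star),
            class = "parametric_map")
}

#' Standardized uptake value ratio over a late window
#'
#' Mean target activity divided by mean reference activity over the window
#' (default 60-75 min, where the Patlak plot is linear). Frame contributions
#' are weighted by the overlap of each frame's interval with the window, so
#' frames aligned with the window boundaries contribute exactly.
#'
#' @param img a [dynamic_image()].
#' @param labels a [label_volume()].
#' @param target_region,ref_region region names.
#' @param window minutes, length 2 (default `c(60, 75)`).
#' @return A `suvr_result`: `suvr`, `window`, `region`, `ref_region`.
#' @export
suvr <- function(img, labels, target_region, ref_region = "cerebellum",
                 window = c(60, 75)) {
  stopifnot(inherits(img, "dynamic_image"))
  if (length(window) != 2L || window[2] <= window[1])
    stop("'window' must be (t0, t1) with t1 > t0", call. = FALSE)
  sch <- img$schedule
  w <- pmax(0, pmin(sch$start + sch$duration, window[2]) -
              pmax(sch$start, window[1]))
  if (sum(w) <= 0) stop("window does not overlap the scan", call. = FALSE)
  t_tac <- extract_tac(img, labels, target_region)
  r_tac <- extract_tac(img, labels, ref_region)
  mt <- sum(w * t_tac$value) / sum(w)
  mr <- sum(w * r_tac$value) / sum(w)
  if (mr <= 0)
    stop("reference activity in the window is not positive", call. = FALSE)
  structure(list(suvr = mt / mr, window = window, region = target_region,
                 ref_region = ref_region),
            class = "suvr_result")
}

#' @export
print.suvr_result <- function(x, ...) {
  cat(sprintf("SUVr [%s / %s, %g-%g min]: %.3f\n", x$region, x$ref_region,
              x$window[1], x$window[2], x$suvr))
  invisible(x)
}
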