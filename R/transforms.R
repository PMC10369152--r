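#' Rigid-body (6-DOF) transform
#'
#' A rigid transform is parameterized by three translations (mm, x/y/z) and
#' three rotations (radians: pitch about x, roll about y, yaw about z),
#' applied about the volume centre. The rotation matrix is
#' `R = Rz(yaw) %*% Ry(roll) %*% Rx(pitch)`; a point `p` (mm, centred
#' coordinates) maps to `R p + t`.
#'
#' @param translation mm triple (x, y, z).
#' @param rotation radians triple (pitch, roll, yaw).
#' @return A `rigid_transform` object (named numeric of length 6).
#' @export
rigid_transform <- function(translation = c(0, 0, 0), rotation = c(0, 0, 0)) {
  translation <- as.numeric(translation)
  rotation <- as.numeric(rotation)
  stopifnot(length(translation) == 3L, length(rotation) == 3L)
  if (any(abs(rotation) >= pi))
    stop("rotation magnitudes must be < pi radians", call. = FALSE)
  structure(c(tx = translation[1], ty = translation[2], tz = translation[3],
              pitch = rotation[1], roll = rotation[2], yaw = rotation[3]),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("Rigid transform: t = (%.3f, %.3f, %.3f) mm, rot = (%.4f, %.4f, %.4f) rad\n",
              x[1], x[2], x[3], x[4], x[5], x[6]))
  invisible(x)
}

#' @rdname rigid_transform
#' @param x object to test / transform.
#' @export
is_identity_transform <- function(x, tol = 1e-12) {
  all(abs(unclass(x)) < tol)
}

rotation_matrix <- function(rotation) {
  cp <- cos(rotation[1]); sp <- sin(rotation[1])
  cr <- cos(rotation[2]); sr <- sin(rotation[2])
  cy <- cos(rotation[3]); sy <- sin(rotation[3])
  rx <- matrix(c(1, 0, 0, 0, cp, sp, 0, -sp, cp), 3, 3)
  ry <- matrix(c(cr, 0, -sr, 0, 1, 0, sr, 0, cr), 3, 3)
  rz <- matrix(c(cy, sy, 0, -sy, cy, 0, 0, 0, 1), 3, 3)
  rz %*% ry %*% rx
}

transform_matrix <- function(tf) {
  m <- diag(4)
  m[1:3, 1:3] <- rotation_matrix(unclass(tf)[4:6])
  m[1:3, 4] <- unclass(tf)[1:3]
  m
}

#' Invert or compose rigid transforms
#'
#' `invert_transform(a)` returns the transform undoing `a`;
#' `compose_transforms(a, b)` returns the transform equivalent to applying
#' `b` then `a` (matrix product `A %*% B`). Because composed rotations about
#' a common centre remain rigid, both results are exact `rigid_transform`s.
#' @param a,b `rigid_transform` objects.
#' @export
invert_transform <- function(a) {
  m <- transform_matrix(a)
  r <- t(m[1:3, 1:3])
  rigid_transform(translation = as.vector(-r %*% m[1:3, 4]),
                  rotation = angles_from_matrix(r))
}

#' @rdname invert_transform
#' @export
compose_transforms <- function(a, b) {
  m <- transform_matrix(a) %*% transform_matrix(b)
  rigid_transform(translation = m[1:3, 4],
                  rotation = angles_from_matrix(m[1:3, 1:3]))
}

# Euler angles (pitch, roll, yaw) from R = Rz %*% Ry %*% Rx.
angles_from_matrix <- function(r) {
  roll <- asin(max(-1, min(1, -r[3, 1])))
  if (abs(cos(roll)) > 1e-9) {
    pitch <- atan2(r[3, 2], r[3, 3])
    yaw <- atan2(r[2, 1], r[1, 1])
  } else { # gimbal lock: fold everything into pitch
    pitch <- atan2(-r[2, 3], r[2, 2])
    yaw <- 0
  }
  c(pitch, roll, yaw)
}

# mm coordinates of all voxel centres, centred on the volume middle.
# Returns an n x 3 matrix in x-fastest order, matching as.vector(array).
centred_grid_mm <- function(dim3, voxel) {
  ctr <- (dim3 - 1) / 2
  i <- (seq_len(dim3[1]) - 1 - ctr[1]) * voxel[1]
  j <- (seq_len(dim3[2]) - 1 - ctr[2]) * voxel[2]
  k <- (seq_len(dim3[3]) - 1 - ctr[3]) * voxel[3]
  cbind(rep(i, times = dim3[2] * dim3[3]),
        rep(rep(j, each = dim3[1]), times = dim3[3]),
        rep(k, each = dim3[1] * dim3[2]))
}

# Sample vol at rigidly transformed points: returns vol(R p + t) for each
# row p (mm, centred coordinates) of `points`. Out-of-grid samples give 0.
sample_transformed <- function(vol, tf, voxel, points) {
  d <- dim(vol)
  m <- transform_matrix(tf)
  src <- points %*% t(m[1:3, 1:3])
  ctr <- (d - 1) / 2
  fx <- (src[, 1] + m[1, 4]) / voxel[1] + ctr[1]
  fy <- (src[, 2] + m[2, 4]) / voxel[2] + ctr[2]
  fz <- (src[, 3] + m[3, 4]) / voxel[3] + ctr[3]
  trilinear(vol, fx, fy, fz)
}

# Pull-back resampling: out(v) = vol(R v + t) with trilinear interpolation;
# sampling points outside the grid give 0. `grid` may be precomputed with
# centred_grid_mm for speed.
resample_volume <- function(vol, tf, voxel, grid = NULL) {
  d <- dim(vol)
  if (is_identity_transform(tf)) return(vol)
  if (is.null(grid)) grid <- centred_grid_mm(d, voxel)
  array(sample_transformed(vol, tf, voxel, grid), d)
}

# Trilinear interpolation at fractional 0-based voxel coordinates.
trilinear <- function(vol, fx, fy, fz) {
  d <- dim(vol)
  x0 <- floor(fx); y0 <- floor(fy); z0 <- floor(fz)
  wx <- fx - x0; wy <- fy - y0; wz <- fz - z0
  # valid if the whole 8-neighbourhood (clamped corner handling below) exists
  inside <- x0 >= 0 & x0 <= d[1] - 1 & y0 >= 0 & y0 <= d[2] - 1 &
    z0 >= 0 & z0 <= d[3] - 1
  # upper corners clamp to the boundary where the weight is 0
  x1 <- pmin(x0 + 1, d[1] - 1); y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  out <- numeric(length(fx))
  if (any(inside)) {
    ix0 <- x0[inside] + 1; iy0 <- y0[inside] + 1; iz0 <- z0[inside] + 1
    ix1 <- x1[inside] + 1; iy1 <- y1[inside] + 1; iz1 <- z1[inside] + 1
    ux <- wx[inside]; uy <- wy[inside]; uz <- wz[inside]
    n1 <- d[1]; n12 <- d[1] * d[2]
    at <- function(i, j, k) vol[i + (j - 1) * n1 + (k - 1) * n12]
    out[inside] <-
      (1 - ux) * (1 - uy) * (1 - uz) * at(ix0, iy0, iz0) +
      ux * (1 - uy) * (1 - uz) * at(ix1, iy0, iz0) +
      (1 - ux) * uy * (1 - uz) * at(ix0, iy1, iz0) +
      (1 - ux) * (1 - uy) * uz * at(ix0, iy0, iz1) +
      ux * uy * (1 - uz) * at(ix1, iy1, iz0) +
      ux * (1 - uy) * uz * at(ix1, iy0, iz1) +
      (1 - ux) * uy * uz * at(ix0, iy1, iz1) +
      ux * uy * uz * at(ix1, iy1, iz1)
  }
  out
}
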