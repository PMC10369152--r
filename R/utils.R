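# Internal numeric helpers shared across modules.

# Cumulative trapezoidal integral of (t, v) with an implicit (0, 0) sample at
# injection; returns the integral from 0 to each t.
cumtrapz0 <- function(t, v) {
  stopifnot(length(t) == length(v))
  as.vector(pracma::cumtrapz(c(0, t), c(0, v)))[-1L]
}

# Separable Gaussian smoothing of a 3D array; fwhm in mm, voxel = mm triple.
# Zero-padded (Dirichlet) boundaries: adequate for images embedded in an
# air background.
gauss_smooth3d <- function(vol, fwhm, voxel) {
  sd_vox <- (fwhm / 2.35482) / voxel
  out <- vol
  for (ax in 1:3) {
    s <- sd_vox[ax]
    if (s < 1e-6) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r:r)^2) / (2 * s^2))
    k <- k / sum(k)
    out <- convolve_axis(out, k, ax)
  }
  out
}

# 1D convolution of a 3D array along one axis, zero-padded.
convolve_axis <- function(vol, kernel, axis) {
  d <- dim(vol)
  r <- (length(kernel) - 1L) %/% 2L
  acc <- array(0, d)
  n <- d[axis]
  for (j in seq_along(kernel)) {
    off <- j - r - 1L
    src <- seq_len(n) + off
    ok <- src >= 1L & src <= n
    if (!any(ok)) next
    dst <- which(ok)
    idx_src <- src[ok]
    if (axis == 1L) {
      acc[dst, , ] <- acc[dst, , ] + kernel[j] * vol[idx_src, , ]
    } else if (axis == 2L) {
      acc[, dst, ] <- acc[, dst, ] + kernel[j] * vol[, idx_src, ]
    } else {
      acc[, , dst] <- acc[, , dst] + kernel[j] * vol[, , idx_src]
    }
  }
  acc
}

# Downsample a 3D array by 2 along each axis (block mean); odd trailing
# voxels are dropped.
downsample2 <- function(vol) {
  d <- dim(vol) %/% 2L
  v <- vol[seq_len(2L * d[1]), seq_len(2L * d[2]), seq_len(2L * d[3])]
  i1 <- seq(1L, 2L * d[1], by = 2L)
  i2 <- seq(1L, 2L * d[2], by = 2L)
  i3 <- seq(1L, 2L * d[3], by = 2L)
  (v[i1, i2, i3] + v[i1 + 1L, i2, i3] + v[i1, i2 + 1L, i3] +
     v[i1, i2, i3 + 1L] + v[i1 + 1L, i2 + 1L, i3] + v[i1 + 1L, i2, i3 + 1L] +
     v[i1, i2 + 1L, i3 + 1L] + v[i1 + 1L, i2 + 1L, i3 + 1L]) / 8
}

# FNV-1a 32-bit hash of a character scalar, as 8 hex digits. Used for
# config fingerprints in reports (stable across platforms, no external deps).
# Arithmetic kept exact in doubles: the 32-bit product is split as
# h * 16777619 = h * 2^24 + h * 403, reduced mod 2^32 termwise.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), b)
    h <- (((h %% 256) * 16777216) %% 4294967296 + (h * 403) %% 4294967296) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# Evaluate RNG-consuming code under a fixed seed, restoring global RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
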