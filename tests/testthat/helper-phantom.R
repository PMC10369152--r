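# Shared fixtures, built in code. The cache avoids regenerating identical
# phantoms across test files within one run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Noiseless default-geometry phantom (exact generator/extractor agreement).
noiseless_phantom <- function() {
  cached("noiseless", build_phantom(phantom_spec(seed = 1, noise_sigma0 = 0)))
}

# Default-noise phantom.
noisy_phantom <- function() {
  cached("noisy", build_phantom(phantom_spec(seed = 42)))
}

# A small fast phantom for pipeline-level tests: 16x16x12 grid, 6 mm voxels.
small_phantom_spec <- function(seed, noise_sigma0 = 0.35, motion = NULL) {
  regions <- list(
    whole_striatum = list(center = rbind(c(5.5, 10, 7), c(10.5, 10, 7)),
                          semiaxes = rbind(c(1.6, 2.2, 1.8), c(1.6, 2.2, 1.8)),
                          params = kinetic_parameters(
                            K1 = 0.05, k2 = 0.04,
                            k3 = fdopapet:::k3_for_ki(0.05, 0.04, 0.0137))),
    cerebellum = list(center = c(8, 4, 3.5), semiaxes = c(3.5, 2.2, 1.8),
                      params = kinetic_parameters(0.06, 0.06, 0)),
    background = list(center = c(8, 8, 6.5), semiaxes = c(6.5, 6.5, 4.5),
                      params = kinetic_parameters(
                        K1 = 0.054, k2 = 0.06,
                        k3 = fdopapet:::k3_for_ki(0.054, 0.06, 0.0005)))
  )
  phantom_spec(dim3 = c(16, 16, 12), voxel_size = c(6, 6, 6),
               regions = regions, noise_sigma0 = noise_sigma0,
               motion = motion, seed = seed)
}

small_phantom <- function() {
  cached("small", build_phantom(small_phantom_spec(seed = 9)))
}

# Independent dense-grid 2TCM integrator (exact exponential stepping of the
# linear system on a fine time grid) used as the oracle against the package's
# ODE-based simulator and Patlak chain. Deliberately shares no code with
# simulate_tissue_tac().
oracle_2tcm <- function(K1, k2, k3, cp_fun, t_end = 95, dt = 0.005) {
  tg <- seq(0, t_end, by = dt)
  cp <- cp_fun(tg)
  lam <- k2 + k3
  n <- length(tg)
  c1 <- numeric(n)
  e <- exp(-lam * dt)
  # trapezoidal convolution step: c1[n+1] = e*c1[n] + K1*dt*(e*cp[n]+cp[n+1])/2
  for (i in seq_len(n - 1))
    c1[i + 1] <- e * c1[i] + K1 * dt * (e * cp[i] + cp[i + 1]) / 2
  c2 <- k3 * cumsum((c(0, c1[-n]) + c1) / 2) * dt
  list(t = tg, total = c1 + c2, c1 = c1, c2 = c2)
}

# Evaluate RNG-consuming code under a fixed seed, restoring global state.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  force(expr)
}

# Independent dense-grid reference Patlak slope (plain trapezoid + lm).
oracle_patlak_slope <- function(t, target, ref, t_star = 20) {
  cumref <- cumsum(c(0, (ref[-1] + ref[-length(ref)]) / 2 * diff(t)))
  ok <- ref > 1e-6 * max(ref) & t >= t_star
  x <- cumref[ok] / ref[ok]
  y <- target[ok] / ref[ok]
  unname(coef(lm(y ~ x))[2])
}
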