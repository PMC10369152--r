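test_that("the plasma input rises from zero and peaks where requested", {
  sch <- frame_schedule_fdopa()
  zero <- input_function(sch, scale = 0)
  expect_true(all(zero$value == 0))
  expect_error(input_function(sch, scale = -1), "non-negative")
  expect_error(input_function(sch, peak_time = 200), "within the scan")
  for (pk in c(0.7, 1, 2)) {
    cp <- input_function(sch, peak_time = pk, scale = 30)
    f <- attr(cp, "fun")
    expect_equal(f(0), 0)
    tg <- seq(0, 10, by = 1e-3)          # dense argmax oracle
    expect_equal(tg[which.max(f(tg))], pk, tolerance = 2e-3)
    expect_equal(max(f(tg)), 30, tolerance = 1e-6)
    expect_true(all(f(tg) >= 0))
  }
})

test_that("tissue simulation matches an independent dense-grid integrator", {
  sch <- frame_schedule_fdopa()
  cp <- input_function(sch)
  pars <- kinetic_parameters(0.05, 0.04, 0.015)
  got <- simulate_tissue_tac(pars, cp, sch)
  orc <- oracle_2tcm(0.05, 0.04, 0.015, attr(cp, "fun"))
  at_mid <- approx(orc$t, orc$total, xout = sch$mid)$y
  expect_equal(got$value, at_mid, tolerance = 1e-5)
})

test_that("tissue simulation limit cases: zero delivery and 1TCM step response", {
  sch <- frame_schedule_fdopa()
  cp <- input_function(sch)
  expect_equal(simulate_tissue_tac(kinetic_parameters(0, 0.05), cp, sch)$value,
               rep(0, 32))
  # constant infusion, one-tissue: closed form K1/k2*(1-exp(-k2 t))
  step_cp <- function(t) as.numeric(t > 0)
  got <- simulate_tissue_tac(kinetic_parameters(0.06, 0.06), step_cp, sch)
  closed <- 0.06 / 0.06 * (1 - exp(-0.06 * sch$mid))
  expect_equal(got$value, closed, tolerance = 1e-6)
  expect_equal(got$value[32] / 1, 0.06 / 0.06, tolerance = 5e-3)
  # linearity in the plasma scale
  twice <- simulate_tissue_tac(kinetic_parameters(0.06, 0.06),
                               function(t) 2 * step_cp(t), sch)
  expect_equal(twice$value, 2 * got$value, tolerance = 1e-9)
})

test_that("patlak-consistent TACs are exact constructions", {
  sch <- frame_schedule_fdopa()
  ref <- simulate_tissue_tac(kinetic_parameters(0.06, 0.06), input_function(sch),
                             sch)
  flat <- patlak_consistent_tac(ref, ki = 0, intercept = 1)
  expect_equal(flat$value, ref$value)                    # intercept 1, Ki 0
  scaled <- patlak_consistent_tac(ref, ki = 0, intercept = 2.5)
  expect_equal(scaled$value, 2.5 * ref$value)
})

test_that("phantoms are deterministic and agree with their ground truth", {
  a <- build_phantom(small_phantom_spec(seed = 4))
  b <- build_phantom(small_phantom_spec(seed = 4))
  expect_identical(a$image$data, b$image$data)
  c <- build_phantom(small_phantom_spec(seed = 5))
  expect_false(identical(a$image$data, c$image$data))
  # noiseless, motion-free: regional TACs equal the generator's exactly
  ph <- noiseless_phantom()
  for (rg in names(ph$truth$tacs)) {
    got <- extract_tac(ph$image, ph$labels, rg)
    expect_equal(got$value, ph$truth$tacs[[rg]]$value, tolerance = 1e-12)
  }
  expect_equal(ph$truth$regions$whole_striatum$ki_cer, 0.0137, tolerance = 1e-9)
  expect_error(phantom_spec(seed = NULL), "seed")
})

test_that("motion injection is exact for identity and integer-voxel shifts", {
  ph <- small_phantom()
  nf <- dim(ph$image$data)[4]
  ident <- replicate(nf, rigid_transform(), simplify = FALSE)
  expect_equal(inject_motion(ph$image, ident)$data, ph$image$data)
  expect_error(inject_motion(ph$image, ident[-1]), "transforms")
  # one-voxel x translation: exact shifted copy inside the field of view
  tfs <- ident
  tfs[[20]] <- rigid_transform(c(6, 0, 0))   # +1 voxel at 6 mm
  moved <- inject_motion(ph$image, tfs)
  expect_equal(moved$data[1:15, , , 20], ph$image$data[2:16, , , 20],
               tolerance = 1e-12)
  # t then -t returns the original within interpolation tolerance; assessed
  # on a band-limited volume (trilinear error grows with curvature per
  # voxel, so the bound is a property of adequately sampled images)
  xg <- rep(1:32, times = 32 * 24)
  yg <- rep(rep(1:32, each = 32), times = 24)
  zg <- rep(1:24, each = 32 * 32)
  blob <- exp(-((xg - 12)^2 + (yg - 20)^2 + (zg - 12)^2) / (2 * 6^2)) +
    0.6 * exp(-((xg - 22)^2 + (yg - 10)^2 + (zg - 14)^2) / (2 * 7^2))
  smooth_img <- dynamic_image(array(blob, c(32, 32, 24, 1)), c(4, 4, 4),
                              frame_schedule(0, 1))
  fwd <- list(rigid_transform(c(2.7, -1.9, 1.1)))
  bwd <- list(rigid_transform(c(-2.7, 1.9, -1.1)))
  round_trip <- inject_motion(inject_motion(smooth_img, fwd), bwd)
  rng <- diff(range(smooth_img$data))
  err <- max(abs(round_trip$data[4:29, 4:29, 4:21, 1] -
                   smooth_img$data[4:29, 4:29, 4:21, 1]))
  expect_lt(err, 0.02 * rng)
})

test_that("phantom writer emits files pet_io can read back", {
  dir <- withr::local_tempdir()
  write_phantom(small_phantom(), dir)
  expect_true(all(file.exists(file.path(dir, c("dynamic.nii.gz",
                                               "dynamic.json",
                                               "labels.nii.gz",
                                               "ground_truth.json")))))
  img <- read_dynamic(file.path(dir, "dynamic.nii.gz"))
  expect_equal(dim(img$data), dim(small_phantom()$image$data))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$seed, 9)
  expect_equal(gt$regions$whole_striatum$ki_cer, 0.0137, tolerance = 1e-9)
})
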