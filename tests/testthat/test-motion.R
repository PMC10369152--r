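test_that("rigid transforms compose and invert exactly", {
  expect_error(rigid_transform(rotation = c(4, 0, 0)), "pi")
  set.seed(2)
  for (i in 1:20) {
    tf <- rigid_transform(runif(3, -5, 5), runif(3, -0.3, 0.3))
    ident <- compose_transforms(tf, invert_transform(tf))
    expect_lt(max(abs(as.numeric(ident))), 1e-9)
  }
})

test_that("framewise displacement combines translation and arc length", {
  ident <- replicate(3, rigid_transform(), simplify = FALSE)
  expect_equal(framewise_displacement(ident), c(0, 0))
  step <- list(rigid_transform(), rigid_transform(c(3, 4, 0)))
  expect_equal(framewise_displacement(step), 5)
  expect_equal(framewise_displacement(step, radius = 10), 5)
  yaw <- list(rigid_transform(), rigid_transform(rotation = c(0, 0, 0.02)))
  expect_equal(framewise_displacement(yaw, radius = 50), 1.0)
  expect_equal(framewise_displacement(yaw, radius = 50,
                                      mode = "to_reference"), c(0, 1.0))
  expect_error(framewise_displacement(ident[1]), "two transforms")
})

test_that("spike detection counts strict threshold crossings", {
  qc <- detect_spikes(c(0.2, 1.0, 6.1, 0.4), threshold = 5)
  expect_equal(qc$n_spikes, 1L)
  expect_true(qc$flagged)
  expect_equal(qc$total_motion, sum(c(0.2, 1.0, 6.1, 0.4)))
  expect_equal(qc$max_fd, 6.1)
  zero <- detect_spikes(rep(0, 5))
  expect_equal(zero$n_spikes, 0L)
  expect_false(zero$flagged)
  expect_error(detect_spikes(c(1, -0.1)), ">= 0")
  # spike counts are non-increasing in the threshold
  set.seed(3)
  fd <- rexp(50, 1 / 3)
  counts <- vapply(seq(0, 12, by = 0.5),
                   function(th) detect_spikes(fd, th)$n_spikes, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("total motion is additive over concatenated series", {
  set.seed(4)
  a <- rexp(10); b <- rexp(7)
  expect_equal(detect_spikes(c(a, b))$total_motion,
               detect_spikes(a)$total_motion + detect_spikes(b)$total_motion)
})

test_that("the scan-level gate fails at the 8 mm max-displacement limit", {
  pass <- qc_motion(detect_spikes(c(1, 7.9)))
  expect_true(pass$pass)
  fail <- qc_motion(detect_spikes(c(1, 8.0)))
  expect_false(fail$pass)
  expect_match(fail$reasons, "8.0 mm limit", fixed = TRUE)
  # permutation invariance
  set.seed(5)
  fd <- runif(8, 0, 10)
  expect_equal(qc_motion(detect_spikes(fd))$pass,
               qc_motion(detect_spikes(sample(fd)))$pass)
})

test_that("a motion-free noiseless scan realigns to identity", {
  ph <- noiseless_phantom()
  ra <- realign_frames(ph$image)
  expect_equal(ra$reference, which.min(abs(ph$image$schedule$mid - 15)))
  fd <- framewise_displacement(ra$transforms)
  expect_true(all(fd < 0.1))
  # pre-arrival frames are reported, not silently registered
  expect_true(all(ph$image$schedule$mid[ra$low_signal] < 2))
})

test_that("injected translations and rotations are recovered at default noise", {
  ph <- noisy_phantom()
  nf <- dim(ph$image$data)[4]
  tfs <- replicate(nf, rigid_transform(), simplify = FALSE)
  tfs[[22]] <- rigid_transform(c(3, 0, 0))                     # 3 mm x-shift
  tfs[[27]] <- rigid_transform(rotation = c(0, 0, 2 * pi / 180))  # 2 deg yaw
  spec <- phantom_spec(seed = 42, motion = tfs)
  moved <- build_phantom(spec)
  ra <- realign_frames(moved$image, frames = c(22L, 27L))
  est22 <- as.numeric(ra$transforms[[22]])
  expect_equal(sqrt(sum(est22[1:3]^2)), 3, tolerance = 0.5 / 3)
  est27 <- as.numeric(ra$transforms[[27]])
  expect_lt(abs(abs(est27[6]) * 180 / pi - 2), 0.5)
  # untouched frames in the subset convention stay identity
  expect_true(is_identity_transform(ra$transforms[[10]]))
})

test_that("apply_transforms reproduces the realigned series and validates input", {
  ph <- small_phantom()
  nf <- dim(ph$image$data)[4]
  ident <- replicate(nf, rigid_transform(), simplify = FALSE)
  expect_equal(apply_transforms(ph$image, ident)$data, ph$image$data)
  expect_error(apply_transforms(ph$image, ident[-1]), "transforms")
  tfs <- ident; tfs[[15]] <- rigid_transform(c(2, -1, 0.5), c(0.01, 0, -0.02))
  moved <- inject_motion(ph$image, tfs)
  # same transforms on a second series give the same voxel values
  again <- apply_transforms(ph$image, tfs)
  expect_equal(again$data, moved$data)
})

test_that("realignment is idempotent on a noiseless scan", {
  ph <- noiseless_phantom()
  ra1 <- realign_frames(ph$image)
  ra2 <- realign_frames(ra1$image)
  p <- t(vapply(ra2$transforms, as.numeric, numeric(6)))
  expect_lt(max(sqrt(rowSums(p[, 1:3, drop = FALSE]^2))), 0.2)
  expect_lt(max(sqrt(rowSums(p[, 4:6, drop = FALSE]^2))) * 180 / pi, 0.2)
})
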