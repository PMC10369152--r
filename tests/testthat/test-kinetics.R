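test_that("the Patlak transform matches hand-computed trapezoid arithmetic", {
  # 3-point TAC: mids 1, 2, 4; ref 2, 4, 4; implicit (0,0) at injection
  ref <- tac(c(1, 2, 4), c(2, 4, 4), "ref")
  tgt <- tac(c(1, 2, 4), c(1, 3, 9), "roi")
  pts <- patlak_transform(tgt, ref)
  # cumulative integrals: 0.5*1*2 = 1; 1 + 0.5*1*(2+4) = 4; 4 + 0.5*2*(4+4) = 12
  expect_equal(pts$x, c(1 / 2, 4 / 4, 12 / 4))
  expect_equal(pts$y, c(1 / 2, 3 / 4, 9 / 4))
  expect_equal(attr(pts, "n_dropped"), 0L)
  # target == ref: y is exactly one everywhere
  same <- patlak_transform(ref, ref)
  expect_true(all(same$y == 1))
})

test_that("zero-reference points are dropped and an empty plot errors", {
  ref <- tac(1:5, c(0, 0, 2, 2, 2), "ref")
  tgt <- tac(1:5, rep(1, 5), "roi")
  pts <- patlak_transform(tgt, ref)
  expect_equal(nrow(pts), 3L)
  expect_equal(attr(pts, "n_dropped"), 2L)
  dead <- tac(1:5, rep(0, 5), "ref")
  expect_error(patlak_transform(tgt, dead), "dropped")
  expect_error(patlak_transform(tac(1:4, 1:4), ref), "mid-times")
})

test_that("a constant reference makes normalized time approach real time", {
  ref <- tac(seq(5, 90, by = 5), rep(3, 18), "ref")
  pts <- patlak_transform(ref, ref)
  # hand arithmetic: the rise from the implicit (0,0) costs a constant 2.5,
  # so x = t - 2.5 exactly and x/t -> 1 as t grows
  expect_equal(pts$x, pts$mid - 2.5, tolerance = 1e-12)
  expect_equal(pts$x[18] / pts$mid[18], 1, tolerance = 0.05)
})

test_that("patlak_fit equals the brute-force normal equations", {
  set.seed(7)
  ref <- tac(seq(2, 90, by = 4), 5 * exp(-0.01 * seq(2, 90, by = 4)), "ref")
  tgt <- patlak_consistent_tac(ref, 0.012, 1.2)
  tgt$value <- tgt$value * (1 + rnorm(nrow(tgt), 0, 0.02))
  pts <- patlak_transform(tgt, ref)
  fit <- patlak_fit(pts, t_star = 20)
  sel <- pts[pts$mid >= 20, ]
  X <- cbind(1, sel$x)
  beta <- solve(t(X) %*% X, t(X) %*% sel$y)     # independent oracle
  expect_equal(fit$intercept, beta[1], tolerance = 1e-12)
  expect_equal(fit$ki, beta[2], tolerance = 1e-12)
  expect_equal(fit$n_points, nrow(sel))
})

test_that("identical target and reference fit to slope 0, intercept 1", {
  ref <- tac(seq(2, 90, by = 4), 5 * exp(-0.01 * seq(2, 90, by = 4)), "ref")
  fit <- patlak_fit(patlak_transform(ref, ref))
  expect_equal(fit$ki, 0, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  short <- patlak_transform(ref, ref)[1:4, ]
  class(short) <- c("patlak_points", "data.frame")
  expect_error(patlak_fit(short, t_star = 20), ">= 3 Patlak points")
})

test_that("estimated Ki rises strictly with the trapping rate", {
  sch <- frame_schedule_fdopa()
  cp <- input_function(sch)
  ref <- simulate_tissue_tac(kinetic_parameters(0.06, 0.06), cp, sch, "cer")
  slopes <- vapply(c(0.005, 0.01, 0.015, 0.02, 0.025), function(k3) {
    tgt <- simulate_tissue_tac(kinetic_parameters(0.05, 0.04, k3), cp, sch)
    patlak_fit(patlak_transform(tgt, ref))$ki
  }, 0)
  expect_true(all(diff(slopes) > 0))
})

test_that("Ki, intercept and SUVr are invariant to global rescaling", {
  ph <- small_phantom()
  fit1 <- patlak_region(ph$image, ph$labels, "whole_striatum")
  sv1 <- suvr(ph$image, ph$labels, "whole_striatum")
  scaled <- ph$image
  scaled$data <- scaled$data * 37          # kBq -> nCi, say
  fit2 <- patlak_region(scaled, ph$labels, "whole_striatum")
  sv2 <- suvr(scaled, ph$labels, "whole_striatum")
  expect_equal(fit2$ki, fit1$ki, tolerance = 1e-9)
  expect_equal(fit2$intercept, fit1$intercept, tolerance = 1e-9)
  expect_equal(sv2$suvr, sv1$suvr, tolerance = 1e-9)
})

test_that("voxelwise fitting handles dead voxels and matches the region fit", {
  ph <- small_phantom()
  ref <- extract_tac(ph$image, ph$labels, "cerebellum")
  mask <- ph$labels$labels > 0L
  pm <- patlak_voxelwise(ph$image, ref, mask, tv = NULL)
  expect_true(all(is.na(pm$ki_map[!mask])))
  expect_true(all(is.finite(pm$ki_map[mask])))
  fit <- patlak_region(ph$image, ph$labels, "whole_striatum")
  vox_mean <- mean(pm$ki_map[ph$labels$labels == 1L])
  expect_lt(abs(vox_mean - fit$ki), 0.05 * abs(fit$ki))
  # zeroed dynamic inside the mask: NaN voxels, no crash
  dead <- ph$image
  dead$data[8, 8, 6, ] <- 0
  pm2 <- patlak_voxelwise(dead, ref, mask, tv = NULL)
  expect_true(is.na(pm2$ki_map[8, 8, 6]))
  expect_error(patlak_voxelwise(ph$image, ref, array(FALSE, dim(mask))),
               "empty")
})

test_that("duration weighting is a no-op when late frames share one duration", {
  # all default late frames are 300 s, so the weighted fit must agree
  ph <- small_phantom()
  ref <- extract_tac(ph$image, ph$labels, "cerebellum")
  mask <- ph$labels$labels > 0L
  plain <- patlak_voxelwise(ph$image, ref, mask, tv = NULL)
  weighted <- patlak_voxelwise(ph$image, ref, mask, tv = NULL,
                               weight_frames = TRUE)
  expect_equal(weighted$ki_map, plain$ki_map, tolerance = 1e-12)
})

test_that("vanishing TV weight leaves the voxelwise maps unchanged", {
  ph <- small_phantom()
  ref <- extract_tac(ph$image, ph$labels, "cerebellum")
  mask <- ph$labels$labels > 0L
  plain <- patlak_voxelwise(ph$image, ref, mask, tv = NULL)
  tiny <- patlak_voxelwise(ph$image, ref, mask,
                           tv = list(weight = 1e-12, max_iter = 50))
  expect_lt(max(abs(plain$ki_map - tiny$ki_map), na.rm = TRUE), 1e-6)
})

test_that("SUVr is a windowed activity ratio with overlap weighting", {
  ph <- small_phantom()
  one <- suvr(ph$image, ph$labels, "cerebellum", "cerebellum")
  expect_equal(one$suvr, 1)
  doubled <- ph$image
  doubled$data <- doubled$data * 2
  # doubling the whole image leaves the ratio, but scaling only the target
  # region doubles it
  lab <- ph$labels$labels
  tgt_scaled <- ph$image
  for (f in seq_len(dim(tgt_scaled$data)[4])) {
    fr <- tgt_scaled$data[, , , f]
    fr[lab == 1L] <- 2 * fr[lab == 1L]
    tgt_scaled$data[, , , f] <- fr
  }
  expect_equal(suvr(tgt_scaled, ph$labels, "whole_striatum")$suvr,
               2 * suvr(ph$image, ph$labels, "whole_striatum")$suvr,
               tolerance = 1e-12)
  expect_error(suvr(ph$image, ph$labels, "whole_striatum", window = c(200, 300)),
               "overlap")
  zero <- ph$image; zero$data[] <- 0
  expect_error(suvr(zero, ph$labels, "whole_striatum"), "not positive")
})
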