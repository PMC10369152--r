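test_that("frame schedules enforce ordering and non-overlap", {
  expect_error(frame_schedule(c(0, 1), c(0.5, -1)), "positive")
  expect_error(frame_schedule(c(0, 2, 1), rep(0.5, 3)), "increasing")
  expect_error(frame_schedule(c(0, 0.4), c(0.5, 0.5)), "overlap")
  sch <- frame_schedule(c(0, 0.5, 1), c(0.5, 0.5, 2))
  expect_equal(sch$mid, c(0.25, 0.75, 2))
})

test_that("the bolus FDOPA framing covers 95 minutes in 32 frames", {
  sch <- frame_schedule_fdopa()
  expect_equal(nrow(sch), 32L)
  expect_equal(sum(sch$duration), 95)
  expect_equal(scan_duration(sch), 95)
  expect_true(all(diff(sch$mid) > 0))
})

test_that("dynamic volumes round-trip through NIfTI + sidecar", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dyn.nii.gz")
  write_dynamic(ph$image, path, extra = list(TracerName = "FDOPA"))
  back <- read_dynamic(path)
  expect_equal(back$data, unclass(ph$image$data), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$schedule$start, ph$image$schedule$start)
  expect_equal(back$schedule$duration, ph$image$schedule$duration)
  expect_equal(back$voxel_size, ph$image$voxel_size)
  expect_true(back$decay_corrected)
})

test_that("timing sidecars with inconsistent frame counts are rejected", {
  ph <- small_phantom()
  dir <- withr::local_tempdir()
  path <- file.path(dir, "dyn.nii.gz")
  write_dynamic(ph$image, path)
  side <- jsonlite::read_json(file.path(dir, "dyn.json"),
                              simplifyVector = TRUE)
  side$FrameDuration <- side$FrameDuration[-1]
  jsonlite::write_json(side, file.path(dir, "bad.json"), auto_unbox = TRUE)
  expect_error(read_dynamic(path, file.path(dir, "bad.json")), "length")
  side$FrameDuration <- NULL
  jsonlite::write_json(side, file.path(dir, "bad2.json"), auto_unbox = TRUE)
  expect_error(read_dynamic(path, file.path(dir, "bad2.json")),
               "FrameDuration")
})

test_that("decay correction uses frame mid-times and is invertible", {
  sch <- frame_schedule(c(0, 100), c(10, 19.54))
  img <- dynamic_image(array(100, c(2, 2, 2, 2)), c(2, 2, 2), sch)
  hl <- 109.77
  cor <- decay_correct(img, hl)
  expect_equal(cor$data[1, 1, 1, 1], 100 * 2^(5 / hl))
  expect_equal(cor$data[1, 1, 1, 2], 200)   # mid = 109.77 = one half-life
  expect_true(cor$decay_corrected)
  expect_error(decay_correct(cor, hl), "already")
  # infinite half-life leaves data unchanged
  same <- decay_correct(img, Inf)
  expect_equal(same$data, img$data)
  # applying the inverse factor restores the input to 1e-12
  fac <- 2^(-sch$mid / hl)
  back <- cor$data
  for (f in 1:2) back[, , , f] <- back[, , , f] * fac[f]
  expect_equal(back, img$data, tolerance = 1e-12)
})

test_that("frame summation is duration-weighted with mid-time membership", {
  sch <- frame_schedule(c(0, 1), c(1, 2))
  arr <- array(0, c(2, 2, 1, 2))
  arr[, , , 1] <- 3; arr[, , , 2] <- 6
  img <- dynamic_image(arr, c(4, 4, 4), sch)
  expect_equal(sum_frames(img)[1, 1, 1], 3 * 1 + 6 * 2)   # hand arithmetic
  expect_equal(sum_frames(img, c(0, 1))[1, 1, 1], 3)      # one frame x 1 min
  uni <- dynamic_image(array(1, c(2, 2, 1, 2)), c(4, 4, 4), sch)
  expect_equal(sum_frames(uni)[2, 2, 1], sum(sch$duration))
  expect_error(sum_frames(img, c(10, 11)), "no frame")
  expect_error(sum_frames(img, c(2, 1)), "t1 > t0")
})

test_that("TAC extraction means over the region and is linear in the image", {
  sch <- frame_schedule(0, 1)
  lab <- array(0L, c(2, 2, 1)); lab[1, 1, 1] <- 1L; lab[2, 1, 1] <- 1L
  labels <- label_volume(lab, c(roi = 1))
  arr <- array(0, c(2, 2, 1, 1)); arr[1, 1, 1, 1] <- 1; arr[2, 1, 1, 1] <- 3
  img <- dynamic_image(arr, c(4, 4, 4), sch)
  expect_equal(extract_tac(img, labels, "roi")$value, 2)
  expect_error(extract_tac(img, labels, "nope"), "unknown region")
  # uniform image -> constant TAC
  uni <- dynamic_image(array(7, c(2, 2, 1, 1)), c(4, 4, 4), sch)
  expect_equal(extract_tac(uni, labels, "roi")$value, 7)
  # linearity
  a <- 2.5; b <- -1.25
  arr2 <- array(stats::runif(4), c(2, 2, 1, 1))
  img2 <- dynamic_image(arr2, c(4, 4, 4), sch)
  comb <- dynamic_image(a * arr + b * arr2, c(4, 4, 4), sch)
  expect_equal(extract_tac(comb, labels, "roi")$value,
               a * extract_tac(img, labels, "roi")$value +
                 b * extract_tac(img2, labels, "roi")$value,
               tolerance = 1e-12)
})

test_that("label volumes validate their name map", {
  lab <- array(0L, c(2, 2, 2)); lab[1, 1, 1] <- 1L
  expect_error(label_volume(lab, c(roi = 2)), "not present")
  expect_error(label_volume(lab, c(bad = 0)), "background")
  lv <- label_volume(lab, c(roi = 1))
  expect_equal(names(lv$names), "roi")
})

test_that("TAC CSV export writes one row per region frame", {
  tc <- tac(c(1, 2, 3), c(0.5, 1, 2), region = "whole_striatum")
  path <- withr::local_tempfile(fileext = ".csv")
  write_tac_csv(tc, path)
  got <- utils::read.csv(path)
  expect_equal(names(got), c("region", "frame", "mid_min", "activity"))
  expect_equal(got$activity, c(0.5, 1, 2))
})
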