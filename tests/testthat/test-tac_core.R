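test_that("frame schedules enforce ordering, overlap and length invariants", {
  fs <- frame_schedule(c(0, 1, 2), c(1, 2, 4))
  expect_equal(mid_times(fs), c(0.5, 1.5, 3))
  expect_equal(frame_durations(fs), c(1, 1, 2))
  expect_error(frame_schedule(0, 1), "at least 2")
  expect_error(frame_schedule(c(0, 1), c(1, 0.5)), "end > start")
  expect_error(frame_schedule(c(0, 0.5), c(1, 2)), "overlap")
  expect_error(frame_schedule(c(1, 0), c(2, 1)), "sorted")
})

test_that("SUV conversion follows the dose/weight definition and is linear", {
  fs <- frame_schedule(c(0, 1), c(1, 2))
  t1 <- tac(fs, c(100, 40), "HC")
  s1 <- to_suv(t1, injected_activity = 10, body_weight = 25)
  expect_equal(s1$values, c(0.25, 0.10))
  expect_identical(s1$units, "SUV")
  expect_equal(s1$schedule, t1$schedule)

  # zero activity stays zero
  z <- to_suv(tac(fs, c(0, 0), "HC"), 10, 25)
  expect_equal(z$values, c(0, 0))

  # linearity: to_suv(a * C) = a * to_suv(C)
  a <- 3.7
  s2 <- to_suv(tac(fs, a * c(100, 40), "HC"), 10, 25)
  expect_equal(s2$values, a * s1$values)

  # algebraic inverse round trip
  back <- from_suv(s1, 10, 25)
  expect_equal(back$values, t1$values, tolerance = 1e-12)
  expect_identical(back$units, "kBq/mL")

  expect_error(to_suv(t1, -1, 25), "invalid metadata")
  expect_error(to_suv(t1, 10, 0), "invalid metadata")
  expect_error(to_suv(s1, 10, 25), "unit mismatch")
  expect_error(from_suv(t1, 10, 25), "unit mismatch")
})

test_that("decay correction uses the mid-time exponent", {
  # one half-life elapsed doubles the value
  fs <- frame_schedule(c(100, 119.54), c(119.54, 139.08))
  hl <- 109.77
  fs1 <- frame_schedule(c(hl - 1, hl + 1), c(hl + 1, hl + 3))
  expect_equal(decay_correct(c(1, 1), fs1, hl)[1], 2)
  # reference_time at the mid-time leaves the value unchanged
  expect_equal(decay_correct(5, frame_schedule(c(2, 4), c(4, 6)), 20,
                             reference_time = 3)[1], 5)
  # F-18, half a half-life: factor sqrt(2)
  fs2 <- frame_schedule(c(54.885 - 1, 56), c(56, 58))
  fs2 <- frame_schedule(c(53.885, 56), c(55.885, 58))
  expect_equal(decay_correct(c(1, 1), fs2, 109.77)[1], sqrt(2),
               tolerance = 1e-12)
  expect_error(decay_correct(1:2, fs, -1), "positive")
})

test_that("ROI extraction equals a brute-force voxel loop and flags missing codes", {
  set.seed(11)
  img <- array(runif(8 * 8 * 8 * 10), dim = c(8, 8, 8, 10))
  atl <- array(sample(0:3, 8 * 8 * 8, replace = TRUE), dim = c(8, 8, 8))
  rs <- region_set(labels = c("A", "B", "C"), codes = 1:3)
  fs <- frame_schedule(0:9, 1:10)
  tacs <- extract_roi_tacs(img, atl, rs, fs)
  for (i in 1:3)
    expect_equal(tacs[[c("A", "B", "C")[i]]]$values,
                 brute_roi_means(img, atl, i))

  # uniform image: every region TAC is constant
  img2 <- array(rep(seq_len(10), each = 8^3) * 0 + 2.5, dim = c(8, 8, 8, 10))
  t2 <- extract_roi_tacs(img2, atl, rs, fs)
  expect_true(all(vapply(t2, function(x) all(x$values == 2.5), logical(1))))

  # single-voxel region reproduces that voxel's time course
  atl3 <- array(1L, dim = c(4, 4, 4))
  atl3[2, 3, 1] <- 2L
  img3 <- array(rnorm(4 * 4 * 4 * 5), dim = c(4, 4, 4, 5))
  t3 <- extract_roi_tacs(abs(img3), atl3,
                         region_set(labels = c("A", "B"), codes = 1:2),
                         frame_schedule(0:4, 1:5))
  expect_equal(t3$B$values, abs(img3)[2, 3, 1, ])

  # WB is the union of the other region codes
  rs_wb <- region_set(labels = c("A", "B", "WB"), codes = c(1, 2, 99))
  atl4 <- atl3
  img4 <- abs(img3)
  t4 <- extract_roi_tacs(img4, atl4, rs_wb, frame_schedule(0:4, 1:5))
  expect_equal(t4$WB$values,
               sapply(1:5, function(f) mean(img4[, , , f][atl4 %in% 1:2])))

  expect_error(extract_roi_tacs(img, atl, region_set(labels = "Z", codes = 9L),
                                fs), "not found in atlas")
})

test_that("TAC tables round-trip through CSV + sidecar losslessly", {
  scan <- fix_scan()
  path <- file.path(tempdir(), "m01_tacs.csv")
  write_tacs(scan, path)
  back <- read_tacs(path)
  expect_equal(back$subject_id, "m01")
  expect_equal(back$genotype, "WT")
  expect_equal(back$injected_activity, 8)
  expect_equal(back$body_weight, 25)
  expect_equal(back$reference_region, "BS")
  expect_equal(back$tacs$HC$values, scan$tacs$HC$values)
  expect_equal(back$schedule$start, scan$schedule$start)

  # second-generation write is byte-identical (9-significant-digit printing)
  path2 <- file.path(tempdir(), "m01b_tacs.csv")
  write_tacs(back, path2)
  expect_identical(readLines(path), readLines(path2))

  # values with many digits survive one write/read to printed precision
  scan$tacs$HC$values <- scan$tacs$HC$values * pi
  write_tacs(scan, path)
  expect_equal(read_tacs(path)$tacs$HC$values, scan$tacs$HC$values,
               tolerance = 1e-8)
  unlink(c(path, path2, sidecar_paths <- sub("csv$", "meta.json", c(path, path2))))
})

test_that("malformed TAC tables and sidecars are rejected with field names", {
  scan <- fix_scan()
  path <- file.path(tempdir(), "bad_tacs.csv")
  write_tacs(scan, path)
  meta_path <- sub("\\.csv$", ".meta.json", path)

  # overlapping / inverted frames rejected
  tab <- read.csv(path, check.names = FALSE)
  tab$frame_end_min[2] <- tab$frame_start_min[2] - 0.5
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  expect_error(read_tacs(path), "end > start")

  # missing sidecar field named in the error
  write_tacs(scan, path)
  meta <- jsonlite::read_json(meta_path)
  meta$body_weight_g <- NULL
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  expect_error(read_tacs(path), "body_weight_g")

  # unknown units rejected
  meta$body_weight_g <- 25
  meta$units <- "Ci/furlong"
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE)
  expect_error(read_tacs(path), "units")
  unlink(c(path, meta_path))
})

test_that("subject scans validate reference region and schedule sharing", {
  fs <- frame_schedule(c(0, 1), c(1, 2))
  tacs <- list(BS = tac(fs, c(1, 2), "BS"), HC = tac(fs, c(2, 3), "HC"))
  expect_error(subject_scan("x", "WT", 8, 25, tacs, reference_region = "TH"),
               "not present")
  tacs2 <- tacs
  tacs2$HC <- tac(frame_schedule(c(0, 2), c(2, 4)), c(2, 3), "HC")
  expect_error(subject_scan("x", "WT", 8, 25, tacs2), "share one frame")
  expect_error(subject_scan("x", "WT", -8, 25, tacs), "positive")
})

test_that("ROI extraction accepts NIfTI volumes with an external schedule", {
  skip_if_not_installed("RNifti")
  set.seed(3)
  img <- array(runif(4 * 4 * 3 * 5), dim = c(4, 4, 3, 5))
  atl <- array(sample(1:2, 4 * 4 * 3, replace = TRUE), dim = c(4, 4, 3))
  ipath <- file.path(tempdir(), "dyn.nii.gz")
  apath <- file.path(tempdir(), "atlas.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(img), ipath)
  RNifti::writeNifti(RNifti::asNifti(atl), apath)
  fs <- frame_schedule(0:4, 1:5)
  rs <- region_set(labels = c("A", "B"), codes = 1:2)
  from_file <- extract_roi_tacs(ipath, apath, rs, fs)
  from_array <- extract_roi_tacs(img, atl, rs, fs)
  expect_equal(from_file$A$values, from_array$A$values, tolerance = 1e-6)
  expect_equal(from_file$B$values, from_array$B$values, tolerance = 1e-6)
  unlink(c(ipath, apath))
})
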