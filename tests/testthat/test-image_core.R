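test_that("slice and volume constructors enforce their invariants", {
  expect_error(knee_slice(matrix(1, 4, 4)), "at least 8x8")
  expect_error(knee_slice(matrix(-1, 8, 8)), "non-negative")
  expect_error(knee_slice(matrix(c(NA, rep(1, 63)), 8, 8)), "finite")
  s1 <- knee_slice(matrix(1:64, 8, 8), modality = "MR", plane = "sagittal")
  s2 <- knee_slice(matrix(1:100, 10, 10), modality = "MR", plane = "sagittal")
  expect_error(knee_volume(list(s1, s2)), "mixed slice shapes")
  v <- knee_volume(list(s1, s1, s1), subject_id = "t")
  expect_equal(v$n_slices, 3L)
  expect_equal(vapply(v$slices, `[[`, integer(1), "index"), 1:3)
})

test_that("png-stack reading orders slices by file name", {
  d <- withr::local_tempdir()
  set.seed(4)
  mats <- replicate(5, matrix(runif(64), 8, 8), simplify = FALSE)
  for (i in 1:5)
    png::writePNG(mats[[i]], file.path(d, sprintf("s%02d.png", i)))
  v <- read_volume(d, "png-stack", modality = "MR", plane = "sagittal")
  expect_equal(v$n_slices, 5L)
  # 8-bit quantization on write
  expect_lt(max(abs(v$slices[[1]]$pixels - mats[[1]])), 1 / 254)
  expect_error(read_volume(withr::local_tempdir(), "png-stack"), "no PNG")
  expect_error(read_volume(d, "dicom-series"), "DICOM")
})

test_that("volume round-trips through NIfTI and PNG preserve pixels", {
  ph <- fix_sag
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(ph$volume, f, "nifti")
  v2 <- read_volume(f, "nifti", modality = "MR", plane = "sagittal")
  expect_equal(v2$n_slices, ph$volume$n_slices)
  expect_equal(v2$slices[[3]]$pixels, ph$volume$slices[[3]]$pixels,
               tolerance = 1e-6)
  # PNG: written min-max scaled to [0,1] at 8 bits
  nv <- knee_volume(lapply(ph$volume$slices, normalize_intensity), "n")
  d <- withr::local_tempdir()
  write_volume(nv, d, "png-stack")
  v3 <- read_volume(d, "png-stack", modality = "MR", plane = "sagittal")
  expect_lt(max(abs(v3$slices[[2]]$pixels - nv$slices[[2]]$pixels)), 1 / 254)
})

test_that("resampling is identity at the source size and preserves content", {
  s <- ramp_noise_slice(64)
  expect_identical(resample_slice(s, 64, 64)$pixels, s$pixels)
  flat <- knee_slice(matrix(7, 64, 64))
  up <- resample_slice(flat, 256, 256)
  expect_true(all(abs(up$pixels - 7) < 1e-9))
  # checkerboard: mean intensity preserved within 1% on upsampling
  cb <- knee_slice(matrix((outer(1:128, 1:128, "+") %% 2) * 10, 128, 128))
  up2 <- resample_slice(cb, 256, 256)
  expect_equal(mean(up2$pixels), mean(cb$pixels), tolerance = 0.01)
  # idempotent at the target size
  expect_identical(resample_slice(up2, 256, 256)$pixels, up2$pixels)
})

test_that("intensity normalization maps to [0,1] with zero-constant convention", {
  s <- knee_slice(matrix(c(100, 300, 200, seq(110, 290, length.out = 61)),
                         8, 8))
  n <- normalize_intensity(s)
  expect_equal(range(n$pixels), c(0, 1))
  expect_equal(n$pixels[3], 0.5)
  flat <- normalize_intensity(knee_slice(matrix(42, 8, 8)))
  expect_true(all(flat$pixels == 0))
  # already-normalized input is unchanged
  expect_equal(normalize_intensity(n)$pixels, n$pixels)
})

test_that("nearest-neighbour mask resampling keeps masks binary", {
  m <- matrix(0, 64, 64); m[20:40, 25:45] <- 1
  up <- resample_mask(m, 256, 256)
  expect_true(all(up %in% c(0, 1)))
  back <- resample_mask(up, 64, 64)
  expect_equal(back, m)
})
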