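test_that("NIfTI label maps round-trip bitwise with geometry preserved", {
  set.seed(11)
  arr <- array(as.integer(runif(6 * 12 * 10) > 0.5), c(6, 12, 10))
  lv <- labelVolume(arr, pixelSpacing = c(0.75, 0.5), sliceDistance = 2,
                    origin = c(5, -3, 12))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeLabelmap(lv, path)
  rt <- readLabelmap(path)
  expect_identical(labelArray(rt), labelArray(lv))
  expect_equal(pixelSpacing(rt), c(0.75, 0.5), tolerance = 1e-6)
  expect_equal(sliceDistance(rt), 2, tolerance = 1e-6)
  expect_equal(originMm(rt), c(5, -3, 12), tolerance = 1e-5)
})

test_that("non-binary label maps are rejected", {
  arr <- array(0L, c(2, 4, 4)); arr[1, 1, 1] <- 2L
  lv <- labelVolume(array(0L, c(2, 4, 4)))
  lv@labels[1, 1, 1] <- 2L
  expect_error(writeLabelmap(lv, tempfile(fileext = ".nii")), "binary")
})

test_that("CT volumes round-trip through NIfTI with D from metadata", {
  arr <- array(round(rnorm(4 * 8 * 8, 100, 20)), c(4, 8, 8))
  v <- ctVolume(arr, pixelSpacing = c(0.6, 0.6), sliceDistance = 2.0)
  path <- withr::local_tempfile(fileext = ".nii.gz")
  writeCtVolume(v, path)
  rt <- readCtVolume(path)
  expect_equal(sliceDistance(rt), 2.0, tolerance = 1e-6)
  expect_equal(intensities(rt), arr, ignore_attr = TRUE)
})

test_that("DICOM series are ordered by slice position, not file name", {
  arr <- array(round(rnorm(3 * 6 * 5, 80, 10)), c(3, 6, 5))
  v <- ctVolume(arr, pixelSpacing = c(0.7, 0.8), sliceDistance = 2.5,
                origin = c(1, 2, 3))
  dir <- withr::local_tempdir()
  # file 1 holds the last slice, file 3 the first
  writeDicomSeries(v, dir, fileOrder = c(3L, 1L, 2L))
  rt <- readCtVolume(dir)
  expect_equal(intensities(rt), arr, ignore_attr = TRUE)
  expect_equal(sliceDistance(rt), 2.5, tolerance = 1e-9)
  expect_equal(pixelSpacing(rt), c(0.7, 0.8), tolerance = 1e-9)
  expect_equal(originMm(rt), c(1, 2, 3), tolerance = 1e-9)
})

test_that("inconsistent DICOM in-plane spacing raises an explicit error", {
  v1 <- ctVolume(array(0, c(1, 4, 4)), pixelSpacing = c(0.7, 0.7),
                 sliceDistance = 1, origin = c(0, 0, 0))
  v2 <- ctVolume(array(0, c(1, 4, 4)), pixelSpacing = c(0.9, 0.9),
                 sliceDistance = 1, origin = c(0, 0, 2))
  dir <- withr::local_tempdir()
  writeDicomSeries(v1, dir, prefix = "a")
  writeDicomSeries(v2, dir, prefix = "b")
  expect_error(readCtVolume(dir), "PixelSpacing")
})

test_that("irregular slice spacing beyond tolerance is rejected", {
  dir <- withr::local_tempdir()
  for (z in c(0, 2, 5)) {
    v <- ctVolume(array(0, c(1, 4, 4)), pixelSpacing = c(0.7, 0.7),
                  sliceDistance = 1, origin = c(0, 0, z))
    writeDicomSeries(v, dir, prefix = sprintf("z%02d", z))
  }
  expect_error(readCtVolume(dir), "spacing")
})

test_that("voxel indices map to physical mm positions", {
  v <- ctVolume(array(0, c(3, 4, 5)), pixelSpacing = c(0.5, 0.25),
                sliceDistance = 2, origin = c(10, 20, 30))
  p <- voxelToPhysical(v, rbind(c(1, 1, 1), c(2, 3, 4)))
  expect_equal(p[1, ], c(10, 20, 30))
  expect_equal(p[2, ], c(10 + 3 * 0.5, 20 + 2 * 0.25, 30 + 1 * 2))
})
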