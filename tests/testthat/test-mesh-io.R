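test_that("meshes round-trip through ASCII PLY, OFF and STL", {
  m <- icosphere(2)
  for (ext in c("ply", "off", "stl")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    writeMesh(m, path)
    rt <- readMesh(path)
    if (ext == "stl") {
      # STL stores free triangles; vertex identity is restored by merging
      expect_equal(meshArea(rt), meshArea(m), tolerance = 1e-5)
      expect_identical(nrow(rt@faces), nrow(m@faces))
      expect_identical(eulerCharacteristic(rt), 2L)
    } else {
      expect_equal(rt@vertices, m@vertices, tolerance = 1e-6,
                   ignore_attr = TRUE)
      expect_identical(rt@faces, m@faces)
    }
  }
})

test_that("ASCII mesh writes are bit-stable", {
  m <- icosphere(2)
  p1 <- withr::local_tempfile(fileext = ".ply")
  p2 <- withr::local_tempfile(fileext = ".ply")
  writeMesh(m, p1); writeMesh(m, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("binary little-endian PLY reads back correctly", {
  m <- icosphere(1)
  path <- withr::local_tempfile(fileext = ".ply")
  con <- file(path, "wb")
  writeLines(c("ply", "format binary_little_endian 1.0",
               paste("element vertex", nrow(m@vertices)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(m@faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeBin(as.vector(t(m@vertices)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(m@faces))) {
    writeBin(as.raw(3), con)
    writeBin(as.integer(m@faces[i, ] - 1L), con, size = 4,
             endian = "little")
  }
  close(con)
  rt <- readMesh(path)
  expect_equal(rt@vertices, m@vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(rt@faces, m@faces)
})

test_that("landmark CSV files round-trip with 0-based storage", {
  lm <- setNames(c(5L, 17L, 101L), c("1", "2", "10"))
  path <- withr::local_tempfile(fileext = ".csv")
  writeLandmarks(lm, path)
  df <- read.csv(path)
  expect_equal(df$vertex_index, c(4L, 16L, 100L))
  expect_identical(readLandmarks(path), lm)
})

test_that("resection paths round-trip through JSON", {
  p <- list(resectionPath(matrix(rnorm(9), 3), "LHV"),
            resectionPath(matrix(rnorm(6), 2), "RPV"))
  path <- withr::local_tempfile(fileext = ".json")
  writeResectionPaths(p, path)
  rt <- readResectionPaths(path)
  expect_identical(vapply(rt, pathLabel, character(1)), c("LHV", "RPV"))
  expect_equal(pathPoints(rt[[1]]), pathPoints(p[[1]]), ignore_attr = TRUE)
})
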