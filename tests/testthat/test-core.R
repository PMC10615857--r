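# calibration, label maps, file I/O, quadrant tiling, random sampling

test_that("calibration validates and records anisotropy", {
  cal <- calibration(10, 10, 50)
  expect_equal(cal$anisotropy, 5)
  expect_null(calibration(10)$px_z_nm)
  expect_error(calibration(0), "positive")
  expect_error(calibration(10, -5), "positive")
  expect_error(calibration(10, 10, Inf), "positive")
})

test_that("label_map enforces its invariants", {
  cal <- calibration(10)
  m <- matrix(c(0L, 1L, 2L, 2L), 2, 2)
  lm <- label_map(m, "mitochondrion", cal)
  expect_equal(sort(unique(as.vector(lm$data))), c(0L, 1L, 2L))
  expect_error(label_map(m, "mitochondrion", calibration(10, 10, 50)),
               "3D.*2D|calibration")
  expect_error(label_map(matrix(c(0, 1.5), 1, 2), "er", cal), "integer")
  expect_error(label_map(matrix(c(0L, -1L), 1, 2), "er", cal),
               "non-negative")
  # doubles holding integer values are coerced, values preserved
  md <- matrix(c(0, 3, 0, 7), 2, 2)
  expect_identical(label_map(md, "er", cal)$data,
                   matrix(c(0L, 3L, 0L, 7L), 2, 2))
})

test_that("round-trip I/O is bit-exact for TIFF, PNG and HDF5", {
  cal <- calibration(10)
  img <- render(phantom_spec("disc", cal, r_nm = 300))$maps$object
  for (ext in c("tif", "png")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_label_map(img, f)
    back <- load_label_map(f, "mitochondrion", cal)
    expect_identical(back$data, img$data, label = ext)
  }
  # multi-label 2D map above 8-bit range (16-bit TIFF path)
  big <- label_map(matrix(sample.int(4000, 64), 8, 8), "other", cal)
  f <- tempfile(fileext = ".tif")
  write_label_map(big, f)
  expect_identical(load_label_map(f, "other", cal)$data, big$data)

  cal3d <- calibration(10, 10, 50)
  vol <- label_map(array(sample(0:3, 3 * 8 * 8, TRUE), c(3, 8, 8)),
                   "mitochondrion", cal3d)
  for (ext in c("tif", "h5")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_label_map(vol, f)
    back <- load_label_map(f, "mitochondrion", cal3d)
    expect_identical(back$data, vol$data, label = ext)
    expect_equal(dim(back$data), c(3, 8, 8))
  }
})

test_that("phantom HDF5 write-then-read is the identity (oracle)", {
  cal3d <- calibration(10, 10, 10)
  rnd <- render(phantom_spec("sphere", cal3d, r_nm = 120))
  dir <- tempfile()
  files <- mitomorph::write_phantom(rnd, dir)
  back <- load_label_map(files[["object"]], "mitochondrion", cal3d)
  expect_identical(back$data, rnd$maps$object$data)
  truth <- jsonlite::read_json(files[["truth"]])
  expect_equal(truth$volume_um3, rnd$truth$volume_um3)
})

test_that("load_label_map rejects bad input", {
  expect_error(load_label_map(tempfile(), "er", calibration(10)),
               "not found")
  f <- tempfile(fileext = ".txt")
  writeLines("hi", f)
  expect_error(load_label_map(f, "er", calibration(10)), "extension")
  f2 <- tempfile(fileext = ".tif")
  writeLines("not a tiff at all", f2)
  expect_error(load_label_map(f2, "er", calibration(10)), "TIFF")
})

test_that("quadrant_partition tiles exactly with remainder to last row/col", {
  cal <- calibration(10)
  m100 <- label_map(matrix(0L, 100, 100), "other", cal)
  q <- quadrant_partition(m100, 2, 2)
  expect_equal(nrow(q), 4)
  expect_true(all(q$row1 - q$row0 + 1 == 50) && all(q$col1 - q$col0 + 1 == 50))

  m101 <- label_map(matrix(0L, 101, 101), "other", cal)
  q2 <- quadrant_partition(m101, 2, 2)
  expect_setequal(q2$row1 - q2$row0 + 1, c(50, 51))
  expect_setequal(q2$col1 - q2$col0 + 1, c(50, 51))

  m10 <- label_map(matrix(0L, 10, 10), "other", cal)
  q3 <- quadrant_partition(m10, 1, 1)
  expect_equal(unlist(q3[1, c("row0", "row1", "col0", "col1")],
                      use.names = FALSE), c(1, 10, 1, 10))

  # property: ROI areas always sum to the image area
  for (nr in 1:4) for (nc in 1:4) {
    qq <- quadrant_partition(m101, nr, nc)
    expect_equal(sum((qq$row1 - qq$row0 + 1) * (qq$col1 - qq$col0 + 1)),
                 101 * 101)
  }
  expect_error(quadrant_partition(
    label_map(array(0L, c(2, 4, 4)), "other", calibration(10, 10, 10))),
    "2D")
})

test_that("sample_objects is reproducible, uniform, and flags small batches", {
  cal <- calibration(10)
  mk <- function(k) {
    m <- matrix(0L, 10, 60)
    for (i in seq_len(k)) m[5, 3 * i] <- i
    label_map(m, "mitochondrion", cal)
  }
  s12 <- sample_objects(mk(12), min_n = 10, seed = 1)
  expect_length(s12$selected, 10)
  expect_false(s12$insufficient)
  expect_false(anyDuplicated(s12$selected) > 0)
  expect_identical(sample_objects(mk(12), min_n = 10, seed = 1), s12)

  s8 <- sample_objects(mk(8), min_n = 10, seed = 1)
  expect_length(s8$selected, 8)
  expect_true(s8$insufficient)
  expect_error(sample_objects(label_map(matrix(0L, 4, 4), "er", cal),
                              seed = 1), "no objects")

  # uniformity: over 10,000 draws of 10 from 20, each object's inclusion
  # frequency is within 3 standard errors of 0.5
  m20 <- mk(20)
  counts <- integer(20)
  for (i in seq_len(10000)) {
    sel <- sample_objects(m20, 10, seed = i)$selected
    counts[sel] <- counts[sel] + 1L
  }
  freq <- counts / 10000
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_true(all(abs(freq - 0.5) <= 3 * se))
})

test_that("objects straddling quadrant borders are assigned by centroid", {
  cal <- calibration(10)
  m <- matrix(0L, 100, 100)
  m[48:54, 10:12] <- 1L # centroid row 51 -> lower half
  m[10:12, 48:54] <- 2L # centroid col 51 -> right half
  map <- label_map(m, "mitochondrion", cal)
  q <- quadrant_partition(map, 2, 2)
  a <- assign_quadrants(map, q)
  expect_equal(unname(a[["1"]]), 3) # row-major: lower-left
  expect_equal(unname(a[["2"]]), 2) # upper-right
})
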