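# per-object 2D morphometrics

test_that("digitized discs recover analytic area, perimeter, circularity", {
  rec50 <- measure_objects_2d(disc_map(50, px = 10))
  expect_lt(abs(rec50$area_um2 / (pi * 0.5^2) - 1), 0.01)
  expect_lt(abs(rec50$perimeter_um / (2 * pi * 0.5) - 1), 0.02)

  rec100 <- measure_objects_2d(disc_map(100, px = 10))
  expect_gte(rec100$circularity, 0.98)
  expect_lte(rec100$circularity, 1.02)
  expect_lt(abs(rec100$feret_length_um / 2 - 1), 0.02)
})

test_that("area is exactly pixel count times pixel area", {
  m <- disc_mask(30)
  map <- label_map(m * 1L, "mitochondrion", cal2(10))
  expect_equal(measure_objects_2d(map)$area_um2, sum(m) * 100 / 1e6)
  # single pixel at 10 nm/px
  one <- label_map(matrix(c(0L, 1L, 0L, 0L), 2, 2), "mitochondrion", cal2(10))
  # sub-pixel contour of one pixel is a diamond, so circularity warns (> 1.05)
  expect_warning(rec1 <- measure_objects_2d(one), "circularity")
  expect_equal(rec1$area_um2, 1e-4)
})

test_that("axis-aligned rectangle: Feret, perimeter, aspect ratio", {
  m <- matrix(0L, 30, 120)
  m[11:20, 11:110] <- 1L # 100 x 10 px at 10 nm/px = 1.0 x 0.1 um
  rec <- measure_objects_2d(label_map(m, "mitochondrion", cal2(10)))
  expect_lt(abs(rec$feret_length_um / sqrt(1.0^2 + 0.1^2) - 1), 0.01)
  expect_lt(abs(rec$perimeter_um / 2.2 - 1), 0.02)
  expect_equal(rec$aspect_ratio, 10, tolerance = 0.01)
})

test_that("default perimeter handles w x h rectangles within 2% (w,h >= 50)", {
  for (wh in list(c(50, 50), c(80, 50), c(120, 60))) {
    m <- matrix(0L, wh[1] + 20, wh[2] + 20)
    m[11:(10 + wh[1]), 11:(10 + wh[2])] <- 1L
    p <- measure_objects_2d(label_map(m, "mitochondrion", cal2(10)))$perimeter_um
    expect_lt(abs(p / (2 * sum(wh) * 10 / 1000) - 1), 0.02,
              label = paste(wh, collapse = "x"))
  }
})

test_that("the 4-direction Crofton option matches its stereological bias", {
  # kept for comparability: accurate on discs, ~5% low on axis-aligned edges
  d <- disc_mask(100)
  p <- mitomorph:::crofton_perimeter(d, cal2(10))
  expect_lt(abs(p / (2 * pi * 1) - 1), 0.01)
  m <- matrix(FALSE, 70, 70); m[11:60, 11:60] <- TRUE
  psq <- mitomorph:::crofton_perimeter(m, cal2(10))
  expect_lt(abs(psq / 2 - (1 - 0.0575)), 0.01)
})

test_that("circularity follows the 4*pi*A/P^2 formula and boundary rules", {
  expect_equal(circularity(pi, 2 * pi), 1)
  expect_equal(circularity(1, 4), pi / 4)
  expect_error(circularity(0, 1), "positive")
  expect_error(circularity(1, -1), "positive")
  expect_warning(circularity(2, 4), "1.05") # 4*pi*2/16 = 1.57: reported as is
  expect_equal(suppressWarnings(circularity(2, 4)), pi / 2)
})

test_that("circularity ranks disc > square > 10:1 rectangle at equal area", {
  disc <- measure_objects_2d(disc_map(56))$circularity # area ~9852 px
  sq <- matrix(0L, 120, 120); sq[11:109, 11:109] <- 1L # 99^2 = 9801 px
  csq <- measure_objects_2d(label_map(sq, "mitochondrion", cal2(10)))$circularity
  rc <- matrix(0L, 60, 340); rc[11:41, 11:326] <- 1L # 31 x 316 = 9796 px
  crc <- measure_objects_2d(label_map(rc, "mitochondrion", cal2(10)))$circularity
  expect_gt(disc, csq)
  expect_gt(csq, crc)
})

test_that("holes are filled before measuring the organelle outline", {
  m <- disc_mask(40)
  holey <- m
  holey[35:45, 35:45] <- FALSE # internal lumen
  a_full <- measure_objects_2d(label_map(m * 1L, "mitochondrion", cal2(10)))
  a_hole <- measure_objects_2d(label_map(holey * 1L, "mitochondrion", cal2(10)))
  expect_equal(a_hole$area_um2, a_full$area_um2)
  expect_equal(a_hole$perimeter_um, a_full$perimeter_um)
})

test_that("measurements are invariant to relabelling and translation", {
  m <- disc_mask(25, pad = 30L)
  base <- measure_objects_2d(label_map(m * 1L, "mitochondrion", cal2(10)))
  ren <- measure_objects_2d(label_map(m * 7L, "mitochondrion", cal2(10)))
  expect_equal(base[-1], ren[-1]) # all but object_id identical
  shifted <- matrix(FALSE, nrow(m), ncol(m))
  shifted[1:(nrow(m) - 12), 5:ncol(m)] <- m[13:nrow(m), 1:(ncol(m) - 4)]
  tr <- measure_objects_2d(label_map(shifted * 1L, "mitochondrion", cal2(10)))
  expect_equal(base[-1], tr[-1])
})

test_that("count_density and area_histogram follow their conventions", {
  m <- matrix(0L, 20, 20)
  m[2, 2] <- 1L; m[5, 9] <- 2L; m[12, 3] <- 3L; m[18, 18] <- 4L; m[9, 15] <- 5L
  map <- label_map(m, "mitochondrion", cal2(10))
  expect_equal(count_density(map, 100), 0.05)
  expect_equal(count_density(label_map(matrix(0L, 4, 4), "er", cal2(10)), 10), 0)
  expect_error(count_density(map, 0), "positive")

  recs <- data.frame(area_um2 = c(0.1, 0.5, 0.9))
  h <- area_histogram(recs, c(0, 0.5, 1.0))
  expect_equal(h$counts, c(1, 2)) # 0.5 falls in the right bin
  expect_equal(h$n_out_of_range, 0)
  expect_equal(area_histogram(data.frame(area_um2 = numeric(0)),
                              c(0, 1, 2))$counts, c(0, 0))
  h2 <- area_histogram(data.frame(area_um2 = c(-1, 0.2, 5, 2)), c(0, 1, 2))
  expect_equal(h2$counts, c(1, 1)) # final bin closed: 2 included
  expect_equal(h2$n_out_of_range, 2)
  expect_error(area_histogram(recs, c(1, 1)), "increasing")
  expect_error(area_histogram(recs, c(2, 1, 0)), "increasing")
})

test_that("phantom disc ground truth is recovered within stated tolerance", {
  r <- render(phantom_spec("disc", cal2(10), r_nm = 500))
  rec <- measure_objects_2d(r$maps$object)
  expect_lt(abs(rec$area_um2 / r$truth$area_um2 - 1), 0.01)
  expect_lt(abs(rec$perimeter_um / r$truth$perimeter_um - 1), 0.02)
  k <- 5L
  m <- matrix(0L, 40, 40 * k)
  for (i in seq_len(k)) m[15:25, (40 * (i - 1) + 10):(40 * (i - 1) + 20)] <- i
  dens <- count_density(label_map(m, "mitochondrion", cal2(10)),
                        prod(dim(m)) * 100 / 1e6)
  expect_equal(dens, k / (prod(dim(m)) * 100 / 1e6))
})
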