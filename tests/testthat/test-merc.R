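# mitochondria-ER contact detection: gap field, 2D runs, 3D patches

test_that("gap field equals the brute-force boundary minimum (2D, exact)", {
  for (seed in 1:4) {
    mm <- label_map(blob_2d(seed) * 1L, "mitochondrion", cal2(10))
    ee <- label_map(blob_2d(seed + 100) * 1L, "er", cal2(10))
    if (!any(mm$data > 0) || !any(ee$data > 0)) next
    gf <- suppressWarnings(boundary_gap_field(mm, ee))
    oracle <- brute_gap(mm, ee)
    got <- gf$gap_nm[oracle$coords]
    expect_equal(got, oracle$gap, tolerance = 1e-12)
  }
})

test_that("gap field equals the brute-force minimum in anisotropic 3D", {
  for (seed in 1:2) {
    a <- blob_3d(seed); b <- blob_3d(seed + 50)
    cal <- calibration(10, 10, 50) # 5x anisotropy
    mm <- label_map(a * 1L, "mitochondrion", cal)
    ee <- label_map(b * 1L, "er", cal)
    gf <- suppressWarnings(boundary_gap_field(mm, ee))
    oracle <- brute_gap(mm, ee)
    expect_equal(gf$gap_nm[oracle$coords], oracle$gap, tolerance = 1e-12)
  }
})

test_that("distant organelles and overlapping labels behave as stated", {
  m <- matrix(0L, 120, 120); m[5:10, 5:10] <- 1L
  e <- matrix(0L, 120, 120); e[110:115, 110:115] <- 1L
  gf <- boundary_gap_field(label_map(m, "mitochondrion", cal2(10)),
                           label_map(e, "er", cal2(10)))
  expect_true(all(gf$gap_nm[!is.na(gf$gap_nm)] >= 1000))
  expect_equal(nrow(detect_contacts_2d(label_map(m, "mitochondrion", cal2(10)),
                                       label_map(e, "er", cal2(10)))), 0)
  mm <- label_map(m, "mitochondrion", cal2(10))
  expect_warning(gfo <- boundary_gap_field(mm, label_map(m, "er", cal2(10))),
                 "overlap")
  expect_true(all(gfo$gap_nm[!is.na(gfo$gap_nm)] == 0))
  expect_match(gf$convention, "boundary-element centers")
})

test_that("parallel membranes at 30 nm give one site with exact statistics", {
  r <- render(phantom_spec("apposed_pair_2d", cal2(10), gap_nm = 30,
                           span_nm = 1000))
  s <- detect_contacts_2d(r$maps$mito, r$maps$er)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_gap_nm, 30)
  expect_equal(s$min_gap_nm, 30)
  expect_equal(s$contact_length_um, 1, tolerance = 0.02)
  expect_true(s$in_ca_band) # 30 nm is inside [15, 30] inclusively

  r60 <- render(phantom_spec("apposed_pair_2d", cal2(10), gap_nm = 60,
                             span_nm = 1000))
  expect_equal(nrow(detect_contacts_2d(r60$maps$mito, r60$maps$er)), 0)
})

test_that("2D coverage is the boundary fraction in contact", {
  # ER square ring; mito membrane segment apposed to its bottom edge
  e <- matrix(0L, 140, 140)
  e[20:120, 20:120] <- 1L; e[21:119, 21:119] <- 0L # 1-px ring
  m <- matrix(0L, 140, 140)
  m[123, 20:120] <- 1L # 3 px below the ring bottom (row 120): 30 nm
  s <- detect_contacts_2d(label_map(m, "mitochondrion", cal2(10)),
                          label_map(e, "er", cal2(10)))
  expect_equal(nrow(s), 1)
  ring_px <- sum(e)
  # ~bottom edge of the ring (101 px) plus the few side pixels within 50 nm
  expect_lt(abs(s$coverage_er_pct - 100 * (101 + 4) / ring_px), 2)
  expect_lte(s$coverage_er_pct, 100)
  expect_lte(s$coverage_mito_pct, 100)
})

test_that("a wrapping ER sheath reaches ~100% mitochondrial coverage", {
  r <- render(phantom_spec("wrap_sheath", cal2(10), mito_r_nm = 500,
                           gap_nm = 30, sheath_nm = 30))
  s <- detect_contacts_2d(r$maps$mito, r$maps$er)
  expect_equal(sum(s$coverage_mito_pct), 100, tolerance = 0.01)
  expect_true(all(s$coverage_er_pct <= 100))
})

test_that("contact extent is monotone in the gap threshold", {
  mm <- label_map(blob_2d(7, n = 64, k = 5) * 1L, "mitochondrion", cal2(10))
  ee <- label_map(blob_2d(21, n = 64, k = 5) * 1L, "er", cal2(10))
  lens <- covs <- numeric(0)
  for (thr in c(20, 50, 100, 200, 400)) {
    s <- suppressWarnings(
      detect_contacts_2d(mm, ee, merc_config(gap_threshold_nm = thr)))
    lens <- c(lens, sum(s$contact_length_um))
    covs <- c(covs, sum(s$coverage_er_pct))
  }
  expect_true(all(diff(lens) >= -1e-9))
  expect_true(all(diff(covs) >= -1e-9))
})

test_that("swapping organelle roles swaps the coverage fractions", {
  r <- render(phantom_spec("apposed_pair_2d", cal2(10), gap_nm = 30,
                           span_nm = 500))
  s_ab <- detect_contacts_2d(r$maps$mito, r$maps$er)
  swapped_m <- label_map(r$maps$er$data, "mitochondrion", cal2(10))
  swapped_e <- label_map(r$maps$mito$data, "er", cal2(10))
  s_ba <- detect_contacts_2d(swapped_m, swapped_e)
  expect_equal(s_ab$coverage_mito_pct, s_ba$coverage_er_pct, tolerance = 1e-9)
  expect_equal(s_ab$coverage_er_pct, s_ba$coverage_mito_pct, tolerance = 1e-9)
})

test_that("3D slabs: one patch with area, gap, cleft and geodesic length", {
  cal <- calibration(10, 10, 1)
  r <- render(phantom_spec("apposed_slabs_3d", cal, gap_nm = 30,
                           span_nm = 1000, slab_nm = 40))
  s <- detect_contacts_3d(r$maps$mito, r$maps$er)
  expect_equal(nrow(s), 1)
  expect_equal(s$mean_gap_nm, 30)
  expect_equal(s$contact_area_um2, r$truth$contact_area_um2, tolerance = 0.01)
  expect_equal(s$cleft_volume_um3, r$truth$cleft_volume_um3, tolerance = 1e-9)
  # the analytic cleft equals area x gap up to the one-voxel-pitch void offset
  expect_lt(abs(s$cleft_volume_um3 / (1 * 30 / 1000) - 1), 0.05)
  expect_equal(s$contact_length_um, r$truth$contact_length_um,
               tolerance = 0.05)
  # 200 nm apart: no patches at the default 50 nm threshold
  r200 <- render(phantom_spec("apposed_slabs_3d", cal, gap_nm = 200,
                              span_nm = 500, slab_nm = 40))
  expect_equal(nrow(detect_contacts_3d(r200$maps$mito, r200$maps$er)), 0)
})

test_that("anisotropic phantoms recover the physical gap within a voxel diagonal", {
  cal <- calibration(10, 10, 50) # px_z = 5 x px_x
  r <- render(phantom_spec("apposed_slabs_3d", cal, gap_nm = 100,
                           span_nm = 500, slab_nm = 150))
  s <- detect_contacts_3d(r$maps$mito, r$maps$er,
                          merc_config(gap_threshold_nm = 120))
  expect_equal(nrow(s), 1)
  diag_nm <- sqrt(sum(mitomorph:::cal_spacing(cal)^2))
  expect_lt(abs(s$mean_gap_nm - 100), diag_nm)
})

test_that("ca-band annotation is inclusive at both bounds", {
  cfg <- merc_config()
  df <- data.frame(mean_gap_nm = c(20, 40, 30, 15, 14.9))
  out <- annotate_ca_band(df, cfg)
  expect_equal(out$in_ca_band, c(TRUE, FALSE, TRUE, TRUE, FALSE))
  expect_error(merc_config(gap_threshold_nm = -1), "positive")
  expect_error(merc_config(ca_band_nm = c(30, 15)), "increasing")
})
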