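# 3D morphometrics: volume, surface, skeleton length, branching, MOAS

test_that("volume is exact and the single-voxel case scales anisotropically", {
  b <- ball_map(12)
  rec <- measure_objects_3d(b, skeleton = FALSE)
  expect_equal(rec$volume_um3, sum(b$data > 0) * 1000 / 1e9)
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  rec1 <- measure_objects_3d(label_map(one, "mitochondrion",
                                       calibration(10, 10, 50)),
                             skeleton = FALSE)
  expect_equal(rec1$volume_um3, 5e-6) # 10 x 10 x 50 nm voxel
})

test_that("sphere surface recovery is within 5% and improves with radius", {
  errs <- vapply(c(10, 20, 40), function(r) {
    rec <- measure_objects_3d(ball_map(r), skeleton = FALSE)
    abs(rec$surface_area_um2 / (4 * pi * (r * 10 / 1000)^2) - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.05) # r = 20 within 5%
  expect_lt(errs[3], 0.05)
  expect_true(all(diff(errs) < 0)) # error decreases with radius
  rec20 <- measure_objects_3d(ball_map(20), skeleton = FALSE)
  expect_lt(abs(rec20$volume_um3 / (4 / 3 * pi * 0.2^3) - 1), 0.02)
})

test_that("straight cylinders: length within 5%, invariant to tube radius", {
  lens <- vapply(c(2, 4, 8) * 10, function(r_nm) {
    ph <- render(phantom_spec("cylinder", cal3(10), r_nm = r_nm,
                              len_nm = 2000))
    sk <- skeletonize(ph$maps$object, 1)
    len <- object_length(sk)
    expect_false(len$fallback)
    br <- branch_stats(sk)
    expect_equal(br$junction_count, 0)
    expect_equal(br$endpoint_count, 2)
    len$length_um
  }, numeric(1))
  expect_true(all(abs(lens / 2 - 1) < 0.05))
  expect_lt(diff(range(lens)) / 2, 0.03) # radius invariance
})

test_that("quarter-torus centerline length matches (pi/2) R within 5%", {
  ph <- render(phantom_spec("bent_tube", cal3(10), arc_radius_nm = 1000,
                            tube_r_nm = 50))
  len <- object_length(skeletonize(ph$maps$object, 1))
  expect_false(len$fallback)
  expect_lt(abs(len$length_um / (pi / 2 * 1) - 1), 0.05)
})

test_that("Y, H and straight tubes give 1, 2 and 0 junctions", {
  sky <- skeletonize(render(y_tube())$maps$object, 1)
  bry <- branch_stats(sky)
  expect_equal(bry$junction_count, 1)
  expect_equal(bry$endpoint_count, 3)
  skh <- skeletonize(render(h_tube())$maps$object, 1)
  brh <- branch_stats(skh)
  expect_equal(brh$junction_count, 2)
  expect_equal(brh$endpoint_count, 4)
  expect_true(branch_stats(skh, hyperbranch_min_junctions = 2)$hyperbranched)
  expect_false(bry$hyperbranched)
})

test_that("a compact blob falls back to the Feret caliper with a flag", {
  sk <- skeletonize(ball_map(20), 1)
  len <- object_length(sk)
  expect_true(len$fallback)
  expect_equal(len$length_um, 0.4, tolerance = 0.05)
  expect_false(detect_moas(sk)$moas)
  # degenerate tiny object: single-node graph
  tiny <- array(0L, c(5, 5, 5)); tiny[3, 3, 3] <- 1L
  sk1 <- skeletonize(label_map(tiny, "mitochondrion", cal3(10)), 1)
  expect_true(sk1$degenerate)
  expect_equal(branch_stats(sk1)$junction_count, 0)
})

test_that("beads-on-string is detected as MOAS; uniform tubes are not", {
  ph <- render(phantom_spec("beads_on_string", cal3(10), bulb_r_nm = 200,
                            tunnel_r_nm = 40, tunnel_len_nm = 500,
                            n_bulbs = 3L))
  expect_true(ph$truth$moas)
  sk <- skeletonize(ph$maps$object, 1)
  mo <- detect_moas(sk)
  expect_true(mo$moas)
  expect_equal(mo$tunnel_segments, 2)
  expect_equal(mo$bulb_count, 3)
  expect_equal(branch_stats(sk)$junction_count, ph$truth$junction_count)

  tube <- render(phantom_spec("cylinder", cal3(10), r_nm = 150,
                              len_nm = 2000))
  expect_false(detect_moas(skeletonize(tube$maps$object, 1))$moas)
  expect_error(moas_params(tunnel_radius_frac = 1.2), "0, 1")
})

test_that("isotropic metrics are invariant under axis permutation", {
  ph <- render(phantom_spec("bent_tube", cal3(10), arc_radius_nm = 600,
                            tube_r_nm = 40))
  base_map <- ph$maps$object
  rec <- measure_objects_3d(base_map)
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    pm <- label_map(aperm(base_map$data, perm), "mitochondrion", cal3(10))
    prec <- measure_objects_3d(pm)
    expect_equal(prec$volume_um3, rec$volume_um3)
    expect_equal(prec$surface_area_um2, rec$surface_area_um2,
                 tolerance = 1e-6)
    expect_equal(prec$length_um, rec$length_um, tolerance = 0.01)
    expect_equal(prec$junction_count, rec$junction_count)
  }
})

test_that("anisotropic stacks are resampled before thinning", {
  # same cylinder rendered on an anisotropic grid (z pitch 50 nm)
  ph <- render(phantom_spec("cylinder", calibration(10, 10, 50), r_nm = 60,
                            len_nm = 2000))
  len <- object_length(skeletonize(ph$maps$object, 1))
  expect_lt(abs(len$length_um / 2 - 1), 0.05)
})
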