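# phantom generator: determinism, margins, jitter, ground-truth recovery

test_that("rendering is deterministic for a fixed seed", {
  a <- render(phantom_spec("disc", cal2(10), seed = 3, r_nm = 400))
  b <- render(phantom_spec("disc", cal2(10), seed = 3, r_nm = 400))
  expect_identical(a$maps$object$data, b$maps$object$data)
  c <- render(phantom_spec("disc", cal2(10), seed = 4, r_nm = 400))
  expect_false(identical(a$maps$object$data, c$maps$object$data))
  s1 <- render(phantom_spec("beads_on_string", cal3(10), seed = 11))
  s2 <- render(phantom_spec("beads_on_string", cal3(10), seed = 11))
  expect_identical(s1$maps$object$data, s2$maps$object$data)
})

test_that("shapes that do not fit the canvas raise an error", {
  # a tube_set segment pushed outside its stated canvas
  bad <- phantom_spec("tube_set", cal3(10), canvas = c(20L, 30L, 30L),
                      segments = list(list(p0 = c(100, 100, 10),
                                           p1 = c(100, 100, 500), r_nm = 60)))
  expect_error(render(bad), "margin|canvas")
})

test_that("jitter: identity at amplitude 0, reproducible, bounded effect", {
  d <- disc_map(50)
  expect_identical(jitter_map(d, 0, seed = 1)$data, d$data)
  j1 <- jitter_map(d, 1, seed = 9)
  expect_identical(jitter_map(d, 1, seed = 9)$data, j1$data)
  expect_false(identical(j1$data, d$data))

  # topology preserved and area change <= 3% at r = 50 px, across 100 seeds
  a0 <- sum(d$data > 0)
  worst <- 0
  for (s in 1:100) {
    j <- jitter_map(d, 1, seed = s)
    expect_equal(attr(mitomorph:::components(j$data > 0L, "full"),
                      "n_components"), 1L)
    worst <- max(worst, abs(sum(j$data > 0) - a0) / a0)
  }
  expect_lt(worst, 0.03)
  expect_error(jitter_map(d, -1, seed = 1), ">= 0")
})

test_that("every analytically determined truth field is recovered", {
  # 2D: disc, rectangle, ellipse
  rd <- render(phantom_spec("disc", cal2(10), r_nm = 500))
  m <- measure_objects_2d(rd$maps$object)
  expect_lt(abs(m$area_um2 / rd$truth$area_um2 - 1), 0.01)
  expect_lt(abs(m$perimeter_um / rd$truth$perimeter_um - 1), 0.02)

  rr <- render(phantom_spec("rectangle", cal2(10), w_nm = 900, h_nm = 500))
  mr <- measure_objects_2d(rr$maps$object)
  expect_lt(abs(mr$area_um2 / rr$truth$area_um2 - 1), 0.03)
  expect_lt(abs(mr$perimeter_um / rr$truth$perimeter_um - 1), 0.02)
  expect_lt(abs(mr$feret_length_um / rr$truth$feret_um - 1), 0.03)

  re <- render(phantom_spec("ellipse", cal2(10), a_nm = 700, b_nm = 250))
  me <- measure_objects_2d(re$maps$object)
  expect_lt(abs(me$area_um2 / re$truth$area_um2 - 1), 0.01)
  expect_lt(abs(me$aspect_ratio / re$truth$aspect_ratio - 1), 0.05)

  # 3D: sphere volume/surface, cylinder length
  rs <- render(phantom_spec("sphere", cal3(10), r_nm = 200))
  ms <- measure_objects_3d(rs$maps$object, skeleton = FALSE)
  expect_lt(abs(ms$volume_um3 / rs$truth$volume_um3 - 1), 0.02)
  expect_lt(abs(ms$surface_area_um2 / rs$truth$surface_area_um2 - 1), 0.05)

  rc <- render(phantom_spec("cylinder", cal3(10), r_nm = 60, len_nm = 1500))
  mc <- measure_objects_3d(rc$maps$object)
  expect_lt(abs(mc$length_um / rc$truth$length_um - 1), 0.05)
  expect_equal(mc$junction_count, rc$truth$junction_count)
  expect_equal(mc$moas, rc$truth$moas)

  # contact phantoms
  rp <- render(phantom_spec("apposed_pair_2d", cal2(10), gap_nm = 30))
  sp <- detect_contacts_2d(rp$maps$mito, rp$maps$er)
  expect_equal(sp$mean_gap_nm, rp$truth$gap_nm)
  expect_lt(abs(sp$contact_length_um / rp$truth$contact_length_um - 1), 0.02)
})

test_that("jittered phantoms still recover their coarse truth", {
  rj <- render(phantom_spec("disc", cal2(10), r_nm = 500,
                            jitter_amplitude = 1))
  mj <- measure_objects_2d(rj$maps$object)
  expect_lt(abs(mj$area_um2 / rj$truth$area_um2 - 1), 0.05)
})

test_that("write_phantom emits the reader formats plus JSON truth", {
  dir <- tempfile()
  files <- write_phantom(render(phantom_spec("wrap_sheath", cal2(10))), dir)
  expect_true(all(file.exists(files)))
  expect_match(files[["mito"]], "\\.tif$")
  truth <- jsonlite::read_json(files[["truth"]])
  expect_equal(truth$coverage_mito_pct, 100)
  back_m <- load_label_map(files[["mito"]], "mitochondrion", cal2(10))
  back_e <- load_label_map(files[["er"]], "er", cal2(10))
  s <- detect_contacts_2d(back_m, back_e)
  expect_equal(sum(s$coverage_mito_pct), 100, tolerance = 0.01)
})
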