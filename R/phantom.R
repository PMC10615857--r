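#' Synthetic phantom specification
#'
#' Phantoms are analytically defined organelle scenes rendered to label
#' maps by pixel-center inclusion (an element is foreground iff its center
#' lies inside the analytic shape), which makes pixel-count oracles exact
#' and rendering deterministic and platform-independent. Every phantom
#' returns the closed-form ground truth for the metrics its geometry
#' determines, which is what the cross-module recovery tests measure
#' against.
#'
#' Kinds and their main parameters (nm):
#' * `disc` (`r_nm`), `ellipse` (`a_nm`, `b_nm`, `theta`), `rectangle`
#'   (`w_nm`, `h_nm`): single 2D object.
#' * `cristae_mix` (`mito_r_nm`, `n_lamellar`, `n_tubular`, ...): a
#'   mitochondrion profile containing elongated lamellar sheets and round
#'   tubular cross-sections.
#' * `apposed_pair_2d` (`gap_nm`, `span_nm`): two parallel 1-px membrane
#'   segments at an exact center-to-center gap; `wrap_sheath` (`mito_r_nm`,
#'   `gap_nm`, `sheath_nm`): an ER annulus fully wrapping a disc.
#' * `sphere` (`r_nm`), `cylinder` (`r_nm`, `len_nm`), `bent_tube`
#'   (`arc_radius_nm`, `tube_r_nm`; a quarter turn), `beads_on_string`
#'   (`bulb_r_nm`, `tunnel_r_nm`, `tunnel_len_nm`, `n_bulbs`), `tube_set`
#'   (`segments`: list of `list(p0_nm, p1_nm, r_nm)`): single 3D object.
#' * `apposed_slabs_3d` (`gap_nm`, `span_nm`, `slab_nm`): two parallel
#'   slabs spanning the full lateral canvas, at an exact center-to-center
#'   gap along z.
#'
#' The seed shifts the scene by a deterministic sub-pixel offset (never
#' along the controlled gap axis of apposed phantoms), so repeated seeds
#' probe rasterization variability without changing the stated geometry.
#'
#' @param kind phantom kind (see above).
#' @param calibration a [calibration()]; 2D kinds need a 2D calibration.
#' @param seed integer; deterministic sub-pixel placement.
#' @param jitter_amplitude boundary jitter amplitude in px, applied by
#'   [jitter_map()] at render time (0 = off).
#' @param ... kind-specific geometric parameters.
#' @return An object of class `"phantom_spec"`.
#' @export
phantom_spec <- function(kind, calibration, seed = 1L, jitter_amplitude = 0,
                         ...) {
  kinds <- c("disc", "ellipse", "rectangle", "sphere", "cylinder",
             "bent_tube", "beads_on_string", "apposed_pair_2d",
             "apposed_slabs_3d", "cristae_mix", "wrap_sheath", "tube_set")
  kind <- match.arg(kind, kinds)
  structure(list(kind = kind, calibration = calibration,
                 seed = as.integer(seed),
                 jitter_amplitude = jitter_amplitude, params = list(...)),
            class = "phantom_spec")
}

#' Render a phantom to label maps with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return list with `maps` (named list of [label_map()]s) and `truth`
#'   (named list of analytic values).
#' @export
render <- function(spec) UseMethod("render")

#' @export
render.phantom_spec <- function(spec) {
  cal <- spec$calibration
  p <- spec$params
  off <- with_seed(spec$seed, (runif(3) - 0.5) * 0.9)
  out <- switch(spec$kind,
    disc = render_disc(cal, p, off),
    ellipse = render_ellipse(cal, p, off),
    rectangle = render_rectangle(cal, p, off),
    sphere = render_sphere(cal, p, off),
    cylinder = render_cylinder(cal, p, off),
    bent_tube = render_bent_tube(cal, p, off),
    beads_on_string = render_beads(cal, p, off),
    apposed_pair_2d = render_apposed_pair_2d(cal, p, off),
    apposed_slabs_3d = render_apposed_slabs_3d(cal, p, off),
    cristae_mix = render_cristae_mix(cal, p, off),
    wrap_sheath = render_wrap_sheath(cal, p, off),
    tube_set = render_tube_set(cal, p, off))
  if (spec$jitter_amplitude > 0) {
    out$maps <- lapply(out$maps, jitter_map, amplitude = spec$jitter_amplitude,
                       seed = spec$seed)
  }
  out$spec <- spec
  out
}

# physical center coordinates (nm) of 2D pixels, sub-pixel offset in px
coords_2d <- function(ny, nx, cal, off) {
  list(y = ((seq_len(ny) - 1) - off[1]) * cal$px_y_nm,
       x = ((seq_len(nx) - 1) - off[2]) * cal$px_x_nm)
}

coords_3d <- function(nz, ny, nx, cal, off) {
  list(z = ((seq_len(nz) - 1) - off[1]) * cal$px_z_nm,
       y = ((seq_len(ny) - 1) - off[2]) * cal$px_y_nm,
       x = ((seq_len(nx) - 1) - off[3]) * cal$px_x_nm)
}

check_margin <- function(mask, margin = 2L) {
  d <- dim(mask)
  nd <- length(d)
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) stopf("phantom rendered empty: shape exceeds canvas?")
  lo <- apply(w, 2, min); hi <- apply(w, 2, max)
  if (any(lo <= margin) || any(hi > d - margin)) {
    stopf("rendered shape does not keep a %d px margin inside the canvas",
          margin)
  }
  invisible(TRUE)
}

render_disc <- function(cal, p, off) {
  r <- p$r_nm %||% 500
  px <- cal$px_x_nm
  n <- 2L * ceiling(r / px) + 11L
  ctr <- (n - 1) / 2 * px
  g <- coords_2d(n, n, cal, off)
  m <- outer(g$y, g$x, function(y, x) (y - ctr)^2 + (x - ctr)^2 <= r^2) * 1L
  check_margin(m == 1L)
  list(maps = list(object = label_map(m, "mitochondrion", cal)),
       truth = list(area_um2 = pi * r^2 / NM_PER_UM^2,
                    perimeter_um = 2 * pi * r / NM_PER_UM,
                    circularity = 1))
}

render_ellipse <- function(cal, p, off) {
  a <- p$a_nm %||% 800; b <- p$b_nm %||% 300; th <- p$theta %||% 0
  px <- cal$px_x_nm
  n <- 2L * ceiling(a / px) + 11L
  ctr <- (n - 1) / 2 * px
  g <- coords_2d(n, n, cal, off)
  m <- outer(g$y, g$x, function(y, x) {
    u <- (x - ctr) * cos(th) + (y - ctr) * sin(th)
    v <- -(x - ctr) * sin(th) + (y - ctr) * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  }) * 1L
  check_margin(m == 1L)
  list(maps = list(object = label_map(m, "mitochondrion", cal)),
       truth = list(area_um2 = pi * a * b / NM_PER_UM^2,
                    aspect_ratio = a / b,
                    feret_um = 2 * a / NM_PER_UM))
}

render_rectangle <- function(cal, p, off) {
  w <- p$w_nm %||% 1000; h <- p$h_nm %||% 100
  px <- cal$px_x_nm
  ny <- ceiling(h / cal$px_y_nm) + 11L
  nx <- ceiling(w / px) + 11L
  g <- coords_2d(ny, nx, cal, off)
  y0 <- 5 * cal$px_y_nm; x0 <- 5 * px
  m <- outer(g$y, g$x, function(y, x)
    y >= y0 & y < y0 + h & x >= x0 & x < x0 + w) * 1L
  check_margin(m == 1L)
  list(maps = list(object = label_map(m, "mitochondrion", cal)),
       truth = list(area_um2 = w * h / NM_PER_UM^2,
                    perimeter_um = 2 * (w + h) / NM_PER_UM,
                    feret_um = sqrt(w^2 + h^2) / NM_PER_UM,
                    circularity = 4 * pi * w * h / (2 * (w + h))^2))
}

render_sphere <- function(cal, p, off) {
  r <- p$r_nm %||% 200
  sp <- cal_spacing(cal)
  n <- 2L * ceiling(r / sp) + 11L
  g <- coords_3d(n[1], n[2], n[3], cal, off)
  ctr <- (n - 1) / 2 * sp
  a <- array(0L, n)
  dz2 <- (g$z - ctr[1])^2; dy2 <- (g$y - ctr[2])^2; dx2 <- (g$x - ctr[3])^2
  for (k in seq_len(n[3])) {
    a[, , k] <- outer(dz2, dy2, `+`) + dx2[k] <= r^2
  }
  check_margin(a == 1L)
  list(maps = list(object = label_map(a, "mitochondrion", cal)),
       truth = list(volume_um3 = 4 / 3 * pi * r^3 / NM_PER_UM^3,
                    surface_area_um2 = 4 * pi * r^2 / NM_PER_UM^2,
                    feret_um = 2 * r / NM_PER_UM))
}

# generic capsule-union rasterizer; segs: list(p0, p1 (nm, z/y/x), r_nm)
rasterize_capsules <- function(n, cal, off, segs) {
  g <- coords_3d(n[1], n[2], n[3], cal, off)
  a <- array(0L, n)
  for (k in seq_len(n[3])) {
    x <- g$x[k]
    acc <- matrix(FALSE, n[1], n[2])
    for (s in segs) {
      d <- s$p1 - s$p0
      L2 <- sum(d^2)
      if (L2 < 1e-12) {
        dz <- g$z - s$p0[1]; dy <- g$y - s$p0[2]; dx <- x - s$p0[3]
        acc <- acc | (outer(dz^2, dy^2, `+`) + dx^2 <= s$r_nm^2)
      } else {
        # t for each (z,y) at this x: project, clamp, distance
        tz <- outer(g$z - s$p0[1], rep(1, n[2]))
        ty <- outer(rep(1, n[1]), g$y - s$p0[2])
        tx <- x - s$p0[3]
        tt <- (tz * d[1] + ty * d[2] + tx * d[3]) / L2
        tt[tt < 0] <- 0; tt[tt > 1] <- 1
        dd <- (tz - tt * d[1])^2 + (ty - tt * d[2])^2 + (tx - tt * d[3])^2
        acc <- acc | (dd <= s$r_nm^2)
      }
    }
    a[, , k] <- acc
  }
  a
}

render_cylinder <- function(cal, p, off) {
  r <- p$r_nm %||% 80; len <- p$len_nm %||% 2000
  sp <- cal_spacing(cal)
  n <- c(2L * ceiling(r / sp[1]) + 11L, 2L * ceiling(r / sp[2]) + 11L,
         ceiling(len / sp[3]) + 13L)
  ctr <- c((n[1] - 1) / 2 * sp[1], (n[2] - 1) / 2 * sp[2])
  x0 <- 6 * sp[3]
  a <- rasterize_capsules(n, cal, off, list(
    list(p0 = c(ctr, x0 + r), p1 = c(ctr, x0 + len - r), r_nm = r)))
  # capsule end caps: analytic length is the full extent len
  check_margin(a == 1L)
  list(maps = list(object = label_map(a, "mitochondrion", cal)),
       truth = list(length_um = len / NM_PER_UM,
                    junction_count = 0L, moas = FALSE))
}

render_bent_tube <- function(cal, p, off) {
  R <- p$arc_radius_nm %||% 1000; r <- p$tube_r_nm %||% 50
  sp <- cal_spacing(cal)
  n <- c(2L * ceiling(r / sp[1]) + 11L,
         ceiling((R + r) / sp[2]) + 13L, ceiling((R + r) / sp[3]) + 13L)
  g <- coords_3d(n[1], n[2], n[3], cal, off)
  cz <- (n[1] - 1) / 2 * sp[1]
  oy <- 6 * sp[2]; ox <- 6 * sp[3] # arc center
  a <- array(0L, n)
  for (k in seq_len(n[3])) {
    x <- g$x[k] - ox
    yy <- g$y - oy
    # quarter arc: angle 0..90 deg means x >= 0 and y >= 0 (flat caps)
    inplane <- (sqrt(yy^2 + x^2) - R)^2
    ok_ang <- yy >= 0 & x >= 0
    dz2 <- (g$z - cz)^2
    a[, , k] <- outer(dz2, inplane, `+`) <= r^2 & rep(ok_ang, each = n[1])
  }
  check_margin(a == 1L)
  list(maps = list(object = label_map(a, "mitochondrion", cal)),
       truth = list(length_um = (pi / 2) * R / NM_PER_UM,
                    junction_count = 0L, moas = FALSE))
}

render_beads <- function(cal, p, off) {
  br <- p$bulb_r_nm %||% 200; tr <- p$tunnel_r_nm %||% 40
  tl <- p$tunnel_len_nm %||% 500; nb <- p$n_bulbs %||% 3L
  sp <- cal_spacing(cal)
  sepx <- 2 * br + tl
  cx <- 6 * sp[3] + br + (seq_len(nb) - 1) * sepx
  n <- c(2L * ceiling(br / sp[1]) + 13L, 2L * ceiling(br / sp[2]) + 13L,
         ceiling((max(cx) + br) / sp[3]) + 7L)
  ctr <- c((n[1] - 1) / 2 * sp[1], (n[2] - 1) / 2 * sp[2])
  segs <- lapply(seq_len(nb), function(i)
    list(p0 = c(ctr, cx[i]), p1 = c(ctr, cx[i]), r_nm = br))
  for (i in seq_len(nb - 1)) {
    segs[[nb + i]] <- list(p0 = c(ctr, cx[i]), p1 = c(ctr, cx[i + 1]),
                           r_nm = tr)
  }
  a <- rasterize_capsules(n, cal, off, segs)
  check_margin(a == 1L)
  mp <- moas_params()
  moas_true <- tr <= mp$tunnel_radius_frac * br &&
    tl >= mp$min_tunnel_length_nm && nb >= mp$min_bulbs
  list(maps = list(object = label_map(a, "mitochondrion", cal)),
       truth = list(moas = moas_true,
                    tunnel_segments = if (moas_true) nb - 1L else 0L,
                    bulb_count = as.integer(nb),
                    junction_count = 0L,
                    length_um = ((nb - 1) * sepx + 2 * br) / NM_PER_UM))
}

render_tube_set <- function(cal, p, off) {
  segs <- p$segments
  if (is.null(segs)) stopf("tube_set requires a `segments` parameter")
  n <- p$canvas
  a <- rasterize_capsules(n, cal, off, segs)
  check_margin(a == 1L)
  truth <- list()
  if (!is.null(p$junction_count)) truth$junction_count <- p$junction_count
  if (!is.null(p$endpoint_count)) truth$endpoint_count <- p$endpoint_count
  list(maps = list(object = label_map(a, "mitochondrion", cal)), truth = truth)
}

render_apposed_pair_2d <- function(cal, p, off) {
  gap <- p$gap_nm %||% 30; span <- p$span_nm %||% 1000
  px <- cal$px_x_nm; py <- cal$px_y_nm
  if (abs(gap / py - round(gap / py)) > 1e-9) {
    stopf("apposed_pair_2d: gap_nm must be a multiple of px_y_nm (the gap is defined between pixel centers)")
  }
  gpx <- round(gap / py)
  nspan <- round(span / px)
  ny <- gpx + 21L; nx <- nspan + 13L
  m <- matrix(0L, ny, nx); e <- matrix(0L, ny, nx)
  row_m <- 10L; row_e <- row_m + gpx
  cols <- 7:(7 + nspan - 1)
  # one-pixel membrane segments: every boundary element sits at exactly the
  # stated center-to-center gap
  m[row_m, cols] <- 1L
  e[row_e, cols] <- 1L
  list(maps = list(mito = label_map(m, "mitochondrion", cal),
                   er = label_map(e, "er", cal)),
       truth = list(gap_nm = gap, contact_length_um = span / NM_PER_UM))
}

render_apposed_slabs_3d <- function(cal, p, off) {
  gap <- p$gap_nm %||% 30; span <- p$span_nm %||% 1000
  slab <- p$slab_nm %||% 40
  sp <- cal_spacing(cal)
  if (abs(gap / sp[1] - round(gap / sp[1])) > 1e-9) {
    stopf("apposed_slabs_3d: gap_nm must be a multiple of px_z_nm")
  }
  gvx <- round(gap / sp[1])
  svx <- max(3L, round(slab / sp[1]))
  ny <- round(span / sp[2]); nx <- round(span / sp[3])
  nz <- 2L * svx + gvx + 9L
  mi <- array(0L, c(nz, ny, nx)); er <- array(0L, c(nz, ny, nx))
  z_m <- 5L + svx - 1L # top boundary slice of the mito slab
  mi[5:z_m, , ] <- 1L
  er[(z_m + gvx):(z_m + gvx + svx - 1L), , ] <- 1L
  # slabs deliberately span the full lateral canvas: the field of view cuts
  # them, so the only exposed surfaces are the apposed faces and the backs
  list(maps = list(mito = label_map(mi, "mitochondrion", cal),
                   er = label_map(er, "er", cal)),
       truth = list(gap_nm = gap,
                    contact_area_um2 = span^2 / NM_PER_UM^2,
                    cleft_volume_um3 = span^2 * (gap - sp[1]) / NM_PER_UM^3,
                    contact_length_um = sqrt(2) * span / NM_PER_UM))
}

render_cristae_mix <- function(cal, p, off) {
  R <- p$mito_r_nm %||% 1500
  nl <- p$n_lamellar %||% 3L; nt <- p$n_tubular %||% 3L
  lw <- p$lamellar_w_nm %||% 600; lh <- p$lamellar_h_nm %||% 100
  tr <- p$tubular_r_nm %||% 80
  px <- cal$px_x_nm
  n <- 2L * ceiling(R / px) + 11L
  ctr <- (n - 1) / 2 * px
  g <- coords_2d(n, n, cal, off)
  mito <- outer(g$y, g$x, function(y, x) (y - ctr)^2 + (x - ctr)^2 <= R^2) * 1L
  cr <- matrix(0L, n, n)
  # lamellae stacked in the upper half, tubules in a row in the lower half
  for (i in seq_len(nl)) {
    cy <- ctr - R / 2 + (i - 1) * 2.5 * lh
    sel <- outer(g$y, g$x, function(y, x)
      abs(y - cy) <= lh / 2 & abs(x - ctr) <= lw / 2)
    cr[sel] <- 1L
  }
  for (i in seq_len(nt)) {
    cx <- ctr - (nt - 1) / 2 * 3.5 * tr + (i - 1) * 3.5 * tr
    cy <- ctr + R / 2
    sel <- outer(g$y, g$x, function(y, x) (y - cy)^2 + (x - cx)^2 <= tr^2)
    cr[sel] <- 1L
  }
  if (any(cr == 1L & mito == 0L)) stopf("cristae_mix: cristae leak outside")
  list(maps = list(mito = label_map(mito, "mitochondrion", cal),
                   cristae = label_map(cr, "crista", cal)),
       truth = list(cristae_count = nl + nt,
                    pct_lamellar = 100 * nl / (nl + nt),
                    pct_tubular = 100 * nt / (nl + nt)))
}

render_wrap_sheath <- function(cal, p, off) {
  R <- p$mito_r_nm %||% 500; gap <- p$gap_nm %||% 30
  th <- p$sheath_nm %||% 30
  px <- cal$px_x_nm
  rin <- R + gap; rout <- rin + th
  n <- 2L * ceiling(rout / px) + 13L
  ctr <- (n - 1) / 2 * px
  g <- coords_2d(n, n, cal, off)
  d2 <- outer(g$y, g$x, function(y, x) (y - ctr)^2 + (x - ctr)^2)
  mito <- (d2 <= R^2) * 1L
  er <- (d2 >= rin^2 & d2 <= rout^2) * 1L
  check_margin(er == 1L)
  list(maps = list(mito = label_map(mito, "mitochondrion", cal),
                   er = label_map(er, "er", cal)),
       truth = list(coverage_mito_pct = 100, gap_nm = gap))
}

#' Perturb a label map's boundary (robustness harness)
#'
#' Flips pixels in the one-pixel shell around each object boundary
#' independently with probability `min(0.5, 0.25 * amplitude)`, then
#' verifies that object topology survived (foreground and background
#' component counts unchanged); broken draws are resampled up to
#' `max_retry` times. Amplitude 0 returns the map unchanged.
#'
#' @param map a [label_map()].
#' @param amplitude jitter amplitude in pixels (>= 0).
#' @param seed RNG seed; fixed seed gives reproducible output.
#' @param max_retry resample attempts before giving up.
#' @return A jittered [label_map()].
#' @export
jitter_map <- function(map, amplitude, seed, max_retry = 25L) {
  if (amplitude < 0) stopf("amplitude must be >= 0")
  if (amplitude == 0) return(map)
  prob <- min(0.5, 0.25 * amplitude)
  fg <- map$data > 0L
  n_fg <- attr(components(fg, "full"), "n_components")
  n_bg <- attr(components(!fg, "faces"), "n_components")
  shell <- boundary_mask(fg) | (boundary_mask(!fg) & !fg)
  idx <- which(shell)
  d <- dim(map$data)
  for (k in seq_len(max_retry)) {
    newdat <- with_seed(seed + (k - 1L) * 7919L, {
      draws <- runif(length(idx)) < prob
      cur <- map$data
      # sequential flips, each gated by a local topology check, so the
      # perturbation cannot split, merge or puncture objects
      for (i in idx[draws]) {
        if (flip_is_safe(cur, i, d)) {
          cur[i] <- if (cur[i] > 0L) 0L else fill_label(cur, i)
        }
      }
      cur
    })
    nf <- newdat > 0L
    if (attr(components(nf, "full"), "n_components") == n_fg &&
        attr(components(!nf, "faces"), "n_components") == n_bg) {
      return(label_map(newdat, map$organelle_class, map$calibration))
    }
  }
  stopf("jitter_map: could not preserve topology within %d retries", max_retry)
}

# a boundary flip is safe when the foreground (8/26-conn) and background
# (4/6-conn) component counts inside the local 3^nd window are unchanged
flip_is_safe <- function(dat, i, d) {
  nd <- length(d)
  coord <- arrayInd(i, d)
  lo <- pmax(coord - 1L, 1L); hi <- pmin(coord + 1L, d)
  ix <- lapply(seq_len(nd), function(k) lo[k]:hi[k])
  win <- do.call(`[`, c(list(dat), ix, list(drop = FALSE))) > 0L
  ctr <- coord - lo + 1L
  after <- win
  ctr_i <- if (nd == 2L) ctr[1] + (ctr[2] - 1L) * dim(win)[1] else
    ctr[1] + dim(win)[1] * ((ctr[2] - 1L) + dim(win)[2] * (ctr[3] - 1L))
  after[ctr_i] <- !after[ctr_i]
  ncomp <- function(m, conn) attr(components(m, conn), "n_components")
  ncomp(win, "full") == ncomp(after, "full") &&
    ncomp(!win, "faces") == ncomp(!after, "faces")
}

# label to assign when a background shell pixel flips to foreground: the
# most common positive label among its neighbors (array-agnostic, small n)
fill_label <- function(dat, idx) {
  d <- dim(dat)
  nd <- length(d)
  vapply(idx, function(i) {
    coord <- arrayInd(i, d)
    lo <- pmax(coord - 1L, 1L); hi <- pmin(coord + 1L, d)
    sl <- do.call(`[`, c(list(dat), lapply(seq_len(nd), function(k)
      lo[k]:hi[k]), list(drop = FALSE)))
    v <- sl[sl > 0L]
    if (!length(v)) 1L else as.integer(names(which.max(table(v))))
  }, integer(1))
}

#' Write a rendered phantom to disk
#'
#' Writes each label map in the formats the readers accept (TIFF for 2D,
#' HDF5 for 3D) plus the analytic ground truth as JSON, so command-line
#' round trips exercise the full I/O path.
#'
#' @param rendered result of [render()].
#' @param dir output directory (created if needed).
#' @return Named character vector of the files written, invisibly.
#' @export
write_phantom <- function(rendered, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(rendered$maps)) {
    map <- rendered$maps[[nm]]
    ext <- if (lm_ndim(map) == 2L) "tif" else "h5"
    f <- file.path(dir, paste0(nm, ".", ext))
    write_label_map(map, f)
    files[nm] <- f
  }
  tf <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(rendered$truth, tf, auto_unbox = TRUE, digits = NA)
  files["truth"] <- tf
  invisible(files)
}
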