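# Shared fixture builders. All fixtures are generated in code; nothing is
# read from disk except where a test exercises the I/O layer itself.

cal2 <- function(px = 10) calibration(px)
cal3 <- function(px = 10, pz = px) calibration(px, px, pz)

# digitized disc mask (logical matrix), radius in px, center at pixel (c,c)
disc_mask <- function(r_px, pad = 10L) {
  n <- 2L * r_px + 2L * pad + 1L
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n), function(y, x)
    (y - ctr)^2 + (x - ctr)^2 <= r_px^2)
}

disc_map <- function(r_px, px = 10, pad = 10L) {
  label_map(disc_mask(r_px, pad) * 1L, "mitochondrion", cal2(px))
}

# voxelized ball mask, radius in voxels
ball_mask <- function(r_vox, pad = 5L) {
  n <- 2L * r_vox + 2L * pad + 1L
  ctr <- (n + 1) / 2
  a <- array(FALSE, c(n, n, n))
  dz2 <- (seq_len(n) - ctr)^2
  for (k in seq_len(n)) {
    a[, , k] <- outer(dz2, dz2, `+`) + dz2[k] <= r_vox^2
  }
  a
}

ball_map <- function(r_vox, px = 10, pad = 5L) {
  label_map(ball_mask(r_vox, pad) * 1L, "mitochondrion", cal3(px))
}

# deterministic random blob: union of discs/spheres, for oracle tests
blob_2d <- function(seed, n = 48L, k = 4L) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  for (i in seq_len(k)) {
    cy <- runif(1, 8, n - 8); cx <- runif(1, 8, n - 8); r <- runif(1, 3, 7)
    m <- m | outer(seq_len(n), seq_len(n), function(y, x)
      (y - cy)^2 + (x - cx)^2 <= r^2)
  }
  m
}

blob_3d <- function(seed, n = 24L, k = 3L) {
  set.seed(seed)
  a <- array(FALSE, c(n, n, n))
  g <- seq_len(n)
  for (i in seq_len(k)) {
    c0 <- runif(3, 6, n - 6); r <- runif(1, 2.5, 5)
    for (z in g) {
      a[z, , ] <- a[z, , ] | outer(g, g, function(y, x)
        (z - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2 <= r^2)
    }
  }
  a
}

# Y- and H-shaped tube phantom specs (3D), radius in nm
y_tube <- function(px = 10, r_nm = 40) {
  phantom_spec("tube_set", cal3(px), canvas = c(40L, 120L, 120L),
               segments = list(
                 list(p0 = c(200, 600, 100), p1 = c(200, 600, 600), r_nm = r_nm),
                 list(p0 = c(200, 600, 600), p1 = c(200, 1000, 1000), r_nm = r_nm),
                 list(p0 = c(200, 600, 600), p1 = c(200, 200, 1000), r_nm = r_nm)),
               junction_count = 1L, endpoint_count = 3L)
}

h_tube <- function(px = 10, r_nm = 40) {
  phantom_spec("tube_set", cal3(px), canvas = c(40L, 120L, 120L),
               segments = list(
                 list(p0 = c(200, 200, 100), p1 = c(200, 200, 1100), r_nm = r_nm),
                 list(p0 = c(200, 1000, 100), p1 = c(200, 1000, 1100), r_nm = r_nm),
                 list(p0 = c(200, 200, 450), p1 = c(200, 1000, 450), r_nm = r_nm)),
               junction_count = 2L, endpoint_count = 4L)
}

# brute-force membrane gap oracle: for every ER boundary element, the
# minimum distance to any mitochondrial boundary element (physical nm)
brute_gap <- function(mito_map, er_map) {
  sp <- mitomorph:::cal_spacing(mito_map$calibration)
  mb <- which(mitomorph:::boundary_mask(mito_map$data > 0L), arr.ind = TRUE)
  eb <- which(mitomorph:::boundary_mask(er_map$data > 0L), arr.ind = TRUE)
  mphys <- sweep(mb - 1, 2, sp, `*`)
  ephys <- sweep(eb - 1, 2, sp, `*`)
  out <- numeric(nrow(ephys))
  for (i in seq_len(nrow(ephys))) {
    dd <- sweep(mphys, 2, ephys[i, ])
    out[i] <- sqrt(min(rowSums(dd^2)))
  }
  # stated convention: overlapping labels report gap 0
  inside_mito <- mito_map$data[eb] > 0L
  out[inside_mito] <- 0
  list(coords = eb, gap = out)
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
mw_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  m <- length(x)
  idx <- utils::combn(length(pooled), m)
  ustat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  us <- apply(idx, 2, function(ii) ustat(pooled[ii], pooled[-ii]))
  p_le <- mean(us <= u_obs + 1e-12)
  p_ge <- mean(us >= u_obs - 1e-12)
  min(1, 2 * min(p_le, p_ge))
}
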