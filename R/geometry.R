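# Shared geometric primitives (connected components, boundaries, distance
# transforms, contour perimeters, moments, geodesics).

# connected components of a logical/integer array.
# connectivity: "full" (8 in 2D / 26 in 3D, the object-identity convention),
# "faces" (4/6), "edges" (18, 3D only).
components <- function(arr, connectivity = c("full", "faces", "edges")) {
  connectivity <- match.arg(connectivity)
  lvl <- switch(connectivity, faces = 1L, edges = 2L, full = 3L)
  d <- dim(arr)
  lab <- .cc_label(as.integer(arr != 0), d, lvl)
  n <- attr(lab, "n_components")
  out <- array(as.integer(lab), d)
  attr(out, "n_components") <- n
  out
}

# logical array: foreground elements with a face-adjacent background element.
# Truncation-aware: out-of-canvas is treated as unknown (foreground), so an
# object cut by the field of view exposes no boundary there -- contact and
# coverage statistics then describe only the visible membrane.
boundary_mask <- function(fg) {
  d <- dim(fg)
  nd <- length(d)
  out <- array(FALSE, d)
  # vectorized: for each axis/direction, mark fg cells whose neighbor is bg
  for (ax in seq_len(nd)) {
    n <- d[ax]
    if (n < 2L) { out[fg] <- TRUE; next }
    ix_a <- lapply(d, seq_len); ix_b <- ix_a
    ix_a[[ax]] <- 1:(n - 1); ix_b[[ax]] <- 2:n
    a <- do.call(`[`, c(list(fg), ix_a, list(drop = FALSE)))
    b <- do.call(`[`, c(list(fg), ix_b, list(drop = FALSE)))
    hit_a <- a & !b # fg at low side, bg neighbor at high side
    hit_b <- b & !a
    sub_assign <- function(ix, val) {
      cur <- do.call(`[`, c(list(out), ix, list(drop = FALSE)))
      do.call(`[<-`, c(list(out), ix, list(cur | val)))
    }
    out <- sub_assign(ix_a, hit_a)
    out <- sub_assign(ix_b, hit_b)
  }
  out
}

# squared -> physical Euclidean distance (nm) from every element to the
# nearest TRUE source element; spacing in array order.
distance_to <- function(src, spacing) {
  d <- dim(src)
  sq <- .edt_sq(as.logical(src), d, as.numeric(spacing))
  array(sqrt(sq), d)
}

# fill holes of a 2D mask: background components (4-connectivity, the dual of
# 8-connected foreground) not touching the canvas border are foreground.
fill_holes_2d <- function(mask) {
  d <- dim(mask)
  bg <- components(!mask, "faces")
  border_labs <- unique(c(bg[1, ], bg[d[1], ], bg[, 1], bg[, d[2]]))
  border_labs <- border_labs[border_labs > 0L]
  hole <- bg > 0L & !(bg %in% border_labs)
  array(mask | hole, d)
}

# sub-pixel contour perimeter (um). mask: 2D logical; cal: calibration.
# method "contour": crack-traced 0.5-level polygon simplified by
# Douglas-Peucker (eps, px units) -- near-exact on straight edges and discs.
# method "crofton": classical 4-direction Cauchy-Crofton estimate.
perimeter_2d <- function(mask, cal, method = c("contour", "crofton"),
                         eps = 1.0) {
  method <- match.arg(method)
  if (!any(mask)) return(0)
  if (method == "crofton") return(crofton_perimeter(mask, cal))
  loops <- .trace_contours(as.logical(mask), dim(mask), eps)
  sy <- cal$px_y_nm; sx <- cal$px_x_nm
  tot <- 0
  for (pm in loops) {
    dy <- diff(pm[, 1]) * sy
    dx <- diff(pm[, 2]) * sx
    tot <- tot + sum(sqrt(dy^2 + dx^2))
  }
  tot / NM_PER_UM
}

# 4-direction Cauchy-Crofton perimeter (um): P = pi * mean over directions of
# (chord count x line spacing). Stated bias: underestimates long axis-aligned
# edges by ~5%; kept for comparability with stereological conventions.
crofton_perimeter <- function(mask, cal) {
  if (!isTRUE(all.equal(cal$px_x_nm, cal$px_y_nm))) {
    warnf("Crofton perimeter assumes isotropic pixels; using px_x_nm")
  }
  px <- cal$px_x_nm
  m <- mask * 1L
  d <- dim(m)
  chords_along_rows <- function(m) {
    # 0 -> 1 transitions scanning across columns, per row
    nc <- ncol(m)
    if (nc < 2L) return(sum(m))
    sum(m[, -1, drop = FALSE] == 1L & m[, -nc, drop = FALSE] == 0L) +
      sum(m[, 1] == 1L)
  }
  n0 <- chords_along_rows(m)
  n90 <- chords_along_rows(t(m))
  diag_chords <- function(m, anti = FALSE) {
    dd <- dim(m)
    if (anti) m <- m[, rev(seq_len(dd[2])), drop = FALSE]
    pad <- rbind(0L, cbind(0L, m)) # pad[i+1, j+1] == m[i, j]
    prev <- pad[seq_len(dd[1]), seq_len(dd[2]), drop = FALSE]
    sum(m == 1L & prev == 0L)
  }
  n45 <- diag_chords(m)
  n135 <- diag_chords(m, anti = TRUE)
  p_px <- pi / 4 * (n0 + n90 + (n45 + n135) / sqrt(2))
  p_px * px / NM_PER_UM
}

# maximum caliper (Feret) diameter (um) of a 2D mask, measured over the
# convex hull of the pixel-corner cloud.
feret_2d <- function(mask, cal) {
  w <- which(mask, arr.ind = TRUE)
  sy <- cal$px_y_nm; sx <- cal$px_x_nm
  corners <- rbind(
    cbind((w[, 1] - 1.5) * sy, (w[, 2] - 1.5) * sx),
    cbind((w[, 1] - 1.5) * sy, (w[, 2] - 0.5) * sx),
    cbind((w[, 1] - 0.5) * sy, (w[, 2] - 1.5) * sx),
    cbind((w[, 1] - 0.5) * sy, (w[, 2] - 0.5) * sx))
  corners <- unique(corners)
  hull <- corners[chull(corners[, 2], corners[, 1]), , drop = FALSE]
  .max_pairwise_dist(hull) / NM_PER_UM
}

# second-moment (inertia-equivalent) ellipse of a 2D mask in physical
# coordinates; returns semi-axes (nm) and the aspect ratio (>= 1). The
# 1/12-pixel variance term makes one-pixel-wide shapes well-defined.
moment_axes_2d <- function(mask, cal) {
  w <- which(mask, arr.ind = TRUE)
  y <- w[, 1] * cal$px_y_nm
  x <- w[, 2] * cal$px_x_nm
  n <- length(y)
  pop_var <- function(v) if (n > 1) var(v) * (n - 1) / n else 0
  cyy <- pop_var(y) + cal$px_y_nm^2 / 12
  cxx <- pop_var(x) + cal$px_x_nm^2 / 12
  cxy <- if (n > 1) sum((y - mean(y)) * (x - mean(x))) / n else 0
  ev <- eigen(matrix(c(cyy, cxy, cxy, cxx), 2), symmetric = TRUE)$values
  ev <- pmax(ev, 1e-12)
  list(major_nm = 2 * sqrt(ev[1]), minor_nm = 2 * sqrt(ev[2]),
       aspect_ratio = sqrt(ev[1] / ev[2]))
}

# longest shortest path (geodesic diameter) over a set of elements, using
# 8/26-neighbor adjacency with physical step weights (double-sweep
# approximation: exact on trees, standard for curve- and patch-like sets).
# coords: n x ndim matrix of array indices; spacing: physical per axis.
# Returns list(length_nm, from, to) or NULL when n < 2.
geodesic_diameter <- function(coords, spacing) {
  n <- nrow(coords)
  if (n < 2L) return(list(length_nm = 0, from = 1L, to = 1L))
  g <- adjacency_graph(coords, spacing)
  far <- function(v) {
    dvec <- igraph::distances(g, v = v)[1, ]
    dvec[!is.finite(dvec)] <- -1
    which.max(dvec)
  }
  a <- far(1L)
  dvec <- igraph::distances(g, v = a)[1, ]
  dvec[!is.finite(dvec)] <- -1
  b <- which.max(dvec)
  list(length_nm = max(dvec), from = as.integer(a), to = as.integer(b))
}

# weighted graph over elements adjacent within a Chebyshev distance of 1
adjacency_graph <- function(coords, spacing) {
  n <- nrow(coords)
  nd <- ncol(coords)
  dmax <- vapply(seq_len(nd), function(k) max(coords[, k]) + 1L, numeric(1))
  lin <- as.numeric(coords[, 1])
  mult <- 1
  for (k in seq_len(nd - 1)) {
    mult <- mult * dmax[k]
    lin <- lin + as.numeric(coords[, k + 1]) * mult
  }
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  # keep one of each +/- pair
  keep <- apply(offs, 1, function(o) {
    nz <- o[o != 0]
    nz[1] > 0
  })
  offs <- offs[keep, , drop = FALSE]
  ei <- integer(0); ej <- integer(0); ew <- numeric(0)
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    shifted <- lin
    mult <- 1
    shifted <- shifted + o[1]
    for (k in seq_len(nd - 1)) {
      mult <- mult * dmax[k]
      shifted <- shifted + o[k + 1] * mult
    }
    m <- match(shifted, lin)
    hit <- which(!is.na(m))
    if (!length(hit)) next
    wgt <- sqrt(sum((o * spacing)^2))
    ei <- c(ei, hit); ej <- c(ej, m[hit]); ew <- c(ew, rep(wgt, length(hit)))
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(ei)) {
    g <- igraph::add_edges(g, rbind(ei, ej))
    igraph::E(g)$weight <- ew
  }
  g
}
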