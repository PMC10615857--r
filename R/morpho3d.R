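#' Per-object 3D morphometrics of a label volume
#'
#' One record per labelled object in a volume-EM stack: exact physical
#' volume (voxel count times voxel volume), surface area from a smoothed
#' 0.5-level isosurface, skeleton-based length and branching statistics,
#' and the MOAS / nanotunnel flag. Surface meshing uses marching
#' tetrahedra on the object's binary mask after Gaussian smoothing
#' (sigma = 1 voxel): meshing the raw binary mask overestimates a sphere's
#' area by ~9%, the smoothed level set is accurate to ~2% at radius 10
#' voxels and better for larger objects.
#'
#' @param map a 3D [label_map()].
#' @param moas a [moas_params()].
#' @param hyperbranch_min_junctions junction count from which an object is
#'   called hyperbranched (default 3).
#' @param skeleton set `FALSE` to skip skeleton-derived columns (faster for
#'   volume/surface-only screens).
#' @return data.frame with columns `object_id, volume_um3,
#'   surface_area_um2, length_um, feret_um, length_fallback,
#'   junction_count, hyperbranched, moas, tunnel_segments`.
#' @export
measure_objects_3d <- function(map, moas = moas_params(),
                               hyperbranch_min_junctions = 3L,
                               skeleton = TRUE) {
  if (lm_ndim(map) != 3L) stopf("measure_objects_3d requires a 3D label map")
  ids <- lm_labels(map)
  if (!length(ids)) stopf("label volume contains no objects")
  sp <- cal_spacing(map$calibration)
  voxvol_um3 <- prod(sp) / NM_PER_UM^3
  rows <- lapply(ids, function(id) {
    mask <- map$data == id
    vol <- sum(mask) * voxvol_um3
    surf <- surface_area_3d(mask, sp)
    rec <- data.frame(object_id = id, volume_um3 = vol,
                      surface_area_um2 = surf,
                      length_um = NA_real_, feret_um = NA_real_,
                      length_fallback = NA, junction_count = NA_integer_,
                      hyperbranched = NA, moas = NA,
                      tunnel_segments = NA_integer_)
    if (skeleton) {
      sk <- skeletonize(map, id)
      len <- object_length(sk)
      br <- branch_stats(sk, hyperbranch_min_junctions)
      mo <- detect_moas(sk, moas)
      rec$length_um <- len$length_um
      rec$feret_um <- len$feret_um
      rec$length_fallback <- len$fallback
      rec$junction_count <- br$junction_count
      rec$hyperbranched <- br$hyperbranched
      rec$moas <- mo$moas
      rec$tunnel_segments <- mo$tunnel_segments
    }
    rec
  })
  do.call(rbind, rows)
}

# surface area (um^2) of a binary mask: Gaussian-smoothed (sigma voxels)
# marching-tetrahedra isosurface at the 0.5 level, anisotropy-aware.
# Falls back to the raw binary level set for objects too small to survive
# smoothing.
surface_area_3d <- function(mask, spacing, sigma = 1.0) {
  w <- which(mask, arr.ind = TRUE)
  if (!nrow(w)) return(0)
  marg <- as.integer(ceiling(3 * sigma) + 1L)
  lo <- pmax(1L, apply(w, 2, min) - marg)
  hi <- pmin(dim(mask), apply(w, 2, max) + marg)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  # zero-pad so the level set closes even for objects at the canvas edge
  d <- dim(sub) + 2L
  vol <- array(0, d)
  vol[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- sub
  sm <- array(.gauss3d(vol, d, sigma), d)
  a <- .mt_area(sm, d, 0.5, spacing)
  if (a <= 0) a <- .mt_area(vol, d, 0.5, spacing)
  a / NM_PER_UM^2
}
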