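#' Circularity index
#'
#' The roundness measure `4 * pi * A / P^2`: 1 for an ideal circle,
#' decreasing with elongation and membrane irregularity. Discretization can
#' push estimates slightly above 1; such values are reported as computed
#' (not clipped), with a warning above 1.05.
#'
#' @param area area A (um^2, > 0).
#' @param perimeter perimeter P (um, > 0).
#' @return Dimensionless circularity.
#' @examples
#' circularity(pi, 2 * pi)  # ideal unit disc -> 1
#' circularity(1, 4)        # ideal unit square -> pi / 4
#' @export
circularity <- function(area, perimeter) {
  if (any(!is.finite(area)) || any(!is.finite(perimeter)) ||
      any(area <= 0) || any(perimeter <= 0)) {
    stopf("circularity requires positive area and perimeter")
  }
  ci <- 4 * pi * area / perimeter^2
  if (any(ci > 1.05)) {
    warnf("circularity above 1.05 (%.3f): check segmentation/discretization",
          max(ci))
  }
  ci
}

#' Per-object 2D morphometrics of a TEM section
#'
#' One record per positive label: physical area (pixel count times pixel
#' area), sub-pixel contour perimeter, circularity index, maximum Feret
#' (caliper) length and second-moment aspect ratio. Holes inside an object
#' profile (e.g. cristae lumens within a mitochondrion) are filled before
#' measuring area and perimeter: the metrics describe the organelle outline,
#' and cristae are measured separately by [measure_cristae()].
#'
#' @param map a 2D [label_map()] with at least one object.
#' @param perimeter_method `"contour"` (default, sub-pixel) or `"crofton"`
#'   (4-direction stereological estimator; see [perimeter_2d] notes on its
#'   axis-aligned bias).
#' @return data.frame with columns `object_id, area_um2, perimeter_um,
#'   circularity, feret_length_um, aspect_ratio`.
#' @export
measure_objects_2d <- function(map, perimeter_method = "contour") {
  if (lm_ndim(map) != 2L) stopf("measure_objects_2d requires a 2D label map")
  ids <- lm_labels(map)
  if (!length(ids)) stopf("label map contains no objects")
  cal <- map$calibration
  px_area_um2 <- cal$px_x_nm * cal$px_y_nm / NM_PER_UM^2
  rows <- lapply(ids, function(id) {
    mask <- map$data == id
    filled <- fill_holes_2d(mask)
    area <- sum(filled) * px_area_um2
    per <- perimeter_2d(filled, cal, method = perimeter_method)
    data.frame(object_id = id,
               area_um2 = area,
               perimeter_um = per,
               circularity = suppressWarnings(circularity(area, per)),
               feret_length_um = feret_2d(filled, cal),
               aspect_ratio = moment_axes_2d(filled, cal)$aspect_ratio)
  })
  out <- do.call(rbind, rows)
  ci <- out$circularity
  if (any(ci > 1.05)) {
    warnf("circularity above 1.05 for object(s) %s",
          paste(out$object_id[ci > 1.05], collapse = ", "))
  }
  out
}

#' Object count density
#'
#' Number of objects per square micron of a reference region (a cell
#' profile, a quadrant, or the whole field).
#'
#' @param map a [label_map()].
#' @param region_area_um2 reference area (um^2, > 0).
#' @return Objects per um^2.
#' @export
count_density <- function(map, region_area_um2) {
  if (!is.numeric(region_area_um2) || region_area_um2 <= 0) {
    stopf("region_area_um2 must be positive")
  }
  length(lm_labels(map)) / region_area_um2
}

#' Histogram of object areas
#'
#' Left-closed right-open bins (the final bin is closed) over `bin_edges`;
#' values outside the range are counted separately rather than silently
#' dropped. Area histograms expose population shifts (e.g. fragmentation)
#' that a mean comparison hides.
#'
#' @param records output of [measure_objects_2d()] (or any data.frame with
#'   an `area_um2` column).
#' @param bin_edges strictly increasing numeric vector (length >= 2), um^2.
#' @return list with `counts` (length `length(bin_edges) - 1`), `bin_edges`,
#'   and `n_out_of_range`.
#' @export
area_histogram <- function(records, bin_edges) {
  if (length(bin_edges) < 2L || is.unsorted(bin_edges, strictly = TRUE)) {
    stopf("bin_edges must be strictly increasing with length >= 2")
  }
  x <- records$area_um2
  k <- length(bin_edges) - 1L
  if (!length(x)) {
    return(list(counts = rep(0L, k), bin_edges = bin_edges,
                n_out_of_range = 0L))
  }
  idx <- findInterval(x, bin_edges, rightmost.closed = TRUE)
  in_range <- idx >= 1L & idx <= k
  counts <- tabulate(idx[in_range], nbins = k)
  list(counts = counts, bin_edges = bin_edges,
       n_out_of_range = sum(!in_range))
}
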