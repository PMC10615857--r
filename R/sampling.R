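#' Partition a 2D image into rectangular ROIs (quadrants)
#'
#' Tiles a section into `n_rows x n_cols` rectangles for quadrant-based
#' sampling of a cell profile. The tiling is exact (no overlap, no gap);
#' when a dimension is not divisible the remainder pixels are assigned to
#' the last row/column.
#'
#' @param map a 2D [label_map()].
#' @param n_rows,n_cols number of tiles per dimension (>= 1).
#' @return A data.frame with one row per ROI and 1-based inclusive pixel
#'   bounds `row0,row1,col0,col1` plus `roi` index (row-major order).
#' @export
quadrant_partition <- function(map, n_rows = 2L, n_cols = 2L) {
  if (lm_ndim(map) != 2L) stopf("quadrant_partition requires a 2D label map")
  if (n_rows < 1L || n_cols < 1L) stopf("n_rows and n_cols must be >= 1")
  d <- dim(map$data)
  cuts <- function(n, k) {
    base <- n %/% k
    starts <- (seq_len(k) - 1L) * base + 1L
    ends <- starts + base - 1L
    ends[k] <- n # remainder goes to the last row/column
    cbind(starts, ends)
  }
  rr <- cuts(d[1], as.integer(n_rows))
  cc <- cuts(d[2], as.integer(n_cols))
  out <- expand.grid(cr = seq_len(n_rows), ccol = seq_len(n_cols))
  out <- out[order(out$cr, out$ccol), ]
  data.frame(roi = seq_len(nrow(out)),
             row0 = rr[out$cr, 1], row1 = rr[out$cr, 2],
             col0 = cc[out$ccol, 1], col1 = cc[out$ccol, 2])
}

#' Assign objects to quadrant ROIs by centroid
#'
#' Objects straddling an ROI border belong to the ROI containing their
#' centroid (the tie-free convention this package uses, since border
#' handling is otherwise unspecified in quadrant sampling protocols).
#'
#' @param map a 2D [label_map()].
#' @param rois output of [quadrant_partition()].
#' @return Named integer vector: ROI index per object label.
#' @export
assign_quadrants <- function(map, rois) {
  ids <- lm_labels(map)
  out <- integer(length(ids))
  for (i in seq_along(ids)) {
    w <- which(map$data == ids[i], arr.ind = TRUE)
    cy <- mean(w[, 1]); cx <- mean(w[, 2])
    hit <- which(cy >= rois$row0 - 0.5 & cy <= rois$row1 + 0.5 &
                 cx >= rois$col0 - 0.5 & cx <= rois$col1 + 0.5)
    out[i] <- hit[1]
  }
  setNames(out, ids)
}

#' Randomly sample objects for measurement
#'
#' Uniform sampling without replacement of object labels, reproducible for
#' a fixed seed. Unbiased random selection with a stated minimum batch size
#' (default 10) is the standard guard against cherry-picking profiles; when
#' fewer than `min_n` objects exist, all are returned and the insufficiency
#' flag is set rather than silently passing a small batch.
#'
#' @param map a [label_map()] with at least one object.
#' @param min_n minimum number of objects per batch (default 10).
#' @param seed RNG seed (mandatory, for an auditable selection).
#' @param rois optional [quadrant_partition()] output; if given, each
#'   selected object's quadrant index (by centroid) is recorded.
#' @return An object of class `"roi_sample"`: `selected` (object ids),
#'   `insufficient`, `n_available`, `min_n`, `seed`, `quadrant_index`.
#' @export
sample_objects <- function(map, min_n = 10L, seed, rois = NULL) {
  ids <- lm_labels(map)
  if (!length(ids)) stopf("label map contains no objects")
  insufficient <- length(ids) < min_n
  selected <- if (insufficient) ids else
    with_seed(seed, sort(sample(ids, min_n)))
  quad <- NULL
  if (!is.null(rois)) {
    all_q <- assign_quadrants(map, rois)
    quad <- all_q[as.character(selected)]
  }
  structure(list(selected = selected, insufficient = insufficient,
                 n_available = length(ids), min_n = as.integer(min_n),
                 seed = as.integer(seed), quadrant_index = quad),
            class = "roi_sample")
}

#' @export
print.roi_sample <- function(x, ...) {
  cat(sprintf("<roi_sample: %d/%d objects%s, seed %d>\n", length(x$selected),
              x$n_available, if (x$insufficient) " (INSUFFICIENT n)" else "",
              x$seed))
  invisible(x)
}
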