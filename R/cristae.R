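#' Cristae metrics within each mitochondrion
#'
#' Measures inner-membrane folds from paired 2D label maps: one for the
#' mitochondrial profiles and one for the cristae. Each 8-connected crista
#' component is assigned to the mitochondrion with which it shares the most
#' pixels; crista pixels falling outside every mitochondrion are clipped
#' (and components with zero overlap reported and excluded). Per
#' mitochondrion the summary gives the crista count, the areal ("volume")
#' density Sum(crista area)/mito area -- the standard stereological
#' estimator of 3D volume fraction from a 2D section -- the total crista
#' membrane length as a surface-area proxy, and the lamellar/tubular split.
#'
#' @param mito_map,cristae_map 2D [label_map()]s on the same grid and
#'   calibration. `cristae_map` is binarized; crista identity comes from
#'   8-connected components.
#' @param lamellar_min_aspect aspect-ratio threshold (inclusive) above which
#'   a crista profile is classified lamellar (sheet-like) rather than
#'   tubular. Default 3.0 (an explicit, tunable convention; sheet profiles
#'   in sections are strongly elongated, tube cross-sections near-round).
#' @param membrane_factor multiply the membrane-length surface proxy by a
#'   section thickness (nm) to report an area instead; `NULL` (default)
#'   reports length in um.
#' @return list with `cristae` (per-crista data.frame: `mito_id, crista_id,
#'   area_um2, membrane_length_um, aspect_ratio, shape_class`) and
#'   `summary` (per-mito data.frame: `mito_id, cristae_count,
#'   volume_density, total_crista_area_um2, surface_proxy_um, pct_lamellar,
#'   pct_tubular`).
#' @export
measure_cristae <- function(mito_map, cristae_map, lamellar_min_aspect = 3.0,
                            membrane_factor = NULL) {
  if (lm_ndim(mito_map) != 2L) stopf("measure_cristae requires 2D label maps")
  check_same_grid(mito_map, cristae_map)
  cal <- mito_map$calibration
  px_area_um2 <- cal$px_x_nm * cal$px_y_nm / NM_PER_UM^2
  mito_ids <- lm_labels(mito_map)
  comp <- components(cristae_map$data > 0L, "full")
  n_cristae <- attr(comp, "n_components")
  recs <- list()
  for (cid in seq_len(n_cristae)) {
    cmask <- comp == cid
    over <- mito_map$data[cmask]
    over <- over[over > 0L]
    if (!length(over)) {
      warnf("crista component %d overlaps no mitochondrion; excluded", cid)
      next
    }
    host <- as.integer(names(which.max(table(over))))
    # clip to the host mitochondrion's support so density stays <= 1
    cmask <- cmask & mito_map$data == host
    if (!any(cmask)) next
    ax <- moment_axes_2d(cmask, cal)
    rec <- data.frame(
      mito_id = host, crista_id = cid,
      area_um2 = sum(cmask) * px_area_um2,
      membrane_length_um = perimeter_2d(cmask, cal),
      aspect_ratio = ax$aspect_ratio)
    rec$shape_class <- classify_crista(rec, lamellar_min_aspect)
    recs[[length(recs) + 1]] <- rec
  }
  cristae <- if (length(recs)) do.call(rbind, recs) else
    data.frame(mito_id = integer(0), crista_id = integer(0),
               area_um2 = numeric(0), membrane_length_um = numeric(0),
               aspect_ratio = numeric(0), shape_class = character(0))
  summary <- do.call(rbind, lapply(mito_ids, function(mid) {
    sub <- cristae[cristae$mito_id == mid, , drop = FALSE]
    marea <- sum(fill_holes_2d(mito_map$data == mid)) * px_area_um2
    n <- nrow(sub)
    proxy <- sum(sub$membrane_length_um)
    if (!is.null(membrane_factor)) proxy <- proxy * membrane_factor
    data.frame(
      mito_id = mid,
      cristae_count = n,
      volume_density = if (marea > 0) sum(sub$area_um2) / marea else 0,
      total_crista_area_um2 = sum(sub$area_um2),
      surface_proxy_um = proxy,
      pct_lamellar = if (n) 100 * sum(sub$shape_class == "lamellar") / n else NA_real_,
      pct_tubular = if (n) 100 * sum(sub$shape_class == "tubular") / n else NA_real_)
  }))
  list(cristae = cristae, summary = summary)
}

#' Classify a crista profile as lamellar or tubular
#'
#' Sheet-like (lamellar) cristae appear as strongly elongated profiles in a
#' section, tubular cristae as near-round cross-sections; the aspect ratio
#' of the second-moment ellipse separates the two. The threshold is
#' inclusive: a ratio exactly at `lamellar_min_aspect` is lamellar. The
#' classification is scale-invariant (rescaling the calibration does not
#' change it).
#'
#' @param record one-row data.frame (or list) with an `aspect_ratio` field.
#' @param lamellar_min_aspect inclusive lamellar threshold (default 3.0).
#' @return `"lamellar"` or `"tubular"`.
#' @export
classify_crista <- function(record, lamellar_min_aspect = 3.0) {
  if (record$aspect_ratio >= lamellar_min_aspect) "lamellar" else "tubular"
}

#' Validate and summarize human cristae scores
#'
#' The cristae score is a human-assigned rating of cristae quantity and
#' form from 0 (worst) to 4 (best). It is a subjective judgment: this
#' package validates and aggregates scores but never computes them, and the
#' returned metadata carries that caveat for downstream reports.
#'
#' @param scores data.frame with columns `mito_id` and `score`, e.g. read
#'   from the scoring CSV of a blinded quantifier.
#' @return list with `mean`, `median`, `n`, and `note` (the subjectivity
#'   caveat). With no scores, `n` is 0 and the statistics are `NA`.
#' @export
validate_scores <- function(scores) {
  if (is.null(scores) || !nrow(scores)) {
    return(list(mean = NA_real_, median = NA_real_, n = 0L,
                note = "cristae scoring is a subjective judgment"))
  }
  s <- scores$score
  bad <- !is.finite(s) | s != round(s) | s < 0 | s > 4
  if (any(bad)) {
    stopf("cristae score out of range 0-4 for mito_id %s",
          paste(scores$mito_id[bad], collapse = ", "))
  }
  list(mean = mean(s), median = median(s), n = length(s),
       note = "cristae scoring is a subjective judgment")
}
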