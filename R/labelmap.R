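ORGANELLE_CLASSES <- c("mitochondrion", "er", "crista", "lysosome", "other")

#' Integer label map of one organelle class
#'
#' The container consumed by every measurement module: a 2D image or 3D stack
#' of non-negative integer labels (0 = background, each positive label one
#' object) together with its [calibration()]. 3D arrays are ordered (z, y, x),
#' matching slice-stack acquisition order; 2D arrays are (y, x). Coordinates
#' reported by the package are 0-based.
#'
#' @param data integer matrix (y, x) or 3D array (z, y, x) of labels.
#' @param organelle_class one of `"mitochondrion"`, `"er"`, `"crista"`,
#'   `"lysosome"`, `"other"`.
#' @param calibration a [calibration()] whose dimensionality (2D/3D) matches
#'   `data`.
#' @return An object of class `"labelmap"`.
#' @export
label_map <- function(data, organelle_class = "other", calibration) {
  organelle_class <- match.arg(organelle_class, ORGANELLE_CLASSES)
  if (!inherits(calibration, "calibration")) {
    stopf("`calibration` must be a calibration object")
  }
  if (is.null(dim(data))) stopf("`data` must be a matrix or 3D array")
  nd <- length(dim(data))
  if (!nd %in% c(2L, 3L)) stopf("`data` must have 2 or 3 dimensions")
  if (nd != cal_ndim(calibration)) {
    stopf("calibration is %dD but data is %dD", cal_ndim(calibration), nd)
  }
  if (is.double(data)) {
    if (any(abs(data - round(data)) > 1e-6, na.rm = TRUE)) {
      stopf("label data must be integer-valued")
    }
    storage.mode(data) <- "integer"
  }
  if (!is.integer(data)) storage.mode(data) <- "integer"
  if (anyNA(data) || any(data < 0L)) {
    stopf("labels must be non-negative integers without NA")
  }
  structure(list(data = data, organelle_class = organelle_class,
                 calibration = calibration),
            class = "labelmap")
}

#' @export
print.labelmap <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<labelmap %s: %s, %d object(s)>\n", x$organelle_class,
              paste(d, collapse = "x"), length(lm_labels(x))))
  print(x$calibration)
  invisible(x)
}

#' @export
dim.labelmap <- function(x) dim(x$data)

lm_ndim <- function(map) length(dim(map$data))

# sorted positive labels present in the map
lm_labels <- function(map) {
  u <- sort(unique(as.vector(map$data)))
  u[u > 0L]
}

check_same_grid <- function(a, b) {
  if (!identical(dim(a$data), dim(b$data))) {
    stopf("label maps have different shapes (%s vs %s)",
          paste(dim(a$data), collapse = "x"), paste(dim(b$data), collapse = "x"))
  }
  if (!isTRUE(all.equal(cal_spacing(a$calibration), cal_spacing(b$calibration)))) {
    stopf("label maps have different calibrations")
  }
  invisible(TRUE)
}

#' Relabel a mask by connected components
#'
#' Utility for binary masks exported without object identities: each
#' connected component (8-connectivity in 2D, 26-connectivity in 3D, the
#' package-wide object-identity convention) becomes one positive label.
#'
#' @param map a [label_map()].
#' @return A `labelmap` with components labelled 1..k in scan order.
#' @export
relabel_components <- function(map) {
  nd <- lm_ndim(map)
  lab <- .cc_label(as.integer(map$data != 0L), dim(map$data), 3L)
  arr <- array(lab, dim(map$data))
  label_map(arr, map$organelle_class, map$calibration)
}
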