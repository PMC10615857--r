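#' Load an integer label map from disk
#'
#' Reads segmentation label maps in the formats segmentation pipelines
#' export: multi-page TIFF (each page one z slice), PNG (2D only, 8- or
#' 16-bit grayscale) and HDF5 (the common export format for volume-EM
#' segmentations, typically 8-bit). Values are preserved bit-exactly and
#' coerced to integers; 3D stacks are ordered (z, y, x). A calibration is
#' mandatory: there is no implicit "1 px = 1 nm" scale.
#'
#' For HDF5, the first dataset found at the file root is read unless
#' `dataset` names one explicitly (the 8-bit HDF5 export convention does not
#' fix a dataset name). Datasets are read with the dimension order rhdf5
#' reports; files written by this package round-trip exactly. Files written
#' by C-order tools (e.g. h5py) arrive with reversed axes; pass
#' `reverse_dims = TRUE` for those.
#'
#' @param path file path ending in `.tif`, `.tiff`, `.png`, `.h5`, `.hdf5`
#'   or `.hdf`.
#' @param organelle_class organelle class stored on the map.
#' @param calibration a [calibration()]; its dimensionality must match the
#'   file contents.
#' @param dataset optional HDF5 dataset name.
#' @param reverse_dims reverse axis order of an HDF5 dataset after reading.
#' @return A [label_map()].
#' @export
load_label_map <- function(path, organelle_class = "other", calibration,
                           dataset = NULL, reverse_dims = FALSE) {
  if (!file.exists(path)) stopf("file not found: '%s'", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    tif = , tiff = {
      pages <- read_tiff_pages(path)
      if (length(pages) == 1L) pages[[1]]
      else {
        d <- dim(pages[[1]])
        a <- array(0L, c(length(pages), d))
        for (i in seq_along(pages)) a[i, , ] <- pages[[i]]
        a
      }
    },
    png = read_png_labels(path),
    h5 = , hdf5 = , hdf = read_h5_labels(path, dataset, reverse_dims),
    stopf("unsupported file extension '.%s'", ext)
  )
  label_map(arr, organelle_class, calibration)
}

read_png_labels <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] %in% c(2L, 4L)) x <- x[, , -dim(x)[3], drop = FALSE] # alpha
    if (length(dim(x)) == 3L && dim(x)[3] > 1L) {
      if (max(abs(x[, , 1] - x[, , 2])) > 0 ||
          max(abs(x[, , 1] - x[, , 3])) > 0) {
        stopf("PNG label maps must be grayscale")
      }
    }
    x <- x[, , 1]
  }
  # readPNG normalises by 2^depth - 1; recover the stored integers
  v8 <- x * 255
  if (max(abs(v8 - round(v8))) < 1e-6) return(matrix(as.integer(round(v8)), nrow(x)))
  v16 <- x * 65535
  if (max(abs(v16 - round(v16))) < 1e-3) return(matrix(as.integer(round(v16)), nrow(x)))
  stopf("PNG does not contain integer label data")
}

read_h5_labels <- function(path, dataset, reverse_dims) {
  info <- rhdf5::h5ls(path)
  on.exit(rhdf5::h5closeAll())
  if (is.null(dataset)) {
    ds <- info[info$otype == "H5I_DATASET", , drop = FALSE]
    root <- ds[ds$group == "/", , drop = FALSE]
    if (nrow(root)) dataset <- root$name[1]
    else if (nrow(ds)) dataset <- file.path(ds$group[1], ds$name[1])
    else stopf("HDF5 file '%s' contains no dataset", path)
  }
  arr <- rhdf5::h5read(path, dataset)
  if (is.raw(arr)) {
    d <- dim(arr)
    arr <- array(as.integer(arr), d)
  }
  if (reverse_dims) arr <- aperm(arr, rev(seq_along(dim(arr))))
  arr
}

#' Write a label map to disk
#'
#' Inverse of [load_label_map()]; the format follows the file extension.
#' TIFF output is uncompressed baseline grayscale (8/16/32-bit as needed,
#' multi-page for stacks); PNG (2D, labels <= 255) is 8-bit grayscale; HDF5
#' stores one dataset (`uint8` when labels fit, 32-bit otherwise), the
#' volume-EM segmentation export convention.
#'
#' @param map a [label_map()].
#' @param path destination path.
#' @param dataset HDF5 dataset name (default `"labels"`).
#' @return `path`, invisibly.
#' @export
write_label_map <- function(map, path, dataset = "labels") {
  ext <- tolower(tools::file_ext(path))
  arr <- map$data
  nd <- lm_ndim(map)
  switch(ext,
    tif = , tiff = {
      pages <- if (nd == 2L) list(arr)
               else lapply(seq_len(dim(arr)[1]), function(i) arr[i, , ])
      write_tiff_pages(pages, path)
    },
    png = {
      if (nd != 2L) stopf("PNG output is 2D only")
      if (max(arr) > 255L) stopf("PNG output supports labels up to 255")
      png::writePNG(arr / 255, path)
    },
    h5 = , hdf5 = , hdf = {
      if (file.exists(path)) file.remove(path)
      rhdf5::h5createFile(path)
      on.exit(rhdf5::h5closeAll())
      h5type <- if (max(arr) <= 255L) "H5T_STD_U8LE" else "H5T_STD_I32LE"
      rhdf5::h5createDataset(path, dataset, dims = dim(arr),
                             H5type = h5type)
      rhdf5::h5write(arr, path, dataset)
    },
    stopf("unsupported file extension '.%s'", ext)
  )
  invisible(path)
}
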