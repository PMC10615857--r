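# Minimal baseline TIFF codec for integer label images.
#
# No TIFF package ships with this R stack, so uncompressed grayscale
# baseline TIFF (the subset segmentation tools export for label maps) is
# implemented directly: 8/16/32-bit unsigned, one sample per pixel,
# compression "none", multi-page (one page per z slice). OME-TIFF files are
# readable as plain multi-page TIFF; OME-XML metadata is ignored.

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_bytes = 279L, sample_format = 339L)

read_tiff_pages <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8) stopf("'%s' is not a TIFF file", path)
  endian <- if (raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) "big"
            else stopf("'%s' is not a TIFF file (bad byte-order mark)", path)
  rd <- function(off, what, n, size) {
    readBin(raw[(off + 1):(off + n * size)], what, n = n, size = size,
            endian = endian, signed = size >= 4) # unsigned only for 1/2 bytes
  }
  magic <- rd(2, "integer", 1, 2)
  if (magic != 42) stopf("'%s' is not a TIFF file (magic %d)", path, magic)
  ifd_off <- rd(4, "integer", 1, 4)
  pages <- list()
  while (ifd_off != 0) {
    n_entries <- rd(ifd_off, "integer", 1, 2)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- rd(e, "integer", 1, 2)
      type <- rd(e + 2, "integer", 1, 2)
      cnt <- rd(e + 4, "integer", 1, 4)
      size <- c(1, 1, 2, 4, 8)[type]
      if (is.na(size)) next
      inline <- size * cnt <= 4
      voff <- if (inline) e + 8 else rd(e + 8, "integer", 1, 4)
      vals <- if (type %in% c(3L, 4L)) rd(voff, "integer", cnt, size) else NULL
      tags[[as.character(tag)]] <- vals
    }
    gt <- function(id, default = NULL) tags[[as.character(id)]] %||% default
    w <- gt(TIFF_TAGS["width"]); h <- gt(TIFF_TAGS["length"])
    if (is.null(w) || is.null(h)) stopf("TIFF page missing dimensions")
    bits <- gt(TIFF_TAGS["bits"], 8L)[1]
    comp <- gt(TIFF_TAGS["compression"], 1L)
    spp <- gt(TIFF_TAGS["spp"], 1L)
    fmt <- gt(TIFF_TAGS["sample_format"], 1L)[1]
    if (comp != 1L) stopf("only uncompressed TIFF is supported (compression %d)", comp)
    if (spp != 1L) stopf("only single-channel label TIFFs are supported")
    if (!bits %in% c(8L, 16L, 32L)) stopf("unsupported bit depth %d", bits)
    if (fmt != 1L) stopf("only unsigned-integer TIFF samples are supported")
    offs <- gt(TIFF_TAGS["strip_offsets"])
    cnts <- gt(TIFF_TAGS["strip_bytes"])
    bpp <- bits %/% 8L
    px <- integer(0)
    for (s in seq_along(offs)) {
      npx <- cnts[s] %/% bpp
      if (bits == 32L) {
        px <- c(px, readBin(raw[(offs[s] + 1):(offs[s] + cnts[s])], "integer",
                            n = npx, size = 4, endian = endian))
      } else {
        px <- c(px, rd(offs[s], "integer", npx, bpp))
      }
    }
    if (length(px) != w * h) stopf("TIFF strip data does not match dimensions")
    # strips are row-major; R matrices are column-major
    pages[[length(pages) + 1]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
    ifd_off <- rd(ifd_off + 2 + n_entries * 12, "integer", 1, 4)
  }
  if (!length(pages)) stopf("TIFF file '%s' contains no pages", path)
  pages
}

write_tiff_pages <- function(pages, path) {
  maxv <- max(0L, vapply(pages, max, integer(1)))
  bits <- if (maxv <= 255L) 8L else if (maxv <= 65535L) 16L else 32L
  bpp <- bits %/% 8L
  # deterministic layout: header(8) | page1 data | page1 IFD | page2 data | ...
  n_entries <- 10L
  ifd_size <- 2L + n_entries * 12L + 4L
  offs <- vector("list", length(pages))
  pos <- 8L
  for (i in seq_along(pages)) {
    nbytes <- length(pages[[i]]) * bpp
    pad <- nbytes %% 2L # keep IFDs word-aligned
    offs[[i]] <- list(data = pos, ifd = pos + nbytes + pad, pad = pad)
    pos <- pos + nbytes + pad + ifd_size
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wint <- function(x, size) writeBin(as.integer(x), con, size = size,
                                     endian = "little")
  writeBin(as.raw(c(0x49, 0x49, 0x2a, 0x00)), con)
  wint(offs[[1]]$ifd, 4)
  for (i in seq_along(pages)) {
    m <- pages[[i]]
    h <- nrow(m); w <- ncol(m)
    vals <- as.integer(t(m)) # row-major
    if (bits == 32L) writeBin(vals, con, size = 4, endian = "little")
    else writeBin(vals, con, size = bpp, endian = "little")
    if (offs[[i]]$pad) writeBin(as.raw(0), con)
    entry <- function(tag, type, count, value) {
      wint(tag, 2); wint(type, 2); wint(count, 4)
      if (type == 3L) { wint(value, 2); wint(0, 2) } else wint(value, 4)
    }
    wint(n_entries, 2)
    entry(TIFF_TAGS[["width"]], 4L, 1L, w)
    entry(TIFF_TAGS[["length"]], 4L, 1L, h)
    entry(TIFF_TAGS[["bits"]], 3L, 1L, bits)
    entry(TIFF_TAGS[["compression"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["photometric"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["strip_offsets"]], 4L, 1L, offs[[i]]$data)
    entry(TIFF_TAGS[["spp"]], 3L, 1L, 1L)
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, 1L, h)
    entry(TIFF_TAGS[["strip_bytes"]], 4L, 1L, length(m) * bpp)
    entry(TIFF_TAGS[["sample_format"]], 3L, 1L, 1L)
    wint(if (i < length(pages)) offs[[i + 1]]$ifd else 0L, 4)
  }
  invisible(path)
}
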