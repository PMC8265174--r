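# Minimal baseline TIFF codec.
#
# No TIFF reader ships with the pre-installed R stack, so the package carries
# its own: little-endian or big-endian baseline TIFF, uncompressed,
# single-sample grayscale, 8/16-bit unsigned integer or 32-bit float,
# multi-page. Written files are little-endian, one strip per page, and are
# readable by standard tools (validated against Python tifffile in the test
# suite). Anything fancier (compression, tiles, RGB, BigTIFF) is rejected
# with a clear error.

.TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
                photometric = 262L, strip_offsets = 273L, spp = 277L,
                rows_per_strip = 278L, strip_bytes = 279L,
                sample_format = 339L)

.tiff_read_raw <- function(raw, what, n, size, offset, endian, signed = TRUE) {
  readBin(raw[(offset + 1L):(offset + n * size)], what = what, n = n,
          size = size, endian = endian, signed = signed)
}

# Parse one IFD; returns list(tags = named list of numeric vectors,
# next_offset). `raw` is the whole file.
.tiff_read_ifd <- function(raw, offset, endian) {
  nent <- .tiff_read_raw(raw, "integer", 1L, 2L, offset, endian,
                         signed = FALSE)
  tags <- list()
  base <- offset + 2L
  for (i in seq_len(nent)) {
    e <- base + (i - 1L) * 12L
    tag <- .tiff_read_raw(raw, "integer", 1L, 2L, e, endian, signed = FALSE)
    type <- .tiff_read_raw(raw, "integer", 1L, 2L, e + 2L, endian,
                           signed = FALSE)
    cnt <- .tiff_read_raw(raw, "integer", 1L, 4L, e + 4L, endian)
    size <- switch(as.character(type), "1" = 1L, "2" = 1L, "3" = 2L,
                   "4" = 4L, "11" = 4L, NA_integer_)
    if (is.na(size)) next  # skip RATIONAL etc.
    nbytes <- size * cnt
    voff <- if (nbytes <= 4L) e + 8L else
      .tiff_read_raw(raw, "integer", 1L, 4L, e + 8L, endian)
    vals <- switch(as.character(type),
      "1" = .tiff_read_raw(raw, "integer", cnt, 1L, voff, endian,
                           signed = FALSE),
      "2" = .tiff_read_raw(raw, "integer", cnt, 1L, voff, endian,
                           signed = FALSE),
      "3" = .tiff_read_raw(raw, "integer", cnt, 2L, voff, endian,
                           signed = FALSE),
      "4" = .tiff_read_raw(raw, "integer", cnt, 4L, voff, endian),
      "11" = .tiff_read_raw(raw, "double", cnt, 4L, voff, endian))
    tags[[as.character(tag)]] <- vals
  }
  nxt <- .tiff_read_raw(raw, "integer", 1L, 4L,
                        base + nent * 12L, endian)
  list(tags = tags, next_offset = nxt)
}

# Read a (multi-page) grayscale TIFF. Returns list(pages = list of numeric
# matrices [y, x], bits, sample_format).
.read_tiff <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  order <- rawToChar(raw[1:2])
  endian <- if (order == "II") "little" else if (order == "MM") "big" else
    stop("not a TIFF file: ", path, call. = FALSE)
  magic <- .tiff_read_raw(raw, "integer", 1L, 2L, 2L, endian, signed = FALSE)
  if (magic != 42L) stop("not a baseline TIFF: ", path, call. = FALSE)
  offset <- .tiff_read_raw(raw, "integer", 1L, 4L, 4L, endian)
  pages <- list()
  bits <- NULL
  fmt <- NULL
  while (offset != 0L) {
    ifd <- .tiff_read_ifd(raw, offset, endian)
    tg <- ifd$tags
    gv <- function(id, default = NULL) {
      v <- tg[[as.character(id)]]
      if (is.null(v)) default else v
    }
    comp <- gv(259L, 1L)[1]
    if (comp != 1L)
      stop("unsupported TIFF compression (", comp, "); only uncompressed ",
           "baseline TIFF is supported", call. = FALSE)
    w <- gv(256L)[1]
    h <- gv(257L)[1]
    b <- gv(258L, 8L)[1]
    sf <- gv(339L, 1L)[1]
    spp <- gv(277L, 1L)[1]
    if (is.null(w) || is.null(h))
      stop("malformed TIFF: missing dimensions", call. = FALSE)
    if (spp != 1L)
      stop("unsupported TIFF: ", spp, " samples per pixel (grayscale only)",
           call. = FALSE)
    ok <- (sf == 1L && b %in% c(8L, 16L)) || (sf == 3L && b == 32L)
    if (!ok)
      stop("unsupported TIFF dtype: ", b, "-bit, sample format ", sf,
           " (8/16-bit unsigned or 32-bit float only)", call. = FALSE)
    so <- gv(273L)
    sb <- gv(279L)
    if (is.null(so)) stop("malformed TIFF: no strip offsets", call. = FALSE)
    if (is.null(sb)) sb <- rep(w * h * (b / 8L) / length(so), length(so))
    buf <- do.call(c, lapply(seq_along(so), function(i) {
      raw[(so[i] + 1L):(so[i] + sb[i])]
    }))
    vals <- if (sf == 3L) {
      readBin(buf, "double", n = w * h, size = 4L, endian = endian)
    } else {
      readBin(buf, "integer", n = w * h, size = b / 8L, endian = endian,
              signed = FALSE)
    }
    # TIFF rows are y, fastest index x; build [y, x]
    pages[[length(pages) + 1L]] <- matrix(as.numeric(vals), nrow = h,
                                          ncol = w, byrow = TRUE)
    if (is.null(bits)) {
      bits <- b
      fmt <- sf
    } else if (bits != b || fmt != sf) {
      stop("inconsistent dtypes across TIFF pages", call. = FALSE)
    }
    offset <- ifd$next_offset
  }
  if (!length(pages)) stop("TIFF contains no images: ", path, call. = FALSE)
  list(pages = pages, bits = bits, sample_format = fmt)
}

.tiff_u16le <- function(v) {
  v <- as.integer(v)
  as.raw(rbind(bitwAnd(v, 255L), bitwShiftR(v, 8L)))
}

.tiff_u32le <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
               (v %/% 16777216) %% 256))
}

# Write pages (list of numeric [y, x] matrices) as little-endian baseline
# TIFF. dtype one of "uint8", "uint16", "float32".
.write_tiff <- function(pages, path, dtype = "uint16") {
  bits <- switch(dtype, uint8 = 8L, uint16 = 16L, float32 = 32L,
                 stop("unsupported dtype: ", dtype, call. = FALSE))
  sf <- if (dtype == "float32") 3L else 1L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(.tiff_u16le(42L), con)
  pos <- 8L  # next free byte after header (offset of first page's data)
  writeBin(.tiff_u32le(0L), con)  # patched below; first IFD comes after data
  # layout: header | page1 data | page1 IFD | page2 data | page2 IFD | ...
  ifd_entries <- 10L
  ifd_size <- 2L + ifd_entries * 12L + 4L
  offsets <- numeric(0)
  for (p in pages) {
    nb <- length(p) * (bits / 8L)
    offsets <- c(offsets, pos)
    pos <- pos + nb + ifd_size
  }
  seek(con, 4L, rw = "write")
  writeBin(.tiff_u32le(offsets[1] + length(pages[[1]]) * (bits / 8L)), con)
  seek(con, 8L, rw = "write")
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    h <- nrow(p)
    w <- ncol(p)
    vals <- as.vector(t(p))  # x fastest
    if (dtype == "uint8") {
      writeBin(as.raw(as.integer(vals)), con)
    } else if (dtype == "uint16") {
      writeBin(.tiff_u16le(vals), con)
    } else {
      writeBin(as.numeric(vals), con, size = 4L, endian = "little")
    }
    data_off <- offsets[i]
    nb <- length(p) * (bits / 8L)
    nxt <- if (i < length(pages))
      offsets[i + 1] + length(pages[[i + 1]]) * (bits / 8L) else 0L
    entry <- function(tag, type, count, value) {
      c(.tiff_u16le(tag), .tiff_u16le(type), .tiff_u32le(count),
        if (type == 3L) c(.tiff_u16le(value), as.raw(c(0L, 0L)))
        else .tiff_u32le(value))
    }
    ifd <- c(
      .tiff_u16le(ifd_entries),
      entry(256L, 4L, 1L, w),
      entry(257L, 4L, 1L, h),
      entry(258L, 3L, 1L, bits),
      entry(259L, 3L, 1L, 1L),       # no compression
      entry(262L, 3L, 1L, 1L),       # BlackIsZero
      entry(273L, 4L, 1L, data_off), # one strip per page
      entry(277L, 3L, 1L, 1L),
      entry(278L, 4L, 1L, h),
      entry(279L, 4L, 1L, nb),
      entry(339L, 3L, 1L, sf),
      .tiff_u32le(nxt)
    )
    writeBin(ifd, con)
  }
  invisible(path)
}
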