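# Minimal baseline TIFF codec: multi-page, grayscale, uncompressed,
# little-endian, one strip per page; sample formats uint8, uint16 and
# float32.  Written by hand because no TIFF-capable R package is available
# in the target environment; covers exactly the volumes and float maps this
# package exchanges (and anything else baseline-conformant a scanner
# export would produce in that envelope).

tiff_types <- c(uint8 = 1L, uint16 = 2L, float32 = 4L) # bytes per sample

u16le <- function(v) {
  v <- as.integer(v)
  as.raw(as.vector(rbind(v %% 256L, v %/% 256L)))
}
u32le <- function(v) {
  v <- as.numeric(v)
  b0 <- v %% 256; v <- v %/% 256
  b1 <- v %% 256; v <- v %/% 256
  b2 <- v %% 256; b3 <- v %/% 256
  as.raw(as.vector(rbind(b0, b1, b2, b3)))
}

tiff_entry <- function(tag, type, count, value) {
  # type 3 = SHORT, 4 = LONG; value fits inline (count 1 here)
  val <- if (type == 3L) c(u16le(value), as.raw(c(0, 0))) else u32le(value)
  c(u16le(tag), u16le(type), u32le(count), val)
}

encode_page <- function(mat, type) {
  # TIFF is row-major; R matrices are column-major
  v <- as.vector(t(mat))
  switch(type,
    uint8 = as.raw(as.integer(round(v))),
    uint16 = u16le(as.integer(round(v))),
    float32 = writeBin(as.numeric(v), raw(), size = 4L, endian = "little"))
}

#' Write a multi-page grayscale TIFF
#'
#' Baseline uncompressed little-endian TIFF, one page per matrix, one strip
#' per page.  `uint8`/`uint16` pages expect integer sample values in range;
#' `float32` pages store IEEE single-precision samples.
#'
#' @param pages A matrix, 3-D array (first index = page), or list of
#'   matrices, all of one shape.
#' @param path Output file path.
#' @param type `"uint8"`, `"uint16"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, type = c("uint16", "uint8", "float32")) {
  type <- match.arg(type)
  if (is.matrix(pages)) pages <- list(pages)
  if (is.array(pages) && length(dim(pages)) == 3L) {
    arr <- pages
    pages <- lapply(seq_len(dim(arr)[1]), function(i) {
      m <- arr[i, , ]
      dim(m) <- dim(arr)[2:3]
      m
    })
  }
  stopifnot(is.list(pages), length(pages) >= 1L,
            all(vapply(pages, is.matrix, logical(1))))
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  if (!all(vapply(pages, function(p) nrow(p) == h && ncol(p) == w, logical(1))))
    stop("all TIFF pages must share one shape", call. = FALSE)
  bps <- 8L * tiff_types[[type]]
  fmt <- if (type == "float32") 3L else 1L
  strip_len <- h * w * tiff_types[[type]]

  n <- length(pages)
  data_off <- 8
  strip_off <- data_off + (seq_len(n) - 1) * strip_len
  ifd_size <- 2 + 10 * 12 + 4
  ifd_off <- data_off + n * strip_len + (seq_len(n) - 1) * ifd_size

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(0x49, 0x49)), u16le(42L), u32le(ifd_off[1])), con)
  for (p in pages) writeBin(encode_page(p, type), con)
  for (i in seq_len(n)) {
    next_off <- if (i < n) ifd_off[i + 1] else 0
    ifd <- c(
      u16le(10L),
      tiff_entry(256L, 4L, 1L, w),            # ImageWidth
      tiff_entry(257L, 4L, 1L, h),            # ImageLength
      tiff_entry(258L, 3L, 1L, bps),          # BitsPerSample
      tiff_entry(259L, 3L, 1L, 1L),           # Compression: none
      tiff_entry(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
      tiff_entry(273L, 4L, 1L, strip_off[i]), # StripOffsets
      tiff_entry(277L, 3L, 1L, 1L),           # SamplesPerPixel
      tiff_entry(278L, 4L, 1L, h),            # RowsPerStrip
      tiff_entry(279L, 4L, 1L, strip_len),    # StripByteCounts
      tiff_entry(339L, 3L, 1L, fmt),          # SampleFormat
      u32le(next_off))
    writeBin(ifd, con)
  }
  invisible(path)
}

read_uint <- function(raw, size) {
  readBin(raw, "integer", n = length(raw) / size, size = size,
          signed = size == 4L, endian = "little")
}

#' Read a multi-page grayscale TIFF
#'
#' Supports the baseline envelope [write_tiff()] produces: uncompressed,
#' little-endian, single-sample grayscale pages (uint8/uint16/float32),
#' any strip layout.
#'
#' @param path TIFF file path.
#' @return List with `pages` (list of numeric matrices; raw sample values,
#'   not normalized) and `type`.
#' @export
read_tiff <- function(path) {
  raw_all <- readBin(path, "raw", file.size(path))
  if (length(raw_all) < 8 || raw_all[1] != 0x49 || raw_all[2] != 0x49)
    stop("not a little-endian TIFF", call. = FALSE)
  if (read_uint(raw_all[3:4], 2L) != 42L)
    stop("bad TIFF magic", call. = FALSE)
  at <- function(off, len) raw_all[(off + 1):(off + len)] # 0-based offsets
  u <- function(off, size) read_uint(at(off, size), size)

  ifd_off <- u(4, 4L)
  pages <- list()
  type <- NULL
  while (ifd_off != 0) {
    n_entries <- u(ifd_off, 2L)
    tags <- list()
    for (i in seq_len(n_entries)) {
      e <- ifd_off + 2 + (i - 1) * 12
      tag <- u(e, 2L); typ <- u(e + 2, 2L); cnt <- u(e + 4, 4L)
      sz <- c(1L, 1L, 2L, 4L)[typ] # BYTE/ASCII/SHORT/LONG
      if (is.na(sz)) next
      vals <- if (cnt * sz <= 4) read_uint(at(e + 8, cnt * sz), sz)[seq_len(cnt)]
              else read_uint(at(u(e + 8, 4L), cnt * sz), sz)
      tags[[as.character(tag)]] <- vals
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default)) stop(sprintf("TIFF tag %d missing", tag), call. = FALSE)
        default
      } else v
    }
    w <- need(256L); h <- need(257L)
    bps <- need(258L, 8L)
    if (need(259L, 1L) != 1L) stop("compressed TIFF not supported", call. = FALSE)
    if (need(277L, 1L) != 1L) stop("multi-sample TIFF not supported", call. = FALSE)
    fmt <- need(339L, 1L)
    ptype <- if (fmt == 3L && bps == 32L) "float32"
             else if (fmt == 1L && bps == 16L) "uint16"
             else if (fmt == 1L && bps == 8L) "uint8"
             else stop("unsupported TIFF sample format", call. = FALSE)
    if (is.null(type)) type <- ptype
    else if (type != ptype) stop("mixed sample formats across pages", call. = FALSE)

    offs <- need(273L)
    counts <- need(279L)
    buf <- do.call(c, lapply(seq_along(offs), function(i) at(offs[i], counts[i])))
    v <- if (ptype == "float32")
      readBin(buf, "double", n = w * h, size = 4L, endian = "little")
    else read_uint(buf, tiff_types[[ptype]])
    pages[[length(pages) + 1L]] <- matrix(v, h, w, byrow = TRUE)
    ifd_off <- u(ifd_off + 2 + n_entries * 12, 4L)
  }
  list(pages = pages, type = type)
}
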