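# Minimal baseline TIFF codec for volumetric grayscale stacks.
#
# Scope: uncompressed single-sample pages, float32 / uint16 / uint8, multi-page
# (one page per z slice), both byte orders on read, little-endian on write,
# arbitrary strip layout on read, one strip per page on write. This is not a
# general TIFF library; it exists because the deployment environment offers no
# R TIFF reader and pipeline inputs/outputs are plain multi-page TIFF stacks.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                    `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                    `11` = 4L, `12` = 8L)

read_tiff_stack <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 8L) stop("not a TIFF file (truncated): ", path, call. = FALSE)

  endian <- if (raw[1] == as.raw(0x49) && raw[2] == as.raw(0x49)) "little"
            else if (raw[1] == as.raw(0x4d) && raw[2] == as.raw(0x4d)) "big"
            else stop("not a TIFF file (bad byte-order mark): ", path,
                      call. = FALSE)
  u16 <- function(off, n = 1L)
    readBin(raw[(off + 1):(off + 2L * n)], "integer", n = n, size = 2L,
            signed = FALSE, endian = endian)
  u32 <- function(off, n = 1L) {
    v <- readBin(raw[(off + 1):(off + 4L * n)], "integer", n = n, size = 4L,
                 endian = endian)
    ifelse(v < 0, v + 2^32, v)  # R has no unsigned 32-bit
  }
  if (u16(2L) != 42L) stop("not a TIFF file (bad magic): ", path, call. = FALSE)

  read_entry_values <- function(off) {
    type <- u16(off + 2L)
    count <- u32(off + 4L)
    size <- TIFF_TYPE_SIZE[as.character(type)]
    if (is.na(size)) return(NULL)
    nbytes <- size * count
    voff <- if (nbytes <= 4) off + 8L else u32(off + 8L)
    if (type %in% c(3L)) u16(voff, count)
    else if (type %in% c(4L)) u32(voff, count)
    else if (type %in% c(1L)) as.integer(raw[(voff + 1):(voff + count)])
    else NULL
  }

  pages <- list()
  ifd_off <- u32(4L)
  while (ifd_off != 0) {
    n_entries <- u16(ifd_off)
    tags <- list()
    for (k in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + 12L * (k - 1L)
      tag <- u16(eoff)
      tags[[as.character(tag)]] <- read_entry_values(eoff)
    }
    need <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) {
        if (is.null(default))
          stop(sprintf("TIFF page missing required tag %d", tag), call. = FALSE)
        default
      } else v
    }
    nx <- need(256); ny <- need(257)
    bps <- need(258, 1L)
    compression <- need(259, 1L)
    sf <- need(339, 1L)
    spp <- need(277, 1L)
    if (compression != 1L)
      stop("unsupported TIFF: compressed data", call. = FALSE)
    if (spp != 1L)
      stop("unsupported TIFF: multi-sample pixels", call. = FALSE)
    offs <- need(273); cnts <- need(279)
    strip_raw <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + cnts[i])]))
    vals <- if (bps == 32L && sf == 3L) {
      readBin(strip_raw, "double", n = nx * ny, size = 4L, endian = endian)
    } else if (bps == 16L && sf %in% c(1L, NA)) {
      readBin(strip_raw, "integer", n = nx * ny, size = 2L, signed = FALSE,
              endian = endian)
    } else if (bps == 8L) {
      as.integer(strip_raw[seq_len(nx * ny)])
    } else {
      stop(sprintf(
        "unsupported TIFF pixel type (bits=%d, sample format=%d)", bps, sf),
        call. = FALSE)
    }
    if (length(vals) < nx * ny)
      stop("TIFF strip data shorter than page", call. = FALSE)
    pages[[length(pages) + 1L]] <- matrix(vals, nrow = ny, ncol = nx,
                                          byrow = TRUE)
    ifd_off <- u32(ifd_off + 2L + 12L * n_entries)
  }
  if (length(pages) == 0L) stop("TIFF contains no pages", call. = FALSE)
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("ragged TIFF: pages differ in size", call. = FALSE)

  arr <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
  arr
}

write_tiff_stack <- function(values, path, pixel_type = c("float32", "uint16")) {
  pixel_type <- match.arg(pixel_type)
  stopifnot(is.array(values), length(dim(values)) == 3L)
  d <- dim(values); nz <- d[1]; ny <- d[2]; nx <- d[3]
  bytes_per <- if (pixel_type == "float32") 4L else 2L
  strip_bytes <- nx * ny * bytes_per
  ifd_n <- 10L
  ifd_size <- 2L + 12L * ifd_n + 4L
  data_start <- 8L
  ifd_start <- data_start + nz * strip_bytes

  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path,
                                           call. = FALSE))
  on.exit(close(con), add = TRUE)
  wb <- function(v, size) writeBin(v, con, size = size, endian = "little")

  writeBin(as.raw(c(0x49, 0x49)), con)          # "II"
  wb(42L, 2L)
  wb(ifd_start, 4L)                              # first IFD offset

  # pixel data: page-major, rows top-down, x fastest within a row
  vec <- as.vector(aperm(values, c(3L, 2L, 1L)))
  if (pixel_type == "float32") {
    writeBin(as.numeric(vec), con, size = 4L, endian = "little")
  } else {
    iv <- as.integer(round(vec))
    if (any(iv < 0L) || any(iv > 65535L))
      stop("values out of uint16 range", call. = FALSE)
    iv[iv > 32767L] <- iv[iv > 32767L] - 65536L  # two's complement for writeBin
    writeBin(iv, con, size = 2L, endian = "little")
  }

  entry <- function(tag, type, count, value) {
    wb(as.integer(tag), 2L); wb(as.integer(type), 2L)
    wb(as.integer(count), 4L)
    if (type == 3L) { wb(as.integer(value), 2L); wb(0L, 2L) }
    else wb(as.integer(value), 4L)
  }
  bps <- if (pixel_type == "float32") 32L else 16L
  sfmt <- if (pixel_type == "float32") 3L else 1L
  for (z in seq_len(nz)) {
    wb(ifd_n, 2L)                                # entry count
    entry(256L, 4L, 1L, nx)                      # ImageWidth
    entry(257L, 4L, 1L, ny)                      # ImageLength
    entry(258L, 3L, 1L, bps)                     # BitsPerSample
    entry(259L, 3L, 1L, 1L)                      # Compression: none
    entry(262L, 3L, 1L, 1L)                      # Photometric: BlackIsZero
    entry(273L, 4L, 1L, data_start + (z - 1L) * strip_bytes)  # StripOffsets
    entry(277L, 3L, 1L, 1L)                      # SamplesPerPixel
    entry(278L, 4L, 1L, ny)                      # RowsPerStrip
    entry(279L, 4L, 1L, strip_bytes)             # StripByteCounts
    entry(339L, 3L, 1L, sfmt)                    # SampleFormat
    next_off <- if (z == nz) 0L else ifd_start + z * ifd_size
    wb(next_off, 4L)
  }
  invisible(path)
}
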