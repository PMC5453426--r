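# Minimal raster I/O for 8-bit RGB images.
#
# The environment this package targets has no R image-codec package, so two
# simple uncompressed containers are supported natively:
#   * binary PPM (P6, maxval 255)
#   * baseline uncompressed TIFF, 8-bit, 3 samples/pixel, chunky planar layout
# PNG is rejected with an informative error (no codec available).
# Images are represented in R as integer arrays of dim c(height, width, 3)
# with values in 0..255, indexed [row, col, channel].

#' Validate an 8-bit RGB image array
#'
#' @param img Object to check.
#' @param where Label used in error messages.
#' @return The image, invisibly, if valid; otherwise an error.
#' @export
check_rgb_image <- function(img, where = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("%s must be an array of dim (height, width, 3)", where),
         call. = FALSE)
  if (anyNA(img)) stop(sprintf("%s contains NA pixels", where), call. = FALSE)
  rng <- range(img)
  if (rng[1] < 0 || rng[2] > 255)
    stop(sprintf("%s has pixel values outside [0, 255]", where), call. = FALSE)
  invisible(img)
}

# interleave (h,w,3) -> raw vector in row-major RGBRGB order
rgb_array_to_raw <- function(img) {
  as.raw(as.integer(aperm(img, c(3L, 2L, 1L))))
}

raw_to_rgb_array <- function(bytes, h, w) {
  aperm(array(as.integer(bytes), dim = c(3L, w, h)), c(3L, 2L, 1L))
}

write_ppm <- function(img, path) {
  check_rgb_image(img)
  d <- dim(img)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", d[2], d[1]), con, eos = NULL)
  writeBin(rgb_array_to_raw(img), con)
  invisible(path)
}

read_ppm <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  # parse textual header: magic, width, height, maxval, single whitespace
  pos <- 1L
  next_token <- function() {
    # skip whitespace and comment lines
    repeat {
      while (pos <= length(bytes) && bytes[pos] %in% as.raw(c(9, 10, 13, 32)))
        pos <<- pos + 1L
      if (pos <= length(bytes) && bytes[pos] == as.raw(35L)) { # '#'
        while (pos <= length(bytes) && bytes[pos] != as.raw(10L)) pos <<- pos + 1L
      } else break
    }
    start <- pos
    while (pos <= length(bytes) && !(bytes[pos] %in% as.raw(c(9, 10, 13, 32))))
      pos <<- pos + 1L
    rawToChar(bytes[start:(pos - 1L)])
  }
  magic <- next_token()
  if (!identical(magic, "P6")) stop("not a binary PPM (P6) file: ", path, call. = FALSE)
  w <- as.integer(next_token()); h <- as.integer(next_token())
  maxval <- as.integer(next_token())
  if (is.na(w) || is.na(h) || is.na(maxval) || maxval != 255L)
    stop("unsupported PPM header in ", path, call. = FALSE)
  pos <- pos + 1L  # single whitespace after maxval
  need <- h * w * 3L
  if (length(bytes) - pos + 1L < need) stop("truncated PPM pixel data: ", path, call. = FALSE)
  raw_to_rgb_array(bytes[pos:(pos + need - 1L)], h, w)
}

# ---- TIFF (baseline, uncompressed, 8-bit RGB) --------------------------------

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L, spp = 277L,
               rows_per_strip = 278L, strip_counts = 279L, planar = 284L)

write_tiff <- function(img, path) {
  check_rgb_image(img)
  h <- dim(img)[1]; w <- dim(img)[2]
  n_entries <- 10L
  ifd_offset <- 8L
  ifd_size <- 2L + n_entries * 12L + 4L
  bits_offset <- ifd_offset + ifd_size       # 3 SHORTs (6 bytes)
  data_offset <- bits_offset + 6L
  nbytes <- h * w * 3L

  con <- file(path, "wb")
  on.exit(close(con))
  wr16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  entry_long <- function(tag, value) { wr16(tag); wr16(4L); wr32(1L); wr32(value) }
  entry_short <- function(tag, value) { wr16(tag); wr16(3L); wr32(1L); wr16(value); wr16(0L) }

  writeChar("II", con, eos = NULL); wr16(42L); wr32(ifd_offset)
  wr16(n_entries)
  entry_long(256L, w)                         # ImageWidth
  entry_long(257L, h)                         # ImageLength
  { wr16(258L); wr16(3L); wr32(3L); wr32(bits_offset) }  # BitsPerSample -> offset
  entry_short(259L, 1L)                       # Compression: none
  entry_short(262L, 2L)                       # Photometric: RGB
  entry_long(273L, data_offset)               # StripOffsets (single strip)
  entry_short(277L, 3L)                       # SamplesPerPixel
  entry_long(278L, h)                         # RowsPerStrip
  entry_long(279L, nbytes)                    # StripByteCounts
  entry_short(284L, 1L)                       # PlanarConfiguration: chunky
  wr32(0L)                                    # next IFD
  wr16(c(8L, 8L, 8L))                         # bits-per-sample array
  writeBin(rgb_array_to_raw(img), con)
  invisible(path)
}

read_tiff <- function(path) {
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (length(bytes) < 8L) stop("not a TIFF file: ", path, call. = FALSE)
  order_tag <- rawToChar(bytes[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file: ", path, call. = FALSE))
  get_int <- function(at, size, n = 1L) {
    readBin(bytes[at:(at + size * n - 1L)], "integer",
            n = n, size = size, endian = endian, signed = size == 4L)
  }
  if (get_int(3L, 2L) != 42L) stop("not a TIFF file: ", path, call. = FALSE)
  ifd <- get_int(5L, 4L)
  n_entries <- get_int(ifd + 1L, 2L)
  type_size <- c(1L, 1L, 2L, 4L, 8L)  # BYTE ASCII SHORT LONG RATIONAL
  tags <- list()
  for (i in seq_len(n_entries)) {
    at <- ifd + 3L + (i - 1L) * 12L
    tag <- get_int(at, 2L); type <- get_int(at + 2L, 2L)
    count <- get_int(at + 4L, 4L)
    if (!(type %in% c(1L, 3L, 4L))) next    # keep integer-valued tags only
    sz <- type_size[type]
    total <- sz * count
    src <- if (total <= 4L) at + 8L else get_int(at + 8L, 4L) + 1L
    tags[[as.character(tag)]] <- get_int(src, sz, count)
  }
  need <- function(tag, default = NULL) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) {
      if (is.null(default)) stop("TIFF missing required tag ", tag, call. = FALSE)
      default
    } else v
  }
  w <- need(256L); h <- need(257L)
  if (!identical(unique(need(258L, 8L)), 8L))
    stop("unsupported TIFF: only 8 bits per sample are supported", call. = FALSE)
  if (need(259L, 1L) != 1L)
    stop("unsupported TIFF: compressed data is not supported", call. = FALSE)
  if (need(262L) != 2L || need(277L, 1L) != 3L)
    stop("unsupported TIFF: only 3-sample RGB is supported", call. = FALSE)
  if (need(284L, 1L) != 1L)
    stop("unsupported TIFF: only chunky planar layout is supported", call. = FALSE)
  offs <- need(273L); cnts <- need(279L, h * w * 3L)
  if (length(cnts) < length(offs)) cnts <- rep_len(cnts, length(offs))
  data <- raw(0)
  for (i in seq_along(offs))
    data <- c(data, bytes[(offs[i] + 1L):(offs[i] + cnts[i])])
  if (length(data) < h * w * 3L) stop("truncated TIFF pixel data: ", path, call. = FALSE)
  raw_to_rgb_array(data[seq_len(h * w * 3L)], w = w, h = h)
}

#' Read an 8-bit RGB image (PPM or uncompressed TIFF)
#'
#' @param path Path to a `.ppm`/`.pnm` or `.tif`/`.tiff` file.
#' @return Integer array of dim `(height, width, 3)`, values 0--255.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    ppm = , pnm = read_ppm(path),
    tif = , tiff = read_tiff(path),
    png = stop("PNG is not supported in this build (no codec available); ",
               "use uncompressed TIFF or binary PPM", call. = FALSE),
    stop("unsupported image extension '.", ext, "' for ", path, call. = FALSE))
  check_rgb_image(img, where = path)
}

#' Write an 8-bit RGB image (PPM or uncompressed TIFF)
#'
#' Format is chosen from the file extension.
#'
#' @param img Integer array `(height, width, 3)`, values 0--255.
#' @param path Output path ending in `.ppm`, `.tif` or `.tiff`.
#' @return The path, invisibly.
#' @export
write_image <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    ppm = write_ppm(img, path),
    tif = , tiff = write_tiff(img, path),
    stop("unsupported image extension '.", ext, "'; use .ppm/.tif/.tiff",
         call. = FALSE))
  invisible(path)
}
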