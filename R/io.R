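# Image and table I/O. TIFF support is a minimal reader/writer for
# uncompressed single-sample grayscale baseline TIFF (8/16-bit,
# little-endian) - sufficient for micrograph and label-map exchange; PNG via
# the png package; PGM (plain text P2) for text-only fixtures.

img_ext <- function(path) tolower(tools::file_ext(path))

#' Read a grayscale image
#'
#' Supported: TIFF (uncompressed grayscale 8/16-bit), PNG (8/16-bit; RGB(A)
#' is converted to luminance by channel mean), PGM (plain P2). Intensities
#' are returned in \[0, 1\] (integer values divided by the format's maximum).
#'
#' @param path input file.
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  switch(img_ext(path),
    tif = ,
    tiff = {
      r <- read_tiff_raw(path)
      r$data / (2^r$bits - 1)
    },
    png = {
      a <- png::readPNG(path)
      if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3]),
                                            drop = FALSE], c(1, 2), mean)
      a
    },
    pgm = {
      r <- read_pgm(path)
      r$data / r$maxval
    },
    stop("unsupported image format: ", path))
}

#' Write a grayscale image
#'
#' Values are clamped to \[0, 1\] and quantized to `bits` (TIFF: 8 or 16;
#' PNG: 8 or 16; PGM: 8).
#' @param image numeric matrix in \[0, 1\].
#' @param path output file; format chosen by extension (tif/tiff, png, pgm).
#' @param bits bit depth (default 16).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 16L) {
  assert_image(image)
  q <- round(pmin(pmax(image, 0), 1) * (2^bits - 1))
  switch(img_ext(path),
    tif = ,
    tiff = write_tiff_raw(q, path, bits),
    png = png::writePNG(pmin(pmax(image, 0), 1), path),
    pgm = write_pgm(q, path, maxval = 2^bits - 1),
    stop("unsupported image format: ", path))
  invisible(path)
}

#' Write / read a label map as 16-bit TIFF
#'
#' Integer labels are stored verbatim; the reserved ambiguous label `-1` is
#' stored as 65535 and restored to `-1` on reading.
#' @param labels integer matrix (0 background, positive cell labels, -1
#'   ambiguous).
#' @param path `.tif`/`.tiff` file.
#' @return `write_labels`: `path` invisibly; `read_labels`: integer matrix.
#' @export
write_labels <- function(labels, path) {
  x <- labels
  x[x == -1L] <- 65535L
  if (any(x < 0 | x > 65535)) stop("labels out of 16-bit range")
  write_tiff_raw(x, path, 16L)
  invisible(path)
}

#' @rdname write_labels
#' @export
read_labels <- function(path) {
  r <- read_tiff_raw(path)
  x <- r$data
  x[x == 65535L] <- -1L
  x
}

# ---- minimal baseline TIFF ------------------------------------------------

write_tiff_raw <- function(data, path, bits = 16L) {
  stopifnot(bits %in% c(8L, 16L))
  H <- nrow(data); W <- ncol(data)
  con <- file(path, "wb")
  on.exit(close(con))
  vals <- as.integer(t(data)) # row-major
  data_bytes <- H * W * (bits %/% 8L)
  ifd_offset <- 8L + data_bytes
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_offset, con, size = 4, endian = "little")
  writeBin(vals, con, size = bits %/% 8L, endian = "little")
  tags <- list( # tag, type (3 = SHORT, 4 = LONG), count, value
    c(256L, 4L, 1L, W),           # ImageWidth
    c(257L, 4L, 1L, H),           # ImageLength
    c(258L, 3L, 1L, bits),        # BitsPerSample
    c(259L, 3L, 1L, 1L),          # Compression: none
    c(262L, 3L, 1L, 1L),          # Photometric: BlackIsZero
    c(273L, 4L, 1L, 8L),          # StripOffsets
    c(277L, 3L, 1L, 1L),          # SamplesPerPixel
    c(278L, 4L, 1L, H),           # RowsPerStrip
    c(279L, 4L, 1L, data_bytes)   # StripByteCounts
  )
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    tg <- as.integer(tg)
    writeBin(tg[1], con, size = 2, endian = "little")
    writeBin(tg[2], con, size = 2, endian = "little")
    writeBin(tg[3], con, size = 4, endian = "little")
    if (tg[2] == 3L) { # SHORT padded to 4 bytes
      writeBin(tg[4], con, size = 2, endian = "little")
      writeBin(0L, con, size = 2, endian = "little")
    } else {
      writeBin(tg[4], con, size = 4, endian = "little")
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  invisible(path)
}

read_tiff_raw <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) u16(off) + 65536 * u16(off + 2)
  if (rawToChar(raw[1:2]) != "II" || u16(2) != 42L)
    stop("not a little-endian TIFF: ", path)
  ifd <- u32(4)
  n_tags <- u16(ifd)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2L + (i - 1L) * 12L
    id <- u16(base); type <- u16(base + 2); count <- u32(base + 4)
    val <- if (type == 3L) u16(base + 8) else u32(base + 8)
    tags[[as.character(id)]] <- list(type = type, count = count, val = val,
                                     off = base + 8)
  }
  need <- function(id, default = NULL) {
    t <- tags[[as.character(id)]]
    if (is.null(t)) {
      if (is.null(default)) stop("TIFF tag ", id, " missing")
      return(default)
    }
    t$val
  }
  W <- need(256); H <- need(257); bits <- need(258, 1L)
  if (need(259, 1L) != 1L) stop("compressed TIFF not supported")
  if (need(277, 1L) != 1L) stop("multi-sample TIFF not supported")
  if (!bits %in% c(8L, 16L)) stop("only 8/16-bit TIFF supported")
  # strip offsets / byte counts (possibly arrays stored out of line)
  read_arr <- function(id) {
    t <- tags[[as.character(id)]]
    if (t$count == 1L) return(t$val)
    sz <- if (t$type == 3L) 2L else 4L
    off <- t$val
    vapply(seq_len(t$count), function(i) {
      if (t$type == 3L) u16(off + (i - 1L) * sz) else u32(off + (i - 1L) * sz)
    }, numeric(1))
  }
  offs <- read_arr(273)
  cnts <- read_arr(279)
  bytes <- unlist(lapply(seq_along(offs), function(i)
    raw[offs[i] + seq_len(cnts[i])]))
  vals <- readBin(as.raw(bytes), "integer", n = H * W, size = bits %/% 8L,
                  signed = FALSE, endian = "little")
  list(data = matrix(vals, H, W, byrow = TRUE), bits = bits)
}

# ---- plain PGM (P2) -------------------------------------------------------

write_pgm <- function(data, path, maxval = 255L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(data), nrow(data)),
               as.character(maxval)), con)
  write(t(data), con, ncolumns = ncol(data))
  invisible(path)
}

read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  toks <- scan(text = paste(txt, collapse = " "), what = character(),
               quiet = TRUE)
  if (toks[1] != "P2") stop("only plain (P2) PGM supported")
  W <- as.integer(toks[2]); H <- as.integer(toks[3])
  maxval <- as.integer(toks[4])
  vals <- as.integer(toks[-(1:4)])
  list(data = matrix(vals, H, W, byrow = TRUE), maxval = maxval)
}

# ---- tables & reports -----------------------------------------------------

#' Write / read cell centroids as CSV
#'
#' Columns `id,row,col`; coordinates are 0-based pixel indices (row-major),
#' converted from/to the package's 1-based convention on the way through.
#' @param centroids matrix with columns `row`, `col` (1-based).
#' @param path CSV file.
#' @return `read_centroids_csv` returns a matrix with columns `row`, `col`
#'   (1-based).
#' @export
write_centroids_csv <- function(centroids, path) {
  df <- data.frame(id = seq_len(nrow(centroids)),
                   row = centroids[, 1] - 1,
                   col = centroids[, 2] - 1)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_centroids_csv
#' @export
read_centroids_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("row", "col") %in% names(df)))
    stop("centroid CSV must have columns id,row,col")
  cbind(row = df$row + 1, col = df$col + 1)
}

#' Write a run/metrics report as JSON
#' @param report a list.
#' @param path JSON file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Read a pipeline configuration file (YAML or JSON)
#' @param path `.yaml`/`.yml` or `.json` file with (a subset of) the
#'   [pipeline_config()] fields.
#' @return a `pipeline_config`.
#' @export
read_config <- function(path) {
  lst <- switch(img_ext(path),
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config format: ", path))
  do.call(pipeline_config, lst)
}

#' Write a pipeline configuration (YAML or JSON); round-trips losslessly
#' @param config a [pipeline_config()].
#' @param path output file.
#' @export
write_config <- function(config, path) {
  plain <- unclass(config)
  switch(img_ext(path),
    yaml = ,
    yml = yaml::write_yaml(plain, path),
    json = jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
    stop("unsupported config format: ", path))
  invisible(path)
}
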