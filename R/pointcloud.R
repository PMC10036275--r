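#' Colored point cloud tables
#'
#' A colored point cloud is an ordinary tibble with columns `x`, `y`, `z`
#' (meters, planar CRS, `z` height above ground once normalized) and integer
#' color bands `r`, `g`, `b`. The color bit depth (8 or 16) is carried in the
#' `bit_depth` attribute; all band values must lie in `[0, 2^depth - 1]`.
#' Any data frame with these columns is accepted by the pipeline functions;
#' `as_point_cloud()` validates and stamps the class.
#'
#' @param df Data frame with columns x, y, z, r, g, b.
#' @param bit_depth Color bit depth, 8 or 16.
#' @return A tibble of class `point_cloud`.
#' @export
as_point_cloud <- function(df, bit_depth = 8L) {
  need <- c("x", "y", "z", "r", "g", "b")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("point cloud is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!bit_depth %in% c(8L, 16L)) stop("`bit_depth` must be 8 or 16", call. = FALSE)
  hi <- 2^bit_depth - 1
  for (b in c("r", "g", "b")) {
    v <- df[[b]]
    if (any(v < 0 | v > hi, na.rm = TRUE)) {
      stop("color band `", b, "` outside [0, ", hi, "] for declared bit depth ",
           bit_depth, call. = FALSE)
    }
  }
  out <- tibble::as_tibble(df)
  attr(out, "bit_depth") <- as.integer(bit_depth)
  class(out) <- unique(c("point_cloud", class(out)))
  out
}

#' @rdname as_point_cloud
#' @param cloud A point cloud data frame.
#' @export
bit_depth <- function(cloud) {
  d <- attr(cloud, "bit_depth")
  if (is.null(d)) 8L else as.integer(d)
}

#' Read a colored point cloud from LAS or delimited text
#'
#' Text files are whitespace-delimited `x y z r g b` (an optional header row
#' is detected and skipped). LAS files must be point format 2 or 3 (the
#' formats carrying RGB); the reader handles the uncompressed LAS 1.x point
#' formats written by [write_point_cloud()]. Color is required by the
#' downstream greenness analysis, so files without RGB are rejected; files
#' whose RGB values are all zero load with a "colorless" warning.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"las"`, or `"text"`.
#' @return A [as_point_cloud()] tibble.
#' @export
read_point_cloud <- function(path, format = c("auto", "las", "text")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.la[sz]$", tolower(path))) "las" else "text"
  }
  cloud <- if (format == "las") read_las_rgb(path) else read_xyzrgb_text(path)
  if (nrow(cloud) > 0 && all(cloud$r == 0 & cloud$g == 0 & cloud$b == 0)) {
    warning("point cloud is colorless (all RGB values are zero)", call. = FALSE)
  }
  cloud
}

read_xyzrgb_text <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "\\s+")[[1]][1])))
  raw <- utils::read.table(path, header = has_header, colClasses = "character",
                           fill = TRUE)
  if (ncol(raw) < 6) stop("text point cloud must have 6 columns (x y z r g b)", call. = FALSE)
  df <- as.data.frame(suppressWarnings(lapply(raw[, 1:6], as.numeric)))
  names(df) <- c("x", "y", "z", "r", "g", "b")
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    stop("malformed point record on data row ", bad[1], " of ", path, call. = FALSE)
  }
  depth <- if (max(df$r, df$g, df$b) > 255) 16L else 8L
  as_point_cloud(df, bit_depth = depth)
}

#' Write a colored point cloud to LAS or delimited text
#'
#' LAS output is version 1.2, point data format 2 (XYZ + RGB), coordinates
#' stored at millimeter resolution. Colors are stored at the cloud's native
#' bit depth so that write/read round-trips preserve them exactly.
#'
#' @param cloud Point cloud data frame.
#' @param path Output path.
#' @param format `"auto"` (by extension), `"las"`, or `"text"`.
#' @return `path`, invisibly.
#' @export
write_point_cloud <- function(cloud, path, format = c("auto", "las", "text")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.la[sz]$", tolower(path))) "las" else "text"
  }
  if (format == "las") {
    write_las_rgb(cloud, path)
  } else {
    df <- as.data.frame(cloud)[, c("x", "y", "z", "r", "g", "b")]
    utils::write.table(format(df, digits = 10, scientific = FALSE, trim = TRUE),
                       path, quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

# --- minimal LAS 1.2 point-format-2 reader/writer -------------------------
# Header layout per the ASPRS LAS 1.2 specification (227-byte header, no
# variable-length records). Only what this package needs: XYZ + RGB.

write_las_rgb <- function(cloud, path) {
  n <- nrow(cloud)
  scale <- 0.001
  off <- if (n > 0) c(min(cloud$x), min(cloud$y), min(cloud$z)) else c(0, 0, 0)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("LASF", con, nchars = 4, eos = NULL)
  writeBin(rep(0L, 2), con, size = 2)                       # source id, encoding
  writeBin(raw(16), con)                                    # GUID
  writeBin(c(1L, 2L), con, size = 1)                        # version 1.2
  writeChar(formatC("crownscorch", width = 32, flag = "-"), con, nchars = 32, eos = NULL)
  writeChar(formatC("crownscorch", width = 32, flag = "-"), con, nchars = 32, eos = NULL)
  writeBin(c(1L, 2026L), con, size = 2)                     # day, year
  writeBin(227L, con, size = 2)                             # header size
  writeBin(227L, con, size = 4)                             # offset to points
  writeBin(0L, con, size = 4)                               # number of VLRs
  writeBin(2L, con, size = 1)                               # point format 2
  writeBin(26L, con, size = 2)                              # record length
  writeBin(n, con, size = 4)                                # point count
  writeBin(c(n, 0L, 0L, 0L, 0L), con, size = 4)             # by return
  writeBin(rep(scale, 3), con, size = 8)
  writeBin(off, con, size = 8)
  rng <- function(v) if (n > 0) c(max(v), min(v)) else c(0, 0)
  writeBin(c(rng(cloud$x), rng(cloud$y), rng(cloud$z)), con, size = 8)
  if (n > 0) {
    ix <- as.integer(round((cloud$x - off[1]) / scale))
    iy <- as.integer(round((cloud$y - off[2]) / scale))
    iz <- as.integer(round((cloud$z - off[3]) / scale))
    rec <- matrix(raw(1), nrow = 26, ncol = n)
    rec[1:4, ]   <- writeBin(ix, raw(), size = 4)
    rec[5:8, ]   <- writeBin(iy, raw(), size = 4)
    rec[9:12, ]  <- writeBin(iz, raw(), size = 4)
    # intensity(2) flags(1) class(1) angle(1) user(1) source(2) all zero
    rec[21:22, ] <- writeBin(as.integer(cloud$r), raw(), size = 4)[c(TRUE, TRUE, FALSE, FALSE)]
    rec[23:24, ] <- writeBin(as.integer(cloud$g), raw(), size = 4)[c(TRUE, TRUE, FALSE, FALSE)]
    rec[25:26, ] <- writeBin(as.integer(cloud$b), raw(), size = 4)[c(TRUE, TRUE, FALSE, FALSE)]
    writeBin(as.vector(rec), con)
  }
  invisible(path)
}

read_las_rgb <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readChar(con, 4, useBytes = TRUE)
  if (!identical(sig, "LASF")) stop("not a LAS file: ", path, call. = FALSE)
  seek(con, 96)
  offset_to_points <- readBin(con, integer(), size = 4)
  readBin(con, integer(), size = 4)                         # n VLRs
  fmt <- readBin(con, integer(), size = 1, signed = FALSE)
  rec_len <- readBin(con, integer(), size = 2, signed = FALSE)
  n <- readBin(con, integer(), size = 4)
  if (!fmt %in% c(2L, 3L)) {
    stop("LAS point format ", fmt, " carries no RGB; format 2 or 3 required",
         call. = FALSE)
  }
  seek(con, 131)
  scale <- readBin(con, numeric(), n = 3, size = 8)
  off <- readBin(con, numeric(), n = 3, size = 8)
  seek(con, offset_to_points)
  bytes <- readBin(con, raw(), n = n * rec_len)
  rec <- matrix(bytes, nrow = rec_len)
  int4 <- function(rows) readBin(as.vector(rec[rows, ]), integer(), n = n, size = 4)
  uint2 <- function(rows) {
    readBin(as.vector(rec[rows, ]), integer(), n = n, size = 2, signed = FALSE)
  }
  rgb_at <- if (fmt == 2L) 21L else 29L                     # fmt 3 adds GPS time
  cloud <- tibble::tibble(
    x = int4(1:4) * scale[1] + off[1],
    y = int4(5:8) * scale[2] + off[2],
    z = int4(9:12) * scale[3] + off[3],
    r = uint2(rgb_at + 0:1),
    g = uint2(rgb_at + 2:3),
    b = uint2(rgb_at + 4:5)
  )
  depth <- if (nrow(cloud) && max(cloud$r, cloud$g, cloud$b) > 255) 16L else 8L
  as_point_cloud(cloud, bit_depth = depth)
}
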