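# Volume and mask input/output: MRC2014 and multi-page TIFF.
#
# The MRC2014 layout (1024-byte header + column-major data, x fastest) is
# implemented directly; only modes 0 (int8), 1 (int16), 2 (float32) and
# 6 (uint16) are supported, which covers tomogram practice. Voxel pitch is
# taken from the cell dimensions (Angstrom) divided by the grid size and
# converted to nm.

read_mrc_header <- function(con) {
  h <- list()
  ints <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  h$nx <- ints[1]; h$ny <- ints[2]; h$nz <- ints[3]; h$mode <- ints[4]
  h$mx <- ints[8]; h$my <- ints[9]; h$mz <- ints[10]
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  h$cella <- cella
  seek(con, 1024)
  h
}

#' Read an MRC2014 volume
#'
#' @param path file path.
#' @param pitch fallback voxel pitch (nm) when the header carries no cell
#'   dimensions.
#' @return a [volume_grid].
#' @export
read_mrc <- function(path, pitch = 2) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- read_mrc_header(con)
  if (h$nx <= 0 || h$ny <= 0 || h$nz <= 0)
    stop("corrupt MRC header: nonpositive dimensions")
  n <- as.numeric(h$nx) * h$ny * h$nz
  data <- switch(as.character(h$mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE,
                  endian = "little"),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"),
    "6" = readBin(con, "integer", n = n, size = 2, signed = FALSE,
                  endian = "little"),
    stop("unsupported MRC mode: ", h$mode))
  if (length(data) < n) stop("truncated MRC data block")
  if (h$mx > 0 && h$cella[1] > 0) {
    p <- h$cella / c(h$mx, h$my, h$mz) / 10  # Angstrom -> nm
    if (max(abs(p - p[1])) > 1e-6 * p[1]) {
      warning("anisotropic voxel pitch in MRC header; using x pitch")
    }
    pitch <- p[1]
  }
  volume_grid(array(as.numeric(data), c(h$nx, h$ny, h$nz)), pitch = pitch)
}

#' Write an MRC2014 volume
#'
#' Data are stored as 32-bit floats (mode 2); voxel pitch goes into the cell
#' dimensions in Angstrom.
#'
#' @param vol a [volume_grid] (or a plain 3D array plus `pitch`).
#' @param path file path.
#' @param pitch voxel pitch in nm, used when `vol` is a bare array.
#' @export
write_mrc <- function(vol, path, pitch = 2) {
  if (inherits(vol, "volume_grid")) { data <- vol$data; pitch <- vol$pitch }
  else data <- vol
  d <- dim(data)
  data[is.na(data)] <- 0
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(c(d, 2L)), con, size = 4, endian = "little")        # nx..mode
  writeBin(integer(3), con, size = 4, endian = "little")                  # nxstart..
  writeBin(as.integer(d), con, size = 4, endian = "little")               # mx,my,mz
  writeBin(as.numeric(d * pitch * 10), con, size = 4, endian = "little")  # cella (A)
  writeBin(as.numeric(c(90, 90, 90)), con, size = 4, endian = "little")   # cellb
  writeBin(1:3, con, size = 4, endian = "little")                         # mapc/r/s
  writeBin(as.numeric(c(min(data), max(data), mean(data))), con, size = 4,
           endian = "little")                                             # dmin..dmean
  writeBin(c(1L, 0L), con, size = 4, endian = "little")                   # ispg,nsymbt
  writeBin(raw(4 * 25), con)                                              # extra
  writeBin(integer(3), con, size = 4, endian = "little")                  # origin
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)                        # stamp
  writeBin(as.numeric(stats::sd(data)), con, size = 4, endian = "little") # rms
  writeBin(0L, con, size = 4, endian = "little")                          # nlabl
  writeBin(raw(800), con)
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a volume from MRC or a multi-page TIFF stack
#'
#' TIFF pages are z slices; page rows map to y and columns to x.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mrc"` or `"tiff"`.
#' @param pitch voxel pitch (nm) used when the file format carries none.
#' @return a [volume_grid].
#' @export
read_volume <- function(path, format = c("auto", "mrc", "tiff"), pitch = 2) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE))
      "tiff" else "mrc"
  }
  if (format == "mrc") return(read_mrc(path, pitch = pitch))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d2 <- dim(pages[[1]])
  arr <- array(0, c(d2[2], d2[1], nz))  # (x, y, z)
  for (z in seq_len(nz)) arr[, , z] <- t(pages[[z]])
  volume_grid(arr, pitch = pitch)
}

#' Write a volume as a multi-page TIFF stack (32-bit float pages)
#'
#' @inheritParams write_mrc
#' @export
write_tiff_stack <- function(vol, path, pitch = 2) {
  data <- if (inherits(vol, "volume_grid")) vol$data else vol
  data[is.na(data)] <- 0
  pages <- lapply(seq_len(dim(data)[3]), function(z) t(data[, , z]))
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(path)
}

#' Read a label mask volume
#'
#' Integer-valued volume in the same formats as [read_volume]; values are
#' rounded to the nearest integer label.
#'
#' @inheritParams read_volume
#' @param domain optional domain-tag array passed to [label_mask].
#' @return a [label_mask].
#' @export
read_mask <- function(path, format = c("auto", "mrc", "tiff"), pitch = 2,
                      domain = NULL) {
  v <- read_volume(path, format = format, pitch = pitch)
  label_mask(array(as.integer(round(v$data)), dim(v$data)),
             pitch = v$pitch, origin = v$origin, domain = domain)
}

#' Write a label mask volume (MRC mode 2, integer-valued)
#' @param mask a [label_mask].
#' @param path file path.
#' @export
write_mask <- function(mask, path) {
  write_mrc(array(as.numeric(mask$labels), dim(mask$labels)), path,
            pitch = mask$pitch)
}
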