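## Minimal 16-bit grayscale multi-page TIFF I/O (little-endian, uncompressed,
## one strip per page).  No TIFF library ships with the supported R stack,
## and the subset needed here -- write a stack of uint16 matrices, read it
## back -- is small and fixed, so it is implemented directly against the
## TIFF 6.0 baseline rather than pulled in as a dependency.

tiff_u16 <- function(v) {
  v <- as.integer(round(v))
  v[v < 0L] <- 0L
  v[v > 65535L] <- 65535L
  ifelse(v > 32767L, v - 65536L, v)
}

#' Write / read 16-bit grayscale TIFF stacks
#'
#' `write_tiff16()` writes a list of numeric matrices (or one matrix) as a
#' multi-page uncompressed 16-bit grayscale TIFF; values are rounded and
#' clipped to `[0, 65535]`.  `read_tiff16()` reads such a file back into a
#' list of integer matrices.  Only the baseline subset this package writes
#' is supported on read (16-bit, single sample, single strip, uncompressed).
#'
#' @param images a numeric matrix or list of matrices (rows = image rows).
#' @param path file path.
#' @return `write_tiff16` returns `path` invisibly; `read_tiff16` returns a
#'   list of integer matrices.
#' @export
write_tiff16 <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  stopifnot(length(images) >= 1L, all(vapply(images, is.matrix, logical(1L))))
  con <- file(path, open = "wb")
  on.exit(close(con))
  w16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  w32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  n_tags <- 9L
  ifd_size <- 2L + 12L * n_tags + 4L
  sizes <- vapply(images, function(im) 2L * length(im), integer(1L))
  data_pos <- integer(length(images))
  ifd_pos <- integer(length(images))
  pos <- 8L
  for (i in seq_along(images)) {
    data_pos[i] <- pos
    ifd_pos[i] <- pos + sizes[i]
    pos <- ifd_pos[i] + ifd_size
  }
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_pos[1L])
  tag_short <- function(id, value) { w16(id); w16(3L); w32(1L); w16(value); w16(0L) }
  tag_long  <- function(id, value) { w16(id); w16(4L); w32(1L); w32(value) }
  for (i in seq_along(images)) {
    im <- images[[i]]
    writeBin(tiff_u16(t(im)), con, size = 2L, endian = "little")
    w16(n_tags)
    tag_long(256L, ncol(im))          # ImageWidth
    tag_long(257L, nrow(im))          # ImageLength
    tag_short(258L, 16L)              # BitsPerSample
    tag_short(259L, 1L)               # Compression: none
    tag_short(262L, 1L)               # Photometric: BlackIsZero
    tag_long(273L, data_pos[i])       # StripOffsets
    tag_short(277L, 1L)               # SamplesPerPixel
    tag_long(278L, nrow(im))          # RowsPerStrip
    tag_long(279L, sizes[i])          # StripByteCounts
    w32(if (i < length(images)) ifd_pos[i + 1L] else 0L)
  }
  invisible(path)
}

#' @rdname write_tiff16
#' @export
read_tiff16 <- function(path) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  r16 <- function() readBin(con, "integer", size = 2L, signed = FALSE, endian = "little")
  r32 <- function() readBin(con, "integer", size = 4L, endian = "little")
  if (rawToChar(readBin(con, "raw", 2L)) != "II" || r16() != 42L) {
    stop("read_tiff16: not a little-endian TIFF file")
  }
  nxt <- r32()
  out <- list()
  while (nxt != 0L) {
    seek(con, nxt)
    n_tags <- r16()
    tags <- list()
    for (i in seq_len(n_tags)) {
      id <- r16(); typ <- r16(); cnt <- r32()
      val <- if (typ == 3L) { v <- r16(); r16(); v } else r32()
      needed <- id %in% c(256L, 257L, 258L, 259L, 262L, 273L, 277L, 278L, 279L)
      if (cnt != 1L) {
        if (needed) stop("read_tiff16: unsupported multi-valued tag ", id)
        next  # e.g. ImageDescription / Software strings from other writers
      }
      if (needed) tags[[as.character(id)]] <- val
    }
    nxt <- r32()
    need <- c("256", "257", "273", "279")
    if (!all(need %in% names(tags))) stop("read_tiff16: missing required tags")
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1L) {
      stop("read_tiff16: compressed TIFF not supported")
    }
    if (!is.null(tags[["258"]]) && tags[["258"]] != 16L) {
      stop("read_tiff16: only 16-bit data supported")
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    seek(con, tags[["273"]])
    px <- readBin(con, "integer", n = w * h, size = 2L, signed = FALSE,
                  endian = "little")
    out[[length(out) + 1L]] <- matrix(px, nrow = h, ncol = w, byrow = TRUE)
  }
  out
}
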