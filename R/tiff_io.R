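#' @title Two-channel 16-bit TIFF interchange
#' @name tiff_io
#' @description
#' Micrographs are exchanged as two-page (axon channel first, AChR channel
#' second) uncompressed 16-bit grayscale little-endian baseline TIFF files,
#' with acquisition metadata (pixel size, embryo id, group, drug id) in a
#' JSON sidecar next to the image. The codec implemented here covers exactly
#' this baseline subset; it is not a general TIFF reader.
NULL

TIFF_TAGS <- c(width = 256L, length = 257L, bits = 258L, compression = 259L,
               photometric = 262L, strip_offsets = 273L,
               rows_per_strip = 278L, strip_byte_counts = 279L)

# one IFD with 8 SHORT/LONG tags; returns raw vector
tiff_ifd <- function(h, w, data_offset, next_ifd_offset) {
  entry <- function(tag, type, value) {
    # type 3 = SHORT, 4 = LONG; value fits in the 4-byte field
    c(writeBin(as.integer(tag), raw(), size = 2, endian = "little"),
      writeBin(as.integer(type), raw(), size = 2, endian = "little"),
      writeBin(1L, raw(), size = 4, endian = "little"),
      if (type == 3L) {
        c(writeBin(as.integer(value), raw(), size = 2, endian = "little"),
          as.raw(c(0, 0)))
      } else {
        writeBin(as.integer(value), raw(), size = 4, endian = "little")
      })
  }
  c(writeBin(8L, raw(), size = 2, endian = "little"),
    entry(TIFF_TAGS[["width"]], 4L, w),
    entry(TIFF_TAGS[["length"]], 4L, h),
    entry(TIFF_TAGS[["bits"]], 3L, 16L),
    entry(TIFF_TAGS[["compression"]], 3L, 1L),
    entry(TIFF_TAGS[["photometric"]], 3L, 1L),
    entry(TIFF_TAGS[["strip_offsets"]], 4L, data_offset),
    entry(TIFF_TAGS[["rows_per_strip"]], 4L, h),
    entry(TIFF_TAGS[["strip_byte_counts"]], 4L, 2L * h * w),
    writeBin(as.integer(next_ifd_offset), raw(), size = 4,
             endian = "little"))
}

# channel matrix -> row-major uint16 raw payload, clipping to 0..65535
tiff_payload <- function(mat) {
  v <- as.integer(pmin(pmax(round(t(mat)), 0), 65535))
  writeBin(v, raw(), size = 2, endian = "little")
}

#' Write an NMJ image as a two-page 16-bit TIFF with a JSON sidecar
#'
#' @param image an [nmj_image()] object.
#' @param path output TIFF path; the sidecar is written next to it with a
#'   `.json` extension.
#' @return invisibly, `c(tiff = path, json = sidecar_path)`.
#' @export
write_nmj_image <- function(image, path) {
  stopifnot(inherits(image, "nmj_image"))
  h <- nrow(image$axon_channel); w <- ncol(image$axon_channel)
  page_bytes <- 2L * h * w
  data1 <- 8L
  data2 <- data1 + page_bytes
  ifd1 <- data2 + page_bytes
  ifd2 <- ifd1 + (2L + 8L * 12L + 4L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd1, con, size = 4, endian = "little")
  writeBin(tiff_payload(image$axon_channel), con)
  writeBin(tiff_payload(image$achr_channel), con)
  writeBin(tiff_ifd(h, w, data1, ifd2), con)
  writeBin(tiff_ifd(h, w, data2, 0L), con)

  sidecar <- paste0(sub("\\.tiff?$", "", path), ".json")
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size_um, embryo_id = image$embryo_id,
         group = image$group, drug_id = image$drug_id),
    sidecar, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(tiff = path, json = sidecar))
}

read_uint16 <- function(raw, n) {
  readBin(raw, "integer", n = n, size = 2, signed = FALSE,
          endian = "little")
}

#' Read a two-page 16-bit TIFF written by [write_nmj_image()]
#'
#' Only the baseline subset produced by this package is supported:
#' little-endian, uncompressed, 16-bit grayscale, one strip per page.
#'
#' @param path TIFF path; the JSON sidecar is read from the matching `.json`
#'   file when present.
#' @return an [nmj_image()] object.
#' @export
read_nmj_image <- function(path) {
  if (!file.exists(path)) {
    stage_error("nmj_imaging", paste0("file not found: ", path))
  }
  bytes <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(bytes[1:2]) != "II" ||
      readBin(bytes[3:4], "integer", size = 2, endian = "little") != 42L) {
    stage_error("nmj_imaging", "not a little-endian TIFF file")
  }
  u32 <- function(off) readBin(bytes[off + 1:4], "integer", size = 4,
                               endian = "little")
  u16 <- function(off) readBin(bytes[off + 1:2], "integer", size = 2,
                               signed = FALSE, endian = "little")
  pages <- list()
  ifd <- u32(4L)
  while (ifd != 0L) {
    n_entries <- u16(ifd)
    tags <- list()
    for (k in seq_len(n_entries)) {
      base <- ifd + 2L + (k - 1L) * 12L
      tag <- u16(base)
      type <- u16(base + 2L)
      value <- if (type == 3L) u16(base + 8L) else u32(base + 8L)
      tags[[as.character(tag)]] <- value
    }
    need <- as.character(unname(TIFF_TAGS))
    if (!all(need %in% names(tags))) {
      stage_error("nmj_imaging", "TIFF page lacks required baseline tags")
    }
    if (tags[["259"]] != 1L || tags[["258"]] != 16L) {
      stage_error("nmj_imaging",
                  "only uncompressed 16-bit TIFF pages are supported")
    }
    h <- tags[["257"]]; w <- tags[["256"]]
    off <- tags[["273"]]
    v <- read_uint16(bytes[off + seq_len(2L * h * w)], h * w)
    pages[[length(pages) + 1L]] <- t(matrix(v, nrow = w, ncol = h))
    ifd <- u32(ifd + 2L + n_entries * 12L)
  }
  if (length(pages) != 2L) {
    stage_error("nmj_imaging", sprintf(
      "expected 2 channels (axon, AChR), found %d page(s)", length(pages)))
  }
  sidecar <- paste0(sub("\\.tiff?$", "", path), ".json")
  meta <- if (file.exists(sidecar)) jsonlite::read_json(sidecar) else list()
  nmj_image(axon_channel = pages[[1]], achr_channel = pages[[2]],
            pixel_size_um = meta$pixel_size_um %||% 1.0,
            embryo_id = meta$embryo_id %||% basename(path),
            group = meta$group, drug_id = meta$drug_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
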