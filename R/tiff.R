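# Minimal baseline TIFF support: uncompressed 16-bit grayscale, little-endian,
# one strip per page, time as pages. No pre-installed R package reads TIFF in
# this toolchain, so the subset of the format the pipeline emits is handled
# here directly. Physical calibration travels in a JSON sidecar
# ("<path>.json"), not in TIFF tags.

.u16_raw <- function(v) {
  v <- as.integer(pmin(pmax(round(v), 0), 65535))
  as.raw(rbind(v %% 256L, v %/% 256L))
}

.u32_raw <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256,
               (v %/% 16777216) %% 256))
}

.rd_u16 <- function(raw, off) {
  as.integer(raw[off + 1L]) + 256L * as.integer(raw[off + 2L])
}

.rd_u32 <- function(raw, off) {
  as.numeric(raw[off + 1L]) + 256 * as.numeric(raw[off + 2L]) +
    65536 * as.numeric(raw[off + 3L]) + 16777216 * as.numeric(raw[off + 4L])
}

.ifd_entry <- function(tag, type, count, value) {
  c(.u16_raw(tag), .u16_raw(type), .u32_raw(count),
    if (type == 3L) c(.u16_raw(value), as.raw(c(0, 0))) else .u32_raw(value))
}

#' Write an image stack as a multi-page 16-bit grayscale TIFF
#'
#' Intensities are rounded and clamped to the unsigned 16-bit range. A JSON
#' sidecar `<path>.json` records pixel size, frame interval and start time so
#' that [read_tiff_stack()] can restore the calibrated stack.
#'
#' @param stack an [image_stack()].
#' @param path output file path.
#' @param sidecar write the JSON calibration sidecar (default `TRUE`).
#' @param params optional list echoed into the sidecar (e.g. generator
#'   parameters).
#' @return `path`, invisibly.
#' @export
write_tiff_stack <- function(stack, path, sidecar = TRUE, params = NULL) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  h <- d[1L]; w <- d[2L]; nf <- d[3L]
  frame_bytes <- 2 * h * w
  data_start <- 8
  ifd_start <- data_start + nf * frame_bytes
  ifd_size <- 2 + 10 * 12 + 4   # entry count + 10 entries + next pointer

  con <- file(path, "wb")
  on.exit(close(con))
  # header: little-endian magic, offset of first IFD
  writeBin(charToRaw("II"), con)
  writeBin(.u16_raw(42L), con)
  writeBin(.u32_raw(ifd_start), con)
  for (i in seq_len(nf)) {
    frame <- stack$data[, , i]
    writeBin(.u16_raw(as.vector(t(frame))), con)  # row-major strip
  }
  for (i in seq_len(nf)) {
    strip_off <- data_start + (i - 1) * frame_bytes
    nxt <- if (i < nf) ifd_start + i * ifd_size else 0
    entries <- c(
      .ifd_entry(256L, 3L, 1L, w),            # ImageWidth
      .ifd_entry(257L, 3L, 1L, h),            # ImageLength
      .ifd_entry(258L, 3L, 1L, 16L),          # BitsPerSample
      .ifd_entry(259L, 3L, 1L, 1L),           # Compression: none
      .ifd_entry(262L, 3L, 1L, 1L),           # Photometric: BlackIsZero
      .ifd_entry(273L, 4L, 1L, strip_off),    # StripOffsets
      .ifd_entry(277L, 3L, 1L, 1L),           # SamplesPerPixel
      .ifd_entry(278L, 4L, 1L, h),            # RowsPerStrip
      .ifd_entry(279L, 4L, 1L, frame_bytes),  # StripByteCounts
      .ifd_entry(339L, 3L, 1L, 1L))           # SampleFormat: unsigned int
    writeBin(c(.u16_raw(10L), entries, .u32_raw(nxt)), con)
  }
  if (isTRUE(sidecar)) {
    meta <- list(pixel_size = stack$pixel_size,
                 frame_interval = stack$frame_interval,
                 t_start = stack$t_start)
    if (!is.null(params)) meta$params <- params
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

.read_ifd_tags <- function(raw, off) {
  n <- .rd_u16(raw, off)
  tags <- list()
  for (k in seq_len(n)) {
    e <- off + 2 + (k - 1) * 12
    tag <- .rd_u16(raw, e)
    type <- .rd_u16(raw, e + 2)
    count <- .rd_u32(raw, e + 4)
    if (type == 3L && count == 1) {
      val <- .rd_u16(raw, e + 8)
    } else if (type == 4L && count == 1) {
      val <- .rd_u32(raw, e + 8)
    } else if (type %in% c(3L, 4L)) {
      sz <- if (type == 3L) 2L else 4L
      voff <- if (count * sz <= 4) e + 8 else .rd_u32(raw, e + 8)
      rd <- if (type == 3L) .rd_u16 else .rd_u32
      val <- vapply(seq_len(count), function(j) rd(raw, voff + (j - 1) * sz),
                    numeric(1))
    } else {
      val <- NULL  # unsupported entry type: ignored
    }
    tags[[as.character(tag)]] <- val
  }
  list(tags = tags, next_ifd = .rd_u32(raw, off + 2 + n * 12))
}

#' Read a multi-page 16-bit grayscale TIFF as an image stack
#'
#' Reads the uncompressed baseline subset written by [write_tiff_stack()]
#' (little-endian, 16-bit unsigned grayscale; multiple strips allowed).
#' Calibration is taken from the JSON sidecar when present, otherwise from
#' the arguments.
#'
#' @param path TIFF file path.
#' @param pixel_size,frame_interval calibration overrides; required when no
#'   sidecar exists.
#' @return an [image_stack()].
#' @export
read_tiff_stack <- function(path, pixel_size = NULL, frame_interval = NULL) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (rawToChar(raw[1:2]) != "II" || .rd_u16(raw, 2) != 42L) {
    stop_data("not a little-endian TIFF: ", path)
  }
  frames <- list()
  off <- .rd_u32(raw, 4)
  while (off != 0) {
    ifd <- .read_ifd_tags(raw, off)
    tg <- ifd$tags
    w <- tg[["256"]]; h <- tg[["257"]]
    if (is.null(w) || is.null(h)) stop_data("TIFF page missing dimensions")
    if (!identical(as.integer(tg[["258"]] %||% 16L), 16L) ||
        !identical(as.integer(tg[["259"]] %||% 1L), 1L)) {
      stop_data("only uncompressed 16-bit grayscale TIFF is supported")
    }
    offs <- tg[["273"]]; counts <- tg[["279"]]
    bytes <- unlist(lapply(seq_along(offs), function(j) {
      raw[(offs[j] + 1):(offs[j] + counts[j])]
    }))
    idx <- seq(1, length(bytes), by = 2)
    px <- as.integer(bytes[idx]) + 256L * as.integer(bytes[idx + 1])
    frames[[length(frames) + 1L]] <- t(matrix(px, nrow = w, ncol = h))
    off <- ifd$next_ifd
  }
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    pixel_size <- pixel_size %||% meta$pixel_size
    frame_interval <- frame_interval %||% meta$frame_interval
    t_start <- meta$t_start %||% 0
  } else {
    t_start <- 0
  }
  if (is.null(pixel_size) || is.null(frame_interval)) {
    stop_data("no sidecar found; supply pixel_size and frame_interval")
  }
  arr <- array(0, dim = c(dim(frames[[1]]), length(frames)))
  for (i in seq_along(frames)) arr[, , i] <- frames[[i]]
  image_stack(arr, pixel_size, frame_interval, t_start)
}
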