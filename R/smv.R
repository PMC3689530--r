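#' Write a detector frame as an SMV (ADSC-style) image
#'
#' Fixed-size ASCII header (`HEADER_BYTES`, `DIM`, `BYTE_ORDER`, `TYPE`,
#' `SIZE1`/`SIZE2`, `PIXEL_SIZE`, `DISTANCE`, `WAVELENGTH`,
#' `BEAM_CENTER_X`/`Y`) padded to 512 bytes, followed by a little-endian
#' unsigned 16-bit payload with the fast axis contiguous.  `SIZE1` is the
#' fast dimension and `SIZE2` the slow dimension.  Reading back a written
#' frame is the identity on counts and geometry.
#'
#' @param frame A [detector_frame()]; counts must fit in 16 bits.
#' @param path Output path.
#' @param header_bytes Header size (default 512).
#' @return `path`, invisibly.
#' @export
write_smv <- function(frame, path, header_bytes = 512) {
  cnt <- frame$counts
  if (any(cnt > 65535)) stop("counts exceed 65535: unsigned 16-bit SMV cannot store them")
  g <- frame$geometry
  hdr <- paste0("{\n",
                sprintf("HEADER_BYTES=%5d;\n", header_bytes),
                "DIM=2;\n",
                "BYTE_ORDER=little_endian;\n",
                "TYPE=unsigned_short;\n",
                sprintf("SIZE1=%d;\n", ncol(cnt)),
                sprintf("SIZE2=%d;\n", nrow(cnt)),
                sprintf("PIXEL_SIZE=%.6f;\n", g$pixel_size),
                sprintf("DISTANCE=%.6f;\n", g$distance),
                sprintf("WAVELENGTH=%.6f;\n", g$wavelength),
                sprintf("BEAM_CENTER_X=%.6f;\n", g$beam_center[1]),
                sprintf("BEAM_CENTER_Y=%.6f;\n", g$beam_center[2]),
                "}\n")
  raw_hdr <- charToRaw(hdr)
  if (length(raw_hdr) > header_bytes) stop("header does not fit HEADER_BYTES")
  raw_hdr <- c(raw_hdr, rep(charToRaw(" "), header_bytes - length(raw_hdr)))
  v <- as.integer(t(cnt))               # fast axis contiguous
  payload <- as.raw(rbind(v %% 256L, v %/% 256L))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw_hdr, con)
  writeBin(payload, con)
  invisible(path)
}

#' Read an SMV (ADSC-style) image
#'
#' Parses the ASCII `key=value;` header, honours `HEADER_BYTES` as the
#' payload offset and reads the unsigned 16-bit payload in the declared
#' byte order.  The returned frame carries an all-active mask (SMV stores
#' no mask).
#'
#' @param path Input path.
#' @return A [detector_frame()].
#' @export
read_smv <- function(path) {
  if (!file.exists(path)) stop(sprintf("SMV file '%s' does not exist", path))
  con <- file(path, "rb")
  on.exit(close(con))
  raw_probe <- readBin(con, "raw", 4096)
  nul <- which(raw_probe == as.raw(0))
  if (length(nul)) raw_probe <- raw_probe[seq_len(nul[1] - 1)]
  probe <- rawToChar(raw_probe)
  close_brace <- regexpr("}", probe, fixed = TRUE)
  if (close_brace > 0) probe <- substr(probe, 1, close_brace)
  kv <- regmatches(probe, gregexpr("[A-Z_0-9]+=[^;]*;", probe))[[1]]
  hdr <- list()
  for (item in kv) {
    p <- strsplit(sub(";$", "", item), "=")[[1]]
    hdr[[p[1]]] <- trimws(p[2])
  }
  need <- c("HEADER_BYTES", "SIZE1", "SIZE2", "TYPE")
  for (k in need) {
    if (is.null(hdr[[k]])) stop(sprintf("malformed SMV header: missing key %s", k))
  }
  if (hdr$TYPE != "unsigned_short") {
    stop("unsupported SMV TYPE '", hdr$TYPE, "' (only unsigned_short)")
  }
  off <- as.integer(hdr$HEADER_BYTES)
  nf <- as.integer(hdr$SIZE1); ns <- as.integer(hdr$SIZE2)
  endian <- if (identical(hdr$BYTE_ORDER, "big_endian")) "big" else "little"
  seek(con, off)
  v <- readBin(con, "integer", n = ns * nf, size = 2, signed = FALSE,
               endian = endian)
  if (length(v) < ns * nf) stop("SMV payload truncated")
  counts <- t(matrix(v, nf, ns))
  num <- function(k, default) if (is.null(hdr[[k]])) default else as.numeric(hdr[[k]])
  geometry <- detector_geometry(
    distance = num("DISTANCE", 100),
    wavelength = num("WAVELENGTH", 1),
    beam_center = c(num("BEAM_CENTER_X", ns / 2 * num("PIXEL_SIZE", 0.1)),
                    num("BEAM_CENTER_Y", nf / 2 * num("PIXEL_SIZE", 0.1))),
    pixel_size = num("PIXEL_SIZE", 0.1),
    image_size = c(ns, nf))
  detector_frame(counts, geometry)
}

#' Write/read an active-pixel mask as PNG
#'
#' White (1) = active, black (0) = inactive; shape matches the frame.
#'
#' @param mask Logical matrix.
#' @param path PNG path.
#' @return `path` / logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), target = path)
  invisible(path)
}

#' @rdname write_mask_png
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img > 0.5
}
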