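# Minimal DICOM reader for OCT pullbacks.
#
# Scope is deliberately narrow: uncompressed little-endian transfer syntaxes
# (explicit or implicit VR), and only the tags needed to recover the pixel
# grid — rows, columns, number of frames, samples per pixel, bits allocated,
# planar configuration, pixel spacing and the pixel data element. Vendor
# private tags and sequence contents are skipped, compressed pixel data is
# rejected.

TS_IMPLICIT_LE <- "1.2.840.10008.1.2"
TS_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

dcm_u16 <- function(bytes, pos) {
  as.integer(bytes[pos]) + 256L * as.integer(bytes[pos + 1L])
}
dcm_u32 <- function(bytes, pos) {
  # double arithmetic: lengths can exceed .Machine$integer.max / 2
  sum(as.numeric(bytes[pos + 0:3]) * 256^(0:3))
}
dcm_str <- function(bytes, pos, len) {
  if (len == 0) return("")
  b <- bytes[pos:(pos + len - 1L)]
  b <- b[b != as.raw(0)]                 # UI values are NUL-padded
  trimws(rawToChar(b))
}

# VRs that use a 2-byte reserved field + 4-byte length in explicit VR
DCM_LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "OV", "SQ", "UC", "UR", "UT", "UN")

# parse data elements from `pos`, returning a named list of the tags of
# interest; stops after the pixel-data element or at `limit`
dcm_parse <- function(bytes, pos, explicit, limit = length(bytes)) {
  out <- list()
  while (pos + 7 <= limit + 1 && pos + 7 <= length(bytes)) {
    group <- dcm_u16(bytes, pos); elem <- dcm_u16(bytes, pos + 2L)
    if (explicit || group == 0x0002) {
      vr <- rawToChar(bytes[(pos + 4L):(pos + 5L)])
      if (vr %in% DCM_LONG_VRS) {
        len <- dcm_u32(bytes, pos + 8L); vpos <- pos + 12L
      } else {
        len <- dcm_u16(bytes, pos + 6L); vpos <- pos + 8L
      }
    } else {
      vr <- NA_character_
      len <- dcm_u32(bytes, pos + 4L); vpos <- pos + 8L
    }
    if (len == 4294967295) {  # undefined length
      if (group == 0x7FE0 && elem == 0x0010)
        stop_octlumen("compressed (encapsulated) pixel data is not supported",
                      "octlumen_input_format_error")
      stop_octlumen("undefined-length sequences are not supported",
                    "octlumen_input_format_error")
    }
    key <- sprintf("%04X%04X", group, elem)
    if (key == "00020010") out$transfer_syntax <- dcm_str(bytes, vpos, len)
    else if (key == "00280008") out$n_frames <- as.integer(dcm_str(bytes, vpos, len))
    else if (key == "00280002") out$samples <- dcm_u16(bytes, vpos)
    else if (key == "00280006") out$planar <- dcm_u16(bytes, vpos)
    else if (key == "00280010") out$rows <- dcm_u16(bytes, vpos)
    else if (key == "00280011") out$cols <- dcm_u16(bytes, vpos)
    else if (key == "00280100") out$bits <- dcm_u16(bytes, vpos)
    else if (key == "00280030") {
      sp <- strsplit(dcm_str(bytes, vpos, len), "\\\\")[[1]]
      out$pixel_spacing_mm <- as.numeric(sp[1])
    } else if (key == "7FE00010") {
      out$pixel_data <- bytes[vpos:(vpos + len - 1L)]
      return(out)
    }
    pos <- vpos + len
  }
  out
}

# Read a (multiframe) DICOM file; returns list(frames = list of [row, col]
# matrices or [row, col, 3] arrays scaled to [0, 1], pixel_spacing_mm or NULL)
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140)
    stop_octlumen(sprintf("'%s' is not a DICOM file", path),
                  "octlumen_input_format_error")
  pos <- 1L
  if (rawToChar(bytes[129:132]) == "DICM") pos <- 133L
  # file meta group is always explicit VR little endian; find its extent
  meta <- dcm_parse(bytes, pos, explicit = TRUE)
  ts <- meta$transfer_syntax %||% TS_EXPLICIT_LE
  if (!ts %in% c(TS_IMPLICIT_LE, TS_EXPLICIT_LE))
    stop_octlumen(sprintf("unsupported transfer syntax '%s'", ts),
                  "octlumen_input_format_error")
  # skip past the meta group: re-walk until first non-0002 group
  p <- pos
  while (p + 7 <= length(bytes) && dcm_u16(bytes, p) == 0x0002) {
    vr <- rawToChar(bytes[(p + 4L):(p + 5L)])
    if (vr %in% DCM_LONG_VRS) p <- p + 12L + dcm_u32(bytes, p + 8L)
    else p <- p + 8L + dcm_u16(bytes, p + 6L)
  }
  d <- dcm_parse(bytes, p, explicit = ts == TS_EXPLICIT_LE)
  if (is.null(d$pixel_data) || is.null(d$rows) || is.null(d$cols))
    stop_octlumen(sprintf("'%s' has no readable pixel data", path),
                  "octlumen_input_format_error")
  samples <- d$samples %||% 1L
  bits <- d$bits %||% 8L
  n_frames <- d$n_frames %||% 1L
  if (!bits %in% c(8L, 16L))
    stop_octlumen("only 8- and 16-bit pixel data are supported",
                  "octlumen_input_format_error")
  if (!is.null(d$planar) && d$planar != 0L && samples == 3L)
    stop_octlumen("planar-configuration-1 RGB is not supported",
                  "octlumen_input_format_error")
  vals <- if (bits == 8L) as.integer(d$pixel_data) / 255
  else readBin(d$pixel_data, "integer", n = length(d$pixel_data) / 2,
               size = 2, signed = FALSE, endian = "little") / 65535
  per_frame <- d$rows * d$cols * samples
  if (length(vals) < per_frame * n_frames)
    stop_octlumen("pixel data shorter than rows*cols*frames",
                  "octlumen_input_format_error")
  frames <- lapply(seq_len(n_frames), function(f) {
    v <- vals[((f - 1) * per_frame + 1):(f * per_frame)]
    if (samples == 1L) {
      matrix(v, nrow = d$rows, ncol = d$cols, byrow = TRUE)     # row-major
    } else {
      aperm(array(v, c(3L, d$cols, d$rows)), c(3, 2, 1))        # interleaved RGB
    }
  })
  list(frames = frames, pixel_spacing_mm = d$pixel_spacing_mm)
}
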