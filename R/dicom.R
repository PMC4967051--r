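# Minimal DICOM series reader.
#
# Scope: uncompressed explicit-VR little-endian files (transfer syntax
# 1.2.840.10008.1.2.1), one image frame per file, integer pixel data of 8
# or 16 bits — the form whole-body PET workstations export. Sequences with
# defined length are skipped; compressed or implicit-VR files are rejected
# with a clear error. No installed R package reads DICOM, hence this
# deliberately narrow parser.

DCM_EXPLICIT_LE <- "1.2.840.10008.1.2.1"

read_dicom_series <- function(dir) {
  if (!dir.exists(dir)) stop_input("no such DICOM directory '", dir, "'")
  files <- list.files(dir, full.names = TRUE)
  files <- files[!dir.exists(files)]
  files <- Filter(is_dicom_file, files)
  if (length(files) == 0L) stop_input("no DICOM files found in '", dir, "'")

  slices <- lapply(files, read_dicom_file)

  rows <- unique(vapply(slices, function(s) s$rows, 0L))
  cols <- unique(vapply(slices, function(s) s$cols, 0L))
  if (length(rows) != 1L || length(cols) != 1L)
    stop_input("inconsistent slice dimensions across DICOM series '", dir, "'")

  z <- vapply(slices, function(s) s$z_pos, 0)
  ord <- if (all(is.finite(z))) order(z) else
    order(vapply(slices, function(s) s$instance, 0))
  slices <- slices[ord]

  ps <- slices[[1]]$pixel_spacing       # (row spacing, column spacing) mm
  if (anyNA(ps)) stop_input("DICOM series '", dir, "' lacks PixelSpacing")
  dz <- slices[[1]]$z_spacing
  if (is.na(dz) && length(slices) >= 2L) {
    zz <- vapply(slices, function(s) s$z_pos, 0)
    if (all(is.finite(zz))) dz <- stats::median(diff(zz))
  }
  if (is.na(dz) || dz <= 0)
    stop_input("DICOM series '", dir, "' lacks slice spacing metadata")

  arr <- array(0, c(cols, rows, length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]$pixels
  scan_volume(arr, spacing = c(ps[2], ps[1], dz))
}

is_dicom_file <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  hdr <- readBin(con, "raw", 132L)
  length(hdr) == 132L && rawToChar(hdr[129:132]) == "DICM"
}

read_dicom_file <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 132L || rawToChar(raw[129:132]) != "DICM")
    stop_input("'", path, "' is not a DICOM file (no DICM magic)")
  elems <- parse_dicom_elements(raw, 133L, path)

  ts <- dcm_string(elems, "0002,0010")
  if (!is.na(ts) && ts != DCM_EXPLICIT_LE)
    stop_input("'", path, "': unsupported transfer syntax '", ts,
               "' (only explicit-VR little endian is supported)")

  rows <- dcm_uint(elems, "0028,0010")
  cols <- dcm_uint(elems, "0028,0011")
  bits <- dcm_uint(elems, "0028,0100")
  signed <- isTRUE(dcm_uint(elems, "0028,0103") == 1L)
  if (is.na(rows) || is.na(cols)) stop_input("'", path, "': missing Rows/Columns")
  if (!bits %in% c(8L, 16L))
    stop_input("'", path, "': unsupported BitsAllocated ", bits)

  px_raw <- elems[["7fe0,0010"]]
  if (is.null(px_raw)) stop_input("'", path, "': no PixelData")
  n <- rows * cols
  pixels <- if (bits == 16L)
    readBin(px_raw, "integer", n, size = 2L, signed = signed, endian = "little")
  else
    readBin(px_raw, "integer", n, size = 1L, signed = signed)
  if (length(pixels) < n) stop_input("'", path, "': truncated PixelData")
  slope <- dcm_numeric(elems, "0028,1053"); if (is.na(slope)) slope <- 1
  inter <- dcm_numeric(elems, "0028,1052"); if (is.na(inter)) inter <- 0
  pixels <- pixels * slope + inter

  ipp <- dcm_numeric_vec(elems, "0020,0032")
  list(
    rows = rows, cols = cols,
    pixels = matrix(pixels, nrow = cols, ncol = rows),  # column-fastest = x
    pixel_spacing = dcm_numeric_vec(elems, "0028,0030", 2L),
    z_spacing = {
      s <- dcm_numeric(elems, "0018,0088")              # SpacingBetweenSlices
      if (is.na(s)) s <- dcm_numeric(elems, "0018,0050")  # SliceThickness
      s
    },
    z_pos = if (length(ipp) >= 3L) ipp[3] else NA_real_,
    instance = { i <- dcm_numeric(elems, "0020,0013"); if (is.na(i)) 0 else i }
  )
}

# Walk the element stream, returning a named list tag -> raw value.
parse_dicom_elements <- function(raw, pos, path) {
  n <- length(raw)
  long_vrs <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")
  out <- list()
  while (pos + 7L <= n + 1L && pos <= n) {
    group <- rd_u16(raw, pos); elem <- rd_u16(raw, pos + 2L)
    vr <- rawToChar(raw[(pos + 4L):(pos + 5L)])
    if (!grepl("^[A-Z]{2}$", vr))
      stop_input("'", path, "': implicit-VR or corrupt element at byte ", pos,
                 " (only explicit-VR little endian is supported)")
    if (vr %in% long_vrs) {
      len <- rd_u32(raw, pos + 8L)
      hdr <- 12L
    } else {
      len <- rd_u16(raw, pos + 6L)
      hdr <- 8L
    }
    if (len == 4294967295) # undefined length (encapsulated/SQ): unsupported
      stop_input("'", path, "': undefined-length element ", sprintf("%04x,%04x", group, elem),
                 " is not supported")
    tag <- sprintf("%04x,%04x", group, elem)
    if (vr != "SQ" && len > 0)
      out[[tag]] <- raw[(pos + hdr):(pos + hdr + len - 1L)]
    pos <- pos + hdr + len
  }
  out
}

rd_u16 <- function(raw, pos)
  as.integer(raw[pos]) + 256L * as.integer(raw[pos + 1L])
rd_u32 <- function(raw, pos)
  as.numeric(raw[pos]) + 256 * as.numeric(raw[pos + 1L]) +
  65536 * as.numeric(raw[pos + 2L]) + 16777216 * as.numeric(raw[pos + 3L])

dcm_string <- function(elems, tag) {
  v <- elems[[tag]]
  if (is.null(v)) return(NA_character_)
  trimws(rawToChar(v[v != as.raw(0)]))
}
dcm_uint <- function(elems, tag) {
  v <- elems[[tag]]
  if (is.null(v)) return(NA_integer_)
  rd_u16(v, 1L)
}
dcm_numeric <- function(elems, tag) {
  s <- dcm_string(elems, tag)
  if (is.na(s) || !nzchar(s)) NA_real_ else suppressWarnings(as.numeric(s))
}
dcm_numeric_vec <- function(elems, tag, expect = NULL) {
  s <- dcm_string(elems, tag)
  if (is.na(s)) return(if (is.null(expect)) numeric(0) else rep(NA_real_, expect))
  suppressWarnings(as.numeric(strsplit(s, "\\\\")[[1]]))
}
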