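# Shared fixtures: all built in code at test time.

# Brute-force box-count oracle: explicit triple loop over the box grid.
# Mirrors both boundary conventions of box_count() independently.
brute_box_count <- function(occ, s_vox, boundary = "complete") {
  d <- dim(occ)
  nb <- if (boundary == "complete") pmax(d %/% s_vox, 1L) else (d - 1L) %/% s_vox + 1L
  cnt <- 0L
  for (bx in seq_len(nb[1]) - 1L)
    for (by in seq_len(nb[2]) - 1L)
      for (bz in seq_len(nb[3]) - 1L) {
        xs <- (bx * s_vox + 1L):min((bx + 1L) * s_vox, d[1])
        ys <- (by * s_vox + 1L):min((by + 1L) * s_vox, d[2])
        zs <- (bz * s_vox + 1L):min((bz + 1L) * s_vox, d[3])
        if (any(occ[xs, ys, zs])) cnt <- cnt + 1L
      }
  cnt
}

# Closed-form nested counts for an m-of-27 generator fractal at depth k:
# N(3^j) = m^(k - j) on the exact scale ladder.
generator_counts <- function(m, k, j) m^(k - j)

# Binomial multiplicative cascade (1D analogue): masses after `levels`
# bisections with weights (w, 1 - w).
cascade_measure <- function(w = 0.7, levels = 6) {
  p <- 1
  for (i in seq_len(levels)) p <- as.vector(outer(c(w, 1 - w), p))
  box_measure(p, epsilon = 2^-levels)
}

# Random valid box measure under a fixed seed.
random_measure <- function(n, seed) {
  withr::with_seed(seed, {
    p <- runif(n, min = 1e-6)
    box_measure(p / sum(p), epsilon = runif(1, 0.05, 0.9))
  })
}

# --- minimal explicit-VR little-endian DICOM writer (fixture only) -------

dcm_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
dcm_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

dcm_elem_short <- function(group, elem, vr, value_raw) {
  if (length(value_raw) %% 2 == 1)
    value_raw <- c(value_raw, if (vr == "UI") as.raw(0) else charToRaw(" "))
  c(dcm_u16(group), dcm_u16(elem), charToRaw(vr),
    dcm_u16(length(value_raw)), value_raw)
}

dcm_elem_ow <- function(group, elem, value_raw) {
  c(dcm_u16(group), dcm_u16(elem), charToRaw("OW"), as.raw(c(0, 0)),
    dcm_u32(length(value_raw)), value_raw)
}

# One slice: `pix` is a cols x rows integer matrix (x fastest), written as
# 16-bit unsigned little-endian pixel data.
write_dicom_slice <- function(path, pix, z_pos, instance,
                              pixel_spacing = c(2.03642, 2.03642),
                              slice_thickness = 4) {
  stopifnot(max(pix) < 32768, min(pix) >= 0)
  body <- c(
    dcm_elem_short(0x0018, 0x0050, "DS", charToRaw(format(slice_thickness))),
    dcm_elem_short(0x0020, 0x0013, "IS", charToRaw(format(instance))),
    dcm_elem_short(0x0020, 0x0032, "DS",
                   charToRaw(paste(0, 0, z_pos, sep = "\\"))),
    dcm_elem_short(0x0028, 0x0010, "US", dcm_u16(ncol(pix))),   # Rows
    dcm_elem_short(0x0028, 0x0011, "US", dcm_u16(nrow(pix))),   # Columns
    dcm_elem_short(0x0028, 0x0030, "DS",
                   charToRaw(paste(pixel_spacing[1], pixel_spacing[2], sep = "\\"))),
    dcm_elem_short(0x0028, 0x0100, "US", dcm_u16(16)),          # BitsAllocated
    dcm_elem_short(0x0028, 0x0103, "US", dcm_u16(0)),           # unsigned
    dcm_elem_ow(0x7FE0, 0x0010,
                writeBin(as.integer(as.vector(pix)), raw(), size = 2,
                         endian = "little")))
  meta <- dcm_elem_short(0x0002, 0x0010, "UI", charToRaw("1.2.840.10008.1.2.1"))
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), meta, body), con)
  invisible(path)
}

# --- cached default-condition simulation runs ----------------------------
# The reference-condition runs (L = 81, n = 10, p = 0.001, T = 100 L^3) are
# expensive; several acceptance checks share them via this memo.
.kmc_memo <- new.env(parent = emptyenv())

default_kmc_runs <- function(seeds = 1:3) {
  key <- paste(seeds, collapse = ",")
  if (is.null(.kmc_memo[[key]])) {
    net <- build_network(4)
    .kmc_memo[[key]] <- lapply(seeds, function(s)
      simulate_kmc(kmc_config(seed = s), net))
  }
  .kmc_memo[[key]]
}
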