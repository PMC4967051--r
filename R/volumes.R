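#' 3D scan volume
#'
#' Container for a 3D non-negative intensity grid (arbitrary activity units)
#' with per-axis voxel spacing in mm. Negative intensities, which can arise
#' from iterative reconstruction, are clipped to zero with a warning.
#'
#' @param intensities 3D numeric array of voxel intensities.
#' @param spacing numeric length-3, voxel edge lengths in mm per axis.
#' @return An object of class `scan_volume` with fields `intensities`,
#'   `spacing` and `dims`.
#' @examples
#' vol <- scan_volume(array(1, c(4, 4, 4)), spacing = c(2, 2, 4))
#' vol
#' @export
scan_volume <- function(intensities, spacing) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop_input("'intensities' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("'spacing' must be 3 positive voxel edge lengths (mm)")
  if (anyNA(intensities)) stop_input("intensities contain NA")
  if (any(intensities < 0)) {
    warning("negative intensities clipped to 0", call. = FALSE)
    intensities[intensities < 0] <- 0
  }
  structure(
    list(intensities = intensities, spacing = spacing, dims = dim(intensities)),
    class = "scan_volume"
  )
}

#' @export
print.scan_volume <- function(x, ...) {
  cat("<scan_volume> ", paste(x$dims, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 6), collapse = " x "),
      " mm\n", sep = "")
  cat("  intensity range [", signif(min(x$intensities), 4), ", ",
      signif(max(x$intensities), 4), "], total ",
      signif(sum(x$intensities), 6), "\n", sep = "")
  invisible(x)
}

# physical body extent per axis, mm
body_extent <- function(volume) volume$dims * volume$spacing

is_isotropic <- function(volume, tol = 1e-6) {
  diff(range(volume$spacing)) <= tol * max(volume$spacing)
}

#' Read a 3D volume from disk
#'
#' Reads NIfTI files (`.nii` / `.nii.gz`, via \pkg{RNifti}) or a directory
#' containing an uncompressed explicit-VR little-endian DICOM series (one
#' slice per file). Voxel spacing is taken from the file header; a missing
#' spacing is an error, since all downstream box geometry is metric.
#'
#' @param path file path (NIfTI) or directory path (DICOM series).
#' @param format `"auto"` (default; directories are treated as DICOM series),
#'   `"nifti"` or `"dicom_series"`.
#' @return A [scan_volume()].
#' @export
read_volume <- function(path, format = c("auto", "nifti", "dicom_series")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_input("cannot read volume: no such path '", path, "'")
  if (format == "auto")
    format <- if (dir.exists(path)) "dicom_series" else "nifti"
  if (format == "dicom_series") return(read_dicom_series(path))

  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_input("unreadable NIfTI '", path, "': ",
                                                 conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop_input("'", path, "' is not a 3D volume (dims: ",
               paste(dim(arr), collapse = "x"), ")")
  spacing <- RNifti::pixdim(img)[seq_len(3)]
  if (length(spacing) < 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop_input("'", path, "' has no usable voxel spacing metadata")
  scan_volume(arr, spacing)
}

#' Write a volume or mask as NIfTI
#'
#' @param x a [scan_volume()] or [lesion_mask()] (masks are written as 0/1).
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "lesion_mask")) {
    arr <- array(as.numeric(x$occupancy), dim(x$occupancy))
    spacing <- rep(x$spacing, 3)
  } else if (inherits(x, "scan_volume")) {
    arr <- x$intensities
    spacing <- x$spacing
  } else stop_input("'x' must be a scan_volume or lesion_mask")
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Regrid a volume to an isotropic analysis lattice
#'
#' Aggregates blocks of voxels so that the output voxel is a cube of edge
#' `target_edge` mm; each output intensity is the SUM of its constituent
#' input voxels, so total activity is conserved. In-plane pixel sizes that
#' are only nominally commensurate (e.g. 2.03642 mm pixels aggregated 2x2
#' into a 4 mm cube) are accepted within `tol` relative tolerance. Partial
#' blocks at the far boundary are kept as (partial) output voxels rather
#' than truncated, so no activity is lost.
#'
#' @param volume a [scan_volume()].
#' @param target_edge output cubic voxel edge, mm (default 4).
#' @param tol relative tolerance on spacing commensurability (default 0.02).
#' @return A [scan_volume()] with isotropic spacing `target_edge`.
#' @export
regrid_isotropic <- function(volume, target_edge = 4, tol = 0.02) {
  stopifnot(inherits(volume, "scan_volume"))
  if (!(length(target_edge) == 1L && is.finite(target_edge) && target_edge > 0))
    stop_input("'target_edge' must be a positive length (mm)")
  f <- round(target_edge / volume$spacing)
  if (any(f < 1) || any(abs(f * volume$spacing - target_edge) > tol * target_edge))
    stop_input("spacing (", paste(signif(volume$spacing, 6), collapse = ", "),
               ") not commensurate with target edge ", target_edge,
               " mm within ", tol * 100, "% tolerance")
  arr <- volume$intensities
  for (axis in 1:3) arr <- block_sum_axis(arr, f[axis], axis)
  scan_volume(arr, rep(target_edge, 3))
}

# Sum blocks of `f` consecutive planes along `axis`; a short final block is
# zero-padded (partial block kept).
block_sum_axis <- function(arr, f, axis) {
  if (f == 1L) return(arr)
  d <- dim(arr)
  n <- d[axis]
  m <- ceiling(n / f)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  if (m * f > n) {
    pad <- array(0, c(m * f - n, d[perm[2]], d[perm[3]]))
    a2 <- array(0, c(m * f, d[perm[2]], d[perm[3]]))
    a2[seq_len(n), , ] <- a
    a <- a2
  }
  dim(a) <- c(f, m * d[perm[2]] * d[perm[3]])
  a <- colSums(a)
  dim(a) <- c(m, d[perm[2]], d[perm[3]])
  aperm(a, order(perm))
}

#' Tracer-presence threshold policy
#'
#' Policy deciding which voxels count as containing tracer. The default is
#' relative: a voxel is occupied iff its intensity exceeds
#' `value * max(volume)` (default 5% of the maximum), which removes
#' reconstruction background while staying operator independent. An
#' absolute-intensity mode is also provided. Neither is claimed to be a
#' clinical standard; the choice is recorded in the mask provenance.
#'
#' @param type `"relative"` or `"absolute"`.
#' @param value relative fraction of the volume maximum (default 0.05), or
#'   an absolute intensity when `type = "absolute"`.
#' @return A `threshold_policy` object.
#' @export
threshold_policy <- function(type = c("relative", "absolute"), value = 0.05) {
  type <- match.arg(type)
  if (!(length(value) == 1L && is.finite(value) && value >= 0))
    stop_input("threshold 'value' must be a non-negative scalar")
  structure(list(type = type, value = value), class = "threshold_policy")
}

policy_threshold <- function(policy, intensities) {
  switch(policy$type,
         relative = policy$value * max(intensities),
         absolute = policy$value)
}

#' Binarize a volume into a tracer-occupancy mask
#'
#' A voxel is occupied iff its intensity strictly exceeds the policy
#' threshold. The volume must already be isotropic (post-regrid), since the
#' mask feeds cubic box counting. An all-empty mask is an error: fractal
#' fits are undefined without occupied voxels.
#'
#' @param volume an isotropic [scan_volume()].
#' @param policy a [threshold_policy()].
#' @return A `lesion_mask`: boolean `occupancy` array, scalar `spacing`
#'   (mm), and the policy + realized threshold as provenance.
#' @export
binarize <- function(volume, policy = threshold_policy()) {
  stopifnot(inherits(volume, "scan_volume"))
  if (!inherits(policy, "threshold_policy")) stop_input("'policy' must be a threshold_policy")
  if (!is_isotropic(volume))
    stop_input("binarize requires an isotropic volume; call regrid_isotropic() first")
  thr <- policy_threshold(policy, volume$intensities)
  occ <- volume$intensities > thr
  if (!any(occ)) stop_numeric("empty mask: no voxel exceeds threshold ", signif(thr, 6))
  lesion_mask(occ, volume$spacing[1], policy = policy, threshold = thr)
}

#' Lesion occupancy mask
#'
#' @param occupancy 3D logical array.
#' @param spacing isotropic voxel edge, mm (or 1 for lattice units).
#' @param policy,threshold provenance of how the mask was derived (optional).
#' @return A `lesion_mask` object.
#' @export
lesion_mask <- function(occupancy, spacing, policy = NULL, threshold = NA_real_) {
  if (!is.array(occupancy) || length(dim(occupancy)) != 3L || !is.logical(occupancy))
    stop_input("'occupancy' must be a 3D logical array")
  if (!(length(spacing) == 1L && is.finite(spacing) && spacing > 0))
    stop_input("'spacing' must be a positive scalar")
  structure(list(occupancy = occupancy, spacing = as.numeric(spacing),
                 dims = dim(occupancy), policy = policy, threshold = threshold),
            class = "lesion_mask")
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("<lesion_mask> ", paste(x$dims, collapse = " x "), " voxels @ ",
      signif(x$spacing, 6), " mm, ", sum(x$occupancy), " occupied\n", sep = "")
  invisible(x)
}
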