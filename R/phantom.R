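#' Phantom specification
#'
#' Describes a synthetic whole-body tracer phantom standing in for a real
#' emission scan: a few smooth compact high-intensity "organ" blobs, plus
#' point-like "lesions" at given voxel sites (typically sampled on a
#' generated fractal vascular network), over a low additive non-negative
#' background. All geometry is metric (mm); voxel sites are 1-based array
#' indices.
#'
#' @param extent_mm numeric length-3, body extent per axis in mm.
#' @param spacing voxel spacing in mm per axis; defaults to the 2.03642 x
#'   2.03642 mm in-plane pixel and 4 mm slice geometry of clinical
#'   whole-body scans, so that phantoms exercise the regridding step.
#' @param blobs list of organ blobs, each `list(center = mm xyz, radius =
#'   mm, peak = intensity)`; rendered as a smooth parabolic cap
#'   `peak * (1 - (r/radius)^2)` with compact support.
#' @param lesions integer matrix (n x 3) of 1-based voxel coordinates, or
#'   `NULL`; `lesion_intensity` gives their brightness (recycled).
#' @param lesion_intensity intensity added at each lesion voxel.
#' @param noise_level background noise amplitude; each voxel gets an
#'   additive Uniform(0, noise_level) term. 0 disables noise.
#' @param seed RNG seed making the phantom bit-reproducible.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(extent_mm,
                         spacing = c(2.03642, 2.03642, 4),
                         blobs = list(),
                         lesions = NULL,
                         lesion_intensity = 10,
                         noise_level = 0,
                         seed = 1L) {
  extent_mm <- as.numeric(extent_mm)
  if (length(extent_mm) != 3L || any(extent_mm <= 0))
    stop_input("'extent_mm' must be 3 positive lengths (mm)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop_input("'spacing' must be 3 positive lengths (mm)")
  if (!(length(noise_level) == 1L && is.finite(noise_level) && noise_level >= 0))
    stop_input("'noise_level' must be >= 0")
  dims <- pmax(1L, as.integer(ceiling(extent_mm / spacing)))
  for (b in blobs) {
    if (!all(c("center", "radius", "peak") %in% names(b)))
      stop_input("each blob needs fields center, radius, peak")
    if (any(b$center - b$radius < 0) || any(b$center + b$radius > extent_mm))
      stop_input("blob at (", paste(b$center, collapse = ", "),
                 ") extends outside the body extent")
  }
  if (!is.null(lesions)) {
    lesions <- as.matrix(lesions)
    storage.mode(lesions) <- "integer"
    if (ncol(lesions) != 3L) stop_input("'lesions' must be an n x 3 matrix of voxel coords")
    bad <- lesions < 1L | lesions > matrix(dims, nrow(lesions), 3, byrow = TRUE)
    if (any(bad)) stop_input(sum(rowSums(bad) > 0), " lesion site(s) outside the body extent")
  }
  structure(list(extent_mm = extent_mm, spacing = spacing, dims = dims,
                 blobs = blobs, lesions = lesions,
                 lesion_intensity = lesion_intensity,
                 noise_level = noise_level, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Generate a synthetic phantom volume
#'
#' Deterministic for a fixed spec seed (bit-identical across runs). The
#' caller's RNG state is left untouched.
#'
#' @param spec a [phantom_spec()].
#' @return A [scan_volume()].
#' @examples
#' sp <- phantom_spec(c(40, 40, 40), spacing = c(4, 4, 4),
#'                    lesions = rbind(c(5, 5, 5)), noise_level = 0)
#' vol <- generate_phantom(sp)
#' sum(vol$intensities > 0)  # exactly one bright voxel
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$dims
  arr <- array(0, d)

  if (spec$noise_level > 0) {
    arr <- arr + with_local_seed(spec$seed,
      array(runif(prod(d), 0, spec$noise_level), d))
  }

  # voxel-center coordinates, mm
  if (length(spec$blobs) > 0) {
    cx <- (seq_len(d[1]) - 0.5) * spec$spacing[1]
    cy <- (seq_len(d[2]) - 0.5) * spec$spacing[2]
    cz <- (seq_len(d[3]) - 0.5) * spec$spacing[3]
    for (b in spec$blobs) {
      r2 <- outer(outer((cx - b$center[1])^2, (cy - b$center[2])^2, `+`),
                  (cz - b$center[3])^2, `+`)
      cap <- b$peak * pmax(0, 1 - r2 / b$radius^2)
      arr <- arr + cap
    }
  }

  if (!is.null(spec$lesions) && nrow(spec$lesions) > 0) {
    inten <- rep_len(spec$lesion_intensity, nrow(spec$lesions))
    idx <- spec$lesions[, 1] +
      d[1] * (spec$lesions[, 2] - 1L) +
      d[1] * d[2] * (spec$lesions[, 3] - 1L)
    arr[idx] <- arr[idx] + inten
  }

  scan_volume(arr, spec$spacing)
}

#' Place phantom lesions on a fractal vascular network
#'
#' Maps the sites of a [build_network()] lattice to 1-based voxel
#' coordinates so they can be passed as the `lesions` field of a
#' [phantom_spec()] whose voxel grid is at least as large as the lattice.
#'
#' @param network a `vascular_network`.
#' @return Integer matrix (n x 3) of voxel coordinates.
#' @export
lesions_from_network <- function(network) {
  stopifnot(inherits(network, "vascular_network"))
  network$sites + 1L
}

#' Read / write a phantom spec as YAML
#'
#' Key-value schema: `extent_mm`, `spacing`, `noise_level`, `seed`,
#' `lesion_intensity`, `blobs` (list of center/radius/peak), `lesions`
#' (list of 3-vectors, 1-based voxel coords).
#'
#' @param path YAML file path.
#' @return [phantom_spec()] for `read_phantom_spec`; `path` for the writer.
#' @export
read_phantom_spec <- function(path) {
  if (!file.exists(path)) stop_input("no such phantom spec '", path, "'")
  y <- yaml::read_yaml(path)
  lesions <- if (!is.null(y$lesions)) do.call(rbind, y$lesions)
  phantom_spec(extent_mm = y$extent_mm,
               spacing = if (is.null(y$spacing)) c(2.03642, 2.03642, 4) else y$spacing,
               blobs = if (is.null(y$blobs)) list() else y$blobs,
               lesions = lesions,
               lesion_intensity = if (is.null(y$lesion_intensity)) 10 else y$lesion_intensity,
               noise_level = if (is.null(y$noise_level)) 0 else y$noise_level,
               seed = if (is.null(y$seed)) 1L else y$seed)
}

#' @rdname read_phantom_spec
#' @param spec a [phantom_spec()] to serialize.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  y <- list(extent_mm = spec$extent_mm, spacing = spec$spacing,
            blobs = spec$blobs,
            lesions = if (!is.null(spec$lesions))
              lapply(seq_len(nrow(spec$lesions)), function(i) as.integer(spec$lesions[i, ])),
            lesion_intensity = spec$lesion_intensity,
            noise_level = spec$noise_level, seed = spec$seed)
  yaml::write_yaml(y, path)
  invisible(path)
}
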