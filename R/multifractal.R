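#' Normalized box-intensity measure
#'
#' The multifractal analysis works on the finest available scale: the
#' volume is regridded to cubic boxes of edge `box_edge` (4 mm by default),
#' occupied boxes are selected by the threshold policy, and each occupied
#' box gets the probability mass `p_i` = (box intensity) / (total intensity
#' over occupied boxes), so that `sum(p_i) = 1` regardless of the subject's
#' absolute activity. The dimensionless scale entering the dimension
#' formulas is `epsilon = box_edge / largest body-axis extent`, which is
#' < 1, so `ln(epsilon) < 0` and the generalized dimensions come out
#' positive for mass spread over many boxes.
#'
#' @param volume a [scan_volume()] (regridded internally if needed).
#' @param box_edge box edge in mm (default 4).
#' @param policy a [threshold_policy()].
#' @return A `box_measure`: fields `p` (masses over occupied boxes),
#'   `n_boxes` (total boxes covering the body), `s_mm`, `epsilon`.
#' @export
compute_measure <- function(volume, box_edge = 4, policy = threshold_policy()) {
  stopifnot(inherits(volume, "scan_volume"))
  if (!is_isotropic(volume) || abs(volume$spacing[1] - box_edge) > 1e-9)
    volume <- regrid_isotropic(volume, box_edge)
  thr <- policy_threshold(policy, volume$intensities)
  occ <- volume$intensities > thr
  vals <- volume$intensities[occ]
  total <- sum(vals)
  if (length(vals) == 0L || total <= 0)
    stop_numeric("zero total intensity above threshold: measure undefined")
  box_measure(p = vals / total,
              epsilon = box_edge / max(body_extent(volume)),
              s_mm = box_edge,
              n_boxes = prod(volume$dims))
}

#' @rdname compute_measure
#' @param p vector of positive masses summing to 1 (within 1e-12).
#' @param epsilon dimensionless relative box scale, in (0, 1).
#' @param s_mm box edge in mm (metadata).
#' @param n_boxes total number of boxes covering the body (metadata).
#' @export
box_measure <- function(p, epsilon, s_mm = NA_real_, n_boxes = NA_integer_) {
  p <- as.numeric(p)
  if (length(p) == 0L || any(p <= 0)) stop_input("all p_i must be > 0")
  if (abs(sum(p) - 1) > 1e-12) stop_input("sum(p_i) must be 1 (got ", sum(p), ")")
  if (!(length(epsilon) == 1L && epsilon > 0 && epsilon < 1)) {
    # a single box covering the whole body has epsilon = 1; allow it so the
    # degenerate one-box measure (D_q = 0) is representable
    if (!(length(epsilon) == 1L && epsilon == 1 && length(p) == 1L))
      stop_input("'epsilon' must lie in (0, 1)")
  }
  structure(list(p = p, epsilon = as.numeric(epsilon), s_mm = s_mm,
                 n_boxes = n_boxes),
            class = "box_measure")
}

#' @export
print.box_measure <- function(x, ...) {
  cat("<box_measure> ", length(x$p), " occupied boxes of ",
      signif(x$s_mm, 4), " mm, epsilon = ", signif(x$epsilon, 5), "\n", sep = "")
  invisible(x)
}

#' Generalized (Renyi) dimension of a box measure
#'
#' Single-scale estimate at the measure's own `epsilon`:
#' `D_q = ln(sum p_i^q) / ((q - 1) ln epsilon)` for `q != 1`, and the
#' information dimension `D_1 = sum(p_i ln p_i) / ln(epsilon)` on the
#' branch `|q - 1| < 1e-9`. Sums run over occupied boxes only, which keeps
#' negative-q sums finite. Evaluation goes through log-sum-exp so large
#' `|q|` cannot overflow.
#'
#' @param measure a `box_measure`.
#' @param q dimension order(s), any real value(s).
#' @return Numeric vector of `D_q`, one per `q`.
#' @examples
#' m <- box_measure(c(0.75, 0.25), epsilon = 0.5)
#' generalized_dimension(m, 2)   # log(0.625)/log(0.5) = 0.678
#' @export
generalized_dimension <- function(measure, q) {
  stopifnot(inherits(measure, "box_measure"))
  if (length(measure$p) == 1L) return(rep(0, length(q)))  # single box: D_q = 0
  lp <- log(measure$p)
  le <- log(measure$epsilon)
  vapply(as.numeric(q), function(qi) {
    if (abs(qi - 1) < 1e-9) {
      sum(measure$p * lp) / le
    } else {
      x <- qi * lp
      m <- max(x)
      (m + log(sum(exp(x - m)))) / ((qi - 1) * le)
    }
  }, numeric(1))
}

#' Multifractal spectrum on an integer q grid
#'
#' Evaluates [generalized_dimension()] on the grid `-q_max .. q_max`
#' (default 10). The q = 1 information-dimension branch is checked for
#' continuity against `q = 1 +/- 1e-6`; the largest gap is stored in the
#' `continuity_gap` attribute.
#'
#' @param measure a `box_measure`.
#' @param q_max highest dimension order `L` of the grid (positive integer).
#' @return Tibble of class `mf_spectrum` with columns `q`, `d_q`;
#'   attributes `q_max`, `epsilon`, `s_mm`, `continuity_gap`.
#' @export
mf_spectrum <- function(measure, q_max = 10) {
  if (!is_count(q_max)) stop_input("'q_max' must be a positive integer")
  q <- seq.int(-q_max, q_max)
  d_q <- generalized_dimension(measure, q)
  d1 <- d_q[q == 1]
  gap <- max(abs(generalized_dimension(measure, c(1 - 1e-6, 1 + 1e-6)) - d1))
  new_tibble(list(q = as.integer(q), d_q = d_q), class = "mf_spectrum",
             q_max = as.integer(q_max), epsilon = measure$epsilon,
             s_mm = measure$s_mm, continuity_gap = gap)
}

#' Averaged multifractal index between two studies
#'
#' Mean of `D_q(a) - D_q(b)` over the shared integer grid `-L .. L`
#' (2L + 1 points), summarizing the shift of the whole spectrum between
#' two serial studies in one scalar. By convention positive values are
#' read as improvement and negative values as deterioration. The index is
#' antisymmetric in its arguments and additive along study chains
#' (early + late = final).
#'
#' @param spec_a,spec_b `mf_spectrum` objects on identical q grids
#'   (study a = earlier, study b = later).
#' @param stage_label `"early"` (I to II), `"late"` (II to III) or
#'   `"final"` (I to III).
#' @return An `mf_index` with fields `value`, `stage_label`, `q_max`.
#' @export
average_mf_index <- function(spec_a, spec_b,
                             stage_label = c("early", "late", "final")) {
  stage_label <- match.arg(stage_label)
  if (!all(c("q", "d_q") %in% names(spec_a)) || !all(c("q", "d_q") %in% names(spec_b)))
    stop_input("spectra need columns q and d_q")
  if (length(spec_a$q) != length(spec_b$q) || any(spec_a$q != spec_b$q))
    stop_input("mismatched q grids between spectra")
  structure(list(value = mean(spec_a$d_q - spec_b$d_q),
                 stage_label = stage_label,
                 q_max = max(spec_a$q)),
            class = "mf_index")
}

#' @export
print.mf_index <- function(x, ...) {
  cat("<mf_index> D_MF(", x$stage_label, ") = ",
      sprintf("%+.4f", x$value), " (L = ", x$q_max, ")\n", sep = "")
  invisible(x)
}

#' @export
as.double.mf_index <- function(x, ...) x$value
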