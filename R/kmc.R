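#' Default 18-of-27 generator pattern
#'
#' The deterministic fractal vascular lattice is built by recursive 3x3x3
#' refinement, keeping a fixed subset of the 27 subcells at every level.
#' The default motif keeps 18 of 27 cells — all except the 8 corners and
#' the center — a symmetric, face-connected choice whose limit set has
#' dimension `log3(18) ~= 2.6309`, in the 2.6–2.7 range reported for
#' vascular trees.
#'
#' @return Integer matrix (18 x 3) of 0-based subcell offsets in {0,1,2}.
#' @export
default_pattern <- function() {
  g <- as.matrix(expand.grid(x = 0:2, y = 0:2, z = 0:2))
  corners <- rowSums(g == 1) == 0
  center <- rowSums(g == 1) == 3
  out <- g[!(corners | center), , drop = FALSE]
  dimnames(out) <- NULL
  storage.mode(out) <- "integer"
  out
}

#' Build the deterministic fractal vascular network
#'
#' At each refinement level every retained cell is split 3x3x3 and only the
#' pattern subcells survive, so after `k` iterations the lattice has edge
#' `3^k` and exactly `|pattern|^k` network sites. Site coordinates are
#' 0-based lattice positions in `[0, 3^k)^3`.
#'
#' @param iterations generator depth `k >= 1`.
#' @param pattern integer matrix (m x 3) of subcell offsets in {0,1,2};
#'   default [default_pattern()] (m = 18).
#' @return A `vascular_network` with fields `lattice_edge`, `iterations`,
#'   `pattern`, `sites` (n x 3 integer matrix) and `dimension`
#'   (`log3 |pattern|`).
#' @examples
#' net <- build_network(2)
#' nrow(net$sites)  # 18^2 = 324
#' @export
build_network <- function(iterations, pattern = default_pattern()) {
  if (!is_count(iterations)) stop_input("'iterations' must be a positive integer")
  pattern <- as.matrix(pattern)
  storage.mode(pattern) <- "integer"
  if (nrow(pattern) < 1L || ncol(pattern) != 3L)
    stop_input("'pattern' must be a non-empty m x 3 matrix")
  if (any(pattern < 0L | pattern > 2L)) stop_input("pattern offsets must lie in {0,1,2}")
  if (anyDuplicated(pattern)) stop_input("duplicate pattern offsets")

  sites <- matrix(0L, 1, 3)
  for (i in seq_len(iterations)) {
    n <- nrow(sites); m <- nrow(pattern)
    sites <- sites[rep(seq_len(n), each = m), , drop = FALSE] * 3L +
      pattern[rep(seq_len(m), times = n), , drop = FALSE]
  }
  structure(list(lattice_edge = 3L^as.integer(iterations),
                 iterations = as.integer(iterations),
                 pattern = pattern,
                 sites = sites,
                 dimension = log(nrow(pattern)) / log(3)),
            class = "vascular_network")
}

#' @export
print.vascular_network <- function(x, ...) {
  cat("<vascular_network> ", x$lattice_edge, "^3 lattice, ",
      nrow(x$pattern), "-of-27 generator, depth ", x$iterations, ": ",
      nrow(x$sites), " sites (dimension ", signif(x$dimension, 5), ")\n", sep = "")
  invisible(x)
}

network_linear_idx <- function(network) {
  L <- network$lattice_edge
  network$sites[, 1] + L * (network$sites[, 2] + L * network$sites[, 3])
}

#' Occupancy mask of a site set on the simulation lattice
#'
#' @param sites integer matrix (n x 3) of 0-based lattice coordinates.
#' @param lattice_edge lattice linear size.
#' @return A [lesion_mask()] with unit spacing (lattice units).
#' @export
sites_to_mask <- function(sites, lattice_edge) {
  occ <- array(FALSE, rep(lattice_edge, 3))
  if (nrow(sites) > 0)
    occ[sites[, 1] + 1L + lattice_edge * (sites[, 2] + lattice_edge * sites[, 3])] <- TRUE
  lesion_mask(occ, 1)
}

#' Kinetic Monte Carlo configuration
#'
#' Defaults reproduce the reference study conditions: an 81^3 body, 10
#' malignant cells, per-step colonization probability 0.001, and a run of
#' `T = 100 * L^3` elementary steps per walker. One sweep moves every
#' walker once; `t_total` counts sweeps (= per-walker steps), and the
#' reported time axis is rescaled to `t = sweeps / L^3`, so the default
#' run spans t = 0..100.
#'
#' @param lattice_edge body linear size `L` (sites per axis), a power of 3.
#' @param n_walkers number of diffusing malignant cells `n`.
#' @param p_infect per-step colonization probability `p` in [0, 1].
#' @param t_total per-walker elementary steps `T` (default `100 * L^3`).
#' @param record_every sampling stride in sweeps; default gives ~200
#'   samples.
#' @param seed integer RNG seed (xoshiro256++; bit-reproducible).
#' @param myopic use the myopic-ant walk (uniform over accessible
#'   neighbors) instead of the default blind ant.
#' @return A `kmc_config`.
#' @export
kmc_config <- function(lattice_edge = 81, n_walkers = 10, p_infect = 0.001,
                       t_total = 100 * lattice_edge^3, record_every = NULL,
                       seed = 1L, myopic = FALSE) {
  if (!is_count(lattice_edge)) stop_input("'lattice_edge' must be a positive integer")
  k <- round(log(lattice_edge) / log(3))
  if (3^k != lattice_edge) stop_input("'lattice_edge' must be a power of 3")
  if (!is_count(n_walkers)) stop_input("'n_walkers' must be >= 1")
  if (!(length(p_infect) == 1L && p_infect >= 0 && p_infect <= 1))
    stop_input("'p_infect' must lie in [0, 1]")
  if (!(length(t_total) == 1L && t_total >= 1 && t_total == round(t_total)))
    stop_input("'t_total' must be a positive integer number of sweeps")
  if (is.null(record_every)) record_every <- max(1, floor(t_total / 200))
  if (!is_count(record_every)) stop_input("'record_every' must be a positive integer")
  structure(list(lattice_edge = as.integer(lattice_edge),
                 iterations = as.integer(k),
                 n_walkers = as.integer(n_walkers),
                 p_infect = p_infect,
                 t_total = t_total,
                 record_every = record_every,
                 seed = as.integer(seed),
                 myopic = isTRUE(myopic)),
            class = "kmc_config")
}

#' Simulate metastatic spread on the vascular lattice
#'
#' Walkers start at uniformly sampled network sites and perform independent
#' blind-ant random walks confined to the network (a step onto a
#' non-network or out-of-bounds site is rejected and the step is spent).
#' After each elementary step, with probability `p_infect` one uniformly
#' chosen not-yet-infected non-network 6-neighbor of the walker's site
#' becomes infected; if no such neighbor exists the event lapses.
#' Reinfection of a site is not possible, so `N_m(t)` is non-decreasing
#' and saturates at the number of tissue sites adjacent to the network.
#'
#' @param config a [kmc_config()].
#' @param network a [build_network()] result with matching lattice edge.
#' @param snapshot_at optional sweep times at which to snapshot the
#'   infected set (used by [dimension_vs_time()]).
#' @return A `kmc_result`: `series` (tibble `sweep`, `t`, `n_m`, class
#'   `kmc_series`), `infected` (0-based n x 3 site matrix), `walkers` and
#'   `walker_starts` (0-based linear indices), `snapshots`, and the config.
#' @export
simulate_kmc <- function(config, network, snapshot_at = numeric(0)) {
  stopifnot(inherits(config, "kmc_config"), inherits(network, "vascular_network"))
  if (network$lattice_edge != config$lattice_edge)
    stop_input("network lattice edge (", network$lattice_edge,
               ") does not match config (", config$lattice_edge, ")")
  snapshot_at <- sort(unique(as.numeric(snapshot_at)))
  if (length(snapshot_at) && max(snapshot_at) > config$t_total)
    stop_input("snapshot times must be <= t_total")
  res <- kmc_run_cpp(config$lattice_edge, network_linear_idx(network),
                     config$n_walkers, config$p_infect, config$t_total,
                     config$record_every, config$seed, snapshot_at,
                     config$myopic)
  L <- config$lattice_edge
  series <- new_tibble(
    list(sweep = res$t_sweep,
         t = res$t_sweep / L^3,
         n_m = res$n_m),
    class = "kmc_series", lattice_edge = L)
  infected <- linear_to_coords(res$infected, L)
  snaps <- lapply(res$snapshots, linear_to_coords, L = L)
  names(snaps) <- as.character(snapshot_at)
  structure(list(series = series,
                 infected = infected,
                 walkers = res$walkers,
                 walker_starts = res$walker_starts,
                 walkers_on_network = res$walkers_on_network,
                 snapshots = snaps,
                 snapshot_at = snapshot_at,
                 config = config,
                 network_dimension = network$dimension),
            class = "kmc_result")
}

linear_to_coords <- function(idx, L) {
  cbind(x = idx %% L, y = (idx %/% L) %% L, z = idx %/% (L * L))
}

#' @export
print.kmc_result <- function(x, ...) {
  cat("<kmc_result> L = ", x$config$lattice_edge, ", n = ", x$config$n_walkers,
      ", p = ", x$config$p_infect, ", T = ", format(x$config$t_total, big.mark = ","),
      " sweeps, seed ", x$config$seed, "\n  final N_m = ", nrow(x$infected), "\n", sep = "")
  invisible(x)
}

#' Box-count the final lesion distribution of a simulation
#'
#' Applies the same box-counting machinery used for scan volumes to the
#' infected-site set, with the voxel edge equal to one lattice unit and the
#' size ladder `s = 1..20` by default.
#'
#' @param result a `kmc_result` with a non-empty infected set.
#' @param sizes box edges in lattice units (default `1:20`).
#' @return List with `curve` (`box_count_curve`) and `fit` (`fractal_fit`).
#' @export
boxcount_lesions <- function(result, sizes = 1:20) {
  stopifnot(inherits(result, "kmc_result"))
  if (nrow(result$infected) == 0L)
    stop_numeric("empty infected set: no lesions to box-count")
  mask <- sites_to_mask(result$infected, result$config$lattice_edge)
  curve <- box_count(mask, sizes)
  list(curve = curve, fit = fit_fractal_dimension(curve))
}

#' Lesion-set dimension as a function of simulation time
#'
#' Runs one simulation, snapshots the infected set at each checkpoint, and
#' fits the box-counting dimension of every snapshot. Checkpoints falling
#' before the first infection (or with fewer than 2 infected sites, where a
#' log-log fit is meaningless) are flagged undefined rather than fitted.
#'
#' @param config a [kmc_config()].
#' @param network matching `vascular_network`.
#' @param checkpoints sweep times (<= `t_total`) at which to evaluate.
#' @param sizes box-size ladder in lattice units.
#' @return Tibble with columns `sweep`, `t`, `n_m`, `d_f`, `defined`.
#' @export
dimension_vs_time <- function(config, network, checkpoints, sizes = 1:20) {
  res <- simulate_kmc(config, network, snapshot_at = checkpoints)
  dimension_trajectory(res, sizes)
}

#' @rdname dimension_vs_time
#' @param result a `kmc_result` carrying snapshots.
#' @export
dimension_trajectory <- function(result, sizes = 1:20) {
  stopifnot(inherits(result, "kmc_result"))
  L <- result$config$lattice_edge
  rows <- lapply(seq_along(result$snapshots), function(i) {
    snap <- result$snapshots[[i]]
    sweep <- result$snapshot_at[i]
    if (nrow(snap) < 2L)
      return(tibble(sweep = sweep, t = sweep / L^3, n_m = nrow(snap),
                    d_f = NA_real_, defined = FALSE))
    fit <- fit_fractal_dimension(box_count(sites_to_mask(snap, L), sizes))
    tibble(sweep = sweep, t = sweep / L^3, n_m = nrow(snap),
           d_f = fit$d_f, defined = TRUE)
  })
  dplyr::bind_rows(rows)
}

#' Fit the lesion growth law
#'
#' Nonlinear least squares of `N_m(t) = A * t^alpha * exp(-beta * t)` on
#' the recorded series, using the rescaled time axis (`t = sweeps / L^3`,
#' spanning 0..100 for the default run). The power law captures the
#' fractal growth regime; the exponential factor the levelling-off as the
#' tissue adjacent to the network saturates. Initial guesses come from OLS
#' of `ln N_m` on `ln t` with `beta0 = 0`; `beta` is unconstrained in
#' sign. On non-convergence the fit is restarted over a deterministic
#' ladder of `beta` starting values before failing with diagnostics.
#'
#' @param series a `kmc_series` tibble (or data frame with columns `t`,
#'   `n_m`); samples with `t = 0` or `n_m = 0` are dropped, and at least 5
#'   positive samples are required.
#' @return A `growth_fit` with fields `A`, `alpha`, `beta`, `correlation`
#'   (Pearson r between observed and fitted) and the underlying `nls`
#'   model. Supports [tidy()] / [glance()].
#' @export
fit_growth <- function(series) {
  if (!all(c("t", "n_m") %in% names(series)))
    stop_input("'series' needs columns t and n_m")
  d <- data.frame(t = as.numeric(series$t), n_m = as.numeric(series$n_m))
  d <- d[d$t > 0 & d$n_m > 0, ]
  if (nrow(d) < 5L) stop_input("need >= 5 samples with t > 0 and N_m > 0")

  if (sd(d$n_m) == 0) {
    # constant series: the growth law degenerates to N_m = A
    return(structure(list(A = d$n_m[1], alpha = 0, beta = 0,
                          correlation = NA_real_, n_obs = nrow(d),
                          model = NULL, data = d),
                     class = "growth_fit"))
  }
  ols <- lm(log(n_m) ~ log(t), data = d)
  start <- list(A = exp(unname(coef(ols)[1])),
                alpha = unname(coef(ols)[2]),
                beta = 0)
  # deterministic restart ladder over beta starting values
  attempts <- lapply(c(0, 0.01, -0.01, 0.001, -0.001, 0.005),
                     function(b) list(A = start$A, alpha = start$alpha, beta = b))
  fit <- NULL; errs <- character(0)
  for (st in attempts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(n_m ~ A * t^alpha * exp(-beta * t), data = d,
                        start = st,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) { errs <<- c(errs, conditionMessage(e)); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    stop_numeric("growth-law fit failed to converge after restarts: ",
                 paste(unique(errs), collapse = "; "))
  cf <- coef(fit)
  obs <- d$n_m; pred <- fitted(fit)
  correlation <- if (sd(obs) == 0 || sd(pred) == 0) NA_real_ else cor(obs, pred)
  structure(list(A = unname(cf["A"]), alpha = unname(cf["alpha"]),
                 beta = unname(cf["beta"]), correlation = correlation,
                 n_obs = nrow(d), model = fit, data = d),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat("<growth_fit> N_m(t) = A t^alpha exp(-beta t)\n",
      "  A = ", signif(x$A, 5), ", alpha = ", signif(x$alpha, 5),
      ", beta = ", signif(x$beta, 5),
      ", corr(obs, fit) = ", signif(x$correlation, 6), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.growth_fit <- function(x, ...) {
  tibble(term = c("A", "alpha", "beta"),
         estimate = c(x$A, x$alpha, x$beta))
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble(A = x$A, alpha = x$alpha, beta = x$beta,
         correlation = x$correlation, n_obs = x$n_obs)
}
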