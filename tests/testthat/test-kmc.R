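test_that("the iterative generator produces |pattern|^k sites", {
  expect_equal(nrow(build_network(1)$sites), 18L)
  expect_equal(nrow(build_network(4)$sites), 18L^4)

  full <- build_network(2, as.matrix(expand.grid(0:2, 0:2, 0:2)))
  expect_equal(nrow(full$sites), 729L)
  expect_true(all(sites_to_mask(full$sites, 9)$occupancy))  # space-filling limit

  net <- build_network(2)
  expect_true(all(net$sites >= 0 & net$sites < 9))
  expect_equal(anyDuplicated(net$sites), 0L)
  expect_equal(net$dimension, log(18) / log(3))

  expect_error(build_network(2, matrix(integer(0), 0, 3)), class = "fm_input_error")
  expect_error(build_network(0), class = "fm_input_error")
})

test_that("walkers stay on the network and infections stay off it", {
  net <- build_network(3)
  cfg <- kmc_config(lattice_edge = 27, p_infect = 0.05, t_total = 2000, seed = 3)
  res <- simulate_kmc(cfg, net)
  expect_true(res$walkers_on_network)

  L <- 27
  net_occ <- sites_to_mask(net$sites, L)$occupancy
  inf_occ <- sites_to_mask(res$infected, L)$occupancy
  # no infected site on the network
  expect_false(any(inf_occ & net_occ))
  # every infected site touches the network via a face
  neighbor_of_net <- array(FALSE, dim(net_occ))
  for (ax in 1:3) for (d in c(-1, 1)) {
    idx <- which(net_occ, arr.ind = TRUE)
    idx[, ax] <- idx[, ax] + d
    idx <- idx[idx[, ax] >= 1 & idx[, ax] <= L, , drop = FALSE]
    neighbor_of_net[idx] <- TRUE
  }
  expect_true(all(neighbor_of_net[inf_occ]))
  # walkers start and finish on network sites
  expect_true(all(res$walker_starts %in%
                    (net$sites[, 1] + L * (net$sites[, 2] + L * net$sites[, 3]))))
})

test_that("infection probability limits behave as contracted", {
  net <- build_network(2)
  none <- simulate_kmc(kmc_config(lattice_edge = 9, p_infect = 0,
                                  t_total = 500, seed = 1), net)
  expect_equal(nrow(none$infected), 0L)
  expect_true(all(none$series$n_m == 0))

  sure <- simulate_kmc(kmc_config(lattice_edge = 9, n_walkers = 1, p_infect = 1,
                                  t_total = 1, seed = 2), net)
  expect_gte(nrow(sure$infected), 1L)
})

test_that("simulations are bit-reproducible for a fixed seed", {
  net <- build_network(2)
  cfg <- kmc_config(lattice_edge = 9, p_infect = 0.01, t_total = 3000, seed = 99)
  a <- simulate_kmc(cfg, net); b <- simulate_kmc(cfg, net)
  expect_identical(a$series$n_m, b$series$n_m)
  expect_identical(a$infected, b$infected)
  expect_identical(a$walkers, b$walkers)
  c <- simulate_kmc(kmc_config(lattice_edge = 9, p_infect = 0.01,
                               t_total = 3000, seed = 100), net)
  expect_false(identical(a$infected, c$infected))
})

test_that("N_m is non-decreasing and bounded by the tissue shell", {
  net <- build_network(3); L <- 27
  res <- simulate_kmc(kmc_config(lattice_edge = L, p_infect = 0.05,
                                 t_total = 20000, seed = 5), net)
  expect_true(all(diff(res$series$n_m) >= 0))

  net_occ <- sites_to_mask(net$sites, L)$occupancy
  shell <- array(FALSE, dim(net_occ))
  for (ax in 1:3) for (d in c(-1, 1)) {
    idx <- which(net_occ, arr.ind = TRUE)
    idx[, ax] <- idx[, ax] + d
    idx <- idx[idx[, ax] >= 1 & idx[, ax] <= L, , drop = FALSE]
    shell[idx] <- TRUE
  }
  shell <- shell & !net_occ
  expect_lte(nrow(res$infected), sum(shell))
})

test_that("mean-squared displacement grows with run length", {
  net <- build_network(3)
  msd <- function(t_total) {
    res <- simulate_kmc(kmc_config(lattice_edge = 27, n_walkers = 200,
                                   p_infect = 0, t_total = t_total, seed = 17), net)
    L <- 27
    to_xyz <- function(idx) cbind(idx %% L, (idx %/% L) %% L, idx %/% (L * L))
    mean(rowSums((to_xyz(res$walkers) - to_xyz(res$walker_starts))^2))
  }
  expect_gt(msd(2000), msd(50))
})

test_that("lesion box counting matches the oracle and the limits", {
  net <- build_network(3); L <- 27
  # infected set = the network itself: nested-count oracle applies
  res <- simulate_kmc(kmc_config(lattice_edge = L, p_infect = 0.02,
                                 t_total = 5000, seed = 11), net)
  fake <- res; fake$infected <- net$sites
  f <- boxcount_lesions(fake, sizes = c(1, 3, 9))
  expect_equal(f$curve$n, generator_counts(18, 3, 0:2))
  expect_equal(f$fit$d_f, log(18) / log(3), tolerance = 1e-9)

  # brute-force equivalence on the real infected set
  occ <- sites_to_mask(res$infected, L)$occupancy
  bc <- boxcount_lesions(res, sizes = 1:10)
  for (i in seq_len(10))
    expect_equal(bc$curve$n[i], brute_box_count(occ, i))

  # degenerate limits
  fake$infected <- cbind(3L, 5L, 7L)
  expect_equal(boxcount_lesions(fake, sizes = c(1, 2, 3))$fit$d_f, 0)
  fake$infected <- fake$infected[0, , drop = FALSE]
  expect_error(boxcount_lesions(fake), "empty", class = "fm_numeric_error")

  full <- res; full$infected <- as.matrix(expand.grid(0:(L - 1), 0:(L - 1), 0:(L - 1)))
  expect_equal(boxcount_lesions(full, sizes = c(1, 3, 9))$fit$d_f, 3, tolerance = 0.05)
})

test_that("the lesion dimension grows towards the network dimension", {
  net <- build_network(3); L <- 27
  cfg_t <- 10 * L^3
  checkpoints <- round(seq(cfg_t / 5, cfg_t, length.out = 5))
  trajs <- lapply(1:5, function(seed)
    dimension_vs_time(kmc_config(lattice_edge = L, t_total = cfg_t, seed = seed),
                      net, checkpoints, sizes = 1:9))
  d <- sapply(trajs, function(tr) tr$d_f)     # checkpoints x seeds
  med <- apply(d, 1, stats::median)
  expect_true(all(diff(med) >= -1e-9))
  expect_gt(med[5], 2)  # well on its way to ~2.6 by the end of a short run

  # checkpoints before the first infection are flagged, not fitted
  tr0 <- dimension_vs_time(kmc_config(lattice_edge = L, p_infect = 0,
                                      t_total = 100, seed = 1), net, c(50, 100))
  expect_true(all(!tr0$defined))
  expect_true(all(is.na(tr0$d_f)))
})

test_that("growth-law fits recover known parameters exactly on clean data", {
  t <- 1:100
  n_m <- 5 * t^0.8 * exp(-0.005 * t)
  fit <- fit_growth(tibble::tibble(t = t, n_m = n_m))
  expect_equal(fit$A, 5, tolerance = 1e-6)
  expect_equal(fit$alpha, 0.8, tolerance = 1e-6)
  expect_equal(fit$beta, 0.005, tolerance = 1e-6)
  expect_equal(fit$correlation, 1, tolerance = 1e-9)

  const <- fit_growth(tibble::tibble(t = t, n_m = rep(7, 100)))
  expect_equal(const$alpha, 0, tolerance = 1e-6)
  expect_equal(const$beta, 0, tolerance = 1e-6)

  # negative beta (pure growth) is representable: the sign is unconstrained
  n_m2 <- 2 * t^0.5 * exp(0.004 * t)
  expect_equal(fit_growth(tibble::tibble(t = t, n_m = n_m2))$beta, -0.004,
               tolerance = 1e-6)

  expect_error(fit_growth(tibble::tibble(t = 1:4, n_m = 1:4)), ">= 5",
               class = "fm_input_error")
})

test_that("growth exponent survives multiplicative measurement noise", {
  alphas <- withr::with_seed(55, {
    vapply(1:20, function(i) {
      t <- 1:100
      n_m <- 40 * t^0.8 * exp(-0.01 * t) * (1 + rnorm(100, 0, 0.02))
      fit_growth(tibble::tibble(t = t, n_m = n_m))$alpha
    }, numeric(1))
  })
  expect_lt(stats::median(abs(alphas - 0.8)), 0.05)
})

test_that("config validation rejects inconsistent setups", {
  expect_error(kmc_config(lattice_edge = 80), "power of 3", class = "fm_input_error")
  expect_error(kmc_config(p_infect = 1.5), class = "fm_input_error")
  expect_error(simulate_kmc(kmc_config(lattice_edge = 9, t_total = 10),
                            build_network(3)),
               "does not match", class = "fm_input_error")
  cfg <- kmc_config(lattice_edge = 9, t_total = 10)
  expect_error(simulate_kmc(cfg, build_network(2), snapshot_at = 20),
               class = "fm_input_error")
})

test_that("growth fits expose tidy()/glance() and series plot", {
  net <- build_network(2)
  res <- simulate_kmc(kmc_config(lattice_edge = 9, p_infect = 0.02,
                                 t_total = 4000, seed = 12), net)
  fit <- fit_growth(res$series)
  expect_equal(tidy(fit)$term, c("A", "alpha", "beta"))
  expect_true(abs(glance(fit)$correlation) <= 1)
  expect_s3_class(ggplot2::autoplot(res$series, fit = fit), "ggplot")
})
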