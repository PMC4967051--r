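test_that("NIfTI round trip preserves dims, intensities and spacing", {
  arr <- array(runif(4 * 4 * 4), c(4, 4, 4))
  vol <- scan_volume(arr, c(2.03642, 2.03642, 4))
  path <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_equal(back$dims, c(4L, 4L, 4L))
  expect_equal(back$intensities, arr, tolerance = 1e-6, ignore_attr = TRUE)
  # spacing stored as float32 in the header; preserved to that precision
  expect_equal(back$spacing, c(2.03642, 2.03642, 4), tolerance = 1e-6)
})

test_that("negative intensities are clipped to zero with a warning", {
  arr <- array(1, c(3, 3, 3)); arr[2, 2, 2] <- -5
  expect_warning(vol <- scan_volume(arr, c(1, 1, 1)), "clipped")
  expect_equal(vol$intensities[2, 2, 2], 0)
  expect_true(all(vol$intensities >= 0))
})

test_that("read_volume errors name the offending path", {
  expect_error(read_volume("/nonexistent/vol.nii"), "/nonexistent/vol.nii",
               class = "fm_input_error")
  bad <- withr::local_tempfile(fileext = ".nii")
  writeLines("not a nifti", bad)
  expect_error(suppressWarnings(read_volume(bad)), class = "fm_input_error")
})

test_that("regridding block-sums intensities onto the isotropic lattice", {
  vol <- scan_volume(array(1, c(4, 4, 2)), c(2, 2, 4))
  out <- regrid_isotropic(vol, 4)
  expect_equal(out$dims, c(2L, 2L, 2L))
  expect_equal(out$spacing, c(4, 4, 4))
  expect_true(all(out$intensities == 4))

  zero <- regrid_isotropic(scan_volume(array(0, c(4, 4, 2)), c(2, 2, 4)), 4)
  expect_true(all(zero$intensities == 0))
})

test_that("regridding conserves total intensity", {
  withr::with_seed(11, {
    for (dims in list(c(8, 8, 4), c(6, 10, 3), c(7, 9, 5))) {
      arr <- array(runif(prod(dims)), dims)
      vol <- scan_volume(arr, c(2, 2, 4))
      out <- regrid_isotropic(vol, 4)
      # partial far-boundary blocks are kept, so conservation is exact even
      # when the block size does not divide the axis
      expect_equal(sum(out$intensities), sum(arr))
    }
  })
})

test_that("nominally commensurate spacing is accepted, others rejected", {
  # 2.03642 mm pixels aggregate 2x2x1 into a 4 mm cube (within 2%)
  vol <- scan_volume(array(1, c(4, 4, 2)), c(2.03642, 2.03642, 4))
  out <- regrid_isotropic(vol, 4)
  expect_equal(out$dims, c(2L, 2L, 2L))
  expect_error(regrid_isotropic(scan_volume(array(1, c(4, 4, 2)), c(1.7, 1.7, 4)), 4),
               "not commensurate", class = "fm_input_error")
})

test_that("binarize applies the threshold policy and records provenance", {
  arr <- array(0, c(4, 4, 4)); arr[2, 3, 1] <- 5
  vol <- scan_volume(arr, c(4, 4, 4))
  mask <- binarize(vol, threshold_policy("absolute", 0))
  expect_equal(sum(mask$occupancy), 1L)
  expect_equal(mask$policy$type, "absolute")

  uni <- scan_volume(array(7, c(3, 3, 3)), c(4, 4, 4))
  expect_equal(sum(binarize(uni, threshold_policy("relative", 0.5))$occupancy), 27L)

  expect_error(binarize(scan_volume(array(0, c(2, 2, 2)), c(4, 4, 4)),
                        threshold_policy("absolute", 10)),
               "empty mask", class = "fm_numeric_error")
  aniso <- scan_volume(array(1, c(4, 4, 4)), c(2, 2, 4))
  expect_error(binarize(aniso), "isotropic", class = "fm_input_error")
})

test_that("binarize is monotone in the threshold", {
  withr::with_seed(5, {
    arr <- array(runif(6^3), c(6, 6, 6))
    vol <- scan_volume(arr, c(4, 4, 4))
    counts <- vapply(seq(0, 0.9, by = 0.1), function(tau)
      sum(binarize(vol, threshold_policy("relative", tau))$occupancy), 0L)
    expect_true(all(diff(counts) <= 0))
  })
})

test_that("phantoms are deterministic and honour their spec", {
  lesions <- rbind(c(2, 2, 2), c(5, 8, 3), c(9, 9, 9))
  sp <- phantom_spec(c(40, 40, 40), spacing = c(4, 4, 4), lesions = lesions,
                     noise_level = 0.3, seed = 42)
  v1 <- generate_phantom(sp); v2 <- generate_phantom(sp)
  expect_identical(v1$intensities, v2$intensities)

  empty <- generate_phantom(phantom_spec(c(20, 20, 20), spacing = c(4, 4, 4)))
  expect_true(all(empty$intensities == 0))

  # lesion voxels sit above the noise floor; nothing else does
  noiseless <- phantom_spec(c(40, 40, 40), spacing = c(4, 4, 4),
                            lesions = lesions, noise_level = 0, seed = 1)
  mask <- binarize(generate_phantom(noiseless), threshold_policy("absolute", 0))
  expect_equal(sum(mask$occupancy), nrow(lesions))

  expect_error(phantom_spec(c(10, 10, 10), spacing = c(4, 4, 4),
                            lesions = rbind(c(50, 1, 1))),
               "outside", class = "fm_input_error")
  expect_error(phantom_spec(c(10, 10, 10),
                            blobs = list(list(center = c(9, 5, 5), radius = 3, peak = 1))),
               "outside", class = "fm_input_error")
})

test_that("blob phantoms render smooth compact bright regions", {
  sp <- phantom_spec(c(40, 40, 40), spacing = c(2, 2, 2),
                     blobs = list(list(center = c(20, 20, 20), radius = 10, peak = 8)))
  vol <- generate_phantom(sp)
  expect_equal(max(vol$intensities), 8, tolerance = 0.05)
  # compact support: intensity vanishes away from the blob
  expect_equal(vol$intensities[1, 1, 1], 0)
  expect_gt(sum(vol$intensities > 0), 100)
})

test_that("phantom specs survive a YAML round trip", {
  sp <- phantom_spec(c(40, 40, 40), spacing = c(4, 4, 4),
                     blobs = list(list(center = c(20, 20, 20), radius = 8, peak = 5)),
                     lesions = rbind(c(1, 2, 3)), noise_level = 0.1, seed = 9)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_phantom_spec(sp, path)
  back <- read_phantom_spec(path)
  expect_identical(generate_phantom(back)$intensities,
                   generate_phantom(sp)$intensities)
})
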