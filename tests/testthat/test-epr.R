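test_that("a point object gives flat k-space magnitude at every delay", {
  ph <- make_tumor_phantom(c(9, 9, 9), "uniform", seed = 1)
  # single nonzero voxel at the acquisition-grid centre
  ph$spin_density[] <- 0
  ph$spin_density[5, 5, 5] <- 1
  ph$body_mask[] <- TRUE
  acq <- epr_acquisition(grid = c(9, 9, 9), zerofill = 9, tukey_r = 0,
                         delays = c(0.5, 1.5))
  ks <- simulate_spi(ph, acq, seed = 1, snr_scale = 0)
  for (k in ks$kspace) {
    expect_lt(diff(range(Mod(k))) / mean(Mod(k)), 1e-10)
  }
})

test_that("k-space centre decays as exp(-tp R2*) for a uniform phantom", {
  ph <- make_tumor_phantom(c(12, 12, 12), "uniform", seed = 1,
                           overrides = list(po2 = 10))
  calib <- oximetry_calibration()
  tp <- 0.7
  acq <- epr_acquisition(grid = c(15, 15, 15), zerofill = 15, tukey_r = 0,
                         delays = c(tp, 2 * tp))
  ctr <- floor(acq$grid / 2) + 1
  r2 <- calib$r2star_anoxic + calib$slope * 10
  # restrict support to the tumor so a single R2* governs the decay
  ph$spin_density[!ph$tumor_mask] <- 0
  ph$body_mask <- ph$tumor_mask
  ks <- simulate_spi(ph, acq, calib, seed = 1, snr_scale = 0)
  k1 <- Mod(ks$kspace[[1]][ctr[1], ctr[2], ctr[3]])
  k2 <- Mod(ks$kspace[[2]][ctr[1], ctr[2], ctr[3]])
  expect_equal(k2 / k1, exp(-tp * r2), tolerance = 1e-10)
})

test_that("noiseless k-space of a real object is Hermitian about the DC sample", {
  ph <- default_rim_phantom(c(12, 12, 12))
  acq <- epr_acquisition(grid = c(15, 15, 15), zerofill = 16,
                         delays = c(0.5, 1.0))
  ks <- simulate_spi(ph, acq, seed = 1, snr_scale = 0)
  k <- ks$kspace[[1]]
  n <- dim(k)
  ctr <- floor(n / 2) + 1
  idx <- lapply(1:3, function(i) {
    j <- (2 * ctr[i] - seq_len(n[i])) %% n[i]
    j[j == 0] <- n[i]
    j
  })
  k_reflect <- k[idx[[1]], idx[[2]], idx[[3]]]
  expect_lt(max(Mod(k_reflect - Conj(k))), 1e-8 * max(Mod(k)))
})

test_that("reconstruction matches the brute-force direct inverse DFT on 5^3 grids", {
  set.seed(7)
  for (case in 1:2) {
    k <- array(complex(real = rnorm(125), imaginary = rnorm(125)),
               c(5, 5, 5))
    ks <- structure(list(kspace = list(k), delays = 1, grid = c(5L, 5L, 5L)),
                    class = "spi_kspace_series")
    tk <- if (case == 1) 0.7 else 0
    zf <- if (case == 1) 8 else 5
    acq <- epr_acquisition(grid = c(5, 5, 5), zerofill = zf, tukey_r = tk,
                           delays = c(0.5, 1))
    rec <- reconstruct_spi(ks, acq)
    oracle <- brute_force_recon(k, tk, zf)
    expect_lt(max(abs(rec$images[, , , 1] - oracle)) / max(oracle), 1e-10)
  }
})

test_that("impulse k-space reconstructs to a discrete impulse at the centre", {
  k <- array(1 + 0i, c(7, 7, 7))
  ks <- structure(list(kspace = list(k), delays = 1, grid = c(7L, 7L, 7L)),
                  class = "spi_kspace_series")
  acq <- epr_acquisition(grid = c(7, 7, 7), zerofill = 7, tukey_r = 0,
                         delays = c(0.5, 1))
  rec <- reconstruct_spi(ks, acq, dc_correct = FALSE)
  img <- rec$images[, , , 1]
  ctr <- floor(dim(img) / 2) + 1
  expect_equal(img[ctr[1], ctr[2], ctr[3]], 1, tolerance = 1e-12)
  img[ctr[1], ctr[2], ctr[3]] <- 0
  expect_lt(max(img), 1e-12)
})

test_that("reconstruction is linear in the k-space data", {
  set.seed(1)
  k <- array(complex(real = rnorm(125), imaginary = rnorm(125)), c(5, 5, 5))
  mk <- function(kk) structure(list(kspace = list(kk), delays = 1,
                                    grid = c(5L, 5L, 5L)),
                               class = "spi_kspace_series")
  acq <- epr_acquisition(grid = c(5, 5, 5), zerofill = 8, tukey_r = 0.5,
                         delays = c(0.5, 1))
  r1 <- reconstruct_spi(mk(k), acq)$images
  r2 <- reconstruct_spi(mk(3.7 * k), acq)$images
  expect_equal(r2, 3.7 * r1, tolerance = 1e-12)
})

test_that("zero-fill below the acquired grid is rejected", {
  ph <- default_rim_phantom(c(12, 12, 12))
  acq <- epr_acquisition(grid = c(15, 15, 15), zerofill = 15,
                         delays = c(0.5, 1))
  ks <- simulate_spi(ph, acq, seed = 1, snr_scale = 0)
  bad <- acq
  bad$zerofill <- c(8L, 8L, 8L)
  expect_error(reconstruct_spi(ks, bad), "zerofill")
  expect_error(epr_acquisition(zerofill = 10), "zerofill")
})

test_that("phase-cycled baseline offsets of any magnitude cancel exactly", {
  ph <- default_rim_phantom(c(12, 12, 12))
  acq <- epr_acquisition(grid = c(15, 15, 15), zerofill = 15, tukey_r = 0,
                         delays = c(0.5, 1.5))
  k0 <- simulate_spi(ph, acq, seed = 1, snr_scale = 0, dc_offset = 0)
  k1 <- simulate_spi(ph, acq, seed = 1, snr_scale = 0,
                     dc_offset = 1e4 + 5e3i)
  for (j in seq_along(k0$kspace)) {
    expect_lt(max(Mod(k1$kspace[[j]] - k0$kspace[[j]])),
              1e-7 * max(Mod(k0$kspace[[j]])))
  }
})

test_that("R2* fitting recovers two-point and flat closed forms", {
  img <- array(0, c(1, 1, 1, 2))
  img[1, 1, 1, ] <- c(1.0, 0.5)
  fit <- fit_r2star(img, delays = c(1, 2))
  expect_equal(fit$r2star[1, 1, 1], log(2), tolerance = 1e-12)
  img[1, 1, 1, ] <- c(0.8, 0.8)
  fit <- fit_r2star(img, delays = c(1, 2))
  expect_equal(fit$r2star[1, 1, 1], 0)
  # negative slope clamps to zero with the clamp flagged
  img[1, 1, 1, ] <- c(0.5, 1.0)
  fit <- fit_r2star(img, delays = c(1, 2))
  expect_equal(fit$r2star[1, 1, 1], 0)
  expect_true(fit$clamped[1, 1, 1])
  # non-positive intensities flag and exclude the voxel
  img[1, 1, 1, ] <- c(1, -0.1)
  fit <- fit_r2star(img, delays = c(1, 2))
  expect_true(fit$flag[1, 1, 1])
  expect_true(is.na(fit$r2star[1, 1, 1]))
})

test_that("pO2 conversion is the calibrated linear map with flooring", {
  calib <- oximetry_calibration(r2star_anoxic = 0.25, slope = 0.02)
  r2map <- structure(list(
    r2star = array(c(0.25, 0.25 + 10 * 0.02, 0.2), c(3, 1, 1)),
    r2 = array(1, c(3, 1, 1)), i0 = array(1, c(3, 1, 1)),
    flag = array(FALSE, c(3, 1, 1)), mask = array(TRUE, c(3, 1, 1))),
    class = "r2star_map")
  po2 <- r2star_to_po2(r2map, calib)
  expect_equal(po2$po2[1, 1, 1], 0)
  expect_equal(po2$po2[2, 1, 1], 10)
  expect_equal(po2$po2[3, 1, 1], 0)     # floored
  expect_true(po2$floored[3, 1, 1])
})

test_that("noiseless matched-grid round trip recovers R2* and pO2 exactly", {
  ph <- default_rim_phantom()
  acq <- epr_acquisition(zerofill = 19, tukey_r = 0)
  calib <- oximetry_calibration()
  ks <- simulate_spi(ph, acq, calib, seed = 1, snr_scale = 0)
  imgs <- reconstruct_spi(ks, acq, dc_correct = FALSE)
  emask <- qmriphantom:::embed_mask(ph$tumor_mask, imgs$grid, ks$offset,
                                    ks$grid)
  r2map <- fit_r2star(imgs, mask = emask)
  truth_r2 <- calib$r2star_anoxic + calib$slope * ph$po2[ph$tumor_mask]
  expect_lt(max(abs(r2map$r2star[emask] - truth_r2) / truth_r2), 1e-8)
  po2 <- r2star_to_po2(r2map, calib)
  expect_lt(sqrt(mean((po2$po2[emask] - ph$po2[ph$tumor_mask])^2)), 0.01)
})

test_that("the shell DC estimate removes uncancelled offsets and touches only the centre voxel", {
  ph <- default_rim_phantom()
  acq <- epr_acquisition(zerofill = 19, tukey_r = 0)
  ks <- simulate_spi(ph, acq, seed = 1, snr_scale = 0)
  # an uncancelled DC offset added directly to the recorded k-space
  ks_off <- ks
  ks_off$kspace <- lapply(ks$kspace, function(k) k + 0.8 * Mod(k[1, 1, 1]) +
                            max(Mod(k)) * 0.01)
  rec_ref <- reconstruct_spi(ks, acq, dc_correct = FALSE)$images
  rec_cor <- reconstruct_spi(ks_off, acq, dc_correct = TRUE)$images
  ctr <- floor(dim(rec_ref)[1:3] / 2) + 1
  diff <- abs(rec_cor - rec_ref)
  diff[ctr[1], ctr[2], ctr[3], ] <- 0   # a constant in k-space maps there
  expect_lt(max(diff), 1e-2 * max(rec_ref))
})

test_that("hypoxic fraction counts strictly-below voxels over the mask", {
  m <- array(TRUE, c(4, 1, 1))
  expect_equal(hypoxic_fraction(array(5, c(4, 1, 1)), mask = m), 100)
  expect_equal(hypoxic_fraction(array(c(5, 5, 20, 20), c(4, 1, 1)),
                                mask = m), 50)
  expect_equal(hypoxic_fraction(array(10, c(4, 1, 1)), mask = m), 0)
  ph <- default_rim_phantom()
  # brute-force independent scan
  cnt <- 0; tot <- 0
  for (i in seq_len(ph$shape[1])) for (j in seq_len(ph$shape[2]))
    for (k in seq_len(ph$shape[3])) {
      if (ph$tumor_mask[i, j, k]) {
        tot <- tot + 1
        if (ph$po2[i, j, k] < 10) cnt <- cnt + 1
      }
    }
  expect_equal(hypoxic_fraction(ph$po2, mask = ph$tumor_mask),
               100 * cnt / tot)
  expect_error(hypoxic_fraction(ph$po2, mask = array(FALSE, ph$shape)),
               "empty")
})

test_that("median pO2 uses the midpoint convention and matches a sort oracle", {
  m <- array(TRUE, c(4, 1, 1))
  expect_equal(median_po2(array(12, c(4, 1, 1)), mask = m), 12)
  expect_equal(median_po2(array(c(2, 4, 8, 100), c(4, 1, 1)), mask = m), 6)
  ph <- default_rim_phantom()
  v <- sort(ph$po2[ph$tumor_mask])
  n <- length(v)
  oracle <- if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  expect_equal(median_po2(ph$po2, mask = ph$tumor_mask), oracle)
})

test_that("HF10 is invariant to voxel reordering of the map", {
  ph <- default_rim_phantom()
  v <- ph$po2[ph$tumor_mask]
  set.seed(1)
  perm <- sample(length(v))
  arr <- array(v[perm], c(length(v), 1, 1))
  expect_equal(hypoxic_fraction(arr, mask = array(TRUE, dim(arr))),
               hypoxic_fraction(ph$po2, mask = ph$tumor_mask))
})

test_that("noiseless round-trip error shrinks as the window taper is released", {
  ph <- default_rim_phantom()
  calib <- oximetry_calibration()
  rmse_at <- function(r) {
    acq <- epr_acquisition(zerofill = 19, tukey_r = r)
    ks <- simulate_spi(ph, acq, calib, seed = 1, snr_scale = 0)
    imgs <- reconstruct_spi(ks, acq, dc_correct = FALSE)
    emask <- qmriphantom:::embed_mask(ph$tumor_mask, imgs$grid, ks$offset,
                                      ks$grid)
    po2 <- r2star_to_po2(fit_r2star(imgs, mask = emask), calib)
    ok <- emask & !po2$flag & !is.na(po2$po2)
    truth <- qmriphantom:::embed_centered(ph$po2, ks$grid)
    sqrt(mean((po2$po2[ok] - truth[ok])^2))
  }
  errs <- vapply(c(0.7, 0.3, 0), rmse_at, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01)
})

test_that("k-space containers round trip through the NIfTI/JSON persistence", {
  ph <- default_rim_phantom(c(12, 12, 12))
  acq <- epr_acquisition(grid = c(15, 15, 15), zerofill = 15,
                         delays = c(0.5, 1.0, 2.0))
  ks <- simulate_spi(ph, acq, seed = 6, snr_scale = 1)
  stem <- file.path(withr::local_tempdir(), "kspace")
  write_kspace(ks, stem)
  back <- read_kspace(stem)
  expect_equal(back$delays, ks$delays)
  for (j in seq_along(ks$kspace)) {
    expect_lt(max(Mod(back$kspace[[j]] - ks$kspace[[j]])),
              1e-6 * max(Mod(ks$kspace[[j]])))
  }
})
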