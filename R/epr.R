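# Pulsed-EPR single-point-imaging (SPI) oximetry. SPI is a pure
# phase-encoding acquisition: at each gradient step one FID sample is
# kept at a fixed delay tp after excitation, so the k-space image at
# delay tp is the spin density attenuated voxelwise by exp(-tp * R2*).
# R2* of the trityl probe grows linearly with local pO2, so a series of
# delays yields, after reconstruction and log-linear fitting, a
# pixelwise pO2 map.

#' EPR SPI acquisition protocol
#'
#' Defaults follow a 19 x 19 x 19 Cartesian phase-encode grid, 5 ns dwell
#' with 1000 sampled FID points, four phase cycles, 4000 signal averages,
#' Tukey window `r = 0.7`, and zero-filling to 64^3. Acquisition delays
#' default to 8 log-spaced values over 0.4-3.0 us, bracketing the decay
#' times produced by the default calibration.
#'
#' @param grid Phase-encode steps per axis.
#' @param delays Acquisition delays tp in us (strictly increasing, >= 2).
#' @param dwell Dwell time in ns (metadata).
#' @param n_points Sampled FID points (metadata).
#' @param phase_cycles Phase-cycling steps; DC offsets injected per cycle
#'   cancel exactly under the modelled cycling.
#' @param averages Signal averages; enters only through the noise level,
#'   which scales as `1/sqrt(averages)`.
#' @param zerofill Zero-filled matrix size per axis (>= grid).
#' @param tukey_r Tukey window taper fraction in `[0, 1]`.
#' @param noise_ref_snr Image-domain SNR at the shortest delay when
#'   `averages` equals `noise_ref_averages`.
#' @param noise_ref_averages Reference average count for `noise_ref_snr`.
#' @return A list of class `epr_acquisition`.
#' @export
epr_acquisition <- function(grid = c(19, 19, 19),
                            delays = exp(seq(log(0.4), log(3.0),
                                             length.out = 8)),
                            dwell = 5, n_points = 1000, phase_cycles = 4,
                            averages = 4000, zerofill = 64, tukey_r = 0.7,
                            noise_ref_snr = 50, noise_ref_averages = 4000) {
  if (length(delays) < 2 || any(diff(delays) <= 0)) {
    stop("delays must be >= 2 strictly increasing values")
  }
  if (tukey_r < 0 || tukey_r > 1) stop("tukey_r must lie in [0, 1]")
  if (length(grid) == 1) grid <- rep(grid, 3)
  if (length(zerofill) == 1) zerofill <- rep(zerofill, 3)
  if (any(zerofill < grid)) stop("zerofill must be at least the grid size")
  structure(list(grid = as.integer(grid), delays = delays, dwell = dwell,
                 n_points = as.integer(n_points),
                 phase_cycles = as.integer(phase_cycles),
                 averages = averages, zerofill = as.integer(zerofill),
                 tukey_r = tukey_r, noise_ref_snr = noise_ref_snr,
                 noise_ref_averages = noise_ref_averages),
            class = "epr_acquisition")
}

#' Oximetry calibration
#'
#' The probe's effective transverse rate is linear in oxygen:
#' `R2*(pO2) = r2star_anoxic + slope * pO2`. The constants are
#' instrument/probe properties; the defaults place the default phantom's
#' decay times inside the default delay window. The self-broadening guard
#' records that the probe concentration is assumed low enough for the
#' linear law to hold.
#'
#' @param r2star_anoxic R2* at zero oxygen, in 1/us.
#' @param slope Sensitivity in 1/us per mmHg.
#' @param max_probe_conc_flag Logical; `TRUE` asserts the low-probe
#'   concentration condition.
#' @return A list of class `oximetry_calibration`.
#' @export
oximetry_calibration <- function(r2star_anoxic = 0.25, slope = 0.02,
                                 max_probe_conc_flag = TRUE) {
  if (r2star_anoxic <= 0 || slope <= 0) {
    stop("calibration constants must be positive")
  }
  structure(list(r2star_anoxic = r2star_anoxic, slope = slope,
                 max_probe_conc_flag = max_probe_conc_flag),
            class = "oximetry_calibration")
}

# Embed a phantom-sized array centred in the acquisition grid.
embed_centered <- function(arr, grid) {
  d <- dim(arr)
  stopifnot(all(d <= grid))
  out <- array(0, grid)
  off <- floor((grid - d) / 2)
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), off[3] + seq_len(d[3])] <- arr
  out
}

# Index offset of embed_centered, for mapping phantom masks onto the
# acquisition grid.
embed_offset <- function(d, grid) floor((grid - d) / 2)

#' Forward-simulate an SPI k-space series
#'
#' For each delay tp, the effective object is
#' `rho(v) * exp(-tp * R2*(v))` with `R2*(v) = r2star_anoxic +
#' slope * pO2(v)`; its DFT over the phase-encode grid (DC at the array
#' centre) is the recorded k-space. Acquisition is modelled with
#' `phase_cycles`-step phase cycling: a constant complex baseline offset
#' injected into every cycle cancels exactly in the cycled combination.
#' Complex white Gaussian noise is added with SD proportional to
#' `1/sqrt(averages)`, calibrated so that image-domain SNR at the
#' shortest delay equals `noise_ref_snr` at the reference average count.
#'
#' @param phantom A [make_tumor_phantom()] result (shape <= acq grid).
#' @param acq An [epr_acquisition()].
#' @param calib An [oximetry_calibration()].
#' @param seed Integer seed; `NULL` or `snr_scale = 0` for noiseless.
#' @param dc_offset Complex baseline offset injected per phase cycle
#'   (cancelled by the cycling; kept as an explicit model knob).
#' @param snr_scale Multiplier on the noise SD (0 = noiseless).
#' @return A list of class `spi_kspace_series`: complex k-space arrays
#'   (one per delay, DC centred), delays, and the noise SD used.
#' @export
simulate_spi <- function(phantom, acq = epr_acquisition(),
                         calib = oximetry_calibration(), seed = 1,
                         dc_offset = 0, snr_scale = 1) {
  stopifnot(inherits(phantom, "tissue_parameter_map"))
  if (any(phantom$shape > acq$grid)) {
    stop("phantom does not fit inside the acquisition grid")
  }
  r2 <- calib$r2star_anoxic + calib$slope * phantom$po2   # 1/us
  rho <- embed_centered(phantom$spin_density, acq$grid)
  r2e <- embed_centered(r2, acq$grid)
  t2max <- 1 / min(r2e[rho > 0])
  if (max(acq$delays) > 5 * t2max) {
    warning("longest delay exceeds 5x the longest T2*; signal is below the noise floor")
  }
  # noise calibration: image-domain SNR at shortest delay
  s_img_max <- max(rho * exp(-min(acq$delays) * r2e))
  snr_eff <- acq$noise_ref_snr * sqrt(acq$averages / acq$noise_ref_averages)
  sd_k <- snr_scale * s_img_max * sqrt(prod(acq$grid)) / snr_eff
  if (!is.null(seed)) set.seed(derive_seed(seed, 1))
  nk <- prod(acq$grid)
  kspace <- lapply(acq$delays, function(tp) {
    obj <- rho * exp(-tp * r2e)
    # symmetric convention: object centre and DC both at floor(n/2)+1
    k_true <- fftshift(stats::fft(ifftshift(obj)))
    # phase cycling: cycle c advances the signal phase by 2*pi*c/P; the
    # injected baseline offset is common to all cycles and cancels in the
    # phase-corrected average.
    ph <- 2 * pi * (seq_len(acq$phase_cycles) - 1) / acq$phase_cycles
    acc <- array(0 + 0i, acq$grid)
    for (c in seq_along(ph)) {
      kc <- k_true * exp(1i * ph[c]) + dc_offset
      acc <- acc + kc * exp(-1i * ph[c])
    }
    k <- acc / acq$phase_cycles
    if (sd_k > 0) {
      k <- k + array(complex(real = stats::rnorm(nk, sd = sd_k),
                             imaginary = stats::rnorm(nk, sd = sd_k)),
                     acq$grid)
    }
    k
  })
  structure(list(kspace = kspace, delays = acq$delays, grid = acq$grid,
                 noise_sd = sd_k, phantom_shape = phantom$shape,
                 offset = embed_offset(phantom$shape, acq$grid)),
            class = "spi_kspace_series")
}

#' Reconstruct an SPI image series
#'
#' Per delay: estimate the DC shift as the mean of the outermost k-space
#' shell and subtract it, apply a separable Tukey window (taper `tukey_r`
#' per axis, defined on the original phase-encode extent), zero-fill
#' symmetrically about the DC sample to the target matrix, inverse-FFT,
#' and return the magnitude image. Image intensities are rescaled by the
#' zero-fill factor so they stay on the scale of the original object.
#'
#' @param kspace A [simulate_spi()] result (or list with `kspace`,
#'   `delays`, `grid`).
#' @param acq The [epr_acquisition()] supplying `tukey_r` and `zerofill`.
#' @param dc_correct Subtract the outer-shell DC estimate (default TRUE).
#' @return A list of class `epr_image_series`: `images` (4D array,
#'   recon grid x delay), `delays`, `grid`.
#' @export
reconstruct_spi <- function(kspace, acq = epr_acquisition(),
                            dc_correct = TRUE) {
  grid <- kspace$grid
  zf <- acq$zerofill
  if (length(zf) == 1) zf <- rep(zf, 3)
  if (any(zf < grid)) stop("zerofill smaller than the acquired grid")
  w <- outer(outer(tukey_window(grid[1], acq$tukey_r),
                   tukey_window(grid[2], acq$tukey_r)),
             tukey_window(grid[3], acq$tukey_r))
  dim(w) <- grid
  # outermost shell: voxels touching any face of the k-space cube
  shell <- array(FALSE, grid)
  shell[c(1, grid[1]), , ] <- TRUE
  shell[, c(1, grid[2]), ] <- TRUE
  shell[, , c(1, grid[3])] <- TRUE
  scale <- prod(zf) / prod(grid)
  images <- array(0, c(zf, length(kspace$kspace)))
  for (j in seq_along(kspace$kspace)) {
    k <- kspace$kspace[[j]]
    if (dc_correct) k <- k - mean(k[shell])
    k <- k * w
    kp <- array(0 + 0i, zf)
    # centre the DC sample: original DC index floor(g/2)+1 must map to
    # padded DC index floor(zf/2)+1
    off <- (floor(zf / 2) + 1) - (floor(grid / 2) + 1)
    kp[off[1] + seq_len(grid[1]), off[2] + seq_len(grid[2]),
       off[3] + seq_len(grid[3])] <- k
    img <- fftshift(stats::fft(ifftshift(kp), inverse = TRUE) / prod(zf))
    images[, , , j] <- Mod(img) * scale
  }
  structure(list(images = images, delays = kspace$delays, grid = zf,
                 acquired_grid = grid),
            class = "epr_image_series")
}

#' Fit a per-voxel R2* map from a delay series
#'
#' Ordinary least squares on `ln I(tp) = ln I0 - R2* tp` per voxel.
#' Voxels with a non-positive intensity at any delay are flagged and
#' excluded; negative fitted rates are clamped to zero and flagged.
#'
#' @param images A [reconstruct_spi()] result, or a 4D array
#'   (x,y,z,delay) of magnitudes.
#' @param delays Delays in us (taken from `images` when present).
#' @param mask Logical 3D array of voxels to fit (default: all voxels;
#'   those with non-positive intensities are flagged).
#' @return A list of class `r2star_map`: `r2star` (1/us), `i0`, `r2`
#'   (fit quality), logical `flag` and `clamped`, and `mask`.
#' @export
fit_r2star <- function(images, delays = NULL, mask = NULL) {
  if (inherits(images, "epr_image_series")) {
    if (is.null(delays)) delays <- images$delays
    images <- images$images
  }
  stopifnot(length(delays) >= 2, dim(images)[4] == length(delays))
  shape <- dim(images)[1:3]
  smat <- matrix(images, prod(shape), length(delays))
  pos <- rowSums(smat <= 0) == 0
  if (is.null(mask)) mask <- array(TRUE, shape)
  idx <- which(mask)
  r2star <- i0 <- r2 <- array(NA_real_, shape)
  flag <- clamped <- array(FALSE, shape)
  usable <- idx[pos[idx]]
  flag[idx[!pos[idx]]] <- TRUE
  if (length(usable)) {
    y <- log(smat[usable, , drop = FALSE])
    x <- delays
    xm <- mean(x)
    ym <- rowMeans(y)
    sxx <- sum((x - xm)^2)
    slope <- as.vector((y - ym) %*% (x - xm)) / sxx
    inter <- ym - slope * xm
    fitted <- outer(inter, rep(1, length(x))) + outer(slope, x)
    ssr <- rowSums((y - fitted)^2)
    sst <- rowSums((y - ym)^2)
    r2v <- ifelse(sst > 0, 1 - ssr / sst, 1)
    rv <- -slope
    cl <- rv < 0
    rv[cl] <- 0
    r2star[usable] <- rv
    i0[usable] <- exp(inter)
    r2[usable] <- r2v
    clamped[usable] <- cl
  }
  structure(list(r2star = r2star, i0 = i0, r2 = r2, flag = flag,
                 clamped = clamped, mask = mask, delays = delays),
            class = "r2star_map")
}

#' Convert an R2* map to a pO2 map
#'
#' `pO2 = (R2* - r2star_anoxic) / slope`; negative results are floored at
#' zero and flagged (they arise from noise below the anoxic rate, not
#' from physiology).
#'
#' @param r2map A [fit_r2star()] result.
#' @param calib An [oximetry_calibration()].
#' @return A list of class `po2_map`: `po2` (mmHg), `r2star`,
#'   `fit_quality`, `mask`, logical `flag` (failed fits) and `floored`.
#' @export
r2star_to_po2 <- function(r2map, calib = oximetry_calibration()) {
  stopifnot(calib$slope > 0)
  po2 <- (r2map$r2star - calib$r2star_anoxic) / calib$slope
  floored <- !is.na(po2) & po2 < 0
  po2[floored] <- 0
  structure(list(po2 = po2, r2star = r2map$r2star,
                 fit_quality = r2map$r2, mask = r2map$mask,
                 flag = r2map$flag, floored = floored, calib = calib),
            class = "po2_map")
}

#' Hypoxic fraction of a pO2 map
#'
#' Percentage of masked, unflagged voxels with pO2 strictly below the
#' threshold (default 10 mmHg, the HF10 biomarker).
#'
#' @param po2map A [r2star_to_po2()] result, or a numeric array with a
#'   `mask` argument.
#' @param threshold Threshold in mmHg.
#' @param mask Optional logical array overriding the map's mask.
#' @return Percent in `[0, 100]`.
#' @export
hypoxic_fraction <- function(po2map, threshold = 10, mask = NULL) {
  v <- .masked_po2(po2map, mask)
  100 * sum(v < threshold) / length(v)
}

#' Median pO2 of a map
#'
#' Median over masked, unflagged voxels (midpoint convention for even
#' counts).
#'
#' @inheritParams hypoxic_fraction
#' @return Median pO2 in mmHg.
#' @export
median_po2 <- function(po2map, mask = NULL) {
  stats::median(.masked_po2(po2map, mask))
}

.masked_po2 <- function(po2map, mask = NULL) {
  if (inherits(po2map, "po2_map")) {
    m <- if (is.null(mask)) po2map$mask else mask
    m <- m & !po2map$flag & !is.na(po2map$po2)
    v <- po2map$po2[m]
  } else {
    if (is.null(mask)) mask <- array(TRUE, dim(po2map))
    v <- po2map[mask & !is.na(po2map)]
  }
  if (length(v) == 0) stop("mask is empty after excluding flagged voxels")
  v
}
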