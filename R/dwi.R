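# Diffusion-weighted MRI: Stejskal-Tanner mono-exponential forward model
# with Rician magnitude noise, and per-voxel ADC fitting.

#' DWI acquisition protocol
#'
#' Defaults follow a five-b-value protocol (12, 50, 500, 800,
#' 1500 s/mm^2) with TR 1.5 s, TE 35 ms and six averages; the averages
#' enter only through the noise level (`1/sqrt(averages)` scaling against
#' the reference count).
#'
#' @param bvalues b-values in s/mm^2, strictly increasing, >= 2 entries.
#' @param tr,te Timing metadata in s.
#' @param averages Signal averages (noise scaling only).
#' @param noise_ref_averages Reference average count at which the stated
#'   SNR applies.
#' @return A list of class `dwi_acquisition`.
#' @export
dwi_acquisition <- function(bvalues = c(12, 50, 500, 800, 1500),
                            tr = 1.5, te = 0.035, averages = 6,
                            noise_ref_averages = 6) {
  if (length(bvalues) < 2 || any(diff(bvalues) <= 0) || any(bvalues < 0)) {
    stop("bvalues must be >= 2 strictly increasing non-negative values")
  }
  structure(list(bvalues = bvalues, tr = tr, te = te, averages = averages,
                 noise_ref_averages = noise_ref_averages),
            class = "dwi_acquisition")
}

#' Simulate a diffusion-weighted series
#'
#' Per voxel, `S(b) = S0 exp(-b * ADC)` with `S0` the spin density. Noise
#' is Rician: independent Gaussian noise on the two quadrature channels,
#' magnitude taken. SNR is defined at the lowest b-value against the mean
#' tumor-voxel signal.
#'
#' @param phantom A [make_tumor_phantom()] result.
#' @param acq A [dwi_acquisition()].
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @param seed Integer seed.
#' @return A list of class `dwi_series` with a 4D array `signal`
#'   (x,y,z,b) and the acquisition.
#' @export
simulate_dwi <- function(phantom, acq = dwi_acquisition(), snr = 50,
                         seed = 1) {
  stopifnot(inherits(phantom, "tissue_parameter_map"))
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive")
  shape <- phantom$shape
  nb <- length(acq$bvalues)
  signal <- array(0, c(shape, nb))
  for (j in seq_len(nb)) {
    signal[, , , j] <- phantom$spin_density *
      exp(-acq$bvalues[j] * phantom$adc)
  }
  if (!is.infinite(snr)) {
    tum <- which(phantom$tumor_mask)
    s_ref <- mean((phantom$spin_density *
                     exp(-acq$bvalues[1] * phantom$adc))[tum])
    sd_n <- s_ref / (snr * sqrt(acq$averages / acq$noise_ref_averages))
    set.seed(derive_seed(seed, 2))
    n <- length(signal)
    signal <- sqrt((signal + stats::rnorm(n, sd = sd_n))^2 +
                     stats::rnorm(n, sd = sd_n)^2)
    dim(signal) <- c(shape, nb)
  }
  structure(list(signal = signal, acq = acq, snr = snr,
                 seed = as.integer(seed)),
            class = "dwi_series")
}

#' Fit an ADC map by the Stejskal-Tanner relation
#'
#' Log-linearises `S(b) = S0 exp(-b ADC)` and fits per voxel by:
#' `"wls"` (default) weighted least squares with weights `S^2`, which
#' undoes the log transform's noise amplification at high b; `"loglinear"`
#' ordinary least squares on the log signal; or `"nls"` nonlinear least
#' squares on the original scale (Gauss-Newton started from the wls
#' estimate). Negative fitted ADCs are clamped to zero and flagged;
#' voxels with any non-positive signal are flagged and excluded.
#'
#' @param series A [simulate_dwi()] result or 4D array (x,y,z,b).
#' @param acq A [dwi_acquisition()] (taken from `series` when present).
#' @param method Fit method.
#' @param mask Logical 3D array of voxels to fit (default: all voxels;
#'   those with non-positive signals are flagged).
#' @return A list of class `adc_map`: `adc` (mm^2/s), `s0`, `r2`,
#'   logical `flag` and `clamped`, and `mask`.
#' @export
fit_adc <- function(series, acq = NULL, method = c("wls", "loglinear", "nls"),
                    mask = NULL) {
  method <- match.arg(method)
  if (inherits(series, "dwi_series")) {
    if (is.null(acq)) acq <- series$acq
    series <- series$signal
  }
  stopifnot(!is.null(acq), dim(series)[4] == length(acq$bvalues))
  b <- acq$bvalues
  shape <- dim(series)[1:3]
  smat <- matrix(series, prod(shape), length(b))
  pos <- rowSums(smat <= 0) == 0
  if (is.null(mask)) mask <- array(TRUE, shape)
  idx <- which(mask)
  adc <- s0 <- r2 <- array(NA_real_, shape)
  flag <- clamped <- array(FALSE, shape)
  usable <- idx[pos[idx]]
  flag[idx[!pos[idx]]] <- TRUE
  if (length(usable) == 0) {
    return(structure(list(adc = adc, s0 = s0, r2 = r2, flag = flag,
                          clamped = clamped, mask = mask),
                     class = "adc_map"))
  }
  s <- smat[usable, , drop = FALSE]
  y <- log(s)
  w <- switch(method, wls = s^2, loglinear = , nls = matrix(1, nrow(s), ncol(s)))
  # weighted simple regression, closed form per voxel
  wsum <- rowSums(w)
  bx <- rowSums(w * rep(b, each = nrow(w))) / wsum
  by <- rowSums(w * y) / wsum
  sxx <- rowSums(w * (rep(b, each = nrow(w)) - bx)^2)
  sxy <- rowSums(w * (rep(b, each = nrow(w)) - bx) * (y - by))
  slope <- sxy / sxx
  inter <- by - slope * bx
  if (method == "nls") {
    # Gauss-Newton on (log S0, ADC) in the signal domain
    for (it in 1:25) {
      pred <- exp(inter + outer(slope, b))
      res <- s - pred
      j1 <- pred                      # d pred / d log S0
      j2 <- pred * rep(b, each = nrow(pred))  # d pred / d slope... slope = -ADC
      a11 <- rowSums(j1 * j1); a12 <- rowSums(j1 * j2); a22 <- rowSums(j2 * j2)
      g1 <- rowSums(j1 * res); g2 <- rowSums(j2 * res)
      det <- a11 * a22 - a12^2
      d1 <- (a22 * g1 - a12 * g2) / det
      d2 <- (a11 * g2 - a12 * g1) / det
      inter <- inter + d1
      slope <- slope + d2
      if (max(abs(c(d1, d2))) < 1e-14) break
    }
  }
  fitted <- inter + outer(slope, b)
  sst <- rowSums((y - rowMeans(y))^2)
  ssr <- rowSums((y - fitted)^2)
  adcv <- -slope
  cl <- adcv < 0
  adcv[cl] <- 0
  adc[usable] <- adcv
  s0[usable] <- exp(inter)
  r2[usable] <- ifelse(sst > 0, 1 - ssr / sst, 1)
  clamped[usable] <- cl
  structure(list(adc = adc, s0 = s0, r2 = r2, flag = flag,
                 clamped = clamped, mask = mask, method = method),
            class = "adc_map")
}
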