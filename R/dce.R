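# Dynamic contrast-enhanced MRI: Tofts forward model, variable-TR
# saturation-recovery T1 mapping, spoiled-gradient-echo (SPGR/FLASH)
# signal synthesis and inversion, and AUC perfusion metrics.

#' DCE acquisition protocol
#'
#' Defaults follow a FLASH dynamic series of 45 frames at 15 s/frame with
#' tracer injection 60 s after the start, preceded by a saturation-recovery
#' (RARE) T1-mapping series at TR = 300/600/1000/2000 ms.
#'
#' @param tr Dynamic-series repetition time in s.
#' @param te Echo time in s (metadata only; TE decay is absorbed into M0).
#' @param flip Flip angle in degrees.
#' @param frame_interval Dynamic frame spacing in s.
#' @param n_frames Number of dynamic frames.
#' @param injection_time Tracer arrival time in s from the series start.
#' @param rare_trs TR values (s) of the variable-TR T1-mapping series.
#' @return A list of class `dce_acquisition`.
#' @export
dce_acquisition <- function(tr = 0.156, te = 0.004, flip = 45,
                            frame_interval = 15, n_frames = 45,
                            injection_time = 60,
                            rare_trs = c(0.3, 0.6, 1.0, 2.0)) {
  stopifnot(injection_time > frame_interval, length(rare_trs) >= 3)
  acq <- structure(list(tr = tr, te = te, flip = flip,
                        frame_interval = frame_interval,
                        n_frames = as.integer(n_frames),
                        injection_time = injection_time,
                        rare_trs = sort(rare_trs)),
                   class = "dce_acquisition")
  if (max(frame_times(acq)) < injection_time) {
    stop("no frames after the injection time")
  }
  acq
}

#' Frame start times of a dynamic acquisition
#' @param acq A `dce_acquisition`.
#' @return Numeric vector of frame times in s (frame i at (i-1) x interval).
#' @export
frame_times <- function(acq) {
  (seq_len(acq$n_frames) - 1) * acq$frame_interval
}

#' Arterial input function model
#'
#' Dose-scaled bi-exponential plasma curve (Weinmann-type small-molecule
#' gadolinium kinetics) with a sharp arrival at `t0`:
#' `Cp(t) = dose * sum_i a_i * exp(-m_i * (t - t0))` for `t >= t0`, zero
#' before. A `"constant"` type (plateau `cp0` after `t0`) is provided for
#' equilibrium checks.
#'
#' @param dose Injected dose in mmol/kg.
#' @param a Amplitudes in kg/L (so `dose * a` is in mM).
#' @param m Decay rates in 1/min.
#' @param t0 Arrival time in s.
#' @param type `"biexp"` or `"constant"`.
#' @param cp0 Plateau concentration in mM (constant type only).
#' @return A list of class `aif_model`.
#' @export
aif_model <- function(dose = 0.2, a = c(3.99, 4.78), m = c(0.144, 0.0111),
                      t0 = 60, type = c("biexp", "constant"), cp0 = 1) {
  type <- match.arg(type)
  structure(list(dose = dose, a = a, m = m, t0 = t0, type = type, cp0 = cp0),
            class = "aif_model")
}

#' Evaluate an arterial input function
#' @param aif An [aif_model()].
#' @param times Times in s.
#' @return Plasma concentration in mM at each time.
#' @export
aif_cp <- function(aif, times) {
  tau <- pmax(0, times - aif$t0) / 60   # minutes since arrival
  on <- times >= aif$t0
  if (aif$type == "constant") return(ifelse(on, aif$cp0, 0))
  cp <- aif$dose * rowSums(vapply(seq_along(aif$a), function(i) {
    aif$a[i] * exp(-aif$m[i] * tau)
  }, numeric(length(tau))))
  ifelse(on, cp, 0)
}

#' Tofts-model tissue concentration
#'
#' Standard (two-parameter) Tofts model:
#' `Ct(t) = Ktrans * integral_0^t Cp(s) exp(-(Ktrans/ve) (t - s)) ds`,
#' evaluated in closed form for the bi-exponential and plateau input
#' functions (exact piecewise-exponential convolution, no numerical
#' quadrature).
#'
#' @param aif An [aif_model()].
#' @param ktrans Transfer constant(s) in 1/min; scalar or vector (voxels).
#' @param ve Extravascular-extracellular volume fraction(s) in (0, 1);
#'   recycled against `ktrans`.
#' @param times Times in s.
#' @return If `ktrans` is scalar, a vector over `times`; otherwise a
#'   matrix of voxels x times, in mM.
#' @export
tofts_concentration <- function(aif, ktrans, ve, times) {
  n <- max(length(ktrans), length(ve))
  ktrans <- rep_len(ktrans, n)
  ve <- rep_len(ve, n)
  if (any(ve <= 0 & ktrans > 0)) {
    stop("ve = 0 with ktrans > 0 is ill-posed")
  }
  kep <- ifelse(ktrans > 0, ktrans / ve, 0)   # 1/min
  tau <- pmax(0, times - aif$t0) / 60          # minutes
  ct <- matrix(0, n, length(times))
  if (aif$type == "constant") {
    for (j in seq_along(tau)) {
      ct[, j] <- ifelse(ktrans > 0,
                        ve * aif$cp0 * (1 - exp(-kep * tau[j])), 0)
    }
  } else {
    for (i in seq_along(aif$a)) {
      Ai <- aif$dose * aif$a[i]
      mi <- aif$m[i]
      for (j in seq_along(tau)) {
        tj <- tau[j]
        dk <- kep - mi
        # exact convolution term; series limit where kep ~ m_i
        term <- ifelse(abs(dk) > 1e-8,
                       (exp(-mi * tj) - exp(-kep * tj)) / dk,
                       tj * exp(-mi * tj))
        ct[, j] <- ct[, j] + ktrans * Ai * term
      }
    }
    ct[ktrans == 0, ] <- 0
  }
  if (n == 1) as.vector(ct) else ct
}

#' Analytic post-injection AUC of a Tofts curve
#'
#' Integral of the noiseless Tofts concentration from tracer arrival to
#' `window` seconds after arrival, in mM min, evaluated in closed form.
#' Used for generator ground truth and as the dense-quadrature reference
#' in round-trip checks.
#'
#' @inheritParams tofts_concentration
#' @param window Integration window in s after tracer arrival.
#' @return AUC in mM min (vector over voxels).
#' @export
tofts_auc <- function(aif, ktrans, ve, window) {
  n <- max(length(ktrans), length(ve))
  ktrans <- rep_len(ktrans, n)
  ve <- rep_len(ve, n)
  if (any(ve <= 0 & ktrans > 0)) stop("ve = 0 with ktrans > 0 is ill-posed")
  kep <- ifelse(ktrans > 0, ktrans / ve, 0)
  w <- window / 60   # minutes
  if (aif$type == "constant") {
    return(ifelse(ktrans > 0,
                  ve * aif$cp0 * (w - (1 - exp(-kep * w)) / kep), 0))
  }
  out <- numeric(n)
  for (i in seq_along(aif$a)) {
    Ai <- aif$dose * aif$a[i]
    mi <- aif$m[i]
    dk <- kep - mi
    term <- ifelse(abs(dk) > 1e-8,
                   ((1 - exp(-mi * w)) / mi - (1 - exp(-kep * w)) / kep) / dk,
                   ((1 - exp(-mi * w)) / mi - w * exp(-mi * w)) / mi)
    out <- out + ktrans * Ai * term
  }
  out[ktrans == 0] <- 0
  out
}

#' Spoiled-gradient-echo steady-state signal
#'
#' `S = M0 sin(a) (1 - E) / (1 - cos(a) E)` with `E = exp(-TR * R1)`.
#'
#' @param m0 Equilibrium signal amplitude (a.u.; TE decay absorbed).
#' @param r1 Longitudinal relaxation rate in 1/s.
#' @param tr Repetition time in s.
#' @param flip Flip angle in degrees.
#' @return Signal in arbitrary units.
#' @export
spgr_signal <- function(m0, r1, tr, flip) {
  a <- flip * pi / 180
  e <- exp(-tr * r1)
  m0 * sin(a) * (1 - e) / (1 - cos(a) * e)
}

#' Simulate variable-TR and dynamic DCE series from a phantom
#'
#' Per voxel, the tracer concentration follows the Tofts model with the
#' phantom's `ktrans` and `ve`; the longitudinal rate is
#' `R1(t) = 1/T1_0 + r1 * Ct(t)` and the dynamic signal is the SPGR
#' closed form. The variable-TR series is saturation recovery
#' `S(TR') = A (1 - exp(-TR'/T1))` at the protocol's `rare_trs`.
#' White Gaussian noise is added at the stated SNR (defined against the
#' mean pre-injection tumor signal).
#'
#' @param phantom A [make_tumor_phantom()] result.
#' @param acq A [dce_acquisition()].
#' @param aif An [aif_model()]; its arrival time is forced to the
#'   acquisition's injection time.
#' @param snr Signal-to-noise ratio; `Inf` for noiseless.
#' @param seed Integer seed.
#' @param r1_relaxivity Tracer relaxivity in 1/(s mM).
#' @return A list of class `dce_series` with 4D arrays `dynamic`
#'   (x,y,z,frame) and `rare` (x,y,z,TR), plus timing metadata.
#' @export
simulate_dce <- function(phantom, acq = dce_acquisition(), aif = aif_model(),
                         snr = 50, seed = 1, r1_relaxivity = 3.8) {
  stopifnot(inherits(phantom, "tissue_parameter_map"))
  if (!is.infinite(snr) && snr <= 0) stop("snr must be positive")
  aif$t0 <- acq$injection_time
  times <- frame_times(acq)
  shape <- phantom$shape
  body <- which(phantom$body_mask)
  nvox <- length(body)

  ct <- tofts_concentration(aif, phantom$ktrans[body], phantom$ve[body], times)
  if (is.null(dim(ct))) ct <- matrix(ct, nrow = 1)
  r1_0 <- 1 / phantom$t1_0[body]
  m0 <- phantom$spin_density[body]
  dyn_mat <- matrix(0, nvox, length(times))
  for (j in seq_along(times)) {
    dyn_mat[, j] <- spgr_signal(m0, r1_0 + r1_relaxivity * ct[, j],
                                acq$tr, acq$flip)
  }
  rare_mat <- vapply(acq$rare_trs, function(trj) {
    m0 * (1 - exp(-trj / phantom$t1_0[body]))
  }, numeric(nvox))

  # Noise level: mean baseline (pre-injection) tumor-voxel signal / SNR.
  sd_noise <- 0
  if (!is.infinite(snr)) {
    base <- times < acq$injection_time
    tum <- phantom$tumor_mask[body]
    sd_noise <- mean(dyn_mat[tum, base]) / snr
    set.seed(derive_seed(seed, 0))
    dyn_mat <- dyn_mat + matrix(stats::rnorm(length(dyn_mat), sd = sd_noise),
                                nrow = nvox)
    rare_mat <- rare_mat + matrix(stats::rnorm(length(rare_mat), sd = sd_noise),
                                  nrow = nvox)
  }
  dynamic <- array(0, c(shape, length(times)))
  rare <- array(0, c(shape, length(acq$rare_trs)))
  for (j in seq_along(times)) {
    fr <- array(0, shape); fr[body] <- dyn_mat[, j]
    dynamic[, , , j] <- fr
  }
  for (j in seq_along(acq$rare_trs)) {
    fr <- array(0, shape); fr[body] <- rare_mat[, j]
    rare[, , , j] <- fr
  }
  structure(list(dynamic = dynamic, rare = rare, times = times,
                 rare_trs = acq$rare_trs, acq = acq, aif = aif,
                 snr = snr, seed = as.integer(seed),
                 r1_relaxivity = r1_relaxivity, noise_sd = sd_noise),
            class = "dce_series")
}

#' Fit T1 from a variable-TR saturation-recovery series
#'
#' Per voxel, least-squares fit of `S(TR) = A (1 - exp(-TR/T1))` over the
#' acquired TRs. The amplitude is profiled out analytically and T1 found
#' by bounded 1D minimisation of the profiled residual sum of squares,
#' which is equivalent to (and more robust than) a two-parameter
#' Levenberg descent from the two-point log estimate. Voxels whose signal
#' is flat across TRs (fully saturated recovery, the T1 -> 0 limit) are
#' flagged as degenerate.
#'
#' @param rare 4D array (x,y,z,TR) of saturation-recovery signals.
#' @param rare_trs TR values in s (>= 3).
#' @param mask Logical 3D array of voxels to fit; default all voxels with
#'   positive mean signal.
#' @param t1_range Search interval for T1 in s.
#' @return A list of class `t1_map` with 3D arrays `t1` (s), `amplitude`,
#'   `r2` (fit quality) and logical `flag` (degenerate / failed voxels).
#' @export
fit_t1 <- function(rare, rare_trs, mask = NULL, t1_range = c(0.02, 20)) {
  stopifnot(length(rare_trs) >= 3, dim(rare)[4] == length(rare_trs))
  shape <- dim(rare)[1:3]
  smat <- matrix(rare, prod(shape), length(rare_trs))
  if (is.null(mask)) mask <- array(rowMeans(smat) > 0, shape)
  idx <- which(mask)
  t1 <- amp <- r2 <- array(NA_real_, shape)
  flag <- array(FALSE, shape)
  for (v in idx) {
    y <- smat[v, ]
    tot <- sum((y - mean(y))^2)
    if (max(y) <= 0 || tot <= (1e-12 * max(abs(y)))^2) {
      flag[v] <- TRUE
      next
    }
    rss_of <- function(t1v) {
      f <- 1 - exp(-rare_trs / t1v)
      a <- sum(y * f) / sum(f * f)
      sum((y - a * f)^2)
    }
    opt <- stats::optimize(rss_of, t1_range, tol = 1e-10)
    f <- 1 - exp(-rare_trs / opt$minimum)
    a <- sum(y * f) / sum(f * f)
    t1[v] <- opt$minimum
    amp[v] <- a
    r2[v] <- 1 - opt$objective / tot
    # boundary solutions mean the model is unidentified on this voxel
    if (opt$minimum <= t1_range[1] * 1.01 || opt$minimum >= t1_range[2] * 0.99) {
      flag[v] <- TRUE
    }
  }
  structure(list(t1 = t1, amplitude = amp, r2 = r2, flag = flag, mask = mask,
                 rare_trs = rare_trs),
            class = "t1_map")
}

#' Invert dynamic SPGR signal to tracer concentration
#'
#' Per voxel, M0 is estimated from the mean pre-injection (baseline)
#' signal and the fitted T1; each frame's signal is then inverted through
#' the SPGR equation for `R1(t)` and converted to concentration
#' `C(t) = (R1(t) - R1_0) / r1`. Baseline frames recover ~0 mM by
#' construction. Frames whose signal exceeds the SPGR ceiling for any R1
#' (a noise outlier) are flagged and set to `NA`.
#'
#' @param dce A `dce_series` (or any list with `dynamic`, `times`).
#' @param t1map A [fit_t1()] result on the same grid.
#' @param acq The [dce_acquisition()] used.
#' @param r1_relaxivity Tracer relaxivity in 1/(s mM).
#' @return A list of class `concentration_series` with 4D array `c`
#'   (mM), `times`, `baseline_frames`, and a logical `flag` array of
#'   inversion failures.
#' @export
signal_to_concentration <- function(dce, t1map, acq = dce_acquisition(),
                                    r1_relaxivity = 3.8) {
  dynamic <- dce$dynamic
  times <- dce$times
  shape <- dim(dynamic)[1:3]
  nt <- dim(dynamic)[4]
  base <- which(times < acq$injection_time)
  if (length(base) < 1) stop("no baseline frames before the injection time")
  a <- acq$flip * pi / 180
  idx <- which(t1map$mask & !t1map$flag & !is.na(t1map$t1))
  smat <- matrix(dynamic, prod(shape), nt)
  s0 <- rowMeans(smat[, base, drop = FALSE])
  r1_0 <- 1 / t1map$t1[idx]
  e0 <- exp(-acq$tr * r1_0)
  m0 <- s0[idx] * (1 - cos(a) * e0) / (sin(a) * (1 - e0))
  cmat <- matrix(NA_real_, length(idx), nt)
  flag <- array(FALSE, c(shape, nt))
  fmat <- matrix(FALSE, length(idx), nt)
  for (j in seq_len(nt)) {
    s <- smat[idx, j]
    e <- (m0 * sin(a) - s) / (m0 * sin(a) - s * cos(a))
    bad <- !(e > 0 & e < 1)
    r1 <- rep(NA_real_, length(e))
    r1[!bad] <- -log(e[!bad]) / acq$tr
    cmat[, j] <- (r1 - r1_0) / r1_relaxivity
    fmat[, j] <- bad
  }
  conc <- array(NA_real_, c(shape, nt))
  for (j in seq_len(nt)) {
    fr <- array(NA_real_, shape); fr[idx] <- cmat[, j]
    conc[, , , j] <- fr
    fl <- array(FALSE, shape); fl[idx] <- fmat[, j]
    flag[, , , j] <- fl
  }
  structure(list(c = conc, times = times,
                 baseline_frames = length(base), flag = flag,
                 mask = t1map$mask & !t1map$flag),
            class = "concentration_series")
}

#' Post-injection area-under-the-curve perfusion metrics
#'
#' Per voxel, trapezoidal integral of the concentration curve from tracer
#' arrival to `window` seconds later, with linear interpolation to the
#' window endpoints when they fall between frames. Reported in mM min.
#'
#' @param conc A [signal_to_concentration()] result (or list with 4D `c`
#'   and `times`).
#' @param acq The [dce_acquisition()] used (supplies the injection time).
#' @param windows Integration windows in s after injection; default 60 s
#'   (AUC1min) and 600 s (AUC10min).
#' @return A list of class `perfusion_metrics` with one 3D array per
#'   window (named `auc1`, `auc10` for the defaults, else `auc<w>s`).
#' @export
auc_metrics <- function(conc, acq = dce_acquisition(), windows = c(60, 600)) {
  times <- conc$times
  t0 <- acq$injection_time
  if (max(times) < t0 + max(windows)) {
    stop("integration window extends beyond the acquisition")
  }
  shape <- dim(conc$c)[1:3]
  nt <- dim(conc$c)[4]
  cmat <- matrix(conc$c, prod(shape), nt)
  interp_col <- function(tq) {
    if (tq <= times[1]) return(cmat[, 1])
    j <- findInterval(tq, times)
    if (times[j] == tq || j >= nt) return(cmat[, min(j, nt)])
    w <- (tq - times[j]) / (times[j + 1] - times[j])
    (1 - w) * cmat[, j] + w * cmat[, j + 1]
  }
  out <- list()
  for (w in windows) {
    inside <- which(times > t0 & times < t0 + w)
    tg <- c(t0, times[inside], t0 + w)
    ymat <- cbind(interp_col(t0), cmat[, inside, drop = FALSE],
                  interp_col(t0 + w))
    auc <- trapz_rows(tg, ymat) / 60   # mM s -> mM min
    nm <- if (w == 60) "auc1" else if (w == 600) "auc10" else
      sprintf("auc%gs", w)
    out[[nm]] <- array(auc, shape)
  }
  structure(c(out, list(windows = windows, injection_time = t0)),
            class = "perfusion_metrics")
}
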