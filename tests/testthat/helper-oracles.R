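# Independent oracles used across the suite. Each is a deliberately
# slow, direct implementation kept separate from the package's code
# paths.

# Direct O(N^6) inverse DFT of a centred (DC at floor(n/2)+1) k-space
# array under the symmetric convention (image centre at floor(n/2)+1
# too): magnitude image on the same grid.
brute_force_idft <- function(k) {
  d <- dim(k)
  ctr <- floor(d / 2) + 1
  out <- array(0 + 0i, d)
  for (x in 1:d[1]) for (y in 1:d[2]) for (z in 1:d[3]) {
    acc <- 0 + 0i
    for (kx in 1:d[1]) for (ky in 1:d[2]) for (kz in 1:d[3]) {
      ph <- 2 * pi * ((kx - ctr[1]) * (x - ctr[1]) / d[1] +
                        (ky - ctr[2]) * (y - ctr[2]) / d[2] +
                        (kz - ctr[3]) * (z - ctr[3]) / d[3])
      acc <- acc + k[kx, ky, kz] * exp(1i * ph)
    }
    out[x, y, z] <- acc / prod(d)
  }
  out
}

# Replicates the reconstruction definition (DC removal by outer shell,
# separable Tukey window, centred zero-fill) but inverts by the direct
# DFT above instead of the FFT.
brute_force_recon <- function(k, tukey_r, zerofill, dc_correct = TRUE) {
  d <- dim(k)
  shell <- array(FALSE, d)
  shell[c(1, d[1]), , ] <- TRUE
  shell[, c(1, d[2]), ] <- TRUE
  shell[, , c(1, d[3])] <- TRUE
  if (dc_correct) k <- k - mean(k[shell])
  w <- outer(outer(tukey_window(d[1], tukey_r), tukey_window(d[2], tukey_r)),
             tukey_window(d[3], tukey_r))
  dim(w) <- d
  k <- k * w
  zf <- rep(zerofill, length.out = 3)
  kp <- array(0 + 0i, zf)
  off <- (floor(zf / 2) + 1) - (floor(d / 2) + 1)
  kp[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]),
     off[3] + seq_len(d[3])] <- k
  Mod(brute_force_idft(kp)) * prod(zf) / prod(d)
}

# Explicit-Euler integration of the two-site exchange system at step dt,
# with the same record/consume RF schedule as evolve_two_site.
euler_two_site <- function(kpl, r1p, r1l, klp, p0, flip, frame_interval,
                           n_frames, dt) {
  sa <- sin(flip * pi / 180)
  ca <- cos(flip * pi / 180)
  nsub <- round(frame_interval / dt)
  P <- p0; L <- 0
  pyr <- lac <- numeric(n_frames)
  for (j in seq_len(n_frames)) {
    pyr[j] <- sa * P
    lac[j] <- sa * L
    P <- ca * P; L <- ca * L
    for (s in seq_len(nsub)) {
      dP <- -(kpl + r1p) * P + klp * L
      dL <- kpl * P - (r1l + klp) * L
      P <- P + dt * dP
      L <- L + dt * dL
    }
  }
  list(pyr = pyr, lac = lac)
}

# Numerical-quadrature Tofts convolution: integrate Cp(s) exp(-kep (t-s))
# with adaptive quadrature, independent of the closed form.
quad_tofts <- function(aif, ktrans, ve, t_s) {
  kep <- ktrans / ve / 60   # 1/s
  vapply(t_s, function(t) {
    if (t <= aif$t0 || ktrans == 0) return(0)
    ktrans / 60 * stats::integrate(function(s) {
      aif_cp(aif, s) * exp(-kep * (t - s))
    }, lower = aif$t0, upper = t, rel.tol = 1e-10)$value
  }, numeric(1))
}

# Dense-quadrature AUC of the analytic Tofts curve over a window after
# arrival.
quad_tofts_auc <- function(aif, ktrans, ve, window) {
  stats::integrate(function(t) {
    tofts_concentration(aif, ktrans, ve, t)
  }, lower = aif$t0, upper = aif$t0 + window, rel.tol = 1e-10,
  subdivisions = 500L)$value / 60
}

default_rim_phantom <- function(shape = c(16, 16, 16)) {
  make_tumor_phantom(shape, "rim_core", seed = 1)
}
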