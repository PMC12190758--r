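# Digital tumor phantoms: per-voxel ground-truth physiology that every
# forward simulator reads. The default phantom is an ellipsoidal tumor
# inside an ellipsoidal body support on a 16^3 grid, with a hypoxic,
# poorly perfused core and an oxygenated, well-perfused rim.

# Nominal tissue values. Tumor core/rim pairs define the radial profile;
# "muscle" values fill the body support outside the tumor.
.phantom_defaults <- function() {
  list(
    po2_core    = 2,      po2_rim    = 28,     po2_muscle    = 40,    # mmHg
    ktrans_core = 0.05,   ktrans_rim = 0.25,   ktrans_muscle = 0.08,  # 1/min
    ve_core     = 0.15,   ve_rim     = 0.35,   ve_muscle     = 0.20,  # fraction
    adc_core    = 0.7e-3, adc_rim    = 1.1e-3, adc_muscle    = 1.4e-3, # mm^2/s
    kpl_core    = 0.05,   kpl_rim    = 0.02,   kpl_muscle    = 0.005, # 1/s
    t1_core     = 1.9,    t1_rim     = 1.6,    t1_muscle     = 1.5,   # s
    r1p = 1 / 43, r1l = 1 / 33,                                        # 1/s
    # Multiplicative per-phantom scale factors (per-mouse variation and
    # breathing-gas conditioning are applied through these).
    po2_scale = 1, ktrans_scale = 1, ve_scale = 1, adc_scale = 1,
    kpl_scale = 1,
    # Radial ramp: parameters hold their core value for normalized
    # ellipsoidal radius u < ramp_lo and their rim value for u > ramp_hi.
    ramp_lo = 0.35, ramp_hi = 0.85,
    # Tumor and body semi-axes as fractions of the grid dimensions.
    tumor_frac = c(0.34, 0.28, 0.31), body_frac = c(0.47, 0.44, 0.47)
  )
}

#' Generate a digital tumor phantom
#'
#' Builds a [tissue parameter map][TissueParameterMap] on a regular 3D grid:
#' an ellipsoidal tumor inside an ellipsoidal body support, with per-voxel
#' spin density, oxygen partial pressure (pO2), pre-contrast T1, Tofts
#' `ktrans` and `ve`, apparent diffusion coefficient, and apparent
#' pyruvate-to-lactate conversion rate `kpl`.
#'
#' The `rim_core` profile places a hypoxic, low-`ktrans`, low-ADC,
#' high-`kpl` core at the tumor centre and an oxygenated, well-perfused rim
#' at its boundary, connected by a smooth radial ramp; the `uniform`
#' profile fills the tumor with constant values (midpoint of core and rim
#' unless overridden). The phantom is fully deterministic given `seed`.
#'
#' @param shape Integer vector of 3 grid dimensions, each at least 8.
#' @param profile `"rim_core"` or `"uniform"`.
#' @param seed Integer seed (reserved for stochastic texture; the default
#'   phantom is piecewise smooth and deterministic).
#' @param overrides Named list overriding nominal parameters. For the
#'   `uniform` profile, scalar entries named after a field (e.g.
#'   `po2 = 5`) set that field's constant tumor value; entries such as
#'   `po2_core`, `ktrans_rim`, `ktrans_scale`, `tumor_frac` adjust the
#'   profile itself.
#' @return An object of class `tissue_parameter_map`: a list of 3D arrays
#'   `spin_density`, `po2`, `t1_0`, `ktrans`, `ve`, `adc`, `kpl`, logical
#'   arrays `tumor_mask` and `body_mask`, scalars `r1p`, `r1l`, and a
#'   `meta` record of the generating parameters.
#' @examples
#' ph <- make_tumor_phantom(c(16, 16, 16), "rim_core", seed = 1)
#' mean(ph$po2[ph$tumor_mask])
#' @export
make_tumor_phantom <- function(shape = c(16, 16, 16),
                               profile = c("rim_core", "uniform"),
                               seed = 1, overrides = list()) {
  if (length(shape) != 3 || any(shape < 8)) {
    stop("`shape` must be three grid dimensions, each >= 8")
  }
  if (length(profile) > 1) profile <- profile[1]
  if (!profile %in% c("rim_core", "uniform")) {
    stop("unknown phantom profile: ", profile)
  }
  p <- .phantom_defaults()
  uniform_vals <- list()
  for (nm in names(overrides)) {
    if (nm %in% names(p)) {
      p[[nm]] <- overrides[[nm]]
    } else if (nm %in% c("po2", "ktrans", "ve", "adc", "kpl", "t1_0")) {
      uniform_vals[[nm]] <- overrides[[nm]]
    } else {
      stop("unknown phantom override: ", nm)
    }
  }

  centre <- (shape + 1) / 2
  ax <- lapply(1:3, function(i) seq_len(shape[i]) - centre[i])
  grid <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]])
  tum_ax <- p$tumor_frac * shape
  body_ax <- p$body_frac * shape
  u <- sqrt((grid$x / tum_ax[1])^2 + (grid$y / tum_ax[2])^2 +
              (grid$z / tum_ax[3])^2)
  ub <- sqrt((grid$x / body_ax[1])^2 + (grid$y / body_ax[2])^2 +
               (grid$z / body_ax[3])^2)
  tumor_mask <- array(u <= 1, dim = shape)
  body_mask <- array(ub <= 1, dim = shape)
  if (!any(tumor_mask)) stop("tumor mask is empty; enlarge `shape`")

  s <- smoothstep(u, p$ramp_lo, p$ramp_hi)
  radial <- function(core, rim) array(core + (rim - core) * s, dim = shape)
  fields <- list(
    po2   = list(p$po2_core, p$po2_rim, p$po2_muscle, p$po2_scale),
    ktrans = list(p$ktrans_core, p$ktrans_rim, p$ktrans_muscle, p$ktrans_scale),
    ve    = list(p$ve_core, p$ve_rim, p$ve_muscle, p$ve_scale),
    adc   = list(p$adc_core, p$adc_rim, p$adc_muscle, p$adc_scale),
    kpl   = list(p$kpl_core, p$kpl_rim, p$kpl_muscle, p$kpl_scale),
    t1_0  = list(p$t1_core, p$t1_rim, p$t1_muscle, 1)
  )
  out <- list()
  for (nm in names(fields)) {
    f <- fields[[nm]]
    if (profile == "uniform") {
      val <- if (!is.null(uniform_vals[[nm]])) uniform_vals[[nm]] else
        (f[[1]] + f[[2]]) / 2
      arr <- array(f[[3]], dim = shape)
      arr[tumor_mask] <- val
    } else {
      arr <- radial(f[[1]], f[[2]])
      arr[!tumor_mask] <- f[[3]]
    }
    arr <- arr * f[[4]]
    arr[!body_mask] <- 0
    out[[nm]] <- arr
  }
  out$ve <- pmin(out$ve, 0.95)            # keep ve in [0, 1)
  spin_density <- array(0, dim = shape)
  spin_density[body_mask] <- 1

  obj <- structure(list(
    shape = as.integer(shape),
    spin_density = spin_density,
    po2 = out$po2, t1_0 = out$t1_0, ktrans = out$ktrans, ve = out$ve,
    adc = out$adc, kpl = out$kpl,
    r1p = p$r1p, r1l = p$r1l,
    tumor_mask = tumor_mask, body_mask = body_mask,
    meta = list(profile = profile, seed = as.integer(seed), params = p)
  ), class = "tissue_parameter_map")
  validate_phantom(obj)
  obj
}

#' Validate a tissue parameter map
#'
#' Checks the structural invariants every forward simulator relies on:
#' non-negative pO2, `ktrans`, `adc` and `kpl`; `ve` in `[0, 1)`; a
#' non-empty tumor mask; and zero spin density outside the body support.
#'
#' @param phantom A `tissue_parameter_map`.
#' @return `phantom`, invisibly; errors if an invariant is violated.
#' @export
validate_phantom <- function(phantom) {
  stopifnot(inherits(phantom, "tissue_parameter_map"))
  with(phantom, {
    if (any(po2 < 0)) stop("po2 must be non-negative")
    if (any(ve < 0 | ve >= 1)) stop("ve must lie in [0, 1)")
    if (any(ktrans < 0) || any(adc < 0) || any(kpl < 0)) {
      stop("ktrans, adc and kpl must be non-negative")
    }
    if (!any(tumor_mask)) stop("tumor mask is empty")
    if (any(spin_density[!body_mask] != 0)) {
      stop("spin density must vanish outside the body support")
    }
  })
  invisible(phantom)
}

#' @export
print.tissue_parameter_map <- function(x, ...) {
  cat("Tissue parameter map", paste(x$shape, collapse = " x "),
      sprintf("(%s profile)\n", x$meta$profile))
  cat(sprintf("  tumor voxels: %d | body voxels: %d\n",
              sum(x$tumor_mask), sum(x$body_mask)))
  cat(sprintf("  tumor pO2 [mmHg]: %.1f-%.1f | ktrans [1/min]: %.3f-%.3f\n",
              min(x$po2[x$tumor_mask]), max(x$po2[x$tumor_mask]),
              min(x$ktrans[x$tumor_mask]), max(x$ktrans[x$tumor_mask])))
  invisible(x)
}

#' Continuous-profile hypoxic fraction of a rim_core phantom
#'
#' Fraction (in percent) of the tumor ellipsoid volume whose pO2 lies
#' strictly below `threshold`, computed analytically from the radial
#' profile rather than by counting voxels. This is the generator-side
#' ground truth against which the voxel-counted [hypoxic_fraction()] of a
#' reconstructed map is compared; being continuous in the per-phantom
#' `po2_scale`, it is strictly monotone where the voxel count moves in
#' steps.
#'
#' @param params The phantom parameter list (`phantom$meta$params`), or any
#'   list with the `po2_*`, `ramp_*` entries.
#' @param threshold Hypoxia threshold in mmHg.
#' @return Percent of tumor volume below threshold.
#' @export
hf_true_rim_core <- function(params, threshold = 10) {
  core <- params$po2_core * params$po2_scale
  rim <- params$po2_rim * params$po2_scale
  if (threshold <= core) return(0)
  if (threshold >= rim) return(100)
  s_cross <- (threshold - core) / (rim - core)
  t_cross <- smoothstep_inv(s_cross)
  u_cross <- params$ramp_lo + t_cross * (params$ramp_hi - params$ramp_lo)
  100 * min(1, u_cross)^3
}

#' Tumor volume from caliper measurements
#'
#' Standard caliper convention for subcutaneous tumors:
#' volume = length x width^2 / 2, with length the longer of the two axes.
#' If the arguments arrive swapped (width > length) they are exchanged
#' with a warning rather than rejected.
#'
#' @param length Longest tumor axis in mm.
#' @param width Perpendicular axis in mm.
#' @return Volume in mm^3.
#' @examples
#' tumor_volume(10, 5) # 125
#' @export
tumor_volume <- function(length, width) {
  stopifnot(all(width > 0), all(length > 0))
  swap <- width > length
  if (any(swap)) {
    warning("width > length; swapping to follow the caliper convention")
    tmp <- length[swap]
    length[swap] <- width[swap]
    width[swap] <- tmp
  }
  length * width^2 / 2
}
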