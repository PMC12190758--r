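# ROI biomarker reduction and the cohort statistics: normality-gated
# group comparisons against a shared control with Monte Carlo Dunnett
# adjustment, predictive correlations, and relative-change effect sizes.

#' Reduce per-voxel maps to per-tumor ROI biomarkers
#'
#' Applies the convention used throughout the analysis: median for pO2,
#' strict-threshold fraction for HF10, ROI means for the AUC and ADC
#' maps, and the scalar time-summed ratio for lactate/pyruvate. Voxels
#' flagged by the fitting stages are excluded per modality; flagged
#' voxels therefore never move a summary.
#'
#' @param maps Named list with any of: `po2` (a [r2star_to_po2()] result
#'   or array), `auc1`, `auc10`, `adc` (a [fit_adc()] result or array),
#'   `lac_pyr` (scalar or `metabolite_curves`).
#' @param mask Logical 3D ROI mask on the maps' grid.
#' @param hf_threshold HF10 threshold in mmHg.
#' @return One-row `data.frame` with `median_po2`, `hf10`, `auc1`,
#'   `auc10`, `adc`, `lac_pyr`, `n_voxels` (NA for modalities not
#'   supplied).
#' @export
summarize_roi <- function(maps, mask, hf_threshold = 10) {
  stopifnot(any(mask))
  grab <- function(x, field, flag_fields = c("flag")) {
    if (is.null(x)) return(NULL)
    if (is.list(x) && !is.null(x[[field]])) {
      m <- mask
      for (ff in flag_fields) if (!is.null(x[[ff]])) m <- m & !x[[ff]]
      v <- x[[field]][m]
    } else {
      v <- x[mask]
    }
    v <- v[is.finite(v)]
    if (length(v) == 0) stop("all ROI voxels are flagged for ", field)
    v
  }
  po2 <- if (!is.null(maps$po2)) grab(maps$po2, "po2") else NULL
  auc1 <- if (!is.null(maps$auc1)) grab(maps$auc1, "auc1") else NULL
  auc10 <- if (!is.null(maps$auc10)) grab(maps$auc10, "auc10") else NULL
  adc <- if (!is.null(maps$adc)) grab(maps$adc, "adc") else NULL
  lac_pyr <- if (is.null(maps$lac_pyr)) NA_real_
  else if (inherits(maps$lac_pyr, "metabolite_curves"))
    lactate_pyruvate_ratio(maps$lac_pyr)
  else as.numeric(maps$lac_pyr)
  data.frame(
    median_po2 = if (is.null(po2)) NA_real_ else stats::median(po2),
    hf10 = if (is.null(po2)) NA_real_ else
      100 * sum(po2 < hf_threshold) / length(po2),
    auc1 = if (is.null(auc1)) NA_real_ else mean(auc1),
    auc10 = if (is.null(auc10)) NA_real_ else mean(auc10),
    adc = if (is.null(adc)) NA_real_ else mean(adc),
    lac_pyr = lac_pyr,
    n_voxels = sum(mask))
}

# Monte Carlo sample of the many-to-one max-|t| statistic for groups of
# sizes n_vec (control first), pooled-variance df. Used both to adjust
# per-comparison p values and to locate critical values.
mc_max_abs_t <- function(nsim, n_vec, df, seed) {
  set.seed(derive_seed(seed, 11))
  k <- length(n_vec) - 1
  z0 <- stats::rnorm(nsim) / sqrt(n_vec[1])
  s <- sqrt(stats::rchisq(nsim, df) / df)
  mx <- rep(0, nsim)
  for (j in seq_len(k)) {
    zj <- stats::rnorm(nsim) / sqrt(n_vec[j + 1])
    tj <- abs(zj - z0) / (s * sqrt(1 / n_vec[j + 1] + 1 / n_vec[1]))
    mx <- pmax(mx, tj)
  }
  mx
}

#' Monte Carlo critical value for Dunnett's many-to-one comparison
#'
#' Two-sided equicoordinate `1 - alpha` quantile of the maximum absolute
#' many-to-one t statistic for `k` comparisons against a common control,
#' with a common pairwise correlation (1/2 for balanced designs),
#' estimated by Monte Carlo. Deterministic given `seed`; the standard
#' error of the quantile is estimated from the sample density.
#'
#' @param k Number of comparisons (>= 1).
#' @param df Residual degrees of freedom (>= 2).
#' @param alpha Familywise level.
#' @param correlation Common correlation between comparison statistics.
#' @param nsim Monte Carlo draws; below 1e4 a warning is issued.
#' @param seed Integer seed.
#' @return A list with `critical` (the quantile), `se` (its estimated
#'   standard error), and the call parameters.
#' @export
dunnett_critical <- function(k, df, alpha = 0.05, correlation = 0.5,
                             nsim = 1e5, seed = 1) {
  stopifnot(k >= 1, df >= 2, alpha > 0, alpha <= 1,
            correlation >= 0, correlation < 1)
  if (nsim < 1e4) warning("nsim < 1e4 gives an unstable quantile estimate")
  if (alpha >= 1) {
    return(list(critical = 0, se = 0, k = k, df = df, alpha = alpha,
                nsim = nsim, seed = seed))
  }
  set.seed(derive_seed(seed, 12))
  z0 <- stats::rnorm(nsim)
  s <- sqrt(stats::rchisq(nsim, df) / df)
  mx <- rep(0, nsim)
  for (j in seq_len(k)) {
    tj <- abs(sqrt(correlation) * z0 +
                sqrt(1 - correlation) * stats::rnorm(nsim)) / s
    mx <- pmax(mx, tj)
  }
  q <- as.numeric(stats::quantile(mx, 1 - alpha, names = FALSE))
  dens <- stats::density(mx, from = q, to = q, n = 1)$y
  se <- sqrt(alpha * (1 - alpha) / nsim) / max(dens, .Machine$double.eps)
  list(critical = q, se = se, k = k, df = df, alpha = alpha,
       correlation = correlation, nsim = nsim, seed = seed)
}

#' Normality-gated group comparison with many-to-one adjustment
#'
#' Reproduces the statistical protocol of the cohort analysis: the
#' Anderson-Darling test (at `alpha`) on the residuals (value minus group
#' mean) selects the branch. Parametric branch: Student's t test for two
#' groups, one-way ANOVA for more, with each non-control group compared
#' to the control and adjusted by the Monte Carlo Dunnett max-|t|
#' distribution. Nonparametric branch: Mann-Whitney U for two groups,
#' Kruskal-Wallis for more, with a rank-transform Dunnett-type adjustment
#' (the same many-to-one machinery applied to midranks, labelled as
#' such). All tests are two-tailed. Zero-variance (degenerate) groups are
#' reported as non-significant with a flag, never dropped.
#'
#' @param table A `data.frame` (e.g. a [simulate_cohort()] table) with a
#'   `group` column and the metric column.
#' @param metric Name of the metric column.
#' @param control Control group label.
#' @param alpha Significance/normality level.
#' @param nsim Monte Carlo draws for the Dunnett adjustment.
#' @param seed Integer seed for the adjustment (deterministic given
#'   seed).
#' @return A list of class `group_comparison`: `branch`
#'   (`"parametric"`/`"nonparametric"`), `omnibus` (statistic, p, test
#'   name), `comparisons` (per-group estimate, t, unadjusted and adjusted
#'   p), `normality` (AD p overall and per group), `degenerate` flag.
#' @export
compare_groups <- function(table, metric, control = "control", alpha = 0.05,
                           nsim = 2e4, seed = 1) {
  stopifnot(metric %in% names(table), "group" %in% names(table))
  keep <- is.finite(table[[metric]])
  g <- as.character(table$group)[keep]
  y <- table[[metric]][keep]
  levels <- unique(g)
  if (!control %in% levels) stop("control group not present: ", control)
  levels <- c(control, setdiff(levels, control))
  ns <- table(factor(g, levels = levels))
  if (any(ns < 3)) {
    stop("group(s) with fewer than 3 observations: ",
         paste(names(ns)[ns < 3], collapse = ", "))
  }
  gm <- tapply(y, factor(g, levels = levels), mean)
  resid <- y - gm[match(g, levels)]
  degenerate <- stats::sd(resid) == 0 ||
    any(tapply(y, factor(g, levels = levels), stats::sd) == 0)

  ad_all <- if (!degenerate && length(resid) >= 8) {
    tryCatch(nortest::ad.test(resid)$p.value, error = function(e) NA_real_)
  } else NA_real_
  ad_group <- vapply(levels, function(l) {
    r <- resid[g == l]
    if (length(r) >= 8 && stats::sd(r) > 0) {
      tryCatch(nortest::ad.test(r)$p.value, error = function(e) NA_real_)
    } else NA_real_
  }, numeric(1))
  branch <- if (degenerate) "parametric"
  else if (!is.na(ad_all) && ad_all < alpha) "nonparametric" else "parametric"

  k <- length(levels) - 1
  n_tot <- length(y)
  comparisons <- data.frame(group = levels[-1], estimate = NA_real_,
                            statistic = NA_real_, p_unadj = NA_real_,
                            p_adj = NA_real_)
  if (degenerate) {
    omnibus <- list(test = if (k == 1) "t" else "anova",
                    statistic = NA_real_, p = NA_real_)
    comparisons$estimate <- gm[-1] - gm[1]
    comparisons$p_unadj <- 1
    comparisons$p_adj <- 1
    return(structure(list(metric = metric, branch = branch,
                          omnibus = omnibus, comparisons = comparisons,
                          alpha = alpha,
                          normality = list(overall = ad_all,
                                           per_group = ad_group),
                          degenerate = TRUE, control = control),
                     class = "group_comparison"))
  }

  yw <- if (branch == "nonparametric") rank(y) else y   # midranks on ties
  gmw <- tapply(yw, factor(g, levels = levels), mean)
  df <- n_tot - (k + 1)
  ssw <- sum((yw - gmw[match(g, levels)])^2)
  s2 <- ssw / df

  if (branch == "parametric") {
    if (k == 1) {
      tt <- stats::t.test(y[g == levels[2]], y[g == control],
                          var.equal = TRUE)
      omnibus <- list(test = "t", statistic = unname(tt$statistic),
                      p = tt$p.value)
    } else {
      ssb <- sum(ns * (gm - mean(y))^2)
      f <- (ssb / k) / s2
      omnibus <- list(test = "anova", statistic = f,
                      p = stats::pf(f, k, df, lower.tail = FALSE))
    }
  } else {
    if (k == 1) {
      wt <- stats::wilcox.test(y[g == levels[2]], y[g == control],
                               exact = FALSE, correct = TRUE)
      omnibus <- list(test = "mann-whitney",
                      statistic = unname(wt$statistic), p = wt$p.value)
    } else {
      kw <- stats::kruskal.test(y, factor(g))
      omnibus <- list(test = "kruskal-wallis",
                      statistic = unname(kw$statistic), p = kw$p.value)
    }
  }

  tstat <- (gmw[-1] - gmw[1]) / sqrt(s2 * (1 / ns[-1] + 1 / ns[1]))
  p_unadj <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  if (k == 1) {
    p_adj <- p_unadj    # a single comparison needs no familywise correction
  } else {
    mx <- mc_max_abs_t(nsim, as.numeric(ns), df, seed)
    p_adj <- vapply(abs(tstat), function(t0) mean(mx >= t0), numeric(1))
    p_adj <- pmax(p_adj, p_unadj)   # adjusted p can never undercut unadjusted
  }
  comparisons$estimate <- unname(gm[-1] - gm[1])
  comparisons$statistic <- unname(tstat)
  comparisons$p_unadj <- unname(p_unadj)
  comparisons$p_adj <- unname(p_adj)
  structure(list(metric = metric, branch = branch, omnibus = omnibus,
                 comparisons = comparisons, alpha = alpha,
                 normality = list(overall = ad_all, per_group = ad_group),
                 degenerate = FALSE, control = control,
                 adjustment = if (branch == "parametric") "dunnett-mc"
                 else "rank-transform dunnett-type (mc)"),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Group comparison of '%s' vs control '%s' (%s branch)\n",
              x$metric, x$control, x$branch))
  cat(sprintf("  omnibus %s: statistic %.4g, p %.4g\n",
              x$omnibus$test, x$omnibus$statistic, x$omnibus$p))
  if (x$degenerate) cat("  [degenerate zero-variance groups: reported non-significant]\n")
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Correlation between two biomarkers
#'
#' Spearman (default; midranks for ties) or Pearson correlation with a
#' two-sided p value.
#'
#' @param x,y Numeric vectors, length >= 3, finite, non-constant.
#' @param method `"spearman"` or `"pearson"`.
#' @return A list of class `correlation_result`: `method`, `coefficient`,
#'   `p`, `n`.
#' @export
correlate <- function(x, y, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 paired finite observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y; correlation undefined")
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = method, exact = FALSE,
                    alternative = "two.sided"))
  structure(list(method = method, coefficient = unname(ct$estimate),
                 p = ct$p.value, n = length(x)),
            class = "correlation_result")
}

#' Relative change between two groups of values
#'
#' Percent mode returns `100 * (mean(treated) / mean(reference) - 1)`;
#' fold mode returns `mean(treated) / mean(reference)`. The two modes
#' satisfy `fold = 1 + percent / 100` exactly.
#'
#' @param reference Reference-group values (mean must be positive).
#' @param treated Treated-group values.
#' @param mode `"percent"` or `"fold"`.
#' @return Scalar effect size.
#' @examples
#' relative_change(1, 1.71, "percent") # 71
#' @export
relative_change <- function(reference, treated, mode = c("percent", "fold")) {
  mode <- match.arg(mode)
  mr <- mean(reference)
  if (!is.finite(mr) || mr <= 0) stop("reference mean must be positive")
  ratio <- mean(treated) / mr
  if (mode == "percent") 100 * (ratio - 1) else ratio
}
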