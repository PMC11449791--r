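#' Pointwise mean of several PSD estimates
#'
#' @param psds list of `psd_estimate` objects on identical frequency grids.
#' @return a `psd_estimate` with the pointwise mean power.
#' @export
mean_psd <- function(psds) {
  stopifnot(length(psds) >= 1L)
  f0 <- psds[[1]]$freq_hz
  for (p in psds) {
    if (length(p$freq_hz) != length(f0) || any(p$freq_hz != f0)) {
      stop("PSD frequency grids differ")
    }
  }
  out <- psds[[1]]
  out$power <- Reduce(`+`, lapply(psds, `[[`, "power")) / length(psds)
  out
}

#' Compare the spectral slopes of two groups' mean PSDs
#'
#' Fits the log-log slope ([fit_slope()]) on each group's mean PSD, and
#' tests the slope difference through the group-by-log-frequency
#' interaction term of a pooled regression
#' `log10(P) ~ log10(f) * group` over the band points.
#'
#' @param psds_a,psds_b lists of `psd_estimate` objects, one group each.
#' @param band fit band in Hz.
#' @param exclude_hz optional ranges excluded from the fits (see
#'   [fit_slope()]).
#' @return object of class `group_comparison`: list with `slope_a`,
#'   `slope_b`, `fit_a`, `fit_b`, `t_stat`, `df`, `p_value`, `test_name`,
#'   `n_a`, `n_b`.
#' @export
compare_mean_psd_slopes <- function(psds_a, psds_b, band = c(30, 50),
                                    exclude_hz = NULL) {
  ma <- mean_psd(psds_a)
  mb <- mean_psd(psds_b)
  fa <- fit_slope(ma, band = band, exclude_hz = exclude_hz)
  fb <- fit_slope(mb, band = band, exclude_hz = exclude_hz)
  dat <- rbind(band_points(ma, band, exclude_hz),
               band_points(mb, band, exclude_hz))
  dat$group <- rep(c(0, 1), c(fa$n_points, fb$n_points))
  fit <- stats::lm(ly ~ lx * group, data = dat)
  sm <- summary(fit)$coefficients
  t_stat <- sm["lx:group", "t value"]
  p <- sm["lx:group", "Pr(>|t|)"]
  structure(
    list(slope_a = fa$b, slope_b = fb$b, fit_a = fa, fit_b = fb,
         t_stat = t_stat, df = fit$df.residual, p_value = p,
         test_name = "log-log regression interaction",
         n_a = length(psds_a), n_b = length(psds_b)),
    class = "group_comparison"
  )
}

band_points <- function(psd, band, exclude_hz) {
  sel <- psd$freq_hz >= band[1] & psd$freq_hz <= band[2] & psd$power > 0
  if (!is.null(exclude_hz)) {
    ex <- matrix(as.numeric(exclude_hz), ncol = 2)
    for (i in seq_len(nrow(ex))) {
      sel <- sel & !(psd$freq_hz >= ex[i, 1] & psd$freq_hz <= ex[i, 2])
    }
  }
  data.frame(lx = log10(psd$freq_hz[sel]), ly = log10(psd$power[sel]))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> slopes %.3f vs %.3f (diff %.3f); %s: t = %.3f, df = %.1f, p = %.3g\n",
              x$slope_a, x$slope_b, x$slope_a - x$slope_b, x$test_name,
              x$t_stat, x$df, x$p_value))
  invisible(x)
}

#' Welch's unequal-variance t test
#'
#' Two-sided t test with Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return list with `t`, `df`, `p`.
#' @examples
#' welch_t(c(1, 2, 3), c(2, 3, 4))   # t = -1.2247, df = 4
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs n >= 2")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = length(a) + length(b) - 2, p = 1))
    stop("both samples have zero variance")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Shapiro-Wilk normality test
#'
#' Royston's (AS R94) W statistic and p value, as the gate for choosing
#' parametric vs nonparametric group tests.
#'
#' @param x numeric sample, 3 <= n <= 5000, non-constant.
#' @return list with `W`, `p`.
#' @export
shapiro_wilk <- function(x) {
  if (length(x) < 3L || length(x) > 5000L) stop("n must be in [3, 5000]")
  if (stats::sd(x) == 0) stop("constant sample")
  ht <- stats::shapiro.test(x)
  list(W = unname(ht$statistic), p = ht$p.value)
}

#' Grubbs' test for a single outlier
#'
#' Two-sided Grubbs statistic `G = max|x - mean| / sd` compared against
#' the critical value
#' `G_crit = (n-1)/sqrt(n) * sqrt(t^2 / (n - 2 + t^2))` with
#' `t = qt(1 - alpha/(2n), n - 2)`. At most one point is flagged per
#' call; for iterative screening remove the flagged point and re-run.
#'
#' @param x numeric sample, n >= 3.
#' @param alpha significance level (default 0.05).
#' @return list with `outlier_idx` (index into `x`, or `NA` when nothing
#'   is flagged), `outlier_value`, `G`, `G_crit`.
#' @examples
#' grubbs_test(c(1, 2, 3, 100))   # flags 100
#' @export
grubbs_test <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3L) stop("Grubbs' test needs n >= 3")
  s <- stats::sd(x)
  if (s == 0) stop("constant sample")
  dev <- abs(x - mean(x))
  i <- which.max(dev)
  G <- dev[i] / s
  tq <- stats::qt(1 - alpha / (2 * n), df = n - 2)
  G_crit <- (n - 1) / sqrt(n) * sqrt(tq^2 / (n - 2 + tq^2))
  flagged <- G > G_crit
  list(outlier_idx = if (flagged) i else NA_integer_,
       outlier_value = if (flagged) x[i] else NA_real_,
       G = G, G_crit = G_crit)
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. The exact null distribution is used when the
#' smaller sample has at most 8 observations and the data are tie-free;
#' otherwise the normal approximation with tie correction applies.
#'
#' @param a,b numeric samples (each n >= 1).
#' @return list with `U` (statistic for `a` relative to `b`), `p`,
#'   `method` ("exact" or "normal approximation").
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))   # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L) stop("empty sample")
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- min(length(a), length(b)) <= 8L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact)
  )
  list(U = unname(ht$statistic), p = ht$p.value,
       method = if (use_exact) "exact" else "normal approximation")
}

#' Mean and standard error of the mean
#'
#' @param x numeric sample (n >= 1).
#' @return list with `mean`, `sem` (`sd/sqrt(n)`; 0 with a warning for a
#'   single observation), `n`.
#' @export
summarize_mean_sem <- function(x) {
  n <- length(x)
  if (n < 1L) stop("empty sample")
  if (n == 1L) {
    warning("SEM of a single observation reported as 0")
    return(list(mean = x, sem = 0, n = 1L))
  }
  list(mean = mean(x), sem = stats::sd(x) / sqrt(n), n = n)
}
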