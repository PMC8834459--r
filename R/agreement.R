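#' Mean absolute error between paired series
#'
#' `MAE = (1/n) * sum(|dm_i - da_i|)` where `dm` are the reference (manual
#' digitisation) values and `da` the test (markerless) values.
#'
#' @param dm,da Equal-length numeric vectors, no missing values.
#' @return MAE in the input units.
#' @export
agreement_mae <- function(dm, da) {
  if (length(dm) != length(da)) abort("paired series lengths differ")
  if (length(dm) < 1 || anyNA(dm) || anyNA(da)) {
    abort("paired series must be non-empty with no missing values")
  }
  mean(abs(dm - da))
}

#' Cohen's d between two summarised groups
#'
#' Standardised mean difference `d = (Mm - Ma) / sqrt((sm^2 + sa^2) / 2)`
#' with the magnitude labelled trivial (|d| < 0.2), small (0.2-0.59),
#' moderate (0.6-1.19) or large (>= 1.2).
#'
#' @param Mm,Ma Group means (reference, test).
#' @param sm,sa Group standard deviations.
#' @return One-row tibble `d`, `label`.
#' @export
effect_size <- function(Mm, Ma, sm, sa) {
  if (sm < 0 || sa < 0) abort("standard deviations must be non-negative")
  if (sm^2 + sa^2 == 0) {
    warn("both standard deviations are zero: effect size undefined")
    return(tibble(d = NA_real_, label = "undefined"))
  }
  d <- (Mm - Ma) / sqrt((sm^2 + sa^2) / 2)
  tibble(d = d, label = effect_size_label(d))
}

effect_size_label <- function(d) {
  a <- abs(d)
  dplyr::case_when(a < 0.2 ~ "trivial", a < 0.6 ~ "small",
                   a < 1.2 ~ "moderate", TRUE ~ "large")
}

#' Cohen's d from paired samples
#'
#' Convenience wrapper of [effect_size()] on the sample means and standard
#' deviations of two vectors.
#'
#' @param x Reference sample, `y` test sample.
#' @param y See `x`.
#' @return One-row tibble `d`, `label`.
#' @export
effect_size_paired <- function(x, y) {
  effect_size(mean(x), mean(y), sd(x), sd(y))
}

#' Pointwise effect-size profile across normalized curves
#'
#' Computes Cohen's d at every point of the normalized grid (means and SDs
#' taken across trials, reference minus test) and summarises the profile by
#' its mean ("overall"), minimum and maximum.
#'
#' @param manual,automatic Numeric matrices, trials x grid points, same
#'   shape.
#' @return One-row tibble `overall`, `min`, `max` plus the pointwise `d`
#'   vector in column `profile` (list column).
#' @export
effect_size_profile <- function(manual, automatic) {
  manual <- as.matrix(manual); automatic <- as.matrix(automatic)
  if (!all(dim(manual) == dim(automatic))) abort("matrices must share shape")
  if (nrow(manual) < 2) abort("effect-size profile needs >= 2 trials (SD undefined)")
  Mm <- colMeans(manual); Ma <- colMeans(automatic)
  sm <- apply(manual, 2, sd); sa <- apply(automatic, 2, sd)
  pooled <- sqrt((sm^2 + sa^2) / 2)
  d <- (Mm - Ma) / pooled
  tibble(overall = mean(d), min = min(d), max = max(d), profile = list(d))
}

#' Pearson correlation with Fisher confidence interval and magnitude label
#'
#' Product-moment correlation with a 95% CI from the Fisher z transform
#' (`z +/- 1.96 / sqrt(n - 3)`, back-transformed) and a two-sided p-value
#' from `t = r sqrt((n-2)/(1-r^2))`. The magnitude of `|r|` is labelled
#' trivial (<0.1), small (0.1-0.3), moderate (0.3-0.5), large (0.5-0.7),
#' very large (0.7-0.9) or almost perfect (0.9-1.0); when the CI spans both
#' -0.1 and +0.1 the correlation is deemed `"unclear"`.
#'
#' @param x,y Paired numeric vectors, n >= 4, non-constant.
#' @param conf Confidence level (default 0.95).
#' @return One-row tibble `r`, `ci_lo`, `ci_hi`, `ci_half_width`, `p`,
#'   `label`, `n`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  n <- length(x)
  if (n != length(y)) abort("paired series lengths differ")
  if (n < 4) abort("correlation needs n >= 4")
  if (sd(x) == 0 || sd(y) == 0) abort("constant input: correlation undefined")
  r <- cor(x, y)
  zc <- qnorm(1 - (1 - conf) / 2)
  if (abs(r) >= 1) {
    lo <- hi <- r
    p <- 0
  } else {
    z <- atanh(r)
    lo <- tanh(z - zc / sqrt(n - 3))
    hi <- tanh(z + zc / sqrt(n - 3))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  label <- correlation_label(r)
  if (lo < -0.1 && hi > 0.1) label <- "unclear"
  tibble(r = r, ci_lo = lo, ci_hi = hi, ci_half_width = (hi - lo) / 2,
         p = p, label = label, n = n)
}

correlation_label <- function(r) {
  a <- abs(r)
  dplyr::case_when(a <= 0.1 ~ "trivial", a <= 0.3 ~ "small",
                   a <= 0.5 ~ "moderate", a <= 0.7 ~ "large",
                   a <= 0.9 ~ "very large", TRUE ~ "almost perfect")
}

#' Shared variance (r squared) with magnitude label
#'
#' Square of the Pearson correlation, labelled small (r2 <= 0.30), moderate
#' (0.3-0.5) or large (> 0.50).
#'
#' @inheritParams pearson_with_ci
#' @return One-row tibble `r2`, `label`, `p`.
#' @export
shared_variance <- function(x, y) {
  pr <- pearson_with_ci(x, y)
  r2 <- pr$r^2
  label <- dplyr::case_when(r2 <= 0.3 ~ "small", r2 <= 0.5 ~ "moderate",
                            TRUE ~ "large")
  tibble(r2 = r2, label = label, p = pr$p)
}

#' Intraclass correlation ICC(2,1)
#'
#' Two-way random-effects, absolute-agreement, single-measures intraclass
#' correlation between two raters/methods, estimated from the two-way ANOVA
#' mean squares, with the F-test `MSR / MSE` for the null of no subject
#' effect.
#'
#' @param x,y Paired numeric vectors (the two methods), n >= 5.
#' @return One-row tibble `icc`, `F`, `df1`, `df2`, `p`.
#' @export
icc21 <- function(x, y) {
  n <- length(x)
  if (n != length(y)) abort("paired series lengths differ")
  if (n < 5) abort("ICC needs >= 5 pairs")
  k <- 2
  dat <- cbind(x, y)
  grand <- mean(dat)
  row_m <- rowMeans(dat)
  col_m <- colMeans(dat)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((dat - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr == 0 && mse == 0) {
    warn("degenerate variance: ICC undefined")
    return(tibble(icc = NA_real_, F = NA_real_, df1 = n - 1,
                  df2 = (n - 1) * (k - 1), p = NA_real_))
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  Fv <- msr / mse
  p <- pf(Fv, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  tibble(icc = icc, F = Fv, df1 = n - 1, df2 = (n - 1) * (k - 1), p = p)
}

#' Ratio limits of agreement
#'
#' Bland-Altman agreement on the multiplicative scale: per-pair ratios
#' `q_i = y_i / x_i` are log-transformed; the geometric mean ratio
#' `exp(mean(log q))` measures systematic bias and the agreement factor
#' `exp(1.96 * sd(log q))` the random error, reported in the
#' "ratio x / / factor" form (a value of `1.0 x/÷ 1.0` means identical
#' methods).
#'
#' @param x Reference values (strictly positive).
#' @param y Test values (strictly positive).
#' @return One-row tibble `ratio`, `factor`, `loa_lo`, `loa_hi`, `label`.
#' @export
rloa <- function(x, y) {
  if (length(x) != length(y)) abort("paired series lengths differ")
  bad <- which(x <= 0 | y <= 0)
  if (length(bad) > 0) {
    abort(sprintf("ratio limits of agreement need strictly positive values; offending pairs: %s",
                  paste(head(bad, 10), collapse = ", ")))
  }
  lq <- log(y / x)
  gm <- exp(mean(lq))
  fac <- exp(1.96 * sd(lq))
  tibble(ratio = gm, factor = fac, loa_lo = gm / fac, loa_hi = gm * fac,
         label = sprintf("%.3f ×/÷ %.3f", gm, fac))
}
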