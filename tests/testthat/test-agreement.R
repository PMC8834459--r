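# brute-force loop oracles, kept deliberately naive
oracle_mae <- function(a, b) {
  s <- 0
  for (i in seq_along(a)) s <- s + abs(a[i] - b[i])
  s / length(a)
}
oracle_d <- function(x, y) {
  (mean(x) - mean(y)) / sqrt((sd(x)^2 + sd(y)^2) / 2)
}
oracle_r <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_along(x)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}
oracle_rloa <- function(x, y) {
  lq <- log(y) - log(x)
  c(exp(mean(lq)), exp(1.96 * sd(lq)))
}
oracle_icc21 <- function(x, y) {
  # two-way ANOVA mean squares via stats::aov on the long layout
  n <- length(x)
  long <- data.frame(score = c(x, y),
                     subject = factor(rep(seq_len(n), 2)),
                     rater = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(score ~ subject + rater, data = long))[[1]]
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["rater", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  (msr - mse) / (msr + mse + 2 * (msc - mse) / n)
}

test_that("MAE matches the definition and the loop oracle", {
  expect_equal(agreement_mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(agreement_mae(c(1, 2, 3), c(2, 2, 1)), 1)
  expect_error(agreement_mae(1:3, 1:4), "lengths differ")

  set.seed(101)
  for (rep in 1:20) {
    a <- rnorm(1000); b <- rnorm(1000)
    expect_equal(agreement_mae(a, b), oracle_mae(a, b), tolerance = 1e-12)
  }
})

test_that("effect size follows the pooled-SD formula and taxonomy", {
  expect_equal(effect_size(3, 3, 1, 2)$d, 0)
  expect_equal(effect_size(3, 3, 1, 2)$label, "trivial")
  es <- effect_size(1, 0, 1, 1)
  expect_equal(es$d, 1)
  expect_equal(es$label, "moderate")
  es2 <- effect_size(2, 1, 1, 2)
  expect_equal(es2$d, 1 / sqrt(2.5), tolerance = 1e-12)
  expect_equal(es2$label, "moderate")

  expect_equal(effect_size(0.1, 0, 1, 1)$label, "trivial")
  expect_equal(effect_size(0.4, 0, 1, 1)$label, "small")
  expect_equal(effect_size(-1.5, 0, 1, 1)$label, "large")
  expect_warning(out <- effect_size(1, 2, 0, 0), "zero")
  expect_true(is.na(out$d))
})

test_that("effect-size profiles match the pointwise loop oracle", {
  m <- matrix(rnorm(30 * 101), 30, 101)
  expect_equal(effect_size_profile(m, m)$overall, 0)
  expect_equal(effect_size_profile(m, m)$min, 0)

  # constant shift with unit per-point SDs gives d = -c everywhere
  set.seed(55)
  base <- matrix(rnorm(40 * 101), 40, 101)
  base <- apply(base, 2, function(col) (col - mean(col)) / sd(col))
  shifted <- base + 0.8
  prof <- effect_size_profile(base, shifted)
  expect_equal(prof$overall, -0.8, tolerance = 1e-10)
  expect_equal(prof$min, -0.8, tolerance = 1e-10)
  expect_equal(prof$max, -0.8, tolerance = 1e-10)

  a <- matrix(rnorm(30 * 101), 30, 101)
  b <- matrix(rnorm(30 * 101, 0.2), 30, 101)
  prof2 <- effect_size_profile(a, b)
  d_loop <- vapply(1:101, function(j) oracle_d(a[, j], b[, j]), numeric(1))
  expect_equal(prof2$profile[[1]], d_loop, tolerance = 1e-12)
  expect_equal(prof2$overall, mean(d_loop), tolerance = 1e-12)

  expect_error(effect_size_profile(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               ">= 2 trials")
})

test_that("Pearson r carries Fisher CI, p and magnitude labels", {
  x <- seq_len(30)
  pr <- pearson_with_ci(x, x * 2 + 3)
  expect_equal(pr$r, 1)
  expect_equal(pr$label, "almost perfect")

  set.seed(77)
  for (rep in 1:50) {
    x <- rnorm(40); y <- 0.5 * x + rnorm(40)
    pr <- pearson_with_ci(x, y)
    ct <- stats::cor.test(x, y)
    expect_equal(pr$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(pr$p, ct$p.value, tolerance = 1e-10)
    expect_equal(pr$r, oracle_r(x, y), tolerance = 1e-12)
    z <- atanh(pr$r)
    expect_equal(pr$ci_lo, tanh(z - qnorm(0.975) / sqrt(37)),
                 tolerance = 1e-10)
  }

  # a weak correlation whose CI spans -0.1 and +0.1 is unclear
  set.seed(3)
  repeat {
    x <- rnorm(30); y <- rnorm(30)
    r <- cor(x, y)
    if (abs(r) < 0.05) break
  }
  expect_equal(pearson_with_ci(x, y)$label, "unclear")

  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_with_ci(1:3, 1:3), "n >= 4")
})

test_that("correlation magnitude taxonomy cuts at the stated bounds", {
  labels <- vapply(c(0.05, 0.2, 0.4, 0.6, 0.8, 0.95),
                   kinekick:::correlation_label, character(1))
  expect_equal(labels, c("trivial", "small", "moderate", "large",
                         "very large", "almost perfect"))
})

test_that("shared variance squares r with its own taxonomy", {
  x <- rnorm(30)
  expect_equal(shared_variance(x, x)$r2, 1)
  expect_equal(shared_variance(x, x)$label, "large")
  set.seed(12)
  for (rep in 1:20) {
    a <- rnorm(25); b <- rnorm(25) + 0.4 * a
    expect_equal(shared_variance(a, b)$r2, pearson_with_ci(a, b)$r^2,
                 tolerance = 1e-15)
  }
})

test_that("ICC(2,1) matches the ANOVA oracle and penalises bias", {
  x <- rnorm(50)
  expect_equal(icc21(x, x)$icc, 1)

  set.seed(42)
  for (rep in 1:50) {
    a <- rnorm(30); b <- 0.7 * a + rnorm(30, sd = 0.5)
    expect_equal(icc21(a, b)$icc, oracle_icc21(a, b), tolerance = 1e-10)
  }

  a <- rnorm(100)
  b <- a + 5  # large constant bias
  expect_lt(icc21(a, b)$icc, 0.2)
  expect_gt(pearson_with_ci(a, b)$r, 0.99)

  expect_error(icc21(1:4, 2:5), ">= 5")
})

test_that("ICC recovers a known intraclass correlation in simulation", {
  set.seed(2024)
  rho <- 0.5
  n <- 200
  subj <- rnorm(n, sd = sqrt(rho))
  x <- subj + rnorm(n, sd = sqrt(1 - rho))
  y <- subj + rnorm(n, sd = sqrt(1 - rho))
  expect_lt(abs(icc21(x, y)$icc - rho), 0.15)
})

test_that("ratio limits of agreement follow the log-normal model", {
  x <- c(10, 20, 30, 40)
  r1 <- rloa(x, x)
  expect_equal(r1$ratio, 1)
  expect_equal(r1$factor, 1)
  r2 <- rloa(x, 2 * x)
  expect_equal(r2$ratio, 2)
  expect_equal(r2$factor, 1)
  expect_match(r2$label, "2.000 ×/÷ 1.000")

  set.seed(88)
  for (rep in 1:20) {
    a <- exp(rnorm(200, 2)); b <- a * exp(rnorm(200, 0, 0.2))
    expect_equal(unlist(rloa(a, b)[, c("ratio", "factor")], use.names = FALSE),
                 oracle_rloa(a, b), tolerance = 1e-12)
  }

  big <- exp(rnorm(10000, 0, 1))
  ratios <- exp(rnorm(10000, 0, 0.1))
  rl <- rloa(big, big * ratios)
  expect_lt(abs(rl$factor - exp(1.96 * 0.1)) / exp(1.96 * 0.1), 0.01)

  expect_error(rloa(c(1, -2, 3), c(1, 2, 3)), "strictly positive")
})
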