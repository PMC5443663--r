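# Circular statistics: each test is validated against an independent
# from-definition oracle and a permutation/simulation reference.

# Independent Watson U2 oracle: plain loop over the pooled observations,
# computing the two empirical CDFs at each point (ties averaged over the
# tied block) and the weighted variance of their difference.
watson_u2_oracle <- function(a, b) {
  u1 <- (a %% 360) / 360
  u2 <- (b %% 360) / 360
  n <- length(u1); m <- length(u2); N <- n + m
  pooled <- sort(c(u1, u2))
  d <- vapply(pooled, function(v) mean(u1 <= v) - mean(u2 <= v), numeric(1))
  (n * m) / N^2 * (sum(d^2) - sum(d)^2 / N)
}

test_that("watson U2 agrees with the from-definition oracle", {
  set.seed(17)
  for (i in 1:10) {
    a <- runif_deg(sample(5:12, 1))
    b <- runif_deg(sample(5:12, 1))
    expect_equal(unname(watson_u2(a, b)$statistic),
                 watson_u2_oracle(a, b), tolerance = 1e-12)
  }
  # identical samples: minimal statistic, large p
  a <- c(10, 40, 95, 200, 310)
  r <- watson_u2(a, a)
  expect_equal(unname(r$statistic), 0, tolerance = 1e-12)
  expect_gt(r$p_value, 0.5)
  expect_error(watson_u2(1:3, 1:10), "n >= 4")
})

test_that("watson U2 asymptotic p matches the published critical points", {
  # the 5% critical value of the asymptotic distribution is ~0.187, and a
  # statistic of 0.256 sits near p = 0.01
  expect_equal(ormiasrm:::watson_u2_pval(0.187), 0.05, tolerance = 0.01)
  expect_equal(ormiasrm:::watson_u2_pval(0.256), 0.0128, tolerance = 0.02)
})

test_that("watson U2 p-values track an independent permutation oracle", {
  # Monte-Carlo permutation oracle built on the from-definition statistic
  perm_oracle_p <- function(a, b, nsim = 1500) {
    obs <- watson_u2_oracle(a, b)
    pooled <- c(a, b)
    n <- length(a)
    hits <- vapply(seq_len(nsim), function(i) {
      idx <- sample(length(pooled), n)
      watson_u2_oracle(pooled[idx], pooled[-idx]) >= obs - 1e-12
    }, logical(1))
    mean(hits)
  }
  set.seed(23)
  for (i in 1:5) {
    a <- runif_deg(6)
    b <- wrap_deg(runif_deg(6) + 40 * (i %% 2))
    pa <- watson_u2(a, b)$p_value      # exact enumeration at this size
    pp <- perm_oracle_p(a, b)
    expect_lt(abs(pa - pp), 0.05)
  }
  # rank correlation of default and Monte-Carlo permutation p-values
  # across 100 random datasets
  ps <- t(vapply(1:100, function(i) {
    a <- rnorm_deg(8, 0, 40)
    b <- rnorm_deg(8, runif(1, 0, 60), 40)
    c(watson_u2(a, b)$p_value,
      watson_u2(a, b, p_method = "permutation", n_perm = 400,
                seed = i)$p_value)
  }, numeric(2)))
  expect_gt(cor(ps[, 1], ps[, 2], method = "spearman"), 0.95)
})

test_that("watson-williams matches linear ANOVA at small dispersion", {
  set.seed(3)
  a <- rnorm(12, 5, 0.4)   # degrees; tiny spread on the circle
  b <- rnorm(12, 5.6, 0.4)
  ww <- watson_williams(a, b)
  lin <- summary(stats::aov(c(a, b) ~ factor(rep(1:2, each = 12))))[[1]]
  expect_equal(unname(ww$statistic), lin$`F value`[1], tolerance = 0.01)
  expect_equal(ww$df, c(1, 22))
  # identical samples: F ~ 0
  expect_lt(unname(watson_williams(a, a)$statistic), 1e-10)
  # low concentration warns but still returns
  expect_warning(r <- watson_williams(runif_deg(20), runif_deg(20)),
                 "0.7")
  expect_true(is.finite(r$p_value))
})

test_that("paired hotelling handles identical, rotated, and noisy pairs", {
  a <- c(10, 50, 100, 200, 300, 340)
  expect_equal(unname(hotelling_paired(a, a)$statistic), 0)
  expect_equal(hotelling_paired(a, a)$p_value, 1)
  # exact rotation with zero variance: singular-covariance path, p -> 0
  r <- hotelling_paired(rep(30, 6), rep(40, 6))
  expect_equal(r$p_value, 0)
  # consistent rotation of concentrated headings is detected
  set.seed(9)
  ac <- rnorm_deg(10, 15, 12)
  b <- wrap_deg(ac + 25 + rnorm(10, sd = 4))
  expect_lt(hotelling_paired(ac, b)$p_value, 0.05)
  expect_error(hotelling_paired(c(1, 2), c(3, 4)), "3 pairs")
})

test_that("harrison-kanji detects the factor that rotates the data", {
  set.seed(41)
  fa <- rep(1:2, each = 30)
  fb <- rep(rep(1:3, each = 10), 2)
  ang <- rnorm_deg(60, 0, 15) + ifelse(fa == 2, 40, 0)
  r <- circular_anova_hk(ang, fa, fb)
  expect_equal(r$table$effect, c("A", "B", "interaction"))
  expect_lt(r$table$p_value[1], 0.001)
  expect_gt(r$table$p_value[2], 0.05)
  # all cells identical: no effects
  same <- rep(c(10, 30), 30)
  r0 <- circular_anova_hk(same, rep(1:2, each = 30), rep(rep(1:3, each = 10), 2))
  expect_true(all(r0$table$p_value > 0.99))
  expect_error(circular_anova_hk(1:10, rep(1, 10), rep(1:2, 5)), "levels")
})

test_that("all tests are invariant to rotation and angle units", {
  set.seed(53)
  a <- rnorm_deg(10, 20, 30)
  b <- rnorm_deg(10, 50, 30)
  rot <- 123.4
  expect_equal(watson_u2(a, b)$statistic,
               watson_u2(wrap_deg(a + rot), wrap_deg(b + rot))$statistic,
               tolerance = 1e-10)
  expect_equal(watson_williams(a, b)$statistic,
               watson_williams(wrap_deg(a + rot), wrap_deg(b + rot))$statistic,
               tolerance = 1e-10)
  expect_equal(hotelling_paired(a, b)$statistic,
               hotelling_paired(wrap_deg(a + rot), wrap_deg(b + rot))$statistic,
               tolerance = 1e-10)
  ang <- c(a, b); fa <- rep(1:2, each = 10); fb <- rep(rep(1:2, each = 5), 2)
  expect_equal(circular_anova_hk(ang, fa, fb)$table$statistic,
               circular_anova_hk(wrap_deg(ang + rot), fa, fb)$table$statistic,
               tolerance = 1e-10)
  # degrees vs radians with correct declaration
  expect_equal(watson_u2(a, b)$statistic,
               watson_u2(a * pi / 180, b * pi / 180,
                         degrees = FALSE)$statistic, tolerance = 1e-10)
  expect_equal(watson_williams(a, b)$statistic,
               watson_williams(a * pi / 180, b * pi / 180,
                               degrees = FALSE)$statistic, tolerance = 1e-10)
})

test_that("circular descriptive statistics behave on wrapped data", {
  expect_equal(circ_mean_deg(c(350, 10)), 0, tolerance = 1e-9)
  expect_equal(circ_mean_deg(c(170, -170)), 180, tolerance = 1e-9)
  expect_equal(circ_r(c(45, 45, 45)), 1, tolerance = 1e-12)
  expect_lt(circ_sem_deg(rep(c(10, 12), 20)), 1)
  expect_equal(wrap_deg(c(190, -190, 540)), c(-170, 170, 180))
})
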