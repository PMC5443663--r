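# Circular statistics for angular headings: descriptive circular mean /
# SEM, the two-sample Watson U2 test, the Watson-Williams F test, the
# paired Hotelling (second-order) test, and the Harrison-Kanji two-factor
# circular ANOVA. Angles are degrees throughout unless `degrees = FALSE`.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Wrap angles to (-180, 180]
#'
#' @param x Angles in degrees.
#' @return Equivalent angles in (-180, 180].
#' @export
wrap_deg <- function(x) {
  y <- (x + 180) %% 360 - 180
  y[y == -180] <- 180
  y
}

#' Circular mean of angles in degrees
#'
#' @param x Angles in degrees.
#' @return Circular mean in (-180, 180].
#' @export
circ_mean_deg <- function(x) {
  a <- deg2rad(x)
  wrap_deg(rad2deg(atan2(mean(sin(a)), mean(cos(a)))))
}

#' Mean resultant length
#'
#' @param x Angles in degrees.
#' @return R-bar in [0, 1].
#' @export
circ_r <- function(x) {
  a <- deg2rad(x)
  sqrt(mean(sin(a))^2 + mean(cos(a))^2)
}

#' Circular standard error of the mean, in degrees
#'
#' Uses the circular standard deviation sqrt(-2 log R-bar) divided by
#' sqrt(n); reported for heading summaries as "mean +/- SEM".
#'
#' @param x Angles in degrees.
#' @return Circular SEM in degrees.
#' @export
circ_sem_deg <- function(x) {
  rbar <- min(circ_r(x), 1 - 1e-12)
  rad2deg(sqrt(-2 * log(rbar)) / sqrt(length(x)))
}

# von Mises A1(kappa) = I1/I0 (mean resultant length at concentration kappa)
vm_a1 <- function(kappa) {
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)
}

# Standard approximate ML estimate of the von Mises concentration from the
# mean resultant length, with the usual small-sample correction.
est_kappa <- function(rbar, n = Inf) {
  kappa <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  if (is.finite(n) && n <= 15) {
    kappa <- if (kappa < 2) max(kappa - 2 / (n * kappa), 0)
             else kappa * (n - 1)^3 / (n^3 + n)
  }
  kappa
}

as_circ_frac <- function(x, degrees) {
  if (degrees) (x %% 360) / 360 else (x %% (2 * pi)) / (2 * pi)
}

# Two-sample Watson U2 statistic on circular fractions in [0, 1).
# Ties are handled by processing tied values as one block, which gives the
# mid-rank convention on the pooled cumulative fractions.
watson_u2_stat <- function(u1, u2) {
  n <- length(u1)
  m <- length(u2)
  N <- n + m
  vals <- sort(unique(c(u1, u2)))
  c1 <- cumsum(tabulate(match(sort(u1), vals), nbins = length(vals)))
  c2 <- cumsum(tabulate(match(sort(u2), vals), nbins = length(vals)))
  mult <- tabulate(match(c(u1, u2), vals), nbins = length(vals))
  d <- c1 / n - c2 / m
  sum_d <- sum(mult * d)
  sum_d2 <- sum(mult * d^2)
  (n * m) / N^2 * (sum_d2 - sum_d^2 / N)
}

# Asymptotic upper tail of the Watson U2 distribution.
watson_u2_pval <- function(u, kmax = 100) {
  if (u <= 0) return(1)
  k <- seq_len(kmax)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * pi^2 * u))
  min(max(p, 0), 1)
}

#' Two-sample Watson U2 test
#'
#' Nonparametric comparison of two samples of circular data, invariant to
#' the choice of origin. The statistic is computed on the pooled cumulative
#' fractions (ties by mid-ranks). By default the p-value is exact (full
#' enumeration of label assignments) when the samples are small enough,
#' since the asymptotic series is noticeably anti-conservative there, and
#' the standard asymptotic series otherwise.
#'
#' @param a,b Angle samples (degrees by default), each of size >= 4.
#' @param degrees Interpret angles as degrees (default) or radians.
#' @param p_method `"auto"` (default: exact enumeration when
#'   `choose(n1+n2, n1) <= 20000`, asymptotic otherwise), `"asymptotic"`,
#'   or `"permutation"` (Monte-Carlo).
#' @param n_perm Number of random permutations for `"permutation"`
#'   (exhaustive enumeration is used instead when there are fewer distinct
#'   assignments).
#' @param seed Optional seed for the Monte-Carlo permutation draw.
#' @return An object of class `circ_test` with `statistic` (U2), `p_value`,
#'   `n`, and `method`.
#' @export
watson_u2 <- function(a, b, degrees = TRUE,
                      p_method = c("auto", "asymptotic", "permutation"),
                      n_perm = 1999, seed = NULL) {
  p_method <- match.arg(p_method)
  if (length(a) < 4 || length(b) < 4)
    stop("watson_u2: each sample needs n >= 4")
  u1 <- as_circ_frac(a, degrees)
  u2 <- as_circ_frac(b, degrees)
  u2stat <- watson_u2_stat(u1, u2)
  pooled <- c(u1, u2)
  n <- length(u1)
  N <- length(pooled)
  exact_p <- function() {
    combs <- utils::combn(N, n)
    stats_perm <- apply(combs, 2, function(idx)
      watson_u2_stat(pooled[idx], pooled[-idx]))
    mean(stats_perm >= u2stat - 1e-12)
  }
  if (p_method == "auto")
    p_method <- if (choose(N, n) <= 20000) "exact" else "asymptotic"
  p <- switch(p_method,
    asymptotic = watson_u2_pval(u2stat),
    exact = exact_p(),
    permutation = {
      if (choose(N, n) <= n_perm) {
        exact_p()
      } else {
        stats_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
          idx <- sample.int(N, n)
          watson_u2_stat(pooled[idx], pooled[-idx])
        }, numeric(1)))
        (1 + sum(stats_perm >= u2stat - 1e-12)) / (n_perm + 1)
      }
    })
  structure(list(statistic = c(U2 = u2stat), p_value = p,
                 n = c(n1 = length(a), n2 = length(b)),
                 method = paste0("Watson two-sample U2 (", p_method, ")")),
            class = "circ_test")
}

#' Watson-Williams test for equality of two circular means
#'
#' The classic high-concentration F test with the 1 + 3/(8 kappa)
#' correction factor. Valid for reasonably concentrated samples; a
#' `low_concentration` flag is set (with a warning) when the pooled mean
#' resultant length is below 0.7, and the result is still returned.
#'
#' @param a,b Angle samples (degrees by default).
#' @param degrees Interpret angles as degrees (default) or radians.
#' @return A `circ_test` with `statistic` (F), `df`, `p_value`, and
#'   `low_concentration`.
#' @export
watson_williams <- function(a, b, degrees = TRUE) {
  if (!degrees) { a <- rad2deg(a); b <- rad2deg(b) }
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  if (n1 < 2 || n2 < 2) stop("watson_williams: each sample needs n >= 2")
  R1 <- n1 * circ_r(a)
  R2 <- n2 * circ_r(b)
  R <- N * circ_r(c(a, b))
  rbar_w <- (R1 + R2) / N
  low <- rbar_w < 0.7
  if (low)
    warning("watson_williams: pooled resultant < 0.7; ",
            "high-concentration approximation may be inaccurate")
  kappa <- est_kappa(rbar_w, N)
  g <- 1 + 3 / (8 * kappa)
  Fstat <- g * (N - 2) * (R1 + R2 - R) / (N - R1 - R2)
  p <- stats::pf(Fstat, 1, N - 2, lower.tail = FALSE)
  structure(list(statistic = c(F = Fstat), df = c(1, N - 2), p_value = p,
                 n = c(n1 = n1, n2 = n2), kappa = kappa,
                 low_concentration = low,
                 method = "Watson-Williams F test"),
            class = "circ_test")
}

#' Paired Hotelling test for angular data
#'
#' Second-order paired analysis: each subject contributes the difference of
#' its two unit vectors (cos, sin); the bivariate mean difference is tested
#' against zero with a one-sample Hotelling T2, converted to an F with
#' (2, n - 2) degrees of freedom.
#'
#' @param a,b Paired angle samples (degrees by default), same length n >= 3.
#' @param degrees Interpret angles as degrees (default) or radians.
#' @return A `circ_test` with `statistic` (F), `df`, and `p_value`.
#'   Degenerate zero-variance differences give F = 0 / p = 1 when the mean
#'   difference is zero and F = Inf / p = 0 otherwise.
#' @export
hotelling_paired <- function(a, b, degrees = TRUE) {
  if (length(a) != length(b)) stop("hotelling_paired: samples must be paired")
  n <- length(a)
  if (n < 3) stop("hotelling_paired: need at least 3 pairs")
  if (degrees) { a <- deg2rad(a); b <- deg2rad(b) }
  d <- cbind(cos(a) - cos(b), sin(a) - sin(b))
  m <- colMeans(d)
  S <- stats::cov(d)
  if (rcond_2x2(S) < 1e-12) {
    if (sum(m^2) < 1e-20)
      return(structure(list(statistic = c(F = 0), df = c(2, n - 2),
                            p_value = 1, n = n,
                            method = "paired Hotelling test (degenerate)"),
                       class = "circ_test"))
    return(structure(list(statistic = c(F = Inf), df = c(2, n - 2),
                          p_value = 0, n = n,
                          method = "paired Hotelling test (degenerate)"),
                     class = "circ_test"))
  }
  T2 <- n * drop(crossprod(m, solve(S, m)))
  Fstat <- (n - 2) / (2 * (n - 1)) * T2
  p <- stats::pf(Fstat, 2, n - 2, lower.tail = FALSE)
  structure(list(statistic = c(F = Fstat), df = c(2, n - 2), p_value = p,
                 n = n, method = "paired Hotelling test"),
            class = "circ_test")
}

rcond_2x2 <- function(S) {
  e <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (max(abs(e)) == 0) 0 else min(abs(e)) / max(abs(e))
}

#' Harrison-Kanji two-factor ANOVA for circular data
#'
#' Two-way analysis of angular observations via resultant-length
#' decompositions. With high pooled concentration (kappa > 2) the main
#' effects and interaction are tested with F ratios against the residual
#' (with the 1 + 3/(8 kappa) correction); otherwise chi-squared
#' approximations with 2*(levels - 1) style degrees of freedom are used.
#' Repeated measurements across factors are treated as independent groups.
#'
#' @param angles Angle observations (degrees by default).
#' @param factor_a,factor_b Factor labels, one per observation; no cell may
#'   be empty.
#' @param degrees Interpret angles as degrees (default) or radians.
#' @return An object of class `circ_anova`: a data.frame `table` with one
#'   row per effect (A, B, interaction) holding the statistic, df, and
#'   p-value, plus the pooled `kappa` and the approximation used.
#' @export
circular_anova_hk <- function(angles, factor_a, factor_b, degrees = TRUE) {
  if (!degrees) angles <- rad2deg(angles)
  fa <- factor(factor_a)
  fb <- factor(factor_b)
  stopifnot(length(angles) == length(fa), length(angles) == length(fb))
  if (nlevels(fa) < 2 || nlevels(fb) < 2)
    stop("circular_anova_hk: each factor needs at least 2 levels")
  if (any(table(fa, fb) == 0))
    stop("circular_anova_hk: design has empty cells")
  p <- nlevels(fa); q <- nlevels(fb); N <- length(angles)
  res_len <- function(x) length(x) * circ_r(x)
  Rtot <- res_len(angles)
  Ra <- vapply(split(angles, fa), res_len, numeric(1))
  na <- as.numeric(table(fa))
  Rb <- vapply(split(angles, fb), res_len, numeric(1))
  nb <- as.numeric(table(fb))
  cell <- split(angles, interaction(fa, fb, drop = FALSE))
  Rc <- vapply(cell, res_len, numeric(1))
  nc <- vapply(cell, length, numeric(1))
  qa <- sum(Ra^2 / na) - Rtot^2 / N
  qb <- sum(Rb^2 / nb) - Rtot^2 / N
  qc <- sum(Rc^2 / nc) - Rtot^2 / N
  qi <- qc - qa - qb
  kappa <- est_kappa(circ_r(angles), N)
  if (kappa > 2) {
    corr <- 1 + 3 / (8 * kappa)
    ss_res <- N - sum(Rc^2 / nc)
    df_res <- N - p * q
    ms_res <- ss_res / df_res
    eff <- function(ss, df) {
      Fv <- corr * (ss / df) / ms_res
      c(Fv, df, stats::pf(Fv, df, df_res, lower.tail = FALSE))
    }
    ta <- eff(qa, p - 1); tb <- eff(qb, q - 1); ti <- eff(qi, (p - 1) * (q - 1))
    tab <- data.frame(effect = c("A", "B", "interaction"),
                      statistic = c(ta[1], tb[1], ti[1]),
                      df1 = c(ta[2], tb[2], ti[2]),
                      df2 = df_res,
                      p_value = c(ta[3], tb[3], ti[3]))
    approx_used <- "high-concentration F"
  } else {
    rr <- vm_a1(kappa)
    f <- 2 / (1 - rr^2)
    eff <- function(ss, df) {
      x <- f * ss
      c(x, df, stats::pchisq(x, df, lower.tail = FALSE))
    }
    ta <- eff(qa, 2 * (p - 1))
    tb <- eff(qb, 2 * (q - 1))
    ti <- eff(qi, 2 * (p - 1) * (q - 1))
    tab <- data.frame(effect = c("A", "B", "interaction"),
                      statistic = c(ta[1], tb[1], ti[1]),
                      df1 = c(ta[2], tb[2], ti[2]),
                      df2 = NA_real_,
                      p_value = c(ta[3], tb[3], ti[3]))
    approx_used <- "low-concentration chi-squared"
  }
  structure(list(table = tab, kappa = kappa, approximation = approx_used,
                 n = N, levels = c(A = p, B = q)),
            class = "circ_anova")
}

#' @export
print.circ_anova <- function(x, ...) {
  cat(sprintf("Harrison-Kanji two-factor circular ANOVA (%s; n = %d, kappa = %.3g)\n",
              x$approximation, x$n, x$kappa))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
print.circ_test <- function(x, ...) {
  cat(sprintf("%s: %s = %.4g", x$method, names(x$statistic)[1], x$statistic[1]))
  if (!is.null(x$df)) cat(sprintf(", df = (%s)", paste(x$df, collapse = ", ")))
  cat(sprintf(", p = %.4g\n", x$p_value))
  invisible(x)
}
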