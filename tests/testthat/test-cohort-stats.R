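test_that("paired t-test matches the from-scratch formula oracle", {
  set.seed(21)
  pre <- rnorm(6, 5, 1); post <- rnorm(6, 6, 1)
  got <- paired_test(pre, post)
  d <- post - pre
  n <- length(d)
  t_oracle <- mean(d) / (sd(d) / sqrt(n))
  # two-sided p by numerical integration of the t density
  dens <- function(x) {
    gamma((n) / 2) / (sqrt((n - 1) * pi) * gamma((n - 1) / 2)) *
      (1 + x^2 / (n - 1))^(-n / 2)
  }
  p_oracle <- 2 * stats::integrate(dens, abs(t_oracle), Inf,
                                   rel.tol = 1e-12)$value
  expect_equal(got$statistic, t_oracle, tolerance = 1e-8)
  expect_equal(got$p, p_oracle, tolerance = 1e-8)
  expect_false(got$degenerate)
})

test_that("paired t-test flags degenerate inputs", {
  x <- c(4, 5, 6, 7)
  same <- paired_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_true(same$degenerate)
  shifted <- paired_test(x, x + 2)
  expect_true(is.infinite(shifted$statistic) && shifted$statistic > 0)
  expect_true(shifted$degenerate)
  expect_error(paired_test(1:4, 1:5), "paired")
  expect_error(paired_test(1:2, 3:4), "at least 3")
})

test_that("Grubbs exclusion flags gross outliers and nothing else", {
  expect_identical(grubbs_outliers(c(5, 5, 5, 5)), integer(0))

  x <- c(5.1, 4.9, 5.0, 50.0)
  # oracle: G statistic against the t-based critical value
  G <- max(abs(x - mean(x))) / sd(x)
  n <- 4
  tc <- qt(1 - 0.05 / (2 * n), n - 2)
  Gcrit <- (n - 1) / sqrt(n) * sqrt(tc^2 / (n - 2 + tc^2))
  expect_gt(G, Gcrit)     # the oracle agrees there is an outlier
  expect_identical(grubbs_outliers(x), 4L)

  # permutation equivariance of the flag set
  set.seed(13)
  y <- c(rnorm(8), 12, rnorm(3))
  perm <- sample(length(y))
  f1 <- sort(perm[grubbs_outliers(y[perm])])
  expect_identical(f1, sort(grubbs_outliers(y)))
  expect_error(grubbs_outliers(c(1, 2)), "at least 3")
})

test_that("Kruskal-Wallis matches the tie-corrected rank formula oracle", {
  g1 <- c(3, 3, 3); g2 <- c(3, 3, 3)
  same <- kruskal_wallis(list(g1, g2))
  expect_equal(same$H, 0)
  expect_true(same$degenerate)

  set.seed(31)
  groups <- list(rnorm(5), rnorm(4, 1), c(2, 2, rnorm(4, 2)))
  got <- kruskal_wallis(groups)
  # from-scratch tie-corrected H
  x <- unlist(groups); n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  H <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (n^3 - n))
  expect_equal(got$H, H, tolerance = 1e-10)
  # chi-square survival oracle by numerical integration
  k <- length(groups)
  dens <- function(y) y^((k - 1) / 2 - 1) * exp(-y / 2) /
    (2^((k - 1) / 2) * gamma((k - 1) / 2))
  p_oracle <- stats::integrate(dens, H, Inf, rel.tol = 1e-12)$value
  expect_equal(got$p, p_oracle, tolerance = 1e-8)
})

test_that("two-way ANOVA reproduces the balanced sums-of-squares oracle", {
  set.seed(41)
  d <- expand.grid(sex = c("m", "f"), time = c("t0", "t1", "t2"),
                   rep = 1:4)
  d$y <- rnorm(nrow(d), mean = as.numeric(d$sex) + as.numeric(d$time))
  got <- two_way_anova(d, "y", c("sex", "time"))

  # classical SS decomposition (balanced, so Type II = textbook formulas)
  a <- factor(d$sex); b <- factor(d$time); y <- d$y
  gm <- mean(y)
  na <- nlevels(a); nb <- nlevels(b); r <- 4
  ssa <- r * nb * sum((tapply(y, a, mean) - gm)^2)
  ssb <- r * na * sum((tapply(y, b, mean) - gm)^2)
  cell <- tapply(y, list(a, b), mean)
  ssab <- r * sum((sweep(sweep(cell, 1, tapply(y, a, mean) - gm),
                         2, tapply(y, b, mean) - gm) - gm)^2)
  sse <- sum((y - cell[cbind(a, b)])^2)
  dfe <- length(y) - na * nb
  Fa <- (ssa / (na - 1)) / (sse / dfe)
  Fb <- (ssb / (nb - 1)) / (sse / dfe)
  Fab <- (ssab / ((na - 1) * (nb - 1))) / (sse / dfe)
  expect_equal(got$F, c(Fa, Fb, Fab), tolerance = 1e-8)
  expect_equal(attr(got, "ss_type"), "II")

  # location invariance
  d2 <- d; d2$y <- d2$y + 100
  expect_equal(two_way_anova(d2, "y", c("sex", "time"))$F, got$F,
               tolerance = 1e-8)

  # additive cell means with no noise: interaction F vanishes
  d3 <- expand.grid(sex = c("m", "f"), time = c("t0", "t1"), rep = 1:3)
  d3$y <- as.numeric(d3$sex) + 2 * as.numeric(d3$time) +
    c(-0.1, 0, 0.1)[d3$rep]
  got3 <- two_way_anova(d3, "y", c("sex", "time"))
  expect_lt(got3$F[3], 1e-20)

  # empty cells are named
  d4 <- d[!(d$sex == "m" & d$time == "t2"), ]
  expect_error(two_way_anova(d4, "y", c("sex", "time")), "empty design cell")
})

test_that("Tukey-Kramer reduces to the studentized-range oracle", {
  g <- list(a = c(4, 5, 6), b = c(4, 5, 6))
  expect_gt(tukey_kramer(g)$p_adj, 0.99)

  set.seed(51)
  g2 <- list(a = rnorm(5), b = rnorm(7, 1.5))
  got <- tukey_kramer(g2)
  # two-group closed form: q = |diff| / sqrt(MSE/2 * (1/n1 + 1/n2))
  n1 <- 5; n2 <- 7
  mse <- ((n1 - 1) * var(g2$a) + (n2 - 1) * var(g2$b)) / (n1 + n2 - 2)
  q <- abs(mean(g2$b) - mean(g2$a)) / sqrt(mse / 2 * (1 / n1 + 1 / n2))
  p_oracle <- stats::ptukey(q, nmeans = 2, df = n1 + n2 - 2,
                            lower.tail = FALSE)
  expect_equal(got$p_adj, p_oracle, tolerance = 1e-8)

  # adjusted p is conservative relative to the unadjusted pairwise t-test
  set.seed(52)
  g3 <- list(a = rnorm(5), b = rnorm(5, 1), c = rnorm(6, 2))
  tk <- tukey_kramer(g3)
  pooled_df <- sum(lengths(g3)) - 3
  mse3 <- sum(vapply(g3, function(v) (length(v) - 1) * var(v),
                     numeric(1))) / pooled_df
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    x <- g3[[pair[1]]]; y <- g3[[pair[2]]]
    tstat <- abs(mean(x) - mean(y)) /
      sqrt(mse3 * (1 / length(x) + 1 / length(y)))
    p_t <- 2 * pt(tstat, pooled_df, lower.tail = FALSE)
    row <- tk$p_adj[tk$comparison == paste(pair[2], pair[1], sep = "-")]
    expect_gte(row, p_t - 1e-12)
  }
})

test_that("ANCOVA recovers piecewise slopes and matches the OLS oracle", {
  minute <- 1:90
  inj <- 30
  mean_line <- ifelse(minute <= inj, 60.7 + 0.05 * minute,
                      60.7 + 0.05 * inj - 0.21 * (minute - inj))
  clean <- ambient_series(minute, mean_line, inj)
  got <- ancova_slopes(clean)
  expect_equal(got$slope_pre, 0.05, tolerance = 1e-10)
  expect_equal(got$slope_post, -0.21, tolerance = 1e-10)

  # one global line: equal slopes, interaction p ~ 1 on noisy data
  set.seed(61)
  line <- ambient_series(minute, 60 + 0.1 * minute, inj)
  g2 <- ancova_slopes(line)
  expect_equal(g2$slope_pre, g2$slope_post, tolerance = 1e-9)

  # noisy series vs closed-form per-segment OLS (normal equations)
  noisy <- ambient_series(minute, mean_line + rnorm(90, sd = 1.3), inj)
  g3 <- ancova_slopes(noisy)
  ols <- function(t, y) sum((t - mean(t)) * (y - mean(y))) /
    sum((t - mean(t))^2)
  pre <- minute <= inj
  expect_equal(g3$slope_pre, ols(minute[pre], noisy$serotonin_nM[pre]),
               tolerance = 1e-10)
  expect_equal(g3$slope_post, ols(minute[!pre], noisy$serotonin_nM[!pre]),
               tolerance = 1e-10)
  expect_error(ancova_slopes(ambient_series(1:5, rnorm(5), 1)),
               ">= 3 points")
})

test_that("first significant departure finds the earliest departing minute", {
  minute <- 1:60; inj <- 30
  flat <- lapply(1:4, function(i) ambient_series(minute, rep(50, 60), inj))
  expect_true(is.na(first_significant_departure(flat)))

  # noiseless step decrease at minute 42
  step <- lapply(1:4, function(i) {
    v <- rep(50, 60); v[minute >= 42] <- 40
    ambient_series(minute, v + 0.001 * i, inj)  # tiny spread, sd > 0
  })
  expect_equal(as.numeric(first_significant_departure(step)), 42)

  # stochastic cohort vs a from-scratch Tukey-Kramer recomputation
  set.seed(71)
  drift <- lapply(1:5, function(i) {
    v <- ifelse(minute <= inj, 60, 60 - 0.4 * (minute - inj)) + rnorm(60)
    ambient_series(minute, v, inj)
  })
  got <- first_significant_departure(drift)
  # oracle: one-way groups (pooled control + each post minute), Kramer p
  vals <- lapply(drift, function(s) s$serotonin_nM)
  ctrl <- unlist(lapply(vals, function(v) v[minute <= inj]))
  post_m <- minute[minute > inj]
  groups <- c(list(ctrl), lapply(post_m, function(m) {
    vapply(vals, function(v) v[m], numeric(1))
  }))
  k <- length(groups)
  N <- sum(lengths(groups))
  means <- vapply(groups, mean, numeric(1))
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2),
                    numeric(1))) / (N - k)
  p_or <- vapply(seq_along(post_m), function(j) {
    q <- abs(means[j + 1] - means[1]) /
      sqrt(mse / 2 * (1 / lengths(groups)[j + 1] + 1 / length(ctrl)))
    stats::ptukey(q, nmeans = k, df = N - k, lower.tail = FALSE)
  }, numeric(1))
  oracle_minute <- post_m[which(p_or < 0.05)[1]]
  expect_equal(as.numeric(got), oracle_minute)
})

test_that("the normality gate routes comparisons as documented", {
  # deterministic fixtures: normal scores always pass the Shapiro gate,
  # a heavily right-skewed sample always fails it
  gauss <- function(n, mu = 0) qnorm(ppoints(n)) + mu
  r1 <- compare_groups(list(gauss(12), gauss(12, 0.5)))
  expect_equal(r1$method, "t_test")
  r2 <- compare_groups(list(gauss(10), gauss(10), gauss(10, 1)))
  expect_equal(r2$method, "anova")
  skewed <- list(exp(seq(0, 6, length.out = 20)), gauss(20), gauss(20, 1))
  r3 <- compare_groups(skewed)
  expect_equal(r3$method, "kruskal_wallis")
  expect_true(all(c(r1$p, r2$p, r3$p) >= 0 & c(r1$p, r2$p, r3$p) <= 1))
})

test_that("test statistics are invariant to unit rescaling and ordering", {
  set.seed(91)
  pre <- rnorm(8, 5); post <- rnorm(8, 6)
  expect_equal(paired_test(pre * 1e3, post * 1e3)$statistic,
               paired_test(pre, post)$statistic, tolerance = 1e-10)
  groups <- list(rnorm(6), rnorm(6, 1), rnorm(6, 2))
  scaled <- lapply(groups, function(g) g / 17.3)
  expect_equal(kruskal_wallis(scaled)$H, kruskal_wallis(groups)$H,
               tolerance = 1e-12)
  perm <- sample(8)
  expect_equal(paired_test(pre[perm], post[perm])$statistic,
               paired_test(pre, post)$statistic, tolerance = 1e-12)
})
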