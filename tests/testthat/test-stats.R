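test_that("fold changes report ratios of means with direction", {
  expect_equal(as.numeric(fold_change(c(1, 2, 3), c(1, 2, 3))), 1)
  fc <- fold_change(c(2, 2, 2), c(1, 1, 1))
  expect_equal(as.numeric(fc), 2)
  expect_identical(attr(fc, "direction"), "increase")
  dec <- fold_change(c(1, 1), c(4, 4))
  expect_identical(attr(dec, "direction"), "decrease")
  expect_equal(attr(dec, "magnitude"), 4)
  expect_error(fold_change(1:3, c(-1, 1)), "zero")
})

test_that("one-way ANOVA F matches the sum-of-squares formulas", {
  g1 <- c(6.1, 5.8, 6.4, 6.0)
  g2 <- c(7.2, 7.9, 7.4)
  g3 <- c(5.1, 4.8, 5.5, 5.0, 5.2)
  vals <- c(g1, g2, g3)
  grp <- rep(c("a", "b", "c"), c(4, 3, 5))
  out <- anova_tukey(vals, grp)

  gm <- mean(vals)
  ssb <- 4 * (mean(g1) - gm)^2 + 3 * (mean(g2) - gm)^2 + 5 * (mean(g3) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2) +
    sum((g3 - mean(g3))^2)
  Fref <- (ssb / 2) / (ssw / 9)
  expect_equal(out$statistic, Fref, tolerance = 1e-10)
  expect_equal(out$p, pf(Fref, 2, 9, lower.tail = FALSE), tolerance = 1e-12)
  expect_equal(out$summary$n, c(4L, 3L, 5L))
  expect_equal(nrow(out$contrasts), 3L)
  expect_true(all(out$contrasts$p_adj >= out$contrasts$p_raw - 1e-12))
})

test_that("identical groups give a null ANOVA result", {
  set.seed(21)
  v <- rnorm(24)
  out <- anova_tukey(rep(v[1:8], 3), rep(c("a", "b", "c"), each = 8))
  expect_lt(out$statistic, 1e-20)
  expect_true(all(out$contrasts$p_adj > 0.999))
})

test_that("Kruskal-Wallis H matches the rank-sum formula", {
  out <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  # ranks 1..6: R1 = 6, R2 = 15; H = 12/(6*7) * (36/3 + 225/3) - 3*7
  expect_equal(out$statistic, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-12)
  const <- kruskal_wallis(rep(1, 9), rep(c("a", "b", "c"), 3))
  expect_identical(const$statistic, 0)
  expect_identical(const$p, 1)
})

test_that("chi-square p is close to the exhaustive permutation p", {
  # two groups of 10 with all C(20,10) splits enumerated through rank sums
  x <- c(2.1, 3.4, 1.8, 4.2, 3.9, 2.7, 5.1, 3.3, 2.2, 4.8,
         4.5, 5.6, 3.8, 6.1, 5.9, 4.1, 6.6, 5.2, 4.9, 6.3)
  g <- rep(c("a", "b"), each = 10)
  out <- kruskal_wallis(x, g)

  r <- rank(x)  # distinct values: no ties
  N <- 20; n1 <- 10
  h_from_r1 <- function(R1) {
    R2 <- sum(r) - R1
    12 / (N * (N + 1)) * (R1^2 / n1 + R2^2 / n1) - 3 * (N + 1)
  }
  splits <- utils::combn(N, n1)
  H_all <- apply(splits, 2, function(idx) h_from_r1(sum(r[idx])))
  p_perm <- mean(H_all >= out$statistic - 1e-12)
  expect_lt(abs(out$p - p_perm), 0.02)
})

test_that("two-stage step-up matches the brute-force enumeration", {
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212,
         0.216)
  out <- bky_two_stage(p, q = 0.05)
  expect_identical(out$rejected, bky_oracle(p, 0.05))
  expect_identical(bky_two_stage(rep(1, 6), 0.05)$rejected, rep(FALSE, 6))
  expect_true(bky_two_stage(0.01, 0.05)$rejected)
  set.seed(31)
  for (i in 1:100) {
    m <- sample(3:25, 1)
    pv <- round(runif(m)^sample(1:3, 1), 4)
    expect_identical(bky_two_stage(pv, 0.05)$rejected, bky_oracle(pv, 0.05))
  }
  expect_error(bky_two_stage(c(0.2, 1.4)), "0, 1")
  expect_error(bky_two_stage(0.5, q = 1.2), "q")
})

test_that("two-stage rejections contain the plain BH rejections", {
  set.seed(32)
  checked <- 0L
  for (i in 1:200) {
    m <- sample(5:30, 1)
    pv <- runif(m)^2
    qp <- 0.05 / 1.05
    r1 <- sum(p.adjust(pv, "BH") <= qp)
    if (r1 >= 1 && r1 < m) {
      checked <- checked + 1L
      bh <- p.adjust(pv, "BH") <= 0.05 / 1.05
      bky <- bky_two_stage(pv, 0.05)$rejected
      expect_true(all(bky[bh]))
    }
  }
  expect_gt(checked, 50L)
})

test_that("Pearson correlation matches hand computation", {
  expect_equal(pearson_corr(1:10, 1:10)$r, 1)
  expect_equal(pearson_corr(1:10, 10:1)$r, -1)
  out <- pearson_corr(c(1, 2, 3, 4), c(2, 1, 4, 3))
  expect_equal(out$r, 0.6)
  nas <- pearson_corr(c(1, 2, 3, 4, NA), c(2, 1, 4, 3, 5))
  expect_equal(nas$n, 4L)
  expect_equal(nas$n_dropped, 1L)
  expect_error(pearson_corr(rep(1, 5), 1:5), "variance")
})

test_that("simple linear regression is exact on exact lines", {
  # summary.lm warns that a perfect fit makes the p-value unreliable
  out <- suppressWarnings(linreg(1:6, 2 * (1:6) + 1))
  expect_equal(out$slope, 2)
  expect_equal(out$intercept, 1)
  expect_equal(out$r2, 1)
  expect_error(linreg(rep(2, 5), 1:5), "constant")
})

test_that("normal-equation solution matches a grid-search minimizer", {
  x <- c(0.5, 1.1, 1.9, 3.2, 4.0, 4.9)
  y <- c(1.2, 2.6, 2.9, 5.4, 5.8, 7.1)
  out <- linreg(x, y)
  sse <- function(b0, b1) sum((y - b0 - b1 * x)^2)
  b1g <- seq(out$slope - 0.05, out$slope + 0.05, length.out = 801)
  b0g <- seq(out$intercept - 0.05, out$intercept + 0.05, length.out = 801)
  grid_best <- Inf; best <- c(NA, NA)
  for (b1 in b1g) {
    b0opt <- mean(y) - b1 * mean(x)  # profile the intercept
    v <- sse(b0opt, b1)
    if (v < grid_best) { grid_best <- v; best <- c(b0opt, b1) }
  }
  expect_lt(abs(best[2] - out$slope), 1e-4)
  expect_lte(sse(out$intercept, out$slope), grid_best + 1e-6)
})

test_that("null slope stays within three standard errors at large n", {
  set.seed(77)
  x <- rnorm(10000)
  y <- rnorm(10000)
  out <- linreg(x, y)
  se <- sqrt(sum((y - out$intercept - out$slope * x)^2) / 9998 /
               sum((x - mean(x))^2))
  expect_lt(abs(out$slope), 3 * se)
})

test_that("parametric and rank tests agree on well-separated groups", {
  set.seed(55)
  agree <- 0L
  for (i in 1:100) {
    a <- rnorm(10, 0, 1); b <- rnorm(10, 4, 1); c <- rnorm(10, 8, 1)
    vals <- c(a, b, c); grp <- rep(c("a", "b", "c"), each = 10)
    pa <- anova_tukey(vals, grp)$p
    pk <- kruskal_wallis(vals, grp)$p
    if ((pa <= 0.05) == (pk <= 0.05)) agree <- agree + 1L
  }
  expect_identical(agree, 100L)
})
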