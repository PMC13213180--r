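test_that("Friedman statistic honours its boundary cases", {
  m_id <- matrix(5, 6, 3)                     # identical columns
  fr <- friedman_rm(m_id)
  expect_equal(fr$chi2_uncorrected, 0)
  expect_equal(fr$p, 1)
  # perfectly ordered matrix, no ties: chi2 = N (k - 1)
  set.seed(1)
  n <- 9
  ordered <- t(replicate(n, sort(rnorm(3))))
  fr2 <- friedman_rm(ordered)
  expect_equal(fr2$chi2_uncorrected, n * 2)
  expect_equal(fr2$w, 1)
  expect_error(friedman_rm(matrix(1, 5, 1)), "2 conditions")
})

test_that("Friedman agrees with the reference implementation", {
  set.seed(42)
  m <- matrix(rnorm(45), 15, 3)
  fr <- friedman_rm(m)
  ref <- stats::friedman.test(m)
  expect_equal(fr$chi2, unname(ref$statistic))
  expect_equal(fr$p, ref$p.value)
})

test_that("Friedman p matches the exhaustive permutation distribution", {
  # 5 x 3 matrix with no ties; the oracle enumerates all (3!)^5 = 7776
  # within-subject rank assignments
  m <- matrix(c(-0.7,  0.3,  0.2,
                -1.1, -0.3,  1.1,
                -1.4,  0.9, -0.1,
                -0.2,  0.7,  0.9,
                -0.4,  1.1, -0.2), 5, 3, byrow = TRUE)
  fr <- friedman_rm(m)
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  idx <- as.matrix(expand.grid(1:6, 1:6, 1:6, 1:6, 1:6))
  chi2_of <- function(ranks) {
    rj <- colSums(ranks)
    12 / (5 * 3 * 4) * sum(rj^2) - 3 * 5 * 4
  }
  null_chi2 <- apply(idx, 1, function(ii) chi2_of(perms[ii, ]))
  p_exact <- mean(null_chi2 >= fr$chi2_uncorrected - 1e-12)
  expect_lt(abs(fr$p - p_exact), 0.005)
})

test_that("Kendall's w reproduces the published worked examples", {
  expect_equal(round(as.numeric(kendalls_w(20.67, 21, 3)), 2), 0.49)
  expect_equal(round(as.numeric(kendalls_w(40.09, 21, 3)), 2), 0.95)
  expect_equal(as.numeric(kendalls_w(0, 10, 4)), 0)
  expect_identical(attr(kendalls_w(20.67, 21, 3), "label"), "moderate")
  expect_identical(attr(kendalls_w(40.09, 21, 3), "label"), "large")
  expect_error(kendalls_w(5, 10, 1), "k")
})

test_that("w from the uncorrected statistic stays within [0, 1]", {
  set.seed(7)
  for (i in 1:50) {
    m <- matrix(sample(1:4, 8 * 3, replace = TRUE), 8, 3)  # heavy ties
    fr <- friedman_rm(m)
    expect_gte(fr$w, 0)
    expect_lte(fr$w, 1)
  }
})

test_that("Tukey post-hoc on ranks behaves at its boundaries", {
  m_id <- matrix(5, 8, 3)
  ph <- tukey_posthoc(m_id)
  expect_equal(nrow(ph), 3)
  expect_true(all(abs(ph$p - 1) < 1e-6))
  # two well-separated columns with an intermediate one: the extreme pair
  # has the smallest p
  set.seed(2)
  m <- cbind(rnorm(20), rnorm(20) + 1, rnorm(20) + 3)
  colnames(m) <- c("a", "b", "c")
  ph2 <- tukey_posthoc(m)
  expect_equal(ph2$p[ph2$i == "a" & ph2$j == "c"], min(ph2$p))
})

test_that("at k = 2 the studentized-range p collapses to the Friedman p", {
  set.seed(5)
  for (i in 1:10) {
    m <- matrix(rnorm(24), 12, 2)
    expect_lt(abs(tukey_posthoc(m)$p - friedman_rm(m)$p), 0.01)
  }
})

test_that("absolute-agreement ICC matches a reference ANOVA decomposition", {
  m <- matrix(c(9, 2, 5, 8, 6, 7,
                10, 4, 6, 9, 7, 8), 6, 2)
  res <- icc_absolute_single(m)
  # oracle: two-way ANOVA mean squares from stats::aov
  df <- data.frame(y = as.vector(m),
                   subject = factor(rep(1:6, 2)),
                   method = factor(rep(1:2, each = 6)))
  ms <- summary(stats::aov(y ~ subject + method, df))[[1]][["Mean Sq"]]
  n <- 6; k <- 2
  icc_oracle <- (ms[1] - ms[3]) /
    (ms[1] + (k - 1) * ms[3] + k / n * (ms[2] - ms[3]))
  expect_equal(res$icc, icc_oracle)
  expect_equal(res$msr, ms[1]); expect_equal(res$mse, ms[3])
})

test_that("absolute agreement penalises constant offsets, consistency does not", {
  set.seed(9)
  a <- rnorm(12, 10, 2)
  m <- cbind(a, a + 5)
  res <- icc_absolute_single(m)
  consistency <- (res$msr - res$mse) / (res$msr + (2 - 1) * res$mse)
  expect_lt(res$icc, consistency)
  expect_gt(consistency, 0.99)
  # identical columns with between-subject variance: perfect agreement
  expect_equal(icc_absolute_single(cbind(a, a))$icc, 1)
})

test_that("TOST equivalence follows the 90% CI inclusion rule", {
  res0 <- tost_equivalence(rep(0, 8))
  expect_equal(res0$ci90, c(0, 0))
  expect_true(res0$equivalent)
  # mean 0, sd 10, N = 5: the t-based CI is far wider than +/- 1 mA
  d <- c(-10, -5, 0, 5, 10)
  res <- tost_equivalence(d, bounds = 1)
  half <- qt(0.95, 4) * sd(d) / sqrt(5)
  expect_equal(res$ci90, c(-half, half))
  expect_false(res$equivalent)
  # translation equivariance
  res_c <- tost_equivalence(d + 3, bounds = 1)
  expect_equal(res_c$ci90, res$ci90 + 3)
})

test_that("Bland-Altman limits are symmetric about the bias", {
  ba0 <- bland_altman(1:6, 1:6)
  expect_equal(ba0$bias, 0); expect_equal(ba0$loa, c(0, 0))
  ba <- bland_altman(c(0, 2), c(1, 1))   # differences {-1, 1}
  expect_equal(ba$bias, 0)
  expect_equal(ba$loa, c(-1.96, 1.96) * sqrt(2))
  set.seed(4)
  ba2 <- bland_altman(rnorm(20), rnorm(20))
  expect_equal(mean(ba2$loa), ba2$bias)
})

test_that("the battery is invariant to subject reordering", {
  set.seed(11)
  m <- matrix(rnorm(36), 12, 3)
  perm <- sample(12)
  expect_equal(friedman_rm(m[perm, ])$chi2, friedman_rm(m)$chi2)
  expect_equal(tukey_posthoc(m[perm, ])$p, tukey_posthoc(m)$p)
  expect_equal(icc_absolute_single(m[perm, 1:2])$icc,
               icc_absolute_single(m[, 1:2])$icc)
  d <- m[, 1] - m[, 2]
  expect_equal(tost_equivalence(d[perm])$ci90, tost_equivalence(d)$ci90)
})

test_that("the Friedman test holds its nominal type-I error on null data", {
  set.seed(2024)
  rejections <- vapply(1:2000, function(i) {
    friedman_rm(matrix(rnorm(63), 21, 3))$p < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})
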