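test_that("Cronbach's alpha matches hand arithmetic and its invariances", {
  X <- cbind(A = c(0, 1, 2, 0), B = c(0, 2, 1, 1), C = c(1, 1, 2, 0))
  expect_equal(cronbach_alpha(X), 1.5 * (1 - (11/12 + 2/3 + 2/3) / 4.25),
               tolerance = 1e-12)
  expect_equal(round(cronbach_alpha(X), 3), 0.706)
  # parallel items are perfectly reliable
  expect_equal(cronbach_alpha(cbind(1:5, 1:5, 1:5)), 1)
  # strongly negative covariance drives alpha negative
  expect_lt(cronbach_alpha(cbind(1:6, -2 * (1:6))), 0)
  # shifting one item by a constant changes nothing
  Xs <- X; Xs[, 2] <- Xs[, 2] + 7
  expect_equal(cronbach_alpha(Xs), cronbach_alpha(X))
  expect_error(cronbach_alpha(X[1, , drop = FALSE]), ">= 2")
  expect_error(cronbach_alpha(matrix(1, 4, 3)), "variance")
})

test_that("KR-20 matches hand arithmetic and the synthetic reference band", {
  B <- cbind(A = c(1, 1, 0, 0), B = c(1, 0, 1, 0), C = c(1, 1, 1, 0))
  expect_equal(kr20(B), 1.5 * (1 - 0.6875 / (4.75 / 3)), tolerance = 1e-12)
  expect_equal(round(kr20(B), 3), 0.849)
  # identical items: the p(1-p)-item / sample-total convention reaches 1
  # only in the large-n limit (exact value k/(k-1) * (1 - (n-1)/(k n)))
  rep_item <- rep(c(0, 1), 1000)
  expect_equal(kr20(cbind(rep_item, rep_item)),
               2 * (1 - 1999 / 4000), tolerance = 1e-12)
  expect_lt(abs(kr20(cbind(rep_item, rep_item)) - 1), 1e-3)
  expect_error(kr20(cbind(c(0, 2), c(1, 0))), "binary")
  # calibrated generator keeps the 9-criterion reference in the plausible
  # reliability band
  d <- generate_dataset(igdc_config(n_persons = 5000, seed = 19))
  k <- kr20(d$dsm_items)
  expect_gte(k, 0.6)
  expect_lte(k, 0.9)
})

test_that("pearson_r matches exact cases and refuses degenerate input", {
  x <- c(1, 4, 2, 8, 5)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  y <- c(2, 1, 5, 3, 9)
  expect_equal(pearson_r(x, y),
               sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)),
               tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 5)), "constant")
  expect_error(pearson_r(1:2, 2:1), ">= 3")
})

test_that("pooled t statistic matches hand arithmetic and is antisymmetric", {
  expect_equal(two_sample_t(c(1, 2, 3), c(1, 2, 3))$statistic, 0)
  r <- two_sample_t(c(0, 1, 2), c(3, 4, 5))
  expect_equal(r$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  swapped <- two_sample_t(c(3, 4, 5), c(0, 1, 2))
  expect_equal(swapped$statistic, -r$statistic)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "pooled variance")
  # Welch form reproduces base R
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.3, 0.1, 0.9)
  w <- two_sample_t(a, b, pooled = FALSE)
  tt <- t.test(a, b)
  expect_equal(w$statistic, unname(tt$statistic))
  expect_equal(w$df, unname(tt$parameter))
})

test_that("Mann-Whitney U matches exhaustive pair counting in both orientations", {
  r <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(r$u_a, 0)
  expect_equal(r$u_b, 4)
  tied <- mann_whitney_u(rep(2, 3), rep(2, 5))
  expect_equal(tied$u_a, 7.5)
  expect_equal(tied$u_b, 7.5)
  set.seed(12)
  for (i in 1:25) {
    xa <- sample(0:5, sample(2:12, 1), replace = TRUE)
    xb <- sample(0:5, sample(2:12, 1), replace = TRUE)
    r <- mann_whitney_u(xa, xb)
    expect_identical(r$u_a, pair_u(xa, xb))
    expect_identical(r$u_b, pair_u(xb, xa))
    expect_equal(r$u_a + r$u_b, length(xa) * length(xb))
  }
})

test_that("chi-square independence statistic follows its definition", {
  # a table equal to its independence expectation scores zero
  indep <- outer(c(10, 30), c(2, 3)) / 5
  expect_equal(chi_square_independence(indep)$statistic, 0)
  r <- chi_square_independence(matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(r$statistic, 20 / 3, tolerance = 1e-12)
  expect_equal(r$df, 1L)
  r10 <- chi_square_independence(10 * matrix(c(10, 20, 20, 10), 2, byrow = TRUE))
  expect_equal(r10$statistic, 10 * r$statistic)
  expect_warning(rz <- chi_square_independence(matrix(c(10, 0, 20, 20, 0, 10), 3)),
                 "zero-margin")
  expect_equal(rz$statistic, 20 / 3, tolerance = 1e-12)
})

test_that("default synthetic data lands in the published reliability bands", {
  d <- generate_dataset(igdc_config(n_persons = 5000, seed = 23))
  items27 <- setdiff(colnames(d$responses), dropped_items)
  expect_gt(cronbach_alpha(d$responses[, items27]), 0.85)
  for (f in names(cigdc_factor_map())) {
    sub <- intersect(cigdc_factor_map()[[f]], items27)
    expect_gt(cronbach_alpha(d$responses[, sub]), 0.5)
  }
})
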