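test_that("identical replicate weights give the mean with zero sem", {
  d <- constant_design(4)
  est <- brr_estimate(1:4, d)
  expect_equal(est$estimate, 2.5)
  expect_equal(est$sem, 0)
})

test_that("a two-replicate design reproduces the closed-form sem", {
  d <- survey_design(c(1, 1), cbind(c(1, 0), c(0, 1)))
  est <- brr_estimate(c(2, 3), d)
  expect_equal(est$estimate, 2.5)
  expect_equal(est$sem, sqrt((0.25 + 0.25) / 2))  # 0.5
})

test_that("weighted means respect the weights", {
  d <- survey_design(c(1, 1, 2), matrix(c(1, 1, 2), 3, 2))
  expect_equal(brr_estimate(c(0, 0, 3), d)$estimate, 1.5)
})

test_that("brr sem matches an independent loop on random designs", {
  set.seed(14)
  for (i in 1:5) {
    n <- 30
    w <- runif(n, 0.5, 2)
    rw <- bootstrap_replicate_weights(w, 40)
    x <- rnorm(n)
    d <- survey_design(w, rw)
    expect_equal(brr_estimate(x, d)$sem, oracle_brr_sem(x, w, rw))
    # median as a non-linear statistic through the same machinery
    med <- function(x, w) oracle_weighted_quantile(x, w, 0.5)
    expect_equal(brr_estimate(x, d, statistic = med)$sem,
                 oracle_brr_sem(x, w, rw, med))
  }
})

test_that("brr sem is invariant to uniform weight rescaling", {
  set.seed(15)
  w <- runif(20, 0.5, 2)
  rw <- bootstrap_replicate_weights(w, 30)
  x <- rnorm(20)
  a <- brr_estimate(x, survey_design(w, rw))
  b <- brr_estimate(x, survey_design(7 * w, 7 * rw))
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$sem, b$sem)
})

test_that("degenerate all-zero replicate columns are refused", {
  d <- survey_design(c(1, 1), cbind(c(1, 1), c(0, 0)))
  expect_error(brr_estimate(1:2, d), "degenerate replicate")
})

test_that("weighted quantiles match the brute-force scan", {
  set.seed(16)
  for (i in 1:20) {
    x <- sample(0:50, 15, replace = TRUE)
    w <- runif(15, 0.1, 3)
    p <- runif(1)
    expect_equal(weighted_quantile(x, w, p),
                 oracle_weighted_quantile(x, w, p))
  }
})

test_that("equal-weight quartiles split 1..8 into consecutive pairs", {
  d <- constant_design(8)
  q <- weighted_quartiles(1:8 * 10, d)
  expect_equal(q$cutpoints, c(20, 40, 60))
  expect_equal(as.integer(q$quartile), rep(1:4, each = 2))
})

test_that("quartiles are weight-scale invariant and partition the sample", {
  set.seed(17)
  n <- 101
  shares <- runif(n, 0, 60)
  w <- runif(n, 0.5, 3)
  rw <- bootstrap_replicate_weights(w, 10)
  q1 <- weighted_quartiles(shares, survey_design(w, rw))
  q2 <- weighted_quartiles(shares, survey_design(2 * w, 2 * rw))
  expect_equal(q1$cutpoints, q2$cutpoints)
  expect_equal(q1$quartile, q2$quartile)
  expect_false(anyNA(q1$quartile))
  # each weighted quartile share is near 25%
  shares_by_q <- tapply(w, q1$quartile, sum) / sum(w)
  expect_true(all(abs(shares_by_q - 0.25) < 0.05))
})

test_that("tied shares collapse to the lower quartile with a warning", {
  d <- constant_design(8)
  expect_warning(q <- weighted_quartiles(rep(10, 8), d), "degenerate")
  expect_true(all(q$quartile == "Q1_COMPLIER"))
  expect_error(weighted_quartiles(c(1, 2, 3), constant_design(3)),
               "fewer than 4")
})

test_that("unadjusted equal-weight group means equal raw group means", {
  y <- c(1, 2, 3, 10, 11, 12)
  g <- factor(rep(c("a", "b"), each = 3))
  d <- constant_design(6)
  am <- adjusted_group_means(y, g, NULL, d)
  expect_equal(unname(am$estimate), c(2, 11))

  flat <- adjusted_group_means(rep(5, 6), g, NULL, d)
  expect_equal(unname(flat$estimate), c(5, 5))
  expect_true(flat$trend$p_value > 0.05)
})

test_that("adjusted means recover a known gradient and its sign", {
  set.seed(18)
  n <- 400
  g <- factor(sample(paste0("Q", 1:4), n, replace = TRUE))
  age <- runif(n, 19, 90)
  mu <- c(Q1 = 12, Q2 = 10, Q3 = 9, Q4 = 7)
  y <- mu[as.character(g)] + 0.01 * (age - 50) + rnorm(n, 0, 1.5)
  w <- runif(n, 0.5, 2)
  d <- survey_design(w, bootstrap_replicate_weights(w, 100))
  am <- adjusted_group_means(y, g, data.frame(age = age), d)
  expect_true(all(abs(am$estimate - mu) < 4 * pmax(am$sem, 0.1)))
  expect_lt(am$trend$slope, 0)
  expect_lt(am$trend$p_value, 0.05)
})

test_that("binary outcomes go through the weighted logistic path", {
  set.seed(19)
  n <- 600
  g <- factor(sample(paste0("Q", 1:4), n, replace = TRUE))
  p <- c(Q1 = 0.1, Q2 = 0.2, Q3 = 0.3, Q4 = 0.4)[as.character(g)]
  y <- rbinom(n, 1, p)
  w <- rep(1, n)
  d <- survey_design(w, bootstrap_replicate_weights(w, 80))
  am <- adjusted_group_means(y, g, NULL, d, binary = TRUE)
  expect_true(all(am$estimate >= 0 & am$estimate <= 1))
  expect_true(all(abs(am$estimate - c(0.1, 0.2, 0.3, 0.4)) < 0.1))
  expect_gt(am$trend$slope, 0)
})

test_that("collinear covariates raise a singular-fit error by name", {
  y <- rnorm(20)
  g <- factor(rep(c("a", "b"), 10))
  covs <- data.frame(x1 = 1:20, x2 = 2 * (1:20))
  d <- constant_design(20)
  expect_error(adjusted_group_means(y, g, covs, d), "x2")
})
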