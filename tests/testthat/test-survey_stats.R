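test_that("weighted quantiles follow the left-continuous type-1 convention", {
  expect_equal(weighted_quantile(c(10, 20, 30), c(1, 1, 2), 0.5), 20)
  expect_equal(weighted_quantile(c(10, 20, 30), c(1, 1, 2), 0), 10)
  expect_equal(weighted_quantile(c(10, 20, 30), c(1, 1, 2), 1), 30)

  # equal weights, odd n: the ordinary sample median
  set.seed(5)
  for (i in 1:10) {
    x <- rnorm(2 * sample(1:20, 1) + 1)
    expect_equal(weighted_quantile(x, probs = 0.5), median(x))
  }

  # integer weights behave as a weight-expanded sample (type-1 quantile)
  for (i in 1:10) {
    x <- rnorm(8); w <- sample(1:4, 8, replace = TRUE)
    q <- runif(1)
    expect_equal(weighted_quantile(x, w, q),
                 unname(quantile(rep(x, w), q, type = 1)))
  }

  expect_error(weighted_quantile(numeric(0)), "empty")
  expect_error(weighted_quantile(1:3, c(1, 0, 1)), "positive")
  expect_error(weighted_quantile(1:3, probs = 1.5), "probs")
})

test_that("exact Mann-Whitney matches the enumeration oracle, ties included", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 0.1)

  # identical multisets give p = 1
  expect_equal(mann_whitney(c(2, 7, 7), c(7, 2, 7))$p_value, 1)

  set.seed(11)
  for (rep in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    x <- sample(1:5, n1, replace = TRUE)  # discrete -> ties are common
    y <- sample(1:5, n2, replace = TRUE)
    got <- mann_whitney(x, y)
    oracle <- mw_oracle(x, y)
    expect_equal(unname(got$statistic), oracle$U)
    expect_equal(got$p_value, oracle$p)
  }
})

test_that("the U statistic equals the pairwise comparison count", {
  set.seed(13)
  for (rep in 1:10) {
    x <- sample(1:10, 8, replace = TRUE)
    y <- sample(1:10, 9, replace = TRUE)
    got <- mann_whitney(x, y, exact = FALSE)
    expect_equal(unname(got$statistic),
                 sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "==")))
  }
})

test_that("the normal approximation agrees with the reference implementation", {
  set.seed(17)
  for (rep in 1:10) {
    x <- round(rnorm(20), 1); y <- round(rnorm(25, 0.3), 1)
    got <- mann_whitney(x, y)
    ref <- suppressWarnings(wilcox.test(x, y, correct = FALSE, exact = FALSE))
    expect_false(got$exact)
    expect_equal(unname(got$statistic), unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
})

test_that("integerised-weight replication reproduces the expanded-sample test", {
  x <- c(1, 4, 6); y <- c(2, 3, 9)
  wx <- c(2, 1, 3); wy <- c(1, 2, 1)
  got <- mann_whitney(x, y, weights_x = wx, weights_y = wy)
  expect_equal(got$p_value, mann_whitney(rep(x, wx), rep(y, wy))$p_value)
})

test_that("Kruskal-Wallis H matches closed forms and the reference implementation", {
  r <- kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))
  expect_equal(unname(r$statistic), 32 / 7)
  expect_equal(r$df, 2)
  expect_equal(r$p_value, pchisq(32 / 7, 2, lower.tail = FALSE))

  set.seed(19)
  for (rep in 1:10) {
    g <- lapply(sample(3:8, 3), function(n) sample(1:6, n, replace = TRUE))
    got <- kruskal_wallis(g)
    ref <- kruskal.test(g)
    expect_equal(unname(got$statistic), unname(ref$statistic))
    expect_equal(got$p_value, ref$p.value)
  }
  expect_error(kruskal_wallis(list(1:3)), "two groups")
  expect_error(kruskal_wallis(list(1:3, numeric(0))), "non-empty")
})

test_that("H is invariant under monotone transformations and ties collapse to H = 0", {
  set.seed(23)
  g <- lapply(1:4, function(i) rnorm(7, i / 2))
  h1 <- kruskal_wallis(g)$statistic
  h2 <- kruskal_wallis(lapply(g, function(v) exp(v)))$statistic
  expect_equal(h1, h2)
  # all observations identical: no information, p = 1
  same <- kruskal_wallis(list(rep(2, 3), rep(2, 4)))
  expect_equal(unname(same$statistic), 0)
  expect_equal(same$p_value, 1)
})

test_that("with two groups and no ties, H equals the squared Mann-Whitney z", {
  set.seed(29)
  for (rep in 1:10) {
    x <- rnorm(12); y <- rnorm(15, 0.5)
    mw <- mann_whitney(x, y, exact = FALSE)
    kw <- kruskal_wallis(list(x, y))
    expect_equal(unname(kw$statistic), mw$z^2)
  }
})

test_that("the linear trend test recovers the closed-form weighted slope", {
  r <- linear_trend(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(r$statistic), 1)
  expect_equal(r$p_value, 0)

  r <- linear_trend(rep(4, 6), 1:6)
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p_value, 1)

  set.seed(37)
  for (rep in 1:10) {
    n <- sample(5:40, 1)
    x <- sample(1:9, n, replace = TRUE)
    y <- 0.5 * x + rnorm(n)
    w <- runif(n, 0.2, 3)
    got <- linear_trend(y, x, w)
    expect_equal(unname(got$statistic), wls_slope_oracle(y, x, w))
    ref <- summary(lm(y ~ x, weights = w))$coefficients["x", ]
    expect_equal(unname(got$statistic), unname(ref["Estimate"]))
    expect_equal(got$p_value, unname(ref["Pr(>|t|)"]))
  }
  expect_error(linear_trend(1:3, c(2, 2, 2)), "single band")
})

test_that("group summaries reproduce hand-computed weighted medians and IQRs", {
  participants <- data.frame(
    participant_id = c("A", "B", "C", "D", "E"),
    age_years = c(30, 40, 50, 25, 35),
    sex = c("male", "male", "male", "female", "female"),
    nssec = c(1L, 2L, NA, 3L, 4L),
    survey_weight = c(1, 2, 1, 1, 3),
    n_diary_days = 4L,
    energy_MJ_per_day = 10,
    stringsAsFactors = FALSE)
  intakes <- data.frame(
    participant_id = participants$participant_id,
    wg_gd_any = c(10, 20, 30, 0, 5),
    wg_g10mj_any = c(10, 20, 30, 0, 5),
    nonconsumer_any = c(FALSE, FALSE, FALSE, TRUE, FALSE))

  s <- summarize_intakes(intakes, participants, by = "sex")
  # males: values 10,20,30, weights 1,2,1 -> cum 0.25, 0.75, 1
  m <- s[s$stratum == "male", ]
  expect_equal(c(m$q25, m$median, m$q75), c(10, 20, 20))
  expect_equal(c(m$min, m$max), c(10, 30))
  expect_equal(m$pct_nonconsumer, 0)
  # females: 0 (w 1), 5 (w 3) -> cum 0.25, 1
  f <- s[s$stratum == "female", ]
  expect_equal(c(f$q25, f$median, f$q75), c(0, 5, 5))
  expect_equal(f$pct_nonconsumer, 25)
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))

  # missing NS-SEC participants drop out of NS-SEC strata but not sex strata
  sn <- summarize_intakes(intakes, participants, by = "nssec")
  expect_equal(sum(sn$n), 4)
  expect_equal(sum(s$n), 5)

  # all-zero intakes: median 0 and 100 % non-consumers
  z <- intakes
  z$wg_gd_any <- 0; z$wg_g10mj_any <- 0
  sz <- summarize_intakes(z, participants, by = "adult_child")
  a <- sz[sz$stratum == "adult", ]
  expect_equal(a$median, 0)
  expect_equal(a$pct_nonconsumer, 100)

  expect_error(summarize_intakes(intakes, participants, by = "region"),
               "unknown stratum")
})
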