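test_that("perfect agreement gives ICC = 1; degenerate tables error", {
  tab <- cbind(1:10, 1:10, 1:10)
  r <- icc_2way_random_single(tab)
  expect_equal(r$icc, 1)
  expect_error(icc_2way_random_single(matrix(5, 8, 3)), "undefined")
  expect_error(icc_2way_random_single(matrix(1:4, 1)), "at least 2")
  expect_error(icc_2way_random_single(cbind(c(1, NA, 3), c(1, 2, 3))),
               "missing")
})

test_that("ICC(2,1) and its CI reproduce an independent reference", {
  # frozen reference computed once with an independent two-way random-effects
  # implementation on this exact table
  tab <- make_rater_table(12, 3, 4, 0.5, 1, seed = 7)
  r <- icc_2way_random_single(tab)
  expect_equal(r$icc, 0.847837, tolerance = 1e-6)
  # reference interval printed to 2 decimals: [0.44, 0.96]
  expect_equal(round(r$ci_low, 2), 0.44)
  expect_equal(round(r$ci_high, 2), 0.96)
})

test_that("ICC recovers the variance ratio and penalizes rater shifts", {
  tab <- make_rater_table(100, 2, var_subject = 4, var_rater = 0,
                          var_error = 1, seed = 99)
  r <- icc_2way_random_single(tab)
  expect_lt(abs(r$icc - 0.8), 0.05)

  # absolute agreement penalizes a constant shift, increasingly with |c|
  set.seed(5)
  base <- rnorm(40, sd = 2)
  prev <- 1
  for (shift in c(0.5, 1, 2, 4)) {
    ri <- icc_2way_random_single(cbind(base, base + shift))
    expect_lt(ri$icc, prev)
    prev <- ri$icc
  }

  # invariant to adding a common constant to all cells
  tab2 <- make_rater_table(30, 3, 2, 0.3, 0.5, seed = 17)
  r1 <- icc_2way_random_single(tab2)
  r2 <- icc_2way_random_single(tab2 + 100)
  expect_equal(r1$icc, r2$icc, tolerance = 1e-9)
  expect_true(r1$icc > -1 && r1$icc <= 1)
})

test_that("pilot sample size reproduces the closed form and its properties", {
  r <- pilot_sample_size(0.90, 0.10)
  expect_equal(r$n_1dp, 21.9)
  expect_equal(r$n, log(0.1) / log(0.9), tolerance = 1e-12)
  expect_equal(pilot_sample_size(0.75, 0.50)$n, 2, tolerance = 1e-12)
  expect_error(pilot_sample_size(1, 0.1), "confidence")
  expect_error(pilot_sample_size(0.9, 0), "pi")

  # monotone: increasing in confidence, decreasing in pi
  expect_gt(pilot_sample_size(0.95, 0.10)$n, r$n)
  expect_lt(pilot_sample_size(0.90, 0.20)$n, r$n)

  # ceiling(n) is the least integer m with 1 - (1 - pi)^m >= confidence
  set.seed(61)
  for (trial in 1:10) {
    conf <- runif(1, 0.5, 0.99)
    pi <- runif(1, 0.02, 0.6)
    m <- pilot_sample_size(conf, pi)$n_ceiling
    brute <- which(1 - (1 - pi)^(1:500) >= conf - 1e-12)[1]
    expect_equal(m, brute)
  }
})

test_that("summarize_sides pairs records and routes the right test", {
  df <- expand.grid(subject = 1:12, side = c("extraction", "control"),
                    period = c("T1-T0", "T2-T0"), metric = c("stvc", "rms"),
                    stringsAsFactors = FALSE)
  set.seed(62)
  df$value <- rnorm(nrow(df))
  # identical sides -> zero differences
  df0 <- df
  key <- paste(df0$subject, df0$period, df0$metric)
  vals <- rnorm(length(unique(key)))
  df0$value <- vals[match(key, unique(key))]
  out0 <- summarize_sides(df0)
  expect_true(all(out0$mean_diff == 0))

  # a known side effect is detected by the paired t-test
  df1 <- df[df$metric == "stvc" & df$period == "T1-T0", ]
  df1$subject <- as.integer(df1$subject)
  n <- 30
  base <- rnorm(n, sd = 0.5)
  delta <- 1
  df2 <- data.frame(
    subject = rep(1:n, 2),
    side = rep(c("extraction", "control"), each = n),
    period = "T1-T0", metric = "stvc",
    value = c(base + delta + rnorm(n, sd = 0.5), base + rnorm(n, sd = 0.5)))
  out <- summarize_sides(df2)
  expect_equal(out$test, "paired-t")
  expect_lt(out$p_value, 0.001)
  # differences are first side level minus second (alphabetical):
  # control - extraction = -delta
  expect_equal(out$mean_diff, -delta, tolerance = 0.5)

  # single subject cannot be paired-tested
  expect_error(summarize_sides(df2[df2$subject == 1, ]), "at least 2")
  # unpaired records error
  expect_error(summarize_sides(df2[-1, ]), "unpaired")
})
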