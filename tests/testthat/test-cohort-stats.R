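test_that("MAD screen rejects a gross outlier and only that", {
  res <- mad_outlier_filter(c(1.0, 1.1, 0.9, 10.0), log_domain = TRUE)
  expect_equal(res$rejected, 4L)

  # brute-force check of the decision in logs
  v <- log(c(1.0, 1.1, 0.9, 10.0))
  m <- median(v)
  mad <- median(abs(v - m))
  expect_true(abs(v[4] - m) > 2.5 * mad)
  expect_true(all(abs(v[1:3] - m) <= 2.5 * mad))
})

test_that("MAD screen accounts for confidence intervals and handles ties", {
  # identical data: MAD = 0, but distances are 0 too; nothing rejected
  res <- mad_outlier_filter(rep(2, 5))
  expect_equal(length(res$rejected), 0)

  # an extreme value whose wide CI reaches back inside the band is retained
  vals <- c(1.0, 1.1, 0.9, 10.0)
  res2 <- mad_outlier_filter(vals, ci_low = c(0.9, 1.0, 0.8, 1.0),
                             ci_high = c(1.1, 1.2, 1.0, 100))
  expect_equal(length(res2$rejected), 0)

  # small groups pass through unfiltered with a warning
  expect_warning(res3 <- mad_outlier_filter(c(1, 100, 1), log_domain = TRUE),
                 "fewer than 4")
  expect_equal(length(res3$rejected), 0)
})

test_that("MAD screen is idempotent on data with an isolated gross outlier", {
  # the regime the screen is designed for: tight log-normal scatter plus one
  # extreme value; removing it barely moves the median/MAD, so re-screening
  # the kept set rejects nothing
  x <- exp(c(seq(-0.25, 0.25, by = 0.05), 3))
  first <- mad_outlier_filter(x)
  expect_equal(first$rejected, 12L)
  kept <- x[first$keep]
  second <- mad_outlier_filter(kept)
  expect_equal(length(second$rejected), 0)
})

test_that("interocular correlation recovers degenerate and null cases", {
  expect_equal(interocular_correlation(1:10, 1:10)$r, 1)
  set.seed(9)
  a <- rnorm(500); b <- rnorm(500)
  expect_lt(abs(interocular_correlation(a, b)$r), 0.1)
  expect_error(interocular_correlation(1:2, 2:3), "3 complete pairs")
})

test_that("bilateral averaging is geometric for facility with quadrature CI", {
  res <- bilateral_average(c(4, 9), c(3, 7), c(5, 11), log_domain = TRUE)
  expect_equal(res$value, 6)  # geometric mean

  # equal log half-widths h combine to h / sqrt(2)
  v <- c(5, 5); lo <- v * exp(-0.2); hi <- v * exp(0.2)
  res2 <- bilateral_average(v, lo, hi, log_domain = TRUE)
  h_comb <- (log(res2$ci_high) - log(res2$ci_low)) / 2
  expect_equal(h_comb, 0.2 / sqrt(2))
  # identical eyes: same estimate, strictly narrower CI
  expect_equal(res2$value, 5)
  expect_lt(h_comb, 0.2)

  # single-eye animals pass through unchanged
  res3 <- bilateral_average(4.2, 3.9, 4.6)
  expect_equal(res3, list(value = 4.2, ci_low = 3.9, ci_high = 4.6, n_eyes = 1L))

  # beta averages arithmetically (can be negative)
  res4 <- bilateral_average(c(-0.1, 0.3), c(-0.3, 0.1), c(0.1, 0.5))
  expect_equal(res4$value, 0.1)
})

test_that("age regression matches closed-form OLS and applies Bonferroni", {
  # exact line
  r <- regress_on_age(1:10, 2 * (1:10) + 1)
  expect_equal(r$slope, 2, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)

  # hand-computed 4-point OLS: slope 0.8, intercept 0.5
  r2 <- regress_on_age(1:4, c(1, 3, 2, 4))
  expect_equal(r2$slope, 0.8)
  expect_equal(r2$intercept, 0.5)

  # Bonferroni triples p, capped at 1
  r3 <- regress_on_age(1:4, c(1, 3, 2, 4), bonferroni_m = 3)
  expect_equal(r3$p_B, min(1, 3 * r3$p))
  set.seed(2)
  r4 <- regress_on_age(1:10, rnorm(10), bonferroni_m = 3)
  expect_lte(r4$p_B, 1)

  expect_error(regress_on_age(rep(3, 5), 1:5), "singular")
  expect_error(regress_on_age(1:2, 1:2), "at least 3")
})

test_that("log-domain regression recovers exponential trends", {
  ages <- seq(2, 32, length.out = 20)
  y <- 80 * exp(-0.035 * ages)
  r <- regress_on_age(ages, y, log_y = TRUE)
  expect_equal(r$slope, -0.035, tolerance = 1e-10)
  expect_equal(r$r_squared, 1, tolerance = 1e-10)
})

test_that("age groups split at 8 and 16 months", {
  g <- age_group(c(3, 7.9, 8, 16, 16.1, 30))
  expect_equal(as.character(g),
               c("young", "young", "middle", "middle", "elderly", "elderly"))
})
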