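test_that("binned means match a brute-force groupby", {
  set.seed(17)
  x <- runif(300, 20, 120)
  y <- 0.8 * x + rnorm(300, sd = 4)
  edges <- seq(20, 120, by = 20)
  mine <- binned_means(x, y, edges, min_count = 5)
  ref <- brute_binned(x, y, edges, min_count = 5)
  expect_equal(mine$center, ref$center)
  expect_equal(mine$mean, ref$mean)
  expect_equal(mine$se, ref$se)
  expect_equal(mine$count, ref$count)
})

test_that("binned means handle constants and degenerate bins", {
  x <- c(1.5, 2.5, 2.6, 3.5, 3.6, 3.7)
  y <- rep(5, 6)
  b <- binned_means(x, y, edges = 1:4, min_count = 1)
  expect_true(all(b$mean == 5))
  expect_true(all(b$se == 0))
  # single-point bin: se reported 0 and flagged undefined
  expect_false(b$se_defined[b$count == 1][1])
  expect_error(binned_means(x, y, edges = 1:4, min_count = 10), "min_count")
})

test_that("linear fit is exact on exact data and unbiased under noise", {
  x <- c(10, 20, 30, 40)
  expect_equal(fit_linear(x, 2 * x)$slope, 2, tolerance = 1e-12)
  expect_equal(fit_linear(x, 2 * x)$intercept, 0, tolerance = 1e-10)
  # two points: the interpolating line
  f2 <- fit_linear(c(1, 3), c(5, 9))
  expect_equal(f2$slope, 2)
  expect_equal(f2$intercept, 3)
  expect_error(fit_linear(c(2, 2), c(1, 5)), "degenerate")

  # proportional data with noise: the intercept CI covers 0 most of the time
  set.seed(23)
  covered <- 0L
  for (i in 1:100) {
    xx <- seq(30, 90, by = 15)
    yy <- 2 * xx + rnorm(length(xx), sd = 6)
    f <- fit_linear(xx, yy)
    ci <- f$intercept + c(-1, 1) * qt(0.975, length(xx) - 2) * f$intercept_se
    if (ci[1] <= 0 && ci[2] >= 0) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("slope recovery on simulated populations is unbiased", {
  # exact law: machine-precision recovery
  pop0 <- simulate_population(n_cells = 100, copies_per_fl = 1.3,
                              obs_noise_cv = 0, seed = 3)
  f0 <- fit_linear(pop0$volume_fl, pop0$copies)
  expect_equal(f0$slope, 1.3, tolerance = 1e-12)
  expect_equal(f0$intercept, 0, tolerance = 1e-9)
  # noisy law: slope estimates centred on the truth over repeated draws
  set.seed(29)
  slopes <- vapply(1:200, function(i) {
    pop <- simulate_population(n_cells = 60, copies_per_fl = 1.3,
                               obs_noise_cv = 0.15, seed = NULL)
    fit_linear(pop$volume_fl, pop$copies)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1.3), 3 * sd(slopes) / sqrt(length(slopes)))
})

test_that("constant-amount concentration ratio is the inverse volume ratio", {
  expect_equal(constant_amount_ratio(50, 100), 0.5)
  expect_equal(constant_amount_ratio(70, 70), 1.0)
  expect_equal(constant_amount_ratio(40, 100), 0.4)
  expect_equal(constant_amount_ratio(40, 100) * (100 / 40), 1.0)
  expect_error(constant_amount_ratio(-1, 10), "positive")
})

test_that("mtDNA per nucleoid recovers a planted ratio of two", {
  pop <- simulate_population(n_cells = 400, copies_per_nucleoid = 2,
                             obs_noise_cv = 0, seed = 19)
  r <- mtdna_per_nucleoid(pop$volume_fl, pop$copies,
                          pop$volume_fl, pop$nucleoids)
  expect_true(all(r$defined))
  expect_equal(r$ratio, rep(2, nrow(r)), tolerance = 1e-12)
  # simple arithmetic case
  r2 <- mtdna_per_nucleoid(c(50, 50), c(40, 40), c(50, 50), c(20, 20),
                           edges = c(40, 60))
  expect_equal(r2$ratio, 2.0)
  # zero nucleoids with copies present: flagged undefined, not dropped
  r3 <- mtdna_per_nucleoid(c(50, 50), c(40, 40), c(50, 50), c(0, 0),
                           edges = c(40, 60))
  expect_false(r3$defined)
  expect_true(is.na(r3$ratio))
  expect_error(mtdna_per_nucleoid(c(1, 2), c(1, 1), c(10, 20), c(1, 1)),
               "overlap")
})

test_that("flow background subtraction and two-day envelope", {
  bins <- data.frame(center = 1:5, mean = c(10, 12, 15, 19, 24),
                     se = rep(0.5, 5))
  ctl <- data.frame(center = 1:5, mean = rep(3, 5), se = rep(0.2, 5))
  # sample equal to control: zero everywhere
  z <- flow_background_subtract(ctl, ctl)
  expect_equal(z$signal, rep(0, 5))
  # constant shift is recovered exactly
  shifted <- bins
  shifted$mean <- ctl$mean + 7
  s <- flow_background_subtract(shifted, ctl)
  expect_equal(s$signal, rep(7, 5))

  # two days: point estimate is the day mean, envelope from day extremes
  d1 <- data.frame(center = 1:3, mean = c(11, 13, 15), se = c(1, 1, 1))
  d2 <- data.frame(center = 1:3, mean = c(9, 15, 17), se = c(0.5, 0.5, 0.5))
  ctl2 <- data.frame(center = 1:3, mean = rep(2, 3), se = rep(0.1, 3))
  e <- flow_background_subtract(list(d1, d2), list(ctl2, ctl2))
  expect_equal(e$signal, c(8, 12, 14))
  expect_equal(e$lower, c(9 - 2 - 0.5, 13 - 2 - 1, 15 - 2 - 1))
  expect_equal(e$upper, c(11 - 2 + 1, 15 - 2 + 0.5, 17 - 2 + 0.5))
  expect_error(flow_background_subtract(d1, ctl2[1:2, ]), "centres|centre|differ")
})

test_that("two-day envelope covers the true signal in most simulations", {
  set.seed(37)
  covered <- 0L
  total <- 0L
  n_rep <- 30L  # replicate events per bin and day
  for (trial in 1:100) {
    truth <- c(5, 8, 12)
    day <- lapply(1:2, function(d) {
      means <- vapply(truth, function(mu) mean(rnorm(n_rep, mu + 2, 2)),
                      numeric(1))
      data.frame(center = 1:3, mean = means, se = 2 / sqrt(n_rep))
    })
    ctl <- lapply(1:2, function(d) {
      data.frame(center = 1:3,
                 mean = vapply(1:3, function(i) mean(rnorm(n_rep, 2, 1)),
                               numeric(1)),
                 se = 1 / sqrt(n_rep))
    })
    e <- flow_background_subtract(day, ctl)
    covered <- covered + sum(e$lower <= truth & truth <= e$upper)
    total <- total + length(truth)
  }
  expect_gte(covered / total, 0.90)
})

test_that("strain comparison reports Welch p and normality checks", {
  set.seed(41)
  out <- compare_strains(rnorm(6, 10), rnorm(6, 14))
  expect_lt(out$p_value, 0.05)
  expect_true(is.finite(out$shapiro_p_x))
})
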