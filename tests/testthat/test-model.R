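wt <- function(kR = 0.1, kD = 1) {
  model_params(kR = kR, kD = kD, K1 = 5, K2 = 100, T = 150, m = 5, a = 100)
}

test_that("rate equation matches its closed form and boundary behavior", {
  p <- wt()
  # hand calculation of the printed expression at n = 1
  expect_equal(mtdna_rate(1, p), 0.5 / 10 - 1 / 200 - log(2) / 150)
  expect_identical(mtdna_rate(0, p), 0)
  # without polymerase only loss terms remain
  p0 <- model_params(kR = 0.1, kD = 1, K1 = 5, K2 = 100, T = 150,
                     m = 1e-12, a = 100)
  expect_lt(mtdna_rate(1, p0), 0)
  expect_error(mtdna_rate(-1, p), "non-negative")
})

test_that("quadratic coefficients follow the cleared-denominator expansion", {
  co <- steady_state_coefficients(wt())
  expect_equal(co[["A"]], 5 * 100 * log(2) + 1 * 5 * 150)
  expect_equal(co[["B"]],
               100 * 5 * log(2) - 100 * 5 * 0.1 * 150 + 100 * 5 * log(2) + 1 * 5 * 150)
  expect_equal(co[["C"]], 100 * 5 * log(2) - 100 * 5 * 0.1 * 150)
  # C = a*m*(ln2 - kR*T) vanishes exactly at kR*T = ln2
  p_crit <- model_params(kR = log(2) / 150, kD = 1, K1 = 5, K2 = 100,
                         T = 150, m = 5, a = 100)
  expect_equal(steady_state_coefficients(p_crit)[["C"]], 0)
  # supercritical replication: C < 0, A > 0
  expect_lt(steady_state_coefficients(wt())[["C"]], 0)
  expect_gt(steady_state_coefficients(wt())[["A"]], 0)
})

test_that("steady state is the rate equation's fixed point", {
  for (p in wild_type_grid()) {
    ss <- steady_state(p)
    expect_true(ss$exists)
    expect_lt(abs(mtdna_rate(ss$n, p)), 1e-10 * ss$n)
  }
})

test_that("no positive steady state below the replication threshold", {
  p <- model_params(kR = 0.001, kD = 1, K1 = 5, K2 = 100, T = 150,
                    m = 5, a = 100)  # kR*T = 0.15 < ln 2
  ss <- steady_state(p)
  expect_false(ss$exists)
  expect_identical(ss$n, 0)
  # trajectory decays toward extinction
  tr <- integrate_model(p, n0 = 1, t_end = 100 * p$T)
  expect_lt(tail(tr$n, 1), 1e-6)
})

test_that("existence criterion is exactly kR*T > ln 2 across a sweep", {
  set.seed(11)
  for (i in 1:50) {
    T <- runif(1, 50, 400)
    p <- model_params(kR = runif(1, 1e-4, 0.05), kD = exp(runif(1, -1, 3)),
                      K1 = exp(runif(1, 0, 3)), K2 = exp(runif(1, 2, 5)),
                      T = T, m = exp(runif(1, 0, 3)), a = exp(runif(1, 2, 5)))
    expect_identical(steady_state(p)$exists, p$kR * p$T > log(2))
  }
})

test_that("homogeneity: scaling m and a together scales the steady state", {
  p <- wt()
  n0 <- steady_state(p)$n
  for (cc in c(0.25, 0.5, 2, 4)) {
    ps <- model_params(kR = p$kR, kD = p$kD, K1 = p$K1, K2 = p$K2, T = p$T,
                       m = cc * p$m, a = cc * p$a)
    expect_equal(steady_state(ps)$n, cc * n0, tolerance = 1e-12)
  }
})

test_that("steady state is non-decreasing in m and in a", {
  base <- wt(kR = 0.1, kD = 10)
  n_of <- function(m, a) {
    steady_state(model_params(kR = base$kR, kD = base$kD, K1 = base$K1,
                              K2 = base$K2, T = base$T, m = m, a = a))$n
  }
  ms <- seq(1, 20, length.out = 15)
  as_ <- seq(20, 400, length.out = 15)
  expect_true(all(diff(vapply(ms, n_of, numeric(1), a = 100)) >= -1e-12))
  expect_true(all(diff(vapply(as_, n_of, numeric(1), m = 5)) >= -1e-12))
})

test_that("trajectories approach the steady state monotonically", {
  p <- wt()
  nstar <- steady_state(p)$n
  # fixed point start stays put
  tr0 <- integrate_model(p, n0 = nstar, t_end = 10 * p$T)
  expect_true(all(abs(tr0$n - nstar) < 1e-8 * nstar))
  # extinct start stays extinct
  expect_true(all(integrate_model(p, n0 = 0, t_end = 5 * p$T)$n == 0))
  # relaxation from above is monotone decreasing toward n*
  tr <- integrate_model(p, n0 = 10 * nstar, t_end = 100 * p$T)
  expect_true(all(diff(tr$n) <= 1e-10))
  expect_equal(tail(tr$n, 1), nstar, tolerance = 1e-8)
})

test_that("dosage ratios: equal scaling is exact, single hemizygotes bounded", {
  for (p in wild_type_grid()) {
    expect_equal(relative_mtdna(p, dosage_perturbation(0.5, 0.5)), 0.5,
                 tolerance = 1e-12)
    expect_equal(relative_mtdna(p, dosage_perturbation(2, 2)), 2,
                 tolerance = 1e-12)
    for (d in list(dosage_perturbation(0.5, 1), dosage_perturbation(1, 0.5))) {
      r <- relative_mtdna(p, d)
      expect_gte(r, 0.5)
      expect_lte(r, 1.0)
    }
  }
  # error when the wild type has no steady state
  p_sub <- model_params(kR = 0.001, kD = 1, K1 = 5, K2 = 100, T = 150,
                        m = 5, a = 100)
  expect_error(relative_mtdna(p_sub, dosage_perturbation(0.5, 0.5)),
               "does not exist")
})

test_that("sweep reproduces the replication/degradation regime pattern", {
  grid <- wild_type_grid()
  sw <- sweep_dosage(grid, list(dosage_perturbation(0.5, 0.5),
                                dosage_perturbation(0.5, 1),
                                dosage_perturbation(1, 0.5)))
  expect_equal(nrow(sw), 12L)
  expect_true(all(sw$relative_mtdna[sw$fm == 0.5 & sw$fa == 0.5] == 0.5))
  # faster replication pushes the polymerase hemizygote toward 50%
  m_hemi <- function(kR, kD) {
    sw$relative_mtdna[sw$kR == kR & sw$kD == kD & sw$fm == 0.5 & sw$fa == 1]
  }
  a_hemi <- function(kR, kD) {
    sw$relative_mtdna[sw$kR == kR & sw$kD == kD & sw$fm == 1 & sw$fa == 0.5]
  }
  expect_lt(m_hemi(0.1, 1), m_hemi(0.01, 1))
  expect_gt(a_hemi(0.1, 1), a_hemi(0.01, 1))
  # faster degradation does the opposite
  expect_gt(m_hemi(0.01, 10), m_hemi(0.01, 1))
  expect_lt(a_hemi(0.01, 10), a_hemi(0.01, 1))
  # empty perturbation list yields an empty table
  expect_equal(nrow(sweep_dosage(grid, list())), 0L)
})

test_that("parameter sets round-trip through JSON", {
  p <- wt(kR = 0.01, kD = 10)
  f <- tempfile(fileext = ".json")
  write_model_params(p, f)
  q <- read_model_params(f)
  expect_equal(unclass(q), unclass(p))
  unlink(f)
})

test_that("invalid parameters are rejected", {
  expect_error(model_params(kR = -1, kD = 1, K1 = 5, K2 = 100, T = 150,
                            m = 5, a = 100), "strictly positive")
  expect_error(model_params(kR = 0.1, kD = 1, K1 = 5, K2 = 100, T = 0,
                            m = 5, a = 100), "strictly positive")
})
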