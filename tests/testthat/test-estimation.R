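test_that("goodness-of-fit statistic matches hand-evaluated cases", {
  # perfect fit
  expect_equal(r_squared(c(3.2, 1.1, 7), c(3.2, 1.1, 7)), 1)
  # calculated series constant at the observed mean: no explained spread
  expect_equal(r_squared(c(2, 2, 2), c(1, 2, 3)), 0)
  # mixed case: SSM = 5, SSE = 1
  expect_equal(r_squared(c(1, 2, 4), c(1, 2, 3)), 5 / 6)
  expect_error(r_squared(numeric(0), numeric(0)), "nonempty")
  expect_error(r_squared(1:3, 1:2), "equal length")
})

test_that("goodness-of-fit statistic is always within [0, 1]", {
  set.seed(51)
  for (i in 1:50) {
    n <- sample(3:20, 1)
    r2 <- r_squared(rnorm(n, sd = runif(1, 0.1, 10)),
                    rnorm(n, sd = runif(1, 0.1, 10)))
    expect_gte(r2, 0)
    expect_lte(r2, 1)
  }
})

test_that("noise-free synthetic data returns the generating parameters", {
  sc <- builtin_scenario("native")
  tc <- simulate_time_course(sc$params, sc$initial, sc$sample_times)
  fit <- fit_kinetics(tc)
  expect_true(fit$converged)
  for (nm in c("mu_max", "C_Xm", "m_S", "alpha", "beta"))
    expect_lt(rel_err(fit$params[[nm]], sc$params[[nm]]), 0.01)
  expect_equal(fit$params$Y_XS, 0.45)  # held fixed
  # perfect-fit limit of the goodness-of-fit statistic
  expect_equal(fit$r2_X, 1, tolerance = 1e-6)
  expect_equal(fit$r2_S, 1, tolerance = 1e-6)
  expect_equal(fit$r2_P, 1, tolerance = 1e-6)
  expect_lt(fit$objective_value, 1e-12)
})

test_that("the fit is deterministic for a fixed multistart seed", {
  sc <- builtin_scenario("BBF001")
  tc <- generate_observations(sc, noise_spec(seed = 8))
  f1 <- fit_kinetics(tc)
  f2 <- fit_kinetics(tc)
  expect_identical(unclass(f1$params), unclass(f2$params))
})

test_that("objective never increases across accepted optimizer iterations", {
  sc <- builtin_scenario("BBF001")
  tc <- generate_observations(sc, noise_spec(seed = 8))
  fit <- fit_kinetics(tc)
  expect_true(all(diff(fit$rss_trace) <= 1e-12))
})

test_that("insufficient data is rejected with a clear message", {
  sc <- builtin_scenario("native")
  tc <- simulate_time_course(sc$params, sc$initial, 0:3)
  expect_error(fit_kinetics(tc), "6 distinct observation times")
  tc6 <- simulate_time_course(sc$params, sc$initial, 0:5)
  tc6$dha_g_per_L[2:6] <- NA  # product seen only at 1 time
  expect_error(fit_kinetics(tc6), "dha_g_per_L")
})

test_that("fit configuration validates bounds", {
  expect_error(fit_config(lower = c(mu_max = 2, C_Xm = 1e-6, m_S = 0,
                                    alpha = 0, beta = 0, Y_XS = 0.05),
                          upper = c(mu_max = 1, C_Xm = 60, m_S = 0.5,
                                    alpha = 1, beta = 0.5, Y_XS = 1)),
               "lower bound")
})

test_that("product formation partitions into growth and non-growth shares", {
  sc <- builtin_scenario("BBF002")
  tc <- simulate_time_course(sc$params, sc$initial, sc$sample_times)
  fit <- fit_kinetics(tc)
  part <- mixed_growth_partition(fit, tc)
  expect_equal(part$growth_share + part$non_growth_share, 1,
               tolerance = 1e-9)
  expect_true(part$growth_dominant)  # alpha 0.055 > beta 0.020
  # growth-associated integral of alpha*mu*C_X equals alpha * delta(C_X)
  p <- fit$params
  dX <- tc$dcw_g_per_L[6] - tc$dcw_g_per_L[1]
  expect_equal(part$growth_formed_g_per_L, p$alpha * dX, tolerance = 1e-5)
  # the two shares account for all product formed
  dP <- tc$dha_g_per_L[6] - tc$dha_g_per_L[1]
  expect_equal(part$total_formed_g_per_L, dP, tolerance = 1e-4)

  # degenerate coefficient cases
  fit0 <- fit
  fit0$params <- kinetic_params(1.617, 19.891, 0.45, 0.033,
                                alpha = 0.055, beta = 0)
  expect_equal(mixed_growth_partition(fit0, tc)$non_growth_share, 0)
  fit0$params <- kinetic_params(1.617, 19.891, 0.45, 0.033,
                                alpha = 0, beta = 0.02)
  expect_equal(mixed_growth_partition(fit0, tc)$growth_share, 0)
})
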