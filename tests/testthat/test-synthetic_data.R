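test_that("built-in scenarios carry the published fitted constants", {
  expected <- list(
    native = c(mu_max = 1.568, C_Xm = 12.934, Y_XS = 0.45, m_S = 0.005,
               alpha = 0.100, beta = 0.001),
    BBF001 = c(mu_max = 1.585, C_Xm = 17.866, Y_XS = 0.45, m_S = 0.024,
               alpha = 0.033, beta = 0.029),
    BBF002 = c(mu_max = 1.617, C_Xm = 19.891, Y_XS = 0.45, m_S = 0.033,
               alpha = 0.055, beta = 0.020))
  for (nm in names(expected)) {
    sc <- builtin_scenario(nm)
    expect_identical(unlist(unclass(sc$params))[names(expected[[nm]])],
                     expected[[nm]])
    expect_identical(sc$sample_times, 0:5)  # daily over the 5-day run
  }
  expect_error(builtin_scenario("BBF999"))
})

test_that("noise specification validates its fields", {
  expect_s3_class(noise_spec(), "noise_spec")
  expect_error(noise_spec(cv_X = -0.1), ">= 0")
  expect_error(noise_spec(replicates = 0), "replicates")
})

test_that("zero noise reproduces the noise-free trajectory exactly", {
  sc <- builtin_scenario("native")
  obs <- generate_observations(sc, noise_spec(cv_X = 0, cv_S = 0, cv_P = 0,
                                              floor_sd_X = 0, floor_sd_S = 0,
                                              floor_sd_P = 0,
                                              replicates = 2))
  clean <- simulate_time_course(sc$params, sc$initial, sc$sample_times)
  for (r in 1:2) {
    sub <- obs[obs$replicate == r, ]
    expect_identical(sub$dcw_g_per_L, clean$dcw_g_per_L)
    expect_identical(sub$glucose_g_per_L, clean$glucose_g_per_L)
    expect_identical(sub$dha_g_per_L, clean$dha_g_per_L)
  }
})

test_that("generation is bit-identical under a fixed seed", {
  sc <- builtin_scenario("BBF001")
  a <- generate_observations(sc, noise_spec(seed = 99))
  b <- generate_observations(sc, noise_spec(seed = 99))
  expect_identical(a, b)
  c <- generate_observations(sc, noise_spec(seed = 100))
  expect_false(identical(a$dcw_g_per_L, c$dcw_g_per_L))
})

test_that("per-variable noise streams are independent of each other", {
  sc <- builtin_scenario("BBF001")
  a <- generate_observations(sc, noise_spec(seed = 5))
  b <- generate_observations(sc, noise_spec(seed = 5, cv_P = 0.2))
  # changing the product CV must not perturb the biomass stream
  expect_identical(a$dcw_g_per_L, b$dcw_g_per_L)
  expect_identical(a$glucose_g_per_L, b$glucose_g_per_L)
})

test_that("truncation keeps all concentrations non-negative", {
  sc <- builtin_scenario("native")
  obs <- generate_observations(sc, noise_spec(cv_X = 1, cv_S = 1, cv_P = 1,
                                              seed = 3, replicates = 20))
  expect_true(all(obs$dcw_g_per_L >= 0))
  expect_true(all(obs$glucose_g_per_L >= 0))
  expect_true(all(obs$dha_g_per_L >= 0))
})

test_that("empirical replicate CV converges to the specified CV", {
  sc <- builtin_scenario("native")
  sc$sample_times <- c(0, 3)  # biomass well above the floor at day 3
  obs <- generate_observations(sc, noise_spec(cv_X = 0.05, cv_S = 0,
                                              cv_P = 0, floor_sd_X = 0,
                                              floor_sd_S = 0, floor_sd_P = 0,
                                              seed = 17, replicates = 1000))
  x <- obs$dcw_g_per_L[obs$time_d == 3]
  expect_equal(stats::sd(x) / mean(x), 0.05, tolerance = 0.05)
})

test_that("generation leaves the caller's RNG state untouched", {
  set.seed(123); before <- .Random.seed
  invisible(generate_observations(builtin_scenario("native"),
                                  noise_spec(seed = 1)))
  expect_identical(.Random.seed, before)
})
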