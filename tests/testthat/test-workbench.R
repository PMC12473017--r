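test_that("time-course files round-trip losslessly at full precision", {
  set.seed(81)
  tc <- as_time_course(data.frame(
    time_d = rep(c(0, exp(1) / 3, pi, 4.123456789012345), each = 2),
    replicate = rep(1:2, 4),
    dcw_g_per_L = runif(8, 0, 20),
    glucose_g_per_L = runif(8, 0, 40),
    dha_g_per_L = runif(8, 0, 3)), label = "rt")
  f <- withr::local_tempfile(fileext = ".csv")
  write_time_course(tc, f)
  back <- read_time_course(f, label = "rt")
  for (v in c("time_d", "dcw_g_per_L", "glucose_g_per_L", "dha_g_per_L"))
    expect_identical(back[[v]], tc[[v]])
})

test_that("reader rejects missing, empty and malformed files", {
  expect_error(read_time_course("does-not-exist.csv"), "no such file")
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), f)
  expect_error(read_time_course(f), "empty")
  writeLines(c("a,b", "1,2"), f)
  expect_error(read_time_course(f), "header")
})

test_that("run configuration requires exactly one data source", {
  expect_error(run_config(), "exactly one")
  expect_error(run_config(scenario = "native", input = "x.csv"),
               "exactly one")
  expect_s3_class(run_config(scenario = "native"), "run_config")
})

test_that("simulation runs write deterministic files plus metadata", {
  out <- withr::local_tempdir()
  cfg <- run_config(scenario = "BBF002", t_end = 10, out_dir = out,
                    seed = 4)
  f1 <- suppressMessages(run_simulate(cfg))
  tc <- read_time_course(f1)
  expect_equal(tc$dcw_g_per_L[nrow(tc)], 19.891, tolerance = 5e-4)
  bytes1 <- readBin(f1, "raw", file.size(f1))
  f2 <- suppressMessages(run_simulate(cfg))
  expect_identical(readBin(f2, "raw", file.size(f2)), bytes1)
  meta <- jsonlite::read_json(sub("\\.csv$", ".json", f1))
  expect_equal(meta$seed, 4)
  expect_true(nzchar(meta$config_hash))
  expect_equal(meta$params$C_Xm, 19.891)
})

test_that("noisy generation through the pipeline honours the root seed", {
  out <- withr::local_tempdir()
  cfg <- run_config(scenario = "native", noise = noise_spec(),
                    out_dir = out, seed = 11)
  f1 <- suppressMessages(run_simulate(cfg))
  a <- readBin(f1, "raw", file.size(f1))
  f2 <- suppressMessages(run_simulate(cfg))
  expect_identical(readBin(f2, "raw", file.size(f2)), a)
  obs <- read_time_course(f1)
  expect_equal(sort(unique(obs$replicate)), 1:3)
})

test_that("the fitting pipeline recovers the generating constants", {
  out <- withr::local_tempdir()
  sim <- run_config(scenario = "native", out_dir = out)
  f <- suppressMessages(run_simulate(sim))
  fit <- suppressMessages(run_fit(run_config(input = f, out_dir = out)))
  expect_lt(rel_err(fit$params$alpha, 0.100), 0.01)
  expect_lt(rel_err(fit$params$m_S, 0.005), 0.01)
  rep_file <- file.path(out, "native_timecourse_fit.csv")
  expect_true(file.exists(rep_file))
  rep <- utils::read.csv(rep_file)
  expect_equal(rep$parameter[1:6],
               c("mu_max", "C_Xm", "Y_XS", "m_S", "alpha", "beta"))
})

test_that("the fitting pipeline rejects under-sampled inputs", {
  out <- withr::local_tempdir()
  sc <- builtin_scenario("native")
  short <- simulate_time_course(sc$params, sc$initial, 0:2)
  f <- file.path(out, "short.csv")
  write_time_course(short, f)
  expect_error(suppressMessages(run_fit(run_config(input = f,
                                                   out_dir = out))),
               "distinct observation times")
})

test_that("the descriptor pipeline reproduces the hand-worked panel", {
  out <- withr::local_tempdir()
  f <- file.path(out, "toy.csv")
  write_time_course(toy_time_course(), f)
  panel <- suppressMessages(run_describe(run_config(input = f,
                                                    out_dir = out)))
  expect_equal(panel$Q_X, 2.0)
  expect_true(file.exists(file.path(out, "toy_descriptors.csv")))
  # BBF002 noise-free run, window before exhaustion: yield below 0.45
  fb <- suppressMessages(run_simulate(run_config(scenario = "BBF002",
                                                 out_dir = out)))
  pb <- suppressMessages(run_describe(run_config(input = fb, out_dir = out),
                                      t1 = 0, t2 = 3))
  expect_lt(pb$Y_XS_obs, 0.45)
  # off-grid window override is a descriptive error
  expect_error(suppressMessages(
    run_describe(run_config(input = fb, out_dir = out), t1 = 0, t2 = 2.5)),
    "not a sampled time")
})

test_that("YAML configurations load into equivalent run configs", {
  out <- withr::local_tempdir()
  yml <- file.path(out, "cfg.yaml")
  writeLines(c("scenario: BBF001",
               "seed: 9",
               paste0("out_dir: ", out),
               "noise:",
               "  cv_X: 0.02",
               "  replicates: 2"), yml)
  cfg <- load_run_config(yml)
  expect_equal(cfg$scenario, "BBF001")
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$noise$cv_X, 0.02)
  expect_equal(cfg$noise$replicates, 2L)
})
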