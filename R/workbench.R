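#' Write a time course to delimited text
#'
#' Comma-separated, header `time_d,replicate,dcw_g_per_L,glucose_g_per_L,
#' dha_g_per_L`, one row per observation. Numbers are written with 17
#' significant digits so a write-then-read round trip is lossless to full
#' double precision. Missing values are written empty.
#'
#' @param data A `time_course` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(data, path) {
  cols <- c("time_d", "replicate", "dcw_g_per_L", "glucose_g_per_L",
            "dha_g_per_L")
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))
  lines <- c(paste(cols, collapse = ","),
             apply(cbind(fmt(data$time_d), as.character(data$replicate),
                         fmt(data$dcw_g_per_L), fmt(data$glucose_g_per_L),
                         fmt(data$dha_g_per_L)),
                   1, paste, collapse = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Read a time course from delimited text
#'
#' @param path CSV file in the format written by [write_time_course()].
#' @param label Run identifier; defaults to the file name without extension.
#' @return A `time_course` data frame.
#' @export
read_time_course <- function(path, label = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readLines(path)
  if (length(raw) < 1L || !nzchar(raw[1]))
    stop("empty time-course file: ", path, call. = FALSE)
  df <- try(utils::read.csv(path, stringsAsFactors = FALSE), silent = TRUE)
  if (inherits(df, "try-error"))
    stop("cannot parse ", path, ": ", attr(df, "condition")$message,
         call. = FALSE)
  need <- c("time_d", "replicate", "dcw_g_per_L", "glucose_g_per_L",
            "dha_g_per_L")
  if (!all(need %in% names(df)))
    stop("bad header in ", path, " (line 1): expected columns ",
         paste(need, collapse = ","), call. = FALSE)
  if (nrow(df) == 0L) stop("no observations in ", path, call. = FALSE)
  for (nm in need) {
    bad <- which(!is.na(df[[nm]]) & !is.numeric(df[[nm]]))
    if (length(bad))
      stop("non-numeric value in column '", nm, "' at line ", bad[1] + 1L,
           " of ", path, call. = FALSE)
  }
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  as_time_course(df, label = label)
}

#' Pipeline run configuration
#'
#' Binds one data source (a built-in scenario or an input time-course file;
#' exactly one must be given) to noise, simulation and fitting settings plus
#' an output directory.
#'
#' @param scenario Name of a built-in scenario, or `NULL`.
#' @param input Path to a time-course CSV, or `NULL`.
#' @param noise A [noise_spec()] or `NULL` for noise-free output.
#' @param sample_times Sampling grid override (days); `NULL` keeps the
#'   scenario default.
#' @param t_end If given with no explicit grid, daily samples to `t_end`.
#' @param fit A [fit_config()].
#' @param out_dir Output directory (created on demand).
#' @param seed Root seed recorded in metadata and threaded into `noise`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(scenario = NULL, input = NULL, noise = NULL,
                       sample_times = NULL, t_end = NULL,
                       fit = fit_config(), out_dir = ".", seed = 1L) {
  if (is.null(scenario) == is.null(input))
    stop("supply exactly one of a built-in scenario or an input file",
         call. = FALSE)
  structure(list(scenario = scenario, input = input, noise = noise,
                 sample_times = sample_times, t_end = t_end, fit = fit,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Recognized top-level keys: `scenario`, `input`, `out_dir`, `seed`,
#' `sample_times` or `t_end`, and nested sections `noise` (fields of
#' [noise_spec()]) and `fit` (fields of [fit_config()]).
#'
#' @param path YAML file.
#' @return A [run_config()].
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  noise <- if (!is.null(y$noise)) do.call(noise_spec, y$noise) else NULL
  fit <- if (!is.null(y$fit)) do.call(fit_config, y$fit) else fit_config()
  run_config(scenario = y$scenario, input = y$input, noise = noise,
             sample_times = y$sample_times, t_end = y$t_end, fit = fit,
             out_dir = y$out_dir %||% ".", seed = y$seed %||% 1L)
}

resolve_source <- function(config) {
  if (!is.null(config$scenario)) {
    sc <- builtin_scenario(config$scenario)
    if (!is.null(config$sample_times)) sc$sample_times <- config$sample_times
    else if (!is.null(config$t_end)) sc$sample_times <- seq(0, config$t_end)
    sc
  } else NULL
}

write_sidecar <- function(path, config, extra = list()) {
  meta <- c(list(
    tool = "fermkin",
    version = as.character(utils::packageVersion("fermkin")),
    seed = config$seed,
    config_hash = fnv1a_hash(paste(deparse(unclass(config)),
                                   collapse = "\n")),
    created = "run-time"), extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate (or generate noisy) data and write it to disk
#'
#' Writes `<out_dir>/<label>_timecourse.csv` plus a JSON metadata sidecar
#' carrying the parameters, seed, tool version and a configuration hash for
#' exact re-runs. With a `noise` section in the config the output carries
#' replicated noisy observations; without one it is the noise-free
#' trajectory.
#'
#' @param config A [run_config()] with a `scenario` source.
#' @return Path of the written data file, invisibly.
#' @export
run_simulate <- function(config) {
  sc <- resolve_source(config)
  if (is.null(sc))
    stop("run_simulate needs a built-in scenario source", call. = FALSE)
  if (!is.null(config$noise)) {
    config$noise$seed <- config$seed
    tc <- generate_observations(sc, config$noise)
  } else {
    tc <- simulate_time_course(sc$params, sc$initial, sc$sample_times,
                               label = sc$name)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(config$out_dir, paste0(sc$name, "_timecourse"))
  write_time_course(tc, paste0(base, ".csv"))
  write_sidecar(paste0(base, ".json"), config,
                extra = list(scenario = sc$name,
                             params = unclass(sc$params),
                             noisy = !is.null(config$noise)))
  message("wrote ", base, ".csv (", nrow(tc), " observations)")
  invisible(paste0(base, ".csv"))
}

#' Fit the kinetic model to a time course and write the parameter report
#'
#' Reads the configured input file (or generates the configured scenario
#' noise-free), runs [fit_kinetics()], logs the multistart trace to standard
#' error, and writes a parameter-by-run report
#' `<out_dir>/<label>_fit.csv` with rows mu_max, C_Xm, Y_XS, m_S, alpha,
#' beta, r2_X, r2_S, r2_P, objective, converged, plus a JSON sidecar.
#'
#' @param config A [run_config()].
#' @return The [fit_kinetics()] result, invisibly.
#' @export
run_fit <- function(config) {
  if (!is.null(config$input)) {
    tc <- read_time_course(config$input)
  } else {
    sc <- resolve_source(config)
    tc <- simulate_time_course(sc$params, sc$initial, sc$sample_times,
                               label = sc$name)
  }
  fit <- fit_kinetics(tc, config$fit)
  apply(fit$multistart, 1, function(r)
    message(sprintf("multistart %d: objective %.6g converged %s",
                    r[["start"]], r[["objective"]], r[["converged"]])))
  label <- attr(tc, "label")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(config$out_dir, paste0(label, "_fit"))
  p <- fit$params
  rep <- data.frame(
    parameter = c("mu_max", "C_Xm", "Y_XS", "m_S", "alpha", "beta",
                  "r2_X", "r2_S", "r2_P", "objective", "converged"),
    value = c(p$mu_max, p$C_Xm, p$Y_XS, p$m_S, p$alpha, p$beta,
              fit$r2_X, fit$r2_S, fit$r2_P, fit$objective_value,
              as.numeric(fit$converged)))
  names(rep)[2] <- label
  utils::write.csv(format(rep, digits = 15), paste0(base, ".csv"),
                   row.names = FALSE, quote = FALSE)
  write_sidecar(paste0(base, ".json"), config,
                extra = list(label = label, params = unclass(p),
                             r2 = list(X = fit$r2_X, S = fit$r2_S,
                                       P = fit$r2_P),
                             converged = fit$converged))
  invisible(fit)
}

#' Compute and write the kinetic descriptor panel
#'
#' One panel row per run, window chosen by [pick_window()] unless `t1`/`t2`
#' are supplied; written to `<out_dir>/<label>_descriptors.csv`.
#'
#' @param config A [run_config()].
#' @param t1,t2 Optional window override (must be sampled times).
#' @return The `descriptor_panel`, invisibly.
#' @export
run_describe <- function(config, t1 = NULL, t2 = NULL) {
  if (!is.null(config$input)) {
    tc <- read_time_course(config$input)
  } else {
    sc <- resolve_source(config)
    tc <- simulate_time_course(sc$params, sc$initial, sc$sample_times,
                               label = sc$name)
  }
  panel <- compute_descriptors(tc, t1, t2)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(config$out_dir,
                    paste0(attr(tc, "label"), "_descriptors"))
  utils::write.csv(format(panel, digits = 15), paste0(base, ".csv"),
                   row.names = FALSE, quote = FALSE)
  write_sidecar(paste0(base, ".json"), config,
                extra = list(label = attr(tc, "label"),
                             window = c(panel$t1, panel$t2)))
  invisible(panel)
}
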