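#' Built-in fitted parameter scenarios
#'
#' Returns one of the three named shake-flask scenarios (native, BBF001,
#' BBF002) with its fitted kinetic constants, the default inoculated initial
#' state, and daily sampling over the 5-day cultivation.
#'
#' @param name One of `"native"`, `"BBF001"`, `"BBF002"`.
#' @return A list of class `scenario` with elements `name`, `params`
#'   ([kinetic_params()]), `initial` ([culture_state()]), `sample_times`.
#' @export
#' @examples
#' builtin_scenario("BBF002")$params
builtin_scenario <- function(name = c("native", "BBF001", "BBF002")) {
  name <- match.arg(name)
  tab <- list(
    native = kinetic_params(mu_max = 1.568, C_Xm = 12.934, Y_XS = 0.45,
                            m_S = 0.005, alpha = 0.100, beta = 0.001),
    BBF001 = kinetic_params(mu_max = 1.585, C_Xm = 17.866, Y_XS = 0.45,
                            m_S = 0.024, alpha = 0.033, beta = 0.029),
    BBF002 = kinetic_params(mu_max = 1.617, C_Xm = 19.891, Y_XS = 0.45,
                            m_S = 0.033, alpha = 0.055, beta = 0.020))
  structure(list(name = name, params = tab[[name]],
                 initial = default_initial_state(),
                 sample_times = 0:5),
            class = "scenario")
}

#' Measurement-noise specification for synthetic shake-flask data
#'
#' Independent Gaussian noise per variable with standard deviation
#' `max(cv * value, floor)`, truncated at zero. CV defaults of 5 % mirror
#' typical dry-cell-weight / HPLC / GC assay precision; floors represent
#' absolute instrument resolution near zero.
#'
#' @param cv_X,cv_S,cv_P Coefficients of variation (dimensionless, >= 0).
#' @param floor_sd_X,floor_sd_S,floor_sd_P Absolute noise floors, g/L (>= 0).
#' @param seed Integer root seed; per-variable child streams are derived
#'   deterministically from it.
#' @param replicates Observations per time point (>= 1); default 3 emulates
#'   independent triplicate flasks.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(cv_X = 0.05, cv_S = 0.05, cv_P = 0.05,
                       floor_sd_X = 0.01, floor_sd_S = 0.05,
                       floor_sd_P = 0.002,
                       seed = 1L, replicates = 3L) {
  ns <- list(cv_X = cv_X, cv_S = cv_S, cv_P = cv_P,
             floor_sd_X = floor_sd_X, floor_sd_S = floor_sd_S,
             floor_sd_P = floor_sd_P,
             seed = as.integer(seed), replicates = as.integer(replicates))
  if (any(unlist(ns[1:6]) < 0))
    stop("CVs and noise floors must be >= 0", call. = FALSE)
  if (ns$replicates < 1L) stop("replicates must be >= 1", call. = FALSE)
  structure(ns, class = "noise_spec")
}

# Deterministic child seed from a root seed and stream index (kept < 2^31).
child_seed <- function(root, k) {
  as.integer((as.numeric(root) %% 2147483647) * 31 + 7919 * k) %% 2147483647L
}

#' Generate noisy synthetic shake-flask observations
#'
#' Simulates the noise-free trajectory of a scenario, then adds independent
#' truncated-Gaussian measurement noise per variable and replicate. The same
#' root seed yields bit-identical output. Each variable draws from its own
#' deterministic child random stream, so e.g. changing `cv_P` does not
#' perturb the biomass noise.
#'
#' @param scenario A [builtin_scenario()] or compatible list with elements
#'   `params`, `initial`, `sample_times`, `name`.
#' @param noise A [noise_spec()].
#' @return A `time_course` data frame with `replicates` rows per time point
#'   and attributes `label`, `params`, `seed`.
#' @export
#' @examples
#' obs <- generate_observations(builtin_scenario("native"),
#'                              noise_spec(seed = 42))
#' head(obs)
generate_observations <- function(scenario, noise = noise_spec()) {
  if (!all(c("params", "initial", "sample_times") %in% names(scenario)))
    stop("scenario must carry params, initial and sample_times",
         call. = FALSE)
  clean <- simulate_time_course(scenario$params, scenario$initial,
                                scenario$sample_times,
                                label = scenario$name %||% "custom")
  nt <- nrow(clean)
  nr <- noise$replicates

  vars <- list(
    dcw_g_per_L     = c(noise$cv_X, noise$floor_sd_X, 1L),
    glucose_g_per_L = c(noise$cv_S, noise$floor_sd_S, 2L),
    dha_g_per_L     = c(noise$cv_P, noise$floor_sd_P, 3L))

  out <- data.frame(time_d = rep(clean$time_d, each = nr),
                    replicate = rep(seq_len(nr), times = nt))
  for (nm in names(vars)) {
    cv <- vars[[nm]][1]; fl <- vars[[nm]][2]; stream <- vars[[nm]][3]
    mu <- rep(clean[[nm]], each = nr)
    sd <- pmax(cv * mu, fl)
    if (all(sd == 0)) {
      out[[nm]] <- mu
    } else {
      y <- with_seed(child_seed(noise$seed, stream),
                     mu + stats::rnorm(length(mu), sd = sd))
      out[[nm]] <- pmax(y, 0)  # concentrations cannot be negative
    }
  }
  tc <- as_time_course(out, label = scenario$name %||% "custom",
                       params = scenario$params)
  attr(tc, "seed") <- noise$seed
  tc
}
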