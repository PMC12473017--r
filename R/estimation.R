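#' Configuration for kinetic parameter estimation
#'
#' Controls the bounded least-squares fit of the five free model constants
#' (mu_max, C_Xm, m_S, alpha, beta) to an observed time course. The
#' stoichiometric yield Y_X/S is fixed (default 0.45) unless `fix_Y_XS` is
#' `FALSE`, in which case it is estimated alongside the others.
#'
#' Default bounds are generous relative to the fitted values reported for
#' this organism: mu_max in (0, 5] 1/d, C_Xm in (0, 60] g/L, m_S in
#' [0, 0.5] g/(g d), alpha in [0, 1] g/g, beta in [0, 0.5] g/(g d).
#'
#' @param lower,upper Named numeric bounds for `mu_max`, `C_Xm`, `m_S`,
#'   `alpha`, `beta` (and `Y_XS` when it is free).
#' @param fix_Y_XS Keep the yield fixed at `Y_XS_value`? Default `TRUE`.
#' @param Y_XS_value The fixed stoichiometric yield, g/g. Default 0.45.
#' @param weight_mode Per-variable residual normalization. `"range"`
#'   (default) divides each variable's residuals by its observed range so
#'   glucose (~40 g/L) does not swamp the product (~2.5 g/L); `"none"` uses
#'   raw residuals.
#' @param multistart_count Number of Latin-hypercube starting points within
#'   the bounds. Default 8.
#' @param multistart_seed Seed for the Latin-hypercube draw, making the fit
#'   deterministic. Default 101.
#' @param rel_tol,abs_tol Integration tolerances used inside the objective.
#' @param max_iter Levenberg-Marquardt iteration cap per start.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(lower = c(mu_max = 1e-6, C_Xm = 1e-6, m_S = 0,
                                 alpha = 0, beta = 0, Y_XS = 0.05),
                       upper = c(mu_max = 5, C_Xm = 60, m_S = 0.5,
                                 alpha = 1, beta = 0.5, Y_XS = 1),
                       fix_Y_XS = TRUE, Y_XS_value = 0.45,
                       weight_mode = c("range", "none"),
                       multistart_count = 8L, multistart_seed = 101L,
                       rel_tol = 1e-8, abs_tol = 1e-10,
                       max_iter = 200L) {
  weight_mode <- match.arg(weight_mode)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("bounds must be finite", call. = FALSE)
  shared <- intersect(names(lower), names(upper))
  if (any(lower[shared] >= upper[shared]))
    stop("each lower bound must be below its upper bound", call. = FALSE)
  if (multistart_count < 1L) stop("multistart_count must be >= 1",
                                  call. = FALSE)
  structure(list(lower = lower, upper = upper, fix_Y_XS = fix_Y_XS,
                 Y_XS_value = Y_XS_value, weight_mode = weight_mode,
                 multistart_count = as.integer(multistart_count),
                 multistart_seed = as.integer(multistart_seed),
                 rel_tol = rel_tol, abs_tol = abs_tol,
                 max_iter = as.integer(max_iter)),
            class = "fit_config")
}

#' Goodness-of-fit statistic for a calculated-versus-observed series
#'
#' The statistic compares the spread of the model-calculated values about the
#' observed mean with the calculated-observed discrepancy:
#' \deqn{R^2 = \frac{\sum (C_{cal} - \bar{C}_{exp})^2}
#'                  {\sum (C_{cal} - \bar{C}_{exp})^2 +
#'                   \sum (C_{cal} - C_{exp})^2}}
#' It is bounded in \[0, 1\] by construction and equals 1 exactly at a
#' perfect fit. Note it is not the classical coefficient of determination
#' (it cannot go negative).
#'
#' @param predicted Model-calculated values.
#' @param observed Observed values of the same length.
#' @return The statistic, in \[0, 1\].
#' @export
#' @examples
#' r_squared(c(1, 2, 4), c(1, 2, 3))  # 5/6
r_squared <- function(predicted, observed) {
  if (length(predicted) == 0L || length(predicted) != length(observed))
    stop("predicted and observed must be nonempty and of equal length",
         call. = FALSE)
  ssm <- sum((predicted - mean(observed))^2)
  sse <- sum((predicted - observed)^2)
  if (ssm + sse == 0) return(1)  # identical constant series: perfect fit
  ssm / (ssm + sse)
}

free_param_names <- function(config) {
  if (config$fix_Y_XS) c("mu_max", "C_Xm", "m_S", "alpha", "beta")
  else c("mu_max", "C_Xm", "Y_XS", "m_S", "alpha", "beta")
}

params_from_vector <- function(theta, config) {
  kinetic_params(mu_max = theta[["mu_max"]], C_Xm = theta[["C_Xm"]],
                 Y_XS = if (config$fix_Y_XS) config$Y_XS_value
                        else theta[["Y_XS"]],
                 m_S = theta[["m_S"]], alpha = theta[["alpha"]],
                 beta = theta[["beta"]])
}

#' Fit the batch fermentation model to an observed time course
#'
#' Joint bounded weighted least squares over all three state variables:
#' the candidate parameters are integrated forward from the first observed
#' state, residuals (observed minus predicted) for biomass, glucose and
#' product are each normalized by the variable's observed range, stacked
#' into one vector, and minimized with Levenberg-Marquardt from several
#' Latin-hypercube starting points (best final objective wins; ties broken
#' by the first start). The fit is deterministic for a fixed
#' `multistart_seed`.
#'
#' @param data A `time_course` data frame with at least 6 distinct times and
#'   each variable observed at 4 or more times.
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: a list with elements `params`
#'   (the estimated [kinetic_params()]), `r2_X`, `r2_S`, `r2_P` (per-variable
#'   goodness-of-fit), `residuals` (long data frame of observed, predicted
#'   and residual per observation), `converged`, `objective_value`, `n_obs`,
#'   `rss_trace` (objective across accepted iterations of the winning
#'   start), and `multistart` (per-start summary).
#' @export
#' @examples
#' sc <- builtin_scenario("native")
#' tc <- simulate_time_course(sc$params, sc$initial, sc$sample_times)
#' fit <- fit_kinetics(tc)
#' fit$params
fit_kinetics <- function(data, config = fit_config()) {
  vars <- c("dcw_g_per_L", "glucose_g_per_L", "dha_g_per_L")
  ut <- sort(unique(data$time_d))
  if (length(ut) < 6L)
    stop("need at least 6 distinct observation times, got ", length(ut),
         call. = FALSE)
  for (v in vars) {
    nt <- length(unique(data$time_d[is.finite(data[[v]])]))
    if (nt < 4L)
      stop("variable '", v, "' must be observed at >= 4 times, got ", nt,
           call. = FALSE)
  }

  # initial state: replicate mean of the earliest observation
  first <- data[data$time_d == ut[1], , drop = FALSE]
  y0 <- culture_state(mean(first$dcw_g_per_L, na.rm = TRUE),
                      mean(first$glucose_g_per_L, na.rm = TRUE),
                      mean(first$dha_g_per_L, na.rm = TRUE))

  wts <- vapply(vars, function(v) {
    if (config$weight_mode == "none") return(1)
    r <- diff(range(data[[v]], na.rm = TRUE))
    if (r > 0) r else max(abs(data[[v]]), 1, na.rm = TRUE)
  }, numeric(1))

  free <- free_param_names(config)
  lower <- config$lower[free]; upper <- config$upper[free]

  obs_long <- do.call(rbind, lapply(vars, function(v) {
    keep <- is.finite(data[[v]])
    data.frame(time_d = data$time_d[keep], replicate = data$replicate[keep],
               variable = v, observed = data[[v]][keep])
  }))

  predict_at <- function(params) {
    tc <- simulate_time_course(params, y0, ut,
                               rel_tol = config$rel_tol,
                               abs_tol = config$abs_tol)
    idx <- match(obs_long$time_d, tc$time_d)
    pred_mat <- as.matrix(tc[vars])
    pred_mat[cbind(idx, match(obs_long$variable, vars))]
  }

  resid_fun <- function(theta) {
    names(theta) <- free
    params <- try(params_from_vector(theta, config), silent = TRUE)
    if (inherits(params, "try-error"))
      return(rep(1e6, nrow(obs_long)))
    pred <- try(predict_at(params), silent = TRUE)
    if (inherits(pred, "try-error") || any(!is.finite(pred)))
      return(rep(1e6, nrow(obs_long)))
    (obs_long$observed - pred) / wts[obs_long$variable]
  }

  # Latin-hypercube starts spanning the box, deterministic for the seed
  grid <- with_seed(config$multistart_seed,
                    lhs::randomLHS(config$multistart_count, length(free)))
  starts <- sweep(sweep(grid, 2, upper - lower, "*"), 2, lower, "+")
  colnames(starts) <- free

  runs <- vector("list", config$multistart_count)
  for (i in seq_len(config$multistart_count)) {
    runs[[i]] <- try(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iter,
                           ftol = 1e-13, ptol = 1e-13)),
      silent = TRUE)
  }
  ok <- !vapply(runs, inherits, logical(1), "try-error")
  if (!any(ok)) stop("all optimizer starts failed", call. = FALSE)
  dev <- vapply(seq_along(runs), function(i)
    if (ok[i]) runs[[i]]$deviance else Inf, numeric(1))
  best_i <- which.min(dev)  # which.min takes the first index on ties
  best <- runs[[best_i]]

  theta <- stats::setNames(as.numeric(best$par), free)
  params_hat <- params_from_vector(theta, config)
  pred <- predict_at(params_hat)
  obs_long$predicted <- pred
  obs_long$residual <- obs_long$observed - pred

  r2 <- vapply(vars, function(v) {
    sel <- obs_long$variable == v
    r_squared(obs_long$predicted[sel], obs_long$observed[sel])
  }, numeric(1))

  structure(list(
    params = params_hat,
    r2_X = r2[["dcw_g_per_L"]],
    r2_S = r2[["glucose_g_per_L"]],
    r2_P = r2[["dha_g_per_L"]],
    residuals = obs_long,
    converged = best$info %in% 1:3,
    objective_value = best$deviance,
    n_obs = nrow(obs_long),
    rss_trace = best$rsstrace,
    initial_state = y0,
    multistart = data.frame(start = seq_along(dev), objective = dev,
                            converged = vapply(seq_along(runs), function(i)
                              ok[i] && runs[[i]]$info %in% 1:3, logical(1))),
    config = config),
    class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Batch kinetic model fit (", x$n_obs, " observations)\n", sep = "")
  print(x$params)
  cat(sprintf("  R2: biomass %.4f  glucose %.4f  product %.4f\n",
              x$r2_X, x$r2_S, x$r2_P))
  cat(sprintf("  objective %.4g  converged: %s\n",
              x$objective_value, x$converged))
  invisible(x)
}

#' Partition product formation into growth- and non-growth-associated shares
#'
#' Under the Luedeking-Piret law the product formation rate splits into a
#' growth-associated term alpha*mu*C_X and a non-growth term beta*C_X. This
#' integrates both terms by trapezoidal quadrature over a densely simulated
#' trajectory spanning the fitted window and reports each as a fraction of
#' total product formed, plus the qualitative mixed-growth verdict
#' (alpha > beta: formation is dominated by the growth-associated pathway).
#'
#' @param result A converged [fit_kinetics()] result.
#' @param trajectory The `time_course` whose time span defines the window.
#' @param n_grid Dense quadrature grid size; default 2001.
#' @return A list with `growth_share`, `non_growth_share` (they sum to 1
#'   within quadrature tolerance), `growth_dominant` (`alpha > beta`), and
#'   the absolute amounts in g/L.
#' @export
mixed_growth_partition <- function(result, trajectory, n_grid = 2001L) {
  p <- result$params
  tspan <- range(trajectory$time_d)
  y0 <- result$initial_state %||% culture_state(
    mean(trajectory$dcw_g_per_L[trajectory$time_d == tspan[1]]),
    mean(trajectory$glucose_g_per_L[trajectory$time_d == tspan[1]]),
    mean(trajectory$dha_g_per_L[trajectory$time_d == tspan[1]]))
  grid <- seq(tspan[1], tspan[2], length.out = n_grid)
  dense <- simulate_time_course(p, y0, grid)
  X <- dense$dcw_g_per_L
  mu <- specific_growth_rate(X, p)
  growth <- trapz_quad(grid, p$alpha * mu * X)
  non_growth <- trapz_quad(grid, p$beta * X)
  total <- growth + non_growth
  if (total <= 0) {
    shares <- c(0, 0)
  } else shares <- c(growth, non_growth) / total
  list(growth_share = shares[1], non_growth_share = shares[2],
       growth_dominant = p$alpha > p$beta,
       growth_formed_g_per_L = growth,
       non_growth_formed_g_per_L = non_growth,
       total_formed_g_per_L = total)
}
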