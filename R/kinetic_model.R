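#' Kinetic parameter set for the batch fermentation model
#'
#' Bundles the six constants of the three-state batch model: logistic growth
#' (`mu_max`, `C_Xm`), glucose consumption with maintenance (`Y_XS`, `m_S`),
#' and Luedeking-Piret product formation (`alpha`, `beta`).
#'
#' @param mu_max Maximum specific growth rate, 1/day. Must be > 0.
#' @param C_Xm Carrying-capacity (maximum) biomass concentration, g/L. Must be > 0.
#' @param Y_XS Stoichiometric biomass yield on glucose, g/g, in (0, 1].
#'   Defaults to 0.45, the value obtained from the elemental biomass formula.
#' @param m_S Maintenance coefficient, g glucose/(g biomass * day). Must be >= 0.
#' @param alpha Growth-associated product formation coefficient, g product/g
#'   biomass. Must be >= 0.
#' @param beta Non-growth-associated product formation coefficient,
#'   g product/(g biomass * day). Must be >= 0.
#'
#' @return An object of class `kinetic_params` (a named list).
#' @export
#' @examples
#' kinetic_params(mu_max = 1.617, C_Xm = 19.891, m_S = 0.033,
#'                alpha = 0.055, beta = 0.020)
kinetic_params <- function(mu_max, C_Xm, Y_XS = 0.45, m_S = 0, alpha = 0,
                           beta = 0) {
  p <- list(mu_max = as.numeric(mu_max), C_Xm = as.numeric(C_Xm),
            Y_XS = as.numeric(Y_XS), m_S = as.numeric(m_S),
            alpha = as.numeric(alpha), beta = as.numeric(beta))
  validate_kinetic_params(p)
  structure(p, class = "kinetic_params")
}

validate_kinetic_params <- function(p) {
  for (nm in c("mu_max", "C_Xm", "Y_XS", "m_S", "alpha", "beta")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$mu_max <= 0) stop("mu_max must be > 0", call. = FALSE)
  if (p$C_Xm <= 0) stop("C_Xm must be > 0", call. = FALSE)
  if (p$Y_XS <= 0 || p$Y_XS > 1)
    stop("Y_XS must lie in (0, 1]", call. = FALSE)
  if (p$m_S < 0) stop("m_S must be >= 0", call. = FALSE)
  if (p$alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (p$beta < 0) stop("beta must be >= 0", call. = FALSE)
  invisible(p)
}

#' Instantaneous culture state
#'
#' @param C_X Biomass dry cell weight, g/L.
#' @param C_S Glucose concentration, g/L.
#' @param C_P Product (DHA) concentration, g/L.
#'
#' @return An object of class `culture_state`: a named numeric vector
#'   `c(C_X, C_S, C_P)`.
#' @export
culture_state <- function(C_X, C_S, C_P) {
  s <- c(C_X = as.numeric(C_X), C_S = as.numeric(C_S), C_P = as.numeric(C_P))
  if (any(!is.finite(s))) stop("culture state must be finite", call. = FALSE)
  if (any(s < 0)) stop("concentrations must be >= 0", call. = FALSE)
  structure(s, class = "culture_state")
}

#' Logistic specific growth rate
#'
#' mu = mu_max * (1 - C_X / C_Xm). Declines affinely with biomass density;
#' negative values for C_X > C_Xm are admitted (the logistic equation then
#' self-corrects toward the carrying capacity), not clamped.
#'
#' @param C_X Biomass concentration, g/L (>= 0).
#' @param params A [kinetic_params()] object.
#' @return Specific growth rate, 1/day.
#' @export
specific_growth_rate <- function(C_X, params) {
  validate_kinetic_params(params)
  if (any(!is.finite(C_X)) || any(C_X < 0))
    stop("C_X must be finite and >= 0", call. = FALSE)
  params$mu_max * (1 - C_X / params$C_Xm)
}

#' Right-hand side of the batch fermentation ODE system
#'
#' The autonomous system
#' \deqn{dC_X/dt = \mu C_X, \quad \mu = \mu_{max}(1 - C_X/C_{Xm})}
#' \deqn{dC_S/dt = -(1/Y_{X/S}) dC_X/dt - m_S C_X}
#' \deqn{dC_P/dt = (\alpha \mu + \beta) C_X}
#' with one physicality rule: once glucose is exhausted (C_S = 0) its
#' derivative is forced to 0; growth and product formation are untouched
#' because the growth law saturates through the carrying capacity, not
#' through substrate.
#'
#' @param state A [culture_state()] or named numeric `c(C_X, C_S, C_P)`.
#' @param params A [kinetic_params()] object.
#' @return Named numeric derivative triple `c(C_X, C_S, C_P)` in g/(L*day).
#' @export
model_rhs <- function(state, params) {
  validate_kinetic_params(params)
  C_X <- state[["C_X"]]; C_S <- state[["C_S"]]
  mu <- params$mu_max * (1 - C_X / params$C_Xm)
  dX <- mu * C_X
  dS <- if (C_S <= 0) 0 else -dX / params$Y_XS - params$m_S * C_X
  dP <- (params$alpha * mu + params$beta) * C_X
  c(C_X = dX, C_S = dS, C_P = dP)
}

#' Closed-form solution of the logistic growth equation
#'
#' Analytic biomass trajectory
#' \deqn{C_X(t) = \frac{C_{Xm} C_{X0} e^{\mu_{max} t}}
#'                     {C_{Xm} - C_{X0} + C_{X0} e^{\mu_{max} t}}}
#' used as the internal oracle against which the numerical integrator is
#' checked.
#'
#' @param t Time(s), days, >= 0 (vectorized).
#' @param C_X0 Initial biomass, g/L, with 0 < C_X0 <= C_Xm.
#' @param params A [kinetic_params()] object.
#' @return Biomass concentration(s), g/L.
#' @export
logistic_closed_form <- function(t, C_X0, params) {
  validate_kinetic_params(params)
  if (!is.numeric(C_X0) || length(C_X0) != 1L || C_X0 <= 0)
    stop("C_X0 must be a single value > 0", call. = FALSE)
  if (C_X0 > params$C_Xm)
    stop("C_X0 must not exceed C_Xm", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  e <- exp(params$mu_max * t)
  params$C_Xm * C_X0 * e / (params$C_Xm - C_X0 + C_X0 * e)
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Batch fermentation kinetic parameters\n")
  cat(sprintf("  mu_max = %g 1/d   C_Xm = %g g/L\n", x$mu_max, x$C_Xm))
  cat(sprintf("  Y_XS   = %g g/g   m_S  = %g g/(g d)\n", x$Y_XS, x$m_S))
  cat(sprintf("  alpha  = %g g/g   beta = %g g/(g d)\n", x$alpha, x$beta))
  invisible(x)
}
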