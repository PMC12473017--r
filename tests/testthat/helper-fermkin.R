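# Shared fixtures built in code.

# A toy two-point run used by the descriptor hand examples.
toy_time_course <- function() {
  as_time_course(data.frame(
    time_d = c(0, 5), replicate = 1L,
    dcw_g_per_L = c(1, 11), glucose_g_per_L = c(40, 0),
    dha_g_per_L = c(0, 1)), label = "toy")
}

# Random parameter draws spanning the range of the three fitted strains
# (and a little beyond), for property checks.
random_params <- function(n, exhausting = TRUE) {
  lapply(seq_len(n), function(i) {
    kinetic_params(
      mu_max = stats::runif(1, 0.8, 2.5),
      C_Xm = stats::runif(1, 8, 25),
      Y_XS = 0.45,
      m_S = stats::runif(1, 0, 0.05),
      alpha = stats::runif(1, 0, 0.15),
      beta = stats::runif(1, 0, 0.05))
  })
}

# Parameter draws guaranteed not to exhaust 40 g/L glucose over 5 days:
# carrying capacity low enough that (C_Xm - C_X0)/Y_XS + m_S * C_Xm * 5
# stays well under the initial glucose.
random_nonexhausting_params <- function(n) {
  lapply(seq_len(n), function(i) {
    kinetic_params(
      mu_max = stats::runif(1, 0.8, 2.5),
      C_Xm = stats::runif(1, 5, 12),
      Y_XS = 0.45,
      m_S = stats::runif(1, 0.001, 0.03),
      alpha = stats::runif(1, 0, 0.15),
      beta = stats::runif(1, 0, 0.05))
  })
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
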