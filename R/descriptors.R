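#' Endpoint kinetic descriptor panel
#'
#' Computes the classical endpoint descriptors of a batch run over a window
#' (t1, t2), both times taken from the sampled grid (no interpolation):
#' \itemize{
#'   \item Q_X = (C_X,2 - C_X,1)/(t2 - t1): biomass production rate, g/(L d)
#'   \item Q_S = -(C_S,2 - C_S,1)/(t2 - t1): glucose consumption rate, g/(L d)
#'   \item Q_P = (C_P,2 - C_P,1)/(t2 - t1): product production rate, g/(L d)
#'   \item mu = Q_X / ((C_X,1 + C_X,2)/2): specific growth rate, 1/d
#'   \item Y_XS_obs = (C_X,2 - C_X,1)/(C_S,1 - C_S,2): observed biomass yield, g/g
#'   \item Y_PS_obs = (C_P,2 - C_P,1)/(C_S,1 - C_S,2): observed product yield, g/g
#' }
#' Replicates are averaged per time point before the endpoint arithmetic.
#' If no glucose was consumed over the window the yields are reported as
#' `NA` (undefined) while the rates are still returned.
#'
#' @param data A `time_course` data frame.
#' @param t1,t2 Window endpoints in days; both must be sampled times with
#'   t2 > t1. Defaults to [pick_window()] of the data.
#' @param per_replicate If `TRUE`, additionally return one panel per
#'   replicate (for spread reporting) in attribute `"replicates"`.
#' @return A one-row data frame of class `descriptor_panel` with columns
#'   `t1`, `t2`, `Q_X`, `Q_S`, `Q_P`, `mu`, `Y_XS_obs`, `Y_PS_obs`, `label`.
#' @export
#' @examples
#' tc <- as_time_course(data.frame(
#'   time_d = c(0, 5), replicate = 1L, dcw_g_per_L = c(1, 11),
#'   glucose_g_per_L = c(40, 0), dha_g_per_L = c(0, 1)))
#' compute_descriptors(tc, 0, 5)
compute_descriptors <- function(data, t1 = NULL, t2 = NULL,
                                per_replicate = FALSE) {
  if (nrow(data) == 0L) stop("empty time course", call. = FALSE)
  if (is.null(t1) || is.null(t2)) {
    w <- pick_window(data)
    if (is.null(t1)) t1 <- w[1]
    if (is.null(t2)) t2 <- w[2]
  }
  ut <- sort(unique(data$time_d))
  for (t in c(t1, t2)) {
    if (!any(abs(ut - t) < 1e-9)) {
      nearest <- ut[order(abs(ut - t))][seq_len(min(2L, length(ut)))]
      stop("time ", t, " d is not a sampled time; nearest available: ",
           paste(format(nearest), collapse = ", "), call. = FALSE)
    }
  }
  if (t2 <= t1) stop("window requires t2 > t1", call. = FALSE)

  panel_from <- function(sub, label) {
    m <- stats::aggregate(sub[c("dcw_g_per_L", "glucose_g_per_L",
                                "dha_g_per_L")],
                          by = list(time_d = sub$time_d), FUN = mean)
    s1 <- m[abs(m$time_d - t1) < 1e-9, ]; s2 <- m[abs(m$time_d - t2) < 1e-9, ]
    dt <- t2 - t1
    dX <- s2$dcw_g_per_L - s1$dcw_g_per_L
    dS <- s1$glucose_g_per_L - s2$glucose_g_per_L  # consumed, >= 0 normally
    dP <- s2$dha_g_per_L - s1$dha_g_per_L
    Q_X <- dX / dt
    Q_S <- dS / dt
    Q_P <- dP / dt
    mu <- Q_X / ((s1$dcw_g_per_L + s2$dcw_g_per_L) / 2)
    if (dS > 0) {
      Y_XS_obs <- dX / dS
      Y_PS_obs <- dP / dS
    } else {
      Y_XS_obs <- NA_real_
      Y_PS_obs <- NA_real_
    }
    data.frame(label = label, t1 = t1, t2 = t2, Q_X = Q_X, Q_S = Q_S,
               Q_P = Q_P, mu = mu, Y_XS_obs = Y_XS_obs, Y_PS_obs = Y_PS_obs)
  }

  out <- panel_from(data, attr(data, "label") %||% "run")
  if (per_replicate) {
    reps <- lapply(sort(unique(data$replicate)), function(r)
      panel_from(data[data$replicate == r, , drop = FALSE],
                 paste0(attr(data, "label") %||% "run", "_rep", r)))
    attr(out, "replicates") <- do.call(rbind, reps)
  }
  class(out) <- c("descriptor_panel", "data.frame")
  out
}

#' Default descriptor window: inoculation to peak product titer
#'
#' t1 is the first sampled time; t2 is the time at which the (replicate-mean)
#' product concentration is maximal, the earliest such time on ties.
#'
#' @param data A `time_course` data frame.
#' @return Numeric `c(t1, t2)` in days.
#' @export
pick_window <- function(data) {
  if (nrow(data) == 0L) stop("empty time course", call. = FALSE)
  m <- stats::aggregate(data["dha_g_per_L"],
                        by = list(time_d = data$time_d), FUN = mean)
  m <- m[order(m$time_d), ]
  c(m$time_d[1], m$time_d[which.max(m$dha_g_per_L)])
}
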