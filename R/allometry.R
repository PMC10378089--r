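#' Metabolic-to-heartbeat time multiplier
#'
#' Ratio \eqn{\tau / t_H} of the characteristic metabolic time to the
#' heartbeat period. Across mammals this multiplier is approximately 30
#' (mouse: \eqn{t_H = 0.1} s, \eqn{\tau = 3} s; elephant:
#' \eqn{t_H = 2} s, \eqn{\tau = 60} s).
#'
#' @param t_H heartbeat period, seconds, > 0.
#' @param tau metabolic time, seconds, > 0.
#' @return The dimensionless multiplier \eqn{\tau / t_H}.
#' @examples
#' metabolic_multiplier(0.1, 3)  # mouse: 30
#' metabolic_multiplier(2, 60)   # elephant: 30
#' @export
metabolic_multiplier <- function(t_H, tau) {
  check_positive_scalar(t_H, "t_H")
  check_positive_scalar(tau, "tau")
  tau / t_H
}

#' Lifetime-to-metabolic-time ratio N = T/tau
#'
#' The degradation invariant: with roughly \eqn{10^9} heartbeats per
#' mammalian lifetime (\eqn{T/t_H \sim 10^9}) and a metabolic multiplier
#' of about 30, the number of metabolic times per lifetime is
#' \eqn{N = T/\tau \sim 3\times10^7}, independent of body size.
#'
#' @param beats_per_lifetime \eqn{T / t_H}, dimensionless, > 0.
#' @param multiplier \eqn{\tau / t_H}, dimensionless, > 0.
#' @return \eqn{N = T/\tau}.
#' @examples
#' lifetime_to_metabolic_ratio(1e9, 30)  # ~3.3e7
#' @export
lifetime_to_metabolic_ratio <- function(beats_per_lifetime, multiplier) {
  check_positive_scalar(beats_per_lifetime, "beats_per_lifetime")
  check_positive_scalar(multiplier, "multiplier")
  beats_per_lifetime / multiplier
}

#' Build a consistent set of organismal timescales
#'
#' Assembles heartbeat period \eqn{t_H}, metabolic time \eqn{\tau} and
#' beats-per-lifetime into the full timescale set: lifetime
#' \eqn{T = (T/t_H)\, t_H}, multiplier \eqn{\tau/t_H}, and the
#' degradation invariant \eqn{N = T/\tau}. An optional lifetime
#' correction factor accommodates species that outlive the generic
#' heartbeat budget (humans, by a factor of 2-3).
#'
#' @param t_H heartbeat period, seconds, > 0.
#' @param tau metabolic time, seconds, > 0.
#' @param beats_per_lifetime dimensionless heartbeat count, > 0.
#' @param lifetime_correction multiplicative correction on the lifetime
#'   (default 1).
#' @return Object of class `timescale_set`: list with `t_H`, `tau`, `T`
#'   (seconds), `beats_per_lifetime`, `multiplier`, `N`.
#' @examples
#' mouse <- build_timescales(0.1, 3, 1e9)
#' mouse$N  # ~3.3e7, the same for an elephant
#' @export
build_timescales <- function(t_H, tau, beats_per_lifetime,
                             lifetime_correction = 1) {
  check_positive_scalar(t_H, "t_H")
  check_positive_scalar(tau, "tau")
  check_positive_scalar(beats_per_lifetime, "beats_per_lifetime")
  check_positive_scalar(lifetime_correction, "lifetime_correction")
  beats <- beats_per_lifetime * lifetime_correction
  structure(list(t_H = t_H, tau = tau,
                 T = beats * t_H,
                 beats_per_lifetime = beats,
                 multiplier = metabolic_multiplier(t_H, tau),
                 N = lifetime_to_metabolic_ratio(beats,
                                                 metabolic_multiplier(t_H, tau))),
            class = "timescale_set")
}

#' @export
print.timescale_set <- function(x, ...) {
  cat(sprintf(paste0("timescale_set: t_H = %g s, tau = %g s, ",
                     "T = %.3g s\n  multiplier tau/t_H = %g, ",
                     "N = T/tau = %.3g\n"),
              x$t_H, x$tau, x$T, x$multiplier, x$N))
  invisible(x)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(name, " must be a single positive number", call. = FALSE)
  invisible(x)
}
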