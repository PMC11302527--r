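#' Environment schedules: time-varying shared net preference
#'
#' Deterministic maps from time (in sweeps) to the net preference for A
#' shared by the whole population. Three kinds are supported:
#' `constant` (\eqn{\Delta o(t) = \Delta o_0}), `linear`
#' (\eqn{\Delta o(t) = \Delta o_0 - r t}, crossing zero at
#' \eqn{t = \Delta o_0 / r}), and `sinusoidal`
#' (\eqn{\Delta o(t) = A_0 \sin(2\pi t / T + \phi)}).
#'
#' @param kind `"constant"`, `"linear"` or `"sinusoidal"`.
#' @param delta_o0 initial / constant net preference (default 10, the
#'   preference scale used throughout).
#' @param rate linear decay rate per sweep (default: zero-crossing at a
#'   quarter of a 400-sweep horizon, i.e. `delta_o0 / 100`).
#' @param amplitude,period,phase sinusoidal parameters; defaults 10, 200
#'   sweeps, 0.
#' @return an object of class `env_schedule`.
#' @export
env_schedule <- function(kind = c("constant", "linear", "sinusoidal"),
                         delta_o0 = 10, rate = delta_o0 / 100,
                         amplitude = 10, period = 200, phase = 0) {
  kind <- match.arg(kind)
  sch <- switch(kind,
    constant = list(kind = kind, delta_o0 = delta_o0),
    linear = {
      assert_scalar_num(rate, "rate")
      list(kind = kind, delta_o0 = delta_o0, rate = rate)
    },
    sinusoidal = {
      stopifnot(period > 0)
      list(kind = kind, amplitude = amplitude, period = period,
           phase = phase)
    })
  structure(sch, class = "env_schedule")
}

#' Evaluate a schedule at given times
#'
#' @param schedule an [env_schedule()].
#' @param t numeric vector of times in sweeps (>= 0).
#' @return numeric vector of net preferences \eqn{\Delta o(t)}.
#' @export
schedule_delta <- function(schedule, t) {
  stopifnot(inherits(schedule, "env_schedule"))
  switch(schedule$kind,
    constant = rep(schedule$delta_o0, length(t)),
    linear = schedule$delta_o0 - schedule$rate * t,
    sinusoidal = schedule$amplitude *
      sin(2 * pi * t / schedule$period + schedule$phase))
}

#' Zero-crossing times of a schedule
#'
#' Times in `[0, horizon]` where \eqn{\Delta o(t)} changes sign, together
#' with the sign it changes to. For constant schedules the result is
#' empty.
#'
#' @inheritParams schedule_delta
#' @param horizon last time considered (sweeps).
#' @return data frame with columns `time` and `to_sign` (+1: A becomes
#'   preferred, -1: B becomes preferred).
#' @export
schedule_crossings <- function(schedule, horizon) {
  stopifnot(inherits(schedule, "env_schedule"))
  out <- data.frame(time = numeric(0), to_sign = numeric(0))
  if (schedule$kind == "linear") {
    if (schedule$rate > 0 && schedule$delta_o0 > 0) {
      tc <- schedule$delta_o0 / schedule$rate
      if (tc <= horizon) out <- data.frame(time = tc, to_sign = -1)
    } else if (schedule$rate < 0 && schedule$delta_o0 < 0) {
      tc <- schedule$delta_o0 / schedule$rate
      if (tc <= horizon) out <- data.frame(time = tc, to_sign = 1)
    }
  } else if (schedule$kind == "sinusoidal") {
    # sin(2*pi*t/T + phi) = 0 at t = T*(k*pi - phi)/(2*pi)
    Tt <- schedule$period; phi <- schedule$phase
    k <- 0:ceiling(2 * horizon / Tt + 2)
    tc <- Tt * (k * pi - phi) / (2 * pi)
    sgn <- ifelse(k %% 2 == 0, 1, -1) * sign(schedule$amplitude)
    keep <- tc > 0 & tc <= horizon
    out <- data.frame(time = tc[keep], to_sign = sgn[keep])
  }
  out
}
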