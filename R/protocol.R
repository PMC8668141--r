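#' Time-dependent force protocols
#'
#' A drive protocol prescribes the applied forces \eqn{\alpha(t)} of a model
#' as a function of time: constant, a single abrupt step, a square wave, a
#' smooth (cosine-ramp) periodic alternation, or an arbitrary
#' piecewise-constant table. Protocols are right-continuous at their declared
#' switch times, and every protocol knows its own discontinuities so that ODE
#' and PDE integrators can stop and restart there instead of stepping across
#' a jump.
#'
#' @param level,before,after,levels force vectors (named numeric vectors in
#'   the model's natural parameterization, e.g. `c(mu = 1, beta = 0.7)` or
#'   `c(r = 0.1, lambda = 0.002, m = 3)`).
#' @param at time of the step discontinuity.
#' @param period full period of the alternation between `levels[[1]]` and
#'   `levels[[2]]`.
#' @param t0 time at which the periodic drive starts (before `t0` the drive
#'   holds `levels[[1]]`).
#' @param ramp_fraction for [protocol_smooth_periodic()]: fraction of each
#'   half-period spent on the cosine ramp between levels (1 = pure cosine
#'   alternation, smaller values hold each level before ramping). The
#'   resulting drive is continuous for any value in (0, 1].
#' @param times,table for [protocol_table()]: switch times and a list with
#'   one force vector per interval (`length(table) == length(times) + 1`).
#'
#' @return An object of class `drive_protocol` with elements
#'   `kind`, `levels`, `evaluate(t)` (scalar time, returns a force vector)
#'   and `switch_times(from, to)` (the declared discontinuities inside a
#'   window).
#' @name drive_protocol
NULL

new_protocol <- function(kind, levels, evaluate, switch_times,
                         period = NA_real_) {
  structure(list(kind = kind, levels = levels, evaluate = evaluate,
                 switch_times = switch_times, period = period),
            class = "drive_protocol")
}

#' @rdname drive_protocol
#' @export
protocol_constant <- function(level) {
  level <- unlist(level)
  new_protocol("constant", list(level),
               function(t) level,
               function(from, to) numeric(0))
}

#' @rdname drive_protocol
#' @export
protocol_step <- function(before, after, at = 0) {
  before <- unlist(before); after <- unlist(after)
  new_protocol("step", list(before, after),
               function(t) if (t >= at) after else before,
               function(from, to) at[at > from & at < to])
}

#' @rdname drive_protocol
#' @export
protocol_square_wave <- function(levels, period, t0 = 0) {
  stopifnot(length(levels) == 2, period > 0)
  levels <- lapply(levels, unlist)
  half <- period / 2
  new_protocol("square_wave", levels,
    function(t) {
      if (t < t0) return(levels[[1]])
      phase <- ((t - t0) / half) %% 2
      if (phase < 1) levels[[2]] else levels[[1]]
    },
    function(from, to) {
      if (to <= t0) return(numeric(0))
      ks <- seq(0, ceiling((to - t0) / half))
      s <- t0 + ks * half
      s[s > from & s < to]
    },
    period = period)
}

#' @rdname drive_protocol
#' @export
protocol_smooth_periodic <- function(levels, period, t0 = 0,
                                     ramp_fraction = 1) {
  stopifnot(length(levels) == 2, period > 0,
            ramp_fraction > 0, ramp_fraction <= 1)
  levels <- lapply(levels, unlist)
  half <- period / 2
  ramp <- ramp_fraction * half
  # weight of levels[[2]] over one half-period: cosine ramp then hold
  wfun <- function(s) {                    # s in [0, 2) half-periods
    up <- s < 1
    u <- ifelse(up, s, s - 1) * half       # time into the half-period
    w <- ifelse(u < ramp, (1 - cos(pi * u / ramp)) / 2, 1)
    ifelse(up, w, 1 - w)
  }
  new_protocol("smooth_periodic", levels,
    function(t) {
      if (t < t0) return(levels[[1]])
      w <- wfun(((t - t0) / half) %% 2)
      (1 - w) * levels[[1]] + w * levels[[2]]
    },
    function(from, to) numeric(0),         # continuous drive: no jumps
    period = period)
}

#' @rdname drive_protocol
#' @export
protocol_table <- function(times, table) {
  stopifnot(length(table) == length(times) + 1, !is.unsorted(times))
  table <- lapply(table, unlist)
  new_protocol("custom_table", table,
    function(t) table[[findInterval(t, times) + 1]],
    function(from, to) times[times > from & times < to])
}

#' @rdname drive_protocol
#' @param fn for [protocol_custom()]: function `t -> force vector`.
#' @param switches for [protocol_custom()]: declared discontinuity times of
#'   `fn` (empty for a continuous drive).
#' @export
protocol_custom <- function(fn, switches = numeric(0)) {
  new_protocol("custom", list(fn(0)), fn,
               function(from, to) switches[switches > from & switches < to])
}

#' Evaluate a protocol on a vector of times
#'
#' @param protocol a [drive_protocol] object.
#' @param times numeric vector.
#' @return matrix with one row per time and one column per force.
#' @export
evaluate_protocol <- function(protocol, times) {
  out <- t(vapply(times, protocol$evaluate, protocol$evaluate(times[1])))
  rownames(out) <- NULL
  out
}
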