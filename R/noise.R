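#' Two-state (dichotomous) renewal noise specification
#'
#' Defines the on/off telegraph process \eqn{\xi(t) \in \{0, 1\}} that
#' modulates technological growth: sojourn times in each state are
#' independent exponentials with the given means. Two parameterisations are
#' supported:
#'
#' * `"asymmetric-means"`: the sojourn means in the off (\eqn{\xi = 0}) and
#'   on (\eqn{\xi = 1}) states are given directly. The survival experiment
#'   default is mean 1 yr in the growth state and 4 yr in the stagnation
#'   state, the stop-and-go economic-cycle calibration the collapse
#'   analysis is built on.
#' * `"symmetric-rate"`: both means equal `2 / gamma`, so the centred
#'   process \eqn{\bar\xi = 2(\xi - 1/2)} has autocorrelation
#'   \eqn{e^{-\gamma|\tau|}}. This is the case with closed-form telegrapher
#'   and first-passage densities (see [fpt_density()]); each state flips at
#'   rate `gamma / 2`.
#'
#' @param mean_off mean sojourn in the off state (years).
#' @param mean_on mean sojourn in the on (growth) state (years).
#' @param mode `"asymmetric-means"` or `"symmetric-rate"`.
#' @param gamma correlation decay rate (yr^-1); required in
#'   `"symmetric-rate"` mode, where it overrides the means with `2 / gamma`.
#' @param initial_state_rule how the state at t = 0 is drawn:
#'   `"stationary"` (on with probability `mean_on / (mean_on + mean_off)`),
#'   `"fixed-on"`, or `"fixed-off"`.
#' @return an object of class `dichotomous_spec`.
#' @examples
#' dichotomous_spec(mean_off = 4, mean_on = 1)
#' dichotomous_spec(mode = "symmetric-rate", gamma = 4)
#' @export
dichotomous_spec <- function(mean_off = 4, mean_on = 1,
                             mode = c("asymmetric-means", "symmetric-rate"),
                             gamma = NULL,
                             initial_state_rule = c("stationary", "fixed-on",
                                                    "fixed-off")) {
  mode <- match.arg(mode)
  initial_state_rule <- match.arg(initial_state_rule)
  if (mode == "symmetric-rate") {
    if (is.null(gamma) || !is.numeric(gamma) || length(gamma) != 1L ||
        gamma <= 0) {
      stop("symmetric-rate mode requires a positive scalar 'gamma'")
    }
    mean_off <- mean_on <- 2 / gamma
  } else {
    if (!all(is.numeric(c(mean_off, mean_on))) || mean_off <= 0 || mean_on <= 0) {
      stop("sojourn means must be strictly positive")
    }
    gamma <- NULL
  }
  structure(list(mean_off = mean_off, mean_on = mean_on, mode = mode,
                 gamma = gamma, initial_state_rule = initial_state_rule),
            class = "dichotomous_spec")
}

#' @export
print.dichotomous_spec <- function(x, ...) {
  cat(sprintf("Dichotomous noise (%s): mean_off = %g yr, mean_on = %g yr",
              x$mode, x$mean_off, x$mean_on))
  if (!is.null(x$gamma)) cat(sprintf(" (gamma = %g /yr)", x$gamma))
  cat(sprintf(", initial state: %s\n", x$initial_state_rule))
  invisible(x)
}

#' Stationary probability of the growth state
#'
#' Long-run fraction of time spent in the on state,
#' `mean_on / (mean_on + mean_off)` (renewal-reward).
#'
#' @param spec a [dichotomous_spec()].
#' @return a probability.
#' @export
stationary_on_fraction <- function(spec) {
  stopifnot(inherits(spec, "dichotomous_spec"))
  spec$mean_on / (spec$mean_on + spec$mean_off)
}

draw_initial_state <- function(spec) {
  switch(spec$initial_state_rule,
         "fixed-on" = 1L,
         "fixed-off" = 0L,
         "stationary" = as.integer(stats::runif(1) < stationary_on_fraction(spec)))
}

#' Sample one realisation of the dichotomous process
#'
#' Draws the switching times of \eqn{\xi(t)} over `[0, horizon]`: the
#' initial state per the spec's `initial_state_rule`, then alternating
#' exponential sojourns with the state-specific means.
#'
#' @param spec a [dichotomous_spec()].
#' @param horizon length of the realisation (years, > 0).
#' @param seed optional integer seed (see [mix_seed()]); `NULL` uses the
#'   current RNG stream.
#' @return an object of class `switch_series`: a list with `t_end`,
#'   `state_0` (state on `[0, first switch)`), and the strictly increasing
#'   `switch_times` within `(0, t_end)`.
#' @examples
#' s <- sample_switch_series(dichotomous_spec(), horizon = 50, seed = 1)
#' head(s$switch_times)
#' @export
sample_switch_series <- function(spec, horizon, seed = NULL) {
  stopifnot(inherits(spec, "dichotomous_spec"),
            is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  with_seed(seed, {
    state0 <- draw_initial_state(spec)
    means <- c(spec$mean_off, spec$mean_on) # index by state + 1
    times <- numeric(0)
    t <- 0
    state <- state0
    # draw sojourns in chunks; alternation makes the mean pattern periodic
    repeat {
      k <- max(16L, ceiling((horizon - t) / (spec$mean_off + spec$mean_on)) * 2L)
      states <- (state + seq_len(k) - 1L) %% 2L
      d <- stats::rexp(k, rate = 1 / means[states + 1L])
      ends <- t + cumsum(d)
      times <- c(times, ends)
      t <- ends[k]
      state <- (state + k) %% 2L
      if (t >= horizon) break
    }
    structure(list(t_end = horizon,
                   switch_times = times[times < horizon],
                   state_0 = state0),
              class = "switch_series")
  })
}

#' Evaluate a switch series
#'
#' State of \eqn{\xi(t)} at arbitrary times; intervals are right-open
#' (`[switch, next switch)`).
#'
#' @param series a `switch_series`.
#' @param t vector of times in `[0, t_end]`.
#' @return integer vector of 0/1 states.
#' @export
eval_switch_series <- function(series, t) {
  stopifnot(inherits(series, "switch_series"))
  if (any(t < 0 | t > series$t_end)) stop("'t' outside the series horizon")
  n_before <- findInterval(t, series$switch_times)
  as.integer((series$state_0 + n_before) %% 2L)
}

# on-intervals of a series as a matrix [start, end) clipped to the horizon
on_intervals <- function(series) {
  bounds <- c(0, series$switch_times, series$t_end)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1L]
  state <- (series$state_0 + seq_along(starts) - 1L) %% 2L
  cbind(start = starts[state == 1L], end = ends[state == 1L])
}
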