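#' Technology growth parameters
#'
#' Parameters of the stop-and-go exponential growth model
#' \deqn{dT/dt = \alpha\, T\, \xi(t)} where `T` is the technology level,
#' proxied by world energy consumption. The defaults are the current world
#' consumption `T_init = 1e13` W and the Dyson limit `T_target = 4e26` W
#' (full exploitation of the Sun's output), with the Moore-law rate
#' `alpha = 0.345` per year (a doubling every two years).
#'
#' @param alpha technological growth rate (yr^-1, > 0).
#' @param T_init starting level (Watt).
#' @param T_target threshold level (Watt), at least `T_init`.
#' @return an object of class `tech_params`.
#' @examples
#' tech_params(alpha = alpha_moore())
#' @export
tech_params <- function(alpha = 0.345, T_init = 1e13, T_target = 4e26) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0) {
    stop("'alpha' must be a positive scalar")
  }
  if (!(T_init > 0 && T_target >= T_init)) {
    stop("levels must satisfy 0 < T_init <= T_target")
  }
  structure(list(alpha = alpha, T_init = T_init, T_target = T_target),
            class = "tech_params")
}

#' @export
print.tech_params <- function(x, ...) {
  cat(sprintf("Technology growth: alpha = %g /yr, from %g W to %g W\n",
              x$alpha, x$T_init, x$T_target))
  cat(sprintf("  minimum (all-on) passage time: %.4g yr\n",
              min_passage_time(x)))
  invisible(x)
}

#' Minimum possible passage time
#'
#' The hard lower bound on the first-passage time to `T_target`: growth
#' only happens in the on state, so no trajectory can cross before
#' `log(T_target / T_init) / alpha` years.
#'
#' @param params a [tech_params()].
#' @return years.
#' @export
min_passage_time <- function(params) {
  stopifnot(inherits(params, "tech_params"))
  log(params$T_target / params$T_init) / params$alpha
}

#' Integrate the technology level along a noise realisation
#'
#' The modulated growth equation is piecewise linear in `log T`: the level
#' multiplies by `exp(alpha * d)` over each on-interval of length `d` and
#' is constant over off-intervals. The integration is therefore exact (no
#' discretisation error) and performed on `log T` so that long horizons
#' cannot overflow.
#'
#' @param series a [sample_switch_series()] realisation.
#' @param params a [tech_params()].
#' @return an object of class `tech_path`: a data frame with the segment
#'   node times `t`, the state on the segment starting at each node
#'   (`NA` for the final node), and `log_T` / `T` at the nodes.
#' @examples
#' s <- sample_switch_series(dichotomous_spec(), horizon = 50, seed = 1)
#' path <- integrate_technology(s, tech_params())
#' tail(path)
#' @export
integrate_technology <- function(series, params) {
  stopifnot(inherits(series, "switch_series"), inherits(params, "tech_params"))
  nodes <- c(0, series$switch_times, series$t_end)
  k <- length(nodes) - 1L
  state <- as.integer((series$state_0 + seq_len(k) - 1L) %% 2L)
  d <- diff(nodes)
  logT <- log(params$T_init) + c(0, cumsum(params$alpha * d * state))
  path <- data.frame(t = nodes, state = c(state, NA_integer_),
                     log_T = logT, T = exp(logT))
  class(path) <- c("tech_path", "data.frame")
  attr(path, "params") <- params
  path
}

#' Evaluate a technology path at arbitrary times
#'
#' @param path a `tech_path` from [integrate_technology()].
#' @param t times within the path's span.
#' @return technology levels `T(t)` (Watt).
#' @export
tech_level <- function(path, t) {
  stopifnot(inherits(path, "tech_path"))
  if (any(t < 0 | t > max(path$t))) stop("'t' outside the path span")
  params <- attr(path, "params")
  i <- findInterval(t, path$t, rightmost.closed = TRUE)
  grow <- path$state[i] == 1L & !is.na(path$state[i])
  exp(path$log_T[i] + ifelse(grow, params$alpha * (t - path$t[i]), 0))
}

#' Exact first-passage time of a technology trajectory
#'
#' Crossing time of `T_target` along one noise realisation, solved in
#' closed form on the on-interval where the log-level crosses (growth is
#' deterministic given the noise, so no grid search is involved). The
#' passage happens once the cumulative on-time reaches
#' `log(T_target / T_init) / alpha`.
#'
#' @param series a [sample_switch_series()] realisation.
#' @param params a [tech_params()].
#' @return a list with `time` (years, `NA` if censored) and `censored`
#'   (`TRUE` when the horizon ends before the crossing).
#' @examples
#' s <- sample_switch_series(dichotomous_spec(), horizon = 2000, seed = 1)
#' first_passage_time(s, tech_params())
#' @export
first_passage_time <- function(series, params) {
  stopifnot(inherits(series, "switch_series"), inherits(params, "tech_params"))
  needed <- min_passage_time(params)
  if (needed == 0) return(list(time = 0, censored = FALSE))
  iv <- on_intervals(series)
  if (nrow(iv) == 0L) return(list(time = NA_real_, censored = TRUE))
  len <- iv[, "end"] - iv[, "start"]
  cum <- cumsum(len)
  j <- which(cum >= needed)
  if (length(j) == 0L) return(list(time = NA_real_, censored = TRUE))
  j <- j[1L]
  prior <- if (j == 1L) 0 else cum[j - 1L]
  list(time = unname(iv[j, "start"]) + (needed - prior), censored = FALSE)
}
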