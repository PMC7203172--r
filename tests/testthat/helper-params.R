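# Shared fixtures: the world-scale baseline parameter sets.

baseline_forest <- function(beta = 170, ...) {
  forest_params(beta = beta, ...)
}

moore_tech <- function(alpha = 0.345) {
  tech_params(alpha = alpha, T_init = 1e13, T_target = 4e26)
}

# growth/stagnation calibration used by the survival experiment
cycle_spec <- function(...) {
  dichotomous_spec(mean_off = 4, mean_on = 1, ...)
}

# total time spent in the on state of a switch series, from its intervals
series_on_time <- function(series) {
  bounds <- c(0, series$switch_times, series$t_end)
  d <- diff(bounds)
  state <- (series$state_0 + seq_along(d) - 1L) %% 2L
  sum(d[state == 1L])
}
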