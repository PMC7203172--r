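# Survival experiment: couple the deterministic no-return time with
# stochastic technology trajectories and count the ones that reach the
# Dyson limit first. The population dynamics is independent of the noise,
# so the no-return time is computed once per parameter cell and every
# trial in the cell shares it.

#' Deadline implied by a forest parameter set
#'
#' Integrates the humans-forest system and extracts the no-return time;
#' when no qualifying population maximum exists within the horizon the
#' deadline falls back to the horizon itself and is flagged as censored.
#'
#' @param forest a [forest_params()] object.
#' @param horizon integration horizon (years).
#' @param step Euler step (years).
#' @return list with `deadline` (years), `t_nr` (`NA` if not found),
#'   `N_max`, and `censored_deadline` (logical).
#' @export
no_return_deadline <- function(forest, horizon = 500, step = 0.01) {
  traj <- integrate_humans_forest(forest, horizon = horizon, step = step)
  nr <- find_no_return(traj)
  if (nr$found) {
    list(deadline = nr$t_nr, t_nr = nr$t_nr, N_max = nr$N_max,
         censored_deadline = FALSE)
  } else {
    list(deadline = horizon, t_nr = NA_real_, N_max = max(traj$N),
         censored_deadline = TRUE)
  }
}

#' Run a single success/failure trial
#'
#' Draws one technology trajectory and classifies it a success if it
#' reaches the target level no later than the no-return time of the
#' deterministic population dynamics (a closed inequality; the boundary
#' event has probability zero). The deterministic side can be supplied
#' precomputed via `deadline_info` to avoid re-integrating the ODE.
#'
#' @param forest a [forest_params()] object.
#' @param tech a [tech_params()] object.
#' @param spec a [dichotomous_spec()] object.
#' @param seed optional integer seed for the technology trajectory.
#' @param horizon,step passed to the ODE integration.
#' @param deadline_info optional result of [no_return_deadline()].
#' @return an object of class `trial_outcome`: list with `success`,
#'   `crossing_time` (`NA` unless successful), `no_return_time`,
#'   `censored_deadline` and `seed`.
#' @examples
#' run_trial(forest_params(beta = 700), tech_params(),
#'           dichotomous_spec(), seed = 1)
#' @export
run_trial <- function(forest, tech, spec, seed = NULL, horizon = 500,
                      step = 0.01, deadline_info = NULL) {
  if (is.null(deadline_info)) {
    deadline_info <- no_return_deadline(forest, horizon = horizon, step = step)
  }
  cross <- sample_fpt_batch(spec, tech, n = 1L,
                            deadline = deadline_info$deadline, seed = seed)
  success <- !is.na(cross)
  structure(list(success = success,
                 crossing_time = if (success) cross else NA_real_,
                 no_return_time = deadline_info$deadline,
                 censored_deadline = deadline_info$censored_deadline,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "trial_outcome")
}

#' Estimate the success probability for one parameter cell
#'
#' Monte Carlo estimate of `p_suc`, the probability that the technology
#' level reaches its target before the population's no-return point, from
#' `n_trials` independent trajectories sharing the deterministic deadline.
#'
#' @inheritParams run_trial
#' @param n_trials number of trajectories (default 10000).
#' @return an object of class `success_estimate`: list with `p_suc`,
#'   `ci_halfwidth` (binomial normal-approximation 95% half-width),
#'   `n_trials`, `successes`, `tau_success` (mean crossing time over
#'   successes, `NA` if none), `tau_failure` (the no-return time when any
#'   failure occurred, `NA` otherwise), `t_no_return`, `censored_deadline`
#'   and `seed`.
#' @examples
#' estimate_success_probability(forest_params(beta = 170),
#'                              tech_params(alpha = 3),
#'                              dichotomous_spec(), n_trials = 200, seed = 1)
#' @export
estimate_success_probability <- function(forest, tech, spec, n_trials = 10000,
                                         seed = NULL, horizon = 500,
                                         step = 0.01, deadline_info = NULL) {
  stopifnot(n_trials >= 1)
  if (is.null(deadline_info)) {
    deadline_info <- no_return_deadline(forest, horizon = horizon, step = step)
  }
  cross <- sample_fpt_batch(spec, tech, n = n_trials,
                            deadline = deadline_info$deadline, seed = seed)
  outcomes <- list(crossing_time = cross,
                   no_return_time = deadline_info$deadline)
  taus <- conditional_mean_times(outcomes)
  k <- sum(!is.na(cross))
  p <- k / n_trials
  structure(list(p_suc = p,
                 ci_halfwidth = 1.96 * sqrt(p * (1 - p) / n_trials),
                 n_trials = n_trials, successes = k,
                 tau_success = taus$tau_success,
                 tau_failure = taus$tau_failure,
                 t_no_return = deadline_info$t_nr,
                 censored_deadline = deadline_info$censored_deadline,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "success_estimate")
}

#' @export
print.success_estimate <- function(x, ...) {
  cat(sprintf("p_suc = %.4g (95%% CI +/- %.2g, %d/%d successes)\n",
              x$p_suc, x$ci_halfwidth, x$successes, x$n_trials))
  cat(sprintf("  deadline: %s%.4g yr; tau_success = %.4g yr, tau_failure = %.4g yr\n",
              if (x$censored_deadline) "horizon-censored " else "no-return at ",
              if (x$censored_deadline || is.na(x$t_no_return)) {
                if (is.na(x$t_no_return)) NA_real_ else x$t_no_return
              } else x$t_no_return,
              x$tau_success, x$tau_failure))
  invisible(x)
}

#' Conditional mean times of a batch of trials
#'
#' Mean crossing time over successful trajectories and mean no-return time
#' over failures. The deterministic dynamics makes the failure-side time
#' equal to the cell's no-return time whenever any failure occurs; empty
#' classes yield `NA`, never zero.
#'
#' @param outcomes list with `crossing_time` (numeric vector, `NA` for
#'   failures) and `no_return_time` (scalar or vector).
#' @return list with `tau_success` and `tau_failure` (years, `NA` when the
#'   class is empty).
#' @export
conditional_mean_times <- function(outcomes) {
  cross <- outcomes$crossing_time
  stopifnot(length(cross) >= 1)
  nr <- rep_len(outcomes$no_return_time, length(cross))
  succ <- !is.na(cross)
  list(tau_success = if (any(succ)) mean(cross[succ]) else NA_real_,
       tau_failure = if (any(!succ)) mean(nr[!succ]) else NA_real_)
}

#' Sweep success probability over parameter grids
#'
#' Runs the survival experiment over a grid of technology growth rates
#' `alpha`, extraction parameters `a` (continental units, Km^2 yr^-1) and
#' carrying-capacity ratios `beta`. The ODE is integrated once per
#' `(beta, a)` pair (the noise does not feed back on the population), and
#' each cell uses an independent, reproducible substream derived from the
#' master seed, so any cell can be re-run in isolation.
#'
#' @param alpha_grid technology growth rates (yr^-1).
#' @param a_grid extraction parameters `a = a0 * R_W` (Km^2 yr^-1).
#' @param beta_values carrying-capacity ratios.
#' @param n_trials trials per cell (default 10000).
#' @param seed master seed; per-cell seeds are derived with [mix_seed()].
#' @param spec noise specification (default: growth/stagnation means 1 and
#'   4 years, stationary start).
#' @param tech technology parameters (levels and default Moore rate; the
#'   `alpha` field is overridden cell by cell).
#' @param forest base forest parameters in absolute units; `beta` and `a0`
#'   are overridden cell by cell and the system is integrated in
#'   continental units.
#' @param horizon,step ODE integration controls.
#' @return an object of class `sweep_result`: a data frame with one row
#'   per cell and columns `beta`, `alpha`, `a`, `n_trials`, `p_suc`,
#'   `ci95`, `tau_success`, `tau_failure`, `t_no_return`,
#'   `censored_deadline`.
#' @examples
#' sweep_success(alpha_grid = c(1, 3), a_grid = 1.5e-4, beta_values = 170,
#'               n_trials = 100, seed = 1)
#' @export
sweep_success <- function(alpha_grid, a_grid, beta_values, n_trials = 10000,
                          seed = 1, spec = dichotomous_spec(),
                          tech = tech_params(), forest = forest_params(),
                          horizon = 500, step = 0.01) {
  stopifnot(length(alpha_grid) >= 1, length(a_grid) >= 1,
            length(beta_values) >= 1)
  cells <- expand.grid(alpha = alpha_grid, a = a_grid, beta = beta_values,
                       KEEP.OUT.ATTRS = FALSE)
  rows <- vector("list", nrow(cells))
  for (bi in seq_along(beta_values)) {
    for (ai in seq_along(a_grid)) {
      fp <- forest_params(beta = beta_values[bi],
                          a0 = a_grid[ai] / forest$R_W,
                          r = forest$r, r_prime = forest$r_prime,
                          R_c = forest$R_c, N0 = forest$N0, R0 = forest$R0,
                          t0 = forest$t0, R_W = forest$R_W)
      dl <- no_return_deadline(rescale_to_continental(fp),
                               horizon = horizon, step = step)
      for (gi in seq_along(alpha_grid)) {
        tp <- tech_params(alpha = alpha_grid[gi], T_init = tech$T_init,
                          T_target = tech$T_target)
        cell_seed <- mix_seed(seed, bi, ai, gi)
        est <- estimate_success_probability(NULL, tp, spec,
                                            n_trials = n_trials,
                                            seed = cell_seed,
                                            deadline_info = dl)
        i <- which(cells$alpha == alpha_grid[gi] & cells$a == a_grid[ai] &
                     cells$beta == beta_values[bi])
        rows[[i]] <- data.frame(
          beta = beta_values[bi], alpha = alpha_grid[gi], a = a_grid[ai],
          n_trials = n_trials, p_suc = est$p_suc, ci95 = est$ci_halfwidth,
          tau_success = est$tau_success, tau_failure = est$tau_failure,
          t_no_return = if (is.na(est$t_no_return)) NA_real_ else est$t_no_return,
          censored_deadline = est$censored_deadline)
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seed") <- seed
  attr(out, "spec") <- spec
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' Export a sweep result as CSV
#'
#' @param sweep a [sweep_success()] result.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "sweep_result"))
  utils::write.csv(format_numeric_df(as.data.frame(sweep)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
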