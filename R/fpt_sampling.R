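# Vectorised first-passage sampling.
#
# All Monte Carlo estimates in the package funnel through sample_fpt_batch():
# n trajectories are advanced in lock-step rounds, one sojourn per active
# trajectory per round, entirely in vector operations. Crossings are solved
# exactly on the on-interval where the cumulative on-time reaches the
# requirement, so the sampler has no discretisation error and never
# materialises a full switch series per trajectory.

#' Sample first-passage times of the technology process
#'
#' Draws `n` independent first-passage times of the stop-and-go growth
#' model: the time at which the cumulative on-time of the dichotomous
#' noise reaches `log(T_target / T_init) / alpha`. Trajectories still short
#' of the target at `deadline` are censored (`NA`).
#'
#' @param spec a [dichotomous_spec()].
#' @param params a [tech_params()].
#' @param n number of trajectories.
#' @param deadline censoring horizon in years (default `Inf`: sample the
#'   full distribution, which is proper since the on-fraction is positive).
#' @param seed optional integer seed.
#' @return numeric vector of length `n`: crossing times in years, `NA`
#'   where censored at `deadline`.
#' @seealso [empirical_fpt_distribution()] for the packaged experiment.
#' @export
sample_fpt_batch <- function(spec, params, n, deadline = Inf, seed = NULL) {
  stopifnot(inherits(spec, "dichotomous_spec"), inherits(params, "tech_params"),
            n >= 1)
  needed <- min_passage_time(params)
  with_seed(seed, {
    if (needed == 0) return(numeric(n))
    p_on <- stationary_on_fraction(spec)
    on <- switch(spec$initial_state_rule,
                 "fixed-on" = rep(TRUE, n),
                 "fixed-off" = rep(FALSE, n),
                 "stationary" = stats::runif(n) < p_on)
    t <- numeric(n)      # elapsed time
    A <- numeric(n)      # accumulated on-time
    cross <- rep(NA_real_, n)
    active <- rep(TRUE, n)
    while (any(active)) {
      idx <- which(active)
      rate <- ifelse(on[idx], 1 / spec$mean_on, 1 / spec$mean_off)
      d <- stats::rexp(length(idx), rate = rate)
      is_on <- on[idx]
      if (any(is_on)) {
        io <- idx[is_on]
        dio <- d[is_on]
        ct <- t[io] + (needed - A[io])
        hit <- ct <= pmin(t[io] + dio, deadline)
        if (any(hit)) {
          cross[io[hit]] <- ct[hit]
          active[io[hit]] <- FALSE
        }
        A[io] <- A[io] + dio
      }
      t[idx] <- t[idx] + d
      if (is.finite(deadline)) {
        dead <- idx[active[idx] & t[idx] >= deadline]
        if (length(dead)) active[dead] <- FALSE
      }
      on[idx] <- !on[idx]
    }
    cross
  })
}

#' Empirical first-passage-time distribution
#'
#' Runs `n` independent trajectories of the technology process and returns
#' their first-passage times together with a density-scaled histogram, the
#' Monte Carlo side of the closed-form validation (see [fpt_density()]).
#' In symmetric-rate mode the realisations start in the growth state by
#' default, matching the initial condition under which the closed-form
#' first-passage density (and its mean, which is then independent of
#' `gamma`) is derived.
#'
#' @param spec a [dichotomous_spec()].
#' @param params a [tech_params()].
#' @param n number of trajectories (default 10000).
#' @param seed optional integer seed.
#' @param horizon censoring horizon (years); the default `Inf` samples the
#'   complete distribution.
#' @param breaks passed to [graphics::hist()] semantics via [base::cut()]:
#'   number of histogram cells (default 100).
#' @return an object of class `fpt_samples`: list with `times` (crossing
#'   times, `NA` if censored), `censored`, `spec`, `params`, and
#'   `histogram` (data frame `mid`, `density` over the uncensored samples).
#' @examples
#' spec <- dichotomous_spec(mode = "symmetric-rate", gamma = 4,
#'                          initial_state_rule = "fixed-on")
#' fpt <- empirical_fpt_distribution(spec, tech_params(), n = 500, seed = 1)
#' mean(fpt$times)
#' @export
empirical_fpt_distribution <- function(spec, params, n = 10000, seed = NULL,
                                       horizon = Inf, breaks = 100) {
  stopifnot(n >= 1)
  if (spec$mode == "symmetric-rate" && spec$initial_state_rule == "stationary") {
    spec <- dichotomous_spec(mode = "symmetric-rate", gamma = spec$gamma,
                             initial_state_rule = "fixed-on")
  }
  times <- sample_fpt_batch(spec, params, n, deadline = horizon, seed = seed)
  censored <- is.na(times)
  finite <- times[!censored]
  histogram <- NULL
  if (length(finite) > 1L) {
    h <- graphics::hist(finite, breaks = breaks, plot = FALSE)
    histogram <- data.frame(mid = h$mids, density = h$density)
  }
  structure(list(times = times, censored = censored, spec = spec,
                 params = params, histogram = histogram),
            class = "fpt_samples")
}

#' @export
print.fpt_samples <- function(x, ...) {
  n <- length(x$times)
  nc <- sum(x$censored)
  cat(sprintf("First-passage sample: n = %d (%d censored)\n", n, nc))
  if (nc < n) {
    cat(sprintf("  mean = %.4g yr, min = %.4g yr (hard bound %.4g yr)\n",
                mean(x$times, na.rm = TRUE), min(x$times, na.rm = TRUE),
                min_passage_time(x$params)))
  }
  invisible(x)
}

#' Export first-passage samples as CSV
#'
#' Writes `trial,seed,first_passage_years,censored` rows.
#'
#' @param fpt an `fpt_samples` object.
#' @param path output file path.
#' @param seed the seed the sample was generated with (recorded per row).
#' @return the path, invisibly.
#' @export
write_fpt_csv <- function(fpt, path, seed = NA_integer_) {
  stopifnot(inherits(fpt, "fpt_samples"))
  out <- data.frame(trial = seq_along(fpt$times), seed = seed,
                    first_passage_years = fpt$times,
                    censored = fpt$censored)
  utils::write.csv(format_numeric_df(out), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
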