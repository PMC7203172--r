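#' Integrate the humans-forest system by forward Euler
#'
#' Advances the coupled logistic system
#' \deqn{dN/dt = r N (1 - N/(\beta R)), \quad
#'       dR/dt = r' R (1 - R/R_c) - a_0 N R}
#' with an explicit Euler scheme of fixed step, the integration method the
#' analysis is defined with. For the parameter ranges of interest the
#' fastest rate is of order 0.01 yr^-1, so the default step of 0.01 yr
#' resolves the dynamics with a large margin; a convergence check (halving
#' the step moves the no-return time by well under 1%) is part of the test
#' suite.
#'
#' @param params a [forest_params()] object (absolute or continental units).
#' @param horizon integration horizon in years (default 500).
#' @param step Euler step in years (default 0.01).
#' @return an object of class `population_trajectory`: a data frame with
#'   columns `t` (years since start), `N` and `R`, carrying the parameters
#'   and step as attributes.
#' @examples
#' traj <- integrate_humans_forest(forest_params(beta = 170), horizon = 100)
#' find_no_return(traj)
#' @export
integrate_humans_forest <- function(params, horizon = 500, step = 0.01) {
  stopifnot(inherits(params, "forest_params"))
  if (!(is.numeric(step) && length(step) == 1L && step > 0)) {
    stop("'step' must be a positive scalar")
  }
  if (!(is.numeric(horizon) && length(horizon) == 1L && horizon >= step)) {
    stop("'horizon' must be at least one step")
  }
  n <- ceiling(horizon / step)
  N <- numeric(n + 1L)
  R <- numeric(n + 1L)
  N[1L] <- params$N0
  R[1L] <- params$R0
  r <- params$r; rp <- params$r_prime; beta <- params$beta
  a0 <- params$a0; Rc <- params$R_c
  for (i in seq_len(n)) {
    Ni <- N[i]; Ri <- R[i]
    N[i + 1L] <- Ni + step * r * Ni * (1 - Ni / (beta * Ri))
    R[i + 1L] <- Ri + step * (rp * Ri * (1 - Ri / Rc) - a0 * Ni * Ri)
    if (!is.finite(N[i + 1L]) || !is.finite(R[i + 1L]) ||
        N[i + 1L] <= 0 || R[i + 1L] <= 0) {
      stop(sprintf(paste0("Euler integration failed at t = %.4g yr: ",
                          "non-positive or non-finite state; step %g yr is ",
                          "too large for these parameters"),
                   i * step, step))
    }
  }
  traj <- data.frame(t = seq(0, by = step, length.out = n + 1L), N = N, R = R)
  attr(traj, "params") <- params
  attr(traj, "step") <- step
  class(traj) <- c("population_trajectory", "data.frame")
  traj
}

#' Locate the no-return point of a population trajectory
#'
#' The no-return point is the time at which the population reaches its
#' maximum before collapsing: past it, the model's population can no longer
#' sustain itself. Operationally this is the first interior strict local
#' maximum of `N` that is followed by a cumulative decline of at least
#' `decline` (default 1%) within the remaining horizon; the decline
#' requirement guards against floating-point plateaus, and boundary maxima
#' (monotone or terminally rising trajectories) are not reported.
#'
#' @param traj a `population_trajectory` from [integrate_humans_forest()].
#' @param decline minimum relative decline after the maximum for it to
#'   qualify as a collapse (default 0.01).
#' @return an object of class `no_return_point`: a list with `found`
#'   (logical), and when found `t_nr` (years since start) and `N_max`.
#' @examples
#' traj <- integrate_humans_forest(forest_params(beta = 170), horizon = 100)
#' find_no_return(traj)
#' @export
find_no_return <- function(traj, decline = 0.01) {
  stopifnot(inherits(traj, "population_trajectory") || is.data.frame(traj))
  N <- traj$N
  n <- length(N)
  if (n == 0L) stop("empty trajectory")
  out <- list(found = FALSE, t_nr = NA_real_, N_max = NA_real_)
  class(out) <- "no_return_point"
  if (n < 3L) return(out)
  # suffix minimum: smallest N at or after each index
  suf_min <- rev(cummin(rev(N)))
  interior <- 2:(n - 1L)
  is_max <- N[interior] > N[interior - 1L] & N[interior] >= N[interior + 1L]
  qualifies <- is_max & suf_min[interior] <= (1 - decline) * N[interior]
  hit <- which(qualifies)
  if (length(hit) == 0L) return(out)
  i <- interior[hit[1L]]
  out$found <- TRUE
  out$t_nr <- traj$t[i]
  out$N_max <- N[i]
  out
}

#' @export
print.no_return_point <- function(x, ...) {
  if (x$found) {
    cat(sprintf("No-return point at t = %.4g yr (population maximum %.4g)\n",
                x$t_nr, x$N_max))
  } else {
    cat("No no-return point within the integration horizon\n")
  }
  invisible(x)
}

#' Export a population trajectory as CSV
#'
#' Writes `t,calendar_year,N,R` rows, optionally decimated to every
#' `every`-th step, in RFC-4180 dialect with `.` decimal separator.
#'
#' @param traj a `population_trajectory`.
#' @param path output file path.
#' @param every decimation factor: keep one row in `every` (default 1).
#' @return the path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, every = 1L) {
  stopifnot(inherits(traj, "population_trajectory"))
  every <- max(1L, as.integer(every))
  keep <- seq(1L, nrow(traj), by = every)
  t0 <- attr(traj, "params")$t0
  out <- data.frame(t = traj$t[keep],
                    calendar_year = t0 + traj$t[keep],
                    N = traj$N[keep], R = traj$R[keep])
  utils::write.csv(format_numeric_df(out), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

# fixed significant-digit formatting so that re-runs are byte-identical
format_numeric_df <- function(df) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(x) {
        if (is.na(x)) return("NA")
        ax <- abs(x)
        if (x == 0 || (ax >= 1e-3 && ax < 1e6)) sprintf("%.10g", x)
        else sprintf("%.10e", x)
      }, character(1))
    }
  }
  df
}
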