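#' Parameters of the humans-forest interaction model
#'
#' Bundles the rates and capacities of the coupled logistic system
#' \deqn{dN/dt = r N (1 - N / (\beta R))}
#' \deqn{dR/dt = r' R (1 - R / R_c) - a_0 N R}
#' where `N` is the human population and `R` the forested surface. The
#' defaults are the world-scale estimates: human growth rate `r = 0.01`
#' per year, forest renewability `r' = 0.001` per year, forest carrying
#' capacity `R_c = 6e7` square kilometres, current population `N0 = 6e9`
#' starting in calendar year 2000 with `R0 = 4e7` square kilometres of
#' forest left, and extraction (technology) parameter `a0 = 1e-12` per
#' person per year.
#'
#' `beta` is the human carrying capacity per unit of forest surface; the
#' planetary estimate is `N_c / R_c ~ 170` (see [estimate_beta()]), while
#' fits to recent population growth suggest values up to 700-900.
#'
#' Note on units: `a0` follows the hybrid convention in which `a0 * N` is
#' the per-year relative deforestation rate with `N` in persons and `R` in
#' square kilometres. After rescaling both `N` and `R` by the total
#' continental area `R_W` (see [rescale_to_continental()]) the equivalent
#' parameter is `a = a0 * R_W` in Km^2 per year.
#'
#' @param beta human carrying capacity per unit forest (dimensionless).
#' @param a0 resource extraction parameter (yr^-1 person^-1, hybrid convention).
#' @param r human population growth rate (yr^-1).
#' @param r_prime forest renewability rate (yr^-1).
#' @param R_c forest carrying capacity (Km^2).
#' @param N0 initial population (persons).
#' @param R0 initial forest surface (Km^2), at most `R_c`.
#' @param t0 initial calendar year (presentation only; integration time
#'   starts at 0).
#' @param R_W total continental area (Km^2), used only for rescaling.
#' @param rescaled logical; `TRUE` for parameter sets already expressed in
#'   continental units (then `a0` is interpreted as `a`, in Km^2 yr^-1).
#' @return an object of class `forest_params`.
#' @seealso [integrate_humans_forest()], [rescale_to_continental()]
#' @examples
#' forest_params(beta = 170)
#' @export
forest_params <- function(beta = 170, a0 = 1e-12, r = 0.01, r_prime = 0.001,
                          R_c = 6e7, N0 = 6e9, R0 = 4e7, t0 = 2000,
                          R_W = 1.5e8, rescaled = FALSE) {
  p <- list(beta = beta, a0 = a0, r = r, r_prime = r_prime, R_c = R_c,
            N0 = N0, R0 = R0, t0 = t0, R_W = R_W, rescaled = isTRUE(rescaled))
  num <- p[c("beta", "a0", "r", "r_prime", "R_c", "N0", "R0", "t0", "R_W")]
  if (!all(vapply(num, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                  logical(1)))) {
    stop("all forest parameters must be finite numeric scalars")
  }
  if (a0 < 0) stop("'a0' must be >= 0")
  for (nm in c("beta", "r", "r_prime", "R_c", "N0", "R0", "R_W")) {
    if (p[[nm]] <= 0) stop(sprintf("'%s' must be strictly positive", nm))
  }
  if (R0 > R_c) stop("'R0' must not exceed the carrying capacity 'R_c'")
  class(p) <- "forest_params"
  p
}

#' @export
print.forest_params <- function(x, ...) {
  units <- if (x$rescaled) "continental units (N' = N/R_W, R' = R/R_W)" else "persons / Km^2"
  cat("Humans-forest model parameters (", units, ")\n", sep = "")
  cat(sprintf("  beta = %g, %s = %g, r = %g /yr, r' = %g /yr\n",
              x$beta, if (x$rescaled) "a" else "a0", x$a0, x$r, x$r_prime))
  cat(sprintf("  R_c = %g, N0 = %g, R0 = %g, start year %g\n",
              x$R_c, x$N0, x$R0, x$t0))
  invisible(x)
}

#' Estimate the carrying-capacity ratio beta
#'
#' The human carrying capacity per unit of intact forest, `beta = N_c / R_c`,
#' from the maximum sustainable population `N_c` and the forest carrying
#' capacity `R_c`. With `N_c ~ 1e10` persons and `R_c ~ 6e7` Km^2 this gives
#' roughly 170.
#'
#' @param N_c maximum human carrying capacity (persons).
#' @param R_c forest carrying capacity (Km^2), strictly positive.
#' @return `N_c / R_c`.
#' @examples
#' estimate_beta(1e10, 6e7)
#' @export
estimate_beta <- function(N_c, R_c) {
  if (!is.numeric(R_c) || any(R_c <= 0)) stop("'R_c' must be strictly positive")
  N_c / R_c
}

#' Estimate the extraction parameter a0 from observed forest loss
#'
#' Inverts the deforestation-dominated balance `(1/R) dR/dt ~ -a0 N`,
#' neglecting regrowth, so that an observed loss `delta_R` over `delta_t`
#' years at forest stock `R` and population `N` yields
#' `a0 = (delta_R / delta_t) / (R * N)`. With the 2000-2012 global loss
#' (2.3e6 Km^2 over 12 years, R ~ 3e7 Km^2, N ~ 7.5e9) the estimate is of
#' order 1e-12.
#'
#' @param R forest surface over the observation window (Km^2).
#' @param delta_R magnitude of forest loss over the window (Km^2, >= 0).
#' @param delta_t window length (years).
#' @param N population over the window (persons).
#' @return the extraction parameter (yr^-1 person^-1, hybrid convention).
#' @examples
#' estimate_a0(3e7, 2.3e6, 12, 7.5e9)
#' @export
estimate_a0 <- function(R, delta_R, delta_t, N) {
  if (any(c(R, delta_t, N) <= 0)) stop("'R', 'delta_t' and 'N' must be positive")
  if (delta_R < 0) stop("'delta_R' is a loss magnitude and must be >= 0")
  (delta_R / delta_t) / (R * N)
}

#' Rescale model parameters to continental units
#'
#' Re-expresses the system in the dimensionless variables `N' = N / R_W`
#' and `R' = R / R_W`, where `R_W` is the total continental area
#' (~1.5e8 Km^2). The structure of the equations is unchanged; the
#' extraction parameter becomes `a = a0 * R_W` (Km^2 yr^-1), the value
#' used by the parameter sweeps (baseline `a = 1.5e-4`).
#'
#' @param params a [forest_params()] object in absolute units.
#' @return a `forest_params` object with `rescaled = TRUE`; its `a0` field
#'   holds `a = a0 * R_W`.
#' @seealso [unrescale_from_continental()] for the inverse.
#' @examples
#' rescale_to_continental(forest_params(beta = 170))
#' @export
rescale_to_continental <- function(params) {
  stopifnot(inherits(params, "forest_params"))
  if (params$rescaled) stop("parameters are already in continental units")
  forest_params(beta = params$beta, a0 = params$a0 * params$R_W,
                r = params$r, r_prime = params$r_prime,
                R_c = params$R_c / params$R_W, N0 = params$N0 / params$R_W,
                R0 = params$R0 / params$R_W, t0 = params$t0,
                R_W = params$R_W, rescaled = TRUE)
}

#' @rdname rescale_to_continental
#' @export
unrescale_from_continental <- function(params) {
  stopifnot(inherits(params, "forest_params"))
  if (!params$rescaled) stop("parameters are not in continental units")
  forest_params(beta = params$beta, a0 = params$a0 / params$R_W,
                r = params$r, r_prime = params$r_prime,
                R_c = params$R_c * params$R_W, N0 = params$N0 * params$R_W,
                R0 = params$R0 * params$R_W, t0 = params$t0,
                R_W = params$R_W, rescaled = FALSE)
}

#' Moore-law technological growth rate
#'
#' The exponential rate corresponding to a doubling every two years,
#' `log(2) / 2`, conventionally rounded to 0.345 per year. Used as the
#' optimistic default for the technology growth rate.
#'
#' @return `log(2) / 2` (yr^-1).
#' @examples
#' alpha_moore()
#' @export
alpha_moore <- function() log(2) / 2
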