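# Closed-form densities for the symmetric dichotomous case.
#
# When both sojourn means equal 2/gamma the centred noise is the classic
# telegraph process and the drift-removed log-level W = (2/alpha) log(T/T0)
# - t performs a persistent random walk whose density solves the
# telegrapher's equation. All densities here carry an explicit singular
# (delta) component, stored as (location, mass) pairs rather than narrow
# kernels, so normalisation can be tested exactly. Bessel factors are
# evaluated in scaled form, exp(z - gamma t / 2) * (e^-z I_n(z)), whose
# exponent is always <= 0, so large arguments cannot overflow.

#' Continuous part of the telegrapher density
#'
#' Density at drift-removed coordinate `W` after time `t` of the persistent
#' random walk with velocity ±1 and flip rate `gamma / 2` (autocorrelation
#' `exp(-gamma |tau|)`). The full distribution also has atoms of mass
#' `exp(-gamma t / 2) / 2` at `W = ±t` (the never-switched trajectories);
#' use [telegrapher_density()] for the complete object. Zero outside
#' `|W| <= t` (finite propagation speed).
#'
#' @param W coordinate(s) at which to evaluate.
#' @param t elapsed time (years, > 0).
#' @param gamma correlation decay rate (yr^-1).
#' @return density values at `W`.
#' @examples
#' telegrapher_pdf(0, t = 2, gamma = 4)
#' @export
telegrapher_pdf <- function(W, t, gamma) {
  if (!(is.numeric(t) && length(t) == 1L && t > 0)) {
    stop("'t' must be a positive scalar")
  }
  stopifnot(gamma > 0)
  out <- numeric(length(W))
  inside <- abs(W) < t
  if (any(inside)) {
    s <- sqrt(t^2 - W[inside]^2)
    z <- gamma * s / 2
    i0 <- besselI(z, 0, expon.scaled = TRUE)
    i1 <- besselI(z, 1, expon.scaled = TRUE)
    out[inside] <- (gamma / 4) * exp(z - gamma * t / 2) * (i0 + t * i1 / s)
  }
  out
}

#' Full telegrapher distribution (atoms + continuous part)
#'
#' @inheritParams telegrapher_pdf
#' @return a [density_with_atom()] object over `W` with atoms at `±t`.
#' @export
telegrapher_density <- function(t, gamma) {
  stopifnot(t > 0, gamma > 0)
  density_with_atom(
    atoms = data.frame(location = c(-t, t),
                       mass = rep(exp(-gamma * t / 2) / 2, 2L)),
    density = function(W) telegrapher_pdf(W, t, gamma),
    support = c(-t, t), var_name = "W")
}

#' Density of the technology level at a fixed time
#'
#' Change of variables of the telegrapher density to the level `T` via
#' `x = (2/alpha) log(T / T0)` (so `W = x - t`), with Jacobian
#' `2 / (alpha T)`. The distribution has atoms of mass
#' `exp(-gamma t / 2) / 2` at `T = T0` (never grown) and at the envelope
#' `T = T0 exp(alpha t)` (never stalled); `pdf_level()` returns the
#' continuous part, zero outside `(T0, T0 exp(alpha t))`.
#'
#' @param T level(s) at which to evaluate (Watt).
#' @param t elapsed time (years, > 0).
#' @param gamma correlation decay rate (yr^-1).
#' @param alpha growth rate (yr^-1).
#' @param T0 starting level (Watt).
#' @return density values (per Watt) at `T`.
#' @examples
#' pdf_level(2e13, t = 5, gamma = 4, alpha = 0.345, T0 = 1e13)
#' @export
pdf_level <- function(T, t, gamma, alpha, T0) {
  stopifnot(t > 0, gamma > 0, alpha > 0, T0 > 0)
  x <- ifelse(T > 0, (2 / alpha) * log(T / T0), -Inf)
  J <- 2 / (alpha * T)
  J * telegrapher_pdf(x - t, t, gamma)
}

#' @rdname pdf_level
#' @return `level_density()`: a [density_with_atom()] object over `T`.
#' @export
level_density <- function(t, gamma, alpha, T0) {
  stopifnot(t > 0, gamma > 0, alpha > 0, T0 > 0)
  density_with_atom(
    atoms = data.frame(location = c(T0, T0 * exp(alpha * t)),
                       mass = rep(exp(-gamma * t / 2) / 2, 2L)),
    density = function(T) pdf_level(T, t, gamma, alpha, T0),
    support = c(T0, T0 * exp(alpha * t)), var_name = "T")
}

#' First-passage-time density for the symmetric process
#'
#' Density of the time at which the level first reaches the target
#' coordinate `x` starting from `x1` (both in the transformed scale
#' `x = (2/alpha) log(T/T0)`), for the symmetric telegraph noise with
#' correlation decay `gamma`, started in the growth state. The minimum
#' possible time is `t_min = (x - x1) / 2` (uninterrupted growth), which
#' carries an atom of mass `exp(-gamma t_min / 2)`; for `t > t_min` the
#' continuous part is a modified-Bessel `I_1` profile. `fpt_density()`
#' evaluates the continuous part (zero at or before `t_min`);
#' [fpt_dist()] returns the full object including the atom, a numeric CDF
#' and the exact mean `x - x1`, which is independent of `gamma`.
#'
#' @param t time(s) at which to evaluate (years).
#' @param x target coordinate.
#' @param x1 starting coordinate (`x > x1` for a non-degenerate problem).
#' @param gamma correlation decay rate (yr^-1).
#' @return density values at `t`.
#' @examples
#' u <- mean_fpt(4e26, 1e13, 0.345)   # x - x1 on the transformed scale
#' fpt_density(u * 0.6, x = u, x1 = 0, gamma = 1 / 4)
#' @export
fpt_density <- function(t, x, x1, gamma) {
  stopifnot(gamma > 0)
  if (x <= x1) stop("degenerate problem: 'x' must exceed 'x1'")
  u <- x - x1
  t_min <- u / 2
  out <- numeric(length(t))
  pos <- t > t_min
  if (any(pos)) {
    s <- t[pos] - t_min
    z <- gamma * sqrt(u * s / 2)
    i1 <- besselI(z, 1, expon.scaled = TRUE)
    out[pos] <- gamma * sqrt(u) / (2 * sqrt(2) * sqrt(s)) *
      exp(z - gamma * t[pos] / 2) * i1
  }
  out
}

#' @rdname fpt_density
#' @return `fpt_dist()`: a [density_with_atom()] object over `t` with the
#'   atom at `t_min`, plus elements `cdf` (a vectorised function of `t`)
#'   and `mean` (`x - x1`).
#' @export
fpt_dist <- function(x, x1, gamma) {
  if (x <= x1) stop("degenerate problem: 'x' must exceed 'x1'")
  u <- x - x1
  t_min <- u / 2
  atom_mass <- exp(-gamma * t_min / 2)
  dens <- function(t) fpt_density(t, x, x1, gamma)
  obj <- density_with_atom(
    atoms = data.frame(location = t_min, mass = atom_mass),
    density = dens, support = c(t_min, Inf), var_name = "t")
  obj$mean <- u
  obj$cdf <- function(t) {
    t <- as.numeric(t)
    ord <- order(t)
    ts <- t[ord]
    acc <- numeric(length(ts))
    prev_t <- t_min
    prev_F <- atom_mass
    for (i in seq_along(ts)) {
      if (ts[i] < t_min) {
        acc[i] <- 0
        next
      }
      if (ts[i] > prev_t) {
        prev_F <- prev_F + stats::integrate(dens, prev_t, ts[i],
                                            rel.tol = 1e-9,
                                            abs.tol = 1e-12)$value
        prev_t <- ts[i]
      }
      acc[i] <- min(prev_F, 1)
    }
    acc[order(ord)]
  }
  obj
}

#' Mean first-passage time to a technology level
#'
#' Exact mean of the first-passage density for the symmetric process:
#' `(2 / alpha) * log(T / T1)` years — twice the uninterrupted-growth
#' time, independent of the switching rate `gamma`. With the Moore rate
#' `alpha = 0.345`, `T1 = 1e13` W and the Dyson limit `T = 4e26` W this is
#' about 180 years.
#'
#' @param T target level (Watt).
#' @param T1 starting level (Watt), `0 < T1 <= T`.
#' @param alpha growth rate (yr^-1).
#' @return years.
#' @examples
#' mean_fpt(4e26, 1e13, 0.345)
#' @export
mean_fpt <- function(T, T1, alpha) {
  if (!(alpha > 0)) stop("'alpha' must be positive")
  if (!(T1 > 0 && T >= T1)) stop("levels must satisfy 0 < T1 <= T")
  (2 / alpha) * log(T / T1)
}

#' Distribution with an explicit singular component
#'
#' Container pairing a continuous density with the locations and masses of
#' its delta components, so that normalisation (atom mass plus quadrature
#' of the continuous part equals one) can be verified without smoothing
#' artefacts.
#'
#' @param atoms data frame with columns `location` and `mass`.
#' @param density vectorised function evaluating the continuous part.
#' @param support numeric length-2 vector, support of the continuous part.
#' @param var_name name of the variable (for printing).
#' @return an object of class `density_with_atom`.
#' @export
density_with_atom <- function(atoms, density, support, var_name = "x") {
  stopifnot(is.data.frame(atoms), all(c("location", "mass") %in% names(atoms)),
            is.function(density), length(support) == 2L)
  if (any(atoms$mass < 0) || sum(atoms$mass) > 1 + 1e-12) {
    stop("atom masses must be non-negative and sum to at most 1")
  }
  structure(list(atoms = atoms, density = density, support = support,
                 var_name = var_name),
            class = "density_with_atom")
}

#' @export
print.density_with_atom <- function(x, ...) {
  cat(sprintf("Distribution in %s with %d atom(s):\n", x$var_name,
              nrow(x$atoms)))
  for (i in seq_len(nrow(x$atoms))) {
    cat(sprintf("  %s = %.6g, mass %.6g\n", x$var_name,
                x$atoms$location[i], x$atoms$mass[i]))
  }
  cat(sprintf("  continuous part on (%g, %g), total mass %.6g\n",
              x$support[1], x$support[2], total_mass(x)))
  invisible(x)
}

#' Total probability mass of a `density_with_atom`
#'
#' Atom masses plus adaptive quadrature of the continuous part over its
#' support; equals 1 (to quadrature tolerance) for a proper distribution.
#'
#' @param obj a [density_with_atom()] object.
#' @param rel.tol quadrature relative tolerance.
#' @return total mass.
#' @export
total_mass <- function(obj, rel.tol = 1e-8) {
  stopifnot(inherits(obj, "density_with_atom"))
  quad <- stats::integrate(obj$density, obj$support[1], obj$support[2],
                           rel.tol = rel.tol, abs.tol = 1e-12,
                           subdivisions = 500L)$value
  sum(obj$atoms$mass) + quad
}

#' Export a density table as CSV
#'
#' Writes `t,density` rows for the continuous part evaluated on a grid,
#' preceded by one `# atom:` comment line per singular component
#' (`location,mass`), keeping the exact atom accounting in the artifact.
#'
#' @param obj a [density_with_atom()] object.
#' @param path output file path.
#' @param grid evaluation grid; defaults to 512 points spanning the
#'   support (capped for infinite supports at the 0.999 quantile scale).
#' @return the path, invisibly.
#' @export
write_density_csv <- function(obj, path, grid = NULL) {
  stopifnot(inherits(obj, "density_with_atom"))
  if (is.null(grid)) {
    hi <- obj$support[2]
    if (!is.finite(hi)) hi <- obj$atoms$location[1] * 8
    grid <- seq(obj$support[1], hi, length.out = 512L)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(obj$atoms))) {
    writeLines(sprintf("# atom: %.10g,%.10g", obj$atoms$location[i],
                       obj$atoms$mass[i]), con)
  }
  writeLines(sprintf("%s,density", obj$var_name), con)
  vals <- obj$density(grid)
  writeLines(sprintf("%.10g,%.10g", grid, vals), con)
  invisible(path)
}

#' Kolmogorov-Smirnov distance between samples and a reference CDF
#'
#' Sup-distance between the empirical CDF of `samples` and a reference
#' distribution function, correct in the presence of ties and of atoms in
#' the reference (both sides of each empirical jump are compared).
#'
#' @param samples numeric vector (censored values must be removed first).
#' @param cdf vectorised distribution function.
#' @return the KS statistic.
#' @export
ks_distance <- function(samples, cdf) {
  stopifnot(is.numeric(samples), !anyNA(samples), length(samples) > 0)
  x <- sort(unique(samples))
  n <- length(samples)
  ecdf_hi <- cumsum(tabulate(match(sort(samples), x), length(x))) / n
  ecdf_lo <- c(0, ecdf_hi[-length(ecdf_hi)])
  Fx <- cdf(x)
  max(abs(ecdf_hi - Fx), abs(ecdf_lo - Fx))
}
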