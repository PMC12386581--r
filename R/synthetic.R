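#' Temperature grid for relaxometry simulations
#'
#' Returns `n_temps` temperatures between `t_min` and `t_max`, by default
#' uniform in reciprocal temperature 1/T (the natural axis of an Arrhenius
#' process, where log T1 branches are straight lines), endpoints included,
#' ascending in T.
#'
#' @param t_min,t_max Temperature range, Kelvin (defaults 80 and 300, the
#'   usual span of a low-temperature relaxometry run).
#' @param n_temps Number of temperatures (default 30).
#' @param grid `"reciprocal"` (uniform in 1/T) or `"uniform"` (uniform in T).
#' @return Numeric vector of temperatures, Kelvin, ascending.
#' @examples
#' default_temperature_grid(100, 300, 3)            # 100, 150, 300
#' default_temperature_grid(100, 300, 3, "uniform") # 100, 200, 300
#' @export
default_temperature_grid <- function(t_min = 80, t_max = 300, n_temps = 30,
                                     grid = c("reciprocal", "uniform")) {
  grid <- match.arg(grid)
  stopifnot(is.numeric(t_min), is.numeric(t_max), is.numeric(n_temps))
  if (!(t_min > 0 && t_max > t_min))
    stop("need 0 < t_min < t_max, got (", t_min, ", ", t_max, ")")
  if (n_temps < 2L) stop("n_temps must be >= 2, got ", n_temps)
  if (grid == "uniform") return(seq(t_min, t_max, length.out = n_temps))
  rev(1 / seq(1 / t_max, 1 / t_min, length.out = n_temps))
}

#' Simulate a noisy T1-versus-temperature series
#'
#' Evaluates the forward BPP model on a temperature grid and multiplies
#' each T1 by i.i.d. lognormal noise with coefficient of variation
#' `noise_cv`. Lognormal noise preserves the positivity of T1 and gives a
#' relative (percent-scale) error model, matching how relaxation-time
#' measurement uncertainty is quoted; at `noise_cv = 0.10` the observed
#' values scatter with 10% CV about the true curve. Gaussian additive
#' noise on the same CV scale is available behind `family = "gaussian"`.
#'
#' @param model A [relaxation_model()] with at least one motion.
#' @param t_min,t_max,n_temps,grid Passed to [default_temperature_grid()].
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (default 0.10). Zero reproduces the forward model exactly.
#' @param seed Integer seed; the generator is reproducible.
#' @param family `"lognormal"` (default) or `"gaussian"` (truncated below
#'   at a small positive floor to keep T1 valid).
#' @return A [t1_series()]; attribute `true_t1` carries the noiseless
#'   model values.
#' @examples
#' m <- relaxation_model(list(motion(2.12e-14, 19.55, 0.110)))
#' simulate_t1_series(m, seed = 42)
#' @export
simulate_t1_series <- function(model, t_min = 80, t_max = 300, n_temps = 30,
                               grid = "reciprocal", noise_cv = 0.10,
                               seed = 1L, family = c("lognormal", "gaussian")) {
  family <- match.arg(family)
  stopifnot(inherits(model, "relaxation_model"), noise_cv >= 0)
  temps <- default_temperature_grid(t_min, t_max, n_temps, grid)
  truth <- t1(model, temps)
  if (noise_cv == 0) {
    obs <- truth
  } else {
    rng <- .seeded_rng(seed)
    on.exit(.restore_rng(rng))
    if (family == "lognormal") {
      # sdlog chosen so the multiplier has mean 1 and CV exactly noise_cv.
      sdlog <- sqrt(log(1 + noise_cv^2))
      obs <- truth * stats::rlnorm(length(truth),
                                   meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else {
      obs <- truth * pmax(1 + stats::rnorm(length(truth), 0, noise_cv), 1e-6)
    }
  }
  out <- t1_series(temps, obs, noise_cv * obs)
  attr(out, "true_t1") <- truth
  out
}

#' Simulate a saturation-recovery curve
#'
#' Samples \eqn{M(t) = M_0(1 - e^{-t/T_1})} at the given delays and adds
#' i.i.d. Gaussian noise of standard deviation `noise_sd` (absolute, in
#' the same arbitrary units as `m0`).
#'
#' @param m0 Equilibrium magnetization, arbitrary units.
#' @param t1 Spin-lattice relaxation time, seconds, > 0.
#' @param times Recovery delays, seconds; default a 16-point logarithmic
#'   ladder from 0.05 T1 to 5 T1 preceded by t = 0.
#' @param noise_sd Additive noise standard deviation, a.u. (default 0).
#' @param seed Integer seed.
#' @param temperature Temperature tag for the returned curve, Kelvin.
#' @return A [recovery_curve()].
#' @examples
#' simulate_recovery_curve(1, 2, noise_sd = 0.02, seed = 7)
#' @export
simulate_recovery_curve <- function(m0, t1, times = NULL, noise_sd = 0,
                                    seed = 1L, temperature = 300) {
  stopifnot(is.numeric(m0), is.numeric(t1), length(t1) == 1L)
  if (!is.finite(t1) || t1 <= 0) stop("t1 must be positive, got ", t1)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.null(times))
    times <- c(0, exp(seq(log(0.05 * t1), log(5 * t1), length.out = 15)))
  mag <- m0 * (1 - exp(-times / t1))
  if (noise_sd > 0) {
    rng <- .seeded_rng(seed)
    on.exit(.restore_rng(rng))
    mag <- mag + stats::rnorm(length(times), 0, noise_sd)
  }
  recovery_curve(temperature, times, mag)
}

#' Simulate a full set of recovery curves along a temperature grid
#'
#' Convenience wrapper: evaluates the model T1 at each grid temperature
#' and emits one noisy recovery curve per temperature, with per-curve
#' seeds derived from `seed`.
#'
#' @inheritParams simulate_t1_series
#' @param m0 Equilibrium magnetization for every curve.
#' @param noise_sd Additive noise s.d. per curve, a.u.
#' @return A list of [recovery_curve()]s suitable for [build_t1_series()].
#' @export
simulate_recovery_set <- function(model, t_min = 80, t_max = 300,
                                  n_temps = 30, grid = "reciprocal",
                                  m0 = 1, noise_sd = 0, seed = 1L) {
  temps <- default_temperature_grid(t_min, t_max, n_temps, grid)
  truth <- t1(model, temps)
  lapply(seq_along(temps), function(i)
    simulate_recovery_curve(m0, truth[i], noise_sd = noise_sd,
                            seed = seed + i, temperature = temps[i]))
}
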