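#' Thermally activated molecular motion
#'
#' A `motion` bundles the three parameters that describe one internal
#' molecular motion in the BPP picture of dipolar spin-lattice relaxation:
#' the Arrhenius pre-exponential correlation time, the activation energy,
#' and the second-moment reduction that weights the motion's contribution
#' to the relaxation rate.
#'
#' @param tau0 Pre-exponential correlation time, seconds. Must be > 0.
#' @param ea Activation energy, kJ/mol. Must be >= 0.
#' @param dm2 Second-moment reduction \eqn{\Delta M_2}, Gauss^2. Must be >= 0.
#' @return An object of class `"bpp_motion"`: a list with elements
#'   `tau0`, `ea`, `dm2`.
#' @examples
#' motion(tau0 = 2.12e-14, ea = 19.55, dm2 = 0.110)
#' @export
motion <- function(tau0, ea, dm2) {
  stopifnot(is.numeric(tau0), length(tau0) == 1L,
            is.numeric(ea),   length(ea) == 1L,
            is.numeric(dm2),  length(dm2) == 1L)
  if (!is.finite(tau0) || tau0 <= 0)
    stop("'tau0' must be a finite positive number of seconds, got ", tau0)
  if (!is.finite(ea) || ea < 0)
    stop("'ea' must be a finite non-negative activation energy in kJ/mol, got ", ea)
  if (!is.finite(dm2) || dm2 < 0)
    stop("'dm2' must be a finite non-negative second-moment reduction in Gauss^2, got ", dm2)
  structure(list(tau0 = tau0, ea = ea, dm2 = dm2), class = "bpp_motion")
}

#' @export
print.bpp_motion <- function(x, ...) {
  cat(sprintf("<motion>  tau0 = %.4g s   Ea = %.4g kJ/mol   dM2 = %.4g G^2\n",
              x$tau0, x$ea, x$dm2))
  invisible(x)
}

# Proton gyromagnetic ratio in rad s^-1 Gauss^-1, and the molar gas constant.
# Chosen so that gamma^2 * dM2[G^2] * tau[s] carries units of s^-1 and
# activation energies can be quoted in kJ/mol.
.GAMMA_H <- 2.6752218744e4
.R_GAS <- 8.314462618

#' Spectrometer context for relaxation calculations
#'
#' Carries the Larmor frequency and the physical constants entering the BPP
#' rate expression. The proton gyromagnetic ratio and the gas constant are
#' fixed physical constants; they are parameters only so that tests can
#' exercise unit conventions.
#'
#' @param frequency_mhz Proton Larmor frequency in MHz (default 25, a
#'   typical low-field solid-state relaxometer).
#' @param gamma Gyromagnetic ratio, rad s^-1 Gauss^-1.
#' @param gas_constant Molar gas constant, J mol^-1 K^-1.
#' @return Object of class `"spectrometer_config"` with fields
#'   `frequency_mhz`, `omega0` (angular Larmor frequency, rad/s), `gamma`,
#'   `gas_constant`.
#' @examples
#' spectrometer_config()           # 25 MHz default
#' spectrometer_config(60)$omega0  # 2*pi*60e6
#' @export
spectrometer_config <- function(frequency_mhz = 25,
                                gamma = .GAMMA_H,
                                gas_constant = .R_GAS) {
  stopifnot(is.numeric(frequency_mhz), length(frequency_mhz) == 1L)
  if (!is.finite(frequency_mhz) || frequency_mhz <= 0)
    stop("'frequency_mhz' must be positive, got ", frequency_mhz)
  structure(list(frequency_mhz = frequency_mhz,
                 omega0 = 2 * pi * frequency_mhz * 1e6,
                 gamma = gamma,
                 gas_constant = gas_constant),
            class = "spectrometer_config")
}

#' Multi-motion BPP relaxation model
#'
#' A relaxation model is an ordered set of [motion()]s plus a
#' [spectrometer_config()]. Per-motion relaxation-rate contributions are
#' additive, so the total rate is the sum over motions.
#'
#' @param motions A list of [motion()] objects (or a single motion).
#' @param config A [spectrometer_config()].
#' @return Object of class `"relaxation_model"`.
#' @examples
#' m <- relaxation_model(list(motion(4.45e-12, 12.77, 0.036),
#'                            motion(2.12e-14, 19.55, 0.110)))
#' t1(m, 200)
#' @export
relaxation_model <- function(motions, config = spectrometer_config()) {
  if (inherits(motions, "bpp_motion")) motions <- list(motions)
  stopifnot(is.list(motions), inherits(config, "spectrometer_config"))
  ok <- vapply(motions, inherits, logical(1), what = "bpp_motion")
  if (length(motions) > 0L && !all(ok))
    stop("all elements of 'motions' must be created by motion()")
  structure(list(motions = motions, config = config),
            class = "relaxation_model")
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat(sprintf("<relaxation_model>  %d motion(s) at %.6g MHz\n",
              length(x$motions), x$config$frequency_mhz))
  for (i in seq_along(x$motions)) {
    m <- x$motions[[i]]
    cat(sprintf("  [%d] tau0 = %.4g s   Ea = %.4g kJ/mol   dM2 = %.4g G^2\n",
                i, m$tau0, m$ea, m$dm2))
  }
  invisible(x)
}

.check_temperature <- function(temperature) {
  if (!is.numeric(temperature) || any(!is.finite(temperature)) ||
      any(temperature <= 0))
    stop("temperature must be positive (Kelvin); got ",
         paste(utils::head(temperature[!is.finite(temperature) | temperature <= 0], 3),
               collapse = ", "))
}

# Correlation times beyond this are outside any measurable regime; the cap
# avoids Inf from exp() at very low temperature. Vectorized over temperature.
.TAU_CAP <- 1e3

#' Arrhenius correlation time
#'
#' Evaluates \eqn{\tau_c(T) = \tau_0 \exp(E_a / RT)} with the activation
#' energy converted from kJ/mol to J/mol. The exponent is evaluated in log
#' space and the result capped at 1000 s (with attribute `capped = TRUE`)
#' so that very low temperatures do not overflow.
#'
#' @param motion A [motion()].
#' @param temperature Temperature(s), Kelvin; must be > 0.
#' @param config A [spectrometer_config()] (supplies the gas constant).
#' @return Correlation time(s) in seconds, same length as `temperature`.
#' @examples
#' correlation_time(motion(4.45e-12, 12.77, 0.036), 300)
#' @export
correlation_time <- function(motion, temperature,
                             config = spectrometer_config()) {
  stopifnot(inherits(motion, "bpp_motion"))
  .check_temperature(temperature)
  expo <- motion$ea * 1000 / (config$gas_constant * temperature)
  capped <- log(motion$tau0) + expo > log(.TAU_CAP)
  tau <- ifelse(capped, .TAU_CAP, motion$tau0 * exp(pmin(expo, 709)))
  if (any(capped)) attr(tau, "capped") <- TRUE
  tau
}

# The two-frequency BPP spectral-density combination evaluated at x = w0*tau:
#   x/(1+x^2) + 4x/(1+4x^2), in units of 1/w0 when multiplied back by tau.
.bpp_j <- function(tau, omega0) {
  tau / (1 + omega0^2 * tau^2) + 4 * tau / (1 + 4 * omega0^2 * tau^2)
}

#' Relaxation-rate contribution of one motion
#'
#' The per-motion BPP rate
#' \deqn{R_1 = \frac{2}{3}\gamma^2 \Delta M_2
#'   \left[\frac{\tau_c}{1+\omega_0^2\tau_c^2} +
#'         \frac{4\tau_c}{1+4\omega_0^2\tau_c^2}\right]}
#' with \eqn{\tau_c} from [correlation_time()].
#'
#' @inheritParams correlation_time
#' @return Rate contribution(s), s^-1. Zero when `dm2` is zero.
#' @examples
#' motion_rate(motion(2.12e-14, 19.55, 0.110), 194)
#' @export
motion_rate <- function(motion, temperature,
                        config = spectrometer_config()) {
  tau <- correlation_time(motion, temperature, config)
  (2 / 3) * config$gamma^2 * motion$dm2 * .bpp_j(as.numeric(tau), config$omega0)
}

#' Total relaxation rate of a multi-motion model
#'
#' Per-motion contributions are additive: the total rate is the sum of
#' [motion_rate()] over the model's motions.
#'
#' @param model A [relaxation_model()] with at least one motion.
#' @param temperature Temperature(s), Kelvin.
#' @return Total rate(s) 1/T1, s^-1.
#' @export
total_rate <- function(model, temperature) {
  stopifnot(inherits(model, "relaxation_model"))
  if (length(model$motions) == 0L)
    stop("model has no motions; refusing to report an infinite T1")
  .check_temperature(temperature)
  rates <- vapply(model$motions, motion_rate, numeric(length(temperature)),
                  temperature = temperature, config = model$config)
  if (length(temperature) == 1L) sum(rates) else rowSums(rates)
}

#' Spin-lattice relaxation time of a model
#'
#' @inheritParams total_rate
#' @return T1 value(s) in seconds, the reciprocal of [total_rate()].
#' @export
t1 <- function(model, temperature) 1 / total_rate(model, temperature)

#' Temperature and depth of the single-motion T1 minimum
#'
#' For one thermally activated motion, T1 passes through a minimum where
#' \eqn{\omega_0 \tau_c \approx 0.6158}. This diagnostic solves for that
#' temperature numerically; it is useful for checking identifiability and
#' for designing temperature grids.
#'
#' @param motion A [motion()] with `ea > 0` and `dm2 > 0`.
#' @param config A [spectrometer_config()].
#' @return A list with `temperature` (K), `t1_min` (s), and `in_range`
#'   (FALSE, with a warning, when the minimum falls outside (1, 1e4) K).
#' @examples
#' t1_minimum(motion(2.12e-14, 19.55, 0.110))  # ~194 K at 25 MHz
#' @export
t1_minimum <- function(motion, config = spectrometer_config()) {
  stopifnot(inherits(motion, "bpp_motion"))
  if (motion$ea <= 0 || motion$dm2 <= 0)
    stop("t1_minimum needs ea > 0 and dm2 > 0; the minimum is undefined otherwise")
  # Rate is maximal where w0*tau equals the root of d/dx [x/(1+x^2)+4x/(1+4x^2)].
  x_star <- .BPP_X_MIN
  # Invert the Arrhenius law: tau(T) = x_star / w0.
  tau_star <- x_star / config$omega0
  t_star <- motion$ea * 1000 /
    (config$gas_constant * (log(tau_star) - log(motion$tau0)))
  in_range <- is.finite(t_star) && t_star > 1 && t_star < 1e4
  if (!in_range)
    warning("T1 minimum at ", format(t_star),
            " K lies outside the physically measurable range (1, 1e4) K")
  mdl <- relaxation_model(list(motion), config)
  list(temperature = t_star,
       t1_min = if (is.finite(t_star) && t_star > 0) t1(mdl, t_star) else NA_real_,
       in_range = in_range)
}

# Root of the derivative of x/(1+x^2) + 4x/(1+4x^2); solved once at load
# time by a dense-bracket Newton/uniroot pass to full double precision.
.bpp_x_min <- function() {
  dfun <- function(x) {
    (1 - x^2) / (1 + x^2)^2 + 4 * (1 - 4 * x^2) / (1 + 4 * x^2)^2
  }
  stats::uniroot(dfun, c(0.3, 1.2), tol = .Machine$double.eps^0.75)$root
}
.BPP_X_MIN <- .bpp_x_min()
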