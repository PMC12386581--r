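#' Saturation-recovery magnetization curve
#'
#' Time-stamped longitudinal magnetization sampled after saturation, at one
#' temperature. At least four points are required so that the two-parameter
#' exponential fit retains residual degrees of freedom.
#'
#' @param temperature Sample temperature, Kelvin.
#' @param times Recovery delays, seconds; strictly increasing, >= 0.
#' @param magnetization Magnetization values, arbitrary units; same length
#'   as `times`.
#' @return Object of class `"recovery_curve"`: a data.frame with columns
#'   `time_s`, `magnetization` and attribute `temperature`.
#' @export
recovery_curve <- function(temperature, times, magnetization) {
  stopifnot(is.numeric(temperature), length(temperature) == 1L,
            is.numeric(times), is.numeric(magnetization))
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be positive Kelvin, got ", temperature)
  if (length(times) != length(magnetization))
    stop("times and magnetization differ in length (",
         length(times), " vs ", length(magnetization), ")")
  if (length(times) < 4L)
    stop("a recovery curve needs at least 4 points, got ", length(times))
  if (any(!is.finite(times)) || any(!is.finite(magnetization)))
    stop("recovery curve contains non-finite values")
  if (any(times < 0)) stop("recovery delays must be >= 0")
  if (any(diff(times) <= 0)) stop("recovery delays must be strictly increasing")
  structure(data.frame(time_s = times, magnetization = magnetization),
            temperature = temperature, class = c("recovery_curve", "data.frame"))
}

#' @export
print.recovery_curve <- function(x, ...) {
  cat(sprintf("<recovery_curve>  %d points at %.6g K, t in [%g, %g] s\n",
              nrow(x), attr(x, "temperature"), min(x$time_s), max(x$time_s)))
  invisible(x)
}

#' T1-versus-temperature series
#'
#' @param temperatures Temperatures, Kelvin, strictly increasing.
#' @param t1_values Spin-lattice relaxation times, seconds, all > 0.
#' @param t1_uncertainty Optional per-point standard errors, seconds.
#' @return Object of class `"t1_series"`: a data.frame with columns
#'   `temperature_K`, `t1_s` and optionally `t1_se_s`.
#' @export
t1_series <- function(temperatures, t1_values, t1_uncertainty = NULL) {
  stopifnot(is.numeric(temperatures), is.numeric(t1_values))
  if (length(temperatures) != length(t1_values))
    stop("temperatures and t1_values differ in length")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop("temperatures must be positive Kelvin")
  if (any(duplicated(temperatures)))
    stop("duplicate temperature in series: ",
         paste(unique(temperatures[duplicated(temperatures)]), collapse = ", "))
  if (is.unsorted(temperatures, strictly = TRUE)) {
    o <- order(temperatures)
    temperatures <- temperatures[o]; t1_values <- t1_values[o]
    if (!is.null(t1_uncertainty)) t1_uncertainty <- t1_uncertainty[o]
  }
  if (any(!is.finite(t1_values)) || any(t1_values <= 0))
    stop("all T1 values must be positive and finite")
  out <- data.frame(temperature_K = temperatures, t1_s = t1_values)
  if (!is.null(t1_uncertainty)) {
    if (length(t1_uncertainty) != length(t1_values))
      stop("t1_uncertainty length mismatch")
    out$t1_se_s <- t1_uncertainty
  }
  structure(out, class = c("t1_series", "data.frame"))
}

#' @export
print.t1_series <- function(x, ...) {
  cat(sprintf("<t1_series>  %d temperatures in [%.6g, %.6g] K, T1 in [%.3g, %.3g] s\n",
              nrow(x), min(x$temperature_K), max(x$temperature_K),
              min(x$t1_s), max(x$t1_s)))
  invisible(x)
}

# Derivative-free starting values: M0 from the plateau, T1 from the time at
# which the signal first crosses (1 - 1/e) of it, by linear interpolation.
.recovery_start <- function(tt, mm) {
  m0 <- max(mm)
  target <- (1 - exp(-1)) * m0
  idx <- which(mm >= target)[1]
  t10 <- if (is.na(idx)) max(tt) else if (idx == 1L) max(tt[1], 1e-9) else {
    t0 <- tt[idx - 1]; t1v <- tt[idx]; y0 <- mm[idx - 1]; y1 <- mm[idx]
    if (y1 > y0) t0 + (target - y0) / (y1 - y0) * (t1v - t0) else t1v
  }
  c(m0 = m0, t1 = max(t10, 1e-9))
}

.fit_recovery_once <- function(tt, mm, start) {
  resid_fn <- function(p) mm - p[1] * (1 - exp(-tt / exp(p[2])))
  fit <- try(minpack.lm::nls.lm(
    par = c(start[["m0"]], log(start[["t1"]])),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12,
                                         maxiter = 500)), silent = TRUE)
  if (inherits(fit, "try-error")) return(NULL)
  if (!fit$info %in% 1:4) return(NULL)
  fit
}

#' Fit the single-exponential saturation-recovery model
#'
#' Estimates the equilibrium magnetization M0 and the spin-lattice
#' relaxation time T1 by unweighted least squares on the recovery model
#' \deqn{M(t) = M_0 (1 - e^{-t/T_1}).}
#' T1 is parameterized on the log scale so that only positive values are
#' reachable. On non-convergence the fit is retried from a log-linear
#' regression start and then from seeded random perturbations before
#' failing.
#'
#' @param curve A [recovery_curve()].
#' @param seed Integer seed for the random-restart ladder.
#' @return A list with `m0`, `t1` (seconds), `m0_se`, `t1_se` (approximate
#'   standard errors from the fit covariance), `rms_residual`, `converged`,
#'   and `n_restarts` used.
#' @examples
#' cv <- recovery_curve(300, seq(0, 10, length.out = 21),
#'                      1 - exp(-seq(0, 10, length.out = 21) / 2))
#' fit_saturation_recovery(cv)[c("m0", "t1")]
#' @export
fit_saturation_recovery <- function(curve, seed = 1L) {
  stopifnot(inherits(curve, "recovery_curve"))
  tt <- curve$time_s; mm <- curve$magnetization
  if (diff(range(mm)) == 0)
    stop("degenerate recovery curve: magnetization is constant")
  start <- .recovery_start(tt, mm)
  tried <- 0L
  fit <- .fit_recovery_once(tt, mm, start)

  if (is.null(fit)) {
    # Log-linear restart: ln(M0 - M) = ln(M0) - t/T1 on the rising part.
    tried <- tried + 1L
    m0g <- start[["m0"]] * 1.05
    pos <- which(m0g - mm > 0 & tt > 0)
    if (length(pos) >= 2L) {
      co <- stats::coef(stats::lm(log(m0g - mm[pos]) ~ tt[pos]))
      if (is.finite(co[2]) && co[2] < 0) {
        fit <- .fit_recovery_once(tt, mm, c(m0 = m0g, t1 = -1 / co[2]))
      }
    }
  }
  if (is.null(fit)) {
    rng <- .seeded_rng(seed)
    for (i in 1:5) {
      tried <- tried + 1L
      jit <- exp(stats::rnorm(2, 0, 0.5))
      fit <- .fit_recovery_once(tt, mm,
                                c(m0 = start[["m0"]] * jit[1],
                                  t1 = start[["t1"]] * jit[2]))
      if (!is.null(fit)) break
    }
    .restore_rng(rng)
  }
  if (is.null(fit))
    stop("saturation-recovery fit failed to converge after ", tried,
         " restart(s); the data may not be recovery-shaped")
  p <- fit$par
  m0 <- p[1]; t1v <- exp(p[2])
  if (m0 <= 0)
    stop("fitted equilibrium magnetization is non-positive (", format(m0),
         "); the data are not recovery-shaped")
  # Covariance via the delta method: par[2] is log(T1).
  se <- rep(NA_real_, 2)
  cv <- try(solve(fit$hessian) * 2 * fit$deviance / max(length(tt) - 2L, 1L),
            silent = TRUE)
  if (!inherits(cv, "try-error") && all(is.finite(diag(cv))) &&
      all(diag(cv) >= 0)) {
    se <- sqrt(diag(cv))
    se[2] <- se[2] * t1v  # d T1 / d log T1 = T1
  }
  list(m0 = m0, t1 = t1v, m0_se = se[1], t1_se = se[2],
       rms_residual = sqrt(mean(fit$fvec^2)),
       converged = TRUE, n_restarts = tried)
}

#' Assemble a T1 series from per-temperature recovery curves
#'
#' Fits each curve with [fit_saturation_recovery()] and collects the
#' estimates into a [t1_series()], sorted by temperature. A curve whose fit
#' fails is skipped and reported in the `failures` attribute, never
#' silently imputed.
#'
#' @param curves A list of [recovery_curve()]s at distinct temperatures
#'   (at least two).
#' @param seed Seed passed to each per-curve fit.
#' @return A [t1_series()] with `t1_se_s` filled from the fit covariance;
#'   attribute `failures` holds per-curve diagnostics for skipped points.
#' @export
build_t1_series <- function(curves, seed = 1L) {
  stopifnot(is.list(curves), length(curves) >= 2L)
  temps <- vapply(curves, function(cv) attr(cv, "temperature"), numeric(1))
  if (any(duplicated(temps)))
    stop("duplicate temperature among curves: ",
         paste(unique(temps[duplicated(temps)]), collapse = ", "))
  fits <- vector("list", length(curves))
  failures <- character(0)
  for (i in seq_along(curves)) {
    res <- try(fit_saturation_recovery(curves[[i]], seed = seed), silent = TRUE)
    if (inherits(res, "try-error")) {
      failures <- c(failures,
                    sprintf("T = %g K: %s", temps[i],
                            conditionMessage(attr(res, "condition"))))
    } else fits[[i]] <- res
  }
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep))
    stop("all recovery-curve fits failed:\n  ",
         paste(failures, collapse = "\n  "))
  out <- t1_series(temps[keep],
                   vapply(fits[keep], `[[`, numeric(1), "t1"),
                   vapply(fits[keep], `[[`, numeric(1), "t1_se"))
  attr(out, "failures") <- failures
  out
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
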