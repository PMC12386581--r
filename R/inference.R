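#' Default parameter bounds for BPP fitting
#'
#' The fit works in the transformed space (log10 tau0, Ea, log10 dM2),
#' which enforces positivity of tau0 and dM2 without a constrained solver.
#' The default box brackets, with generous margin, the parameter ranges
#' reported for thermally activated motions of small organic molecules in
#' the solid state: attempt times of 1e-16 to 1e-8 s, activation energies
#' up to 60 kJ/mol, second-moment reductions of 1e-4 to 10 Gauss^2.
#'
#' @return A list with elements `lower` and `upper`, each a named numeric
#'   vector `c(log10_tau0, ea, log10_dm2)`.
#' @export
bpp_bounds <- function() {
  list(lower = c(log10_tau0 = -16, ea = 1e-2, log10_dm2 = -4),
       upper = c(log10_tau0 = -8,  ea = 60,   log10_dm2 = 1))
}

# Forward model in the optimizer's parameterization. `par` is the stacked
# vector (lt0_1, ea_1, ldm2_1, lt0_2, ...); returns T1 at `temps`.
.t1_from_par <- function(par, temps, config) {
  k <- length(par) / 3L
  rate <- numeric(length(temps))
  for (j in seq_len(k)) {
    p <- par[(3L * j - 2L):(3L * j)]
    tau <- 10^p[1] * exp(p[2] * 1000 / (config$gas_constant * temps))
    rate <- rate + (2 / 3) * config$gamma^2 * 10^p[3] *
      .bpp_j(tau, config$omega0)
  }
  1 / rate
}

.par_from_model <- function(model) {
  unlist(lapply(model$motions, function(m)
    c(log10(m$tau0), m$ea, log10(max(m$dm2, 1e-300)))))
}

.model_from_par <- function(par, config) {
  k <- length(par) / 3L
  motions <- lapply(seq_len(k), function(j) {
    p <- unname(par[(3L * j - 2L):(3L * j)])
    motion(tau0 = 10^p[1], ea = p[2], dm2 = 10^p[3])
  })
  relaxation_model(motions, config)
}

# One damped-least-squares descent from `par0` on log-T1 residuals.
.fit_bpp_single <- function(par0, log_t1_obs, temps, config, lower, upper,
                            maxiter = 1000) {
  resid_fn <- function(p) log_t1_obs - log(.t1_from_par(p, temps, config))
  fit <- try(suppressWarnings(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10,
                                         gtol = 0, maxiter = maxiter,
                                         maxfev = 10 * maxiter))), silent = TRUE)
  if (inherits(fit, "try-error") || !fit$info %in% 1:4) return(NULL)
  fit
}

# Basin-hopping polish around the best multi-start solution: alternates
# small all-parameter jitter with wholesale reinitialization of a single
# motion, accepting only improvements. Rescues solutions in which one
# motion ran to a bound while the remaining motions are near their basin.
.polish_bpp <- function(best, log_t1_obs, temps, config, lower, upper,
                        k, rounds) {
  if (rounds <= 0) return(best)
  width <- upper - lower
  for (r in seq_len(rounds)) {
    if (r %% 2L == 1L) {
      cand <- best$par + stats::rnorm(3L * k, 0, 0.08 * width)
      cand <- pmin(pmax(cand, lower), upper)
    } else {
      j <- sample.int(k, 1L)
      idx <- (3L * j - 2L):(3L * j)
      cand <- best$par
      cand[idx] <- lower[idx] + stats::runif(3L) * width[idx]
    }
    fb <- .fit_bpp_single(cand, log_t1_obs, temps, config, lower, upper,
                          maxiter = 400)
    if (!is.null(fb) && fb$deviance < best$deviance) best <- fb
  }
  best
}

#' Fit a multi-motion BPP/Arrhenius model to a T1 series
#'
#' Minimizes the sum of squared log-residuals
#' \deqn{\sum_i \left[\ln T_1^{obs}(T_i) - \ln T_1^{model}(T_i)\right]^2}
#' over the per-motion parameters (log10 tau0, Ea, log10 dM2) by damped
#' least squares from `n_starts` seeded Latin-hypercube starting points
#' spread over the bounds box, keeping the best converged start. Residuals
#' are taken in log space because T1 spans orders of magnitude between 80
#' and 300 K; a log residual is a relative error, so every temperature
#' contributes on an even footing.
#'
#' The series must contain at least `3k + 2` points so that the `3k`
#' parameters are constrained with residual degrees of freedom.
#'
#' @param series A [t1_series()].
#' @param k Number of motions to fit (>= 1).
#' @param config A [spectrometer_config()]; must match the instrument the
#'   series was measured on.
#' @param n_starts Number of Latin-hypercube starts (default 64).
#' @param seed Integer seed; results are reproducible bit-for-bit for a
#'   fixed (series, k, seed, n_starts, polish_rounds, bounds).
#' @param bounds Parameter box as returned by [bpp_bounds()].
#' @param polish_rounds Number of seeded basin-hopping refinement moves
#'   applied to the best start (default 64). Each move either jitters all
#'   parameters slightly or reinitializes one motion wholesale, keeping
#'   the result only when the objective improves; this rescues fits in
#'   which a motion stalled at a bound. Set to 0 to disable.
#' @return Object of class `"bpp_fit"`: a list with `model` (the estimated
#'   [relaxation_model()], motions sorted by descending dM2), `sse` (sum
#'   of squared log-residuals after polishing), `sse_multistart` (best
#'   start before polishing; `sse <= sse_multistart` always),
#'   `converged`, `n_starts`, `n_converged`, `seed`, `polish_rounds`,
#'   `fitted` (model T1 at the series temperatures), `residuals`
#'   (log scale), `series`, and `motion_order = "desc_dm2"`.
#' @examples
#' truth <- relaxation_model(list(motion(2.12e-14, 19.55, 0.110)))
#' s <- simulate_t1_series(truth, noise_cv = 0, seed = 1)
#' fit_bpp(s, k = 1, n_starts = 16, seed = 1)$model
#' @export
fit_bpp <- function(series, k, config = spectrometer_config(),
                    n_starts = 64, seed = 1L, bounds = bpp_bounds(),
                    polish_rounds = 64) {
  stopifnot(inherits(series, "t1_series"), k >= 1, n_starts >= 1)
  n <- nrow(series)
  if (n < 3 * k + 2)
    stop("series has ", n, " points but fitting k = ", k,
         " motions requires at least 3k + 2 = ", 3 * k + 2)
  temps <- series$temperature_K
  log_obs <- log(series$t1_s)
  lower <- rep(bounds$lower, k)
  upper <- rep(bounds$upper, k)

  rng <- .seeded_rng(seed)
  on.exit(.restore_rng(rng))
  # Starts are drawn in Latin-hypercube blocks of 16 so that a run with
  # more starts extends, rather than replaces, the start sequence of a
  # run with fewer: best-of-starts SSE is then non-increasing in n_starts
  # for a fixed seed.
  blocks <- ceiling(n_starts / 16)
  starts <- do.call(rbind, lapply(seq_len(blocks), function(b)
    lhs::randomLHS(16L, 3L * k)))[seq_len(n_starts), , drop = FALSE]

  best <- NULL; best_sse <- Inf; n_conv <- 0L
  for (s in seq_len(n_starts)) {
    par0 <- lower + starts[s, ] * (upper - lower)
    fit <- .fit_bpp_single(par0, log_obs, temps, config, lower, upper)
    if (is.null(fit)) next
    n_conv <- n_conv + 1L
    if (fit$deviance < best_sse) { best <- fit; best_sse <- fit$deviance }
  }
  if (is.null(best))
    stop("no start converged out of ", n_starts,
         "; the series may be incompatible with k = ", k)
  sse_multistart <- best$deviance
  best <- .polish_bpp(best, log_obs, temps, config, lower, upper, k,
                      polish_rounds)

  # Sort motions by descending dM2 for reporting; matching to references
  # never relies on this order.
  par <- best$par
  ord <- order(par[seq(3, 3 * k, by = 3)], decreasing = TRUE)
  idx <- as.vector(vapply(ord, function(j) (3L * j - 2L):(3L * j), integer(3)))
  par <- par[idx]

  model <- .model_from_par(par, config)
  fitted_t1 <- .t1_from_par(par, temps, config)
  structure(list(model = model, sse = best$deviance,
                 sse_multistart = sse_multistart, converged = TRUE,
                 n_starts = n_starts, n_converged = n_conv, seed = seed,
                 polish_rounds = polish_rounds,
                 fitted = fitted_t1, residuals = log_obs - log(fitted_t1),
                 series = series, bounds = bounds,
                 motion_order = "desc_dm2"),
            class = "bpp_fit")
}

#' @export
print.bpp_fit <- function(x, ...) {
  k <- length(x$model$motions)
  cat(sprintf("<bpp_fit>  k = %d, sse(log T1) = %.4g, %d/%d starts converged\n",
              k, x$sse, x$n_converged, x$n_starts))
  tab <- do.call(rbind, lapply(x$model$motions, function(m)
    data.frame(tau0_s = m$tau0, ea_kJ_per_mol = m$ea, dm2_G2 = m$dm2)))
  if (!is.null(x$param_uncertainty))
    tab$ea_halfwidth_pct <- x$param_uncertainty$ea_pct
  print(format(tab, digits = 4), row.names = TRUE)
  invisible(x)
}

#' Select the number of motions by small-sample information criterion
#'
#' Fits k = 1..`k_max` and scores each with AICc on Gaussian
#' log-residuals, `n log(SSE/n) + 2p + 2p(p+1)/(n - p - 1)` with
#' `p = 3k + 1`. The SSE is floored at `n * 1e-16` (log-residuals below
#' 1e-8 are indistinguishable at the optimizer tolerance), so a perfect
#' fit does not reward further motions and ties resolve toward smaller k.
#' Values of k violating the `3k + 2` length rule are skipped.
#'
#' @param series A [t1_series()].
#' @param k_max Largest motion count to consider (>= 1).
#' @inheritParams fit_bpp
#' @return A list with `k` (selected), `scores` (data.frame of k, sse,
#'   aicc, note), and `fits` (per-k [fit_bpp()] results).
#' @export
select_model_order <- function(series, k_max, config = spectrometer_config(),
                               n_starts = 64, seed = 1L,
                               bounds = bpp_bounds()) {
  stopifnot(k_max >= 1)
  n <- nrow(series)
  rows <- list(); fits <- list()
  for (k in seq_len(k_max)) {
    p <- 3 * k + 1
    if (n < 3 * k + 2 || n - p - 1 <= 0) {
      rows[[k]] <- data.frame(k = k, sse = NA_real_, aicc = NA_real_,
                              note = "skipped: series too short")
      next
    }
    fit <- try(fit_bpp(series, k, config, n_starts, seed, bounds),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      rows[[k]] <- data.frame(k = k, sse = NA_real_, aicc = NA_real_,
                              note = conditionMessage(attr(fit, "condition")))
      next
    }
    sse_eff <- max(fit$sse, n * 1e-16)
    aicc <- n * log(sse_eff / n) + 2 * p + 2 * p * (p + 1) / (n - p - 1)
    rows[[k]] <- data.frame(k = k, sse = fit$sse, aicc = aicc, note = "")
    fits[[k]] <- fit
  }
  scores <- do.call(rbind, rows)
  if (all(is.na(scores$aicc)))
    stop("no candidate k could be fitted; smallest failure: ",
         scores$note[1])
  best <- which(scores$aicc == min(scores$aicc, na.rm = TRUE))[1]
  list(k = scores$k[best], scores = scores, fits = fits)
}

#' Parametric residual bootstrap for BPP fit uncertainty
#'
#' Resamples the fit's log-residuals with replacement, rebuilds synthetic
#' series around the fitted curve, refits each from the point estimate,
#' and reports 95% interval half-widths as a percentage of each estimate.
#' tau0 is assessed on the log10 scale (its natural scale across motions);
#' its half-width is a percentage of |log10 tau0|.
#'
#' @param series The [t1_series()] that was fitted.
#' @param fit A converged [fit_bpp()] result on that series.
#' @param n_boot Number of bootstrap replicates (>= 50; default 200).
#' @param seed Integer seed.
#' @return A list with `table` (data.frame: motion, parameter, estimate,
#'   half-width, halfwidth_pct), `n_failed`, and `draws` (per-replicate
#'   parameter matrix). Errors if more than 20% of refits fail.
#' @export
bootstrap_uncertainty <- function(series, fit, n_boot = 200, seed = 1L) {
  stopifnot(inherits(series, "t1_series"), inherits(fit, "bpp_fit"))
  if (!isTRUE(fit$converged)) stop("fit did not converge; refusing to bootstrap")
  if (n_boot < 50) stop("n_boot must be >= 50, got ", n_boot)
  temps <- series$temperature_K
  cfg <- fit$model$config
  par_hat <- .par_from_model(fit$model)
  k <- length(fit$model$motions)
  lower <- rep(fit$bounds$lower, k)
  upper <- rep(fit$bounds$upper, k)
  res <- fit$residuals
  n <- length(res)

  rng <- .seeded_rng(seed)
  on.exit(.restore_rng(rng))
  draws <- matrix(NA_real_, n_boot, length(par_hat))
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    r_star <- sample(res, n, replace = TRUE)
    log_obs_b <- log(fit$fitted) + r_star
    fb <- .fit_bpp_single(par_hat, log_obs_b, temps, cfg, lower, upper)
    if (is.null(fb)) { n_failed <- n_failed + 1L; next }
    draws[b, ] <- fb$par
  }
  if (n_failed > 0.2 * n_boot)
    stop("unstable fit: ", n_failed, "/", n_boot,
         " bootstrap refits failed to converge")
  ok <- stats::complete.cases(draws)

  rows <- list()
  pnames <- c("log10_tau0", "ea", "log10_dm2")
  for (j in seq_len(k)) {
    for (q in 1:3) {
      col <- 3L * (j - 1L) + q
      qs <- stats::quantile(draws[ok, col], c(0.025, 0.975), names = FALSE)
      hw <- (qs[2] - qs[1]) / 2
      est <- par_hat[col]
      rows[[length(rows) + 1L]] <- data.frame(
        motion = j, parameter = pnames[q], estimate = est,
        halfwidth = hw, halfwidth_pct = 100 * hw / abs(est))
    }
  }
  list(table = do.call(rbind, rows), n_failed = n_failed, draws = draws[ok, , drop = FALSE])
}

#' Match the motions of two relaxation models
#'
#' Pairs motions greedily by nearest neighbor in the normalized
#' (Ea, log10 tau0) plane (coordinates scaled by the default bounds
#' widths: 60 kJ/mol and 8 decades), smallest distance first. Used to
#' score parameter-recovery experiments, where the fitted motion order
#' need not follow the generating order.
#'
#' @param estimated,reference [relaxation_model()]s, both non-empty.
#' @return A list with `pairs` (data.frame: est, ref, distance),
#'   `unmatched_estimated`, `unmatched_reference` (integer indices).
#' @export
match_motions <- function(estimated, reference) {
  stopifnot(inherits(estimated, "relaxation_model"),
            inherits(reference, "relaxation_model"))
  ke <- length(estimated$motions); kr <- length(reference$motions)
  if (ke == 0L || kr == 0L) stop("both models must have at least one motion")
  coord <- function(m) c(m$ea / 60, log10(m$tau0) / 8)
  ce <- vapply(estimated$motions, coord, numeric(2))
  cr <- vapply(reference$motions, coord, numeric(2))
  d <- outer(seq_len(ke), seq_len(kr),
             Vectorize(function(i, j) sqrt(sum((ce[, i] - cr[, j])^2))))
  pairs <- data.frame(est = integer(0), ref = integer(0), distance = numeric(0))
  free_e <- rep(TRUE, ke); free_r <- rep(TRUE, kr)
  for (s in seq_len(min(ke, kr))) {
    dd <- d
    dd[!free_e, ] <- Inf; dd[, !free_r] <- Inf
    w <- which(dd == min(dd), arr.ind = TRUE)[1, ]
    pairs <- rbind(pairs, data.frame(est = w[1], ref = w[2],
                                     distance = d[w[1], w[2]]))
    free_e[w[1]] <- FALSE; free_r[w[2]] <- FALSE
  }
  rownames(pairs) <- NULL
  list(pairs = pairs,
       unmatched_estimated = which(free_e),
       unmatched_reference = which(free_r))
}
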