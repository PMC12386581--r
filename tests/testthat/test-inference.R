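# Multi-motion BPP fitting, model order, bootstrap, and motion matching.

test_that("a single motion is recovered exactly from noiseless data", {
  truth <- single_motion_model()
  s <- noiseless_series(truth)
  f <- fit_bpp(s, k = 1, n_starts = 16, seed = 1)
  est <- f$model$motions[[1]]
  expect_equal(est$ea, 19.55, tolerance = 1e-6)
  expect_equal(log10(est$tau0), log10(2.12e-14), tolerance = 1e-6)
  expect_equal(est$dm2, 0.110, tolerance = 1e-6)
  expect_lt(f$sse, 1e-15)
})

test_that("noiseless multi-motion series identify their generators", {
  # The three-motion magnolol set and the near-degenerate honokiol pair
  # (whose T1 minima sit >100 K apart) are both exactly identifiable.
  for (nm in c("mag_0kGy", "hon_0kGy")) {
    truth <- reference_model(nm)
    k <- length(truth$motions)
    s <- noiseless_series(truth)
    f <- fit_bpp(s, k = k, n_starts = 64, seed = 1)
    mm <- match_motions(f$model, truth)
    expect_equal(nrow(mm$pairs), k)
    for (i in seq_len(k)) {
      e <- f$model$motions[[mm$pairs$est[i]]]
      g <- truth$motions[[mm$pairs$ref[i]]]
      expect_equal(e$ea, g$ea, tolerance = 1e-3)
      expect_lt(abs(log10(e$tau0) - log10(g$tau0)), 0.01)
      expect_equal(e$dm2, g$dm2, tolerance = 1e-3)
    }
  }
})

test_that("fit_bpp is deterministic and monotone in n_starts", {
  truth <- hon0_model()
  s <- simulate_t1_series(truth, noise_cv = 0.10, seed = 3)
  f1 <- fit_bpp(s, k = 2, n_starts = 32, seed = 7)
  f2 <- fit_bpp(s, k = 2, n_starts = 32, seed = 7)
  expect_identical(f1$sse, f2$sse)
  expect_identical(.par_from_model_test(f1), .par_from_model_test(f2))
  # Start blocks extend with n_starts, so the pre-polish best cannot get
  # worse; the polished SSE never exceeds the multistart best.
  f3 <- fit_bpp(s, k = 2, n_starts = 64, seed = 7)
  expect_lte(f3$sse_multistart, f1$sse_multistart)
  expect_lte(f1$sse, f1$sse_multistart)
  expect_lte(f3$sse, f3$sse_multistart)
})

test_that("the 3k+2 length rule is enforced", {
  s <- t1_series(seq(100, 200, length.out = 8), rep(c(1, 2), 4))
  expect_error(fit_bpp(s, k = 3, n_starts = 4, seed = 1), "3k \\+ 2")
})

test_that("noisy honokiol fits keep both T1 minima within 10 K", {
  truth <- hon0_model()
  s <- simulate_t1_series(truth, noise_cv = 0.10, seed = 42)
  f <- fit_bpp(s, k = 2, n_starts = 64, seed = 42)
  mins_true <- sort(vapply(truth$motions, function(m)
    t1_minimum(m, truth$config)$temperature, numeric(1)))
  mins_est <- sort(vapply(f$model$motions, function(m)
    t1_minimum(m, truth$config)$temperature, numeric(1)))
  expect_equal(mins_est, mins_true, tolerance = 10 / 162)
})

test_that("model order selection favors parsimony on perfect fits", {
  s1 <- noiseless_series(single_motion_model(), n_temps = 20)
  sel <- select_model_order(s1, k_max = 3, n_starts = 16, seed = 1)
  expect_identical(sel$k, 1L)
  # Short series skip infeasible orders.
  s8 <- t1_series(seq(100, 240, by = 20),
                  t1(single_motion_model(), seq(100, 240, by = 20)))
  sel8 <- select_model_order(s8, k_max = 4, n_starts = 8, seed = 1)
  expect_true(sel8$k %in% c(1L, 2L))
  expect_match(sel8$scores$note[4], "too short")
})

test_that("model order selection finds three magnolol motions", {
  s <- noiseless_series(mag0_model())
  sel <- select_model_order(s, k_max = 4, n_starts = 48, seed = 1)
  expect_identical(sel$k, 3L)
})

test_that("bootstrap half-widths collapse on noiseless data", {
  truth <- single_motion_model()
  s <- noiseless_series(truth, n_temps = 12)
  f <- fit_bpp(s, k = 1, n_starts = 8, seed = 1)
  b <- bootstrap_uncertainty(s, f, n_boot = 50, seed = 2)
  expect_true(all(b$table$halfwidth_pct < 0.1))
  expect_error(bootstrap_uncertainty(s, f, n_boot = 10, seed = 2),
               "n_boot")
})

test_that("bootstrap intervals are calibrated against noise level", {
  truth <- hon0_model()
  s <- simulate_t1_series(truth, noise_cv = 0.10, seed = 5)
  f <- fit_bpp(s, k = 2, n_starts = 32, seed = 5)
  b <- bootstrap_uncertainty(s, f, n_boot = 60, seed = 6)
  ea_hw <- b$table$halfwidth_pct[b$table$parameter == "ea"]
  # Non-degenerate, finite, and far below the parameter scale.
  expect_true(all(is.finite(ea_hw)))
  expect_true(all(ea_hw > 0.1))
  expect_true(all(ea_hw < 100))
})

test_that("motion matching is order-free and reports the unmatched", {
  a <- mag0_model()
  mm <- match_motions(a, a)
  expect_equal(mm$pairs$est, mm$pairs$ref)
  expect_true(all(mm$pairs$distance == 0))
  # Permuted order recovers the permutation.
  perm <- relaxation_model(a$motions[c(3, 1, 2)], a$config)
  mp <- match_motions(perm, a)
  expect_equal(mp$pairs$ref[order(mp$pairs$est)], c(3, 1, 2))
  expect_true(all(mp$pairs$distance == 0))
  # K mismatch leaves one reference motion unmatched.
  sub <- relaxation_model(a$motions[1:2], a$config)
  ms <- match_motions(sub, a)
  expect_length(ms$unmatched_reference, 1)
  expect_length(ms$unmatched_estimated, 0)
})
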