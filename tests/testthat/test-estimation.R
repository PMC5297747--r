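test_that("progress-curve fit recovers exact parameters", {
  t_grid <- seq(0, 1000, length.out = 60)
  cv <- progress_curve(t_grid, closed_form_progress(2e-3, 5e-3, t_grid))
  fit <- fit_progress_curve(cv)
  expect_lt(rel_err(fit$v0$value, 2e-3), 1e-6)
  expect_lt(rel_err(fit$kobs$value, 5e-3), 1e-6)
})

test_that("round-trip recovery is exact for every estimator", {
  # each estimator applied to the zero-noise output of its paired generator
  ps <- gen_progress_set(c(1, 2, 3, 4, 5) * 1e-7, S = 1e-3, Km = 0.93e-3,
                         kunc = 6.2642e4)
  for (cv in ps) {
    f <- fit_progress_curve(cv)
    expect_lt(rel_err(f$kobs$value, attr(cv, "metadata")$kobs_true), 1e-6)
    expect_lt(rel_err(f$v0$value, attr(cv, "metadata")$v0_true), 1e-6)
  }
  kass <- run_kass_pipeline(ps)
  expect_lt(rel_err(kass$extra$kunc, 6.2642e4), 1e-6)

  tt <- gen_titration(21.13, seq(0, 18, by = 2))
  expect_lt(rel_err(estimate_si(tt)$value, 21.13), 1e-6)

  mm <- gen_mm_dataset(Km = 5e-5, Vmax = 1,
                       S_grid = c(0.01, 0.025, 0.05, 0.1, 0.25, 0.5, 1) * 1e-3)
  lb <- fit_km_lineweaver(mm)
  expect_lt(rel_err(lb$Km$value, 5e-5), 1e-6)
  expect_lt(rel_err(lb$Vmax$value, 1), 1e-6)
})

test_that("strictly linear progress data fail with a curvature error", {
  t <- seq(0, 500, by = 10)
  expect_error(fit_progress_curve(progress_curve(t, 1e-3 * t)),
               "no curvature")
  expect_error(fit_progress_curve(progress_curve(c(0, 1, 2), c(0, 1, 2))),
               "at least 5")
})

test_that("kunc is the OLS slope of kobs against inhibitor", {
  pts <- data.frame(inhibitor_M = c(1e-7, 2e-7, 3e-7),
                    kobs = c(1e-3, 2e-3, 3e-3))
  ku <- fit_kunc(pts)
  expect_equal(ku$value, 1e4)
  expect_equal(ku$extra$intercept, 0, tolerance = 1e-12)
  flat <- data.frame(inhibitor_M = c(1e-7, 2e-7, 3e-7), kobs = rep(2e-3, 3))
  expect_equal(fit_kunc(flat)$value, 0)
  expect_error(fit_kunc(pts[1:2, ]), "at least 3")
  expect_error(fit_kunc(data.frame(inhibitor_M = rep(1e-7, 3),
                                   kobs = 1:3 * 1e-3)), "identical")
})

test_that("substrate-competition correction matches the reference values", {
  expect_equal(correct_kass(5e4, S = 0, Km = 1e-3)$value, 5e4)
  expect_equal(correct_kass(6.2642e4, S = 1e-3, Km = 0.93e-3)$value,
               1.30e5, tolerance = 1e-4)
  expect_equal(correct_kass(4.8209e4, S = 1e-3, Km = 0.82e-3)$value,
               1.07e5, tolerance = 1e-4)
  expect_error(correct_kass(5e4, S = 1e-3, Km = 0), "Km")
  # kass strictly increasing in S; standard error scales with the factor
  k <- vapply(c(0, 0.5, 1, 2) * 1e-3,
              function(S) correct_kass(5e4, S, 1e-3)$value, numeric(1))
  expect_true(all(diff(k) > 0))
  ku <- kinetic_estimate("kunc", 5e4, se = 100)
  expect_equal(correct_kass(ku, 1e-3, 1e-3)$se, 200)
})

test_that("SI is the x-intercept of the titration line", {
  tt <- titration_series(c(0, 2, 4), c(1.0, 0.6, 0.2))
  est <- estimate_si(tt)
  expect_equal(est$value, 5.0)
  expect_equal(est$extra$slope, -0.2)
  expect_error(estimate_si(titration_series(0:5, rep(1, 6))),
               "no inhibition")
  expect_error(estimate_si(titration_series(0:5, rep(0, 6))), "floor")
  # floor points are excluded, not fitted
  tt2 <- gen_titration(5, 0:10)
  est2 <- estimate_si(tt2)
  expect_equal(est2$value, 5, tolerance = 1e-9)
  expect_equal(est2$extra$n_excluded, 6)  # ratios 5..10 at the floor
})

test_that("Lineweaver-Burk and direct MM fits invert exact data", {
  mm <- gen_mm_dataset(Km = 2, Vmax = 10, S_grid = c(0.5, 1, 2, 4, 8, 16))
  lb <- fit_km_lineweaver(mm)
  expect_equal(lb$Km$value, 2, tolerance = 1e-9)
  expect_equal(lb$Vmax$value, 10, tolerance = 1e-9)
  dr <- fit_km(mm, method = "direct")
  expect_equal(dr$Km$value, 2, tolerance = 1e-6)
  expect_error(fit_km_lineweaver(data.frame(substrate_M = c(1, 2, 3),
                                            rate = c(1, -1, 2))), "> 0")
  expect_error(fit_km_lineweaver(mm[1:2, ]), "at least 3")
})

test_that("double-reciprocal and direct fits agree on noisy data", {
  set.seed(31)
  ok <- 0
  for (s in 1:20) {
    mm <- gen_mm_dataset(Km = 2e-4, Vmax = 1,
                         S_grid = 2e-4 * c(0.2, 0.5, 1, 2, 5, 10, 20),
                         noise = noise_model(sd = 0.01, seed = 1000 + s))
    lb <- fit_km_lineweaver(mm); dr <- fit_km(mm, method = "direct")
    tol <- 2 * sqrt(lb$Km$se^2 + dr$Km$se^2)
    if (abs(lb$Km$value - dr$Km$value) <= tol) ok <- ok + 1
  }
  expect_gte(ok, 18)  # agreement within combined standard errors
})

test_that("the kass pipeline equals its composed stages", {
  ps <- gen_progress_set(c(1, 2, 3, 4, 5) * 1e-7, S = 1e-3, Km = 0.93e-3,
                         kunc = 6.2642e4,
                         noise = noise_model(sd = 1e-4, seed = 7))
  piped <- run_kass_pipeline(ps)
  pts <- data.frame(
    inhibitor_M = vapply(ps, attr, numeric(1), "inhibitor_M"),
    kobs = vapply(ps, function(cv) fit_progress_curve(cv)$kobs$value,
                  numeric(1)))
  manual <- correct_kass(fit_kunc(pts), S = 1e-3, Km = 0.93e-3)
  expect_equal(piped$value, manual$value)
  expect_equal(piped$se, manual$se)
  # single curve: explicit failure
  single <- progress_set(ps[1], substrate_M = 1e-3, Km_M = 0.93e-3)
  expect_error(run_kass_pipeline(single), "insufficient concentrations")
})

test_that("kass pipeline recovers the mechanistic truth from ODE curves", {
  rt <- make_rates(si = 3, k_on = 1e6, k_i = 5, kcat = 10, Km = 0.93e-3)
  obs <- effective_observables(rt, S = 1e-3)
  E0 <- 1e-10
  curves <- lapply(c(1, 2, 3, 4, 5) * 1e-7, function(I0) {
    tr <- simulate_timecourse(rt, assay_conditions(
      E0 = E0, I0 = I0, S0 = 1e-3, t_grid = seq(0, 400, by = 5)))
    progress_curve(tr$time_s, tr$P, inhibitor_M = I0, substrate_M = 1e-3)
  })
  kass <- run_kass_pipeline(progress_set(curves, substrate_M = 1e-3,
                                         Km_M = 0.93e-3))
  expect_lt(rel_err(kass$value, obs$kass_true), 0.02)
})

test_that("progress fit agrees with a brute-force grid-search oracle", {
  set.seed(17)
  t_grid <- seq(0, 800, by = 10)
  for (case in 1:20) {
    v0 <- runif(1, 5e-4, 5e-3)
    kobs <- 10^runif(1, -2.5, -1.5)
    sig <- closed_form_progress(v0, kobs, t_grid) +
      rnorm(length(t_grid), 0, 0.01 * v0 / kobs)
    cv <- progress_curve(t_grid, pmax(sig, 0))
    fit <- fit_progress_curve(cv)
    # oracle: exhaustive RSS minimization over a grid around the truth
    v0_grid <- seq(0.8 * v0, 1.2 * v0, length.out = 41)
    k_grid <- seq(0.8 * kobs, 1.2 * kobs, length.out = 41)
    rss <- outer(v0_grid, k_grid, Vectorize(function(a, b)
      sum((cv$signal - closed_form_progress(a, b, t_grid))^2)))
    best <- which(rss == min(rss), arr.ind = TRUE)[1, ]
    expect_lt(abs(fit$v0$value - v0_grid[best[1]]),
              2 * diff(v0_grid[1:2]))
    expect_lt(abs(fit$kobs$value - k_grid[best[2]]),
              2 * diff(k_grid[1:2]))
  }
})

test_that("estimators recover truth under 2% noise across seeds", {
  n_seeds <- 30  # quick screen; the full 100-seed suite runs in acceptance
  si_err <- kunc_err <- km_err <- numeric(n_seeds)
  for (s in seq_len(n_seeds)) {
    tt <- gen_titration(9.49, 0:8, noise = noise_model(0.02, seed = s))
    si_err[s] <- rel_err(estimate_si(tt)$value, 9.49)
    ps <- gen_progress_set(c(1, 2, 3, 4, 5) * 1e-7, S = 1e-3,
                           Km = 0.93e-3, kunc = 6.2642e4,
                           noise = noise_model(0.02 * 0.32, seed = s))
    kunc_err[s] <- rel_err(run_kass_pipeline(ps)$extra$kunc, 6.2642e4)
    # the direct MM fit is the noise-robust variant; the unweighted
    # double-reciprocal transform amplifies noise at low S
    mm <- gen_mm_dataset(5e-5, 1, c(0.01, 0.025, 0.05, 0.1, 0.25, 0.5, 1) *
                           1e-3, noise = noise_model(0.02, seed = s))
    km_err[s] <- rel_err(fit_km(mm, method = "direct")$Km$value, 5e-5)
  }
  expect_lt(median(si_err), 0.10)
  expect_lt(median(kunc_err), 0.10)
  expect_lt(median(km_err), 0.10)
})

test_that("stability summarizer finds the qualifying condition range", {
  prof <- gen_stability_profile(stability_shape_temperature())
  s <- summarize_stability(prof, threshold = 0.90)
  expect_equal(s$range, c(35, 75))
  ph <- gen_stability_profile(stability_shape_ph())
  sp <- summarize_stability(ph, threshold = 0.90)
  expect_equal(sp$range, c(3, 10))  # full measured range
  expect_equal(sp$n_in_range, nrow(ph))
  low <- summarize_stability(ph, threshold = 1.01)
  expect_true(all(is.na(low$range)))
  expect_error(summarize_stability(ph[0, ]), "empty")
})
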