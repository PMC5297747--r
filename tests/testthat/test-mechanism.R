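test_that("input validation rejects degenerate mechanisms", {
  expect_error(rate_constants(k_on = -1, k_i = 0.1), "non-negative")
  expect_error(rate_constants(k_on = 1e6, k_i = 0), "k_i must be > 0")
  expect_error(rate_constants(k_on = 1e6, k_i = 0.1, kcat = 10), "Km")
  expect_error(assay_conditions(1e-8, 1e-8, 0, t_grid = c(0, 1, 1)),
               "strictly increasing")
  expect_error(assay_conditions(-1, 0, 0, t_grid = c(0, 1)),
               "non-negative")
})

test_that("closed-form observables follow branched-pathway theory", {
  rt <- rate_constants(k_on = 2e6, k_off = 0.3, k_i = 0.2, k_s = 0.5)
  obs <- effective_observables(rt, S = 0)
  expect_equal(obs$SI_true, 1 + 0.5 / 0.2)
  expect_equal(obs$kass_true, 2e6 * 0.2 / (0.3 + 0.2 + 0.5))
  # no substrate pathway -> SI = 1
  expect_equal(effective_observables(
    rate_constants(k_on = 1e6, k_i = 0.1))$SI_true, 1)
  # partition ratio 5.82 -> SI 6.82 (hyperthermophilic chymotrypsin-like
  # protease at 100 degC)
  expect_equal(effective_observables(make_rates(si = 6.82))$SI_true, 6.82)
  # S = 0: kobs is uncorrected
  expect_equal(obs$kobs_at(1e-7), obs$kass_true * 1e-7)
  # competition scales kobs down by 1 + S/Km
  obs2 <- effective_observables(make_rates(), S = 1e-3, Km = 0.93e-3)
  expect_equal(obs2$kobs_at(1e-7) * (1 + 1 / 0.93),
               obs2$kass_true * 1e-7)
})

test_that("kobs is proportional to inhibitor concentration", {
  obs <- effective_observables(make_rates(si = 3), S = 1e-3, Km = 0.93e-3)
  I <- seq(1e-7, 5e-7, by = 1e-7)
  k <- obs$kobs_at(I)
  expect_equal(k / I, rep(k[1] / I[1], length(I)))
  expect_equal(k[1] / I[1], obs$kass_true / (1 + 1 / 0.93))
})

test_that("simulated trajectories satisfy all conservation laws", {
  set.seed(11)
  for (rep in 1:5) {
    rt <- rate_constants(k_on = 10^runif(1, 5, 7), k_off = runif(1, 0, 0.5),
                         k_i = runif(1, 0.01, 1), k_s = runif(1, 0, 2),
                         kcat = runif(1, 1, 100), Km = 10^runif(1, -4, -2))
    cond <- assay_conditions(E0 = 5e-8, I0 = runif(1, 1e-8, 1e-6),
                             S0 = 1e-3, t_grid = seq(0, 500, by = 10))
    err <- conservation_error(simulate_timecourse(rt, cond))
    expect_lt(err$enzyme, 1e-6)
    expect_lt(err$serpin, 1e-6)
    expect_lt(err$substrate, 1e-6)
  }
})

test_that("single-pathway limit gives complete 1:1 inhibition", {
  rt <- rate_constants(k_on = 1e6, k_off = 0, k_i = 0.5, k_s = 0)
  cond <- assay_conditions(E0 = 5e-8, I0 = 5e-8, S0 = 0,
                           t_grid = c(0, 10^seq(0, 6, by = 0.5)))
  tr <- simulate_timecourse(rt, cond)
  last <- tr[nrow(tr), ]
  # completion at exactly ratio 1 is algebraically slow (second-order
  # decay), so the residual shrinks like 1/t rather than exponentially
  expect_equal(last$E_inh, 5e-8, tolerance = 1e-4)
  expect_lt((last$E + last$EI) / 5e-8, 1e-4)
})

test_that("equal branch rates leave half the enzyme active at ratio 1", {
  # every consumed serpin inhibits with probability k_i/(k_i+k_s) = 1/2
  rt <- rate_constants(k_on = 1e6, k_off = 0, k_i = 0.2, k_s = 0.2)
  cond <- assay_conditions(E0 = 5e-8, I0 = 5e-8, S0 = 0,
                           t_grid = c(0, 10^seq(0, 6, by = 0.5)))
  tr <- simulate_timecourse(rt, cond)
  last <- tr[nrow(tr), ]
  expect_equal((last$E + last$EI) / 5e-8, 0.5, tolerance = 1e-4)
  # same number from the titration interface
  ts <- simulate_titration(rt, 5e-8, ratios = 1)
  expect_equal(ts$residual_activity, 0.5, tolerance = 1e-4)
})

test_that("no-inhibitor control turns substrate over at the MM rate", {
  rt <- rate_constants(k_on = 1e6, k_i = 0.1, kcat = 50, Km = 0.93e-3)
  cond <- assay_conditions(E0 = 5e-8, I0 = 0, S0 = 1e-3,
                           t_grid = seq(0, 100, by = 1))
  tr <- simulate_timecourse(rt, cond)
  expect_equal(tr$E, rep(5e-8, nrow(tr)))
  v0 <- 50 * 5e-8 * 1e-3 / (0.93e-3 + 1e-3)
  # early product formation is linear at kcat*E0*S0/(Km+S0)
  expect_equal(tr$P[2] / tr$time_s[2], v0, tolerance = 1e-3)
})

test_that("closed-form progress curve evaluates its defining equation", {
  expect_equal(closed_form_progress(2e-3, 5e-3, 200), 0.2528482,
               tolerance = 1e-6)
  # exponential plateau at v0/kobs
  expect_equal(closed_form_progress(3e-3, 2e-2, 1e6), 3e-3 / 2e-2)
  # linear limit at kobs = 0
  expect_equal(closed_form_progress(1, 0, 7), 7)
  expect_error(closed_form_progress(-1, 0.1, 10), "v0")
  expect_error(closed_form_progress(1, -0.1, 10), "kobs")
  # monotone non-decreasing in t
  p <- closed_form_progress(2e-3, 5e-3, seq(0, 2000, by = 10))
  expect_true(all(diff(p) >= 0))
})

test_that("saturating ODE titration matches max(0, 1 - r/SI)", {
  for (si in c(2, 9.49)) {
    rt <- make_rates(si = si, kcat = 0, Km = NA)
    ratios <- seq(0, 2 * si, length.out = 9)
    ts <- simulate_titration(rt, 5e-8, ratios)
    expect_true(all(abs(ts$residual_activity - pmax(0, 1 - ratios / si))
                    < 1e-3))
    # residual activity is non-increasing in the molar ratio
    expect_true(all(diff(ts$residual_activity) <= 1e-9))
  }
  expect_error(simulate_titration(make_rates(), 5e-8, numeric(0)),
               "non-empty")
})

test_that("finite incubation leaves more residual activity than saturating", {
  rt <- make_rates(si = 5, k_on = 1e5, kcat = 0, Km = NA)
  short <- simulate_titration(rt, 5e-8, ratios = 2, incubation = 5)
  sat <- simulate_titration(rt, 5e-8, ratios = 2)
  expect_gt(short$residual_activity, sat$residual_activity)
})

test_that("pseudo-first-order ODE progress matches the closed form", {
  # fast branch drain keeps EI occupancy low; tiny enzyme load keeps the
  # product far below the substrate pool (both pseudo-first-order premises)
  rt <- make_rates(si = 3, k_on = 1e6, k_i = 5, kcat = 10, Km = 0.93e-3)
  E0 <- 1e-10; I0 <- 2e-7; S0 <- 1e-3
  cond <- assay_conditions(E0 = E0, I0 = I0, S0 = S0,
                           t_grid = seq(0, 400, by = 5))
  tr <- simulate_timecourse(rt, cond)
  obs <- effective_observables(rt, S = S0)
  v0 <- rt$kcat * E0 * S0 / (rt$Km + S0)
  expected <- closed_form_progress(v0, obs$kobs_at(I0), cond$t_grid)
  dev <- abs(tr$P[-1] - expected[-1]) / expected[-1]
  expect_lt(max(dev), 0.01)
})
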