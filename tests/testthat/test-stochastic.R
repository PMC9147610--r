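test_that("escape-event generation is deterministic and leaves the RNG alone", {
  tp <- transport_params(v = 2, D = 0.2, L = 1)
  set.seed(123)
  before <- rnorm(1)
  set.seed(123)
  ev1 <- simulate_drift_diffusion_escapes(tp, n_events = 200, dt = 1e-3,
                                          seed = 42)
  after <- rnorm(1)
  ev2 <- simulate_drift_diffusion_escapes(tp, n_events = 200, dt = 1e-3,
                                          seed = 42)
  expect_identical(ev1$times, ev2$times)   # bit-identical under same seed
  expect_identical(before, after)          # caller's RNG stream untouched
  ev3 <- simulate_drift_diffusion_escapes(tp, n_events = 200, dt = 1e-3,
                                          seed = 43)
  expect_false(identical(ev1$times, ev3$times))
})

test_that("vanishing diffusion collapses escapes onto the transit time L/v", {
  tp <- transport_params(v = 2, D = 1e-12, L = 1)
  ev <- simulate_drift_diffusion_escapes(tp, n_events = 50, dt = 1e-3,
                                         seed = 7)
  expect_equal(ev$n_completed, 50)
  expect_lt(max(abs(ev$times - 0.5)), 1e-3)
})

test_that("censoring bookkeeping: completed plus censored equals requested", {
  tp <- transport_params(v = 0, D = 0.05, L = 1)  # slow diffusive passage
  ev <- simulate_drift_diffusion_escapes(tp, n_events = 60, dt = 1e-3,
                                         seed = 5, t_cap = 0.5)
  expect_equal(ev$n_completed + ev$censored, ev$n_requested)
  expect_gt(ev$censored, 0)  # cap far below the 10 time-unit mean
  expect_true(all(ev$times > 0 & ev$times <= 0.5 + 1e-3))
})

test_that("simulated drift-diffusion means match the deterministic solver", {
  tp <- transport_params(v = 2, D = 0.2, L = 1)
  x0 <- 4 / 128
  ev <- simulate_drift_diffusion_escapes(tp, n_events = 1500, dt = 2.5e-4,
                                         seed = 21, x0 = x0)
  fp <- first_passage(tp, spatial_grid(n_x = 128, dt = 5e-4, t_end = 2.5),
                      x0 = x0)
  se <- sd(ev$times) / sqrt(ev$n_completed)
  expect_lt(abs(mean(ev$times) - fp$t_mean), 3 * se)
})

test_that("halving dt leaves the simulated mean statistically unchanged", {
  tp <- transport_params(v = 2, D = 0.2, L = 1)
  ev1 <- simulate_drift_diffusion_escapes(tp, n_events = 1500, dt = 4e-4,
                                          seed = 31)
  ev2 <- simulate_drift_diffusion_escapes(tp, n_events = 1500, dt = 2e-4,
                                          seed = 32)
  se <- sqrt(sd(ev1$times)^2 / ev1$n_completed +
               sd(ev2$times)^2 / ev2$n_completed)
  expect_lt(abs(mean(ev1$times) - mean(ev2$times)), 3 * se)
})

test_that("barrier walker reproduces the boundary-matched MFPT quadrature", {
  # flat landscape: mean near the N^2/2-scale diffusive value
  spf <- polymer_spec(16, gamma1 = 1)
  evf <- simulate_barrier_escapes(spf, thermo_state(0), n_events = 600,
                                  dt = 0.02, seed = 3)
  qf <- mfpt_quadrature(spf, thermo_state(0), lower = 1, upper = 15,
                        x0 = 1)
  sef <- sd(evf$times) / sqrt(evf$n_completed)
  expect_lt(abs(mean(evf$times) - qf$tau), 3 * sef)

  # entropic Gaussian-chain landscape
  sp <- polymer_spec(16, gamma1 = 0.5)
  ev <- simulate_barrier_escapes(sp, thermo_state(0), n_events = 600,
                                 dt = 0.02, seed = 4)
  q <- mfpt_quadrature(sp, thermo_state(0), lower = 1, upper = 15, x0 = 1)
  se <- sd(ev$times) / sqrt(ev$n_completed)
  expect_lt(abs(mean(ev$times) - q$tau), 3 * se)
})

test_that("adverse bias slows the barrier walker relative to favorable bias", {
  sp <- polymer_spec(24, gamma1 = 0.5)
  adv <- simulate_barrier_escapes(sp, thermo_state(2 / 24), n_events = 300,
                                  dt = 0.02, seed = 8)
  fav <- simulate_barrier_escapes(sp, thermo_state(-2 / 24), n_events = 300,
                                  dt = 0.02, seed = 8)
  expect_gt(mean(adv$times), mean(fav$times))
})

test_that("histogram mode estimation recovers a known analytic mode", {
  ev <- generate_bimodal_fixture(mode1 = 1, mode2 = 3, weight = 1,
                                 n_events = 5000, seed = 17)
  hs <- histogram_mode(ev)
  expect_lt(abs(hs$t_p_hat - 1), 3 * hs$se_mode)
  expect_equal(sum(hs$counts), ev$n_completed)
  expect_true(hs$t_p_hat >= min(ev$times) && hs$t_p_hat <= max(ev$times))
})

test_that("histogram mode is scale-equivariant and bootstrap-reproducible", {
  ev <- generate_bimodal_fixture(mode1 = 1, mode2 = 3, weight = 1,
                                 n_events = 2000, seed = 9)
  hs1 <- histogram_mode(ev)
  ev2 <- ev
  ev2$times <- 2 * ev$times
  hs2 <- histogram_mode(ev2)
  expect_equal(hs2$t_p_hat, 2 * hs1$t_p_hat, tolerance = 1e-12)
  # same events, same bootstrap seed: identical error estimate
  expect_identical(histogram_mode(ev)$se_mode, hs1$se_mode)
  expect_error(histogram_mode(generate_bimodal_fixture(1, 3, 1, 10, 1)),
               "at least 50")
})

test_that("bimodal fixture carries its ground truth and resolves two peaks", {
  ev <- generate_bimodal_fixture(mode1 = 1, mode2 = 4, weight = 0.7,
                                 n_events = 5000, seed = 23)
  expect_equal(ev$n_completed, 5000)
  expect_equal(sum(ev$component == 1L), 3500)
  # the majority mode is recovered by the histogram analysis
  hs <- histogram_mode(ev)
  expect_lt(abs(hs$t_p_hat - 1), 3 * hs$se_mode + 0.1)
  # reproducibility of the whole fixture
  ev2 <- generate_bimodal_fixture(mode1 = 1, mode2 = 4, weight = 0.7,
                                  n_events = 5000, seed = 23)
  expect_identical(ev$times, ev2$times)
  # weight = 1 drops the second population entirely
  ev1 <- generate_bimodal_fixture(mode1 = 2, mode2 = 9, weight = 1,
                                  n_events = 500, seed = 2)
  expect_true(all(ev1$component == 1L))
})

test_that("fixture populations follow the requested inverse-Gaussian law", {
  ev <- generate_bimodal_fixture(mode1 = 2, mode2 = 5, weight = 1,
                                 n_events = 20000, seed = 31)
  tr <- ev$truth
  # sample mean and variance against the analytic IG moments
  expect_rel_equal(mean(ev$times), tr$mu1, 0.02)
  expect_rel_equal(var(ev$times), tr$mu1^3 / tr$lambda1, 0.1)
})
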