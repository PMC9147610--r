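test_that("pure diffusion with reflecting walls preserves equilibrium and mass", {
  tp <- transport_params(v = 0, D = 0.5, L = 1)
  gr <- spatial_grid(n_x = 32, dt = 1e-3, t_end = 0.5)
  f <- solve_fpe(tp, gr, initial = function(x) rep(1, length(x)),
                 boundaries = c("reflecting", "reflecting"))
  expect_lt(max(abs(f$P - 1)), 1e-12)  # uniform is the exact equilibrium

  # arbitrary initial data: total probability conserved to 1e-8 per run
  f2 <- suppressMessages(
    solve_fpe(transport_params(v = 1.5, D = 0.3, L = 1), gr,
              initial = function(x) exp(-20 * (x - 0.3)^2),
              boundaries = c("reflecting", "reflecting")))
  expect_lt(max(abs(f2$mass - 1)), 1e-10)
})

test_that("sine eigenmode decays at the analytic rate (absorbing ends)", {
  tp <- transport_params(v = 0, D = 1, L = 1)
  tstar <- 1 / pi^2
  gr <- spatial_grid(n_x = 128, dt = tstar / 400, t_end = tstar)
  f <- solve_fpe(tp, gr, initial = function(x) sin(pi * x),
                 boundaries = c("absorbing", "absorbing"),
                 save_times = tstar, normalize = FALSE)
  exact <- exp(-1) * sin(pi * f$x)
  expect_lt(max(abs(f$P[, ncol(f$P)] - exact)) / max(exact), 1e-4)
})

test_that("error contracts at second order in dx and dt (CN), first in dt (implicit)", {
  tp <- transport_params(v = 0, D = 1, L = 1)
  tstar <- 1 / pi^2
  err_at <- function(n_x, dt, scheme) {
    gr <- spatial_grid(n_x = n_x, dt = dt, t_end = tstar, scheme = scheme)
    f <- solve_fpe(tp, gr, initial = function(x) sin(pi * x),
                   boundaries = c("absorbing", "absorbing"),
                   save_times = tstar, normalize = FALSE)
    max(abs(f$P[, 1] - exp(-1) * sin(pi * f$x)))
  }
  # spatial order: halving dx divides the error by ~4
  e_dx <- c(err_at(16, tstar / 2000, "crank-nicolson"),
            err_at(32, tstar / 2000, "crank-nicolson"))
  expect_gt(e_dx[1] / e_dx[2], 3.2)
  expect_lt(e_dx[1] / e_dx[2], 4.8)
  # temporal order, CN: ratio ~4
  e_dt <- c(err_at(256, tstar / 25, "crank-nicolson"),
            err_at(256, tstar / 50, "crank-nicolson"))
  expect_gt(e_dt[1] / e_dt[2], 3.0)
  # fully-implicit: ratio ~2
  e_im <- c(err_at(256, tstar / 25, "fully-implicit"),
            err_at(256, tstar / 50, "fully-implicit"))
  expect_gt(e_im[1] / e_im[2], 1.6)
  expect_lt(e_im[1] / e_im[2], 2.4)
})

test_that("flux is v*P for uniform fields and zero without drift", {
  gr <- spatial_grid(n_x = 32, dt = 1e-3, t_end = 0.01)
  mk <- function(v) {
    solve_fpe(transport_params(v = v, D = 0.5, L = 1), gr,
              initial = function(x) rep(1, length(x)),
              boundaries = c("reflecting", "reflecting"))
  }
  f0 <- mk(0)
  expect_lt(max(abs(flux(f0))), 1e-10)
  f1 <- mk(0)  # uniform field, then impose drift in the flux formula
  J <- flux(f1, transport_params(v = 2, D = 0.5, L = 1))
  expect_equal(J, 2 * f1$P, tolerance = 1e-10)
})

test_that("continuity residual dP/dt + dJ/dx vanishes under refinement", {
  tp <- transport_params(v = 1, D = 0.4, L = 1)
  # residual of the reconstructed (non-FV) central-difference continuity
  # equation; boundary-adjacent cells are excluded because the one-sided
  # flux stencils there differ from the interior operator
  resid_at <- function(n_x, dt) {
    t1 <- 0.02
    gr <- spatial_grid(n_x = n_x, dt = dt, t_end = t1 + dt)
    f <- suppressMessages(
      solve_fpe(tp, gr, initial = function(x) exp(-60 * (x - 0.45)^2),
                boundaries = c("reflecting", "reflecting"),
                save_times = c(t1, t1 + dt)))
    J <- flux(f, tp)
    dPdt <- (f$P[, 2] - f$P[, 1]) / dt
    Jmid <- (J[, 1] + J[, 2]) / 2
    n <- nrow(J)
    dJdx <- c(NA, (Jmid[3:n] - Jmid[1:(n - 2)]) / (2 * f$dx), NA)
    max(abs(dPdt + dJdx)[5:(n - 4)])
  }
  r <- c(resid_at(64, 2e-4), resid_at(128, 1e-4))
  expect_gt(r[1] / r[2], 3.4)  # O(dx^2 + dt^2): halving both gives ~4
  expect_lt(r[1] / r[2], 4.8)
})

test_that("first passage: diffusive limit matches the classical MFPT", {
  tp <- transport_params(v = 0, D = 1, L = 1)
  gr <- spatial_grid(n_x = 128, dt = 2e-3, t_end = 4)
  fp <- first_passage(tp, gr, x0 = 0.02)
  expect_rel_equal(fp$t_mean, (1 - 0.02^2) / 2, 1e-3)
  # consistency with the rigid-rod closed form as x0 -> 0
  expect_rel_equal(fp$t_mean, tau_rigid_rod(1, 1), 2e-3)
  # distribution bookkeeping: integral of f plus remaining mass is 1
  dt <- diff(fp$times[1:2])
  expect_lt(abs(sum(fp$density) * dt + fp$S_end - 1), 1e-10)
  expect_true(all(diff(fp$survival) <= 1e-14))
  expect_equal(fp$survival[1], 1)
})

test_that("drift-dominated first passage matches the inverse-Gaussian law", {
  # injection mid-channel: the reflecting wall is then irrelevant
  # (v*x0/D = 10) and free-space drift-diffusion is the exact law
  tp <- transport_params(v = 2, D = 0.2, L = 2)
  gr <- spatial_grid(n_x = 400, dt = 5e-4, t_end = 3)
  fp <- first_passage(tp, gr, x0 = 1)
  ig <- inverse_gaussian_reference(tp, x0 = 1, times = fp$times)
  dt <- diff(fp$times[1:2])
  fn <- fp$density / (sum(fp$density) * dt)
  gn <- ig$density / (sum(ig$density) * dt)
  expect_lt(max(abs(fn - gn)) / max(gn), 1e-3)
  expect_rel_equal(fp$t_p, ig$mode, 5e-3)
  # deterministic transit limit: small D at fixed v pins t_p near d/v
  # (n_x keeps the cell Peclet v*dx/D at 1, inside the central-scheme
  # stability range)
  fp2 <- first_passage(transport_params(2, 0.01, 2),
                       spatial_grid(n_x = 400, dt = 2.5e-4, t_end = 1),
                       x0 = 1)
  expect_rel_equal(fp2$t_p, (2 - 1) / 2, 2e-2)
})

test_that("positivity holds and the oscillation fallback engages when needed", {
  tp <- transport_params(v = 2, D = 0.2, L = 2)
  gr <- spatial_grid(n_x = 200, dt = 1e-3, t_end = 1.5)
  fp <- first_passage(tp, gr, x0 = 1)
  expect_gt(min(fp$field$P, na.rm = TRUE), -1e-10)
  expect_true(all(fp$density >= -1e-12))
  # a deliberately hostile CN configuration (huge dt, sharp delta): the
  # detector must engage the fully-implicit fallback and deliver a
  # positivity-clean field
  grh <- spatial_grid(n_x = 64, dt = 0.05, t_end = 1,
                      scheme = "crank-nicolson")
  expect_warning(
    fh <- solve_fpe(transport_params(v = 0, D = 1, L = 1), grh,
                    boundaries = c("reflecting", "absorbing"), x0 = 0.5),
    "fully-implicit")
  expect_equal(fh$scheme, "fully-implicit")
  expect_gt(min(fh$P, na.rm = TRUE), -1e-8)
})

test_that("translocation probability curve is a proper CDF of passage", {
  tp <- transport_params(v = 2, D = 0.2, L = 1)
  gr <- spatial_grid(n_x = 128, dt = 1e-3, t_end = 3)
  fp <- first_passage(tp, gr)
  expect_equal(translocation_probability_curve(fp, 0), 0)
  expect_gt(translocation_probability_curve(fp, 3), 1 - 1e-6)
  tc <- seq(0, 3, length.out = 25)
  Pe <- translocation_probability_curve(fp, tc)
  expect_true(all(diff(Pe) >= -1e-12))
  expect_error(translocation_probability_curve(fp, 5), "within")
})

test_that("inverse-Gaussian reference has unit mass and the analytic mode/variance", {
  tp <- transport_params(v = 2, D = 0.2, L = 1)
  ig <- inverse_gaussian_reference(tp, x0 = 0, times = 1)
  total <- integrate(function(t) {
    inverse_gaussian_reference(tp, x0 = 0, times = t)$density
  }, 0, Inf, rel.tol = 1e-9)$value
  expect_rel_equal(total, 1, 1e-6)
  # mode: stationary point of the density, confirmed by dense grid search
  tgrid <- seq(1e-4, 2, length.out = 200001)
  dens <- inverse_gaussian_reference(tp, x0 = 0, times = tgrid)$density
  expect_lt(abs(tgrid[which.max(dens)] - ig$mode), 2e-5)
  # variance: 2 D (L - x0)/v^3, checked by moment quadrature
  m1 <- ig_moment_quadrature(ig$mu, ig$lambda, 1)
  m2 <- ig_moment_quadrature(ig$mu, ig$lambda, 2)
  expect_rel_equal(m2 - m1^2, 2 * 0.2 * 1 / 2^3, 1e-6)
  expect_rel_equal(ig$variance, m2 - m1^2, 1e-6)
  expect_error(inverse_gaussian_reference(transport_params(-1, 0.2, 1),
                                          times = 1),
               "drift regime")
})
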