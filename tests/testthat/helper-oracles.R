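# Independent oracles, kept deliberately naive so they share no code with
# the implementation under test.

# brute-force maximizer of the free-energy landscape: dense grid argmax
# followed by a local golden-section-free parabolic scan
brute_force_m_star <- function(N, gamma, beta_dmu, n = 200001L) {
  f <- function(m) (1 - gamma) * log(m * (N - m)) + m * beta_dmu
  m <- seq(N * 1e-6, N * (1 - 1e-6), length.out = n)
  y <- f(m)
  i <- which.max(y)
  # parabolic refinement through the argmax and neighbors
  if (i > 1 && i < n) {
    dl <- y[i - 1]; d0 <- y[i]; dr <- y[i + 1]
    m[i] + 0.5 * (dl - dr) / (dl - 2 * d0 + dr) * (m[2] - m[1])
  } else m[i]
}

# trapezoid-rule double integral for the MFPT on a landscape given as a
# function bF, reflecting at `a`, absorbing at `b`, start at `a`.
# The grid is clustered at the ends (y = a + (b-a) sin^2(theta), uniform
# theta) so the integrable m^-(1-gamma) endpoint singularities of
# exp(-bF) are resolved; the trapezoid rule is applied in theta with the
# Jacobian (b-a) sin(2 theta).
brute_force_mfpt <- function(bF, a, b, n = 4000L) {
  h <- (pi / 2) / n
  theta <- (seq_len(n) - 0.5) * h          # midpoint rule: no endpoints
  y <- a + (b - a) * sin(theta)^2
  jac <- (b - a) * sin(2 * theta)
  bFy <- vapply(y, bF, numeric(1))
  w <- exp(-bFy) * jac
  G <- (cumsum(w) - w / 2) * h             # integral of w from 0 to theta_j
  sum(exp(bFy) * G * jac) * h
}

# mean of an inverse-Gaussian(mu, lambda) computed by naive quadrature of
# t * f(t), independent of the package density
ig_moment_quadrature <- function(mu, lambda, power = 1) {
  f <- function(t) sqrt(lambda / (2 * pi * t^3)) *
    exp(-lambda * (t - mu)^2 / (2 * mu^2 * t)) * t^power
  integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object - expected) / abs(expected), tol)
}
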