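#' Mean first-passage time over an arbitrary 1-D potential
#'
#' Quadrature engine for the classical mean-first-passage-time integral of
#' overdamped diffusion in a potential, with a reflecting boundary at
#' `lower` and an absorbing boundary at `upper`:
#' \deqn{\tau(x_0) = \frac{1}{D}\int_{x_0}^{b} e^{\beta F(y)}
#'   \int_{a}^{y} e^{-\beta F(z)}\,dz\,dy.}
#' Both integrals use adaptive quadrature ([stats::integrate()]), which
#' copes with the integrable endpoint singularities that entropic
#' logarithmic potentials produce.
#'
#' @param beta_F vectorized function of position returning the
#'   dimensionless potential.
#' @param lower,upper reflecting and absorbing boundary positions.
#' @param x0 starting position (default `lower`).
#' @param D diffusion coefficient (rate scale; default 1).
#' @param rel_tol target relative accuracy of the outer integral.
#' @return The mean first-passage time (units `1/D` per unit length^2).
#' @export
mfpt_integral <- function(beta_F, lower, upper, x0 = lower, D = 1,
                          rel_tol = 1e-8) {
  stopifnot(is.function(beta_F), upper > lower, x0 >= lower, x0 < upper,
            D > 0)
  inner <- function(y) {
    stats::integrate(function(z) exp(-beta_F(z)), lower, y,
                     rel.tol = rel_tol / 10, subdivisions = 400L,
                     stop.on.error = TRUE)$value
  }
  outer_fun <- function(y) {
    exp(beta_F(y)) * vapply(y, inner, numeric(1))
  }
  out <- tryCatch(
    stats::integrate(outer_fun, x0, upper, rel.tol = rel_tol,
                     subdivisions = 400L, stop.on.error = TRUE),
    error = function(e) stop("MFPT quadrature failed to converge (",
                             conditionMessage(e),
                             "); domain [", lower, ", ", upper, "]",
                             call. = FALSE))
  out$value / D
}

escape_time_result <- function(tau, k0, method, spec = NULL, thermo = NULL,
                               extra = list()) {
  structure(c(list(tau = tau, k0 = k0, method = method,
                   params_echo = list(spec = spec, thermo = thermo)),
              extra),
            class = "escape_time_result")
}

#' @export
print.escape_time_result <- function(x, ...) {
  cat(sprintf("mean escape time tau = %.8g (k0 = %g, method = %s)\n",
              x$tau, x$k0, x$method))
  if (!is.null(x$tau_k0_over_N2))
    cat(sprintf("  tau*k0/N^2 = %.8g\n", x$tau_k0_over_N2))
  invisible(x)
}

#' Mean translocation time by quadrature over the entropic landscape
#'
#' Computes the mean escape (translocation) time
#' \deqn{\tau = \frac{1}{k_0}\int_0^N dy\, e^{\beta F(y)}
#'   \int_0^{y} dz\, e^{-\beta F(z)},}
#' i.e. the mean first passage of the translocation coordinate from the
#' cis side (reflecting at 0) to complete passage (absorbing at N) over
#' the landscape of [free_energy()]. For a Gaussian chain
#' (`gamma1 = gamma2 = 1/2`) at zero bias the integral evaluates exactly
#' to `pi^2 N^2 / (16 k0)`; for a flat landscape (`gamma = 1`, no bias) it
#' is `N^2 / (2 k0)`. Both serve as oracles in the test suite.
#'
#' Endpoint behavior: `exp(-beta F) ~ m^-(1-gamma2)` near 0 is integrable
#' only for `gamma2 > 0` (similarly `gamma1 > 0` at the far end), so
#' non-positive exponents are rejected.
#'
#' @param spec a [polymer_spec()].
#' @param thermo a [thermo_state()].
#' @param k0 attempt-rate proportionality constant (1/time; default 1, so
#'   times are reported in 1/k0 units).
#' @param rel_tol relative quadrature accuracy (default 1e-8).
#' @param lower,upper optional integration limits inside \[0, N\]
#'   (reflecting/absorbing); defaults cover the whole domain. Matched
#'   limits are used when cross-validating against the barrier walker.
#' @param x0 starting coordinate (default `lower`).
#' @return An `escape_time_result` with fields `tau`, `k0`, `tau_k0`,
#'   `tau_k0_over_N2`, `method`.
#' @examples
#' r <- mfpt_quadrature(polymer_spec(64, gamma1 = 0.5), thermo_state(0))
#' r$tau_k0_over_N2  # ~ pi^2/16
#' @export
mfpt_quadrature <- function(spec, thermo = thermo_state(), k0 = 1,
                            rel_tol = 1e-8, lower = 0, upper = spec$N,
                            x0 = lower) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(thermo, "thermo_state"),
            k0 > 0)
  flat <- (spec$gamma1 == 1 && spec$gamma2 == 1)
  if (!flat && (spec$gamma1 <= 0 || spec$gamma2 <= 0))
    stop("non-integrable endpoint: quadrature requires gamma1 > 0 and gamma2 > 0")
  if (lower < 0 || upper > spec$N || upper <= lower)
    stop("integration limits must satisfy 0 <= lower < upper <= N")
  N <- spec$N
  bdm <- beta_dmu(thermo)
  bF <- if (flat) {
    function(m) m * bdm
  } else {
    function(m) {
      # quadrature abscissae stay interior; log(0) -> -Inf maps to weight 0
      (1 - spec$gamma2) * suppressWarnings(log(m)) +
        (1 - spec$gamma1) * suppressWarnings(log(N - m)) + m * bdm
    }
  }
  tau_k0 <- mfpt_integral(bF, lower = lower, upper = upper, x0 = x0,
                          D = 1, rel_tol = rel_tol)
  escape_time_result(tau = tau_k0 / k0, k0 = k0, method = "quadrature",
                     spec = spec, thermo = thermo,
                     extra = list(tau_k0 = tau_k0,
                                  tau_k0_over_N2 = tau_k0 / N^2,
                                  limits = c(lower, upper), x0 = x0))
}

#' Closed-form translocation time in the drift-dominated regime
#'
#' When the entropic terms are negligible against the chemical-potential
#' tilt, the mean translocation time has the closed form
#' \deqn{\tau = \frac{N}{k_0}\frac{k_BT}{\Delta\mu}\left[1 -
#'   \frac{k_BT}{N\Delta\mu}\left(1 - e^{-N\Delta\mu/k_BT}\right)\right],}
#' with limits `N kBT / (k0 delta_mu)` for strong bias
#' (`N delta_mu / kBT >> 1`; linear in N) and `N^2 / (2 k0)` for weak bias
#' (diffusive square law). In this formula's sign convention positive
#' `delta_mu` is the driven direction. The weak-bias limit is evaluated by
#' series expansion for numerical stability (`|u| < 1e-5`, u = N
#' delta_mu/kBT), and exactly at `delta_mu = 0`.
#'
#' @inheritParams mfpt_quadrature
#' @return An `escape_time_result` (method `"drift-closed-form"`), with
#'   `u = N*delta_mu/kBT` echoed.
#' @examples
#' tau_drift_closed_form(polymer_spec(100, gamma1 = 1),
#'                       thermo_state(delta_mu = 0))$tau  # N^2/2
#' @export
tau_drift_closed_form <- function(spec, thermo = thermo_state(), k0 = 1) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(thermo, "thermo_state"),
            k0 > 0)
  N <- spec$N
  u <- N * beta_dmu(thermo)
  tau <- if (abs(u) < 1e-5) {
    # tau * k0 / N^2 = 1/2 - u/6 + u^2/24 - ...
    (N^2 / k0) * (0.5 - u / 6 + u^2 / 24)
  } else {
    (N^2 / (k0 * u)) * (1 - (-expm1(-u)) / u)
  }
  escape_time_result(tau = tau, k0 = k0, method = "drift-closed-form",
                     spec = spec, thermo = thermo,
                     extra = list(u = u, tau_k0 = tau * k0,
                                  tau_k0_over_N2 = tau * k0 / N^2))
}

#' Translocation time of a rigid rod (flat landscape)
#'
#' With no free-energy landscape at all the chain diffuses freely through
#' the pore and the mean passage time over a contour length `L` is
#' `L^2 / (2 D)`. Under Rouse scaling of the chain diffusivity,
#' `D(L) = D1 / L`, this becomes `L^3 / (2 D1)`.
#'
#' @param L contour length (positive).
#' @param D diffusion coefficient (positive), or the reference `D1` when
#'   `rouse = TRUE`.
#' @param rouse apply the Rouse scaling `D = D / L` before evaluating
#'   (default FALSE).
#' @return The mean passage time.
#' @examples
#' tau_rigid_rod(1, 0.5)  # 1
#' @export
tau_rigid_rod <- function(L, D, rouse = FALSE) {
  if (!is.numeric(L) || any(L <= 0)) stop("'L' must be positive")
  if (!is.numeric(D) || any(D <= 0)) stop("'D' must be positive")
  if (rouse) D <- D / L
  L^2 / (2 * D)
}

#' Fit the chain-length scaling of translocation times
#'
#' Least-squares slope of `log(tau)` against `log(N)` (the power-law
#' exponent), together with an exponential alternative `log(tau) ~ N`; the
#' better model by residual sum of squares is reported, which separates
#' the diffusive/driven power-law regimes (exponents 2 and 1) from the
#' exponential blow-up under adverse bias.
#'
#' @param N_values chain lengths (>= 4 positive values).
#' @param tau_values matching translocation times (positive).
#' @return An object of class `scaling_fit` with fields `exponent` (log-log
#'   slope), `exponent_se`, `exp_rate` (semi-log slope), `rss_power`,
#'   `rss_exp`, `preferred` (`"power-law"` or `"exponential"`).
#' @examples
#' scaling_exponent(c(64, 128, 256, 512), 3 * c(64, 128, 256, 512)^2)
#' @export
scaling_exponent <- function(N_values, tau_values) {
  if (length(N_values) < 4 || length(tau_values) != length(N_values))
    stop("need at least 4 matched (N, tau) pairs")
  if (any(N_values <= 0) || any(tau_values <= 0))
    stop("N and tau must be positive for log fits")
  lt <- log(tau_values)
  fit_pow <- stats::lm(lt ~ log(N_values))
  fit_exp <- stats::lm(lt ~ N_values)
  rss <- function(f) sum(stats::residuals(f)^2)
  structure(list(exponent = unname(stats::coef(fit_pow)[2]),
                 exponent_se = unname(suppressWarnings(
                   summary(fit_pow))$coefficients[2, 2]),
                 exp_rate = unname(stats::coef(fit_exp)[2]),
                 rss_power = rss(fit_pow), rss_exp = rss(fit_exp),
                 preferred = if (rss(fit_pow) <= rss(fit_exp)) "power-law"
                             else "exponential",
                 n = length(N_values)),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("scaling fit over %d sizes: tau ~ N^%.4f (se %.2g)\n",
              x$n, x$exponent, x$exponent_se))
  cat(sprintf("  exponential alternative rate %.4g; preferred model: %s\n",
              x$exp_rate, x$preferred))
  invisible(x)
}

#' @importFrom stats residuals
NULL
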