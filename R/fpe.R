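#' Transport parameters of the drift-diffusion description
#'
#' The escape probability P(x, t) of a chain of contour length `L = N a`
#' obeys the drift-diffusion equation
#' `dP/dt = -v dP/dx + D d2P/dx2` with mean drift speed `v` (e.g. from an
#' applied voltage) and effective diffusion coefficient `D`. The Peclet
#' number `v L / D` classifies the passage as drift-dominated (large) or
#' diffusive (small).
#'
#' @param v mean drift speed (length/time; any sign, positive = toward the
#'   trans exit at x = L).
#' @param D effective diffusion coefficient (length^2/time, positive).
#' @param L translocation distance (length, positive).
#' @return An object of class `transport_params` (with `peclet` computed).
#' @examples
#' transport_params(v = 2, D = 0.2, L = 1)
#' @export
transport_params <- function(v, D, L) {
  if (!is.numeric(D) || length(D) != 1L || D <= 0) stop("'D' must be positive")
  if (!is.numeric(L) || length(L) != 1L || L <= 0) stop("'L' must be positive")
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop("'v' must be a finite number")
  structure(list(v = v, D = D, L = L, peclet = v * L / D),
            class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat(sprintf("transport: v = %g, D = %g, L = %g (Peclet = %.4g)\n",
              x$v, x$D, x$L, x$peclet))
  invisible(x)
}

#' Space-time discretization controls for the PDE solver
#'
#' The solver uses a cell-centered finite-volume grid of `n_x` cells of
#' width `dx = L/n_x` (centers at `(i - 1/2) dx`), so boundary faces fall
#' exactly on x = 0 and x = L and the reflecting-reflecting configuration
#' conserves probability to machine precision. Time stepping is
#' Crank-Nicolson (second order) by default, with a fully-implicit
#' (first-order, oscillation-free) alternative.
#'
#' @param n_x number of cells (>= 16).
#' @param dt time step (positive).
#' @param t_end time horizon (>= dt).
#' @param scheme `"crank-nicolson"` or `"fully-implicit"`.
#' @return An object of class `spatial_grid`.
#' @export
spatial_grid <- function(n_x = 128, dt, t_end,
                         scheme = c("crank-nicolson", "fully-implicit")) {
  scheme <- match.arg(scheme)
  if (n_x < 16) stop("'n_x' must be at least 16")
  if (dt <= 0) stop("'dt' must be positive")
  if (t_end < dt) stop("'t_end' must be at least one time step")
  structure(list(n_x = as.integer(n_x), dt = dt, t_end = t_end,
                 scheme = scheme),
            class = "spatial_grid")
}

# Finite-volume drift-diffusion operator dP/dt = A P + b on n_x cells.
# boundaries: length-2 in {reflecting, absorbing, fixed-value};
# bc_values give the Dirichlet P at fixed-value faces.
fv_operator <- function(params, n_x, boundaries, bc_values = c(0, 0)) {
  v <- params$v; D <- params$D; L <- params$L
  dx <- L / n_x
  A <- matrix(0, n_x, n_x)
  b <- numeric(n_x)
  # internal faces between cells i and i+1:
  # J = v (P_i + P_{i+1})/2 - D (P_{i+1} - P_i)/dx
  for (i in seq_len(n_x - 1L)) {
    A[i, i]         <- A[i, i]         - v / (2 * dx) - D / dx^2
    A[i, i + 1L]    <- A[i, i + 1L]    - v / (2 * dx) + D / dx^2
    A[i + 1L, i]    <- A[i + 1L, i]    + v / (2 * dx) + D / dx^2
    A[i + 1L, i + 1L] <- A[i + 1L, i + 1L] + v / (2 * dx) - D / dx^2
  }
  # left face (x = 0): dP_1/dt += +J_left/dx
  switch(boundaries[1],
    reflecting = NULL,
    absorbing = { A[1, 1] <- A[1, 1] - 2 * D / dx^2 },
    `fixed-value` = {
      Pb <- bc_values[1]
      A[1, 1] <- A[1, 1] - 2 * D / dx^2
      b[1] <- b[1] + (v * Pb + 2 * D * Pb / dx) / dx
    },
    stop("unknown boundary type: ", boundaries[1]))
  # right face (x = L): dP_n/dt += -J_right/dx
  switch(boundaries[2],
    reflecting = NULL,
    absorbing = { A[n_x, n_x] <- A[n_x, n_x] - 2 * D / dx^2 },
    `fixed-value` = {
      Pb <- bc_values[2]
      A[n_x, n_x] <- A[n_x, n_x] - 2 * D / dx^2
      b[n_x] <- b[n_x] - (v * Pb - 2 * D * Pb / dx) / dx
    },
    stop("unknown boundary type: ", boundaries[2]))
  list(A = A, b = b, dx = dx)
}

# One-step propagator P <- K P + kb for the chosen implicit scheme.
# The tridiagonal system is LU-factorized once (dense solve; the "modified
# Gauss elimination" of a constant-coefficient tridiagonal) and reused.
fv_propagator <- function(op, dt, scheme) {
  n <- nrow(op$A)
  I <- diag(n)
  if (scheme == "crank-nicolson") {
    M1 <- I - (dt / 2) * op$A
    K <- solve(M1, I + (dt / 2) * op$A)
    kb <- solve(M1, dt * op$b)
  } else {
    K <- solve(I - dt * op$A)
    kb <- K %*% (dt * op$b)
  }
  list(K = K, kb = as.numeric(kb))
}

# Regularized injection: narrow Gaussian (sd = width) at x0, renormalized
# on the grid so sum(P) * dx = 1.
delta_initial <- function(x, dx, x0, width = 2 * dx) {
  P0 <- exp(-(x - x0)^2 / (2 * width^2))
  P0 / (sum(P0) * dx)
}

# TRUE when a profile shows Crank-Nicolson ringing: material negative
# excursions together with several sign flips.
oscillatory <- function(P, tol = 1e-8) {
  amp <- max(abs(P))
  if (amp == 0) return(FALSE)
  if (min(P) >= -tol * amp) return(FALSE)
  s <- sign(P[abs(P) > tol * amp])
  sum(diff(s) != 0) > 4
}

#' Solve the drift-diffusion equation for the escape probability
#'
#' Advances `dP/dt = -v dP/dx + D d2P/dx2` with an implicit
#' finite-volume scheme (second-order central fluxes; one tridiagonal
#' solve per step). Boundary faces may be `reflecting` (zero flux),
#' `absorbing` (P = 0 at the face), or `fixed-value` (Dirichlet constant).
#' The default Crank-Nicolson stepping carries an oscillation detector:
#' if a saved profile shows spurious ringing the solve is restarted with
#' the fully-implicit scheme and a warning is issued.
#'
#' @param params a [transport_params()].
#' @param grid a [spatial_grid()].
#' @param initial initial density: the string `"delta"` (narrow Gaussian of
#'   width `2 dx` at `x0`, the regularized "polymer head enters the pore"
#'   condition), a function of x, or a numeric vector of cell values.
#'   Non-negative; renormalized to unit mass (with a message if off by
#'   more than 1e-6).
#' @param boundaries length-2 character vector, conditions at x = 0 and
#'   x = L (default reflecting, absorbing).
#' @param bc_values Dirichlet constants for `fixed-value` faces.
#' @param x0 injection point for `initial = "delta"` (default `4 dx`).
#' @param save_times times at which to store the profile (default 9 evenly
#'   spaced points plus t_end); snapped to the step grid.
#' @param normalize rescale the initial density to unit mass (default
#'   TRUE; disable to evolve an arbitrary-amplitude mode).
#' @return An object of class `probability_field`: fields `x`, `times`,
#'   `P` (matrix, cells x saved times), `mass` (total probability at every
#'   step), `mass_times`, `scheme`, `peclet`, `dx`, `params`.
#' @examples
#' pr <- transport_params(v = 0, D = 1, L = 1)
#' gr <- spatial_grid(n_x = 32, dt = 1e-3, t_end = 0.05)
#' f <- solve_fpe(pr, gr, initial = function(x) rep(1, length(x)),
#'                boundaries = c("reflecting", "reflecting"))
#' @export
solve_fpe <- function(params, grid, initial = "delta",
                      boundaries = c("reflecting", "absorbing"),
                      bc_values = c(0, 0), x0 = NULL, save_times = NULL,
                      normalize = TRUE) {
  stopifnot(inherits(params, "transport_params"),
            inherits(grid, "spatial_grid"))
  boundaries <- match.arg(boundaries,
                          c("reflecting", "absorbing", "fixed-value"),
                          several.ok = TRUE)
  if (length(boundaries) != 2L) stop("'boundaries' must have two entries")
  n_x <- grid$n_x
  op <- fv_operator(params, n_x, boundaries, bc_values)
  dx <- op$dx
  x <- (seq_len(n_x) - 0.5) * dx
  if (is.null(x0)) x0 <- 4 * dx

  P <- if (identical(initial, "delta")) {
    delta_initial(x, dx, x0)
  } else if (is.function(initial)) {
    initial(x)
  } else if (is.numeric(initial) && length(initial) == n_x) {
    initial
  } else stop("'initial' must be \"delta\", a function, or a vector of length n_x")
  if (any(P < 0)) stop("initial density must be non-negative")
  if (normalize) {
    mass0 <- sum(P) * dx
    if (abs(mass0 - 1) > 1e-6)
      message(sprintf("renormalizing initial density (mass %.6g -> 1)",
                      mass0))
    P <- P / mass0
  }

  n_steps <- max(1L, as.integer(round(grid$t_end / grid$dt)))
  dt <- grid$dt
  if (is.null(save_times))
    save_times <- seq(0, n_steps * dt, length.out = 10L)[-1]
  save_idx <- unique(pmin(pmax(as.integer(round(save_times / dt)), 1L),
                          n_steps))
  prop <- fv_propagator(op, dt, grid$scheme)

  P_save <- matrix(NA_real_, n_x, length(save_idx))
  mass <- numeric(n_steps)
  ringing <- FALSE
  for (k in seq_len(n_steps)) {
    P <- as.numeric(prop$K %*% P) + prop$kb
    mass[k] <- sum(P) * dx
    j <- match(k, save_idx)
    if (!is.na(j)) {
      P_save[, j] <- P
      if (grid$scheme == "crank-nicolson" && oscillatory(P)) {
        ringing <- TRUE
        break
      }
    }
  }
  if (ringing) {
    warning("spurious oscillations detected: falling back to the fully-implicit scheme")
    grid$scheme <- "fully-implicit"
    return(solve_fpe(params, grid, initial, boundaries, bc_values, x0,
                     save_times, normalize))
  }
  structure(list(x = x, times = save_idx * dt, P = P_save,
                 mass = mass, mass_times = seq_len(n_steps) * dt,
                 scheme = grid$scheme, peclet = params$peclet, dx = dx,
                 dt = dt, boundaries = boundaries, params = params),
            class = "probability_field")
}

#' @export
print.probability_field <- function(x, ...) {
  cat(sprintf(
    "probability field: %d cells (dx = %.4g), %d saved times to t = %.4g\n",
    length(x$x), x$dx, length(x$times), max(x$times)))
  cat(sprintf("  scheme %s, boundaries %s/%s, Peclet %.4g, final mass %.6g\n",
              x$scheme, x$boundaries[1], x$boundaries[2], x$peclet,
              x$mass[length(x$mass)]))
  invisible(x)
}

#' Probability flux J(x, t) = v P - D dP/dx
#'
#' Evaluates the probability current of a saved field with second-order
#' central differences (one-sided second-order stencils at the ends).
#'
#' @param field a [solve_fpe()] result.
#' @param params the matching [transport_params()] (default: taken from
#'   the field).
#' @return A matrix of fluxes, same shape as `field$P`.
#' @export
flux <- function(field, params = field$params) {
  stopifnot(inherits(field, "probability_field"), ncol(field$P) >= 1,
            nrow(field$P) >= 3)
  dx <- field$dx
  dPdx <- apply(field$P, 2, function(P) {
    n <- length(P)
    g <- numeric(n)
    g[2:(n - 1)] <- (P[3:n] - P[1:(n - 2)]) / (2 * dx)
    g[1] <- (-3 * P[1] + 4 * P[2] - P[3]) / (2 * dx)
    g[n] <- (3 * P[n] - 4 * P[n - 1] + P[n - 2]) / (2 * dx)
    g
  })
  params$v * field$P - params$D * dPdx
}

# parabolic refinement of a discrete argmax; ties broken to the earliest
# index (reported via message)
peak_refine <- function(t, y) {
  i <- which(y == max(y))
  if (length(i) > 1L) {
    message("tied histogram/density maxima: taking the earliest")
    i <- i[1]
  }
  if (i == 1L || i == length(y)) return(t[i])
  dl <- y[i - 1L]; d0 <- y[i]; dr <- y[i + 1L]
  den <- dl - 2 * d0 + dr
  if (den == 0) return(t[i])
  t[i] + 0.5 * (dl - dr) / den * (t[2] - t[1])
}

#' First-passage-time distribution through the pore
#'
#' Solves the drift-diffusion equation with a reflecting face at x = 0
#' (the chain cannot un-thread) and an absorbing face at x = L (complete
#' passage), injecting a regularized near-delta at `x0`. The first-passage
#' density is obtained from the per-step mass balance,
#' `f(t_{k-1/2}) = (S_{k-1} - S_k)/dt`, which for this scheme equals the
#' time-averaged discrete flux through the absorbing face and makes
#' `integral(f) + S(t_end) = 1` exact. The most-probable time `t_p` is the
#' parabolic-refined argmax of the density; the mean adds the tail
#' correction `t_end * S(t_end)` (flagged when the remaining mass exceeds
#' 1e-3, warned above 0.05).
#'
#' @param params a [transport_params()].
#' @param grid a [spatial_grid()].
#' @param x0 injection point in \[0, L) (default `4 dx`).
#' @return An object of class `first_passage_distribution`: `times`
#'   (step midpoints), `density`, `survival_times` (step ends, starting at
#'   0), `survival`, `t_p`, `t_mean`, `S_end`, `tail_flag`, `scheme`,
#'   `peclet`.
#' @examples
#' fp <- first_passage(transport_params(v = 2, D = 0.2, L = 1),
#'                     spatial_grid(n_x = 64, dt = 2e-3, t_end = 2))
#' c(fp$t_p, fp$t_mean)
#' @export
first_passage <- function(params, grid, x0 = NULL) {
  field <- solve_fpe(params, grid, initial = "delta",
                     boundaries = c("reflecting", "absorbing"), x0 = x0,
                     save_times = seq(grid$t_end / 20, grid$t_end,
                                      length.out = 20L))
  S_ends <- c(1, field$mass)
  t_ends <- c(0, field$mass_times)
  dt <- field$dt
  f <- -diff(S_ends) / dt
  t_mid <- (t_ends[-1] + t_ends[-length(t_ends)]) / 2
  S_end <- S_ends[length(S_ends)]
  t_end <- t_ends[length(t_ends)]
  if (S_end > 0.05)
    warning(sprintf(
      "horizon too short: S(t_end) = %.3g; consider t_end around %.3g",
      S_end, 3 * t_end))
  t_p <- peak_refine(t_mid, f)
  t_mean <- sum(t_mid * f) * dt + t_end * S_end
  structure(list(times = t_mid, density = f,
                 survival_times = t_ends, survival = S_ends,
                 t_p = t_p, t_mean = t_mean, S_end = S_end,
                 tail_flag = S_end > 1e-3,
                 x0 = if (is.null(x0)) 4 * field$dx else x0,
                 scheme = field$scheme, peclet = field$peclet,
                 params = params, field = field),
            class = "first_passage_distribution")
}

#' @export
print.first_passage_distribution <- function(x, ...) {
  cat(sprintf("first-passage distribution (%s, Peclet %.4g)\n",
              x$scheme, x$peclet))
  cat(sprintf("  t_p = %.6g, t_mean = %.6g, S(t_end) = %.3g%s\n",
              x$t_p, x$t_mean, x$S_end,
              if (x$tail_flag) " [tail-corrected]" else ""))
  invisible(x)
}

#' Cumulative translocation probability at a cutoff time
#'
#' The fraction of passages completed within a drive window,
#' `P_e(t) = 1 - S(t)`, interpolated from the solved survival curve.
#'
#' @param dist a [first_passage()] result.
#' @param t_cutoff cutoff time(s), each within the solved horizon.
#' @return `P_e(t_cutoff)`, vectorized.
#' @export
translocation_probability_curve <- function(dist, t_cutoff) {
  stopifnot(inherits(dist, "first_passage_distribution"))
  if (any(t_cutoff < 0) || any(t_cutoff > max(dist$survival_times)))
    stop("'t_cutoff' must lie within [0, t_end]")
  S <- stats::approx(dist$survival_times, dist$survival, xout = t_cutoff)$y
  1 - S
}

#' Inverse-Gaussian reference first-passage density
#'
#' Closed-form first-passage density of free drift-diffusion (drift `v`,
#' diffusion `D`) to a single absorbing point at distance `d = L - x0`:
#' \deqn{f(t) = \frac{d}{\sqrt{4\pi D t^3}}
#'   \exp\left(-\frac{(d - v t)^2}{4 D t}\right),}
#' the inverse-Gaussian law with mean `mu = d/v` and shape
#' `lambda = d^2/(2 D)`. Valid as an oracle for the pore problem at high
#' Peclet number, where the reflecting entrance wall is irrelevant.
#'
#' @param params a [transport_params()] with `v > 0`.
#' @param x0 injection point (default 0).
#' @param times evaluation times (positive).
#' @return An object of class `invgauss_reference`: `times`, `density`,
#'   `mu`, `lambda`, `mode` (analytic), `mean`, `variance`.
#' @examples
#' inverse_gaussian_reference(transport_params(2, 0.2, 1),
#'                            times = c(0.2, 0.5))
#' @export
inverse_gaussian_reference <- function(params, x0 = 0, times) {
  stopifnot(inherits(params, "transport_params"))
  if (params$v <= 0)
    stop("the inverse-Gaussian reference applies to the drift regime (v > 0)")
  if (any(times <= 0)) stop("'times' must be positive")
  d <- params$L - x0
  if (d <= 0) stop("'x0' must be below L")
  mu <- d / params$v
  lambda <- d^2 / (2 * params$D)
  dens <- d / sqrt(4 * pi * params$D * times^3) *
    exp(-(d - params$v * times)^2 / (4 * params$D * times))
  structure(list(times = times, density = dens, mu = mu, lambda = lambda,
                 mode = invgauss_mode(mu, lambda), mean = mu,
                 variance = mu^3 / lambda),
            class = "invgauss_reference")
}

# analytic mode of the inverse-Gaussian(mu, lambda) density
invgauss_mode <- function(mu, lambda) {
  r <- 3 * mu / (2 * lambda)
  mu * (sqrt(1 + r^2) - r)
}

# density of inverse-Gaussian(mu, lambda), vectorized over t
dinvgauss_ <- function(t, mu, lambda) {
  ifelse(t > 0,
         sqrt(lambda / (2 * pi * t^3)) *
           exp(-lambda * (t - mu)^2 / (2 * mu^2 * t)),
         0)
}

# Michael-Schucany-Haas sampler for inverse-Gaussian(mu, lambda)
rinvgauss_ <- function(n, mu, lambda) {
  y <- stats::rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- stats::runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}
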