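#' Describe a translocating polymer chain
#'
#' A chain of `N` monomers of length `a` partitioned by the pore into a
#' trans-side sub-chain of `m` monomers and a cis-side sub-chain of `N - m`
#' monomers. Each tethered sub-chain of `n` monomers contributes a partition
#' function proportional to `n^(gamma - 1)`, so the scaling exponent gamma
#' fixes the entropic cost of threading: 1/2 for Gaussian ideal chains,
#' about 0.69 for self-avoiding chains, and 1 for rigid rods (no entropic
#' barrier at all).
#'
#' @param N integer monomer count (N >= 2).
#' @param a monomer length (default 1; sets the length unit).
#' @param gamma1 scaling exponent of the cis-side sub-chain, in \[0, 1\].
#' @param gamma2 scaling exponent of the trans-side sub-chain, in \[0, 1\];
#'   defaults to `gamma1` (same solvent on both sides).
#' @return An object of class `polymer_spec`.
#' @examples
#' polymer_spec(N = 128, gamma1 = 0.5)
#' @export
polymer_spec <- function(N, a = 1, gamma1 = 0.5, gamma2 = gamma1) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("'N' must be a single integer >= 2")
  if (!is.numeric(a) || length(a) != 1L || a <= 0)
    stop("'a' must be a single positive number")
  for (g in list(gamma1 = gamma1, gamma2 = gamma2)) {
    if (!is.numeric(g) || length(g) != 1L || g < 0 || g > 1)
      stop("scaling exponents must lie in [0, 1]")
  }
  structure(list(N = as.numeric(N), a = a,
                 gamma1 = gamma1, gamma2 = gamma2),
            class = "polymer_spec")
}

#' @export
print.polymer_spec <- function(x, ...) {
  cat(sprintf("polymer chain: N = %g monomers of length a = %g\n", x$N, x$a))
  cat(sprintf("  scaling exponents: gamma1 (cis) = %g, gamma2 (trans) = %g\n",
              x$gamma1, x$gamma2))
  invisible(x)
}

#' Thermodynamic context of the translocation
#'
#' Holds the thermal energy unit and the per-monomer chemical-potential
#' difference `delta_mu = mu1 - mu2` between the trans and cis chambers.
#' Negative `delta_mu` favors translocation (each transferred monomer lowers
#' the free energy); positive values oppose it. With the default `kBT = 1`
#' all energies are expressed in units of kBT.
#'
#' @param delta_mu per-monomer chemical-potential difference (energy units;
#'   any finite value, including 0).
#' @param kBT thermal energy (must be positive; default 1).
#' @return An object of class `thermo_state`.
#' @examples
#' thermo_state(delta_mu = -0.1)
#' @export
thermo_state <- function(delta_mu = 0, kBT = 1) {
  if (!is.numeric(kBT) || length(kBT) != 1L || kBT <= 0)
    stop("'kBT' must be a single positive number")
  if (!is.numeric(delta_mu) || length(delta_mu) != 1L || !is.finite(delta_mu))
    stop("'delta_mu' must be a single finite number")
  structure(list(delta_mu = delta_mu, kBT = kBT), class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("thermo state: delta_mu = %g, kBT = %g (beta*delta_mu = %g)\n",
              x$delta_mu, x$kBT, x$delta_mu / x$kBT))
  invisible(x)
}

#' Relative partition weight of a tethered sub-chain
#'
#' The configurational partition function of a sub-chain of `n` monomers
#' anchored at a hard wall scales as `n^(gamma - 1)`. For gamma < 1 the
#' weight decreases with `n` (confinement entropy is lost); for a rigid rod
#' (gamma = 1) it is constant.
#'
#' @param n sub-chain length in monomers (n >= 1; vectorized).
#' @param gamma scaling exponent.
#' @return `n^(gamma - 1)`.
#' @examples
#' partition_weight(4, gamma = 0.5)  # 0.5
#' @export
partition_weight <- function(n, gamma) {
  if (any(!is.finite(n)) || any(n < 1))
    stop("sub-chain length 'n' must be >= 1")
  n^(gamma - 1)
}

# beta * delta_mu, the dimensionless tilt per monomer
beta_dmu <- function(thermo) thermo$delta_mu / thermo$kBT

#' Dimensionless free energy of partial translocation
#'
#' Evaluates the free-energy landscape over the continuous translocation
#' coordinate m (monomers on the trans side),
#' \deqn{\beta F(m) = (1 - \gamma_2)\ln m + (1 - \gamma_1)\ln(N - m)
#'   + m\,\beta\Delta\mu,}
#' with the m-independent additive constants dropped. The two logarithmic
#' terms are the entropic penalty of the trans and cis sub-chains; the
#' linear term tilts the landscape by the chemical-potential bias. When
#' `gamma1 == gamma2` and `delta_mu == 0` the profile is symmetric about
#' `N/2`.
#'
#' @param m translocation coordinate, strictly inside (0, N); vectorized.
#' @param spec a [polymer_spec()].
#' @param thermo a [thermo_state()].
#' @return `beta * F(m)`, dimensionless; same length as `m`.
#' @examples
#' sp <- polymer_spec(100, gamma1 = 0.5)
#' free_energy(50, sp, thermo_state(0))  # 0.5 * log(2500)
#' @export
free_energy <- function(m, spec, thermo = thermo_state()) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(thermo, "thermo_state"))
  if (any(!is.finite(m)) || any(m <= 0) || any(m >= spec$N))
    stop("'m' must lie strictly inside (0, N): the sub-chain logarithms diverge at the ends")
  (1 - spec$gamma2) * log(m) + (1 - spec$gamma1) * log(spec$N - m) +
    m * beta_dmu(thermo)
}

# derivative d(beta F)/dm, used by the barrier walker and root finding
free_energy_grad <- function(m, spec, thermo = thermo_state()) {
  (1 - spec$gamma2) / m - (1 - spec$gamma1) / (spec$N - m) + beta_dmu(thermo)
}

#' Tabulated free-energy profile with located barrier maximum
#'
#' Tabulates `beta * F(m)` on a uniform grid spanning (0, N) exclusive,
#' locates the grid maximum and refines it with a golden-section/parabolic
#' search ([stats::optimize()]) to about `1e-10 * N` in m. If the maximum
#' sits at the edge of the tabulation window (e.g. gamma = 1 with a bias:
#' no interior barrier) the profile is flagged instead.
#'
#' @param spec a [polymer_spec()].
#' @param thermo a [thermo_state()].
#' @param n_points grid size (>= 3; default 2048).
#' @param margin relative distance of the first/last grid point from the
#'   domain ends (default 1e-4).
#' @return An object of class `free_energy_profile` with fields `m_grid`,
#'   `beta_F`, `m_star`, `F_star`, and logical `boundary` (TRUE when no
#'   interior maximum exists, in which case `m_star`/`F_star` are `NA`).
#' @examples
#' pr <- free_energy_profile(polymer_spec(100, gamma1 = 0.5), thermo_state(0))
#' pr$m_star  # 50
#' @export
free_energy_profile <- function(spec, thermo = thermo_state(),
                                n_points = 2048, margin = 1e-4) {
  stopifnot(inherits(spec, "polymer_spec"))
  if (n_points < 3) stop("'n_points' must be at least 3")
  N <- spec$N
  m_grid <- seq(N * margin, N * (1 - margin), length.out = n_points)
  bF <- free_energy(m_grid, spec, thermo)
  i <- which.max(bF)
  boundary <- (i == 1L || i == n_points)
  if (boundary) {
    m_star <- NA_real_
    F_star <- NA_real_
  } else {
    opt <- stats::optimize(function(m) free_energy(m, spec, thermo),
                           interval = c(m_grid[i - 1L], m_grid[i + 1L]),
                           maximum = TRUE, tol = 1e-10 * N)
    m_star <- opt$maximum
    F_star <- opt$objective
  }
  structure(list(m_grid = m_grid, beta_F = bF, m_star = m_star,
                 F_star = F_star, boundary = boundary,
                 spec = spec, thermo = thermo),
            class = "free_energy_profile")
}

#' @export
print.free_energy_profile <- function(x, ...) {
  cat(sprintf("free-energy profile over (0, %g), %d points\n",
              x$spec$N, length(x$m_grid)))
  if (x$boundary) {
    cat("  no interior maximum (monotone landscape)\n")
  } else {
    cat(sprintf("  barrier: m* = %.6g, beta*F* = %.6g\n", x$m_star, x$F_star))
  }
  invisible(x)
}

#' Critical translocation coordinate m* (barrier position)
#'
#' Location of the free-energy maximum along m. For equal exponents
#' `gamma1 == gamma2 == gamma` the stationarity condition
#' `d(beta F)/dm = 0` clears to the quadratic
#' `m^2 - (N - 2c) m - c N = 0` with `c = (1 - gamma) kBT / delta_mu`,
#' whose unique root in (0, N) is
#' \deqn{m^* = \tfrac12\left(N - 2c + \mathrm{sgn}(\Delta\mu)\sqrt{N^2 + 4c^2}\right).}
#' An alternative algebraic arrangement of this root circulating in the
#' literature, \eqn{(N + 2c + \sqrt{N^2 + 4c^2})/2}, is available via
#' `form = "as-printed"`; it differs by two signs, can leave (0, N), and is
#' provided for comparison only -- the canonical root above is the one
#' verified against the numeric maximizer (see `check`).
#'
#' Degenerate cases: `delta_mu == 0` returns exactly `N/2`; `gamma == 1`
#' has no interior maximum and returns a boundary flag; unequal exponents
#' fall back to the numeric maximizer of [free_energy_profile()].
#'
#' @param spec a [polymer_spec()].
#' @param thermo a [thermo_state()].
#' @param form `"rederived"` (default, canonical) or `"as-printed"`.
#' @param check verify the analytic root against the numeric grid maximum
#'   and report both (default TRUE).
#' @return An object of class `m_star_result` with fields `m_star`,
#'   `boundary`, `method`, and (when `check`) `m_star_numeric`, `rel_diff`.
#' @examples
#' m_star_analytic(polymer_spec(100, gamma1 = 0.5), thermo_state(0.05))
#' @export
m_star_analytic <- function(spec, thermo = thermo_state(),
                            form = c("rederived", "as-printed"),
                            check = TRUE) {
  stopifnot(inherits(spec, "polymer_spec"), inherits(thermo, "thermo_state"))
  form <- match.arg(form)
  N <- spec$N
  res <- list(boundary = FALSE, form = form, N = N)

  if (spec$gamma1 != spec$gamma2) {
    pr <- free_energy_profile(spec, thermo, n_points = 4096)
    res$m_star <- pr$m_star
    res$boundary <- pr$boundary
    res$method <- "numeric"
  } else if (spec$gamma1 == 1) {
    # no entropic term: the landscape is a pure tilt, maximum at a boundary
    res$m_star <- NA_real_
    res$boundary <- TRUE
    res$method <- "flag"
  } else if (thermo$delta_mu == 0) {
    res$m_star <- N / 2
    res$method <- "symmetric"
  } else {
    cc <- (1 - spec$gamma1) * thermo$kBT / thermo$delta_mu
    disc <- sqrt(N^2 + 4 * cc^2)
    res$m_star <- if (form == "rederived") {
      (N - 2 * cc + sign(cc) * disc) / 2
    } else {
      (N + 2 * cc + disc) / 2
    }
    res$method <- "quadratic"
  }

  if (check && !res$boundary) {
    pr <- free_energy_profile(spec, thermo, n_points = 4096)
    res$m_star_numeric <- pr$m_star
    res$rel_diff <- abs(res$m_star - pr$m_star) / N
  }
  structure(res, class = "m_star_result")
}

#' @export
print.m_star_result <- function(x, ...) {
  if (x$boundary) {
    cat("m*: no interior maximum (boundary)\n")
  } else {
    cat(sprintf("m* = %.8g (%s", x$m_star, x$method))
    if (!is.null(x$m_star_numeric))
      cat(sprintf("; numeric maximizer %.8g, |diff|/N = %.2e",
                  x$m_star_numeric, x$rel_diff))
    cat(")\n")
  }
  invisible(x)
}

#' Barrier height F* = beta F(m*)
#'
#' @param profile a [free_energy_profile()].
#' @return The dimensionless barrier height, or `NA` (with a warning) when
#'   the landscape has no interior maximum.
#' @export
barrier_height <- function(profile) {
  stopifnot(inherits(profile, "free_energy_profile"))
  if (profile$boundary) {
    warning("no interior free-energy maximum: barrier height undefined")
    return(NA_real_)
  }
  profile$F_star
}

#' Export a free-energy profile to CSV with a JSON sidecar
#'
#' Writes `m, beta_F` columns plus a JSON sidecar carrying the generating
#' parameters and the located barrier.
#'
#' @param profile a [free_energy_profile()].
#' @param path CSV file path; the sidecar is written to `<path>.json`.
#' @return Invisibly, the two file paths.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "free_energy_profile"))
  df <- data.frame(m = fmt_num(profile$m_grid),
                   beta_F = fmt_num(profile$beta_F))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(N = profile$spec$N, gamma1 = profile$spec$gamma1,
         gamma2 = profile$spec$gamma2,
         beta_delta_mu = beta_dmu(profile$thermo),
         m_star = profile$m_star, F_star = profile$F_star),
    sidecar, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(csv = path, json = sidecar))
}

# 17-significant-digit text form so serialized output is byte-stable
fmt_num <- function(x) sprintf("%.17g", x)
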