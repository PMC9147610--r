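---
title: "Modeling polymer translocation times through nanopores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling polymer translocation times through nanopores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poretime)
```

## The physical picture

A polymer of $N$ monomers (each of length $a$) threads through a nanopore
in a membrane. The natural reaction coordinate is $m$, the number of
monomers already on the *trans* side; the chain is fully translocated when
$m$ reaches $N$. Each tethered sub-chain of $n$ monomers contributes a
configurational partition function $Z_n \propto n^{\gamma-1}$, where the
scaling exponent $\gamma$ encodes chain statistics: $\gamma = 1/2$ for a
Gaussian ideal chain, $\gamma \approx 0.69$ for a self-avoiding chain, and
$\gamma = 1$ for a rigid rod. With exponents $\gamma_1$ (cis side) and
$\gamma_2$ (trans side) and a per-monomer chemical-potential difference
$\Delta\mu$ between the chambers, the dimensionless free energy over the
continuous coordinate $m \in (0, N)$ is

$$\beta F(m) = (1-\gamma_2)\ln m + (1-\gamma_1)\ln(N-m)
  + m\,\beta\Delta\mu,$$

with the $m$-independent constants dropped. For $\gamma < 1$ this is an
entropic barrier peaking at $m^\*$ (exactly $N/2$ when the landscape is
untilted and symmetric); the tilt $m\,\beta\Delta\mu$ is exactly linear,
so favorable bias ($\Delta\mu < 0$) lowers the exit side and shifts
$m^\*$ toward the cis side.

`m_star_analytic()` returns the stationary point in closed form for
$\gamma_1 = \gamma_2 = \gamma \ne 1$. Differentiating $\beta F$ and
clearing denominators gives
$m^2 - (N - 2c)\,m - cN = 0$, $c = (1-\gamma)k_BT/\Delta\mu$, whose
single root inside $(0, N)$ is
$m^\* = \tfrac12\big(N - 2c + \mathrm{sgn}(\Delta\mu)\sqrt{N^2+4c^2}\big)$.
An alternative sign arrangement of this root that circulates in the
literature is available via `form = "as-printed"`; it can exceed $N$ for
adverse bias, which is why the re-derived root is canonical here and the
only one tested against the brute-force maximizer. Every analytic result
is verified at run time against the numeric maximum of
`free_energy_profile()` (2048-point grid by default, golden-section
refinement to $10^{-10} N$).

## Mean translocation time

The mean escape time is the classical mean first-passage time of
overdamped motion over $\beta F$, reflecting at $m = 0$ and absorbing at
$m = N$:

$$\tau = \frac{1}{k_0}\int_0^N dy\, e^{\beta F(y)}
  \int_0^{y} dz\, e^{-\beta F(z)},$$

with $k_0$ an attempt-rate constant that fixes the time unit (all times
are reported in $1/k_0$ units unless a physical $k_0$ is supplied). Two
exact values anchor the implementation:

* Gaussian chain, no bias ($\gamma_1=\gamma_2=1/2$, $\Delta\mu=0$): the
  substitution $m = N\sin^2\theta$ evaluates the double integral exactly
  to $\tau k_0 = \pi^2 N^2/16$.
* Flat landscape ($\gamma=1$, $\Delta\mu=0$): $\tau k_0 = N^2/2$.

Both are reproduced by `mfpt_quadrature()` to better than $10^{-5}$
relative, and the $\log\tau$–$\log N$ slope at zero bias is 2 to machine
precision — the diffusive square law $\tau \sim N^2$. Under a fixed
adverse bias per monomer the barrier grows linearly with $N$ and $\tau$
crosses over to exponential growth, which `scaling_exponent()` detects by
comparing power-law and exponential fits by residual sum of squares.

Numerically, $e^{-\beta F} \sim m^{-(1-\gamma_2)}$ is an integrable
endpoint singularity for $\gamma_2 > 0$; adaptive Gauss–Kronrod
quadrature (`stats::integrate`) handles it directly, and exponents
$\le 0$ are rejected because the integral then diverges. The nested
quadrature targets $10^{-8}$ relative accuracy on the outer integral.

When the entropic terms are negligible against the tilt, the closed form

$$\tau = \frac{N}{k_0}\frac{k_BT}{\Delta\mu}\left[1 -
  \frac{k_BT}{N\Delta\mu}\left(1 - e^{-N\Delta\mu/k_BT}\right)\right]$$

(`tau_drift_closed_form()`) interpolates between the weak-bias diffusive
limit $N^2/(2k_0)$ — evaluated by series below $|N\Delta\mu/k_BT| =
10^{-5}$ to avoid cancellation — and the driven linear regime
$N k_B T/(k_0\Delta\mu)$, approached with an $O(k_BT/(N\Delta\mu))$
correction. Note its sign convention: this formula counts positive
$\Delta\mu$ as the *driven* direction, whereas in the landscape picture
positive $\Delta\mu$ tilts uphill. The two conventions are related by
$\Delta\mu \to -\Delta\mu$, and with entropic terms switched off the
quadrature equals the closed form under exactly that flip — the test
suite asserts the identity to $10^{-6}$. For a rigid rod the landscape
vanishes entirely and `tau_rigid_rod()` gives $L^2/(2D)$; under Rouse
scaling of the chain diffusivity, $D(L) = D_1/L$ (selected with
`rouse = TRUE`), this becomes the familiar $L^3$ law. The unscaled form
is the default because the two statements "$D \sim L$" and
"$\tau \sim L^3$" are mutually inconsistent and only $D \propto 1/L$
yields the cubic.

## The drift–diffusion description

On the spatial side the escape probability $P(x,t)$ of a chain of contour
length $L = Na$ obeys

$$\frac{\partial P}{\partial t} = -v\frac{\partial P}{\partial x}
 + D\frac{\partial^2 P}{\partial x^2},
 \qquad J = vP - D\frac{\partial P}{\partial x},$$

with drift speed $v$ (set, e.g., by the applied voltage) and effective
diffusion coefficient $D$. `solve_fpe()` discretizes the conservation law
on a cell-centered finite-volume grid of $n_x$ cells ($\Delta x = L/n_x$,
centers at $(i-\tfrac12)\Delta x$): second-order central fluxes at cell
faces, boundary faces exactly on $x = 0$ and $x = L$. This choice makes
the discrete fluxes telescope, so with reflecting walls total probability
is conserved to machine precision rather than merely to truncation order.
Faces may be reflecting (zero flux), absorbing ($P = 0$ at the face, via
an antisymmetric ghost cell), or held at a fixed value.

Time stepping is Crank–Nicolson by default (second order in $\Delta t$;
verified against the decaying sine eigenmode
$P = e^{-D\pi^2 t/L^2}\sin(\pi x/L)$ to $10^{-4}$), with one tridiagonal
solve per step; the constant-coefficient system is factorized once and
reapplied. Crank–Nicolson is only neutrally stable for sharp data, so a
detector counts material sign flips in saved profiles and, if ringing
appears, restarts the run with the fully-implicit scheme (first order,
unconditionally damping) and warns. Central fluxes additionally require a
cell Péclet number $v\Delta x/D \lesssim 2$; the first-passage tests keep
it at or below 1.

For first passage (`first_passage()`) the physical configuration is
reflecting at $x=0$ — the chain cannot un-thread once started — and
absorbing at $x=L$. The textbook delta injection "the polymer head enters
at $x = 0$" is hostile to any grid scheme next to a boundary, so it is
regularized as a narrow Gaussian of width $2\Delta x$ centered at
$x_0 = 4\Delta x$ (configurable), renormalized on the grid. The
first-passage density is taken from the per-step mass balance
$f_{k-1/2} = (S_{k-1}-S_k)/\Delta t$, which for this scheme equals the
time-averaged discrete flux through the absorbing face and guarantees
$\int f\,dt + S(t_{\mathrm{end}}) = 1$ exactly. The most-probable time
$t_p$ is the parabolic-refined argmax of $f$ (ties broken toward earlier
times, with a message); the mean adds the tail correction
$t_{\mathrm{end}}\,S(t_{\mathrm{end}})$ and is flagged when more than
$10^{-3}$ of the mass remains, warned above 5%.

Two closed forms validate the solver: the pure-diffusion mean
$(L^2-x_0^2)/(2D)$, and at high Péclet number the inverse-Gaussian
density with mean $\mu = (L-x_0)/v$ and shape $\lambda = (L-x_0)^2/(2D)$
(`inverse_gaussian_reference()`). The latter is exact only when the
reflecting wall is irrelevant, which requires $v x_0/D \gg 1$, not merely
$vL/D \gg 1$ — the oracle tests therefore inject mid-channel.

## Stochastic escape events

`simulate_drift_diffusion_escapes()` realizes the same process as
Euler–Maruyama walkers, $x \leftarrow x + v\Delta t +
\sqrt{2D\Delta t}\,\xi$, reflecting at 0 and absorbed at $L$ with linear
interpolation of the crossing inside the final step; runs are
bit-reproducible from one root seed and leave the caller's RNG state
untouched. Events exceeding a per-event cap are censored and accounted
separately. `simulate_barrier_escapes()` walks the $m$-coordinate on
$\beta F$ with the analytic gradient. Its reflecting boundary sits at
$m_{\min} = 1$ (one monomer threaded) rather than 0, both on physical
grounds and because the $1/m$ entropic force diverges at 0; this
truncation shifts the mean by $O(1/\sqrt N)$ relative to the full-domain
integral, so the cross-validation tests compare the walker against the
quadrature evaluated over the *same* reflecting/absorbing interval — the
matched comparison is the meaningful one.

Histogram analysis (`histogram_mode()`) follows nanopore dwell-time
practice: Freedman–Diaconis bins by default, mode refined by a parabolic
fit through the three peak bins, and a seeded 200-resample bootstrap
standard error for the mode (the error recipes attached to published
two-population histograms are typically not reproducible from their
captions; the bootstrap is the defensible substitute).
`generate_bimodal_fixture()` produces labeled two-population
inverse-Gaussian mixtures — mimicking the dwell-time histograms of two
DNA species of identical length but different sequence arrangement — with
a Michael–Schucany–Haas sampler written for the purpose (no installed
package provides the distribution); the fixture is synthetic by
construction and carries its ground-truth modes for estimator tests. It
emulates only the two-peak shape, not sequence-level physics, capture
kinetics, or experimental drift, so tests passing on it say nothing about
those aspects of real data.

## Cross-validation triangle and chosen problem sizes

`cross_validate()` ties the three routes together at matched parameters
($v = 2$, $D = 0.2$, $L = 1$, Péclet 10 in the shipped tests): simulator
mean vs. solver mean vs. quadrature over the equivalent linear potential
$\beta F = -vx/D$, all pairwise within 3 Monte-Carlo standard errors at
5000 events — the passage count typical of published dwell-time
histograms — plus a Kolmogorov–Smirnov comparison of the event sample
against the solver CDF at the 1% critical value. Simulator steps
($\Delta t = 2.5\times10^{-4}$) keep the Euler–Maruyama absorption bias
(an effective boundary shift of $\approx 0.58\sqrt{D\Delta t}$) below one
standard error; the walker tests use $N = 16$ chains so that a thousand
walkers finish in seconds. The dt-robustness check compares two
independent runs at $\Delta t$ and $\Delta t/2$ at three *combined*
standard errors — two unbiased independent means already differ by
$\sqrt 2$ SE, so a one-SE criterion would reject correct code by design.

## Limitations

The model is strictly one-dimensional in either $m$ or $x$: no
excluded-volume or hydrodynamic corrections, no sequence dependence, no
pore-depth third region, no time-dependent driving, and no coupling
between the free-energy coordinate and the spatial coordinate (they are
alternative descriptions, not a joint model). Experimental dwell-time
scales (hundreds of microseconds) can be reproduced only if the user
supplies physical $v$, $D$, $L$ or $k_0$; the package reports
dimensionless times by default. Nanoparticle-assisted acceleration is
available only as a user-chosen subunitary multiplier on reported times,
not as a mechanism.
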