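# poretime

Estimates how long a polymer — single-stranded DNA or RNA being the
canonical case — takes to translocate through a nanopore in a membrane,
and regenerates the dwell-time distributions that nanopore experiments
record.

## The model

The reaction coordinate is *m*, the number of monomers already on the
trans side of the pore. Tethered sub-chains contribute partition
functions `Z_n ∝ n^(γ−1)` (γ = 1/2 Gaussian chain, ≈ 0.69 self-avoiding,
1 rigid rod), giving the entropic free-energy barrier

    βF(m) = (1 − γ₂) ln m + (1 − γ₁) ln(N − m) + m βΔμ,

tilted by the per-monomer chemical-potential difference Δμ between the
chambers. Three mutually consistent layers sit on top of it:

1. **Mean first-passage time** (module `escape_time`):
   `τ = (1/k₀) ∫₀ᴺ dy e^{βF(y)} ∫₀ʸ dz e^{−βF(z)}`, reflecting at 0,
   absorbing at N. Exact anchors: `τk₀ = π²N²/16` for the unbiased
   Gaussian chain, `N²/2` for a flat landscape, so unbiased
   translocation obeys the square law τ ~ N²; driven passage is linear
   in N, adverse bias exponential.
2. **Drift–diffusion escape probability** (module `fpe`):
   `∂P/∂t = −v ∂P/∂x + D ∂²P/∂x²` over the contour length L = Na,
   solved by a conservative finite-volume Crank–Nicolson scheme (with a
   fully-implicit anti-ringing fallback), yielding the first-passage
   density f(t), survival S(t), most-probable time t_p, mean time, and
   the translocation-probability curve P_e(t) = 1 − S(t).
3. **Stochastic escape events** (module `stochastic`): seeded
   Euler–Maruyama walkers in x or on βF(m), plus dwell-time histogram
   analysis (Freedman–Diaconis bins, parabolic mode refinement,
   bootstrap mode error) and a labeled bimodal inverse-Gaussian fixture
   generator for estimator tests.

All three routes are cross-validated against each other and against
closed forms (inverse-Gaussian first-passage law, classical diffusive
MFPT). See `vignette("translocation-methods")` for the numerics and the
design choices.

## Worked example

```r
library(poretime)

sp <- polymer_spec(N = 128, gamma1 = 0.5)   # Gaussian chain, 128 monomers
th <- thermo_state(delta_mu = 0)            # no chemical-potential bias

free_energy_profile(sp, th)
#> free-energy profile over (0, 128), 2048 points
#>   barrier: m* = 64, beta*F* = 4.15888

mfpt_quadrature(sp, th)
#> mean escape time tau = 10106.475 (k0 = 1, method = quadrature)
#>   tau*k0/N^2 = 0.61685028
```

The barrier of the unbiased symmetric chain peaks at N/2 = 64 with
height (1/2)ln(64·64) ≈ 4.159 kBT, and the mean time ratio
τk₀/N² = 0.61685 is π²/16 to eight digits — the exact diffusive-limit
constant. An adverse bias pushes the barrier maximum toward the exit:

```r
m_star_analytic(polymer_spec(128, gamma1 = 0.5), thermo_state(0.05))
#> m* = 118.77654 (quadratic; numeric maximizer 118.77654, |diff|/N = 2.52e-09)
```

Chain-length scaling and the spatial description:

```r
Ns <- c(64, 128, 256, 512)
taus <- vapply(Ns, function(N)
  mfpt_quadrature(polymer_spec(N, gamma1 = 0.5), thermo_state(0))$tau, 1)
scaling_exponent(Ns, taus)
#> scaling fit over 4 sizes: tau ~ N^2.0000 (se 3.7e-16)
#>   exponential alternative rate 0.008664; preferred model: power-law

tp <- transport_params(v = 2, D = 0.2, L = 1)      # Peclet 10 passage
fp <- first_passage(tp, spatial_grid(n_x = 200, dt = 5e-4, t_end = 2.5))
fp
#> first-passage distribution (crank-nicolson, Peclet 10)
#>   t_p = 0.340582, t_mean = 0.448882, S(t_end) = 1.09e-06

cross_validate(tp, n_events = 5000, dt_sim = 2.5e-4,
               grid = spatial_grid(n_x = 200, dt = 5e-4, t_end = 2.5),
               seed = 1)
#> cross-validation at Peclet 10 (5000 events)
#>   mean escape time: simulator 0.448873 +/- 0.0027 | solver 0.448882 | quadrature 0.449066
#>   pairwise |diff|/SE: sim-fpe 0.00, sim-quad 0.07, fpe-quad 0.07
#>   KS statistic 0.01283 (1% critical 0.02302)
```

The most-probable escape time (0.341) sits below the mean (0.449), the
usual right-skew of first-passage distributions; simulator, PDE solver
and quadrature agree to a small fraction of the Monte-Carlo error.

Reproducible runs with written artifacts go through the interface layer
(or equivalently the CLI script):

```r
cfg <- run_config("sweep", N_values = c(64, 128, 256, 512),
                  gamma1 = 0.5, delta_mu = 0, out_dir = "out")
run_translocation(cfg)   # writes sweep.csv, sweep.json, manifest.json, run.log
```

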