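# polycollapse

Coarse-grained Langevin dynamics and coarsening analysis for collapsing
macromolecules in bad solvent.

## What this is for

When the solvent quality around a polymer is suddenly worsened, the
molecule does not shrink smoothly: dense clusters ("pearls") nucleate
along the strands, grow, and merge until a single compact globule
remains. This out-of-equilibrium process is a *coarsening* phenomenon —
a single length scale grows in time with power-law scaling. The package
is for people who want to simulate that collapse for different
architectures (flexible/semiflexible linear chains, star polymers,
diamond-lattice and disordered microgel networks) and measure the
coarsening quantitatively, or to apply the same analysis operators to
particle trajectories produced elsewhere.

## Model

Beads interact by a Weeks–Chandler–Andersen core shifted by `-eps*phi`
plus a cosine attractive tail up to `1.5 sigma`,

    V(r) = 4*eps*[(s/r)^12 - (s/r)^6 + 1/4] - eps*phi     r <= 2^(1/6) s
           phi*eps/2 * [cos(alpha*(r/s)^2 + beta) - 1]    2^(1/6) s < r <= 1.5 s
           0                                              r > 1.5 s

with `alpha = pi/(2.25 - 2^(1/3))`, `beta = 2*pi - 2.25*alpha` (value and
slope continuous at both joints). The solvent-quality parameter `phi`
plays the role of an effective inverse temperature: `phi = 0` is good
solvent, the collapse (theta) point sits near `phi ~ 0.6`, and quenches
use `phi = 1.2` or `1.5`. Connectivity is FENE (`K = 30`, `R0 = 1.5`),
semiflexible strands add `Ks*(1 - cos theta)` with `Ks = 5`, and the
dynamics is Langevin (Grønbech-Jensen–Farago) at `kT = 1`,
`gamma = 0.05`, `dt = 0.005` in reduced units.

The analysis replaces the noisy particle picture by a smoothed density
field on a cubic grid (`delta = 0.5`): per-cell density within a sphere
`r_c`, a face-neighbour smoothing stencil, and a fill threshold
`rho_min`. On the filled mask it measures chord-length distributions and
the relative domain size `C(t) = (L(t)-L(0))/(L(inf)-L(0))`,
6-connected cluster statistics (fractal relation `Rclus ~ Nclus^nu`,
normalized growth `n(t) ~ t^beta`, `r(t) ~ t^gamma`), and the spin
self-correlation `Ps(t) = <S(t)S(0)> - <S(t)><S(0)>`.

## Worked example

Quench a flexible 200-bead chain into bad solvent and fit its domain
growth (a desk-scale version of the full study; a few seconds of
compute):

```r
library(polycollapse)

ch  <- local({set.seed(1); build_linear_chain(200)})
eq  <- equilibrate_good_solvent(ch$topology, ch$frame,
                                langevin_params(seed = 1))
tr  <- run_quench(eq$frame, ch$topology, quench_protocol(phi_target = 1.2),
                  langevin_params(seed = 2), t_max = 500)
dl  <- domain_length_series(tr, field_params(r_c = 1.0, rho_min = 0.6),
                            n_rotations = 2, seed = 3)
dg  <- relative_domain_size(dl)
dg
#> Domain growth: L 0.869565 -> 3.39299, tau_half = 50.0984 (55 points)
fit_power_law(dg)
#> Power-law fit: exponent 0.679 +/- 0.036 (R2 = 0.933, 27 points, t in [2.51, 50])
```

Read: the mean chord length of the filled density field grew from
~0.9 sigma (swollen coil, isolated blobs) to ~3.4 sigma (collapsed
globule); half of that growth was completed by `t ~ 50 tau`; the
intermediate regime follows `C ~ t^0.68` for this small chain (larger
flexible systems trend toward the ~0.6 regime; semiflexible chains are
distinctly steeper).

Cluster statistics from the same trajectory:

```r
cs <- cluster_series(tr, field_params(1.0, 0.6))
ng <- normalized_growth(cs, N_star = 400)
round(c(beta = ng$beta, gamma = ng$gamma_growth, ratio = ng$ratio), 2)
#>  beta gamma ratio
#>  1.26  0.67  0.53
```

`beta` is the growth exponent of the normalized mean cluster population,
`gamma` the one of the cluster radius; their ratio reflects the
small-cluster fractal exponent (`Rclus ~ Nclus^0.5`).

A thin command-line interface wraps the same functions
(`inst/cli/polycollapse-cli.R`): `build`, `equilibrate`, `quench`,
`analyze-domains`, `analyze-clusters`, `analyze-correlations`,
`fixtures`, `report`.

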