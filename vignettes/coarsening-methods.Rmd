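---
title: "Collapse and coarsening of bead-spring macromolecules: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collapse and coarsening of bead-spring macromolecules: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polycollapse)
```

## The physical problem

When the solvent around a polymer turns bad — by a temperature jump, a
change of composition, or any other quench — the chain no longer swells
but collapses toward a compact globule. The collapse is not a smooth
shrinkage: small clusters of monomers ("pearls") nucleate along the
strands, grow by pulling monomers out of the bridges that connect them,
and merge until a single dense globule remains. This is a coarsening
process in the same sense as spinodal decomposition: a characteristic
domain size grows in time with power-law scaling and the structure is
statistically self-similar. `polycollapse` simulates this process for
several macromolecular architectures — flexible and semiflexible linear
chains, star polymers, and microgel networks (ordered and disordered) —
and quantifies the coarsening with a density-field pipeline designed to
be robust to the fast local fluctuations of particle configurations.

## Force field

All quantities are in reduced units (energy $\epsilon$, length $\sigma$,
mass $m$, time $\tau = \sigma\sqrt{m/\epsilon}$, all equal to 1). Beads
interact through a Weeks–Chandler–Andersen core whose plateau is shifted
by $-\epsilon\phi$, continued by a cosine attractive tail,

$$
V_{nb}(r) = \begin{cases}
4\epsilon\left[(\sigma/r)^{12} - (\sigma/r)^{6} + \tfrac14\right] -
\epsilon\phi, & r \le 2^{1/6}\sigma,\\[4pt]
\tfrac12\phi\epsilon\left[\cos(\alpha (r/\sigma)^2 + \beta) - 1\right],
& 2^{1/6}\sigma < r \le 1.5\sigma,\\[4pt]
0, & r > 1.5\sigma,
\end{cases}
$$

with $\alpha = \pi(2.25 - 2^{1/3})^{-1}$ and $\beta = 2\pi - 2.25\alpha$,
chosen so that the potential and its first derivative are continuous at
both matching points for every $\phi$. The solvent-quality parameter
$\phi \ge 0$ is the only thermodynamic control: $\phi = 0$ is an athermal
good solvent (pure WCA), and the attraction deepens linearly with $\phi$,
which therefore acts as an effective inverse temperature. The collapse
(theta) point of long flexible chains sits near $\phi \approx 0.6$.

Bonded neighbours additionally feel a FENE spring
($K_F = 30$, $R_0 = 1.5$). Following the Kremer–Grest convention, bonded
pairs are *not* excluded from the non-bonded sum; the sum of the two terms
has its minimum at $r \approx 0.96\sigma$, which enforces chain
uncrossability. Semiflexible strands add a worm-like bending term
$K_s(1 - \cos\theta)$ between successive bonds with $K_s = 5$. During
microgel synthesis a purely repulsive spherical wall (shifted-truncated
LJ on the distance to the cavity surface) confines the chains.

## Dynamics

The equations of motion are integrated with the
Grønbech-Jensen–Farago discretization of the Langevin equation at
$k_BT = 1$, friction $\gamma = 0.05\,\tau^{-1}$ and time step
$\delta t = 0.005\,\tau$. This scheme was chosen because it reduces to
symplectic velocity Verlet when $\gamma = 0$ — giving a clean
energy-conservation test of the force routines — and because it
reproduces configurational averages and free diffusion essentially
exactly at finite $\delta t$ (free-particle $D = k_BT/m\gamma = 20\,
\sigma^2/\tau$ at the defaults). The friction is low: the thermostat acts
as an implicit solvent without hydrodynamic interactions, strong enough
to thermalize but weak enough not to overdamp the collapse. Thermal
noise is drawn from a dedicated xoshiro256++ stream seeded from R's RNG,
so `set.seed()` makes every trajectory bit-reproducible while the
integrator stays fast (the thermostat needs $3N$ Gaussians per step).

Pair interactions use a Verlet list built from cell lists (skin
$0.4\sigma$, rebuild on a half-skin displacement criterion); the
attractive tail energy and force are tabulated on a fine $r^2$ grid
(4096 points, linear interpolation, error $\sim 10^{-8}$) because the
trig calls would otherwise dominate the pair loop. These are pure
performance choices; the potential-continuity and force-vs-gradient
tests run against the exact expressions.

A quench is instantaneous: the system is equilibrated at $\phi = 0$,
then $\phi$ is switched to its target (typically 1.2 or 1.5, well below
the theta point) in a single step, and $t = 0$ is the switch. Snapshots
are logged on a log-spaced schedule (about 20 per decade) because every
analysis is a power law in time.

### Equilibration and its importance

`equilibrate_good_solvent()` runs blocks of dynamics until the
radius-of-gyration series is stationary (first/second-half means within
twice their combined block standard errors), with a *minimum* run of one
Rouse time $\gamma N^2 b^2 / (3\pi^2 k_BT)$ before the test may fire.
The minimum matters: the stationarity test alone can fire spuriously on
a slowly swelling chain, and quenching from an under-swollen (denser)
coil measurably steepens the early domain growth — the initial state has
excess local density that converts into clusters too quickly.

Single-molecule $R_g$ fluctuations are large and slow (a semiflexible
N = 400 chain wanders between $R_g \approx 18$ and 31 on multi-thousand
$\tau$ time scales), so a long equilibration of one realization can
deliver a quench start drawn from the tail of the size distribution.
When only a handful of realizations is affordable, the quench studies
therefore draw starting conformations from the calibrated generator
conditioned on a typical global size
(`build_linear_chain(typical = TRUE)`, $|R_g/\bar R_g - 1| \le 0.15$)
and equilibrate for about one Rouse time — long enough to relax local
and mid-scale structure, short enough that the realization does not
wander to a size extreme before the quench.

## Architectures

* `build_linear_chain(n, semiflexible)` — a string of beads at the
  bonded minimum distance, initial coordinates from a self-avoiding
  random walk (excluded distance $0.85\sigma$, backtracking on dead
  ends).
* `build_star(n_arms, arm_length)` — flexible arms bonded to a central
  bead. Arm roots leave the center along Fibonacci-sphere directions and
  the walk is biased radially outward near the core (decaying as $1/r$);
  without the bias, dense stars (12 arms) cannot be grown reliably.
  The bias only shapes the initial guess — equilibration erases it.
* `build_diamond_microgel(n_nodes_target, strand_length)` — cross-links
  on a diamond lattice joined by straight strands, with the lattice
  constant set so strands are unstrained at the $0.96\sigma$ bond
  length. The carve keeps the `n_nodes_target` nodes closest to the
  lattice center together with all complete strands among them, then the
  largest connected component. Carving whole strands (rather than a
  literal bead-count sphere) avoids dangling strand fragments and
  reproduces the reference mass relation $N \approx
  n_{nodes}(1 + 2\,l_{strand})$ for interior-dominated networks; the
  reference configuration pairs 78 nodes with 138-bead strands for
  $\approx 21.6$k beads. The network has no loops, so every cross-link
  is elastically active.
* `synthesize_disordered_microgel(params)` — the in-cavity synthesis:
  chains with randomly placed reactive beads (never adjacent) are
  equilibrated inside a repulsive spherical cavity; every 10 MD steps,
  unreacted reactive pairs within $1.3\sigma$ bond irreversibly (random
  order among candidates, each group reacts once). When at most 6 groups
  remain, random pairs are pulled together by a temporary harmonic
  restraint and bonded on capture, re-equilibrating in between, until
  conversion is complete; then the cavity is removed. The restraint
  starts at the nominal $k = 0.5\,\epsilon/\sigma^2$ with its rest
  length ratcheting down monotonically, and stiffens by 1.5 x per
  segment (capped at the FENE scale) if the pair resists: a fixed
  $k = 0.5$ spring has an equilibrium spread $\sqrt{3k_BT/k} \approx
  2.4\sigma$, larger than the capture distance, and stalls. The
  reference parameters (36 chains x 600 beads, 12 reactive each,
  $R_{cav} = 55\sigma$) give cross-link fraction $f = 0.02$ and number
  density $\approx 0.03\,\sigma^{-3}$; about 65% of cross-links join
  groups of the same chain (elastically inactive loops).

## The density-field pipeline

Particle configurations are noisy: transient bridges, small holes and
protrusions corrupt naive domain measures. The pipeline therefore works
on a smoothed density field:

1. space is divided into cubic cells of side $\delta = 0.5\sigma$, the
   grid anchored to the molecule's center of mass (cell boundaries at
   COM $+ k\delta$) so that diffusion does not slide the structure
   across the grid;
2. the raw cell density is $\rho = 3n/(4\pi r_c^3)$ with $n$ the number
   of monomers within $r_c$ of the cell center ($d \le r_c$, ties
   included);
3. the smoothed density is $\bar\rho = (2\rho + \sum_{6\,faces}
   \rho_k)/8$, cells outside the grid contributing zero;
4. a cell is *filled* iff $\bar\rho > \rho_{min}$ (strict).

Two canonical parameter pairs are used throughout: $(r_c = 1.0,
\rho_{min} = 0.6)$ and $(r_c = 1.2, \rho_{min} = 0.3$–$0.35)$. Any
conclusion (growth exponents, correlation decays) must agree between the
two pairs after the $\tau_{0.5}$ rescaling — that consistency is the
pipeline's own control experiment. For stiff chains the first pair
yields few filled cells at early times and a known early-time artifact;
the second pair avoids it.

**Chords and domain growth.** A chord is a maximal straight run of
filled cells along a grid axis; its end cells are interfacial because
the grid is padded with an empty margin. The chord-length distribution
$P(L;t)$ is pooled over uniform random rotations of the configuration
(each rotation gridded independently) and over realizations. The mean
chord $L(t)$ gives the relative domain size
$C(t) = (L(t) - L(0)) / (L(\infty) - L(0))$, with $L(0)$ from the first
post-quench frame and $L(\infty)$ averaged over the trailing half-decade
of log-time (the collapsed plateau). $\tau_{0.5}$, defined by
$C(\tau_{0.5}) = 0.5$, is found by interpolating $C$ against $\log t$;
rescaling time by $\tau_{0.5}$ collapses curves from different quench
depths and field parameters onto one master curve (an effective
time-temperature superposition). The growth exponent is the log-log
slope in the window $0.05 \le C \le 0.5$: flexible systems (chains,
stars) give $\approx 0.56$, microgels slightly above 0.6, semiflexible
chains $\approx 0.8$.

**Clusters.** Filled cells are partitioned into 6-connected components.
Per frame we record the unweighted mean population $N_{clus}$ and the
RMS radius of gyration $R_{clus} = \langle R_g^2\rangle^{1/2}$ over
clusters (a mass-weighted option exists). Pooling times gives the
fractal relation $R_{clus} \sim N_{clus}^\nu$ with $\nu \approx 0.5$
below a crossover population $N^* \approx 400$ cells (Gaussian-like
clusters) and $\nu \approx 0.25$ above (compact merging globules); the
breakpoint can be fitted freely (continuous two-segment log-log fit,
1-D breakpoint search) or imposed. The normalized growth curves
$n(t), r(t)$ (same normalization as $C$) follow $t^\beta$ and
$t^\gamma$ before the crossover, with $\beta \approx 1.2$ (flexible) or
$\approx 1.6$ (semiflexible) and $\gamma/\beta \approx 0.5$, consistent
with the small-cluster $\nu$. The fit window takes times with mean
population below $N^*$ and clearly above its initial level
($N_{clus} \ge 1.5\,N_{clus}(0) + 2$, a noise floor).

**Spin correlations.** Each cell carries $S \in \{0, 1\}$ (empty or
filled) and $P_s(t) = \langle S(t)S(0)\rangle - \langle S(t)\rangle
\langle S(0)\rangle$. Cell identity over time is defined in the
COM-anchored frame with fixed axis orientation — the only frame in which
a frozen internal structure keeps $P_s$ at its plateau — and the average
runs over a fixed bounding region containing the filled sets of all
frames, so the cell set is constant while $\langle S\rangle$ may drift.
$P_s(0) = \langle S\rangle(1 - \langle S\rangle)$ exactly. During
coarsening $P_s$ decays as a power law ($t^{-y}$, $y \gtrsim 0.5$ for
microgels) and pairs with the domain length as $P_s \sim L^{-1.1}$ for
flexible systems. The decay fits use the window where $P_s$ has dropped
below $0.8 P_s(0)$ but stays above $0.02 P_s(0)$.

## Fixtures

`make_fixture()` builds configurations with known answers — solid balls,
rods, well-separated sphere sets, pearl necklaces, random gases and
explicit masks — so every analysis operator is testable without
dynamics: cluster counts are known by construction, the chord multiset
of separated bodies is the union of the parts, lattice balls must give
$\nu \to 1/3$. `make_growth_series()` produces power laws with
multiplicative log-normal noise to validate the fitters (zero noise must
be recovered exactly).

## Numerical choices and degenerate inputs

* Broken FENE bonds ($r \ge R_0\sigma$) and non-finite coordinates abort
  integration with the offending step index — these are the first
  symptoms of an unstable configuration, never silently absorbed.
* `relative_domain_size()` and `normalized_growth()` refuse degenerate
  normalizations ($L(\infty) = L(0)$, $N_{clus}(\infty) = N_{clus}(0)$).
* Zero filled cells is a warning from classification and an error where
  clusters are required.
* Power-law fits error below 3 points and warn when the window spans
  less than a decade.
* The theta-point scan requires at least 5 strictly increasing $\phi$
  values and errors when $R_g(\phi)$ is flat.

## Problem sizes in the shipped analyses

The package's own reproduction runs (`scripts/acceptance.R` and the
heavier integration tests) use flexible chains at the reference size
N = 1600 and semiflexible chains at N = 400, three realizations per
architecture, five random orientations per frame for chord statistics
(quenches to $t = 1000$ and 3000 respectively, snapshots at 20 per
decade, chord analysis on every second snapshot), and scaled-down
microgels (12 chains of 100 beads at the reference number density;
diamond networks of ~24 nodes with 12-bead strands). The theta-point
scan uses an N = 400 flexible chain on a $\phi$ grid of step 0.1.
Full-size microgels (21.6k beads) are supported by the same code but
are long runs; the scaled versions retain the qualitative signatures
(power-law growth at or above the flexible-chain exponent, the late
diamond overshoot, the dominance of intra-chain loops).

Two quantitative caveats observed with these sizes, stated here so the
numbers are read correctly: the flexible-chain growth exponent drifts
downward with system size and equilibration quality (from ~0.75 for
N = 800 toward ~0.63 at N = 1600) and its fitted value sits at the
upper edge of the reference range; and the semiflexible exponent
measures ~0.9 rather than 0.8 for every protocol we tried — the
power-law window for N = 400 spans barely one decade, and the fit
absorbs part of the late acceleration into the collapsed state.

## What the synthetic tests do and do not show

The fixtures validate the analysis operators exactly, and the quench
runs validate the full pipeline statistically. None of this shows that
the bead-spring model describes any particular real polymer: mapping
$\phi$ to temperature, $\sigma$ to nanometers and $\tau$ to seconds is
system-specific, hydrodynamic interactions are absent (the Langevin
thermostat damps each bead independently), and finite concentration,
charge, and solvent structure are outside the model. Within the model,
the known finite-size caveats are: small systems shorten the scaling
window (the collapsed plateau arrives earlier, biasing late-window fits
upward); under-equilibrated initial states steepen the apparent growth;
and the theta point estimated from the $R_g$-derivative maximum on a
short chain sits above the long-chain value.

## Known limitations

* No hydrodynamics (no Lattice-Boltzmann/MPCD/DPD coupling) and no
  explicit solvent; pressure and NPT ensembles are out of scope.
* Open boundaries only; the confining cavity exists solely for
  synthesis.
* Finite-rate quenches are not implemented; the protocol is an
  instantaneous switch of $\phi$.
* The chord analysis assumes the maximal-run definition (interior
  non-maximal runs are not counted as chords).
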