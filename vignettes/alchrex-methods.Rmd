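---
title: "Alchemical replica exchange at toy scale: models, diagnostics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alchemical replica exchange at toy scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alchrex)
```

## The problem

Relative free energy calculations estimate how a perturbation — in the
motivating application, a protein point mutation — shifts a free energy
difference such as a binding affinity. The calculation morphs one chemical
species into another along a nonphysical ("alchemical") path parameterised
by a coupling variable $\lambda \in [0,1]$, samples configurations at a
ladder of intermediate states, and combines all samples with a multistate
estimator. The estimate is only as good as the sampling: slowly relaxing
conformational degrees of freedom coupled to the transformation produce
drifting, biased free energies that look deceptively precise.

`alchrex` implements this machinery end to end at desk scale, on toy
particle systems with analytic or brute-force oracles, so that every stage —
hybrid topology construction, softcore alchemical potentials, Hamiltonian
replica exchange (AREX), solute tempering (AREST), MBAR estimation, and the
sampling-problem diagnostic workflow — is testable against a known answer.

## The alchemical potential

A mutation is described as a pair of endpoint systems plus an atom map.
Mapped atoms share coordinates in the hybrid topology; unmapped atoms exist
on one side only. Atoms are classified as *unique old*, *unique new*,
*core* (mapped, interactions change) or *environment* (mapped, unmodified).

Nonbonded interactions interpolate per atom:

* charges: $q_i(\lambda)$ is $(1-\lambda)q_i^{old}$ for unique-old,
  $\lambda q_i^{new}$ for unique-new, the linear interpolation for core, and
  constant for environment atoms;
* Lennard-Jones $\sigma$ and $\epsilon$ interpolate the same way
  (Lorentz–Berthelot combination), with environment parameters held fixed;
* every pair involving a unique atom is *lifted*: the interaction is
  evaluated at $r_{\mathrm{eff}} = \sqrt{r^2 + w(\lambda)^2}$, with
  $w(\lambda) = w_{\mathrm{lifting}}(\chi^{old}_{ij}\lambda +
  \chi^{new}_{ij}(1-\lambda))$, so a decoupling pair can never produce a
  singular energy while each side is exactly unlifted at its own endstate.
  The default $w_{\mathrm{lifting}} = 0.4$ nm is of the order of a
  Lennard-Jones diameter: large enough to regularise complete overlaps,
  small enough to preserve overlap between neighbouring states.
* electrostatics use a screened direct-space Coulomb form
  $C q_i q_j \,\mathrm{erfc}(\alpha r_{\mathrm{eff}})/r_{\mathrm{eff}}$; toy
  systems are non-periodic, so the default screening is $\alpha = 0$ (plain
  Coulomb) and no reciprocal-space terms exist.

Valence terms follow the dummy-atom convention: terms involving unique
atoms are always present with their own endstate parameters (dummy atoms
keep their geometry but not their nonbonded interactions), matched terms
whose parameters differ interpolate linearly in $\lambda$, and shared
identical terms are counted once. This is the only convention under which
the defining endstate property holds exactly — $U(x;0)$ equals the
unmodified old-system potential plus the dummy valence terms of the new
side, and symmetrically at $\lambda = 1$ — a property the test suite checks
to $10^{-9}$ kcal/mol on randomized fixtures.

Charge-changing mutations keep the total charge constant in $\lambda$ by a
counter-particle whose charge interpolates from zero to the neutralising
value, an abstraction of transforming a solvent molecule into a counterion.

Units are nm, kcal/mol, K, elementary charge, amu and ps throughout, with
$k_B = 0.0019872041$ kcal/mol/K and $C = 33.20637$ kcal·nm/(mol·e²).

## Sampling: AREX and AREST

`run_arex()` alternates BAOAB Langevin propagation of each replica at its
current state with a Metropolis sweep of state-label swaps (default $K^3$
random pair attempts per iteration, approximating an independent
permutation draw). The swap of states $i, j$ between replicas $a, b$ is
accepted with probability $\min(1, e^{-\Delta})$ where
$\Delta = [u_i(x_b) + u_j(x_a)] - [u_i(x_a) + u_j(x_b)]$ in reduced units.
The joint stationary distribution over configurations and the state
permutation factorises over states; the test suite verifies this against
exact enumeration on a discrete two-replica model (total variation < 0.02).

`run_arest()` additionally scales each interaction by a factor determined
by its REST class: interactions entirely inside a user-defined spatial REST
region (all alchemical atoms plus everything within `radius`, default
0.5 nm, of them in a reference configuration) scale by $\alpha(\lambda)$,
boundary-straddling interactions by $\sqrt{\alpha}$, and the rest are
untouched. $\alpha$ is piecewise linear with $\alpha(0) = \alpha(1) = 1$
(endstates exactly unscaled) and minimum $T_0/T_{\max}$ at $\lambda = 1/2$,
so the REST region's effective temperature peaks at $T_{\max}$ (default
600 K) mid-path. The $\sqrt{\alpha}$ boundary exponent is the standard
solute-tempering scaling that preserves the target distribution across the
region boundary; it is exposed as `inter_exponent` (0.5 or 1) because the
plain-$\alpha$ variant is also in circulation. The thermostat always runs
at $T_0$; tempering enters through the potential only.

Numerical choices: the integrator is the BAOAB splitting with friction
5/ps by default; `suggest_timestep()` probes the stiffest local curvature
across $\lambda \in \{0, 1/2, 1\}$ and targets 0.12 rad of the fastest mode
per step, where the integrator's configurational bias is far below the
statistical resolution of any test in the package. Propagation noise and
swap decisions consume R's RNG, so a run is bitwise reproducible from its
integer seed; `run_arest()` with $T_{\max} = T_0$ reproduces `run_arex()`
bitwise under the same seed because the scale factors are exactly 1.

## Estimation

`decorrelate()` discards a burn-in fraction (default 10%; the equilibration
policy is deliberately simple at toy scale), estimates the statistical
inefficiency $g = 2\tau + 1$ of a driver series — by default the
per-replica $\partial U/\partial\lambda$, taking the maximum over replicas,
since that is the convergence-limiting quantity — and subsamples at stride
$\lceil g \rceil$. Autocorrelations are summed to their first negative lag
(initial-positive truncation), which is stable for the short series these
workflows produce.

`mbar_solve()` solves the MBAR self-consistent equations by a few
self-consistent sweeps followed by Newton–Raphson on the sampled states
(the Boltzmann factors are precomputed with per-sample shifts, to which the
free energies are invariant, so each iteration is pure linear algebra);
states without samples are evaluated afterwards as perturbation states.
MBAR reduces to BAR at $K = 2$, which the tests verify to $10^{-6}$ kT
against an independent root-finding BAR implementation.

`bootstrap_delta_g()` resamples within each state (200 resamples by
default) and reports the bootstrap SD; reported error bars are 2 SD and the
95% CI is the percentile interval. `dg_time_series()` repeats the whole
pipeline on truncations of the record, producing the $\Delta G(t)$ series
whose trailing slope is the convergence criterion.

## Diagnostics

* `convergence_slope_test()`: ordinary least-squares slope of the trailing
  window (default: trailing half). The series is converged when
  $|\mathrm{slope}| \le 0.1$ kcal/mol/ns or zero lies within two standard
  errors of the slope. Iterations carry a nominal time label of 0.1 ns per
  recorded iteration, so thresholds and statistical inefficiencies are
  reported in the field's customary units.
* `replica_mixing_report()`: per-replica occupancy histograms, the
  empirical state-transition matrix and its subdominant eigenvalue, round
  trips (state 1 → K → 1), and a chi-square uniformity test per replica.
  The chi-square is computed on the state sequence thinned at its own
  statistical inefficiency, because the raw per-iteration sequence is
  autocorrelated and the test assumes independent draws; joint assessments
  across replicas should use a multiplicity-corrected level.
* `dof_catalog()` + `dudl_dof_correlation()`: per-replica Pearson
  correlation between $\partial U/\partial\lambda$ and every registered
  conformational observable (torsions in degrees, contact distances,
  neighbour counts within 0.5 nm of the mutating particles, raw tagged
  coordinates), averaged over replicas with a replica-bootstrap CI.
  Degenerate torsion frames are excluded; zero-variance observables are
  flagged rather than propagated. `correlation_summary()` reduces the table
  to the max-|PCC| entry per category, ordered by the statistical
  inefficiency of $\partial U/\partial\lambda$.
* `internal_consistency()`: a transformation estimated forward and in
  reverse is consistent unless *neither* direction's value lies within
  1 kcal/mol of the other's 95% CI; `consistency_metrics()` adds RMSE/MUE
  with bootstrap CIs over a set.
* `restrained_comparison()`: if positional restraints
  (`add_positional_restraints()`, isotropic, kcal/mol/Å², never tempered)
  make the $\Delta G(t)$ series converge while the unrestrained series does
  not, the verdict is a conformational-sampling problem.

## What the synthetic fixtures emulate — and what they do not

`make_harmonic_ladder()` is the exactly solvable backbone: independent 3-D
oscillators whose anchor stiffness interpolates, with
$\Delta G = \tfrac{3}{2} k_B T \ln(k_{new}/k_{old})$ per mutating particle.
The package's headline check runs K = 12 states to ~20,000 decorrelated
samples and demands agreement with this closed form within 3 bootstrap SD.

`make_lj_mutation()` exercises the nonbonded interpolation and the
counter-particle toggle; the two-particle variant reduces to a 1-D radial
integral, used as a quadrature oracle.

`make_double_well_mutation()` plants slow degrees of freedom: several
independent quartic double wells (default 4) whose tilt interpolates with
the mutation, flipping the favoured well between endstates, plus a decoy
chain with a torsion and contacts that are *not* coupled to the
transformation. Only the first slow coordinate is registered as a monitored
observable, emulating the realistic situation where the monitored set does
not exhaust the slow modes. The defaults — barrier 4 kcal/mol (~6.7 kT at
300 K), per-well tilt change 2.5 kcal/mol — were chosen from a hop-rate
analysis: the tilt leaves a downhill barrier of roughly 2–3 kcal/mol, so a
run started with every replica in the old-favoured wells relaxes over tens
of exchange iterations. On the nominal time axis that produces trailing
slopes of a few tenths of a kcal/mol/ns — well above the 0.1 threshold —
while the coordinate's statistical inefficiency stays at tens to hundreds
of samples. Several independent wells matter: with a single well the
ensemble relaxation is one Poisson clock and a short run is as likely to
look flat-but-biased (which a slope test cannot flag) as visibly drifting.

Passing these tests shows the machinery is correct and the diagnostics
behave as designed in a regime engineered to exercise them. It does not
show that real protein mutations converge at any particular rate: the toys
have no solvent, no explicit temperature dependence of dielectric
screening, no periodic electrostatics, and timescale separations that are
orders of magnitude milder than a buried rotamer flip in a binding
interface.

## Experiment scales used by the tests

The packaged experiments use: 12-state ladders with 5,600 iterations of 60
BAOAB steps for the MBAR-vs-analytic check; 100-iteration × 150-step
double-well runs for short-run diagnosis (18-point $\Delta G(t)$ series);
and 2,500-iteration matched AREX/AREST pairs for the tempering comparison —
long enough that *both* methods cross the barriers repeatedly. The last
point is essential: when transitions are absent, the statistical
inefficiency of a stuck series is systematically *under*-estimated, which
would invert the comparison. Problem sizes were chosen so each experiment
has the statistical resolution its claim needs.

## Known limitations

* $\partial U/\partial\lambda$ uses a central finite difference
  (h = 1e-4, verified second-order by Richardson extrapolation) rather than
  an analytic derivative — robust to new potential terms, marginally
  slower.
* Torsion observables enter correlations as raw angles in degrees; a
  coordinate hopping across ±180° would decorrelate spuriously. Toy decoys
  avoid the wrap; real dihedrals would need circular statistics.
* The swap sweep approximates an independent-permutation draw with $K^3$
  random pair attempts; it is a correct MCMC kernel regardless, but its
  mixing rate is an implementation choice, not a claim.
* Nonbonded exclusions are limited to unique-old × unique-new pairs (the
  two sides never coexist physically); there are no 1-2/1-3 exclusions, so
  fixtures either keep bonded pairs nonbonded-silent or use the interaction
  deliberately, as the LJ dimer does.
* With multiple planted slow wells, the registered `slow_dof` coordinate is
  one of several equal contributors to $\partial U/\partial\lambda$, so its
  PCC is ~0.5–0.7 rather than 1 — which is also the realistic regime.

## A worked example

```{r example, eval = FALSE}
pair <- make_harmonic_ladder(1, k_old = 100, k_new = 100 * exp(2),
                             temperature = 300, seed = 1)
hybrid <- build_hybrid(pair)
record <- run_arex(hybrid, lambda_protocol(12), n_iterations = 2000,
                   steps_per_iteration = 60, friction = 10, seed = 1,
                   store_configurations = FALSE)
fe <- bootstrap_delta_g(decorrelate(record), n_bootstrap = 200, seed = 1)
glance(fe)
pair$analytic_delta_g  # 3 kT = 1.7885 kcal/mol
autoplot(replica_mixing_report(record))
```
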