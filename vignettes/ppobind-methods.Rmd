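---
title: "Models and methods behind ppobind"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ppobind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppobind)
library(dplyr)
```

ppobind is a desk-scale companion to the computational and kinetic analysis
of substrate recognition by protoporphyrinogen IX oxidase (PPO), the
FAD-dependent enzyme that catalyzes the last common step of heme and
chlorophyll biosynthesis. The heavy inputs of such a study — docked
macrocycle conformer ensembles, molecular-dynamics trajectories,
umbrella-sampling windows — come from specialized simulation packages and
are far beyond what a laptop reproduces. What *is* reproducible at desk
scale, and what this package implements, is every computation layered on
top of those inputs: hydrogen-bond energy statistics, multi-criteria
conformer triage, WHAM free-energy reconstruction, Michaelis-constant
thermodynamics, and a mechanistic simulator of product feedback
inhibition. Synthetic-data generators with known ground truth stand in for
the simulation outputs, so every stage is testable end to end.

This vignette documents the models, the tunable parameters, the numerical
choices, and the places where the design was genuinely open.

## Hydrogen-bond energetics

Donor–acceptor distances are scored with the classical 12-10 hydrogen-bond
potential

$$E(r) = \varepsilon\left[5\left(\frac{r_{eqm}}{r}\right)^{12}
  - 6\left(\frac{r_{eqm}}{r}\right)^{10}\right],$$

whose minimum is exactly $-\varepsilon$ at $r = r_{eqm}$. The defaults
$r_{eqm} = 1.8$ Å and $\varepsilon = 8.4$ kcal/mol are the published PPO
parameters; they bound every per-bond energy at $-8.4$ kcal/mol from
below. The functional form is a pluggable strategy (`form` argument of
`hbe_potential()`), so an alternative distance- or angle-aware potential
can be slotted in without touching the statistics.

Per-bond statistics (`hbond_stats()`) follow three fixed rules:

* **occupancy** is the percentage of snapshots with distance below a 3.5 Å
  donor–acceptor cutoff — a pure distance criterion, with no angular term,
  because the trajectories this package consumes carry distances only;
* **mean energy** averages the per-snapshot potential over *all* snapshots,
  occupied or not;
* dispersions are population standard deviations of the same per-snapshot
  series.

`total_hbe()` sums mean energies over bonds whose occupancy exceeds the
70% reporting threshold. The published totals are reproduced by this sum:
$-1.9 - 6.2 - 3.9 = -12.0$ kcal/mol for the M14 binding model, and
$-17.3$ for M15 against a printed $-17.4$ — the discrepancy is exactly
what rounding the addends to one decimal can produce, and the package
asserts agreement within 0.1 kcal/mol rather than resolving it further.
(The accompanying table footnote describes the total as an "average"; the
printed M14 arithmetic is unambiguously a sum, and the sum is what is
implemented.)

## Conformer triage

Macrocyclic substrates such as protoporphyrinogen IX defeat rigid-ligand
docking, so the upstream study docked 18 pre-generated macrocycle
conformers and triaged them by consensus. `select_conformers()` implements
that triage verbatim:

1. shortlist the `k_docking = 6` conformers with the best docking scores;
2. shortlist the `k_mmpbsa = 6` conformers with the best MM/PBSA binding
   energies;
3. intersect the shortlists;
4. keep conformers paying **strictly less than 6 kcal/mol** of
   conformational energy penalty (the accepted feasibility bound for
   bioactive macrocycle conformations);
5. keep conformers whose reaction distance — substrate *meso* methylene
   carbon to the flavin N5 — is within `orientation_max` of a productive
   orientation;
6. rank survivors, by MM/PBSA energy by default, since ensemble-averaged
   energetics outrank a single docked pose.

The orientation bound deserves a note: the source criterion is qualitative
("close enough to react"), so the 4.5 Å default is this package's own
choice, prominently configurable in `selection_config()`. Ties in a
shortlist are broken lexicographically by conformer id and announced.
Every exclusion is recorded with the first gate it failed.

On the packaged demonstration table (published scores for the ten
shortlisted conformers, synthetic stand-ins elsewhere — see
`?ppo_conformer_demo`), the triage selects exactly M14 and M15, the two
binding-model candidates carried forward in the study.

## Umbrella sampling and WHAM

`sim_umbrella_windows()` draws window samples by random-walk Metropolis
from $\exp[-(U(x) + w_i(x))/k_BT]$ rather than by molecular dynamics: a
histogram-based free-energy estimator only needs correctly distributed
samples, not dynamics. The bias is harmonic with two selectable
conventions, $w_i = \tfrac{1}{2}k(x - x_i)^2$ (`half_k`, the default) or
$w_i = k(x - x_i)^2$ (`full_k`, the AMBER restraint convention), because
published "force constants" are ambiguous between the two.

`pmf_wham()` solves the standard WHAM self-consistency system in log
space:

$$P_b = \frac{\sum_i n_{ib}}{\sum_i N_i e^{(f_i - w_i(x_b))/k_BT}},
\qquad
f_i = -k_BT \ln \sum_b P_b\, e^{-w_i(x_b)/k_BT},$$

iterated until the largest change in any window constant falls below
`tol` ($10^{-6}$ kcal/mol by default), with a 0.5 damping factor applied
whenever an update grows instead of shrinks. $W(x) = -k_BT\ln P(x)$ is
shifted so its minimum is zero. Numerical choices worth stating:

* bins are anchored at integer multiples of `bin_width` (0.1 Å default,
  the finest window spacing in common use), so identical inputs always
  produce identical binning;
* bins never visited are reported as `NA`, never as zero energy, and are
  excluded from the self-consistency sums;
* windows must form a single chain of histogram overlap; two disconnected
  groups leave their relative constants undetermined, and the unbridged
  interval is named in the error;
* $k_BT$ uses $R = 1.987204\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ with a
  298.15 K default temperature (no temperature is stated in the source;
  all derived quantities are configurable in temperature and insensitive
  to the 298–300 K range).

`pmf_binding_energy()` reads a binding free energy off a profile as minus
the height of the trailing plateau above the global minimum, warning when
the plateau still has slope. The published egress profiles converge at
10.2 kcal/mol (substrate) and 13.1 kcal/mol (product); profiles with those
plateau heights yield $-10.2$ and $-13.1$ kcal/mol. Those two published
values themselves required cluster-scale simulation (120 windows of 1 ns
each on a solvated protein) and are **not** reproduced here; the package's
accuracy claims are made on synthetic landscapes with analytic truth,
where 21–25 windows of $10^4$ Metropolis samples recover harmonic and
double-well potentials with RMSD below 0.2–0.3 kcal/mol and barrier
errors under 0.3 kcal/mol.

`pmf_convergence()` mirrors the study's convergence check: rerun WHAM on
the leading 60/80/100% of every window and report the maximum pairwise
deviation over commonly well-sampled bins (at least `min_count = 20`
counts in every sub-profile — sparser bins are pure histogram noise).
Converged sampling gives sub-0.2 kcal/mol deviations, i.e.
"indistinguishable" curves; a deliberately starved window set fails
loudly.

One documented contradiction: the source defines the reaction coordinate
as a center-of-mass distance in its methods but as the methylene-to-FAD-N5
distance in its figure captions. The estimator here is coordinate-agnostic,
so the package takes no side.

## Mutation thermodynamics

Under rapid equilibration ($K_m \approx K_d$), binding free energies
follow from Michaelis constants against a 1 M standard state:

$$\Delta G_{bind} = RT\ln\left(\frac{K_m}{c^0}\right), \qquad
\Delta\Delta G_{expt} = RT\ln\left(\frac{K_m^{mut}}{K_m^{WT}}\right).$$

Signs follow the printed tables (destabilizing mutants positive): the
published formulas as typeset each carry a sign slip relative to their own
printed values, and printed numbers govern. The wild-type tobacco value,
$K_m = 1.17\ \mu$M, gives $-8.09$ kcal/mol, printed as $-8.1$. The
calculated side aggregates the enthalpic and entropic components of a
computational mutation scan, $\Delta\Delta G_{calc} = \Delta\Delta H +
(-T\Delta\Delta S)$; those components are inputs, never recomputed.
`pearson_r2()` then quantifies calculated-versus-experimental agreement:
0.952 for the ten human-PPO mutants and 0.958 for the eight tobacco
mutants, each within print rounding of the published $r^2 = 0.95$.

Two unit conventions are deliberately preserved rather than silently
normalized: Km values are stored in µM as printed (converted to molar only
inside logarithms), and turnover numbers keep the units of their table
(min$^{-1}$ for human PPO; the tobacco literature values are per second).

`fit_lineweaver_burk()` estimates $K_m$ and $V_{max}$ by ordinary least
squares on the double-reciprocal plot, as the experimental section of the
study did. Double-reciprocal regression is statistically inferior to a
direct nonlinear fit — it over-weights low-substrate points — and the test
suite quantifies this honestly: with 1% velocity noise its median
estimates stay within 5% of truth and track a nonlinear least-squares
oracle. A non-positive intercept (data inconsistent with saturation
kinetics) is an error, not a silent negative $V_{max}$.

## Feedback inhibition kinetics

The catalytic cycle is collapsed to mass action with one effective
chemistry step — the six-electron oxidation offers no published elementary
rates to resolve further:

$$E + S \underset{k_{off,s}}{\overset{k_{on,s}}{\rightleftharpoons}} ES
  \overset{k_{cat}}{\longrightarrow} EP
  \overset{k_{rel}}{\longrightarrow} E + P, \qquad
  E + P \underset{k_{off,p}}{\overset{k_{on,p}}{\rightleftharpoons}}
  EP^{inh},$$

plus an uncatalyzed background oxidation $S \to P$ (`k_auto`). The
distinguishing structural choice is the dead-end complex $EP^{inh}$. A
scheme in which released product re-binds into the *same* EP species
cannot reproduce an enzyme-titration phenotype at all: its enzyme-state
partition is a quasi-static function of instantaneous (S, P) alone, so
progress curves at different enzyme concentrations are merely
time-rescaled copies of one another. Slow tight binding requires what the
name says — association slow on the turnover timescale
($k_{on,p} \ll k_{on,s}$) and dissociation slow enough to be effectively
one-way within an assay ($k_{off,p}$ near zero). With that structure, low
enzyme concentrations are overtaken by sequestration and stall at partial
conversion, while high concentrations finish before sequestration catches
up — the experimentally observed hallmark.

Defaults (`rate_params()`): $k_{on,s} = 100\ \mu$M$^{-1}$min$^{-1}$,
$k_{off,s} = 50$ min$^{-1}$, $k_{cat} = 3$ min$^{-1}$ (the wild-type human
PPO turnover number, the only measured rate in the set),
$k_{rel} = 3$ min$^{-1}$, $k_{on,p} = 0.5\ \mu$M$^{-1}$min$^{-1}$,
$k_{off,p} = 0.005$ min$^{-1}$, $k_{auto} = 0.005$ min$^{-1}$. These are
phenomenological values calibrated once so that the simulator reproduces
the qualitative titration phenotype at the published assay design — 0.34
µM substrate against 0.32–96.66 nM enzyme: verdicts switch monotonically
from inhibited to complete, with completion inside roughly half an hour at
the top of the titration.

The fluorescence signal is linear in *total* product,
$P + EP + EP^{inh}$, with unit scale by default: the porphyrin fluorophore
emits whether free or bound, and counting only free product would impose
an artificial conversion ceiling at high enzyme where a stoichiometric
share of product is enzyme-bound.

Curve analysis (`analyze_velocities()`) estimates the initial velocity as
the least-squares slope over the leading 5% of points, the steady-state
velocity over the trailing 25%, and the inflection as the maximum absolute
second difference of a 5-point moving-average-smoothed signal (smoothing
resists noise; the window fractions must not overlap). The feedback index
$1 - v_{steady}/v_0$ is reported as is, but the titration verdict uses a
**depletion-corrected** variant, $1 - v_{steady}/(v_0(1 - x))$ with $x$
the converted fraction at the steady window: under uninhibited first-order
turnover the late slope falls in proportion to remaining substrate, and
without the correction plain substrate depletion is indistinguishable from
inhibition (the ablation control $k_{on,p} = 0$ would misclassify). A
curve is `inhibited` when the corrected index exceeds 0.2 *and* conversion
has not reached 90% by the 30-minute horizon (the study's completion
timescale); otherwise `complete`.

The integrator is `deSolve::lsoda` (stiff-capable, adaptive) at
`rtol = 1e-10`, `atol = 1e-12`; ligand and enzyme conservation hold to
$10^{-6}$ relative at every output point, and in practice to machine
precision. With product rebinding ablated and fast release, the simulator
reproduces the Michaelis–Menten quasi-steady-state velocity with
$K_m^{eff} = (k_{off,s} + k_{cat})/k_{on,s}$ to well within 1%.

## Synthetic-data generators

The generators exist to make every downstream stage testable with known
ground truth; their defaults are the study conditions where stated, and
statistical-stability choices where not.

* **Distance trajectories** (`sim_hbond_trajectory()`): zero-truncated
  Gaussians, sampled by inverse CDF for seed-stable reproducibility. When
  a pair carries a target occupancy, the location parameter is solved
  analytically from the truncated-normal CDF so that
  $P(r < \text{cutoff})$ equals the target — quantile matching, no
  rejection loops. A target and a mean cannot be honored simultaneously;
  the target wins, and the mean anchors only untargeted pairs. Empirical
  occupancy lands within two percentage points of target from about 2000
  snapshots (binomial noise). Degenerate pairs (`sd = 0`) support targets
  of exactly 0 or 1 only; impossible combinations raise errors naming the
  pair. The default snapshot interval is 1 ps, matching the source's
  coordinate-saving interval.
* **Umbrella windows**: see above; acceptance rates are stored per window
  and a zero acceptance rate suggests shrinking the proposal width.
* **Conformer tables** (`sim_conformer_table()`): the planted ids are
  built to be the only records inside both shortlists that also pass both
  gates; distractors either fill the remaining shortlist slots (good in
  exactly one score) or are ordinary, and all of them carry a penalty
  above the gate as an independent disqualifier, so the construction holds
  for any table size down to `n = length(planted)`. The generator verifies
  its own plant before returning.
* **Progress-curve families** (`sim_progress_curves()`): ODE solutions
  plus i.i.d. Gaussian signal noise, with a paired enzyme-free background
  curve per substrate concentration, mirroring how autoxidation is
  measured and subtracted in the real assay. The default titration uses
  the published concentrations; the 0–120 min grid at 0.5-min resolution
  is this package's study design, long enough for sequestration to
  manifest at the lowest enzyme concentration.

What the generators deliberately do **not** emulate: autocorrelated MD
noise, angular hydrogen-bond criteria, baseline drift or photobleaching in
fluorescence, pipetting error across wells. Passing tests therefore
demonstrate correctness of the estimators on clean, well-specified input —
not robustness to every pathology of real instruments.

## Problem sizes and verification scope

The test suite and the acceptance script keep all simulations at
laptop-friendly sizes chosen for statistical comfort: $10^4$ Metropolis
samples across 21–25 umbrella windows, 4000-snapshot occupancy
calibrations, a thousand planted conformer tables, 241-point kinetic
grids. Published table arithmetic (hydrogen-bond totals, ΔΔG ledgers,
catalytic efficiencies, correlation coefficients) is exact or
print-rounding-limited and verified to those tolerances. Every stochastic
check runs under a fixed seed; independent WHAM verification uses a
convex-minimization solver of the same likelihood as a cross-check,
agreeing to $10^{-3}$ kcal/mol.

## Known limitations

* No MBAR estimator, no 2-D profiles, and no autocorrelation-based error
  bars on the PMF (future work); the protein PMF itself is out of desk
  scale.
* Error propagation from the published ± uncertainties on Km and kcat is
  not implemented; ledger values are point estimates.
* The kinetic scheme is phenomenological: one effective chemistry step,
  one dead-end complex, no FAD redox sub-steps or photochemistry.
* Occupancy statistics use distances only; a trajectory carrying angles
  would need a different occupancy criterion.
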