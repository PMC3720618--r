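# ppobind

Desk-scale analysis of substrate recognition and product feedback
inhibition by protoporphyrinogen IX oxidase (PPO), the FAD-dependent
enzyme catalyzing the last common step of heme and chlorophyll
biosynthesis. PPO is both a major herbicide target and a photodynamic
therapy lead, yet its substrate-bound structure has never been
crystallized; the field's picture of how protoporphyrinogen IX (protogen)
binds and how protoporphyrin IX (proto, the product) feeds back on the
enzyme rests on layered computation validated by mutant kinetics.

ppobind implements every analysis layer of that workflow as tested,
tidyverse-native R:

- **Hydrogen-bond energetics** — occupancy, distance summaries and
  per-bond energies over donor–acceptor distance trajectories, scored with
  the 12-10 potential
  `E(r) = ε[5(r_eqm/r)¹² − 6(r_eqm/r)¹⁰]` (ε = 8.4 kcal/mol,
  r_eqm = 1.8 Å), plus the occupancy-gated total over a bond network.
- **Conformer triage** — the multi-criteria selection of docked macrocycle
  conformers: docking-score shortlist ∩ MM/PBSA shortlist, a strict
  `< 6 kcal/mol` conformational-penalty gate, and a reaction-orientation
  gate on the substrate-to-FAD-N5 distance.
- **Umbrella sampling + WHAM** — Metropolis generation of biased windows on
  analytic landscapes, self-consistent WHAM reconstruction of the
  potential of mean force `W(ξ)`, binding free energies from plateau
  heights, and sub-fraction convergence diagnostics.
- **Mutation thermodynamics** — `ΔG_bind = RT ln(Km/c⁰)` under the
  `Km ≈ Kd` rapid-equilibration assumption, mutational shifts
  `ΔΔG = RT ln(Km^mut/Km^WT)`, calculated-vs-experimental correlation, and
  Lineweaver–Burk estimation of Km/Vmax/kcat. The published mutant tables
  (human and tobacco PPO) ship as packaged fixtures.
- **Feedback kinetics** — a stiff ODE simulator of slow tight-binding
  product inhibition (`E+S ⇌ ES → EP → E+P` with a dead-end `E+P ⇌ EPinh`
  complex), background subtraction, initial/steady-state velocity
  analysis, and titration-wide inhibited/complete classification.
- **Synthetic data** — seeded generators with known ground truth for every
  input class (distance trajectories with calibrated occupancy, Boltzmann
  window samples, conformer tables with a planted answer, noisy progress
  curves with autoxidation backgrounds).

## Worked example

```r
library(ppobind)
library(dplyr)

# 1. Conformer triage on the published docking / MM-PBSA score lists
sel <- select_conformers(ppo_conformer_demo())
sel[, c("id", "mmpbsa_energy", "penalty", "reaction_distance", "rank")]
#> # A tibble: 2 × 5
#>   id    mmpbsa_energy penalty reaction_distance  rank
#>   <chr>         <dbl>   <dbl>             <dbl> <int>
#> 1 M14           -44.5     2.5               4.2     1
#> 2 M15           -35.7     3.5               3.8     2

# 2. Mutant thermodynamics from the packaged Km tables
led  <- ddg_ledger(ppo_hppo_kinetics(), wt = "Wild-type (WT)")
comp <- ppo_ddg_components() |> filter(set == "hppo") |>
  inner_join(led, by = "mutant")
pearson_r2(ddg_calc(comp$ddh, comp$minus_t_dds), comp$ddg_expt)
#> [1] 0.9523986
dg_from_km(1.17)     # wild-type tobacco PPO, Km = 1.17 uM
#> [1] -8.092459

# 3. WHAM on synthetic umbrella windows over a known harmonic landscape
uw <- sim_umbrella_windows(c(0, 0, 1), centers = seq(-2, 2, 0.2),
                           force_constants = 10, n_samples = 5000, seed = 1)
glance(pmf_wham(uw, bin_width = 0.1))
#> # A tibble: 1 × 6
#>   n_bins n_sampled converged iterations temperature bin_width
#>    <int>     <int> <lgl>          <int>       <dbl>     <dbl>
#> 1     49        49 TRUE             172        298.       0.1

# 4. Enzyme titration at the published assay concentrations
fam <- sim_progress_curves(0.34, c(0.32, 3.22, 32.22, 96.66),
                           seq(0, 120, 0.5),
                           params = rate_params(k_auto = 0), seed = 1)
classify_feedback(fam[!fam$background, ]) |>
  select(e0_nM, feedback_index, conversion, verdict)
#> # A tibble: 4 × 4
#>   e0_nM feedback_index conversion verdict
#>   <dbl>          <dbl>      <dbl> <fct>
#> 1  0.32          0.260     0.0235 inhibited
#> 2  3.22          0.865     0.210  inhibited
#> 3 32.2           0.993     0.851  inhibited
#> 4 96.7           1.000     0.991  complete
```

Reading the output: the triage recovers M14 and M15 as the only viable
binding models (ranked by MM/PBSA energy); the calculated mutational
free-energy shifts correlate with the Km-derived experimental ones at
r² ≈ 0.95 across the ten human-PPO mutants; wild-type binding works out to
−8.1 kcal/mol; the WHAM solver converges in a few hundred iterations; and
the simulated enzyme titration shows the hallmark of slow tight-binding
product feedback — low-enzyme curves break and stall below full
conversion, while the highest enzyme concentration converts >99% of the
substrate within the 30-minute horizon and is called complete.

`autoplot()` methods exist for PMF profiles and Lineweaver–Burk fits, and
`plot_progress_curves()` draws titration families. `run_pipeline()`
chains synthetic-data generation through every analysis stage into one
output directory with a machine-readable summary.

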