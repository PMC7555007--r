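# synapsim

Agent-based simulation of immunological synapse (IS) formation and
T cell receptor (TCR) cooperativity, for quantitative immunologists and
modellers who want to ask: *how can the observed TCR–pMHC affinity
change when the molecular rate constants do not?*

When a T cell engages a ligand-bearing surface, TCR–pMHC and
LFA-1–ICAM-1 complexes form, segregate by size, and are dragged towards
the contact centre by contracting F-actin arcs, building the classic
bullseye synapse. Experimentally, the *in situ* dissociation constant

```
cellKD = [TCR_free] [pMHC_free] / [TCR–pMHC]      (molecules/µm²)
```

falls with increasing pMHC density, reaches a minimum, and rises again
— apparent positive-then-negative cooperativity — although single-bond
k_on and k_off stay fixed. synapsim reproduces and dissects this with a
kinetic Monte Carlo model: two paired 2D lattices (T cell membrane,
bilayer) with single-occupancy exclusion, random-walk diffusion
(`p_move = 4Dτ/a²`), binding at colocalised nodes
(`p_on = B·τ/τ_on`, `τ_on = V·N_A/k_on`), exact exponential unbinding
(`p_off = 1 − e^{−k_off τ}`), size-based segregation, class-resolved
centripetal transport, and a three-state F-actin focus automaton on a
third lattice whose formed foci multiply the local TCR–pMHC binding
probability by a coefficient **B** (positive feedback for B > 1,
negative for B < 1). The mechanics and every default are documented in
`vignettes/synapse-model.Rmd`.

The package is tidyverse-native: experiment drivers return tibbles,
fitted summaries have `tidy()` / `glance()` methods, and results plot
with `autoplot()`.

## Worked example

A pMHC titration at the desk scale used throughout the test suite
(synapse radius 1.75 µm, TCR at 18/µm², 10 replicate simulations of
10 minutes each; ~4 minutes of compute per arm):

```r
library(synapsim)

cfg <- lattice_config(nodes_per_side = 45, synapse_radius = 1.75)
plan <- experiment_plan(
  pmhc_grid = c(1, 1.93, 3.73, 7.2, 13.9, 26.8, 51.8, 100),
  n_replicates = 10, base_seed = 20260922,
  measurement_times = c(60, 300, 600), config = cfg,
  kd_window = 24, flag_density = 2.6
)
coupled  <- pmhc_titration(plan)
arrested <- pmhc_titration(plan, coupling = FALSE)

glance(coupled)
#>   tcr coupling B time present argmin_pmhc min_cell_kd pooled_sd n_usable
#> 1  18     TRUE 1   60   FALSE       100.0        2.52     0.416        6
#> 2  18     TRUE 1  300    TRUE        26.8        1.86     0.492        6
#> 3  18     TRUE 1  600    TRUE        26.8        1.80     0.415        6
glance(arrested)
#>   tcr coupling B time present argmin_pmhc min_cell_kd pooled_sd n_usable
#> 1  18    FALSE 1   60   FALSE        51.8        2.63     0.423        6
#> 2  18    FALSE 1  300   FALSE        26.8        2.54     0.501        6
#> 3  18    FALSE 1  600   FALSE       100.0        2.57     0.398        6
```

Read: with centripetal coupling, the mean cellKD curve over pMHC
density acquires an interior minimum (`present = TRUE`) at 26.8
molecules/µm² by the 5-minute readout — cellKD 1.80 at 10 min, versus
~3 at the usable ends of the grid — while at 1 minute no minimum has
formed yet. Arresting the coupling (the in silico analogue of F-actin
inhibition) leaves a flat/slowly declining curve with no minimum at any
time. `tidy()` returns the full per-density summary and
`autoplot(coupled)` draws the curves with replicate-SD error bars.
Densities below `flag_density` are simulated but flagged as
high-variance (pMHC scarcity) and excluded from minimum-finding.

A shell front end wraps the same drivers:

```sh
inst/exec/synapse-abm run --pmhc 26.8 --seed 1 --out out/
inst/exec/synapse-abm titrate --mode b --replicates 5 --out sweep/
```

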