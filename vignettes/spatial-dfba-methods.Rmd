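---
title: "Methods: spatial dynamic FBA of the infant gut microbiota"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial dynamic FBA of the infant gut microbiota}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutsim)
```

## The model

`gutsim` simulates the first weeks of microbial colonization of the
infant colon as a multiscale system. The colon (about 450 mm by 16 mm)
is discretized into a regular lattice of 225 x 8 sites of 2 mm side and
0.05 mL volume (90 mL in total). Each site holds any mix of extracellular
metabolites and at most one bacterial population, representing the
locally dominant species. A timestep is 3 minutes; one day is 480 steps.

Each step proceeds in this order:

1. **Feeding.** A pulse of 211 umol lactose — the dominant carbohydrate
   reaching the colon of a milk-fed neonate — is split equally over the
   six most proximal columns every 60 steps (3 h). Water is treated as
   unlimited; oxygen enters only through the configured oxygen regime.
2. **Metabolism and growth.** Every population solves a flux balance
   problem on its own stoichiometric network (see below) and applies the
   resulting exchange fluxes to its site and the ATP yield to its size.
3. **Division.** Populations at 200x the initial size (1e10 bacteria)
   split half of their biomass into a random empty von Neumann neighbor.
   Populations boxed in keep growing to at most 2e10 bacteria, beyond
   which their metabolism is suspended until space frees.
4. **Turnover.** Each population dies with probability 0.0075 per step;
   populations in the most distal column wash out. Each empty site gains
   a random roster species at 5e7 bacteria with probability 5e-5.
5. **Mixing.** Populations (not metabolites) swap between nearby sites
   (below).
6. **Transport.** Metabolites diffuse (forward Euler, five-point
   Laplacian, no-flux walls, D = 4.4e-5 cm^2/s) and advect one column
   distally per step; the last column's advected content is recorded as
   the fecal outflow. Oxygen diffuses but does not advect.

The run is initialized by seeding each site with probability 0.3 with a
random roster species at 5e7 bacteria (540 populations and about 2.7e10
bacteria on average), then iterated for a configurable horizon (21 days
by default). All stochastic elements draw from one seeded generator, so
runs are exactly reproducible.

## FBA with an enzymatic constraint

Each species is a stoichiometric network compiled to a linear program.
Reversible reactions are split into two irreversible columns so all
fluxes are nonnegative, and the objective is an ATP drain
(ATP + H2O -> ADP + Pi), which is elementally neutral: growth is
measured as umol ATP regenerated per timestep per population unit
(1e10 bacteria). The constraints are

* internal steady state, `S f = 0`;
* environment-limited uptake, `F_in(i) <= amount_i / (B / U)` with
  `U = 1e10`, so a population can never take up more than its site
  holds in one step (water excepted);
* the enzymatic constraint `sum(f) <= a`, with `a = 2` umol flux per
  step per population unit. The sum runs over all columns, including
  exchange and objective fluxes (switchable via `fba_options()`).

The enzymatic constraint represents the finite enzyme capacity of a
cell. It is the ingredient that produces rate/yield switches: when
substrate is scarce the uptake bound binds and the network chooses the
highest-yield pathway; when substrate is abundant the flux cap binds
and the network chooses the pathway with the highest ATP per unit of
total flux. Relative growth rates between species therefore depend on
the local substrate concentration, which is what drives succession in
the whole-lattice runs.

Linear programs are solved by a dense simplex implemented in C++ (big-M,
Dantzig pricing with a Bland anti-cycling fallback, and a final
re-solve of the basic system to purge accumulated pivot error). Among
alternate optima the solution of minimal total flux is returned (a
second, pinned LP), which makes secretion profiles deterministic where
the first-stage optimum is degenerate. Optima below 1e-8 umol/step/unit
— growth of a fraction of a bacterium — are reported as the exact zero
solution, and uptake bounds below 1e-8 are treated as closed; both
choices keep solver-tolerance noise out of the mass ledgers. The test
suite cross-checks the solver against an independent implementation
(scipy's HiGHS interface) on randomized problems.

## The toy roster

The package bundles three hand-written species as genuine SBML files,
read back through the package's own SBML reader. They are lumped,
elementally balanced networks engineered to reproduce, under the FBA
engine (not by construction of the outputs), the three ecological roles
that shape early colonization:

* **BifidToy** — a bifid-shunt fermenter. Lactose enters through the
  phosphoketolase chain (`R_PKL`, `R_F6PE4PL`) and splits into a
  low-yield branch (3 acetate + 2 lactate + 5 ATP per lactose; cheap per
  unit flux) and a high-yield branch (4 acetate + 1 ethanol + 2 formate
  + 6 ATP; expensive per unit flux). Under the enzymatic constraint the
  LP therefore reproduces the classic switch: acetate:ethanol:formate
  4:1:2 at scarce lactose, acetate:lactate 3:2 with a yield of 5 ATP, 2
  lactate and 3 acetate per lactose at abundant lactose. A lactate
  dehydrogenase route re-imports lactate at modest yield.
* **FacAnToy** — a facultative anaerobe. Mixed-acid lactose fermentation
  (4 ATP per lactose) plus aerobic respiration of lactose and lactate
  with far higher yield (32 and 12 ATP); with oxygen present it
  out-grows every fermenter, and without oxygen it is slower than the
  bifid shunt at all lactose levels.
* **CrossToy** — an anaerobic cross-feeder that grows on lactate (1 ATP
  per 2 lactate, the best anaerobic lactate yield in the roster) and
  only weakly on lactose.

A fourth file, `badtoy_synthetic.xml`, is a deliberately mass-imbalanced
copy of CrossToy (one acetate created from nothing) used as the negative
control for the audits; it is never part of the default roster.

Formulas use the neutral (acid) species so C, H, O and N balance with
integer coefficients. Gibbs formation energies for the eight exchanged
metabolites are transformed standard values at pH 7 and ionic strength
0.1 M from the standard biochemical tables, shipped as a CSV fixture.

## Audits

Two audits can run on every solve of a simulation (`audit = TRUE`):

* **Atom balance.** The formula-weighted net exchange of C, H, O and N
  must vanish to within 1e-8 umol per solution. Only these four
  elements are audited because only water, oxygen and lactose ever
  enter the system.
* **Free energy.** `l = sum_i F_net_out(i) E(i)` is the free energy of
  the outputs minus the inputs; admissible solves have `l < 0`, with
  `l = 0` accepted only at (near-)zero growth. The sign convention is
  explicit: negative `l` is energy lost to the environment.

A whole-run ledger additionally closes the per-metabolite books:
feed + oxygen input + net bacterial exchange - outflow = final lattice
content, to solver precision (`mass_balance_report()`).

## Mixing and its calibration

Populations mix by a swap scheme inspired by Kawasaki dynamics: each
step, sites are visited in random order; an unswapped site picks a
partner uniformly from itself and its first-order (von Neumann) and
second-order (diagonal) neighbors and exchanges population contents if
the partner has not yet swapped. Metabolites stay put. The neighborhood
reading was selected by calibration: simulating tracer populations and
fitting mean squared displacement along the colon axis gives a
population diffusion constant of about 5.7e-5 cm^2/s — 1.3x the
metabolite diffusion — for the 8-cell neighborhood, whereas wider
neighborhoods (Manhattan radius 2, or the full 5x5 block, both available
via `mix_offsets()`) mix 1.7x-2.9x too fast. MSD is fitted along the
long axis only, because the 8-row transverse axis saturates within a few
sweeps.

On rescaled lattices (site side scaled by `n`) sweeps are scaled by
`1/n^2`, which keeps the physical diffusion constant; fractional sweep
counts attempt the corresponding fraction of sites, and multiple sweeps
re-arm all sites between passes. Seeding and colonization probabilities
are scaled by `n^2`, which keeps the expected number of events per
physical area constant (the probabilities are per site, and the number
of sites scales as `1/n^2`).

## Desk-scale experiments

The succession experiments in the test suite run on a reduced 60 x 4
lattice for 2-3 simulated days with seeds 1-5, small enough for a
desktop yet large enough for spatial niches to form:

* **Anaerobic baseline** (2 days): the bifid-shunt species ends most
  abundant in a majority of seeds.
* **Initial oxygen** (3 days, 0.02 umol per site): the facultative
  anaerobe dominates early and is replaced by the fermenter after the
  oxygen is consumed. The desk endowment is sized so that depletion
  falls around the first quarter of the run; at full scale (21 days,
  225 x 8) the corresponding regimes are 0.1-10 umol per site, which is
  what the canned `config_oxygen_desk.json` uses and what full-length
  runs should use.
* **Phosphoketolase knockout**: deleting `R_PKL`/`R_F6PE4PL` removes all
  lactose catabolism from the bifid network, and its dominance with it.
* **Lactate-uptake block**: the cross-feeder's time-integrated biomass
  drops relative to baseline. The integrated statistic is used because
  at two days the cross-feeder is still in its establishment phase, so
  final-state abundance is dominated by colonization noise.

These are direction-of-effect checks on a scaled-down analogue of the
full system. They demonstrate that the mechanisms (metabolic switching,
oxygen-driven early dominance, lactate cross-feeding) operate in the
spatial model; they do not reproduce full-scale replicate counts, and
the toy species are archetypes, not curated genome-scale
reconstructions. With downloaded genome-scale models (SBML with FBC
bounds), the same machinery — `load_sbml()`, a curation CSV applied by
`apply_curation_edits()`, `set_atp_objective()`, `compile_model()` and a
`roster` handed to `sim_config()` — runs the full-size system; expect
hours per 21-day replicate.

## Numerical choices and degenerate inputs

* Diffusion requires `4 D dt / dx^2 < 1` per Euler substep (0.792 at
  defaults, one substep); the simulator picks the smallest stable
  substep count for the configured geometry, and a directly unstable
  `diffuse()` call is an error, not a warning.
* Advection moves whole columns after diffusion within a step; the
  outflow record is taken before the shift. On rescaled lattices the
  physical speed (one default-size site, 2 mm, per step) is preserved
  by shifting `1/n` columns per step through an accumulator.
* Division picks uniformly among empty von Neumann neighbors; ties in
  the mixing partner draw are resolved by the single RNG stream.
* `horizon = 0` records only the initial state; an empty roster or a
  zero seeding probability is legal and yields a sterile colon in which
  feed simply transits (mean transit about 11 h at defaults).
* Populations are continuous; sizes below one bacterium can only arise
  transiently from near-zero LP optima and are snapped to zero by the
  solver's zero-solution rule.

## Known limitations

* Only carbon metabolism from lactose is represented; proteins, fats,
  oligosaccharides and mucins are absent, so species whose niches
  depend on them will be under-represented.
* ATP production is the growth proxy for all species alike; species
  with strongly different ATP-to-biomass ratios would need per-species
  yields.
* The lattice is 2-D and populations do not advect, which reads as a
  wall-adherent community fed by a luminal flow.
* pH, host oxygen consumption and mucus dynamics are out of scope.
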