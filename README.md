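# gutsim

Spatial dynamic flux balance analysis (FBA) of the early infant gut
microbiota.

`gutsim` is for microbial ecologists and systems biologists who want to
ask *mechanistic* questions about how the newborn gut community
assembles: why facultative anaerobes such as *E. coli* dominate the
first days, why *Bifidobacterium* usually takes over, and how lactate
cross-feeding and early intracolonic oxygen shape that succession. It
simulates the colon as a 225 x 8 lattice of 2 mm sites through which
lactose pulses advect and diffuse, while local bacterial populations —
each a stoichiometric metabolic model — grow, divide, die, colonize and
mix.

## The model in brief

At every 3-minute timestep, each population of size *B* solves

```
maximize   f_ATP                         (ATP production as growth proxy)
subject to S f = 0                       (internal steady state)
           0 <= F_in(i) <= c_i / (B/U)   (local substrate limitation, U = 1e10)
           sum_j f_j <= a                (enzymatic constraint, a = 2 umol/step/unit)
```

with all reversible reactions split so every flux is nonnegative. The
summed-flux cap `a` encodes finite cellular enzyme capacity and makes
the optimum substrate-dependent: scarce substrate selects the
highest-yield pathway, abundant substrate the highest ATP per unit flux.
For the bundled bifid-shunt network this reproduces the classic switch
from acetate:ethanol:formate 4:1:2 (scarce lactose) to acetate:lactate
3:2 with 5 mol ATP, 2 mol lactate and 3 mol acetate per mol lactose
(abundant lactose). Growth converts ATP at 1e9 bacteria per umol.

Exchange fluxes update the site's metabolite amounts (Euler diffusion at
4.4e-5 cm^2/s, advection one column per step, distal outflow recorded as
the "fecal" stream), populations mix by a swap scheme calibrated to a
diffusion constant of 5.7e-5 cm^2/s, and every solve can be audited for
elemental (C,H,O,N) and Gibbs free-energy consistency.

Models are read from SBML (Level 3, FBC bounds), optionally modified by
a curation-edit CSV, and given a mass-neutral ATP-drain objective. Three
toy species ship as SBML fixtures so everything runs without downloads:
a bifid-shunt fermenter (`BifidToy`), a facultative anaerobe
(`FacAnToy`) and an anaerobic lactate cross-feeder (`CrossToy`).

## Worked example

One FBA solve at abundant lactose (a population of 5e9 bacteria on one
0.05 mL site):

```r
library(gutsim)
models <- build_toy_models()
res <- solve_step(models$BifidToy, B = 5e9,
                  uptake_bounds(c(lcts = 100), B = 5e9), a = 2)
res
#> <gs_fba_result> BifidToy: growth 0.454545 umol ATP/step/unit, sum flux 2 (optimal)
#>   net exchange (umol/step/unit):
#>     ac       +0.2727
#>     h2o      -0.0909
#>     lac_L    +0.1818
#>     lcts     -0.0909
```

The enzymatic constraint binds (`sum flux = 2`); per mol of lactose the
cell gains 0.4545/0.0909 = 5 mol ATP and secretes 2 mol lactate and 3
mol acetate — the bifid-shunt yield at high substrate.

A desk-scale community run (60 x 4 lattice, 2 simulated days) with the
toy roster, anaerobic:

```r
run <- run_simulation(sim_config(width = 60, height = 4,
                                 horizon = 960, seed = 1))
run
#> <gs_run> 60x4 lattice, 960 steps, seed 1
#>   final abundance (bacteria):
#>     BifidToy   1.67e+12
#>     FacAnToy   9.36e+10
#>     CrossToy   5e+07
#>   audit: 61919 solves, 0 element violations (max |net| 1.83e-09 umol), 0 energy violations
```

The bifid-shunt species dominates anaerobically, every one of the 61919
flux solutions conserved C, H, O and N to better than 1e-8 umol, and
none gained free energy. The fecal stream over the last day:

```r
fecal_composition(run, window = 480)
#>   metabolite amount_umol   fraction        mM
#> 1         ac   3211.0286 0.51002823 33.448214
#> 3       etoh    303.2417 0.04816583  3.158768
#> 4        for    606.4835 0.09633166  6.317536
#> 5       lcts    677.3199 0.10758306  7.055416
#> 7        lac   1497.7123 0.23789123 15.601170
```

Acetate-rich with a substantial lactate fraction — the signature of a
bifid-dominated community. `crossfeeding_network()` extracts the
production/consumption edges (lactose -> BifidToy -> acetate, lactate,
...), `spatial_profiles()` the per-column distributions, and
`apply_experiment()` installs the knockout and uptake-block experiments
(phosphoketolase deletion, lactate blocks, oxygen-uptake knockout,
time-triggered lactose blocks).

A thin command line lives at `inst/cli/gutsim.R`
(`fixtures` / `run` / `dose-response` / `audit`).

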