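# vortexflux

Quantifying the genetics of extinction vortices: when a sexual population
shrinks, is the bigger danger that deleterious mutations start fixing
(**mutational meltdown**) or that too few new beneficial mutations arrive
(**mutational drought**)? `vortexflux` answers this for populations near
their critical size, for population geneticists and conservation-genetics
modellers.

## The model

Each co-dominant mutation of effect `s` multiplies fitness by `(1+s)` per
copy and fixes under the diploid Moran process with probability

```
pfix(s) = (1 - e^-s) / (1 - e^-2Ns)
```

Fixations move log mean fitness at the two *fitness fluxes*

```
vd = Ud * N * ∫_{s<0} pd(s) 2s pfix(s, N) ds   (deleterious, <= 0)
vb = Ub * N * ∫_{s>0} pb(s) 2s pfix(s, N) ds   (beneficial,  >= 0)
```

with `pd` a gamma DFE (human non-synonymous preset: shape 0.169, scale
1327.4 / 23646) and `pb` exponential (mean 0.001). The critical population
size `Ncrit` solves `vb + vd + delta_env = 0`, and the
**drought : meltdown ratio** `(dvb/dN) / (dvd/dN)` at `Ncrit` says which
feedback loop dominates the tipping point (>1: drought). A forward-time
Moran simulator over recombining linkage blocks (23 chromosomes x 100
blocks, 2 crossovers each) re-derives `Ncrit` and the ratio under linkage
disequilibrium, with per-mutation fixation tracking and neutral-tracer
coalescent Ne estimation.

## Worked example

```r
library(vortexflux)

p <- model_params(Ud = 2, Ub = 0.002)   # Ud/Ub = 1000, preset DFEs
find_ncrit(p)
#> [1] 3664.306
drought_meltdown_ratio(p)
#> Ncrit = 3664.31; dvb/dN = 7.959e-09, dvd/dN = 9.327e-09; drought:meltdown = 0.8534
whitlock_ncrit(p)                        # exponential-DFE closed form
#> [1] 2361.89
find_ncrit(model_params(Ud = 2, Ub = 0.002, delta_env = -1.5e-5))
#> [1] 4652.65
```

Read: at the static-environment tipping point (about 3,664 diploids), a
marginal loss of individuals harms the beneficial flux 85% as much as it
harms the deleterious flux — drought is nearly as important as meltdown.
Even a slow environmental decline (10% fitness per ~6,700 generations)
raises the tipping point to about 4,653 and pushes the ratio above 1. The
closed-form approximation (2,362) underestimates `Ncrit` because the gamma
DFE is overdispersed (cv 2.43) relative to the exponential it assumes.

Simulation at reduced scale:

```r
run <- sim_run(sim_config(50, model_params(Ud = 0.1, Ub = 0.01),
                          genome_architecture(10, 50, 2),
                          generations = 5000, ledger = TRUE, seed = 3))
flux_decompose(run$fixations, run$burn_in_end, nrow(run$trajectory))
#> Flux decomposition over G* = 4700 generations: vd = -0.0001461 (194 fixations), vb = 1.214e-05 (27 fixations)
```

Canned parameter sets (`list_scenarios()`, `run_scenario("fig2")`) cover
the static and deteriorating environments, the `Ud/Ub` sweep, the
environmental-threshold analysis and a full-scale LD pipeline (`"fig6"`,
tagged with a compute warning). A thin command-line front end lives at
`inst/cli/vortexflux.R`.

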