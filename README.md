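# subflux

Isotope-labeling flux analysis in metabolic subnetworks.

## The problem

¹³C metabolic flux analysis infers intracellular reaction rates from the
transient incorporation of an isotopic tracer after a nutrient switch.
Conventional non-stationary ¹³C-MFA simulates label propagation from the
extracellular nutrient, so the flux model must contain every reaction
between the nutrient and the pathway of interest, and the dataset must
cover uptake fluxes, biomass composition and the labeling of all upstream
intermediates — which confines most flux studies to central carbon
metabolism.

subflux models label propagation **from the metabolic precursors of the
subnetwork of interest** instead. Those precursors — the *local label
inputs* — have time-varying, uncontrolled labeling, but it can be measured
and represented as a smooth analytical curve; the subnetwork can then be
simulated and fitted entirely on its own. The package is for metabolomics
and fluxomics researchers who have time-course enrichment data (e.g.
LC-MS mean molecular ¹³C-enrichments) and steady-state concentrations for
a handful of metabolites and want absolute fluxes through the pathway
connecting them.

## The method

1. **Decomposition** — an atom-mapped network is decomposed into *minimal
   subsystems*: for each intermediate Y, S_Y holds all reactions producing
   Y, their substrates as local inputs, and a balancing sink that keeps
   Y's pool constant (metabolic steady state). Subsystems sharing a
   metabolite merge into larger flux models (`decompose_network()`,
   `merge_subsystems()`, `enumerate_pathway_subsystems()`).
2. **Input representation** — each local input's enrichment series is
   fitted with a logistic `p1/(1+exp(-p2*(t-p3)))` or double-logistic
   `p4+(p5-p6*t)*(1/(1+exp((p7-t)/p8)) - 1/(1+exp((p9-t)/p10)))` curve by
   particle swarm + L-BFGS-B under box constraints (`fit_input()`).
3. **Simulation** — a minimal ODE system over single-atom elementary
   metabolite units (EMUs), assembled by backward traversal from the
   measured metabolites and integrated with a stiff-capable solver:
   `m_Y dx/dt = Σ_r v_r x_src(r) − (Σ_r v_r) x_Y` per simulated atom
   position (`simulate_subsystem()`).
4. **Estimation** — fluxes `v` and pools `m` minimize the weighted least
   squares `h(v,m) = Σ_i ((x_i − y_i(v,m))/σ_i)² + Σ_j ((n_j − m_j)/σ_j)²`
   under box constraints, with a chi-square goodness-of-fit test,
   Monte-Carlo confidence intervals and input-sensitivity analysis
   (`estimate_fluxes()`, `monte_carlo()`, `input_sensitivity()`).

## Worked example

Estimate the flux through reaction r16 (M → N) of the built-in example
network from noisy synthetic data:

```r
library(subflux)

net <- example_network()
net
#> <flux_network> 18 metabolites (17 intermediates), 20 reactions (1 reversible)

sub_N <- minimal_subsystem(net, "N")
sub_N
#> <flux_subsystem> S_N
#>   reactions:     r16
#>   intermediates: N
#>   local inputs:  M
#>   sinks:         sink_N

required_measurements(sub_N)
#> # A tibble: 1 x 7
#>   metabolite positions n_required n_atoms fragment measurable resolvable
#>   <chr>      <list>         <int>   <int> <lgl>    <lgl>      <lgl>
#> 1 M          <int [2]>          2       2 FALSE    NA         TRUE

truth <- example_truth()        # true r16 flux: 1.0 umol/gDW/h
ds <- make_noisy_dataset(simulate_reference_dataset(truth), seed = 10)

wf <- run_workflow(
  sub_N,
  enrichments    = ds$enrichments,
  concentrations = ds$concentrations,
  config = run_config(seed = 1, mc_replicates = 200,
                      flux_units = "umol/gDW/h")
)
wf
#> <flux_fit> S_N
#>   fluxes: r16=1.084
#>   pools:  N=0.3186
#>   objective 7.904 | chi2 dof 10 p 0.638 | converged
#> <flux_mc> S_N: 200 replicates (0 failed)
#>   r16: 1.079 +/- 0.1175 [0.8641, 1.293]
```

Reading the output: the labeling dynamics of the local input M were fitted
with an analytical curve, N's labeling was simulated from it, and the flux
through r16 was estimated at 1.08 ± 0.12 µmol/gDW/h (95% CI [0.86, 1.29]),
covering the true value 1.0 used to simulate the data; the chi-square
p-value of 0.64 says the model explains the 12 fitted observations at
their stated precision. `tidy()`, `glance()` and `autoplot()` methods on
the fit, Monte-Carlo and simulation objects give tibbles and ggplots;
`write_results()` exports a structured JSON plus fitted-curve CSV.

The same workflow scales up: merge connected subsystems into pathway-scale
flux models with `merge_subsystems()`, check the measurement requirements of
any model with `required_measurements()`, and probe the sensitivity of the
fluxes to the input representation with `input_sensitivity()`. A thin
command-line wrapper is installed under `inst/cli/subflux`
(`subflux decompose|fit|fixtures`).

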