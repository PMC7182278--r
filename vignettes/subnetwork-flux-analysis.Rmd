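---
title: "Quantifying fluxes in metabolic subnetworks from transient labeling data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fluxes in metabolic subnetworks from transient labeling data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(subflux)
```

## The problem

Isotopically non-stationary metabolic flux analysis infers intracellular
fluxes from the transient incorporation of a tracer (typically ¹³C) after a
nutrient switch. Conventionally, label propagation is modeled all the way
from the extracellular nutrient, which forces the flux model to include
every reaction between the nutrient and the pathway of interest, and the
dataset to cover uptake fluxes, biomass composition and the labeling of all
upstream intermediates. That requirement confines most flux studies to
central carbon metabolism.

subflux instead models label propagation *from the metabolic precursors of
the subnetwork of interest*. The labeling of those precursors — the **local
label inputs** — is not constant or controlled, but it can be measured; once
it is represented as a smooth function of time, the subnetwork can be
simulated and fitted on its own, with no knowledge of the surrounding
network. The workflow has four stages:

1. **Decomposition.** The atom-mapped network is decomposed into *minimal
   subsystems*: for each intermediate Y, the subsystem S\_Y contains every
   reaction producing Y (each of which may affect Y's labeling), the
   substrates of those reactions as local label inputs, and a sink reaction
   that drains Y so its pool stays constant (metabolic steady state).
   Subsystems that share a metabolite can be merged into larger flux models;
   the local inputs of the merged model are the combined inputs minus the
   metabolites that became intermediates.
2. **Input representation.** The measured enrichment series of each local
   input is fitted with an analytical curve — a logistic
   $y(t) = p_1 / (1 + e^{-p_2 (t - p_3)})$ or a double-logistic
   $y(t) = p_4 + (p_5 - p_6 t)\,\bigl[(1 + e^{(p_7-t)/p_8})^{-1} -
   (1 + e^{(p_9-t)/p_{10}})^{-1}\bigr]$ — because forcing an ODE system with
   discrete, stepwise inputs yields stiff equations and artifacts. The
   curves and their parameters carry no biological meaning; they are a
   continuous stand-in for the data.
3. **Simulation.** Label propagation through the subsystem is simulated by a
   minimal ODE system over single-atom elementary metabolite units (EMUs).
   For a simulated positional enrichment $x_{Y,k}$,
   $m_Y \frac{dx_{Y,k}}{dt} = \sum_{r \in prod(Y)} v_r\,x_{src(r,Y,k)}
   - \bigl(\sum_{r \in prod(Y)} v_r\bigr) x_{Y,k}$,
   where $v$ are fluxes and $m$ pool sizes; consumption drains a pool at its
   current enrichment and cancels against production at steady state.
   Condensations contribute one term per atom position, so mean-enrichment
   condensation is exactly a flux-weighted average of source positional
   enrichments; no isotopologue convolution machinery is needed for mean
   molecular enrichment data.
4. **Estimation.** Fluxes and pool sizes minimize
   $h(v,m) = \sum_i \bigl(\tfrac{x_i - y_i(v,m)}{\sigma_i}\bigr)^2 +
   \sum_j \bigl(\tfrac{n_j - m_j}{\sigma_j}\bigr)^2$ — weighted labeling
   residuals plus weighted deviations of the fitted pools from measured
   concentrations — under box constraints. Goodness of fit is tested against
   the $\chi^2$ distribution with (data − free parameters) degrees of
   freedom; uncertainty comes from Monte-Carlo resampling; the sensitivity
   of the fluxes to the input representation is probed by re-estimating with
   jittered input-curve parameters.

## Identifiability and measurements

The minimal measurement set for S\_Y is the labeling dynamics of its local
inputs plus the labeling of Y itself; those time courses determine the
turnover rate of Y (flux/pool), and the absolute flux follows once Y's
concentration is known. `required_measurements()` derives the exact input
requirements from the atom maps. When a product is a cleavage fragment of
its input, global (mean-enrichment) data on the product must be matched by
data on the corresponding *fragment* of the input; `fragment_series()`
extracts such fragment series from simulations, mirroring what an MS/MS
fragment measurement provides on real data. If only a metabolite-level mean
curve is available, it is used as a proxy with a warning — adequate when the
fragment's enrichment tracks the molecular mean, biased otherwise.

When an input cannot be measured at all, the subsystem is unidentifiable,
but merging it with the upstream subsystem replaces the missing input with
a measurable one; `run_workflow()` fails fast with exactly that suggestion.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| curve bounds | $0<p_1<1$, $|p_2|<100$, $|p_3|<1000$; $|p_4|,|p_5|<1$, $|p_6|<10$, $|p_7|,|p_9|<1000$, $|p_8|,|p_{10}|<100$ | mixed | box constraints that shrink the search space |
| swarm | 50 particles × 500 iterations | — | constriction-coefficient particle swarm over the box |
| local refinement | L-BFGS-B, ≤ 1000 iterations | — | never worsens the swarm optimum; multi-started from heuristic, data-informed candidates |
| flux bounds | $[0, 10^3]$ | flux units | directions of reversible reactions are split, so each directional flux is non-negative; the magnitude cap matches the conventional $|v|<10^3$ box |
| pool bounds | $[10^{-6}, 10^3]$ | concentration | |
| least squares | Levenberg–Marquardt, ≤ 50 iterations, ftol $10^{-8}$ | — | run on the log scale of fluxes and pools: parameters span decades and the flux/pool ridges of $h$ become linear |
| ODE solver | lsoda, rtol $10^{-8}$, atol $10^{-10}$ | — | stiff-capable; smooth analytical inputs keep stiffness mild |
| Monte-Carlo | 200 replicates, 2% enrichment / 10% concentration noise | — | noise follows each observation's stated standard deviation |
| enrichment sd floor | $0.02 \times \max(x, 0.1)$ | enrichment | keeps the unlabeled $t=0$ point from receiving infinite weight |

Sink fluxes are never free parameters: at every candidate flux vector the
sink of each intermediate is recomputed as production minus in-subsystem
consumption, and negative sinks (consumption exceeding production, an
infeasible steady state) are penalized. Pools with measured concentrations
are fitted, not fixed — the concentration term of $h$ is their penalty;
pools of simulated but unmeasured intermediates are free within bounds.
Starting values are deterministic: fluxes at the midpoint of the log-spaced
feasible range, pools at their measured concentrations. Degrees of freedom
count enrichment plus concentration observations; free parameters count
fluxes and fitted pools (sinks and tied fluxes excluded).

## What the synthetic generators emulate

The package validates itself on synthetic systems because the estimator's
inputs and its truth must both be known exactly.

* `example_network()` — 18 metabolites, 20 reactions: a linear pathway from
  the global input X_out, a branching node converging on F, a reversible
  reaction (r6), and a cycle through G/H/K built from a condensation and a
  cleavage. `example_truth()` fixes steady-state-consistent fluxes
  (pathway r10..r16 at 1.0 µmol/gDW/h) and pool sizes chosen once so that
  every labeling half-time is resolvable inside an 11-point sampling window
  (turnover rates of 3–20 h⁻¹ against a 1.5 h window); the converging
  branches C and D deliberately differ in turnover so their contributions
  to E are distinguishable.
* `prenyl_network()` / `prenyl_truth()` — the yeast prenyl pyrophosphate
  chain (IPP → DMAPP → GPP → FPP → GGPP by successive C5 condensations, with
  a terminal GGPP demand). The original yeast dataset is not redistributed;
  the synthetic stand-in emulates its structure: 11 sampling times (dense in
  the first minute, where the sub-minute prenyl pool lags live), a combined
  IPP+DMAPP input curve rising sigmoidally to a 0.96 plateau over ~3 min
  (the lagged rise the long mevalonate cascade produces), a chain flux of
  0.9 nmol/gDW/min, and pools giving a GGPP turnover near 13 min⁻¹. The
  chain is fitted as the merged subsystem of the three measured
  intermediates (GPP, FPP, GGPP) with a single tied pathway flux, with the
  pooled IPP+DMAPP curve forcing both C5-donor inputs.
* `random_linear_pathway()` — property-test generator: chains with
  log-uniform fluxes on [0.1, 10] (sorted decreasing so every sink stays
  feasible) and log-uniform pools on [0.01, 10].
* `make_noisy_dataset()` — Gaussian noise at 2% relative on enrichments
  (clipped to [0, 1]) and 10% on concentrations, the precision typical of
  LC-HRMS metabolomics.

These generators produce smooth, noise-controlled, steady-state-exact data.
Passing the synthetic benchmarks therefore demonstrates the correctness of
the decomposition, simulation and estimation machinery and the method's
noise robustness — it does not demonstrate robustness to model
misspecification (wrong topology, unaccounted consumption, drifting pools),
natural-abundance correction errors, or non-Gaussian measurement error,
none of which the generators emulate.

## Numerical choices

* **EMU reduction and lumping.** Backward traversal from the measured
  metabolites generates only the size-1 EMUs (positional enrichments) a
  mean-enrichment measurement needs; positions with identical producer
  structure are then lumped into one state by partition refinement (the
  GGPP system collapses from 50 positional states to 10). Full isotopologue
  cascades are deliberately out of scope until isotopologue measurements
  are declared.
* **Least-squares conditioning.** The finite-difference step of the
  Levenberg–Marquardt Jacobian is set well above the ODE solver tolerance
  (`epsfcn = 1e-6`); with machine-epsilon steps the Jacobian degenerates
  into solver noise and the search stalls. Optimization runs on
  log-transformed parameters (floor $10^{-9}$).
* **Input-fit search.** The swarm is seeded with data-informed candidates
  (plateau, amplitude, half-rise time, sharp-onset variants) and the best
  candidates are polished by multi-started L-BFGS-B plus jittered local
  restarts; the refinement stage is contractually forbidden from returning
  anything worse than the swarm optimum. Ties in family selection go to the
  logistic (fewer parameters); series shorter than nine points cannot
  support the seven-parameter double-logistic and fall back to the logistic.
* **Degenerate inputs.** Enrichment values are clipped to [0, 1] on read
  with a warning; missing standard deviations get the 2%-with-floor policy;
  analytical input functions are extrapolated for $t$ before the first
  observation (the integration starts at $t=0$) — a documented caveat of
  the continuous representation.
* **Seeds.** Every stochastic stage (swarm, Monte-Carlo, sensitivity)
  consumes an independent sub-seed derived from one master seed, so whole
  analyses are reproducible bit for bit.

## Design choices on open ground

* **One subsystem per intermediate.** A network with *n* intermediates
  decomposes into exactly *n* minimal subsystems. Co-products of a cleavage
  get separate subsystems (same reactions, different simulated metabolite);
  a joint model, when wanted, is one `merge_subsystems()` call away, and
  the pathway enumerator treats such co-products as one joint unit.
* **Merge rule.** Two subsystems may merge when they share any metabolite
  (not only when an intermediate of one is an input of the other); this is
  what lets the two fragments of a cleavage form one joint model.
* **Pathway enumeration.** `enumerate_pathway_subsystems()` returns every
  connected union of the pathway's own minimal subsystems — reproducible,
  conservative semantics; on the example pathway r10–r16 it yields 36
  candidate flux models.
* **Family selection.** The logistic-vs-double-logistic choice uses the
  small-sample corrected information criterion on the weighted SSR; the
  original method leaves this choice to the analyst.
* **Monte-Carlo scope.** Noisy replicates perturb *all* measured series —
  intermediate enrichments, concentrations, and the local-input series
  (whose curves are re-fitted locally per replicate) — because input series
  are measurements like any other.

## Problem sizes used by the validation suite

The test suite runs the full benchmarks at sizes chosen for a responsive
suite: 100 Monte-Carlo replicates for the 17-subsystem precision benchmark,
60 for the merged-subsystem comparison, 50 for the prenyl chain, 100
jitter samples per input-sensitivity analysis, and a nested coverage check
with 50 outer datasets × 80 inner replicates on a single-reaction fixture.
The package default for production analyses remains 200 replicates.

## Known limitations

* Only mean molecular enrichment measurements drive the EMU construction;
  isotopologue distributions and NMR positional data are not yet wired in.
* Fluxes are constants over the experiment (metabolic steady state);
  dynamic flux rearrangements are out of scope.
* Fragment requirements met by metabolite-level proxies bias the fit
  whenever the fragment's labeling deviates from the molecular mean; the
  proxy is warned about, not silently accepted.
* The analytical input families cover monotone and rise-then-drift
  dynamics; oscillatory labeling would need a different representation, and
  the input-sensitivity analysis should be used to check that the chosen
  representation does not dominate the flux error.
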