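---
title: "Core constraint-based models of Pelobacter metabolism: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Core constraint-based models of Pelobacter metabolism: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pelocore` analyses the central metabolism of two fermentative/syntrophic
*Geobacteraceae*, *Pelobacter carbinolicus* and *P. propionicus*, with flux
balance analysis (FBA). This vignette is the package's own account of the
model, the calibration procedures, the numerical machinery and the design
choices that were genuinely open.

## The flux-balance model

Metabolism is a stoichiometric matrix $S$ over two compartments, cytosol
(`c`) and extracellular space (`e`). At steady state every internal
metabolite balances, $S v = 0$, and a flux vector $v$ (mmol/gdw/h; the
biomass reaction in 1/h) is chosen by linear programming within bounds.
Exchange reactions connect single extracellular metabolites to the
environment; negative exchange flux is uptake, positive is secretion. The
default anaerobic minimal medium lets CO2, H+, H2O, K+, Mg2+, NH4+,
phosphate and sulfate move freely; electron donors and acceptors get
explicit maximum uptake rates; every other extracellular metabolite may
only leave.

The models are built programmatically (`buildPcarCore()`,
`buildPproCore()`) rather than shipped as static files, so that every
energy parameter enters as an argument and the calibration procedures can
rebuild the network at each candidate value. Reactions carry
charged-species formulas, and `validateModel()` proves every internal
reaction elementally balanced (and charge balanced, though the charge check
is off by default since charges are a package convention, not source data).

Protons are explicit, with separate cytosolic and extracellular pools.
Everything chemiosmotic is written as proton movement between the pools:
the sulfur reductases translocate their H+/2e- ratio, the *P. propionicus*
fumarate reductase translocates a configurable 2 H+/2e-, the ATP synthase
converts 3 extracellular protons into one ATP (configurable; the data do
not pin it), and acid products leave by proton symport. Because the
extracellular proton pool is buffered by a free exchange, care was taken
that no transporter combination pumps protons without a metabolic cost;
the two-compartment choice itself is an assumption — the organisms'
periplasmic chemistry is folded into the cytosol-to-outside step.

### The lumped biomass

The full biomass composition behind the published reconstructions is not
available, so biomass demand is lumped into the four channels that the
validation ratios actually test: acetyl-CoA (carbon and electrons; default
21 mmol/gdw, about 42 mmol C/gdw), NADPH (anabolic reducing power, 8
mmol/gdw), ammonium (nitrogen, 10 mmol/gdw) and the growth-associated ATP.
CoA and NADP+ are returned so the probe does not drain conserved pools.
The defaults are order-of-magnitude bacterial standards. One coefficient —
acetyl-CoA — is then calibrated once (`calibratedBiomassSpec()`): a
deterministic refining grid search, bounded within ±50% of the default,
matches the hydrogen-producing growth scenario to the published
acetate:2,3-butanediol secretion ratio of 1.80. That scenario was chosen as
the calibration anchor because it is the only printed fermentation ratio
that is sensitive to the biomass carbon coefficient; the acetoin-based
quantities are either unprinted or structurally independent of it (the
acetoin:butanediol yield ratio is exactly 2 for any composition, because a
butanediol route is an acetoin route plus one dehydrogenation). The
calibrated value, about 12.2 mmol acetyl-CoA/gdw, then reproduces the
acetate:ethanol ratio (0.90) and the yield ratio (2.0) without further
fitting — a consistency check, not a fit.

Sensitivity is reported by `biomassSensitivity()`: perturbing any single
coefficient by ±10% moves the optimal growth rate on acetoin by under 15%
(the GAM coefficient dominates, at about 10%).

## Energy-parameter calibration

**Chemostat maintenance regression** (`fitMaintenance()`): for each
observation the measured fluxes (acetoin uptake, acetate secretion) and the
dilution rate are fixed, the growth-associated ATP term is removed from the
biomass reaction so it is not double-counted, and the ATP-maintenance flux
is maximised; ordinary least squares of the maxima on the dilution rate
gives slope GAM and intercept nGAM ($q_{ATP} = a\,\mu + b$). Two choices
matter here. First, only the measured fluxes are fixed: ethanol and
hydrogen are stripped from a gassed chemostat, so their boundary fluxes are
unknown rather than zero, and the fitting condition leaves both exchanges
free in both directions. Neither species carries substrate-level ATP, so
the maximal maintenance flux is still pinned by the measured acetate; the
free vents simply let the carbon and electron balances absorb measurement
error instead of declaring a noisy observation infeasible. Second, the
regression is plain unweighted OLS with $R^2$ reported.

**Yield-based nGAM** (`estimateNgamFromYields()`): with GAM kept in the
biomass reaction, each growth-yield record implies an uptake flux
$\mu/Y$; fixing it together with $\mu$ and maximising the maintenance flux
measures the ATP left per hour after growth, and the estimate is the mean
over records. On noiseless synthetic records this returns the embedded
2.80 mmol ATP/gdw/h exactly.

**Sulfur-reductase stoichiometry** (`scanSreStoichiometry()`): the H+/2e-
ratios of the hydrogen-dependent (SRE) and NADPH-dependent (SRE2) sulfur
reductases are scanned over {1,2}×{1,2}; each cell rebuilds the model,
simulates growth on ethanol/Fe(III) and on hydrogen+acetate/Fe(III), and
the cell whose ethanol:hydrogen biomass-yield ratio is closest to the
observed one wins. Ties are reported in full, ordered SRE then SRE2
ascending, with a flag. One modelling commitment makes the scan
identifiable: in the ethanol scenario the NAD-linked hydrogenase is closed,
so ethanol electrons reach sulfur through SRE2 — the donor-specific
reductase assignment of the scan's own construction. Without it a
thermodynamics-blind LP would route ethanol electrons through internally
produced H2 into whichever reductase pumps more, collapsing the grid. The
orientation and expression state of the hydrogenase under Fe(III)
respiration is genuinely unknown; this is recorded as a limitation.

## Scenarios

`paperScenarios()` encodes the validation conditions. Pure-culture
fermentations close the H2 (and formate) exchanges: accumulating hydrogen
shuts down proton reduction in a closed bottle, and it is exactly the
syntrophic/gas-stripped configurations that reopen them. Printed growth
rates constrain the simulations — 0.087 1/h (*P. carbinolicus*) and 0.144
1/h (*P. propionicus*) — in substrate-minimisation mode; the Fe(III)
scenarios with unprinted growth rates run in biomass-maximisation mode at
fixed substrate uptake, where ratios of exchange fluxes are insensitive to
the uptake scale by linearity. Ratios are always computed from exchange
fluxes, never internal fluxes, because LP optima are degenerate in the
interior but the exchange pattern at the optimum is pinned by the carbon,
electron and ATP balances.

Species chemistry worth noting: the *P. carbinolicus* TCA cycle is
complete, but succinate oxidation runs only into a menaquinone pool with no
reoxidation route, so acetate cannot be oxidised to CO2 with S0 or Fe(III)
as acceptor — the model reproduces incomplete oxidation structurally. The
*P. propionicus* propionate route runs through the methylmalonyl-CoA
pathway with an NADH-coupled, ATP-free reductive carboxylation of
acetyl-CoA, and a succinyl-CoA:acetate CoA-transferase provides ATP-neutral
acetate activation — without it the acetate-consuming propanol and butanol
fermentations would be ATP-negative and infeasible. Lactate enters by a
proton antiporter by default (net gain of one translocated proton per
lactate); symport and diffusion variants are provided for comparison and
yield 20-50% less biomass. In proton-explicit accounting the symport
variant necessarily trails even anion diffusion (it imports an extra
cytosolic proton per lactate), so the package asserts what the comparison
actually supports: the antiporter wins by a wide margin.

## Synthetic data

The generators supply every input the analysis needs, seeded and
reproducible: chemostat observations at dilution rates 0.03-0.06 1/h with
the linear maintenance structure embedded, growth-yield records at 0.144
1/h, and random toy networks (at most 6 metabolites, 8 reactions, finite
bounds) whose optimum is computed by exhaustive basic-solution enumeration.
Noise is multiplicative Gaussian, truncated at ±3 standard deviations so
fluxes cannot flip sign, because flux measurement error scales with
magnitude. What the generators emulate is the *structure* of the
experiments — they are produced by the same core model the estimators
interrogate, so round-trip tests demonstrate estimator correctness, not
fidelity to the original instruments; real chemostat data carry correlated
errors, drift and biological variation that the generators do not attempt.

## Numerics

The LP solver is a dense bounded-variable two-phase primal simplex
(`R/simplex.R`): nonbasic variables sit at bounds, entering variables are
chosen by Bland's smallest-index rule (termination under degeneracy),
bound flips are handled without basis changes, and infeasibility and
unboundedness are reported as statuses, never clipped. Tolerances:
reduced-cost 1e-9, pivot 1e-10, phase-1 feasibility 1e-7; accepted
solutions satisfy $\max |S v| \le 10^{-6} \max(1, \max |v|)$ and bounds to
1e-9, which the tests assert on every optimal solution they touch. The
basis is refactorised each iteration — at 50-70 reactions per model this
costs microseconds and avoids update drift. The independent cross-check is
brute-force enumeration of basic solutions on 100 seeded toy networks.

Grid searches (biomass calibration, the 2×2 scan) are deterministic:
fixed grids, refinement by halving around the incumbent, ties broken by
ascending parameter order. Problem sizes throughout — 4 chemostat
observations, 3 yield records, 100 toy networks, models of ~60-75
reactions — keep the full test suite around a minute and the acceptance
analysis under half a minute on one CPU.

## Limitations

These are core models (~60-75 reactions), not the published genome-scale
reconstructions (~650-710 reactions); gene counts, reaction-category
totals and any quantity that depends on full biosynthetic detail are out
of reach, and the cross-model comparison reproduces the comparison logic,
not the published counts. The lumped biomass slightly exaggerates
acetyl-CoA diversion at growth, which shows up as propionate:acetate
ratios above 1:2 in the *P. propionicus* growth scenarios (exact 1:2 holds
at the catabolic limit). The ATP synthase stoichiometry, the fumarate
reductase translocation ratio and the lactate transporter mechanism are
exposed as parameters precisely because the data do not determine them;
and FBA itself is thermodynamics-blind, which is why the donor-specific
sulfur-reductase assignment must be imposed rather than derived.
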