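---
title: "Constraint-based flux analysis of developing fruit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based flux analysis of developing fruit: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fruitflux)
```

## The modelling problem

A growing fruit imports sucrose and amino acids from the parent plant and
turns them into starch, soluble sugars, organic acids, protein, cell wall and
secondary metabolites, burning part of the carbon for energy. Given
time-course measurements of the accumulated pools and of fruit biometry,
`fruitflux` estimates the flux distribution through central carbon metabolism
at each developmental stage, using the classical constraint-based recipe for
heterotrophic plant tissue:

1. **Per-fruit amounts.** Concentrations (µmol g⁻¹ DW) are multiplied by the
   fitted dry weight per fruit, because pseudo-steady-state balances apply to
   the growing organ, not to a fixed gram of tissue.
2. **Trajectory fitting and differentiation.** Each per-fruit amount is
   fitted with a low-order polynomial in time and differentiated
   analytically; the derivative, divided back by dry weight, is the net
   accumulation flux of that pool (µmol g⁻¹ DW week⁻¹). A negative value
   (e.g. starch after its peak) simply means net degradation.
3. **Flux balance with flux minimization.** At each grid time the network
   must satisfy `S v = 0` for every balanced metabolite, the accumulation
   exchanges of measured pools are pinned to the fitted derivatives, and
   irreversibility/boundary constraints apply. The remaining freedom is
   resolved by minimizing `Σ vⱼ²`, a strictly convex quadratic program whose
   optimum is unique.

The pseudo-steady-state assumption is justified by scale separation: weekly
changes in the small intermediate pools are negligible against the flux
throughput, while the large storage pools (starch, sucrose, protein, cell
wall) are handled explicitly through their accumulation exchanges.

## The stoichiometric network

The packaged plantain network (`plantain_network()`) is a curated,
non-compartmented model of pulp central metabolism: sucrose unloading and
cleavage by both sucrose synthase and invertase, the hexose-phosphate hub,
starch synthesis via ADP-glucose with phosphorolytic and amylolytic
breakdown, glycolysis, the oxidative pentose phosphate pathway, a lumped TCA
cycle, oxidative phosphorylation, and sinks for every measured biomass
component including a C15 flavonoid (polyphenol) unit built from PEP, E4P and
acetyl-CoA. Design points worth knowing:

* **Cofactors are balanced.** ATP/ADP, NAD(P)H/NAD(P)⁺, Pi and PPi are
  internal metabolites, so the network is constrained through its energy and
  redox status, not only through carbon. A maintenance ATPase and a
  transhydrogenase-like NAD(P)H exchange keep the energy/redox balance
  feasible for any reasonable demand.
* **Lumping.** UTP/UDP are represented by ATP/ADP (UDP-glucose still costs
  one nucleotide charge); the FADH₂ step of the TCA cycle is folded into
  NADH; respiration uses a fixed P/O-style yield of 2.5 ATP per NADH.
  These are conventional simplifications for non-compartmented models; the
  network file is plain TSV and users can swap in their own reaction table.
* **Phosphorus supply.** Because hexose phosphates are accumulated species,
  the model needs a phosphate import (`EX_PI`/`T_PI`); without it the
  equality system is structurally inconsistent (the phosphorus moiety is a
  left null vector of `S` touching only the hexose-phosphate exchanges).
* **Carbon audit.** `check_carbon_balance()` verifies
  `Σ coefficient × carbon_count = 0` for every interconversion reaction; CO₂
  is explicit, so decarboxylations balance without exemptions.
* **Boundary construction.** Exchange reactions are one-sided and touch
  exactly one non-internal metabolite. Every metabolite row is balanced at
  pseudo-steady state; accumulation is carried by the exchange flux itself.
  This keeps measured pools connected to the network (the equality count is
  `n_metabolites + n_measured` per stage).

## Fitting choices

* **Degrees.** Dry weight (and fruit volume) are fitted with cubics — the
  conventional description of sigmoid single-organ growth, whose derivative
  captures the three growth phases. Measured pools are fitted by
  `select_degree()` over degrees 1–3.
* **Degree selection.** Among candidate degrees, a higher degree is accepted
  only if it raises the adjusted R² *and* its extra terms pass a nested
  F-test at α = 0.05 (or reduce a nonzero residual to exactly zero). A pure
  adjusted-R² rule would accept a spurious extra term whenever its partial
  F exceeds 1, which happens about a third of the time regardless of noise
  level; the F-guard keeps the selection parsimonious while still picking the
  true degree on clean data.
* **Replicates** enter fits as individual points. Tables of means are
  accepted transparently (they are just one "replicate").
* **Clipping.** If a fitted amount dips below zero anywhere on the solve
  grid, the pool is treated as absent there: the flux is set to 0 and a
  warning is issued. This protects the solver from artefacts of polynomial
  extrapolation in near-zero pools.
* **Onset of net starch breakdown** is the vertex `−b/(2a)` of a quadratic
  fit of the per-fruit starch amount; it requires a negative leading
  coefficient and errors otherwise.

## The quadratic program and its solver

At each stage the problem is
`min ½ vᵀWv + cᵀv` subject to `S v = 0`, `v_j = b_j` for measured
accumulation exchanges, and `lb ≤ v ≤ ub`, with `W` the identity by default
(per-reaction weights are configurable). Bounds: irreversible reactions have
`lb = 0`; reversible ones `−10⁴`; all fluxes are capped at 10⁴ µmol g⁻¹ DW
week⁻¹, a deliberately loose ceiling standing in for unspecified transporter
capacities.

The solver is a dual active-set method of Goldfarb–Idnani type specialised to
diagonal Hessians: it starts at the unconstrained minimizer, repeatedly adds
the most violated constraint with primal/dual steps that preserve dual
feasibility, and drops blocking constraints as their multipliers reach zero.
Strict convexity makes it finite, deterministic and phase-1-free, and it
detects inconsistent constraint systems (reported with the offending row).
Feasibility tolerance is 10⁻⁹ scaled by the constraint magnitude; optimal
solutions carry steady-state residuals around 10⁻¹², and two runs of the
same problem agree coordinate-wise (the optimum is unique). The test suite
cross-checks the solver against the pseudoinverse least-norm closed form on
equality-only instances and against exhaustive active-set enumeration on
small box-constrained instances.

When hard equality constraints conflict — typically from noisy derivative
estimates — `relax_and_diagnose()` turns the measured-exchange equalities
into quadratic penalties (`weight × (v_j − b_j)²`, default 10⁶, per-constraint
weights allowed), keeping steady state and bounds hard. The slack report,
sorted by magnitude, points at the constraint that does not fit the others;
down-weighting a suspect measurement concentrates the slack there. As the
weight grows the relaxed solution converges to the hard solution whenever one
exists (checked at weight 10⁸ in the tests). A problem that is all-zero on
the right-hand side with non-negative bounds yields `v = 0` and is reported
optimal, not as an error.

## The synthetic-study generator

`default_plantain_scenario()` encodes the study design the pipeline assumes:
2 cultivars × 6 sampling weeks (2–12 WAE) × 5 replicate fruits, with
multiplicative log-normal noise. Its ground truth is built so that every
pipeline stage has a known answer:

* Dry weight per fruit follows a sigmoid-shaped cubic (5 → 40 g across the
  window, growth rate peaking near 7 WAE; plausible for plantain pulp).
* Every per-fruit pool is a **cubic**, so its accumulation flux is an exact
  quadratic and, on noise-free data, degree selection over 1–3 recovers the
  trajectories exactly — recovery failures then indicate pipeline defects,
  not representational limits.
* The per-fruit starch pool has its stationary maximum at exactly 9.3 WAE
  (cultivar AG) and 10.2 WAE (cultivar OB); per-gram starch stays within
  260–580 µmol g⁻¹ DW, the scale of measured plantain pulp; sucrose
  concentration rises after week 8; sugar pools start high and decline.
* Structural pools (protein ≈ 450, cell wall ≈ 600, amino acids ≈ 50,
  malate ≈ 30, polyphenols ≈ 20 µmol g⁻¹ DW; hexose phosphates at a few
  µmol g⁻¹ DW) are proportional to dry weight, so their per-gram accumulation
  flux scales with the relative growth rate — highest at 2 WAE. This makes
  glycolysis, the TCA cycle and especially respiration carry their largest
  fluxes at the earliest stage and decline through development, the
  qualitative pattern expected of a fruit whose early growth is dominated by
  cell division.
* Ground-truth *internal* fluxes are **defined** as the minimum-norm
  completion of the truth exchanges. Recovery tests therefore test the
  pipeline (fit → differentiate → solve), not the identifiability of
  arbitrary internal fluxes, which a single objective cannot promise.
* Noise is multiplicative log-normal with bias correction
  (`exp(σZ − σ²/2)`, `σ² = log(1+cv²)`, mean exactly 1); the default
  cv = 0.15 is a plausible assay coefficient of variation, declared as a free
  parameter because the reference tables print no dispersion. Seeds expand
  into per-table substreams through fixed counter offsets, so adding a table
  never perturbs existing draws and regeneration is bit-identical.

What the generator deliberately does **not** emulate: within-fruit sampling
structure, heteroscedastic assay error, missing replicates, cultivar ×
environment interactions, or measurement bias. Passing recovery tests
therefore show the pipeline is faithful to its own model class, not that real
plantain data meet these assumptions.

## Downstream statistics

* `metabolite_ratio()` reproduces ratio summaries of the concentration table;
  the pooled-mean mode averages cultivar means before dividing ("on average
  across the two cultivars"); per-cultivar ratios are available.
* `pearson_screen()` computes Pearson r with exact two-sided p-values via the
  t transform and Benjamini–Hochberg adjustment across all tested pairs
  (method configurable through `p.adjust`). Zero-variance vectors are
  excluded from the FDR family and flagged.
* `two_way_anova_lsd()` fits `value ~ week * cultivar` with type-II sums of
  squares (robust to the mild imbalance of losing replicates late in a
  study), then compares cell means with Fisher's unprotected LSD on the
  pooled residual variance. The compact letter display uses the
  insert-and-absorb construction; letters are ordered so that 'A' contains
  the smallest mean, and the display is validated against the
  non-significance graph by brute force in the tests. With a single cultivar
  the model collapses to a one-way ANOVA on week.

## Problem sizes and numerical conventions

The shipped analyses use: a 38-metabolite × 55-reaction network; a 0.5-week
solve grid over 2–12 WAE (21 stages per cultivar); 50 seeded regenerations
for the stochastic recovery summary, whose median relative error uses a
relative floor of 1% of the largest truth flux so that grid points where a
flux crosses zero do not dominate; 1000 simulations for the ANOVA null-size
check. Polynomial coefficients are stored lowest-degree first; stoichiometric
coefficients are kept as parsed rationals and assembled into floating point
only at solve time; R² is defined as 1 when residual and total variance are
both zero.

## Known limitations

* Non-compartmented by construction: plastidic and cytosolic reactions share
  one pool space, so cycles that exist only between compartments are
  invisible and minimum-norm suppresses futile cycling by design.
* The minimum-norm objective is a modelling choice; fluxes not pinned by
  measurements are the smallest-norm completion, not measurements.
* No error propagation from fit uncertainty into flux confidence intervals;
  the stochastic recovery summary quantifies typical, not per-flux, error.
* Spline/GAM smoothing, flux variability analysis, thermodynamic constraints
  and dynamic FBA are out of scope.
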