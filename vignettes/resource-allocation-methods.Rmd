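---
title: "Constraint-based resource allocation in black soldier fly larvae: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based resource allocation in black soldier fly larvae: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larvaflux)
```

## The modeling problem

*Hermetia illucens* (black soldier fly, BSF) larvae convert low-value
substrates into protein and high-value fatty acids, most prominently
lauric acid (C12:0). How dietary changes — more glucose, more essential
amino acids — redistribute that conversion is a resource-allocation
question that constraint-based metabolic modeling answers at steady state:
given a stoichiometric network $S$ and flux bounds $l \le v \le u$, flux
balance analysis (FBA) solves

$$\max_v \; v_{\text{biomass}} \quad \text{s.t.} \quad S v = 0,\; l \le v \le u,$$

and flux variability analysis (FVA) reports, per reaction $j$, the range
of $v_j$ attainable while the biomass flux stays at or above a fraction
$\gamma$ (here 0.9) of that optimum. The larva's measured composition
enters as the biomass reaction; its measured diet enters as exchange
bounds in mmol per larva per day, the unit used throughout the package.

`larvaflux` implements this pipeline end to end: model containers and
readers/writers (SBML Level 3 + FBC, COBRA JSON, a tabular CSV dialect),
biomass construction from composition assays, diet-to-bound conversion,
FBA/FVA on a built-in LP solver, model quality control, the dietary
carbon-conversion-efficiency statistic, and a deterministic generator of
small larva-like networks with known analytic optima.

## The biomass objective reaction

The biomass reaction consumes precursor pools in proportion to the
measured dry-weight composition and produces one unit of a `biomass`
pseudo-metabolite, so its flux is the growth rate in larva dry weights
per day. Construction (`build_biomass_spec()`):

1. **Normalization.** Assayed macromolecule classes (amino acids, fat,
   glycogen, sugars, glycerol) are renormalized to mass fractions after
   dropping water, ash and unassayed carbohydrates.
2. **Cholesterol grafting.** Cholesterol was not assayed but is a major
   membrane lipid; a donor-model mass ratio (default 0.02, configurable in
   $[0, 0.2]$) is inserted and the assayed classes rescaled.
3. **TAG expansion.** Storage fat is split over two lumped
   triacylglycerols, TAG(12:0/14:0/16:0) and TAG(16:1/18:1/18:2), covering
   the six most abundant measured fatty acids (92.14 g per 100 g fat).
   The declared A:B split is 0.49/0.51; `select_tag_composition()` can
   instead recompute it from the profile (0.495/0.505).
4. **Amino-acid expansion.** The amino-acid class is distributed over the
   twenty dietary amino acids by the mg-per-100-g-protein profile. Free
   and protein-bound amino acids are not distinguished; the sulfur amino
   acid is carried as cystine, the dimer the assay reports.
5. **Mass-to-mole conversion.** Each coefficient is
   $\text{fraction} \times DW / M$ with molar masses derived from Hill
   formulas, which makes mass closure an identity:
   $\sum_i |c_i| M_i = DW$ to 1e-9.

The larva dry weight default is $0.3 \times 0.028$ g — the measured final
wet weight under the common 70%-moisture convention — and is a parameter,
because only the wet weight was measured. The default macromolecule
assay (70 amino acids / 16 fat / 6.3 glycogen / 4.7 sugars / 1.0 glycerol
g per 100 g DW before cholesterol insertion) is chosen so that the
normalized composition lands exactly on the validated dry-weight ratios
(70% amino acid, 16% fat) after the 2% cholesterol graft.

## Diet constraints

The feeding experiment supplies masses: glucose fully consumed (846 g),
egg-white protein partially (560 g of 1870 g), over 9 days. Under the
linear-consumption assumption the chain
g → mg/larva/day → mmol/larva/day (`aa_rates()`) reproduces the published
per-larva amino-acid rate table to three decimals using standard molar
masses (cystine as the 240.30 g/mol dimer).

Two published larva-count figures are mutually inconsistent with the
per-larva rates; the package therefore takes the printed per-larva rates
as the diet description and derives the count that makes totals and rates
commensurate (`implied_larva_count()`, 5357), which fixes the glucose rate
at $846 / 180.16 / (5357 \times 9) = 0.0974$ mmol/larva/day. Dietary
cholesterol is assumed available and non-limiting (0.01 mmol/larva/day by
default) since sterols are required but were not part of the dietary assay.

`apply_diet()` encodes an uptake limit $u$ as a lower bound $-u$ on the
exchange flux (negative flux = uptake), closes all unlisted exchanges to
uptake, and leaves freely exchanged species open: water, O₂, CO₂,
phosphate, sulfate, ammonia — plus protons, which the neutral-formula
bookkeeping uses as its hydrogen-balancing species.

## The LP engine and its validation

No dedicated linear-programming package is available to this package at
runtime, so FBA and FVA run on a built-in dense bounded-variable two-phase
primal simplex (`solve_lp()`): Dantzig pricing with an automatic permanent
switch to Bland's rule after 60 stalled iterations (guaranteeing
termination), pivot tolerance 1e-9, basic values refreshed from the basis
inverse every iteration. Status is always faithful: `optimal`,
`infeasible` or `unbounded`, never a silent fallback.

Validation is dual-route: on random networks of up to 8 reactions, FBA
optima and FVA extrema are compared against an exhaustive
vertex-enumeration oracle (agreement to 1e-7) that shares no code with the
simplex; every optimal solution must satisfy
$\|S v\|_\infty \le 10^{-6} \max(1, \|v\|_\infty)$. FVA constrains the
objective by tightening the objective reaction's own bound to
$\gamma z^*$ — the standard construction, identical in polytope to an
extra constraint row. Because the two FVA extrema are independent LPs,
roundoff can invert a degenerate min/max pair by ~1e-12; such inversions
are snapped to their midpoint.

## The synthetic larva network

`generate_network()` builds a three-compartment
(extracellular/cytosol/mitochondrion) network that emulates the
architecture the pipeline is designed for:

* exchanges and irreversible uptake transports for the 20 dietary amino
  acids, glucose and cholesterol; reversible exchanges for the free
  species above;
* a lumped glycolysis + pyruvate-dehydrogenase reaction (glucose →
  2 acetyl-CoA + 2 ATP), a mitochondrial acetyl-CoA oxidation +
  oxidative-phosphorylation lump (10 ATP per acetyl-CoA), and an
  oxidative pentose-phosphate lump (12 NADPH per glucose);
* one lumped, elementally balanced synthesis reaction per fatty acid,
  with the canonical FAS cost structure ($n/2$ acetyl-CoA, $n/2-1$ ATP,
  $n-4$ NADPH for a C$_n$ saturated chain) and desaturations consuming O₂
  plus reduced cytochrome b5; the cytochrome-b5 reductase recharge
  reaction gates oleate and linoleate synthesis, so removing it blocks
  them;
* two lumped TAG-assembly reactions (glycerol + 3 acyl groups + 3 ATP),
  glycerol/glycogen/trehalose pool synthesis (trehalose is the insect
  blood sugar and stands for the sugar class);
* per-amino-acid catabolic lumps (deamination to acetyl-CoA units, CO₂,
  NH₃, and sulfate for the sulfur species), so surplus dietary amino-acid
  carbon is available for lipogenesis as it is in the animal;
* the composition-derived biomass reaction, a biomass drain, one demand
  drain per fatty acid, and (optionally) balanced decoy dead-end
  reactions, because real reconstructions carry such artifacts.

Every internal reaction except the biomass assembly is elementally
balanced; reactions are balanced at generation time by solving for their
water and proton coefficients after all other elements balance by
construction, and generation fails loudly if any other element cannot be
balanced. The biomass reaction consumes a formula-less pseudo-metabolite
and is deliberately reported by the balance QC as unparseable — the same
category a curated reconstruction's biomass lands in.

**Analytic optimum.** Each amino acid has exactly one source (uptake), so
the growth rate is capped at $\min_i u_i / c_i$ over precursors; under the
reference diet the binding precursor is glutamine/glutamate and carbon
and energy are strictly slack (verified by glucose-doubling invariance),
so the LP optimum equals that closed form to 1e-9. This is what makes
every downstream stage testable without any external model file:
doubled glucose changes growth by exactly 0%, scaling all uptakes by $k$
scales the optimum by exactly $k$, and the fatty-acid drain FVA maxima
rise when glucose doubles.

**Randomness.** The seed only shuffles metabolite/reaction order and
names the decoys; topology and coefficients are deterministic, so
identical parameters give byte-identical model files and the analytic
optimum holds for every seed.

**What the stand-in does not emulate.** The published 407-reaction
reconstruction has redundant internal routes, amino-acid biosynthesis,
and saturated drain capacity. Three consequences, asserted as such in the
tests rather than papered over: (i) doubling the essential amino acids
moves nothing here because the bottleneck amino acid derived from the
dietary profile is non-essential — the +32% growth response is a property
of the published model, not of this topology; (ii) likewise doubled
valine (+2% there) is neutral here; (iii) doubled glucose raises drain
maxima faster than total carbon intake, so the carbon-conversion
efficiency *rises* on the stand-in, whereas the published, more saturated
network shows a drop. The CCE tests therefore assert the exact rescaling
law (efficiency ratio = drain ratio / carbon-intake ratio) and the
orientation duality, not the sign of the change. Passing tests
demonstrate correctness of the machinery, not numeric agreement with the
published model's results.

## Model quality control

Four statistics, reported as percentages to two decimals
(`qc_report()`): dead-end metabolites (can only be produced or only
consumed, given bound directionality), blocked reactions (zero flux in
every feasible solution, decided by two LPs per reaction with exchanges
opened to ±1000 first — configurable to as-given bounds, since either
convention is defensible), elementally unbalanced reactions (computed
over *all* reactions; exchanges are intrinsically unbalanced and
formula-less metabolites make a reaction unparseable-but-counted), and
exchange reactions (single-metabolite boundary reactions). Charge balance
is checked when charges are present but excluded from the unbalanced
statistic.

## Carbon conversion efficiency

For fatty acid $f$ with drain rate $d$ (the FVA maximum at 90% of the
optimum) and diet uptake limits $u_i$ with per-molecule carbon counts
$C_i$:

$$\text{CCE}_{\text{printed}} = 100 \cdot \frac{\sum_i C_i u_i}{C_f d},
\qquad
\text{CCE}_{\text{efficiency}} = 100 \cdot \frac{C_f d}{\sum_i C_i u_i}.$$

The printed orientation is the formula as published; the efficiency
orientation is its reciprocal and is what the accompanying narrative
("efficiency dropped") describes. Both are computed and labeled
(`compute_cce()`, default `"efficiency"`); they satisfy
printed × efficiency = 10000 identically, which the tests assert. Carbon
counts come from metabolite formulas, with an override table for
formula-less species.

## Numerical and reporting conventions

* Default flux bounds ±1000 mmol/larva/day when a file omits them.
* LP tolerances 1e-9 (pivot), 1e-7-relative (phase-1 feasibility);
  steady-state acceptance 1e-6 relative.
* Blocked-reaction flux threshold 1e-6.
* Display rounding is round-half-away-from-zero (`round_half_away()`), so
  19.8 → 20 and 2.5 → 3; percentages print with two decimals, headline
  shares as integers.
* Degenerate FBA optima return one optimal vertex without tie-breaking
  guarantees; all reported statistics use objective values or FVA
  extrema, which are unique.

## Problem sizes

The default synthetic network has 90 metabolites and 113 reactions — large
enough to exercise all three compartments, all seven fatty-acid routes
and the full diet, small enough that a full QC scan (two LPs per
reaction) and the drain FVA run in seconds. Tests use a 3-amino-acid,
2-fatty-acid reduction (about 50 reactions) for whole-model scans and
networks of 4–8 reactions for oracle comparisons; the
relaxation-monotonicity property is checked over 100 seeded random
networks.

## Known limitations

* No growth- or non-growth-associated ATP maintenance is estimated; the
  lumped energetic costs are literature-standard pathway sums, not fitted.
* GPR strings are stored and round-tripped, never evaluated.
* No MATLAB `.mat` dialect; no parsimonious FBA, MOMA, thermodynamic or
  dynamic extensions.
* The consumption model is linear in time; residue-composition kinetics
  are out of scope.
* The published reconstruction's headline numbers (+32% growth under
  doubled essential amino acids, +2% under doubled valine, 2.45% dead-end
  metabolites) require that model file as input; the package reads it
  (SBML or COBRA JSON) when available but does not bundle it.
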