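---
title: "Coupling Boolean nutrient signaling to enzyme-constrained metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupling Boolean nutrient signaling to enzyme-constrained metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`boolec` simulates how nutrient signaling reshapes the metabolism of
budding yeast by joining two model classes that live on different time
scales: a Boolean network for the fast signaling layer, and an
enzyme-constrained stoichiometric model (ecModel) for the metabolic steady
state. This vignette is the package's account of the science: the models
and their assumptions, the parameters that matter, the numerical choices,
and what the packaged synthetic assets can and cannot show.

## The metabolic layer

The metabolic state is a steady-state flux distribution `v` obtained by
linear programming: mass balance `S v = 0` over internal metabolites,
bounds `lb ≤ v ≤ ub`, and a linear objective. Flux units are mmol/gDW/h
throughout; unit conversions happen only at file boundaries.

Enzyme constraints follow the GECKO construction. Each enzyme becomes a
pseudo metabolite consumed by its catalyzed reactions with coefficient
`−1/kcat` (kcat in 1/h), supplied by a usage pseudo reaction `e_j`
(mmol/gDW/h), which in turn draws `Mw_j` grams per mmol from a single
protein-pool metabolite. The pool exchange is capped at `f·σ·P_tot`
(g/gDW):

* `P_tot = 0.46` g/gDW — total cellular protein;
* `f = 0.1732` — the mass fraction of the proteome covered by the model;
* `σ` — an average enzyme saturation factor, the one free parameter, fitted
  (see *Calibration*).

Reversible reactions are split into forward/backward irreversible pairs
(`_fwd`/`_rev`), so backward flux also pays enzyme; reactions with N
isoenzymes are expanded into N parallel arms (`_No1..NoN`); complex
subunits all enter the same arm; a gene-annotated reaction whose kcat is
explicitly marked missing passes through unconstrained — silent defaulting
is rejected at transformation time.

Because usage pseudo reactions are tied to catalysis by exact mass
balance, `e_j` always equals the enzyme demand of the fluxes it supports;
"idle" enzyme does not exist in this formalism. That identity is what
makes usage perturbations (below) propagate into fluxes.

The growth-associated ATP requirement (GAM) of the biomass reaction is a
piecewise-linear function of growth rate: 18→25 mmol ATP/gDW across the
respiratory regime (0 to the critical dilution rate) and 25→30 across the
fermentative regime (critical rate to 0.4 1/h). `apply_gam()` materializes
the coefficient for a given D just before each solve.

## The signaling layer

The Boolean layer is a vector-based network: proteins and enzymes carry
`present` and `state` (phosphorylation/conformation) bits, metabolites and
target-gene groups a single `value` bit. Rules are if/then/else clauses
evaluated synchronously — every field is recomputed from the previous
state only — and every rule carries an else branch, so the network also
relaxes when the conditions for a modification disappear (gap-filling in
place of poorly characterized phosphatases). Crosstalk clauses carry an id
and can be switched off individually, in which case the base rule applies.
Knockouts force a component's presence to 0 before and after each update.

Iteration stops at a fixed point; a recurring non-fixed state is reported
as a limit cycle (a first-class result, though the packaged network
reaches fixed points under all input combinations). Activity projection
maps each component's fields to one bit (e.g. present AND not
inhibitory-phosphorylated) for plotting and for the regulatory coupling.
Successive nutrient conditions chain: each steady state seeds the next
condition, the first starting from the all-starved steady state.

The packaged ruleset covers the PKA chain
(Gpr1/Gpa2/Cdc25/Ira/Ras/Krh/AC/PKA/Rim15/Msn2,4/Gis1), the SNF1 chain
(Sak1/Reg1/Glc7/Snf1/Mig1/Cat8/Sip4/Adr1), the TORC1 chain
(EGO/TORC1/Sch9/Sfp1/PP2A/Rtg1,3/Gat2/Gln3), target-gene groups, and five
crosstalks (PKA⊣Adr1, PKA→Reg1, Snf1⊣TORC1, Snf1⊣PP2A, Snf1⊣AC). It was
curated so that the qualitative steady states and the characteristic
dynamics hold: on glucose depletion Adr1 activates two iterations after
Snf1 because the PKA inhibition must decay first, while on glucose
addition PKA inactivates Adr1 before Snf1 itself is dephosphorylated.
Deletions of Snf1, Reg1, PKA and TORC1 reproduce the expected pathway-level
phenotypes (the tests assert each). It is a reduced reconstruction, not a
complete mechanistic inventory; per-rule provenance lives in the ruleset
JSON notes.

## The regulatory coupling

Transcription-factor activities at the Boolean steady state act on genes
through a signed edge list. Effects on one gene are summed and only the
sign kept — two active repressors and one active activator net to −1, and
stronger sums do not regulate more strongly. Gene directions move
enzyme-usage bounds relative to the *parsimonious* usage `e_opt`
(minimum total protein at fixed growth and glucose uptake) and the usage
variability range `[e_min, e_max]` (per-enzyme min/max usage under the
same fixed context):

* upregulated: `lb ← e_opt + RF·(e_max − e_min)`
* downregulated: `ub ← e_opt − RF·(e_max − e_min)`

with `RF = 0.05` by default (uniform across genes; per-gene factors are
possible but default to uniform, a known simplification). Bounds are then
clamped: `lb ≤ e_max`, `ub ≥ 0`, and on an up/down collision within one
enzyme the lower bound wins.

Clamping keeps each enzyme inside its own variability range, but
per-enzyme ranges say nothing about joint capacity: an adversarial
activity pattern can cap every isoform of an essential reaction at once
and make the fixed-growth context infeasible. `regulate_guarded()`
therefore verifies the regulated LP and, only if it is jointly infeasible,
releases the downregulation caps with a warning. Activity patterns the
packaged Boolean network actually reaches never trigger the guard (this is
a tested property); it exists for robustness under arbitrary inputs.

## The chemostat protocol

For each dilution rate D of a sweep:

1. growth is fixed to D (both bounds) and glucose uptake minimized,
   giving `vGlcIN_min` — glucose-limited cells are assumed to maximize
   biomass yield;
2. the uptake window `[vmin, (1+SF)·vmin]` is opened with SF = 0.15,
   giving regulation room to act suboptimally;
3. `vmin` is discretized against a threshold uptake — the uptake at the
   model's critical dilution rate; the boundary counts as "low" — and fed
   to the Boolean layer, which runs to steady state (chained from the
   previous D, the first from the starved state);
4. TF activities are projected and per-gene directions derived;
5. parsimonious usages and variability ranges are computed at
   `(D, vmin)` (recomputed per D; at this scale that costs little) and the
   regulated bounds applied;
6. a final glucose-minimizing FBA runs under the regulated bounds.

Every stage's artifacts are retained per D. Deletion strains apply their
knockouts in the Boolean layer only. Nitrogen stays at 1 across the sweep.

## Degeneracy and determinism

FBA optima are rarely unique. Every reported solution therefore passes a
three-stage resolution: optimize the primary objective; fix it and
minimize the protein-pool draw (`Σ Mw_j e_j`); fix that too and minimize
total flux `Σ v`. The last stage removes both alternate-isoform and
futile-cycle degeneracy, which a usage-sum tie-break alone would not, and
makes runs bit-identical — also guaranteeing that an `RF = 0` sweep equals
the unregulated sweep flux-for-flux (a tested property).

## Flux control coefficients

Control of enzyme *i* over flux *j* is `(a_i/v_j)·∂v_j/∂a_i` with activity
`a_i = kcat·e_i`. It is measured by finite perturbation: fix `e_i` at
`e_i*(1±0.001)` relative to the parsimonious reference and re-minimize
glucose uptake. The direction is upward first, downward if the upper bound
blocks it, and if both directions are blocked the enzyme's turnover
numbers are scaled by `1.001` instead (recorded as mode `"kcat"`); a
forward difference is used and the mode is kept in the output. A zero
reference usage gives control 0; a zero reference flux yields an explicit
undefined marker. Values are robust to halving the step (<1% change,
asserted on the fixtures).

Two behaviors are worth naming. In the unregulated fixture the single
active hexokinase isoform carries a control coefficient of exactly 1: its
usage ties one-to-one to uptake through the enzyme balance, and no other
route can absorb the perturbation. After regulation both isoforms carry
flux with one bound taut on each side, every perturbation is absorbed by
the partner isoform, and both coefficients drop to 0 — as does that of any
enzyme carrying an induced futile flux, since cycling absorbs its
perturbation for free.

## Calibration

*Saturation factor.* `calibrate_sigma()` bisects σ so that the first grid
point (resolution 0.005 1/h) with positive ethanol excretion matches the
target critical dilution rate, 0.285 1/h by default. Ethanol onset is
located by bisection over the grid, exploiting that the D axis is ordered
respiratory → fermenting → infeasible. The fitted fixture value is ≈0.39;
doubling all kcats halves it (a tested scaling law).

*GAM.* `calibrate_gam()` grid-searches the per-regime linear range
endpoints, minimizing the median relative error of predicted glucose,
oxygen, CO₂ and ethanol exchange against a reference table. The regimes
are fitted independently because each GAM value only affects growth rates
in its own regime. Validation is by parameter recovery on self-generated
references — the package ships no external chemostat dataset.

## The synthetic fixture

The packaged fixture is a ~20-reaction central-carbon scaffold: glucose
uptake; hexokinase with a slow (HXK1) and a fast (HXK2) isoform; lumped
glycolysis; a kcat-free, gene-annotated pentose phosphate shunt supplying
NADPH; pyruvate branching into fermentation (PDC, reversible ADH),
respiration (the PDA1/PDB1 PDH complex, lumped TCA, internal/external NADH
dehydrogenases), and acetate (the promiscuous Ald6 — NAD- and
NADP-dependent — plus Acs1); a glycerol branch as the fermentative redox
valve; a free ATP-dissipation reaction (no fixed maintenance, so zero
growth needs zero glucose); and a biomass pseudo reaction (5 g6p + 8 pyr
+ 2.5 NADPH + GAM ATP per gDW). Turnover numbers and molecular weights are
in physiological ranges and chosen once so that respiration yields more
ATP per glucose while fermentation yields more ATP per unit enzyme mass —
the tension that produces a unique respiro-fermentative switch when the
protein pool tightens. The regulatory fixture wires Cat8/Sip4/Adr1/Mig1 to
the fixture genes so that glucose derepression upregulates the slow
hexokinase isoform, the external NADH dehydrogenase and the acetate
branch, represses the fast isoform and PDC, and induces ADH cycling.

What the fixture does *not* emulate: genome-scale redundancy (dozens of
isoenzyme families, alternative pathways), thermodynamic or metabolomic
constraints, measured kcat uncertainty, compartment-specific cofactor
shuttles beyond the two NADH pools, and real proteomics error structure
(the synthetic tables use i.i.d. log-normal noise with optional dropout).
Passing tests on the fixture therefore demonstrate the machinery — the
transformation, the coupling, the calibrations, the statistics — not the
predictive accuracy of any particular yeast reconstruction.

## Numerical choices

* **Solver.** All LPs go through a dense bounded-variable primal simplex
  implemented in the package (two phases, Bland's anti-cycling rule).
  Enzyme-constrained LPs are small but badly scaled (usages ~1e−5 against
  fluxes ~10) and highly degenerate; columns are scaled to O(1) by their
  bound magnitude, rows equilibrated, and linearly dependent balance rows
  (conserved cofactor pairs) removed by QR factorization, with the dropped
  rows re-verified on every solution. `boot::simplex` and
  `pracma::linprog` remain selectable and serve as independent
  cross-checks in the test suite.
* **Tolerances.** Feasibility 1e−9, zero-flux 1e−6 — declared once
  (`lp_tolerances()`) and used everywhere, because variability ranges and
  control-coefficient difference quotients are tolerance-sensitive.
* **Infinite usage bounds** are replaced at solve time by the implied cap
  `pool capacity / Mw`, which is mathematically equivalent and keeps the
  scaling sane.
* **Problem sizes.** The packaged analyses run the fixture (37 reactions
  after transformation) over dilution grids of 0.005–0.05 1/h resolution;
  a full sweep plus variability analysis and control coefficients
  completes in seconds, which is what makes the property-style tests (100+
  LP solves each) practical.

## Known limitations

* Regulation is directional and uniform (±RF of the variability range);
  no magnitude-weighted TF effects, promoter logic, or TF concentrations.
* Coupling is strictly at the Boolean steady state; no dynamic FBA or
  transient coupling.
* The Boolean engine is synchronous and deterministic by design;
  asynchronous or stochastic updating schemes are out of scope, as is
  exhaustive attractor enumeration.
* EVA is computed at the fixed minimal uptake, not across the
  suboptimality window; bounds derived from it are clamped (and guarded)
  rather than re-derived per window position.
* SBML support is a minimal read-only ingest (species, reactions,
  reversibility); curated models are expected in the native TSV/JSON
  dialects.
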