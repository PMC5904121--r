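---
title: "Designing methanol-essential E. coli: models, estimators and their assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing methanol-essential E. coli: models, estimators and their assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rumpdesign)
```

## The design problem

A heterotroph equipped with an NAD-dependent methanol dehydrogenase (Mdh)
and the ribulose monophosphate (RuMP) entry enzymes — hexulose-6-phosphate
synthase (Hps) and 6-phospho-3-hexuloisomerase (Phi) — can in principle
assimilate methanol: Mdh oxidises methanol to formaldehyde, Hps condenses
formaldehyde with ribulose 5-phosphate (Ru5P) to hexulose 6-phosphate, and
Phi isomerises it to fructose 6-phosphate (F6P). In practice the cell simply
ignores the synthetic pathway while a multi-carbon substrate is available.
The design strategy implemented here couples methanol consumption to
fitness: find gene deletions under which growth on a co-substrate is
impossible *unless* methanol is co-assimilated, while the potential for
growth on methanol alone is retained. Such a strain can then be improved by
laboratory evolution, because every extra unit of methanol flux is selected
for.

The computation is flux balance analysis (FBA): maximise the flux through a
lumped biomass reaction subject to steady-state mass balance `S v = 0` and
flux bounds, where `S` is the stoichiometric matrix. A knockout fixes the
affected reaction fluxes to zero; a medium sets which exchange reactions may
run in the uptake (negative) direction. A genotype is classified on three
diagnostic media — co-substrate alone, co-substrate plus methanol, methanol
alone — against a growth threshold `eps = 0.01 h^-1` at an uptake bound of
7 mmol gCDW^-1 h^-1 per carbon source.

### Classification rule

A knockout set is *methanol essential* when

* growth on the co-substrate alone is at or below `eps`,
* growth on co-substrate plus methanol exceeds `eps` **and** exceeds growth
  on methanol alone by more than `eps`, and
* (by default) growth on methanol alone still exceeds `eps`.

The middle clause deserves a note. Because the augmented wild type grows on
methanol alone, *any* genotype grows once methanol is present; a naive
"grows with methanol" test would classify a co-substrate transporter
knockout as methanol essential although methanol does not rescue
co-substrate use at all — the strain has merely become a pure methylotroph
candidate. Requiring a strict growth advantage of the mixed medium over
methanol alone restores the intended meaning of "rescued by methanol":
transporter and kinase knockouts of the co-substrate become non-rescuable
and are discarded, exactly as in the screening workflow this package
implements.

## The packaged core model

Knockout screening needs a model. The package ships a hand-built reduced
model of *E. coli* central carbon metabolism (`core_model()`, 87 reactions,
64 metabolites, 93 genes) rather than a genome-scale reconstruction: it is
self-contained, fast enough for exhaustive enumeration, and reproduces the
pathway logic that decides methanol essentiality on gluconate. It contains:

* gluconate uptake (GntT/GntU) and gluconokinase to 6-phosphogluconate
  (6PG);
* both 6PG exits: the Entner-Doudoroff pathway (Edd/Eda) and the oxidative
  decarboxylation to Ru5P (Gnd), plus Zwf upstream;
* the full non-oxidative pentose phosphate pathway, reversible (RpiA/RpiB,
  Rpe, TktA/TktB, TalA/TalB);
* glycolysis and gluconeogenesis (including fructose-1,6-bisphosphatase and
  the fructose-6-phosphate aldolase / dihydroxyacetone bypass via GpsA,
  glycerol-3-phosphate phosphatase, GldA and Fsa);
* TCA cycle with both the NAD-dependent malate dehydrogenase (*maldh*) and
  the malate:quinone oxidoreductase (*mqo*) alternative, glyoxylate shunt,
  PEP carboxylase/carboxykinase and both malic enzymes;
* acetate exchange in both directions (ActP uptake, Acs activation and the
  Pta-AckA overflow route);
* endogenous formaldehyde oxidation (FrmA lump) and formate dehydrogenase;
* a lumped nucleoside-salvage catabolism of ribose 5-phosphate
  (`R5PCAT`, *deoB*/*deoC*): the phosphopentomutase branch point of the RuMP
  cycle through (deoxy)ribose phosphates to the aldolase products
  glyceraldehyde 3-phosphate and acetaldehyde;
* lipopolysaccharide precursor synthesis from Ru5P (`KDOS`,
  *kdsD*/*kdsA*), drained by biomass at 0.02 mmol gCDW^-1 and sheddable as
  overflow;
* lumped oxidative phosphorylation (P/O = 2 for NADH, 1 for the
  quinone-level oxidations), a reversible transhydrogenase lump, and a
  biomass reaction drawing the canonical twelve precursors with
  59.81 mmol gCDW^-1 growth-associated ATP, 16 mmol gCDW^-1 NADPH and
  realistic precursor coefficients (42.6 mmol biomass carbon per gCDW).

Two of these components are worth their own paragraphs, because the design
behaviour of the model depends on them.

**Pentose disposal and the single-knockout trap.** Deleting the
ribose-5-phosphate isomerase reaction alone already abolishes growth on
gluconate in a minimal pentose-phosphate network: without Rpi the
non-oxidative pentose phosphate pathway cannot convert Ru5P into hexoses,
and without an Rpi-independent exit Ru5P is a dead end. Genome-scale
*E. coli* models escape this through their lipopolysaccharide branch —
excess Ru5P leaves via arabinose-5-phosphate into KDO synthesis — so the
*rpiAB* deletion alone is *not* growth-coupling there, and a workable
design requires *edd* in addition. The packaged model reproduces this with
the `KDOS` overflow. Conversely, *pure methylotrophic growth* of the
Δ*edd* Δ*rpiAB* genotype requires a carbon-conserving R5P exit (the RuMP
regeneration strands one R5P per two transketolase-derived pentoses); the
`R5PCAT` nucleoside-salvage lump provides it, mirroring the deo-operon
branch point that genome-scale models use for the same purpose. Without
these two features the model cannot simultaneously satisfy "no single
knockout suffices" and "the double knockout retains methylotrophy".

**Carbon accounting.** Metabolite carbon counts track transferable backbone
carbon: acetyl-CoA counts 2, the nicotinamide and adenine carriers count 0.
Every internal (non-exchange, non-biomass) reaction is carbon balanced
under this convention, and the test suite checks it; exchanges and the
lumped biomass are exempt by construction.

The model is shipped as JSON
(`system.file("extdata", "ecoli_core_rump.json", package = "rumpdesign")`,
schema documented alongside) and regenerates bit-identically from
`core_model()`.

```{r core-behaviour}
aug <- add_rump_pathway(core_model())
c(gluconate = growth_on(aug, "EX_glcn"),
  methanol  = growth_on(aug, "EX_meoh"),
  ko_glcn   = growth_on(aug, "EX_glcn", genes = c("edd", "rpiA", "rpiB")),
  ko_both   = growth_on(aug, c("EX_glcn", "EX_meoh"),
                        genes = c("edd", "rpiA", "rpiB")),
  ko_meoh   = growth_on(aug, "EX_meoh", genes = c("edd", "rpiA", "rpiB")))
```

## The linear-programming engine

No linear-programming package is required: the FBA programs are solved by a
dense bounded-variable two-phase primal simplex written for this package
(Rcpp/RcppArmadillo), with Dantzig pricing, a Bland fallback against
cycling, and a product-form basis inverse refactorised every 64 pivots.
Feasibility and pricing tolerances default to 1e-9; reported fluxes below
1e-6 are zeroed, but comparisons against the 0.01 h^-1 growth threshold
always use the raw objective value. Only the objective value is
contractually deterministic — alternate optimal flux vectors exist
throughout, so tests never assert individual fluxes unless uniqueness is
forced. The solver is validated against a brute-force vertex enumeration of
the flux polytope on small networks and against an independently assembled
split-variable formulation of the same models; infeasibility and
unboundedness are explicit statuses, never silent zeros. In the screening
loops an infeasible program is mapped to zero growth (with a warning) so
the search remains total.

## Search: beam and oracle

`methanol_essential_search()` replaces a manually iterated workflow with a
beam search: classify all single knockouts, rank the neutral ones by
*differential fitness* (growth on co-substrate plus methanol minus growth
on the co-substrate alone — a scale-stable difference at equal uptake
bounds), extend the `beam_width` best backgrounds by one deletion, and
repeat, collecting and re-verifying every methanol-essential genotype; by
default the search stops at the shallowest depth with a solution. Screening
reuses background optima: a candidate reaction carrying no flux in a
medium's optimal solution cannot change that optimum when deleted, so its
growth value is inherited exactly.

`enumerate_methanol_essential()` is the independent oracle: brute-force
classification of all knockout subsets up to size 3, pruned only by sound
monotonicity arguments (supersets of methanol-dead sets are methanol-dead;
supersets of essential sets are non-minimal; a cached co-substrate flux
distribution avoiding a subset certifies growth). On gluconate it finds
three minimal pairs — {EDD, RPI}, {EDA, RPI} and {GND, TPI} — and 25
minimal triples. The pair {EDD, RPI} maps through the gene rules to exactly
{*edd*, *rpiA*, *rpiB*}, the reference design; {EDA, RPI} is its immediate
neighbour (cutting the Entner-Doudoroff pathway one step further down), and
{GND, TPI} is a genuine alternative that a genome-scale model confirms
(blocking both the oxidative pentose route and triose isomerisation leaves
hexose synthesis to Hps/Phi). Alternative cut sets of this kind are an
expected feature of redundant central metabolism; a screening campaign
typically pursues one design family and records the rest as alternatives.

A width-5 beam ranked by differential fitness recovers the {EDD, RPI} /
{EDA, RPI} family (the RPI single knockout is the strongest differential
hit by a wide margin) but is *not* complete for all topological
alternatives: the parents of {GND, TPI} rank just below the default beam.
Completeness holds when the beam is run wide enough to extend every viable
single-knockout background, which is how the oracle-equivalence test is
run; the default width is a screening heuristic, not an enumeration
guarantee.

## Physiology estimators

Growth rates come from ordinary least squares on log OD600 versus time
(`fit_exponential_growth()`), with the OD-to-biomass factor 0.33 gCDW L^-1
per OD600 unit (a 0.25 factor appears in metabolome normalisation contexts
and is deliberately not used here). The specific methanol uptake rate uses
the substrate drop of the culture minus that of a non-consuming
evaporation-control culture. The instantaneous-rate formula divides the
interval rate by `X0 e^(mu t)` — a time-dependent quantity with no stated
evaluation time — so the package implements the exact integral mass
balance as the default,

q = dS_corrected * mu / (X0 (e^(mu t2) - e^(mu t1))),

with the literal midpoint-time evaluation available as an option; the two
agree as the window shrinks, which the test suite demonstrates. If the
fitted growth rate is not positive the estimator falls back to a
mean-biomass denominator with a warning. Uncertainty is first-order
variance propagation over the endpoint concentrations and the growth-fit
parameters.

Two-point estimators are exactly identified but statistically wasteful:
with a 500 mM methanol background, a 1% measurement coefficient of
variation is about 5 mM per reading while a full culture consumes only
~65 mM, so endpoint differencing carries a relative error around 15% per
series. `fit_uptake_rate()` therefore fits the same mass-balance model
jointly to *all* points of both series by linear least squares (unknowns:
two intercepts, the shared evaporation rate, and q) and is the recommended
estimator for multi-point data. With the triplicate design the generator
emulates, its median recovery error at 1% noise is below 5%; the two-point
form is retained as the definitional special case.

## The synthetic-data generator

`simulation_spec()` fixes the simulated cultivation conditions: growth
rate 0.081 h^-1,
specific uptake 13 mmol gCDW^-1 h^-1, inoculum OD600 0.05, 500 mM initial
methanol, 1 mM h^-1 linear evaporation (a plausible shake-flask loss,
identical in culture and control), 1% multiplicative Gaussian noise, 8
uniform sampling points over 40 h (about 4.7 doublings to a final OD of
~1.3, a realistic batch-culture trajectory). Multiplicative
noise is the simplest positive-value-friendly choice consistent with
mean-and-standard-deviation reporting; no heavier distributional claim is
intended. Isotopologue data are generated position-wise: a chosen number of
tracer-accessible carbons are labeled so that the expected average labeled
fraction equals the spec value, all remaining carbons carry natural 13C
abundance (0.0107), and the exact distribution receives per-isotopologue
multiplicative noise. Every generator is a pure function of its spec,
including the seed, and restores the caller's RNG state.

What the generator deliberately does **not** emulate: stationary-phase
plateaus and lag phases, evolving (time-varying) uptake rates, formate or
other byproduct accumulation, biological replicate-to-replicate variance
beyond measurement noise, and non-carbon isotope contributions to mass
spectra (the natural-abundance correction is carbon-only, a documented
choice). Passing recovery tests on these data therefore demonstrates
estimator correctness under the stated generative model, not robustness to
every feature of real cultivations.

## Labeling analytics

The average labeled fraction of an n-carbon metabolite is
`sum(A_i * i) / (n * sum(A_i))` over the M+0..M+n abundances; it is
invariant under rescaling and affine in the isotopologue index.
Natural-abundance correction inverts the binomial convolution
`observed = M %*% true` with
`M[j, i] = choose(n-i, j-i) a^(j-i) (1-a)^(n-j)`; the system is
lower-triangular with diagonal `(1-a)^n > 0`, hence always solvable by
forward substitution. Negative corrected abundances (a noise artifact) are
clipped to zero with a warning and the result renormalised to the input
total. The stoichiometric benchmarks are pure carbon arithmetic: under
equimolar co-assimilation a hexose carries one methanol-derived carbon in
six, an expected labeled fraction of 1/6 (17% at half-up nearest-percent
rounding), and the same ratio bounds the biomass gain over the co-substrate
alone when no carbon is lost.

```{r labeling}
percent_round(expected_fraction_equimolar(1, 6))
percent_round(equimolar_yield_gain(6, 1))
```

## Numerical choices and limitations

* Exchange bounds use the +/-1000 "unbounded" convention; media are set
  per-source at the configured uptake bound (the plain reading of a single
  shared uptake value), not as a summed carbon cap.
* Non-growth-associated maintenance is present but not enforced
  (lower bound 0), so the model is homogeneous: doubling uptake doubles
  the optimum, and a carbon-free medium yields growth 0 rather than an
  infeasible program.
* Knockout candidates are gene-associated internal reactions; diffusion
  and maintenance pseudo-reactions cannot be deleted.
* Gene-level reporting derives all minimal gene sets whose deletion
  deactivates exactly the reported reactions (isozymes via rule cut sets);
  reaction sets without an exact gene realisation report none.
* The Mdh/Hps/Phi additions are carbon-balanced with explicit protons on
  the dehydrogenase; charge balance is not audited anywhere in the model.
* The reduced model reproduces qualitative knockout logic and
  order-of-magnitude growth rates, not genome-scale flux values; absolute
  growth rates on the diagnostic media should be read comparatively.
* Problem sizes used in the shipped tests — exhaustive enumeration to
  subset size 3, 21 seeds for uptake recovery, 100 random knockout pairs
  for monotonicity — were chosen as desk-scale settings that exercise every
  code path on a single CPU.
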