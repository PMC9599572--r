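---
title: "Constraint-based niche analysis of a chitin-degrading consortium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based niche analysis of a chitin-degrading consortium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commniche)
```

## The modeling problem

Defined soil consortia assembled around a polymeric carbon source such as
chitin raise a recurring ecological question: is success in the community
driven by the ability to attack the polymer itself, or by the breadth of
breakdown products a species can consume? `commniche` frames that question
with constraint-based metabolic models. Each member species is a
stoichiometric model — metabolites in two compartments (cytosol,
extracellular), reactions with flux bounds in mmol·gDW⁻¹·h⁻¹, and a single
biomass pseudo-reaction. Growth on a medium is decided by flux balance
analysis (FBA): maximize biomass flux $v_{bio}$ subject to steady state
$S v = 0$ and bounds $lb \le v \le ub$, where the medium closes every
exchange reaction for uptake except a carbon-free mineral base and one
focal carbon source with an uptake ceiling.

Three constructions sit on top of FBA:

* **Fundamental niche** — the set of panel carbon sources on which a
  species' own model grows (`fundamental_niche()`).
* **Mixed-bag community model** — the union of all member reactions and
  metabolites with no species boundaries (`merge_mixed_bag()`); duplicate
  reaction ids with identical stoichiometry collapse to one reaction with
  the widest bounds, all member biomass reactions are kept, and the
  community objective is the *sum* of member biomass fluxes. With that
  objective, community growth means "some member's biomass can be
  produced", which is exactly the semantics the realized niche needs.
* **Realized niche** — the growth-supporting panel subset of the mixed-bag
  model (`realized_niche()`). Because adding reactions can only enlarge
  the feasible region of an LP, the realized niche always contains every
  member's fundamental niche; the interesting cases are strict gains, e.g.
  a polymer that only becomes usable when one member's extracellular
  hydrolysis is combined with another member's monomer uptake.

Draft models rarely reproduce observed growth phenotypes directly, so
`gapfill_model()` repairs them against a growth/no-growth phenotype
matrix: for each positive-phenotype medium where the draft fails, it adds
a minimal-cardinality set of reactions from a universal donor set.
Gapfilling only ever adds reactions — negative phenotypes are never
enforced — and any residual false growth on negative media is reported,
not hidden. `phenotype_concordance()` then scores the fraction of
phenotyped (species, source) pairs the models predict correctly.

## Tunable parameters

| Parameter | Default | Units / rationale |
|---|---|---|
| carbon uptake ceiling | 10 | mmol·gDW⁻¹·h⁻¹ per substrate; a uniform bound mirrors growth screens standardized by substrate molarity |
| growth threshold | 1e-6 | biomass flux separating numerical noise from growth; strict inequality |
| gapfill `max_additions` | 3 | largest addition set searched per medium |
| DEG `alpha` | 0.05 | adjusted-P cutoff |
| DEG `min_fold` | 2 | strict fold-change cutoff (\|log2 FC\| > 1) |
| metabolite `alpha` | 0.05 | BH-adjusted Welch test on log abundances |

## Numerical choices

FBA LPs are solved by a dense two-phase primal simplex written for this
package (`R/lp.R`), with bounded fluxes shifted to standard form and
Bland's anti-cycling rule for pivot selection. Bland's rule makes every
solve deterministic (no randomized tie-breaking) and guarantees
termination on the degenerate problems FBA produces (many zero right-hand
sides). The solver is validated against brute-force vertex enumeration on
small models in the test suite. Steady state is verified at every optimum
to a relative tolerance of 1e-9 (absolute floor 1e-7); alternate optima
are irrelevant downstream because only the objective value and the carbon
uptake flux are consumed. Infeasible LPs report growth 0 and are flagged
by status rather than by error.

Gapfilling solves minimal-cardinality addition exactly, by enumerating
candidate subsets in increasing size with a deterministic lexicographic
order (media are visited in ascending carbon-source order, and additions
accumulate across media). A greedy best-improvement fallback exists only
for candidate pools too large to enumerate; the benchmark sizes used here
are always enumerated exactly, and tests confirm the found cardinality
equals the brute-force minimum on small universes.

Biomass yield is the optimal biomass flux divided by the realized carbon
uptake flux. A positive biomass flux with zero carbon uptake can only
mean the model synthesizes carbon from nothing, so it raises an error
instead of returning an infinite yield.

## The differential expression test

Counts are normalized with median-of-ratios size factors computed within
each species' gene set separately, so that changes in a species' overall
abundance between time points are not misread as coordinated expression
changes; factors are rescaled to unit median per species so unshifted
samples sit at factor 1. The two-group (118 h vs 70 h) test is a Wald
test on a negative-binomial mean model. Three choices matter at 3
replicates:

1. **Dispersion** is estimated by method of moments per gene but pooled
   per species (median of per-gene estimates). The per-gene estimator is
   essentially noise at n = 3; the pooled estimate assumes a shared
   mean–variance relation within a species, which holds for the
   generator's data and approximately for real RNA-seq.
2. **Empirical-null recalibration.** The raw Wald statistic has
   heavier-than-normal tails at these replicate counts. Within each
   species the z-values are re-centered by their median and rescaled by
   their MAD before conversion to p-values. The MAD is floored at 1, so
   recalibration can only widen p-values, never sharpen them; under a
   complete null it is a near-identity.
3. **BH adjustment within species**, matching the per-species testing
   structure. A gene is a DEG iff adjusted P ≤ 0.05 and \|fold change\| >
   2, applied as a strict filter; genes with zero counts everywhere are
   excluded and reported as untested.

The test-suite simulations quantify what this buys: planted 4-fold DEGs
at dispersion 0.1 are recovered with empirical FDR at or below 0.1, and
near-null matrices of 1000 genes average at most two false calls.

Abundance profiles are per-sample species fractions of total reads with
Welch t tests on per-replicate fractions; metabolite differences use
Welch tests on log abundances with BH adjustment and ratio-of-means fold
changes. Metabolites with nonpositive abundances are excluded (the log
transform is undefined there), with a warning.

## Pathway coverage scoring

The 8-step chitin/NAG breakdown-and-assimilation pathway ships as an
editable JSON config: chitin binding, GH18 and GH19 chitinases, and CE4
deacetylation as early steps; GH20/GH3 β-N-acetylhexosaminidase and the
NAG PTS transporter as mid steps; NAG-6-phosphate deacetylase and
glucosamine kinase as late steps. A step is covered when any annotation
term matches any accepted term; coverage counts distinct steps, not
genes — a deliberate resolution of the ambiguity in published per-species
gene counts, which sometimes tag more genes than the printed total. EC
matching honors trailing wildcard fields in either direction ("3.5.1.-"
matches "3.5.1.104"), and the Unicode minus that appears in printed
tables is normalized. Because published chitinase tables also list genes
outside these eight steps (GH23 transglycosylases, GH5 endoglucanases),
scores under the shipped config can sit below the published totals; the
test suite freezes the computed values and reports the relationship
rather than forcing agreement.

## What the synthetic consortium emulates

`default_consortium_design()` fixes the study conditions: 8 species over
the 12-substrate panel (chitin, glucose, NAG, fructose, sucrose, maltose,
xylose, arabinose, serine, glycine, alanine, glutamate), designed
fundamental niche sizes decreasing strictly from a broad generalist
(11 substrates, an *Ensifer*-like profile) to a chitin-specialist
(3 substrates, a *Dyadobacter*-like profile), four chitinase-carrying
degraders, and designed community abundances decreasing in the same
order. Transcriptome simulations use 3 replicates per time point and
metabolome simulations 5, matching the emulated two-time-point design.

Generated models grow *exactly* on their designed substrate sets: each
substrate gets an exchange, a transport step, and a catabolic step whose
precursor yield scales with the substrate's carbon count (so NAG
outyields glucose, and disaccharide hydrolysis into two hexoses doubles
the per-mmol glucose yield exactly). Chitin is an extracellular polymer
hydrolyzed in two extracellular steps (chitin → chitobiose → NAG) gated
by chitinase genes; a species grows on chitin alone only if it both
degrades the polymer and consumes NAG, which is what makes community
growth on chitin emergent when those roles are split across members.
Design validation rejects inconsistent blueprints (a chitin grower that
is not a degrader, a degrader consuming NAG whose niche omits chitin, a
consumer of a monomer no one releases) with errors naming the broken
dependency.

What the generator does **not** emulate: genome-scale model complexity
(hundreds of reactions, cofactor and energy metabolism, multiple
compartments), kinetic or resource-ratio effects, regulatory repression,
and absolute biomass yields — the toy models' yields are in arbitrary
units per carbon atom, so only yield *ratios* and growth/no-growth
patterns are meaningful. Passing tests therefore demonstrate that the
pipeline's logic (gapfilling, merging, niche calls, summary statistics)
is correct on inputs with known truth, not that any real consortium has
these niches. Problem sizes throughout (8 species, 12 substrates, a few
hundred genes per species, 100 metabolites) were chosen as the smallest
sizes that exercise every code path with comfortable statistical margins.

## Design choices where the design was open

* **Rank agreement** between niche sizes and abundances is Spearman's
  correlation with average ranks for ties — a qualitative "rankings
  align" claim needs a concrete statistic to be testable.
* **Community objective** is the sum of member biomass fluxes; a
  max-min or weighted objective would encode equity or composition
  assumptions the niche semantics do not need.
* **Concordance accounting**: gapfilling reports false growth on
  negative media both before and after repair, so concordance can be
  read pre- or post-gapfill; the headline number here is post-gapfill.
* **Phenotype noise** is off by default; the benchmark is noiseless, and
  noise is an explicit generator argument rather than a hidden rate.

## Known limitations

* The simplex is dense and unfactorized; fine for hundreds of variables,
  unsuitable for genome-scale models (thousands of reactions).
* The SBML reader accepts only a flat constraint-based subset (two
  compartments, fbc-style bounds) and rejects everything else loudly.
* The DE test's pooled dispersion assumes within-species homogeneity of
  the mean-variance relation; strongly gene-specific dispersions would
  call for shrinkage estimators instead.
* Exact minimal gapfilling is exponential in the addition size; it is
  capped (default 3) and falls back to greedy on very large candidate
  pools.
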