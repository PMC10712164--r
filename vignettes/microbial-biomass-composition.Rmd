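---
title: "Methods: linking growth rate to microbial biomass composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking growth rate to microbial biomass composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microcomp)
```

## Scope and model

`microcomp` analyses how the composition of a growing microbial culture —
its proteome allocation among cellular components, its amino-acid
profile, its macromolecular content and its cytometric properties —
varies with substrate availability and growth rate. The pipeline consumes
four kinds of input: PSM-level proteomics tables (the downstream format
of a search-engine + rescoring + protein-inference chain after 1% FDR),
a protein FASTA database, a local cellular-component ontology (OBO 1.2
subset plus a protein→GO TSV), bioreactor time series, and cytometry
event tables. A synthetic-data generator with known ground truth stands
in for all of them, which makes every stage testable offline and lets
round-trip identities (estimator ∘ generator = identity when noise is
off) serve as the core correctness checks.

## Quantification

Each PSM row carries a count and a candidate protein set. Shared-peptide
evidence is resolved by a razor rule in two deterministic passes: unique
rows are credited first, then shared rows are processed in table order
and assigned entirely to the candidate with the largest accumulated
evidence, ties broken to the lexicographically smallest id. This mirrors
the razor-protein concept of standard protein-inference tools while
being exactly reproducible, which the conservation invariant
(Σ razor = Σ PSM, integer-exact) relies on. Counts are then divided by
protein length; the length-normalized value `q_p` is the single
quantification used everywhere downstream. Proteins with no assigned
PSMs are omitted rather than zero-filled — the spectral-counting
convention — and contaminant entries (`contam_` prefix) are dropped
before assignment. Whether razor "intensities" in the source workflow
were raw or length-normalized counts is not recoverable from the method
description; we use the normalized value as the single quantification
consistently, so shares are unaffected by a global rescaling either way.

## Cellular-component collapse

The reference is built from the descendant closures (over `is_a` and
`part_of`, the only relations traversed) of *cellular anatomical entity*
(GO:0110165), *protein-containing complex* (GO:0032991) and *ribosome*
(GO:0005840). For each annotated protein the annotation set is expanded
to ancestors-plus-self, intersected with the reference, and reduced to
the most specific term per lineage: any matched term that is an ancestor
of another matched term is dropped. This is our operationalisation of
"retain only terms without cross-ontology relations to the others" — it
is deterministic and idempotent, and on nested annotations it yields one
label per lineage. Unmatched annotation sets fall back to their own term
names, with membrane-named terms grouped under "membrane" (the grouping
is keyed on the name substring because no id list exists for it).

Simplification precedence matters: in the real ontology (and in the
generator's toy DAG) *ribosome* is itself a descendant of
*protein-containing complex*, so ribosomal terms are labelled
"ribosome" **before** the complex group is applied; otherwise the
ribosome label would be unreachable and the canonical top-3 components
(cytoplasm, membrane, ribosome) could not emerge. Multi-label proteins
contribute their full `q_p` to each label, since summed term intensities
are not apportioned in the source procedure; allocation shares are
therefore reported against total quantification, alongside the annotated
fraction (quantification carried by proteins with ≥ 1 label). Direct
children instead of full descendant closures are available behind
`build_reference(..., direct_children = TRUE)` for sensitivity analysis.

## Amino-acid profiles

Component profiles are quantification-weighted residue tallies,
`raw_a = Σ_p q_p · count_{p,a}`. Two normalization modes exist because
the reporting unit (g AA/g protein) and the defining product formula
(counts) pull in different directions: `count` mode gives molar
fractions; `mass` mode (the default, matching the g/g unit) weights by
average residue masses after water loss (A = 71.0788 Da, G = 57.0519 Da,
…). Ambiguous residues (B, Z, U, X) count toward protein length but not
composition, initial Met is retained, and fixed cysteine
carbamidomethylation does not alter counts — modification chemistry is
out of scope. Relative differences versus ribosomal proteins are percent
deltas `(f_c − f_ribo)/f_ribo · 100`, undefined (NA) where the ribosomal
fraction is zero. The essential + conditionally essential set is the 15
amino acids relevant to human nutrition; restriction does not
renormalize unless asked.

## Flow cytometry

Singlets are discriminated on the primary fluorescence channel as events
whose BL1 area/height ratio lies within [0.7, 1.3] of the population
median; the bounds are configurable, chosen wide enough for lognormal
singlet noise and narrow enough to reject doubled-area doublets (whose
relative ratio sits near 1.8). Concentrations are gated event counts
divided by the recorded volume (default 0.075 mL) times the dilution
factor; the SGPI panel splits intact (PI-negative) from damaged events,
and intact + damaged = total holds exactly by construction. The
storage-compound gate is a sequential triple threshold (low SSC-H, SYTO
62 on RL1-H, selective stain on BL1-H) with per-stage counts logged; a
kernel-density valley finder (`valley_threshold`) can place thresholds
at the minimum between the two largest modes, since no numeric
thresholds are published for these stains. Intensity summaries are
medians, with intensity assumed linear in compound content; that
assumption is recorded in the output.

## Growth, COD and correlation

Observed growth rates are consecutive-pair log slopes assigned to
interval midpoints — exact on exponentials for any grid, and time-resolved
enough to correlate against composition samples (joined by nearest
midpoint within a 1 h default tolerance, matching a 2 h sampling
cadence); a 3-point rolling mean is optional and used where OD noise
propagates strongly into the differences. Organic substrates are
aggregated as chemical oxygen demand with factors derived from elemental
stoichiometry (fructose 192/180 ≈ 1.067 gCOD/g) and expressed also as
electron equivalents at 8 gCOD/eeq. Limitation phases are classified by
a declared artifact policy — residual limiting substrate below 10% of
initial **and** growth rate below 90% of the run maximum — because
substrate limitation is defined conceptually, not operationally, in the
underlying methodology; both parameters are surfaced in the output (and
the growth-rate condition can be disabled, which reduces the rule to the
pure substrate bound). Correlograms use Spearman's ρ with mid-rank ties
and two-sided p-values from the t approximation at α = 0.05,
pairwise-complete deletion, and no multiplicity correction by default
(a Benjamini–Hochberg option exists); strata are computed for pooled
data, per phase, and per limitation type. Confidence bands around linear
trends are the standard t-based pointwise interval for the mean
response.

## The synthetic generator

The generator's defaults are the study conditions, chosen once:

- **Allocation law.** The functional form linking allocation to growth
  rate is not published; we use a linear stand-in
  `φ_ribo(µ) = 0.12 + 0.45 µ`, spanning ≈ 14–28% over µ ∈ [0.05, 0.35]
  h⁻¹ — the reported ribosomal range. The non-ribosomal remainder is
  split in fixed proportions (cytoplasm 0.24, membrane 0.18, complexes
  0.10, unannotated 0.48), placing the annotated fraction near 60%.
- **Proteome.** 40 proteins per component; ribosomal proteins average
  130 residues (short, as in real ribosomes) versus ≈ 300 for the rest;
  residues are multinomial draws from per-component weight vectors with
  ribosomal enrichment in Arg/Lys/Met/Val and cytoplasmic/membrane
  enrichment in Cys/Leu/Phe/Thr/Trp/Tyr — the directions reported for
  microbial proteomes.
- **PSM tables.** Expected counts ∝ component share × within-component
  weight × length, so length normalization is the exact inverse; a
  50,000-PSM budget; Poisson sampling; 10% of peptide rows share a
  second candidate protein to exercise razor logic. Expected-count mode
  produces fractional counts — accepted by the table validator so the
  noise-free identity is exact.
- **Batch model.** Dual-Monod kinetics, `µ = µmax · min(C/(K_C+C),
  N/(K_N+N))`, integrated by fixed-step RK4 (dt = 0.01 h; the endpoint
  moves < 0.1% under step halving). µmax = 0.35 h⁻¹, K_C = 0.02 gCOD/L,
  K_N = 0.002 gNH₄/L, yields 0.5 gCDW/gCOD and 6.5 gCDW/gNH₄, 2.13
  gCOD/L initial substrate (2 g/L fructose) and 0.064 gCDW/L inoculum
  (OD 0.16). Initial ammonium sets the scenario: 0.5 (carbon
  limitation), 0.08 (nitrogen), 0.164 (dual, both deplete together).
  Phase truth labels switch from abundant to limiting when the residual
  limiting substrate falls below 10 half-saturation constants — the edge
  of the Monod plateau.
- **Composition rules.** Nucleic-acid intensity 40 + 300 µ (A.U.),
  protein 0.68 − 0.6 µ (g/gCDW), carbohydrate 0.08 + 0.15 µ, cell size
  0.9 + 1.0 µ (µm); storage intensity jumps by a gain term during
  nitrogen- or dual-limited deceleration, emulating PHA accumulation.
  Observables get multiplicative lognormal noise at 5% CV.
- **Cytometry.** Per-population lognormal channels; 75% intact fraction
  in the SGPI panel; 40% storage-positive cells and 20% low-scatter
  debris in the BODIPY/SYTO 62 panel; doublets are event pairs with
  summed area and 1.1× the larger height, which makes area/height
  singlet discrimination testable (doublets of two very unequal cells
  can still mimic singlets — also true on real instruments).

All randomness flows through the configuration seed via scoped seeding
(`withr::with_seed`) with fixed offsets per operation, so identical
seed + configuration reproduce outputs byte-for-byte and no global RNG
state leaks.

What the generator does **not** emulate: real spectra or ionization
effects, peptide detectability bias, the full ontology's breadth,
instrument drift or spectral spillover, autocorrelated bioreactor noise,
biological replicate variability. Passing tests therefore demonstrate
the correctness and invertibility of the computations, not the field
behaviour of the assays.

## Numerical choices and degenerate inputs

Razor ties break lexicographically; top-k allocation ties likewise.
Spearman ρ is undefined (NA with a warning) for constant variables and
fewer than three complete pairs. Profiles error on empty subsets;
relative differences return NA, not ±Inf, at zero ribosomal fractions.
Empty event tables yield empty gates without failure; empty gates yield
NA medians with a warning. Zero-variance abscissae are an error in
linear fits. ODE states are clamped at zero before computing Monod
terms. Annotation ids missing from the graph are skipped with a warning
(the analogue of a failed lookup), an error only if all are missing.

## Problem sizes

The shipped tests run the generator at reduced scale — 15–25 proteins
per component for allocation round trips, 3,000–5,000 cytometry events,
50-node random DAGs (up to 120 in the brute-force comparison), 20
Poisson replicates for growth-law recovery, 100 seeded batch replicates
for the headline correlation signs — sizes at which the binomial and
Monte-Carlo tolerances in the tests are already decisive. All fixtures
are generated in code; nothing is downloaded.

## Known limitations

The razor rule is order-dependent for pathological shared-peptide
configurations (ties in accumulated evidence resolved by id); real
protein-inference engines differ in such corners. The membrane grouping
is a name heuristic. The allocation law is linear by construction — it
is a stand-in, and nothing in the pipeline depends on its form. Phase
classification compares residual substrate to its initial value, which
presumes a batch (monotone-depletion) design. FCS binary ingest is out
of scope; event tables arrive as CSV with a JSON metadata sidecar.
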