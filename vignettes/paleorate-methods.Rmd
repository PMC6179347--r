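---
title: "Methods: dating endogenous viral elements and inferring long-term viral rates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dating endogenous viral elements and inferring long-term viral rates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleorate)
```

## The inference problem

Endogenous viral elements (EVEs) are viral sequences that integrated into a
host germline and became fixed. From the moment of endogenization they stop
evolving at the fast viral rate and start evolving at the slow neutral host
rate, which makes them genomic fossils: their ortholog distribution across
host species dates the insertion, and their residual similarity to
reconstructed viral sequences measures how much the *virus* diverged over
millions of years. The package implements this chain for
pararetrovirus-like EVEs in a rice-like host system (the eRTBVL-D group in
*Oryza*), but every step is generic.

The chain has four stages.

**1. Dating by ortholog presence/absence.** On an ultrametric host tree
with node ages in Myr, a locus present in a set of species and absent in
their relatives must have been endogenized on the stem branch of the
presence clade. The lower age bound is the age of the MRCA of the taxa
carrying the locus; the upper bound is the age of the first ancestor that
also subtends a sampled absence lineage. Three refinements:

* A `deleted` ortholog still witnesses the insertion, so deleted taxa count
  as presence evidence.
* An `absent` taxon nested inside the presence clade is inconsistent with a
  single insertion and is reclassified as a deletion (`resolve_conflicts()`).
* `unclear` taxa contribute no evidence. Because unresolved cells can
  straddle a dating boundary, `date_locus()` reports both the strict
  interval (unclear ignored) and an optimistic interval (unclear counted as
  present) instead of guessing.

When no absence lineage is sampled, the interval is open-ended at the root
age and flagged as such; if additionally the presence MRCA is the root the
interval degenerates to a lower bound only.

**2. Host-corrected distances.** The distance `D_u` between an EVE copy and
a reconstructed (consensus) viral sequence mixes virus–virus divergence
with the substitutions the EVE accumulated in the host genome. The host
share `D_h` is estimated as half the distance between an ortholog pair
(each ortholog accumulated host substitutions independently since
speciation), giving the corrected distance

```
D_c = max(D_u - D_h, 0).
```

The floor at zero is a numerical guard: for young or short segments the
subtraction can go stochastically negative; the event is reported with a
warning rather than treated as an error. Note the approximation: `D_h`
counts host substitutions since the *speciation* of the ortholog pair, not
since endogenization, so `D_c` slightly overestimates virus–virus
divergence for loci much older than the speciation. At host rates of
1e-9–1e-8 substitutions/site/year this bias is two to three orders of
magnitude below the viral signal.

**3. Rate bounds and gene rate heterogeneity (GRH).** Dividing `D_c` by the
bounds on the divergence time gives rate bounds `r_lower = D_c / T_max`,
`r_upper = D_c / T_min` in substitutions/site/year. The endogenization lag
(time from germline insertion to fixation) is set to zero — it is unknown
but negligible against millions of years — so the divergence-time bounds
equal the dating bounds minus the young group's endogenization window
(2.41 − 0.16 = 2.25 to 6.76 − 0.01 = 6.75 Myr in the study system). GRH
between a divergent and a conserved gene of the same viral genome is the
fold ratio of their rates computed over the same locus and time interval;
the time denominators cancel, so per-locus folds are ratios of corrected
distances. Significance uses an exact two-sided Wilcoxon signed-rank test
on the paired rate differences, with the null distribution enumerated over
all `2^n` sign assignments (n ≤ 25). Zeros are dropped before ranking
(Wilcoxon's convention; a Pratt variant is available), ties get average
ranks.

Averaging order matters in the third significant digit: dividing the
pooled mean corrected distance by the time bound is not the same as
averaging per-locus rates. The package computes per-locus estimates and
leaves any pooling to the caller, and the demo analysis prints the pooled
order explicitly.

**4. Time-dependent rate decay.** Measured viral substitution rates fall
with the measurement timescale. The package fits ordinary least squares of
`log10(rate)` on `log10(timescale in years)` (`decay_regression()`).
Short-term literature rates enter as an explicit user-supplied table —
they are measurements external to any given EVE dataset — and interval
summaries (rate bounds, time windows) are collapsed to geometric means
before the log-log fit, which is the natural midpoint on that scale.

## Distance models

Pairwise distances support `p`, `JC69`, and `TN93`, the last with an
optional gamma correction (`ln w` terms replaced by `alpha (w^(-1/alpha) - 1)`).
All comparisons use pairwise deletion: a column is dropped for a pair if
either residue is a gap, `N`, or an IUPAC ambiguity code. Ambiguity codes
are retained in sequences (consensus building can emit them on ties) but
are never resolved fractionally at comparison time — the simplest
convention that is exactly testable. Base frequencies for TN93 are pooled
over the two sequences across the counted sites. Saturated pairs (a
logarithm argument ≤ 0) raise an error naming the model rather than
returning `NaN`.

The gamma shape for TN93+Γ defaults to 1.0 and is exposed in
`distance_spec()`; it is an analysis choice, and the reference arithmetic
shipped with the package uses published distances rather than recomputing
them, so nothing downstream depends on this default. Model selection (BIC)
is out of scope; the model is a configuration choice.

Majority-rule consensus takes the plurality residue per column; ties among
bases emit the covering IUPAC code, gaps lose ties to bases, and
gap-plurality columns are dropped so the consensus follows the
reconstructed-viral-genome coordinate convention.

## Neutrality tests

The rate model assumes EVEs evolve neutrally after endogenization. Four
counting-based checks are provided. Site-frequency-spectrum statistics use
complete deletion (columns fully resolved in every sequence).

* **Tajima's D** per the 1989 formula, with significance from Tajima's
  beta-distribution approximation — the generative method behind the
  published critical-value table.
* **Fu & Li's D\*/F\*** (outgroup-free), using the corrected F\* variance
  constants in common use. Significance uses the conservative two-unit
  rule (|statistic| > 2), an approximation to the published critical
  values; both statistics validate against the coalescent null in the test
  suite (mean ≈ 0, type-I error well under nominal).
* **Modified Nei–Gojobori dN/dS**: synonymous/nonsynonymous site counts
  weighted by a transition/transversion ratio `R` (per-change weights `2R`
  for the transition and 1 per transversion, so the expected
  transition:transversion ratio equals `R`, and `R = 0.5` recovers the
  classical unweighted counts). `R` defaults to the pair's observed
  Kimura-style transition/transversion count ratio, capped at 20 when no
  transversions are seen. Differences are averaged over minimal
  mutational pathways, excluding pathways through stop codons unless all
  are excluded; changes creating a stop count as nonsynonymous so that
  synonymous plus nonsynonymous sites sum to three per codon. Jukes–Cantor
  correction converts `pN`, `pS` to `dN`, `dS`.
* **Codon-based Fisher exact test**: one-sided hypergeometric tail on the
  rounded difference/site table, testing in the direction the data
  indicate (purifying when `pN < pS`, positive when `pN > pS`).

## The synthetic endogenization simulator

No sequence accessions accompany the study system, so the package ships a
generator (`simulate_dataset()`) that produces data with exactly the
structure the analysis assumes, plus ground truth:

* a TN93 generator (`tn93_model()`, default κ1 = κ2 = 4, frequencies
  A/T = 0.3, C/G = 0.2 — a mildly AT-rich genome typical of plant
  pararetroviruses) scaled to one expected substitution per site per unit
  distance;
* an exogenous viral lineage evolving at the configured viral rate with
  per-gene rate multipliers (default: a divergent ORFz-like gene at 2×
  over the first third of the genome, a conserved RT/RH-like gene at 1×
  over the middle third);
* endogenization events at configured times (Myr) on the branch of the
  host tree ancestral to a reference taxon, followed by neutral host-rate
  evolution down the dated tree, producing orthologous copies at each
  speciation and the implied presence/absence pattern;
* a young EVE group endogenized in a recent window (default 0.01–0.16
  Myr), branching off the same viral lineage, for majority-rule consensus
  building.

Simulation defaults encode the study conditions: long-term viral rate
5e-8 substitutions/site/year (the scale the corrected-distance method
measures over Myr windows), host rate 1e-9, endogenization at 4 Myr on the
AA stem of the four-taxon calibrated tree (node ages 2.41, 6.76, 15.00
Myr). The short-term viral regime (~1e-4 substitutions/site/year over
decades) enters the decay analysis as external literature points, matching
how such rates are measured in practice.

Two deliberate modelling choices:

* Young-group and neutral-test genealogies are drawn from a Kingman
  coalescent (`ape::rcoal()`; `simulate_neutral_alignment()`), not a star
  phylogeny: EVE copies sampled from a population share a genealogy, and
  the site-frequency-spectrum tests' null distribution is defined on
  coalescent samples. A star genealogy would push Tajima's D and
  especially Fu & Li's D* negative under perfect neutrality.
* Gamma site-rate variation and indels are off by default so closed-form
  expectations are exact in recovery tests; both can be switched on (gamma
  in the generator, gaps via the pairwise-deletion machinery) for
  robustness checks.

What the simulator does **not** emulate — and hence what passing recovery
tests cannot show about real data: recombination between viral groups
(the reason the study system excludes young-group inter-rates),
selection on viral genes before endogenization, insertion-site context,
segmental deletions and rearrangements after insertion, and alignment
error (simulated copies are gap-free and positionally aligned by
construction).

## Numerical choices and degenerate inputs

* Ultrametricity is verified on input trees to a relative tolerance of
  1e-6 of the root age; the error names the worst-offending leaf. Leaf
  ages are clamped to exactly zero afterwards.
* Dating ties: when several absence lineages attach at the same ancestor,
  the upper bound is that single node age; no ambiguity arises because
  intervals are defined by node ages, not lineage identities.
* `corrected_distance()` floors at zero with a warning; `rate_bounds()`
  rejects non-positive time bounds; `grh_fold()` and `rate_ratio()` reject
  zero denominators.
* The exact Wilcoxon null is built by integer convolution over doubled
  ranks (ties produce half-integer average ranks), which enumerates all
  `2^n` assignments without materialising them; beyond n = 25 the normal
  approximation is used and flagged.
* Reports are serialised with six significant digits in a fixed column
  order, so identical inputs give byte-identical files.
* All simulator randomness flows from the single config seed; re-running
  any pipeline stage with the same seed reproduces outputs byte for byte.

## Problem sizes in the test suite

The suite validates the statistical properties at sizes chosen to give
tight Monte-Carlo tolerances while keeping a full run in the order of a
minute or two on one core: 100 replicates of 3-kb loci for rate-interval
containment, 10 independent loci for GRH-fold recovery (tolerance ±0.3
around the true 2.0), 200 coalescent samples (n = 6, 2 kb) for type-I
error control of the neutrality tests (bound 0.08 at nominal 0.05), and
100-kb sequences for divergence-expectation checks. Oracle comparisons
(TN93, Tajima's D, Fu & Li, pathway counts, Wilcoxon enumeration) are
exact to 1e-9 and use small instances.

## Known limitations

* The dating logic assumes orthology calls are correct; it cannot detect
  mis-mapped loci, and precision is limited by taxon sampling — bounds are
  node ages, never interior points.
* `D_h` corrects with the closest sampled ortholog; for loci whose
  endogenization long predates that speciation the correction is an
  underestimate (conservative for rate upper bounds).
* Fu & Li significance thresholds are approximate (see above); the
  statistics themselves are exact.
* The decay regression treats points as independent and homoskedastic on
  the log scale; with two points it is an interpolation, not an estimate
  with uncertainty.
* Consensus building assumes the young-group copies are positionally
  aligned; alignment construction is upstream of this package.
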