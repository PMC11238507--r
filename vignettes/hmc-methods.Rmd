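---
title: "Homologous missense constraint: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Homologous missense constraint: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Purifying selection removes damaging missense variants from human
populations, so positions that matter are depleted of natural variation
relative to a neutral mutational expectation. At current exome cohort sizes
the expected number of observations of any single variant is usually below
one, so depletion cannot be detected residue by residue. `hmcscore`
implements the *homologous missense constraint* idea: residues occupying the
same match column of a protein domain family alignment are evolutionarily
equivalent, and pooling observed and expected rare-variant counts down such
a column (a *meta-position*) recovers enough expectation — tens of counts
for large families — to test depletion at quasi amino-acid resolution.

## The model

For a meta-position, let `O` be the number of distinct rare missense
variants (allele frequency below 0.1%, or absent) observed at any of its
residues, and `E` the summed expectation of such variants under a neutral
mutability model. With

\[ O \sim \mathrm{Poisson}(\lambda E) \]

and a flat (improper uniform) prior on the rate ratio \(\lambda\), the
posterior is \(\mathrm{Gamma}(O + 1,\; E)\). The constraint score is the
upper bound of the equal-tailed 90% credible interval, i.e. the 0.95
posterior quantile. This prior is a deliberate choice: it makes a score
below 1 *exactly* equivalent to one-sided posterior evidence of depletion,
\(P(\lambda \ge 1) < 0.05\), so "score < 1" and "significant at 0.05" are
the same statement, and at `O = 0` the score has the closed form
\(-\log(0.05)/E\). The companion point estimate (MLE) is `O/E`; a position
with score above 1 but MLE below 1 is plausibly constrained yet underpowered,
and the two are reported together for that reason.

The expectation side is a relative trinucleotide mutability table
(192 context/alternate pairs on the coding strand), stratified at CpG sites
by methylation level (0/1/2, with methylation accelerating the C>T
transition), multiplied by a coverage correction factor in [0, 1], and
anchored by a single global calibration constant `k` chosen so that the
summed expectation over assessable synonymous candidates equals the observed
rare synonymous count exactly. Calibration on synonymous variation within the
assessed regions keeps the null model self-contained; no per-gene
recalibration is performed. The calibration is invariant to a global
rescaling of the rate table, and conservation of the synonymous total holds
by construction.

## Parameters that matter

* `maf_threshold` (default 0.001): a variant matched at or above this allele
  frequency is *common* and leaves both the observed and the candidate set —
  it contributes to neither numerator nor denominator.
* `quantile` (default 0.95): the posterior quantile reported; 0.95 is the
  upper bound of the 90% equal-tailed interval.
* `alpha` (default 0.05): the significance level; it also defines the power
  (assessability) filter — a position is powered iff complete depletion
  could be called, i.e. `E > -log(alpha)` (about 3.0). The filter is
  expectation-based rather than copy-number based because expectation is the
  quantity that actually limits power; a configurable minimum copy number
  (default 2) is applied on top, since a single-copy "family" pools nothing.
* `bins` (default 0.5, 0.6, 0.8, 1.0): reporting bins, half-open with strict
  upper comparisons (`score < 0.8` is "highly constrained", `score < 1`
  "constrained", boundaries fall upward).
* Coverage cutoffs (defaults: full weight at depth ≥ 30, excluded below 10,
  linear or table-driven in between): the correction is piecewise,
  non-decreasing and bounded by [0, 1].

Thresholds are strict (`<`) everywhere; `score = 1` is not significant.

## Numerical choices and degenerate inputs

`qgamma` supplies the posterior quantile, so the score is deterministic and
needs no sampling. Positions with candidates but zero total expectation, a
context containing `N` (CDS edge without a supplied flank), or a zero
coverage factor are marked unassessable rather than erroring. Zero cells in
the evaluation statistics trigger 0.5 continuity corrections
(Katz rate ratios, Haldane–Anscombe odds ratios), noted in the result's
`method` field. Ties in precision–sensitivity curves are grouped: a
threshold admits all or none of an equal-score group.

## Open design points, resolved

* **Match columns without reference annotation.** Stockholm `#=GC RF` lines
  define match columns when present; otherwise a column is a match state iff
  its gap fraction is at most 0.5 — the common profile-HMM convention.
  Lowercase residues count as insert-state residues: they consume a protein
  position but never map.
* **Overlapping domain instances.** Within a family, the first instance by
  envelope start keeps a shared residue; across families a residue keeps the
  first family by sorted accession (with a warning), so every variant has at
  most one meta-position.
* **Exon-junction context.** The transcript inputs (CDS plus exon table)
  carry no genome sequence, so trinucleotide context at internal exon
  junctions is read from the spliced transcript; optional flank sequences
  are honoured at the CDS termini, otherwise the edge base is `N` and the
  variant is unassessable. For single-exon and short multi-exon synthetic
  fixtures this affects at most two codons per junction.
* **Allele frequency.** The global AF from the input is used as the minor
  allele frequency; no population-maximum logic.
* **Neighbour-column pooling** is deliberately not part of the score
  (precision is favoured over sensitivity); the bin and threshold machinery
  accepts arbitrary edges so sensitivity analyses can be built on top.

## What the synthetic generator emulates — and what it does not

`sim_reference()` builds domain families whose gapless copies are embedded
in single- or two-exon transcripts (some on the minus strand), a complete
relative rate table, uniform deep coverage, a CpG methylation map, and a
per-column depletion profile `s` in [0, 1]. `sim_cohort()` then observes
each possible SNV as a rare variant with probability
\(1 - e^{-(1-s)\,k\,\mu_{adj}}\) — Poisson *presence*, not per-individual
genotypes, because the score consumes site-level presence. `cohort_scale`
states the cohort size as the target mean expected missense count per
meta-position (the scale the method actually cares about), so study
conditions such as "expectation near 20 per column" are set directly.

Three honest limitations. First, presence saturates: when a variant's
per-cohort expectation approaches 1 the linear expectation model overstates
what can still be discovered. The generator therefore keeps per-variant
rates modest (CpG transition boosts of 2× and 3.5× at methylation levels 1
and 2) so that the simulation stays in the regime the method assumes — the
regime of real exome cohorts, where most per-variant expectations are far
below one. Consequently, checks of MLE recovery use large families (50–60
copies) when per-column expectation is pushed to ~50. Second, alignments are
generated already correct; alignment error, a real failure mode, is not
simulated, so passing tests say nothing about misalignment robustness.
Third, there is no demography, linkage or population structure — allele
frequencies are decorative draws used only to exercise the rarity filter.

Problem sizes used in the shipped checks (chosen as comfortable desk-scale
conditions): 6 families of 8–12 copies and 25–40 columns (~200
meta-positions, ~23,000 possible SNVs) for ranking and calibration checks;
3 families of 50–60 copies for the deep-cohort MLE check; 20,000 directly
simulated Poisson positions for null calibration of the score; 100 label
replicates of 2,000 variants for the risk-ratio calibration check — the
last size matters because under the null ~98% of variants share one
stratum, and the log-normal interval needs non-trivial counts per cell
before its nominal level is honest.

## Evaluation statistics

`rate_ratio()` (Katz log-normal CI), `dnm_burden()` (exact Garwood Poisson
CI and one-sided enrichment p-value), `odds_ratio_2x2()` (Woolf CI) and
`precision_sensitivity()` mirror the comparisons used to evaluate constraint
scores against labelled variant sets, de novo mutation lists and
case–control carrier counts. The CI methods are stated choices, not claims
about the evaluations they imitate: the source analyses report intervals
without naming constructions.

## Known limitations

Only missense SNVs are scored; indels, multi-nucleotide substitutions and
splice effects are out of scope, as are gene-level ("horizontal") scores and
genome-build liftover. Scores inherit every limitation of the input
alignments: residues misassigned to a column dilute or corrupt the pooled
signal, and domain families with few copies are simply unassessable. The
flat prior is convenient and calibrated for the one-sided depletion
question, but it is not a subjective prior on selection strength; users who
need shrinkage across positions should treat the (O, E) pairs as data for
their own hierarchical model.
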