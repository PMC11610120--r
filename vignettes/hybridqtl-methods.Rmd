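---
title: "Pooled-segregant QTL mapping in inter-species hybrid yeast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pooled-segregant QTL mapping in inter-species hybrid yeast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridqtl)
```

# The experiment this package models

An inter-species *Saccharomyces* hybrid (a *S. cerevisiae* x
*S. kudriavzevii* cross) is taken through repeated meiotic cycles to an
F12 generation, producing a few hundred diploid hybrid progeny. Each
progeny carries exactly one recombinant haplotype per **sub-genome** — the
chromosome complement contributed by one parental species — a consequence
of how the diploids are recovered from the tetraploid intermediate, and
the reason all genetics here is haploid per sub-genome.

Progeny are phenotyped for colony size on drug plates (four technical
replicates each), the 20 best and 20 worst strains per condition are
pooled and sequenced, and founder-diagnostic SNP markers let the pooled
reads be assigned a parental origin. A QTL announces itself as a region
where the designated founder allele frequency differs between the two
pools in a diametrically opposite way. The package implements every
computational stage of this design, plus a synthetic-data generator that
emulates the whole experiment so each stage can be tested against a known
truth.

# Phenotype quality control

Replicate colony sizes are screened with a quartile fence: from the four
replicate values, quartiles are computed by linear interpolation
(`type = 7`, R's default; the convention is configurable since the rule's
description does not fix one) and values outside
`[Q1 - 1.25 IQR, Q3 + 1.25 IQR]` are excluded. The median of the kept
replicates is the strain's fitness in that condition. We read the
exclusion rule as dropping outlier *replicates* before the median rather
than whole strains: the median is explicitly the downstream statistic,
and an outlier fence on four values that discarded whole strains would
interact badly with the pool design. A strain is dropped only when it has
no usable replicates.

Normalised colony size is the per-strain ratio of a condition's median to
the control (`YPD`) median; the control label is configurable. Dispersion
across strains is summarised by the quartile coefficient of dispersion
`(Q3 - Q1)/(Q3 + Q1)`, a scale-free statistic suited to comparing spread
between drug and rich media, and viability by the fraction of strains
whose median exceeds a threshold (default 0, i.e. any measurable colony —
the biological notion of "sustaining growth" is not quantified, so the
threshold is exposed).

Pool selection ranks strains once by `(median, strain id)` and takes the
`n` largest and `n` smallest (default `n = 20`). Ranking once guarantees
the two pools are disjoint and deterministic even when ties straddle a
pool boundary. Raw medians are used for ranking; since both pools come
from a single condition, normalisation by the control is a monotone
per-strain rescaling that could reorder strains only through the control
itself, and which scale the original selection used is not recorded — we
chose raw medians and expose the summary table so either is available.

# Founder markers and pool counts

Founder strains are haploid-called individually, so their VCFs carry one
allele per site. Sites are filtered to SNPs (single-nucleotide REF and
ALT); a site becomes a marker for a sub-genome when both founders are
called with depth at least 10, exactly one carries a single alternate
allele, and the site is bi-allelic across the pair. Sites where the two
founders carry different alternates (tri-allelic), heterozygous-looking
calls (impossible under haploid calling), multi-allelic records, and
depth failures are tallied in a rejection report rather than silently
dropped. A founder with no record at a site is treated as depth 0 —
conservative, and consistent with the depth filter's intent. The depth-10
filter is applied to founder calls *and* pool records: the filter's
placement between the two steps in the original description is ambiguous,
and applying it to both is the conservative reading.

Pool VCFs contribute reference (`RO`) and alternate (`AO`) observation
counts at marker sites whose alleles match the panel. Counts are oriented
to one **designated founder** per sub-genome — `a = AO` where that founder
carries the alternate, `a = RO` otherwise — so that a single frequency
track has a consistent meaning along the genome. The default designated
founder is the alt-richer founder of the panel (the non-reference
strain). Markers absent from a pool VCF are no-data, not zero counts:
absence of a record does not encode depth.

# The contrast LOD scan

The scan's latent state at a genomic bin is `j`, the number of the pool's
`N` haploid genomes carrying the designated allele (`N = 20` by default).
Two model ingredients:

* **Transition.** Over a distance `d`, each pooled haplotype
  independently resamples its founder origin from Bernoulli(1/2) with
  probability `r = (1 - exp(-2 d / (100 m)))/2`, where `m` is the
  chain's bp-per-cM scale; a carrier therefore stays a carrier with
  probability `1 - r/2`, and from state `j` the next count is
  `Binomial(j, 1 - r/2) + Binomial(N - j, r/2)`. The kernel's stationary
  distribution is Binomial(N, 1/2) — the null expectation for random
  segregants — and the chain is reversible with respect to it, which the
  contrast below exploits. Because the per-step resampling probability
  saturates at 1/2, a single arbitrarily long step does not reach
  stationarity; stationarity is approached along the chain.

* **Emission.** Reads sample the pool binomially: with state `j` a read
  reports the designated allele with probability
  `q = (j/N)(1 - eps) + (1 - j/N) eps`. The per-read error `eps`
  (default 0.002) keeps single miscalled reads from zeroing a
  likelihood. Markers are aggregated onto a uniform grid of `res_bp`
  bins (default 100 bp; 1-based positions, so position `res_bp` falls in
  the first bin); empty bins carry `(0, 0)` and have emission likelihood
  1.

Scaled forward–backward smoothing gives, per pool, the data likelihood
`L` and per-bin state posteriors `gamma`. The per-bin LOD contrasts two
generative models of the pool pair: fully independent chains, versus a
**tied** model in which one state is drawn from the Binomial(N, 1/2)
prior at the test bin and shared by both pools, dynamics otherwise
independent. By reversibility the tied likelihood collapses to
`L_high L_low sum_j gamma_high(j) gamma_low(j) / prior(j)`, so

```
LOD(x) = -log10 sum_j gamma_high,x(j) gamma_low,x(j) / prior(j)
```

Agreeing pools give LOD below 0 (down to `log10 prior(j)`), disagreeing
pools arbitrarily large values, and an exactly impossible tie (only
reachable with `eps = 0`) returns a `+Inf` sentinel, capped at 1000 in
file output so downstream interval logic keeps an orderable value. For
`N = 1` and a single bin the statistic is fully enumerable by hand —
both pools observing their single haplotype's allele once gives
`LOD = -log10 2` — and the test suite pins the general case against
exhaustive enumeration over all state paths (pairs of paths with an
equality constraint for the tied model) to a relative error below 1e-9.

## The bandwidth of the scan, and why it is not the physical map

`bp_per_cM` in the scan is the decorrelation scale of the latent chain.
It is tempting to set it to the physical recombination density of the
cross divided by the F12 map expansion (2500/6 ≈ 417 bp/cM under the
generator's defaults), and `lod_params()` exposes exactly that choice.
The pipeline default is deliberately different, and much shorter
(25 bp/cM), for a reason worth spelling out.

With pools of only 20 haplotypes, the two pools' allele counts at a null
locus are independent draws from Binomial(20, 1/2): they genuinely
differ, typically by a frequency gap of ~0.16 persisting over a linkage
block (~20 kb at the F12 map scale). At 100x per-marker depth and a
marker every ~500 bp, a physically matched chain pools thousands of
reads per coherence length and resolves those drift states essentially
exactly — whereupon the tied model, which is *false* at every null locus
of a 20-strain pool experiment, is rejected with LOD 30–70 over runs
longer than 20 kb. The LOD >= 5 across >= 20 kb decision rule then
loses all specificity: every seed we simulated produced 2–8 spurious
calls per megabase under the null.

Shortening the chain's memory makes each bin's posterior depend on only
the one or two nearest markers, widening it to a few states. Moderate
drift gaps then keep overlapping posteriors (LOD stays below 5 between
markers, so no 20 kb run survives), while selection signals — frequency
gaps of 0.8 and more spanning the QTL's whole recombination footprint —
still hold LOD above 5 continuously across tens of kilobases. The
default of 25 bp/cM was fixed once by this specificity calibration
against the generator's null at the study design (zero calls in all
calibration runs, with single-interval recovery of strong planted QTLs
retained) and is exposed in `run_config()`; it should be recalibrated if
the pool size, depth, or marker density change materially. The published
tool this scan re-implements does not document the internal settings
used for the original analysis, so the bandwidth is an explicit choice
here rather than a reproduction.

## What the support interval can and cannot do

QTL intervals are maximal runs of consecutive bins with
`LOD >= min_lod` (default 5) spanning at least `min_span_bp` (default
20 kb, measured across the run's outer bin edges — we read the published
"extended across at least 20 kb" as the run, not the support interval).
The peak is the run's maximum bin (leftmost on ties, for determinism),
and the support interval is the widest contiguous range around the peak
within `support_drop` (default 1) of the peak LOD — allowed to extend
beyond the run, as usual for drop-based supports. Intervals whose
posterior pool frequencies do not straddle 1/2 in opposite directions at
the peak are dropped by default ("diametrically opposite trend",
operationalised at the peak bin since no formula is published).

A 1-LOD support interval is a meaningful confidence region when the LOD
surface is smooth and its peak is a few LOD units high. Under strong
selection at high depth this statistic is in a different regime: the
peak LOD is in the hundreds and is a product of near-delta posterior
tails, so it moves by more than one LOD unit between adjacent bins with
the sampling noise of individual markers. The 1-LOD support then
degenerates to roughly one bin placed wherever the noisiest marker sits
within the QTL's plateau — it contains the causal position only by
luck, and our recovery experiments show exactly that (single-bin
supports that miss a planted QTL the LOD >= 5 run covers reliably). For
localisation under strong signals, use the run bounds, or a support
drop comparable to the peak height; the package reports both run and
support coordinates for every interval so the choice stays with the
analyst.

Genes annotate an interval when their 1-based coordinates overlap the
support interval by at least one base, taken from GFF3 `gene` features.

# Cross-condition and cross-sub-genome structure

Pleiotropic regions are connected components of the >= 1 bp overlap graph
of support intervals within a (sub-genome, contig), kept when they join
two or more distinct conditions; component grouping (rather than pairwise
reporting) makes a region found in all three drugs appear once. The group
span is the intersection of member intervals, falling back to the union
(flagged) when the component is chained without a common core.

Sharing across sub-genomes is decided by gene content, never by
coordinates — orthologous regions can occupy different relative positions
on the two species' chromosomes — so two same-condition intervals are
shared when their annotated gene sets contain at least one pair from a
supplied ortholog table (consumed as a plain two-column mapping;
inference of orthology is out of scope). Summaries per condition and
sub-genome report interval counts, de-duplicated gene counts, and mean
± sample-sd support lengths in kb.

# Growth curves for reciprocal hemizygosity

Validation of candidate alleles compares growth of reciprocal
hemizygotes in liquid culture. Well time series are fitted to the
logistic model `N(t) = K / (1 + ((K - N0)/N0) exp(-r t))` by
Levenberg–Marquardt least squares (initialised from the max density,
first positive density, and early log-linear slope; tolerances tight
enough that exact model data are recovered to better than 1e-6
relative). Derived metrics use closed forms: `Tmid = log((K - N0)/N0)/r`
— the time of half capacity, which we take as the intended meaning of
"the time at which the population density reaches 1/K" in the source
description, matching the fitting package it cites — and
`auc_l = (K/r) log((K + N0 (exp(rT) - 1))/K)`, the integral of the
fitted curve to the last observed time `T`, alongside the trapezoidal
integral of the raw data. Group comparisons use the pooled-variance
Student's t-test (two-sided), as in the original analysis; Welch can be
had by passing the metric vectors to any test the analyst prefers. When
comparing `auc_l` across wells with different horizons, integrals should
be computed over the common minimum `T` so they are commensurable.

# The synthetic cross

The generator emulates, per seed: founder-diagnostic markers with
exponential spacing (mean 500 bp); F12 haplotypes as two-state Markov
mosaics whose marker-to-marker switch probability is the Haldane
fraction at `map_expansion * d / (100 bp_per_cM)` Morgans — the twelve
generations are collapsed into a single map-expansion multiplier
(default 6, the g/2 advanced-intercross expectation for g = 12) because
only marginal breakpoint density matters to the inference being tested;
colony sizes as `baseline + additive QTL effects + Gaussian noise`,
with four log-normal technical replicates (multiplicative noise keeps
sizes positive and right-skewed) and occasional 3–10x outliers; and
pooled reads as Poisson depth with binomial allele sampling flipped by a
per-read error. The tetraploid intermediate's four founders are
collapsed to two per sub-genome — all the marker analysis can see.
Default study sizes mirror the modelled experiment: 228 progeny, pools
of 20, per-marker depth 100, 1 Mb contigs.

Everything is emitted in the same formats the analysis consumes (founder
and pool VCFs with `RO`/`AO` counts, phenotype TSV, contig map, GFF3
with synthetic gene features), so a round trip through the real readers
is part of the test suite, bit-exactly for the marker panel. Seed
sub-streams per stage are fixed offsets of the master seed, making every
stage independently reproducible and full runs checksum-stable.

What the generator does *not* emulate — and what green tests therefore
do not certify on real data: mapping bias between sub-genomes and
read-mishoming across them (the real pipeline maps against a
concatenated hybrid reference), structural variation and
loss-of-heterozygosity, shared ancestry among F12 progeny (haplotypes
are simulated independently), plate spatial effects, and
depth-dependent variant-caller artefacts. The generator's role is to
verify the inference machinery against a known truth, not to imitate
every nuisance of the original data.

# Numerical and degenerate-input choices

Forward–backward uses per-bin scaling (verified against log-space
computation to 1e-9 on 10,000-bin tracks); an all-zero emission row
(possible only with `eps = 0`) yields `-Inf` log-likelihood and a
flagged track rather than an error. Quartiles are `type = 7` throughout.
Ties at interval peaks go leftmost; pool-selection ties are broken by
strain id within one global ranking. Empty marker panels, header-only
VCFs, empty interval sets and single-interval summaries (sd reported as
NA) all pass through without special-casing by the caller. Problem
sizes used by the shipped end-to-end tests — 20 seeded pipeline runs
each for planted-QTL recovery and null calibration at the full study
design, plus enumeration oracles at `N <= 3` over up to 4 bins — were
chosen so the whole suite also serves as a worked example of the
recommended analysis scale.
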