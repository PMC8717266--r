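---
title: "Estimating spontaneous mutation rates and spectra from mutation-accumulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating spontaneous mutation rates and spectra from mutation-accumulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mamut)
```

## The experimental design and its model

A mutation-accumulation (MA) experiment propagates many independent
lineages of a microbe through repeated single-colony bottlenecks. Because
each transfer reduces the population to one cell, selection is nearly
powerless and non-lethal mutations fix by drift at the rate at which they
arise. Whole-genome sequencing of the terminal lines, compared against the
ancestral reference, therefore yields a direct and nearly unbiased census
of spontaneous mutations. `mamut` implements the downstream analysis of
such an experiment — from per-line variant call sets to rates, spectra and
hotspot statistics — together with a simulator that generates complete
synthetic experiments with known ground truth, so that every estimator in
the package can be validated end to end.

The number of generations elapsing between bottlenecks is estimated from
colony size: a colony founded by one cell that has grown to `CFU` cells
has undergone `log2(CFU)` doublings (`generations_from_cfu()`). A line
observed through `t` transfers has `T = t * log2(CFU)` generations, and
with `N` callable sites contributes `N * T` *site-generations* of exposure.

Mutation counts are modeled as Poisson. The pooled rate over `n` lines is

$$\hat\mu = \frac{m}{\sum_{i=1}^{n} N_i T_i},$$

with `m` the total number of accepted mutations (`pooled_rate()`). The
95% interval is Garwood's exact Poisson interval obtained from chi-square
quantiles, $[\tfrac12\chi^2_{\alpha/2,\,2m},\ \tfrac12\chi^2_{1-\alpha/2,\,2m+2}]$
divided by the exposure, with the lower bound defined as 0 at `m = 0`
(`poisson_ci()`). The standard error of the mean per-line rate uses the
sample standard deviation (n−1 denominator) of $m_i/(N_iT_i)$ over lines;
the SD convention is not forced by the estimator definition, and the
sample version is the standard choice for an SEM.

## Filtering the call sets

Variant callers produce more candidates than true mutations. The package
applies the filter cascade appropriate to an MA design, with every step
logged at call granularity by `run_pipeline()`:

* **Site quality** (`apply_site_filters()`): QUAL strictly greater than
  100 and RMS mapping quality strictly greater than 59 by default. The
  strict inequality is deliberate; boundary values are rejected.
* **Consensus** (`apply_consensus_filter()`): more than 99% of reads must
  support the line's allele. The 1% allowance absorbs aberrant reads from
  sequencing error or index cross-talk; a true fixed mutation in a clonal
  line should be essentially homogeneous.
* **Uniqueness** (`remove_shared_mutations()`): a (position, ref, alt)
  triple seen in two or more independently bottlenecked lines cannot
  plausibly be independent mutation; it is ancestral variation or a
  systematic artifact and is removed from all lines. Two different ALT
  alleles at the same position in different lines are distinct triples and
  both survive.
* **Dual-caller reconciliation** (`reconcile_callers()`): calls from two
  independent pipelines are matched on (line, position, ref, alt) after
  left-normalizing indels (`normalize_variant()`), since callers anchor
  indels differently. The default merge policy keeps the primary caller's
  set and reports concordance, because the headline rates of a typical MA
  study are computed from a single designated caller; intersection and
  union policies are available.

## Spectrum, equilibrium GC, and the NS:S null

Substitutions collapse into six strand-symmetric classes
(`classify_substitution()`), two transitions and four transversions.
Directional rates are normalized by the composition of the genome:
changes away from G:C pairs divide by the G/C share of the exposure,
changes away from A:T pairs by the A/T share (`conditional_rates()`).
Under mutation pressure alone the genome's GC content converges to

$$\mathrm{GC}_{eq} = \frac{\mu_{A/T \to G/C}}{\mu_{G/C \to A/T} + \mu_{A/T \to G/C}},$$

which is invariant to common rescaling of the two rates
(`equilibrium_gc()`), so composition-normalized counts suffice.

To ask whether selection has skewed coding mutations, the package
computes the expected nonsynonymous:synonymous ratio by enumerating all
`3L` possible single-base changes across every CDS — codon usage enters
implicitly through the actual coding sequence, annotated stop codons
included (`expected_ns_ratio()`). Each specific transition is weighted
`w_ti` and each specific transversion `w_tv = 1`. Because every site
offers exactly one transition and two transversions, setting
`w_ti/w_tv = 2 * (ts/tv)` makes the aggregate expected
transition:transversion count ratio equal the observed ts/tv; the
multiplier is exposed (`ti_weight_multiplier`) because the weighting
convention is a modeling choice, not a theorem. Stop-gain changes count
as nonsynonymous; stop-preserving changes within annotated stop codons as
synonymous. At sites covered by overlapping CDS annotations, a change is
nonsynonymous if it is nonsynonymous in any frame. The observed split is
tested against the expected proportions with a one-degree-of-freedom
goodness-of-fit chi-square without continuity correction
(`ns_ratio_test()`).

Region contrasts (coding vs noncoding, SSR vs non-SSR) use a two-sided
exact test on the 2×2 table of events against non-event site-generations.
`stats::fisher.test()` cannot accept table entries at the 10^11
site-generation scale (they exceed integer range), so the package
evaluates the same conditional hypergeometric test directly
(`fisher_exact_2x2()`); the support of the conditional distribution is
bounded by the event margin, so the computation is exact and cheap at any
denominator scale, and it reproduces `fisher.test()` on small tables.

## SSRs and indel hotspots

Simple sequence repeats are detected as maximal perfect tandem repeats of
primitive 1–6 bp motifs (`find_ssrs()`). The default thresholds — at
least 8 copies for mononucleotide runs, 5 for di-, 4 for tri-, 3 for
tetra- through hexanucleotide motifs — were chosen once so that a
synthetic 60.5% GC genome carries roughly 1% SSR coverage, the figure
typical of prokaryotic genomes; they are fully configurable. Overlapping
candidates are resolved longest-first (ties: smaller motif, then
leftmost). Imperfect or compound repeats are out of scope.

An indel overlaps an SSR when its left-normalized affected span — the
deleted interval for deletions, the insertion point for insertions —
intersects the SSR interval. Events longer than 50 bp are excluded from
the small-indel class with a warning. `indel_region_analysis()` reports
insertion/deletion balance (`indel_size_balance()`), coding-region
depletion against the uniform expectation `total × coding_fraction`
(reported rounded, tested unrounded), and SSR overlap with the
corresponding rate ratio.

## What the simulator emulates — and what it does not

`generate_genome()` builds a single-contig genome with non-overlapping
CDS on both strands (in-frame, internally stop-free under translation
table 11 — the organism emulated is a bacterium), planted SSR tracts, and
a background composition solved so the realized GC matches the target
within 0.01. Coding-hosted SSR motifs are G/C-only, which cannot create a
stop codon in any frame or strand; the noncoding base composition is then
adjusted analytically to compensate, keeping whole-genome GC on target.
Defaults emulate a 4.13 Mb, 60.5% GC genome with 88.3% coding fraction
and ~1% SSR coverage, with ~92% of planted SSR base pairs in coding
sequence.

`simulate_ma_experiment()` draws per-line counts as Poisson
(`rate × N_i × T_i`), samples substitution classes from configurable
spectrum weights conditioned on site composition (a G:C class requires a
G/C site), and places indels with an `ssr_hotspot_multiplier`-fold weight
inside SSR spans. The default multiplier of 64 is the fold-change that
puts ~39% of indels into ~1% of the genome — solving
`k·s/(k·s + 1 − s) = 12/31` at SSR coverage `s = 0.0098` gives `k ≈ 64`.
The default spectrum weights (17, 40, 3, 10, 9, 9 across the six classes)
reproduce a strongly AT-biased, transition-dominated spectrum with ts/tv
57:31; the split between the two transversion classes that empirical
spectra often leave unresolved (A:T>T:A and G:C>C:G) is set to equal
weights.
Deletions remove the bases following the anchor; insertions duplicate the
downstream tract, emulating replication slippage. At most one mutation is
placed per site per line — at realistic rates the per-site collision
probability is ~10^-7, so multiple hits are negligible by design rather
than by accident.

Emitted fixtures are noise-free: every VCF record carries QUAL 500,
MQ 60 and allele fraction 1, comfortably above the default thresholds, so
a clean round trip through ingest and filters is the identity on the
ground truth. CFU values are emitted as `round(2^g)` so that
`log2(CFU)` recovers the generations-per-transfer used in simulation.
The simulator deliberately does **not** model read-level noise,
mapping artifacts, coverage heterogeneity, false-positive calls,
within-colony population dynamics between bottlenecks, or selection.
Passing tests on simulated data therefore validate the estimators and
bookkeeping, not the upstream variant-calling accuracy on real reads.

## Numerical and design choices

* **Coordinates.** All internal coordinates are 1-based inclusive, the
  Biostrings/GenomicRanges convention, so VCF positions need no
  translation on either read or write; BED export converts to 0-based
  half-open. Mixing a 0-based convention into Bioconductor containers
  invites off-by-one errors.
* **Callable sites.** Per-line callable-site counts are taken as input
  metadata (real experiments report them from coverage); the simulator
  accepts per-line values but defaults to a common 3.5e6. Simulated
  mutation positions are drawn over the whole genome — callability is not
  modeled spatially, only as exposure.
* **Degenerate inputs.** Zero events give rate 0 with CI lower bound 0;
  a zero denominator, an empty CDS set for the NS:S null, or two zero
  directional rates for the equilibrium are hard errors rather than NaNs.
  A ts/tv with no transversions reports `Inf` with a warning rather than
  failing, since downstream summaries can still be rendered.
* **Problem sizes.** The test suite exercises the generator at 200 kb
  (the package's standard small-genome validation size, where brute-force
  oracles for SSR detection and NS:S enumeration remain exact and fast)
  and parameter-recovery at the full 69-line design over 100 replicate
  simulations; the genome generator has been run at the full 4.13 Mb
  scale, which completes in seconds and lands on its composition targets
  with the same accuracy.

## Known limitations

* Every summary statistic is computed from the counts the package is
  given, never asserted independently of them, so its outputs are always
  mutually consistent: class counts sum to the substitution total, the
  NS:S ratio and its chi-square follow from the synonymous and
  nonsynonymous counts, and insertion, deletion and combined indel rates
  share one denominator. Reported figures that violate these identities
  cannot be reproduced, by design.
* The coding/noncoding rate contrast uses region fractions of the whole
  genome applied to the pooled denominator. If callable sites are
  distributed unevenly between regions, region exposures are
  approximated; a per-line, per-region callable partition would refine
  this but is not part of the input contract.
* Perfect-repeat SSRs only; mobile elements and structural variants are
  out of scope.
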