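---
title: "Methods: somatic landscape analysis of retinoblastoma exomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: somatic landscape analysis of retinoblastoma exomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbscape)
```

# Scope and model

`rbscape` reimplements, as a tested and reusable pipeline, the analysis
stages used to characterise the somatic genomic landscape of
retinoblastoma from tumor/normal whole-exome sequencing derivatives:

1. **Somatic SNV/INDEL identification** against a pooled, anonymized
   germline variant database, followed by a pathogenicity filter and a
   distinct-patient recurrence rule.
2. **Copy-number profiling** from binned (20 kb) read depth:
   GC/mappability normalization, log2 tumor/normal ratios (LRR),
   piecewise-constant segmentation, arm-level calls, high-level
   amplification calls, chromothripsis detection, a per-gene cumulative
   recurrence score, and genetic-sex QC.
3. **Allelic imbalance / LOH** from mirrored B-allele frequencies (mBAF).
4. **Purity and subclonality**: tumor cellularity from driver VAFs and
   subclonal fractions from copy-number amplitudes.
5. **Event statistics**: a binary tumors-by-events matrix with pairwise
   mutual-exclusivity (phi coefficient, Fisher exact, Benjamini-Hochberg)
   and event-phenotype association tests.
6. **Viral read screening** with a k-mer seed-and-extend classifier and a
   phage spike-in as positive control.

Upstream read processing (trimming, alignment, genotype calling,
transcript annotation) is out of scope; the package consumes variant
tables, binned depths and BAF markers that such tools emit.

Because the original patient-level data are access-controlled, the
package ships a first-class synthetic cohort simulator with fully
recorded ground truth.  All tests and the acceptance analyses run against
simulated cohorts and closed-form arithmetic; nothing requires a
download.

# Key quantitative rules

All thresholds below are function arguments with the listed defaults.

| Rule | Default | Where |
|---|---|---|
| Variant quality filter | discard depth < 5, QUAL < 50, FS > 60 (strict) | `qualityFilter` |
| Somatic call | key (chrom, pos, ref, alt, genotype class) absent from the pooled germline DB and depth >= 10 | `callSomatic` |
| Pathogenic | population frequency < 0.1% in both panels, PASS, truncating/splice or missense with >= 2 of 4 predictor votes | `pathogenicityFilter` |
| Recurrence | >= 2 distinct patients per gene | `recurrentGenes` |
| Ploidy | `2 * 2^lrr` (diploid reference) | `ploidyOf` |
| High-level amplification | segment LRR > 2.32 (> 10 copies, strict) | `callHighLevelAmplifications` |
| Arm altered | length-weighted mean ploidy > 2.3 or < 1.7 | `callArmEvents` |
| Chromothripsis | >= 8 segments, >= 2 discrete states, >= 6 switches on one chromosome | `detectChromothripsis` |
| Marker filter | >= 20x depth in >= 80% of samples (inclusive) | `filterMarkers` |
| Allelic imbalance | segment mean mBAF > 0.6 over >= 5 consecutive markers | `segmentMbaf` |
| LOH | segment mean mBAF > 0.8 (strict) | `callLoh` |
| Purity | compound het: `2 * mean(VAF)`; homozygous after copy-neutral LOH: `mean(VAF)`; clamped to [0, 1] | `purityFromVaf` |
| Subclonal fraction | `f = (observed - 2) / (purity * copyChange)`, clamped | `subclonalFraction` |

Boundary semantics follow the quoted inequalities strictly: a record at
depth 5, QUAL 50 or FS 60 is kept; a segment at mBAF exactly 0.8 is
allelic imbalance, not LOH; a segment at LRR exactly 2.32 is not
amplified; an arm at mean ploidy exactly 2.3 or 1.7 is unaltered.

Where a published rule is qualitative, the package commits to one
quantitative reading and exposes it as configuration:

* **Genotype-class identity.** Two variants are identical only if
  coordinates, alleles *and* genotype class agree.  "Similar genomic
  coordinates" is read as exact equality; no positional tolerance.
* **Population-frequency rule.** The < 0.1% requirement is applied as an
  AND across both reference panels (the stricter reading).
* **mBAF threshold.** The 0.6 imbalance threshold applies to the segment
  mean, not to individual markers.
* **Arm-level mean.** Length-weighted over overlapping segments (robust
  to within-arm segment permutation at a fixed weighted mean).
* **Phi significance.** The published analysis says only that phi was
  "tested for significance"; this package uses a two-sided Fisher exact
  test (chi-square available via `method =`), with one BH family across
  all event pairs and per-phenotype BH families for phenotype tests.
* **MYCN veto.** LOH at RB1 without a detected RB1 variant vetoes a
  MYCN-primary driver classification by default (`lohVetoesMycn`): the
  small variant may simply have been missed, as happens for poorly
  covered first exons.

# Segmentation

The published pipeline delegates segmentation to an external
changepoint package "under default parameters"; `rbscape` supplies its
own implementation so the whole analysis is self-contained and testable
against synthetic truth.  The algorithm is recursive binary
segmentation with a permutation test:

* At each recursion the best split of the series maximises a mean
  contrast statistic.  The statistic at boundary *k* is the larger of a
  global prefix/suffix two-sample contrast (equivalent to the
  RSS-minimising split for a single step) and a **multi-scale local
  contrast** over windows of 3, 5 and 10 bins either side of *k*.  The
  local term is what resolves oscillating (chromothripsis-like)
  profiles, whose two halves have similar global means.
* Statistics are standardised by a robust noise scale (median absolute
  successive difference / 0.954), re-estimated on every permuted series.
  This keeps segments that carry real structure from being penalised by
  their own signal variance.
* A split is accepted when its permutation p-value is below `alpha`
  (default 0.01, 1000 permutations, early-terminated once the p-value
  can no longer fall below `alpha`).  When the prefix split is not
  significant, an interior-window (circular-style) split is tried before
  declaring the segment flat.
* Minimum segment size is 3 bins; segment LRR is the mean of member
  bins; ploidy is `2 * 2^lrr`.

The acceptance surface is breakpoint recovery on synthetic truth (exact
on noiseless profiles, within ±2 bins on noisy single steps), not
equivalence with any external tool.

Numerical details worth knowing: tumor bin depths of zero over a covered
normal bin are floored at half a read before the log-ratio, so
homozygous deletions in near-pure tumors are treated as signal rather
than missing data; LRR profiles are centred on the modal cluster of
half-chromosome block means (a plain genome-wide median is biased by a
few tenths of a copy in gain-heavy genomes, where a quarter of the bins
can sit above the neutral state); bins below mappability 0.5 are
discarded; the GC trend is a degree-2 loess with symmetric
(outlier-resistant) fitting, applied per sample with the sample median
preserved.

# The synthetic cohort: what it emulates, and what it does not

`simulateCohort()` draws, per tumor: purity uniform on [0.9, 1] (these
tumors are typically highly cellular), an RB1 inactivation mode
(compound-heterozygous SNVs 45%, homozygous SNV after copy-neutral LOH
20%, focal homozygous deletion 15%, MYCN amplification 8%, none 12%),
recurrent arm-level events (16q loss in 80%, 6p gain 68%, 1q gain 40%,
2p gain 30%) at tumor-specific clonal fractions uniform on [0.2, 1], and
13q chromothripsis in two tumors drawn from those with no other RB1
mechanism (chromothripsis acts as the alternative inactivation route).

Generative laws:

* Somatic variant allele counts are binomial around
  `f * p * m / (p * cT + (1 - p) * 2)` — clonal fraction `f`, purity
  `p`, `m` mutated copies of `cT` local tumor copies.
* Bin depths are negative binomial around
  `meanDepth * gcBias * (p * cT + (1 - p) * 2) / 2` with dispersion
  0.02 (per-bin depth coefficient of variation about 17% at 100x).  The
  original study reports no depth-noise model; the default was set by a
  power analysis of the amplitude-based clonal-fraction estimator (the
  quantity the recovery tests measure) so that estimator error, not an
  arbitrary noise floor, dominates.  It is a user-visible argument.
* GC bias is a quadratic curve in GC content with configurable
  amplitude; the same positional GC profile is used on every
  chromosome, so a chromosome-level copy change contaminates any GC
  stratum by at most 1/6 of its bins and the robust trend fit ignores
  it.
* BAF markers sit every 20 kb at sites heterozygous in the normal
  (about 60 per arm); marker BAF is binomial around the allele-dosage
  expectation of the strongest local event with a randomly chosen
  affected haplotype.
* Age at diagnosis increases with the implanted 16q clonal fraction
  (older diagnosis, heavier arm-level alteration), so the
  amplitude-age rank correlation is a recoverable truth.
* Chromothripsis truth profiles alternate two copy-number states
  (losses 2/1, or mixed 3/1) across 10-14 segments of at least 8 bins
  (160 kb) spanning the whole chromosome, with the RB1 locus always
  inside an altered segment on chromosome 13.  The scale is set by two
  constraints: real shattering fragments (Mb-scale on a ~100 Mb
  chromosome) map to hundreds of kb on the 4 Mb reduced chromosome, and
  one-copy oscillations narrower than ~8 bins sit below the resolution
  of any mean-contrast segmenter at the depth-dispersion noise floor
  (per-bin LRR sd ~0.3), so narrower truth would be unrecoverable by
  construction rather than by defect.

The reduced genome is six 4 Mb mini-chromosomes (1, 2, 6, 13, 16, X)
with mid-arm gene loci for RB1, MYCN, BCOR, CREBBP, MDM4 and CDH11, so
a full cohort simulates and analyses in tens of seconds.  What the
simulator does **not** emulate: read-level alignment artifacts,
mapping-quality structure, sequencing-error profiles, real hg19
coordinates and real segment-size distributions, germline structural
variation, and multi-clone phylogenies (events are independent
two-population mixtures).  Passing recovery tests therefore demonstrate
the correctness and calibration of the estimators under the stated
generative model, not performance on real libraries.

# Problem sizes used by the tests

Unit tests use 2-10 tumor cohorts; recovery analyses use 24-tumor
cohorts on the reduced genome.  Purity and clonal-fraction recovery are
evaluated at 1500x driver-site depth: binomial VAF noise puts an
irreducible sd of about `2 * sqrt(VAF(1-VAF)/depth) / sqrt(2)` on the
compound-het purity scale (0.07 at 100x — wider than the ±0.05 band
being checked — and 0.018 at 1500x), so the deep setting measures the
estimator rather than counting noise.  At routine 100x the estimators
are unbiased with correspondingly wider spread.  Mutual-exclusivity
power is checked at 40 tumors with a 20/20 exclusive split, and type-I
control with 1000 replicate null matrices.

# Known limitations

* Binary segmentation with a permutation test has limited power for
  alternating segments shorter than ~8 bins at one-copy amplitude under
  the default depth dispersion; chromothripsis truth is generated at or
  above that scale.
* The purity estimator requires detected RB1 driver variants; tumors
  inactivated by deletion or amplification get no VAF-based purity and
  downstream subclonal fractions assume purity 1 for them (flagged in
  the report).
* The two-population mixture for subclonal fractions assumes a diploid
  background and a single event per region; nested or multi-state
  mixtures are out of scope.
* The event-matrix arm rows encode "altered" (either threshold crossed),
  not direction; direction is available from the arm-call table.
* The viral classifier is a presence/absence counter, not an aligner:
  ties are left unassigned and reads hanging more than half off a
  reference are rejected.
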