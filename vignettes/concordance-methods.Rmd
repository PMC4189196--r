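---
title: "Methods: paired primary–metastasis mutational concordance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired primary-metastasis mutational concordance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcconcord)
```

## The question and the model

When a colorectal primary tumor and its distant metastasis are both
sequenced, how faithfully does one lesion's somatic mutation profile
represent the other's? `crcconcord` quantifies this as *concordance*: among
the distinct somatic mutations called in a patient pair (the union of the
two call sets, each genomic event counted once per pair), the fraction
present in both compartments. Mutations called in only one compartment are
*private*. Three mechanisms can make a truly shared mutation look private,
and the pipeline addresses each explicitly:

1. **Calling thresholds.** A mutation at low allele fraction in one sample
   can fall below the retention filter there. *Comparative rescue*
   re-examines the other sample's pileup: if the mutant allele appears in
   at least 3 reads and at least 2% of all reads, the event is relabelled
   present in both (`both_by_comparative`).
2. **Spatial sampling.** A mutation subclonal in the primary may be absent
   from the sequenced block but present elsewhere. Sequencing additional,
   spatially separate regions and re-matching (`resolve_with_regions()`)
   marks such calls `resolved_subclonal_in_*`. Resolution is an overlay on
   the record, never a rewrite of its status, so pre- and post-resolution
   statistics are both reportable.
3. **Copy loss.** A mutation private to the primary may have been deleted
   with its locus in the metastasis. Gene-level tumor/normal depth-ratio
   copy number (`explain_private_by_deletion()`) marks these
   `explained_by_deletion`.

Matching identity is strictly genomic — the normalized
(chromosome, position, ref, alt) key — never gene- or protein-level:
convergent evolution (two different TP53 mutations, one per compartment)
must remain two distinct private events, not one shared one.

## Retention filters

Two published regimes are implemented in `panel_filter()` and
`wgs_filter()`, with every threshold in `threshold_config()`:

* **Panel (deep targeted sequencing):** retain non-synonymous calls with
  allele fraction strictly above 5%. "Above" is read as a strict
  inequality; "at least", where it appears in the rescue and WGS rules, is
  read as non-strict — mirroring the wording asymmetry of the source
  rules. The AF denominator is always total depth at the locus.
* **WGS trio:** retain a call iff it reaches at least 3 mutant reads *and*
  5% allele fraction in at least one of the two tumors, and the best tumor
  frequency is at least 5 times the normal-tissue frequency. The "in
  either tumor" clause is grammatically ambiguous in its source; requiring
  *both* tumors to pass would delete every private mutation by
  construction and contradict the existence of reported WGS-private calls,
  so "at least one tumor" is the implemented reading. A normal frequency
  of exactly 0 passes the ratio clause whenever any tumor frequency is
  positive.

Both filters are idempotent and monotone in their thresholds, and both
return a mandatory rejection log — auditability is not optional in a
pipeline whose downstream use is clinical interpretation.

Whether the panel AF threshold applies per sample or to the pair maximum
is not stated in the source rules; it is applied per sample here, which is
the stricter reading (rescue then recovers cross-sample support).

## Shared-fraction accounting

`cohort_summary()` maintains the partition invariant
`n_shared + n_private_primary + n_private_metastasis = n_distinct` at all
times. Rescued events count toward the shared fraction — on review the
mutation *is* present in both compartments — but the summary also emits
`shared_fraction_as_called`, with rescued events counted on their
originally called side. The two views bracket any published shared
fraction whose rescue accounting is unstated, and rescue only ever moves
mass between categories (never creates or destroys records).

## Copy number

Per-target copy number is the tumor/normal mean-depth ratio. Coverage
depends smoothly and non-linearly on local GC content, so a robust loess
of the raw ratio on GC (span 0.3, quadratic local fit, symmetric family)
is divided out; the symmetric family downweights bins carrying real copy
events, standing in for an explicit neutral-bin mask. Ratios are then
recentred to median 1, which anchors the diploid baseline under the
assumption — stated, not checked — that most of the captured territory is
copy-neutral. Bins with zero normal depth are masked, never imputed.

Gene-level states threshold the mean log2 ratio: deletion at or below
−0.7, gain at or above +0.4, amplification at or above +1.0, requiring at
least 3 unmasked bins. No published values exist for the span or cutoffs;
these are package defaults chosen so that a pure-tumor single-copy loss
(expected log2 = −1) is called while Poisson ratio noise at panel depths
(sd of log2 about 0.1–0.15 per bin) stays clear of every boundary. Purity
is *not* deconvolved: an impure tumor attenuates the expected single-copy
log2 toward 0 (e.g. purity 0.6 gives log2(1.4/2) ≈ −0.51), and tests on
impure simulations must widen their tolerances accordingly.

## MSI typing

From per-marker stability flags (default panel BAT25, BAT26, D17S250,
D2S123, D5S346): MSS iff no marker unstable, MSI-low iff the unstable
fraction is positive but below 30%, MSI-high at or above 30%. With five
markers the 30% boundary is unreachable (fractions are k/5), but the rule
is implemented for arbitrary marker counts. The pipeline's MSI gate keeps
only MSS patients, reproducing the emulated study's inclusion rule.
Electropherogram analysis is out of scope; stability booleans are input.

## Clinical association

`contingency_test()` is Pearson's chi-square with 1 df and **no**
continuity correction by default: on the published 2×2 counts
[[22,6],[11,13]] the uncorrected statistic gives p ≈ 0.015 (printing as
0.01) where the Yates-corrected form gives ≈ 0.031 — the uncorrected form
is what reproduces the published values, and the correction remains
available as a flag that is echoed in every result.
`mean_comparison()` defaults to the Student (pooled-variance) t test, the
plain reading of an unqualified "t test", with Welch as a flag; the
mutation-burden comparison, whose source test is unnamed, goes through the
same operation with the variant recorded. Per-patient discordance and
burden are always derived from the concordance records, never free-entered.

## What the generator emulates — and what it does not

`simulate_cohort()` draws, per patient: treatment, resection timing,
location, stage, and primary size from the emulated study's marginal
distributions; tumor purities uniform on (0.6, 0.9) (tissue is
macrodissected to majority tumor content); Poisson counts of truncal and
private mutations; per-variant read counts as depth ~ Poisson(mean) and
mutant reads ~ Binomial(depth, purity × CCF / 2) for a heterozygous
diploid locus, with normal-sample mutant reads at an error rate of at most
0.1%. This is the simplest model consistent with AF-threshold filtering
logic; an overdispersion layer was considered and left out because panel
depths of several hundred make the binomial noise already dominant over
any plausible extra-Poisson component at the thresholds being tested.

Defaults are the study conditions: 69 trios, 6.3 mutations per pair
(434/69), truncal fraction 0.79, panel depth 692X, WGS depths 87X/50X.
The treatment multiplier on the expected private burden is 0.4,
back-solved from the published arm-level discordance fractions (79%
untreated vs 46% treated) under the Poisson burden model; private rates
are normalized over the treatment marginal so the configured shared
fraction stays the cohort-wide expectation. Two quantities have no
published value and are the package's own choices: private-clone
cancer-cell fractions uniform on (0.3, 0.9) — low enough to be genuinely
subclonal, high enough that a 692X panel almost always calls them, so the
generator's truth and the pipeline's estimate are comparable — and the
fraction of private mutations resolvable in the other compartment, 0.37
(matching the published 17-of-46 resolution rate).

What passing tests on this generator do **not** show about real data: no
FFPE artifacts, no mapping or strand bias, no germline leakage, no
overdispersed capture efficiency, no CCF correlation structure between
mutations of one clone, and indels appear pre-normalized rather than in
the messy right-shifted spellings real callers emit (the normalizer is
exercised on constructed cases instead).

## Numerical and degenerate-input choices

* Coordinates: variants 1-based (VCF convention), coverage targets 0-based
  half-open (BED convention); both stated in the readers and enforced in
  tests.
* Indel keys are left-aligned and parsimonious when flanking sequence is
  available; without it, only shared prefix/suffix trimming is possible,
  and the report metadata records the convention.
* Unknown contigs are preserved verbatim; no "chr" coercion.
* Zero-depth observations give AF 0 (not NaN); a zero-depth alternate
  pileup can never rescue and is logged.
* Empty record sets summarize to zero counts with the shared fraction
  reported as undefined, not 0.
* Degenerate 2×2 marginals and zero-variance mean comparisons are flagged
  and skipped (p = 1 by convention for the latter), never silently tested.
* Reports are sorted (patient, chromosome, position, alt) so reruns are
  byte-identical under a fixed seed.

## Problem sizes used in the test suite

The suite exercises cohorts of 1–600 patients; the recovery study runs
200 replicates of the full 69-trio emulation at each of four configured
truncal fractions (0.25, 0.5, 0.79, 1.0), the copy-number checks use
1000–2000 bins with a 30-bin planted single-copy loss, and the null
calibration of the contingency test uses 500 simulated tables at
study-like arm sizes (28 vs 24). These sizes give Monte-Carlo standard
errors comfortably below every asserted tolerance.

## Worked example

```{r example}
cfg <- sim_config(n_patients = 12, n_extra_regions = 2, seed = 7)
res <- run_pipeline(pipeline_config(sim = cfg))
res$summary
res$resolution_tally[c("examined", "resolved")]
```

## Known limitations

Segmentation (CBS/HMM), allele-specific copy number, purity/ploidy
inference, clonal-ordering reconstruction, annotation (effects and COSMIC
counts are input columns), and survival analysis are out of scope. The
significant-gene list for restricted summaries is user input, as is any
reference gene-frequency table.
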