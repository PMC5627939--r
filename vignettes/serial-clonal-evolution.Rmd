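---
title: "Tracking clonal evolution across serial tumor samples"
author: "clonetracker"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking clonal evolution across serial tumor samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetracker)
```

## The model

`clonetracker` analyzes one patient's serially collected tumor samples
to decide whether the tumor cell population changed over time. The
underlying population model is deliberately simple: each sample is a
mixture of a small number of subclones plus normal cells, each subclone
carries a private set of somatic mutations acquired after divergence
(plus a small shared set acquired before), and a heterozygous somatic
variant carried by a cell population at fraction $f$ is observed at an
expected variant allele fraction

$$\mathrm{VAF} = \frac{f\,m}{f\,c_t + (1-f)\,2},$$

with $m$ mutated copies among $c_t$ tumor copies at the locus. With one
mutated copy on a locally diploid background ($m = 1$, $c_t = 2$) this
reduces to $f/2$: a clonal variant in a pure tumor sits at VAF 0.5, and
a subclone at 20% of cells sits at VAF 0.10. Sequencing adds binomial
noise on top: at depth $d$ the observed alt-read count is
$\mathrm{Binomial}(d, \mathrm{VAF})$.

Clonal *replacement* — the disappearance of one mutation set and the
rise of a disjoint one between adjacent time points — is the signature
this package is built to detect. Because two subclones with disjoint
mutation sets could in principle be unrelated tumors, the package also
tests whether a structural rearrangement (here, a gene fusion) shares
one genomic breakpoint across all samples: an identical breakpoint
implies a common founder cell, placing the rearrangement before the
subclonal divergence.

## Filtering thresholds and their two roles

Two VAF thresholds appear with different jobs, and we keep them
distinct on purpose:

- `filterSomatic(min_depth = 20, min_vaf = 0.20, max_normal_vaf = 0)`
  is the *calling competence* filter: a call is believed somatic when it
  has ≥ 20× tumor depth, ≥ 20% tumor VAF (both inclusive) and zero
  variant reads in the matched blood. Calls whose normal sample has no
  coverage cannot be evaluated against the strict normal rule; they are
  excluded and counted separately rather than silently dropped.
- `callPresence(presence_vaf = 0.10)` is the *tracking* threshold: once
  a variant is believed somatic anywhere in the series, a strictly
  greater than 10% VAF in a sample counts as presence there. The lower
  threshold matters because a replaced clone's variants may persist at
  reduced fractions before vanishing.

Both are exposed as parameters; the package does not attempt to merge
them into one number.

Cross-sample harmonization (`harmonizeAcrossSamples`) enforces the rule
that makes absence meaningful: a variant enters the VAF matrix only if
its locus has ≥ 20 reads in *every* sample ("support" is total locus
depth by default; an `support_metric = "alt"` reading is available). For
this the function needs depth at loci where a sample has no call, so
the pipeline passes the full per-sample observation tables for
depth/VAF and restricts the variant universe to the union of
somatic-pass keys. Cells observed with no variant reads are VAF 0;
cells never observed are `NA` — zero and missing are different states
and are kept distinct through to the heat-map export.

## Partitioning and the exclusivity index

Variants are grouped by their binary presence profile. Variants present
in all samples form the `shared` group. Remaining profiles are merged
single-link at Hamming distance ≤ 1 (one noisy cell tolerated — serial
FFPE data are not perfectly clean), clusters with ≥ 2 variants become
clones labeled by order of first appearance, and singleton profiles are
reported `unassigned` rather than promoted to clones.

"Mutually exclusive mutation sets" is a qualitative claim; we
operationalize it as the exclusivity index: the fraction of
clone-assigned variants whose observed presence touches the
characteristic samples of exactly one clone. Disjoint clone sets with
perfect presence calls give 1.0. There is no published numeric target
for this quantity; it is a descriptive statistic, reported, not
thresholded.

Replacement detection scans adjacent sample pairs: an event
$A \to B$ is emitted when $A$'s presence fraction falls below half of
its previous level while $B$'s is positive, non-decreasing and at least
$A$'s. On a gradual three-sample crossover (fractions
$0.9/0.1 \to 0.5/0.5 \to 0.1/0.9$) this fires exactly once, at the
interval where the outgoing clone's expected VAF crosses below the
presence threshold.

## Copy number, copies and breakpoints

Per-bin tumor/normal counts are normalized by library size,
median-smoothed (running median, default 5 bins) and merged greedily
into segments while each next bin stays within `merge_tol = 0.25` of
the running segment mean. This is intentionally a minimal segmentation:
the downstream conclusions consume segment-level log2 values, not
breakpoint-exact segmentations, and a precomputed SEG file can be
supplied to bypass it entirely. Bins with zero normal coverage are
masked rather than generating infinite ratios.

Focal amplifications are segments with log2 ≥ 0.5 spanning ≤ 10 Mb —
artifact defaults chosen to separate focal events from arm-level gains;
both are parameters. Absolute copies invert the ratio under a
purity/ploidy model, `round((2·2^L − (1−p)·2)/p)` with rounding half
away from zero; the defaults (purity 1, diploid normal) make the
conversion `round(2·2^L)`, which maps 1.4 → 5 and 0.5 → 3 exactly.
Purity defaults to 1 because those two printed conversions imply
pure-tumor arithmetic; the parameter exists because real serial samples
rarely are.

Breakpoint concordance defaults to tolerance 0 (identity): the
common-founder inference rests on the breakpoints being *the same*, and
at tolerance 0 concordance is transitive. A nonzero tolerance is
available for callers with ambiguous breakpoint placement.

## Catalog statistics

The catalog filter mirrors the somatic filter in spirit: ≥ 20 reads,
allele ratio ≥ 0.2, and only protein-coding classes (missense,
nonsense, insertion, deletion, silent) — splice, UTR and RNA variants
are excluded before any per-gene statistic. Whether "20 reads" means
total depth or alt-supporting reads is ambiguous in common usage; total
depth is the default and `support_metric = "alt"` records the other
reading.

The silent-mutation fraction classifies a gene's catalog spectrum:
driver-like when ≤ 5% silent with ≥ 30 total mutations, passenger-like
when ≥ 15%, indeterminate otherwise. The 5%/15% bands bracket the
observed separation between driver oncogenes (a few percent) and the
per-gene average (about a quarter); known exceptions exist on both
sides, so the classification is explicitly advisory and both bands are
parameters. The `min_total = 30` guard exists because catalog genes
with a handful of mutations produce meaningless fractions (a gene with
one mutation is 0% or 100% silent by coin flip).

## Expression and candidates

RPKM is computed as `count / ((length/1000)·(total/10^6))`; the case
value is divided by the *median* of the reference cohort, and the
display fold is the nearest integer, rounded half away from zero (this
convention reproduces all seven printed folds of the motivating case
table, e.g. 274.24/2.80 → ×98 and 722.37/6.54 → ×110). Candidate genes
are those inside a focal amplification with display fold ≥ 5, ranked by
raw fold with alphabetical tie-breaks; the full in-region table is
always reported because the threshold is a reporting cut, not a
biological one — a ×2 in-region gene may still be of interest, so
non-candidates keep their folds and unquantified genes are listed.

## What the synthetic cohort emulates — and what it does not

`cohortConfig()` defaults encode the study design the package targets:
four serial samples (labeled 2007–2013), clone A at 90% in the first
sample and 2–5% after, clone B the mirror image; 37 A-private,
21 B-private and 3 shared variants; Poisson(100) depths truncated at 1
with binomial alt reads; normal samples with exactly zero variant reads
(a contamination knob exists, off by default); one fusion breakpoint
shared by all samples with 5 copies in clone A and 3 in clone B; a
single clone-B-only 2 Mb amplification (true log2 1.0) on a 50 Mb
grid of 100 kb bins at mean normal depth 200; and an expression layer
of 8 in-amplicon genes with true folds (100, 8, 8, 5, 2, 2, 1, 1) over
a 107-sample reference plus 20 diploid background genes. Tumor purity
is a free parameter (the clone fractions), not an asserted case value.

The generator does *not* emulate: read-level artifacts (FFPE damage,
mapping bias, strand bias), mutational signatures, per-variant copy
context outside declared amplifications, subclonal structure beyond two
clones with piecewise-constant fractions, or expression dispersion
beyond Poisson counting noise. Passing tests therefore demonstrate that
the pipeline's logic is correct under its own model assumptions — not
that it is robust to every failure mode of real serial FFPE sequencing.

## Numerical choices and degenerate inputs

- Rounding is half-away-from-zero everywhere a display integer or a
  copy number is produced; base R's half-to-even would break the
  printed conversions at the .5 boundary.
- Depths are truncated Poisson (minimum 1) so VAF is always defined.
- A reference expression median of 0 yields an infinity flag, never a
  division; a gene absent from the catalog has an *undefined* silent
  fraction, distinct from an observed 0%.
- Empty cohorts (0 variants) serialize to valid headers-only files.
- Clone labels are assigned by first chronological appearance, then
  cluster size, making labeling deterministic under row permutation.
- Problem sizes in the tests (cohorts of 61 variants × 4 samples at
  depth 100, 100 random tables of ≤ 2000 records for the brute-force
  comparisons, 500-bin copy-number grids) were chosen as the smallest
  sizes at which the binomial/Poisson noise regime matches the study
  design; they keep the full suite around a minute.

## Known limitations

The partitioner assumes subclone presence profiles are step functions
of time with at most one noisy cell per variant; a subclone oscillating
around the presence threshold can fragment into unassigned singletons.
The segmentation is first-order (no recursive splitting), so two
adjacent amplifications closer than the merge tolerance can merge into
one segment — with the default 100 kb bins and a 0.25 tolerance this
was never limiting in simulated recoveries, which place the segment
mean within ±0.1 of truth. Fold-change ranking inherits RPKM's
length-normalization biases; it is a prioritization, not a test of
differential expression.
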