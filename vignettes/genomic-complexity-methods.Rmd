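---
title: "Methods: quantifying genomic complexity in whole-genome tumor profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying genomic complexity in whole-genome tumor profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genomplexity)
```

# Scope

`genomplexity` quantifies structural and numerical genomic complexity in
whole-genome sequenced tumors from three inputs that any allele-specific
copy-number caller, rearrangement caller and SNV caller can produce:
per-sample copy-number segments (total and minor allele counts with sample
ploidy and purity), typed and oriented rearrangement breakpoint pairs, and
somatic single-base substitutions. On top of these it computes
whole-genome-doubling and chromosome-arm aneuploidy calls, three mutation
feature catalogs (SBS96, SV32, CN40), de-novo mutational-signature
extraction with exposure refitting, kataegis loci, per-chromosome complex
rearrangement classes (breakage-fusion-bridge, chromothripsis, localized
complex) and a set of locus annotations. A synthetic cohort generator with
full truth labels closes the loop: every caller in the package is validated
against data whose ground truth is known by construction.

Upstream read alignment, variant calling and allele-specific copy-number
estimation are out of scope; the package consumes their outputs.

# Coordinate and container conventions

All in-memory coordinates are 1-based inclusive, matching VCF and the
segment tables emitted by copy-number callers. BED and BEDPE files are
0-based half-open on disk and converted at the boundary, so
`read(write(x))` is the identity. Chromosome names are stored without a
`chr` prefix; both dialects are accepted on input.

Segments that span a centromere are split at the arm boundary on load
(`split_segments_at_arms()`). Upstream callers differ in how they treat
centromeric territory and arm-level statistics are ill-defined for
straddling segments, so splitting is applied deterministically rather than
left to the caller. Sex chromosomes are parsed and retained but excluded
from every ploidy, aneuploidy and altered-fraction computation, which are
defined over the autosomal genome only.

# Whole-genome doubling, arm events and aneuploidy

A sample is whole-genome doubled when more than 50% of its autosomal
genome, length-weighted over segments, has a major copy number (the count
of the more frequent parental allele) of at least two. The boundary value
of exactly 50% is negative; both thresholds in this module use strict
inequalities.

Arm-level events compare each segment's total copy number with the
unrounded sample ploidy: above is gained, below lost, equal neutral. An
arm is called gained or lost when more than 80% of its covered segment
length is altered in the same direction. Uncovered arm territory enters
neither numerator nor denominator, since the rule sums segment lengths.
The aneuploidy score counts non-neutral arms over both arms of every
autosome except the short arms of the acrocentric chromosomes 13, 14, 15,
21 and 22, for a maximum of 39.

The altered genome fraction is the autosomal length fraction in any of
four states: amplification (total copy number at least 6), single-copy
loss (total 1), homozygous deletion (total 0) and copy-neutral LOH (total
2 with minor allele 0). These states are defined on absolute copy number,
not relative to ploidy; whether copy-neutral LOH should instead be defined
relative to ploidy in doubled genomes (for example 4+0) is genuinely
ambiguous, and the absolute definition was chosen because the four state
labels (CN0, CN1, CN2 with LOH, CN >= 6) are absolute. For a
whole-genome-doubled tumor the CN1/CN0 components are conservative.

# Feature catalogs

Three catalogs feed signature inference, each with a closed canonical
vocabulary:

* **SBS96** — single-base substitutions in their trinucleotide context,
  folded onto the pyrimidine strand: six substitution classes times 16
  flank combinations. Variants whose context is undefined (chromosome
  edge, N base, or a reference mismatch) are tallied separately and never
  silently dropped: the catalog column plus the excluded count always
  equals the SNV count.
* **SV32** — rearrangements classified by clustered status, type
  (deletion, duplication, inversion, translocation) and, for
  intra-chromosomal events, five size bins (1–10 kb, 10–100 kb,
  100 kb–1 Mb, 1–10 Mb, >10 Mb). Translocations carry no size, giving
  2 x (3 x 5 + 1) = 32 categories. Size bins are half-open at the top
  (a 10 Mb event is ">10Mb"); events under 1 kb fall in the smallest bin.
* **CN40** — copy-number segments classified by zygosity (heterozygous,
  LOH, homozygous deletion), total-copy-number class (0–1 deleted, 2
  neutral, 3–4 duplicated, >4 amplified) and five size bins (0–0.01,
  0.01–0.1, 0.1–1, 1–10, >10 Mb, half-open at the top). Impossible
  combinations are excluded — a heterozygous segment cannot be deleted,
  and homozygous deletions exist only at total 0 — leaving
  15 + 20 + 5 = 40 categories.

Breakpoint clustering is single linkage over all breakpoint ends of a
sample per chromosome: consecutive sorted ends closer than `distance_d`
(default 1 Mb) join a cluster, and an event is clustered when either end
sits in a cluster of at least `min_cluster_size` ends (default 10). The
clustering distance used by published cohorts is typically not reported;
both parameters are plain function arguments and are echoed into pipeline
provenance. Clustering is computed per sample, not per cohort.

# Signature extraction and refitting

De-novo extraction factorizes a catalog matrix V (categories x samples)
as V ~ WH with W, H non-negative, minimizing the generalized
Kullback–Leibler divergence by multiplicative updates — the convention of
the mutational-signature literature. Runs stop after 1000 iterations or a
relative objective change below 1e-8; the objective is non-increasing by
construction and this is asserted in the test suite.

Because NMF is non-convex and the rank is unknown, each candidate rank
(default 2–12) is fitted with `n_runs` random restarts. Samples are
assigned to their dominant signature per restart; the consensus matrix of
co-assignment frequencies yields the cophenetic correlation coefficient
and the mean silhouette width. As an overfitting control the same
diagnostics are computed on randomized data, independently permuting each
category row across samples, freshly for each of `n_randomized_runs`
restarts. The chosen rank is the largest one with cophenetic >= 0.95,
mean silhouette >= 0.8 and both strictly above the randomized baseline at
that rank; when no rank qualifies the rank with maximal cophenetic
coefficient is used. The acceptance rule and its thresholds are explicit
arguments. Defaults of 100 observed and 100 randomized restarts keep a
desk run tractable; published analyses have used as many as 1000
randomized runs, and both counts are plain arguments.

Extracted signatures are matched to a reference set by cosine similarity
on identically ordered category vectors; a best match below 0.85 is
labelled novel.

Per-sample exposures are refitted by non-negative least squares of the
normalized catalog on the signature matrix. Signatures contributing less
than 15% are zeroed and their weight, together with the fit residual, is
reported as unassigned; retained weights are deliberately not re-inflated,
so retained plus unassigned always sums to one. Samples with 50 or fewer
mutations are entirely unassigned. An optional `max_signatures` cap
retains only the largest contributors, mirroring refitting conventions
for sparse catalogs (for example at most 4 signatures for doublet
substitutions).

# Kataegis

Inter-mutation distances (IMDs) are computed within chromosomes and their
log10 values segmented by an exact penalized piecewise-constant fit: an
O(n^2) dynamic program minimizing within-segment squared error plus a
per-segment penalty gamma (default 25, the convention of the kataegis
literature). A fitted segment is a kataegis locus when it spans at least
6 mutations with an arithmetic mean raw IMD of at most 1000 bp.

Two numerical properties of this rule are worth knowing. First, the
dynamic program is exact — it is verified against exhaustive enumeration
of all segmentations on small instances — so there is no heuristic
segmentation error. Second, the rule has a small-sample edge effect: when
a dense cluster sits within one or two mutations of the ends of a
chromosome's mutation sequence, the penalty makes it cheaper to absorb
those boundary IMDs into the cluster segment than to open a new segment,
and a single absorbed megabase-scale IMD pushes the arithmetic mean above
1 kb. The probability of this configuration scales roughly as 4/N for N
mutations on the chromosome, so it is negligible at real whole-genome
mutation counts (hundreds of mutations per chromosome) but visible on
deliberately small simulated chromosomes. Recovery experiments in the
test suite therefore use full-length chromosomes at the cohort's typical
mutation density.

# Complex chromosome detection and classification

Candidate chromosomes are flagged by three criteria: (A) a non-random
breakpoint distribution, tested with the exact one-sample
Kolmogorov–Smirnov statistic against uniformity along the chromosome at
p < 1e-5 (the test is exact for the breakpoint counts involved; the
uniformity test itself is a package choice as published descriptions name
only the threshold); (B) a breakpoints-per-megabase rate above
Q75 + 1.5 IQR of the sample's own per-chromosome rates — zero-breakpoint
chromosomes included at rate 0 — with at least 35 breakpoints; (C) at
least 10 translocations. Any flag makes the chromosome a candidate.

Candidates are classified from explicit, configurable evidence rather
than manual review, so calls are reproducible and the raw evidence
columns let a reviewer overrule them: telomeric loss (a terminal segment
below sample ploidy), fold-back inversions (inversion events whose ends
lie within 30 kb), the fraction of inversion plus translocation events,
copy-number switches and the number of CN states covering 80% of the
clustered region (the span of the chromosome's breakpoint ends), and
heterozygosity retention on the higher CN state. Chromothripsis evidence
requires at least 10 switches between at most 3 states with at least half
of higher-state length retaining the minor allele; BFB evidence requires
telomeric loss with at least 3 fold-backs or an inversion/translocation
fraction of at least 0.4. Both together give BFB/chromothripsis; a
candidate matching neither is localized complex. All thresholds are
function arguments with the defaults above.

# Locus annotations

Tumor mutational burden is mutations per megabase with the genome size as
an explicit argument (the sum of reference chromosome lengths by default;
no callable-genome correction is applied). Genes are amplified when any
overlapping segment has total copy number of at least 6 and homozygously
deleted when any has total 0; both can hold for genes spanning a
breakpoint. Breakpoints within 20 kb upstream of TERT are annotated with
the gap distance of their partner breakpoint to the nearest
super-enhancer, proximal within 100 kb; "upstream" is strand-aware (TERT
is minus-strand on GRCh37) and the locus is supplied as data rather than
hard-coded. Relative telomere length is the log2 ratio of
coverage-normalized telomeric read counts between tumor and normal.
Breakpoint recurrence is summarized by tiling the genome in 1 Mb bins
from position 1 and counting distinct samples with at least one
breakpoint end per bin; no significance model is attached.

# The synthetic cohort generator

`simulate_cohort()` emits, per sample, a segment table, a BEDPE of
rearrangements and an SNV VCF, plus one shared random reference FASTA,
a manifest and truth tables. Each sample's stream is seeded from the
master seed and the sample index, so cohorts are reproducible file-for-file
and samples can be regenerated independently.

Default parameters are the cohort conditions the analysis assumes: 71% of
samples whole-genome doubled (doubled genomes start at 2+2, diploid at
1+1); Poisson(8) arm gains/losses; Poisson(3) focal amplifications
(total >= 6) and Poisson(2) homozygous deletions per genome; a background
rate of 0.18 breakpoint ends per Mb, giving roughly 280 events on a full
genome; 2.1 SNVs per Mb drawn from a planted SBS96 signature mixture; two
kataegis loci per sample (clusters of 8 mutations, exponential spacing
with mean 300 bp, placed at TpC sites with C>T/C>G alternates to mimic
the APOBEC character of kataegis); and one chromothripsis plus one BFB
chromosome. The emitted header ploidy is the base ploidy (2 or 4): it
plays the role of the caller-estimated ploidy, and planting it exactly
keeps truth arm labels well defined.

Structure of the planted events:

* *Chromothripsis* chromosomes carve a shatter window (default 30 Mb,
  capped at 80% of the q arm) into at least 40 breakpoints whose
  alternating intervals drop one copy, producing a two-state oscillation
  with the minor allele retained on the higher state; the lost intervals'
  boundary pairs are emitted as clustered deletion-type joins with a few
  inversions mixed in.
* *BFB* chromosomes lose a telomere-adjacent segment (4–10% of the
  chromosome, capped at 3 Mb), gain amplified blocks proximal to the lost
  telomere, and carry 5 or more fold-back inversions (span <= 25 kb) plus
  larger inversions and translocations concentrated in the same region,
  as successive bridge-breakage cycles produce.
* *Background SNVs* are placed by rejection sampling so each mutation's
  reference trinucleotide context matches its sampled SBS96 category;
  emitted catalogs therefore follow the planted mixture exactly up to
  multinomial noise.
* *Kataegis loci* within a sample are kept at least 5 Mb apart so each
  planted cluster is an independent trial for recovery experiments;
  overlapping plants would measure the detector on a compound event it
  was never defined for.

What the generator does **not** model: subclonality and purity dilution
(purity is emitted but the CN states are clonal integers), replication
timing and chromatin covariates of mutation density, sequence context
beyond a uniform random reference, microhomology at breakpoints, and
read-level artifacts. Passing recovery tests on this generator therefore
demonstrates the correctness of the decision rules and their
implementation — not robustness to noisy segmentations or impure tumors,
which depend on the upstream callers.

Problem sizes in the test suite are chosen for desk-scale runs: oracle
equivalence uses two-chromosome toy genomes of 2 Mb per chromosome
against per-basepair brute force; signature recovery uses 50 samples of
2000 mutations over ranks 2–6 with 20 observed and 20 randomized restarts;
kataegis recovery uses one 249 Mb chromosome at 2.1 SNVs/Mb; complex
chromosome recovery uses 50 samples on four 25 Mb chromosomes; the
calibration of the uniformity test uses 10,000 simulated chromosomes of
50 breakpoints. The packaged `mini` genome (GRCh37 arm table scaled 1:10,
about 310 Mb) is the default simulation genome; the full `grch37` table is
selectable wherever a build is accepted.

# Known limitations

* The WGD, arm and altered-fraction rules are threshold rules on clonal
  integer copy numbers; subclonal or noisy segmentations will blur the
  50%/80% boundaries in ways the generator does not emulate.
* Arm-event truth assumes the emitted ploidy; real caller ploidies are
  non-integer, and segments exactly at ploidy only arise with integer
  ploidy values.
* The kataegis rule inherits the small-sample edge effect described
  above, and the arithmetic-mean criterion rejects compound regions
  formed by nearby clusters separated by a long gap.
* Complex-chromosome classification codifies criteria that were partly
  qualitative in published practice; the emitted evidence columns are the
  audit trail for disagreement.
* Rank selection reports a single rank; closely spaced signatures (cosine
  above roughly 0.7) can merge at the chosen rank, which is why planted
  validation uses signatures with pairwise cosine at most 0.3.
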