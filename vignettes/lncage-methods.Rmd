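---
title: "Methods: discovering age-related lncRNAs with lncage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering age-related lncRNAs with lncage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lncage)
```

# Scope

`lncage` implements the computational core of a leaf-aging lncRNA study as a
reusable pipeline. The input is a set of assembled transcript models (GTF),
their sequences (FASTA), a read-count matrix across a developmental time
course with replicates, and three orthogonal evidence layers: ribosome
footprint coverage, small-RNA read-length coverage, and miRNA-target
interaction tables. The output is the set of long noncoding RNAs, their
genomic and functional classification, the age-related (AR) subset with its
temporal clusters, neighbor co-expression statistics, a ceRNA
(lncRNA-miRNA-mRNA) network, and a list of candidate RNA-RNA duplexes.
Upstream read processing (trimming, alignment, transcript assembly,
counting) is out of scope: the pipeline starts from transcript models and
counts.

# Identification of lncRNAs

Candidates pass a fixed-order filter cascade; each transcript is attributed
to the first rule that removes it, so the per-rule counts in the
`FilterReport` always sum to the input size:

1. **Annotated transcripts.** A candidate that matches a reference
   transcript on the same strand (identical intron chain; for single-exon
   models, reciprocal overlap of at least 50%) is an annotated transcript:
   matches to annotated noncoding models are retained directly as annotated
   lncRNAs, matches to coding models are dropped.
2. **Class codes.** Remaining (novel) transcripts must be intergenic (`u`,
   no overlap with any reference gene span), antisense (`x`, at least 1 bp
   of exonic overlap with a reference transcript on the opposite strand), or
   intronic (`i`, entirely inside one intron of some reference isoform,
   either strand). Same-strand exonic overlap without a chain match is
   ambiguous read-through or fragment and is removed.
3. **Length.** Spliced (exonic) length below 150 nt; length is the exon sum,
   not the genomic span.
4. **Abundance.** Maximum TPM over *all* samples (timepoint x replicate)
   below 1. TPM is recomputed from counts per sample as the
   length-normalized rate scaled to one million.
5. **Coding potential.** See below.

Strand `.` is rejected at parse time: every rule above is strand-dependent,
so unstranded models cannot be classified meaningfully.

## Coding-potential score

External coding-potential classifiers depend on SVM models and protein
databases; `lncage` instead uses a small, fully reproducible stand-in. A
transcript is called coding when its longest forward-frame ORF reaches 100
codons (the classical heuristic threshold), **or** when that ORF covers at
least half of the transcript *and* its in-frame hexamer log-odds (coding vs
noncoding background, add-one smoothing) is positive. The hexamer tables are
trained on packaged synthetic fixtures: codon-usage-biased ORFs versus
uniform random sequence. This reproduces the operational intent of the
cascade — removing transcripts with obvious protein-coding capacity while
sparing short-ORF noncoding RNAs — with a deterministic, dependency-free
computation. Random 300-nt sequences are called coding with probability
below 1% (a property the test suite checks by simulation).

# Classification

## Genomic location

The primary category is decided in order: **antisense** (any exonic overlap
with a protein-coding gene on the opposite strand), **intronic** (entirely
within a single intron of any coding isoform, no exon overlap; either
strand qualifies, since the intron-containment definition is
strand-agnostic), else **intergenic**. Two non-exclusive flags refine the
intergenic neighborhood: **divergent** (head-to-head, a coding TSS on the
opposite strand within 1,000 bp of the lncRNA TSS, without overlap) and
**convergent** (tail-to-tail, 3' ends within 1,000 bp). The 1,000-bp window
is the only window used anywhere in the pipeline and is configurable. Flags
may co-occur, so category proportions can sum to more than 100%.

## Functional classification

Labels are non-exclusive. A lncRNA is a **ribo-lncRNA** when its mean
footprint coverage reaches 1 read/nt. Within ribo-lncRNAs, a translated
sORF is called when some ORF of at least 10 amino acids attains a ribosome
release score (RRS) of at least 0.9. A **small-RNA precursor** needs at
least 20 small-RNA reads of which at least half are 21-22 nt long — the
hallmark lengths of plant miRNA/tasiRNA products. A lncRNA with neither
label is **canonical**; a lncRNA can carry both labels at once.

The RRS used here is the bounded contrast
`rrs = d_orf / (d_orf + d_down)`, where `d_orf` is mean footprint depth
over the coding span (stop codon excluded) and `d_down` the mean depth over
the 100 nt after the stop (shrunk to what exists, minimum 10 nt). The
original release score is an unbounded ratio, which cannot be gated at 0.9
on a [0, 1] scale; the bounded form makes the 0.9 threshold meaningful
(uniform coverage gives 0.5, full ribosome release gives 1) and is
invariant under uniform scaling of coverage. The sORF scan covers the three
forward frames only — footprints are strand-resolved, so antisense ORFs are
not observable in the profile — and reports the 5'-most ATG per stop codon.

# Age-related expression

Counts are normalized with median-of-ratios size factors. Each developmental
window — growth-to-maturation (4 vs 18 d), maturation-to-senescence (16 vs
30 d), and the full lifespan (4 vs 30 d) — is tested as an
endpoint-versus-endpoint two-group contrast (the windows overlap by design
at 16-18 d). The test is a negative-binomial Wald test: group means with a
pseudo-count of 0.5, `log2fc = log2(m2/m1)`, and a delta-method standard
error under `Var = mu + alpha mu^2`.

The dispersion `alpha` is estimated by the method of moments within each
endpoint group, pooled across the two groups, and then pooled across all
tested transcripts (mean of the positive per-transcript estimates, floored
at 1e-8). The cross-transcript pooling is deliberate: with two replicates
per endpoint, a per-transcript moment estimator is so unstable that the
Wald test rejects a true null more than three times too often, while the
count model (and the generator) assume a shared dispersion in the first
place. With pooling, the null rejection rate at `p <= 0.05` sits near
0.05-0.06 and planted four-fold changes are recovered with over 90% power
at two replicates — both properties are checked by simulation in the test
suite. Shrinkage toward a mean-dependent trend, outlier replacement, and
full time-course likelihood-ratio tests are intentionally out of scope.

A transcript is **age-related** in a contrast when `|log2fc| >= 1` and the
Benjamini-Hochberg adjusted p-value (adjusted within contrast, across the
tested lncRNAs) is at most 0.05; the AR set is the union over contrasts.
BH was chosen as the adjustment because the screen reports discovery sets,
for which FDR control is the appropriate error measure.

## Temporal clustering

AR-lncRNA profiles (replicate-mean TPM with pseudo-count 0.5, log2 ratio to
the 4-d timepoint, z-scored per transcript) are clustered with k-means
(`k = 6`, 50 restarts, fixed seed). Cluster labels are then derived purely
from the cluster centroids: positive terminal log2FC makes a `U` cluster,
negative a `D` cluster, and within each direction clusters are numbered by
the (interpolated) time at which half the terminal change is reached —
`U1` is the earliest-rising cluster. Because the relabelling depends only
on centroids, it is invariant to the arbitrary label permutation k-means
returns.

## Localization and stress overlap

A transcript detected in nuclear/cytosolic fractionation data is called
nuclear when its nuclear TPM strictly exceeds its cytosolic TPM; exact ties
go to cytosolic (an arbitrary but fixed break), and transcripts absent from
both fractions are excluded. Stress overlap is plain set arithmetic:
`|stress set ∩ AR set| / |stress set|` per condition.

# Neighbor co-expression

Eight gene-pair categories plus random pairs are enumerated from geometry
and biotype. Coding baselines: APP (coding pairs overlapping on opposite
strands), IPP (each coding gene with its nearest non-overlapping coding
neighbor; ties broken toward the smaller coordinate), DPP and CPP (coding
pairs head-to-head / tail-to-tail within 1,000 bp). The lncRNA categories
ALP, ILP, DLP, CLP mirror them with an AR-lncRNA member; "common promoter
region" for divergent pairs is operationalized as TSS-TSS distance within
the window on opposite strands, since no finer definition is available.
Random pairs are uniformly sampled lncRNA-coding pairs under a fixed seed
and are *not* excluded from qualifying categories. Correlations are Pearson
coefficients of gene-level replicate-mean TPM across all timepoints;
categories are compared with two-tailed Mann-Whitney U tests (exact when
both sides have at most 20 pairs, normal approximation with tie correction
otherwise; fully tied comparisons report p = 1). Antisense pairs with
correlation strictly above 0.7 form the reported correlated-ALP set.

# ceRNA discovery

Candidate ceRNA pairs are all (lncRNA, mRNA) pairs sharing at least one
targeting miRNA. The junction significance is the hypergeometric upper
tail: with `N` miRNAs in the universe, `K` targeting the mRNA and `n` the
lncRNA, the probability of sharing at least `k` by chance is
`P(X >= k), X ~ Hypergeometric(N, K, n)`, summed in log space. The universe
is the set of all distinct miRNAs in the merged interaction table (the
union; configurable, since the choice is not canonical). Retained sets need
`p < 0.05` (raw, per the screening design; a BH option exists but is off by
default) and a *positive* Pearson correlation above 0.7 — the ceRNA
mechanism predicts positive co-expression of the sponge and its target.

One calibration subtlety: conditioning on "shares at least one miRNA"
inflates the apparent detection rate among candidates, because the
smallest observable overlap can already be improbable for small target
sets. Calibration is therefore assessed over all screened pairs (where the
p-value's validity guarantees a rate at or below the nominal 0.05) and
against the exact null expectation computed from the hypergeometric
distribution itself; both checks run in the test suite on generator tables
with no planted triplets.

# RNA-RNA duplex screen

The screen is a seed-and-extension scan under a fully specified additive
energy model: exact Watson-Crick 6-mer seeds (located via a k-mer index),
ungapped antiparallel extension in both directions with per-position
energies GC -2.2, AU -1.1, GU -0.6 kcal/mol and a mismatch penalty, x-drop
termination at 3 kcal/mol, trimming to the best-energy span, merging of
overlapping candidates (best energy wins), and reporting gates
`E < -16 kcal/mol` with at least 15 paired (non-mismatch) positions.
"Interaction length" counts paired bases, not span length. The pairing
energies are calibrated so the reporting gate sits exactly at a 15-nt
AU-only perfect duplex (15 x -1.1 = -16.5 < -16).

The mismatch penalty is +4 kcal/mol, the scale of an internal-loop
destabilization. This choice is load-bearing: with a mild penalty (say +1),
x-drop extensions accumulate net stability through interleaved chance
pairings, and unrelated sequences of a few hundred nucleotides pass the
reporting gate more often than not, which defeats the purpose of a
specificity screen. With +4 (exceeding the x-drop), extension stops at the
first mismatch, so reported duplexes are contiguous paired runs; a duplex
whose optimal alignment bridges interior mismatches is reported as its
component runs. At 1 kb, G:U-extended chance runs still occasionally reach
the gate (roughly one random pair in ten yields some hit) — as in the
original screening design, specificity comes from the subsequent
co-expression filter, which keeps only pairs with `|PCC| >= 0.9`
(non-strict, either sign: stabilizing and destabilizing interactions are
both of interest). The scan core is implemented in C++; a brute-force
substring-alignment oracle in the test suite verifies that reported best
energies equal exhaustive minima on small sequences.

# The synthetic study generator

`sim_config()` fixes the study conditions: a 4-30 d time course sampled
every 2 d with 2 replicates, ~120 coding genes and 8 lncRNAs per
genomic-location category on two chromosomes, negative-binomial counts with
shared dispersion 0.1, log-normal baselines (median 150 counts) and library
sizes, six piecewise-linear temporal archetypes (early/mid/late ramps, up
and mirrored down) with terminal |log2FC| = 3 assigned to 70% of lncRNAs
and 40% of coding genes, planted translated sORFs (60-nt ORFs, footprint
density 12 vs 0.2 reads/nt), sRNA precursors (80% of 100 reads at
21-22 nt), 8 ceRNA triplets with 4 junction miRNAs over an 80-miRNA
universe, and 8 duplex pairs with exact 20-nt reverse-complementary
GC-rich segments. Where the study design fixes a value (timepoints,
replicates, thresholds) the generator uses it; remaining magnitudes were
chosen once as representative of a well-powered plant RNA-seq experiment
and are not tuned.

Gene placement is block-based with at least 3 kb between blocks so that no
unintended neighbor falls inside the 1,000-bp classification window; every
lncRNA placement is verified against the classifier and redrawn if its
intended category is not realized. The archetypes are the generator's own
construction — the study reports six clusters but no centroids — so
clustering accuracy is measured against planted labels, not published
shapes.

Two couplings are built into the truth, because the downstream screens
test for co-expression, not merely for shared trend:

* antisense lncRNAs share their archetype with their host gene (the
  cis-regulation that the neighbor co-expression analysis detects);
* the mRNA member of every planted ceRNA/duplex pair *tracks the realized
  replicate-mean profile* of its lncRNA with a small residual dispersion
  (0.01), emulating the mechanistic coupling (miRNA sequestration, RNA
  stabilization) those screens look for. Sharing only the mean trajectory
  is not enough: at dispersion 0.1 with 14 timepoints, the sample PCC of
  two independent transcripts on the same trajectory has its median near
  0.90, so roughly half of the planted duplex pairs would fall below the
  |PCC| >= 0.9 gate by sampling noise alone, and recovery of planted
  signal — the generator's contract — would be impossible at the study's
  own settings.

What the generator does **not** emulate: read-level artifacts (mapping
bias, positional coverage bias, multi-mapping), batch effects,
mean-dependent dispersion trends, isoform switching, correlated background
co-expression networks, and sequence composition of real genomes (outside
planted elements, sequences are i.i.d. uniform). Passing the recovery
tests therefore demonstrates that the pipeline's logic and statistics are
correct under the stated model, not that real data would behave as
cleanly.

# Numerical and degenerate-input choices

* TPM of an all-zero sample is defined as all-zero with a warning.
* Transcripts with zero counts at both endpoints get `log2fc = 0, p = 1`.
* Size factors fall back to total-count ratios (normalized to geometric
  mean 1) when no transcript is nonzero in all samples.
* Constant expression profiles have no defined correlation and propagate
  `NA`, never a fabricated value; such pairs cannot be retained.
* Fully tied Mann-Whitney comparisons report p = 1.
* `compute_rrs` shrinks its downstream window to what exists and requires
  at least 10 nt after the stop codon; 0/0 coverage yields 0.
* Table output writes 12 significant digits so floats round-trip within
  1e-9; all output ordering is deterministic, making same-seed runs
  byte-identical.
* Problem sizes in the test suite (bundle of ~160 transcripts, 2,000-
  transcript null simulations with 200 replicates, 50-pair duplex oracle)
  were chosen to give stable Monte-Carlo estimates while keeping a full
  test run in minutes on one core.

# Known limitations

* The identification cascade trusts the assembler upstream: it cannot
  rescue fragmented or chimeric models, and the 50% reciprocal-overlap
  rule for single-exon matching is a heuristic.
* The endpoint contrast ignores intermediate timepoints when calling AR
  transcripts; a transcript that rises and falls entirely inside a window
  can be missed (the three overlapping windows mitigate but do not
  eliminate this).
* The duplex energy model is additive and ungapped: no stacking, no
  bulges, no accessibility correction; reported energies are screening
  scores, not physical free energies.
* The hexamer model is trained on synthetic fixtures; for a real genome a
  user should retrain it on curated coding/noncoding sets via
  `hexamer_model()`.
```
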