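---
title: "Methods: error-corrected cfDNA variant, CNV and fragmentation analysis"
author: "duplexplasma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: error-corrected cfDNA variant, CNV and fragmentation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duplexplasma)
```

# Scope and model

Plasma cell-free DNA (cfDNA) carries tumour-derived fragments at allele
fractions often below 1%, far beneath the raw error rate of hybrid-capture
sequencing. duplexplasma implements the error-suppression strategy used by
UMI-based ctDNA assays:

1. **Molecular consensus.** Every sequenced molecule is tagged with a random
   8-mer UMI. Reads sharing a UMI (up to sequencing error) and fragment
   coordinates are collapsed into a consensus read; molecules observed only
   once are discarded, because a single read carries no error-correction
   information.
2. **Step-1 screening.** Candidate variants are read off a consensus-read
   pileup and filtered on coverage, alt-read count, a signal-to-noise ratio
   and the variant's distance from the read ends.
3. **Step-2 double-strand confirmation.** A surviving candidate is kept only
   if it is supported by two consensus families with *distinct* UMIs at
   *identical* fragment coordinates in *complementary* orientation — i.e.
   the variant was observed independently on both strands of one original
   double-stranded molecule. PCR and sequencing errors arise on one strand
   and essentially never produce this configuration.

Around this core sit copy-number calling from per-target coverage
log-ratios with a mixture-model null, cfDNA fragment-length profiling, and
the cohort statistics used to summarize such studies.

# UMI consensus (adjacency grouping)

Reads are bucketed by fragment key: contig, fragment start, fragment end
(from the leftmost mate position and `|TLEN|`) and family orientation.
Within a bucket, UMIs are merged by the *adjacency* rule: a directed edge
`u -> v` exists when `Hamming(u, v) <= 1` (configurable) and
`count(u) >= 2 * count(v) - 1`; families are the components grown
breadth-first from the highest-count unmerged UMI. The count condition is
the standard published criterion for this strategy: an error-derived UMI is
expected at roughly half the parent's count, so a similar-sized neighbour
is treated as an independent molecule. Reads below mapping quality 20,
unmapped reads, and reads whose mate maps elsewhere are excluded.

**Orientation.** We label a family `F` when its first-in-pair read maps to
the forward strand and `R` otherwise. For proper FR pairs the leftmost
mapped read is always on the plus strand, so read-1 strand — not leftmost
strand — is the informative label of which physical strand was sequenced;
this is the usual duplex convention.

**Consensus.** One consensus read per family, spanning the whole fragment:
both mates contribute, per reference position the majority base wins, ties
(and uncovered positions) become `N` with quality 2, and the consensus
quality is the sum of supporting Phred scores capped at 60. The fragment-
span representation keeps one record per molecule and makes the duplex
coordinate comparison exact. Singleton families (`min_family_size = 2`)
yield nothing.

# Step-1 screening

For every non-reference allele at a target position the screen evaluates:

| parameter      | default | stringent | meaning                                   |
|----------------|---------|-----------|-------------------------------------------|
| `min_bq`       | 30      | 30        | base-quality split for the SNR            |
| `min_cov`      | 100     | 100       | consensus-read depth at the site          |
| `min_alt`      | 3       | 3         | alt-supporting consensus reads            |
| `min_snr`      | 4       | 20        | signal-to-noise ratio                     |
| `min_mean_pos` | > 10    | > 15      | mean distance from the nearer read end    |

The *signal-to-noise ratio* is defined here as
`hq / max(lq, 0.5)`, where `hq` and `lq` count alt reads with base quality
at/above versus below `min_bq`; the 0.5 floor keeps the ratio finite when
no low-quality support exists. The *mean read position* is the mean, over
alt reads, of the 1-based distance from the nearer read end — a guard
against alignment artifacts that accumulate at read edges. Both definitions
are implementation choices (the screening literature does not fix them
uniquely) and are therefore stated prominently here and in the function
documentation. `alt_count` counts all alt-supporting consensus reads; the
quality threshold acts through the SNR split.

The stringent preset dominates the default one, so stringent call sets are
provably subsets of default call sets on the same pileup.

Three cohort filters follow, each a pure set operation (they commute):
panel-of-normals (drop variants recurring in ≥ 2 healthy plasma samples),
impact (keep MODERATE/HIGH consequence annotations; unannotated candidates
are dropped by default, the conservative posture), and matched-normal
(drop on any buffy-coat alt read, or on < 100× buffy-coat coverage, since
shallow normals cannot exclude clonal haematopoiesis).

The pileup is substitution-only: consensus reads are modelled as gapless
alignments, so indel candidates are outside the current in-memory model.

# Step-2 double-strand confirmation

A candidate's supporters are all alt-bearing consensus families covering
the site. Support requires a pair of supporters with identical fragment
coordinates, opposite orientation and distinct UMIs. "Identical
coordinates" defaults to both endpoints (`coord_mode = "endpoints"`, the
strictest reading); `"start"` relaxes to the fragment start only, for
libraries where end positions are noisy. Distinct UMIs are required even
within Hamming distance 1 — upstream grouping has already merged
error-derived UMIs, so any surviving distinct pair counts. Confirmed calls
are annotated with the number of qualifying pairs (`ds_pairs`).

# CNV calling by null-distribution estimation

Per-target coverages are converted to fractions of the sample's total
on-target coverage; each target's log2 ratio compares the case fraction to
the median control fraction, with a pseudo-count scaled to library size
keeping ratios finite at zero coverage. The bulk of a targeted panel is
copy-neutral but the ratio distribution is typically multimodal (neutral
mass plus gained/lost clusters), so the null is estimated by fitting both
a 2- and a 3-component Gaussian mixture by EM and choosing the better fit
by AIC (`2(3k - 1) - 2 loglik`); ties go to the bimodal model. The EM uses
k-means++ seeding with 5 restarts (best log-likelihood kept), a variance
floor of 1e-4, and stops when the log-likelihood improves by less than
1e-6; the per-iteration log-likelihood is retained and is non-decreasing.

The **null component is the largest-weight component** — the documented
assumption that most of a targeted panel is copy-neutral — and the calling
thresholds are `null mean ± z · null sd` with `z = 1.96` by default
(configurable). Genes are summarized by the median of their target ratios;
a gene needs at least 3 targets for a call. ERBB2 amplification maps
directly to HER2+ classification, and `classification_metrics()` turns a
validation confusion matrix into precision/sensitivity/specificity
percentages (one-decimal reporting; zero-denominator metrics are `NA`,
never 0).

A caveat worth knowing: on data whose null really is a single Gaussian,
AIC's weak complexity penalty lets a spurious third component win roughly
one replicate in five (measured across seeded simulations at n = 250-1000
targets). This does not disturb the threshold machinery — the null mean of
the selected fit is recovered within ±0.05 in ≈ 96% of replicates — but
the chosen `k` should be read as a fit diagnostic, not as evidence of true
trimodality; the package logs it per sample.

# Fragment-length profiling

Fragment lengths are `|TLEN|` of the leftmost mate, one per read pair,
keeping pairs with both mates at mapping quality ≥ 10, mates on one
chromosome and nonzero TLEN (exclusions are counted by reason). Profiles
are histograms over `[50, 500)` bp in 5-bp bins — bin width is a package
choice — normalized by the sample's total filtered pair count, with
out-of-range mass reported so the total is exactly 1. An external
total-pairs denominator can be supplied instead when profiles should be
normalized to all sequenced pairs. The healthy reference pools all healthy
*reads* (not per-sample averages) before binning. Sample-versus-reference
dissimilarity is `1 - Pearson r` over matched bins, and the
short-fragment fraction is the proportion of fragments under 150 bp — the
sub-mononucleosomal signal enriched in tumour-derived cfDNA.

# Cohort statistics

Concordance classification assesses each plasma variant in primary and
metastatic tissue: a tissue is callable only above 50 reads (strictly),
present at ≥ 3 alt reads — the same support rule used for solid-tumour
calling — and variants with any uncallable tissue are excluded from the
category fractions (concordant in all three, metastasis-only,
primary-only, plasma-only).

The Wilcoxon rank-sum test and Pearson correlation are implemented in the
package rather than delegated: the rank-sum uses mid-ranks for ties, exact
enumeration of all `C(N, nx)` rank assignments when `N <= 12` (two-sided p
as the doubled smaller tail, capped at 1), and otherwise the normal
approximation with tie correction and continuity correction; Pearson's r
uses the product-moment formula with the `t`-transform p-value on `n - 2`
degrees of freedom. Both are cross-checked in the test suite against the
corresponding `stats` implementations at machine precision. At very small,
heavily tied samples the normal approximation can deviate from the exact
tail by up to ≈ 0.08, so the exact branch is the default whenever feasible.

# The synthetic-data generators

All tests and the acceptance experiments run on seeded synthetic data with
written ground truth; no sequencing data is required.

* `simulate_umi_readset()` emulates a targeted-capture cfDNA library:
  molecules per target with nucleosomal fragment lengths (default mixture
  85% N(167, 10) + 15% N(320, 25) bp truncated to [50, 500] — the
  mono/di-nucleosomal shape of healthy plasma), fragment placement uniform
  over positions covering the target, a zero-truncated Poisson (mean 3)
  number of read-pair copies per molecule, 2 × 150 bp reads, uniform
  random 8-mer UMIs, and independent per-base substitution errors per read
  (plus an optional UMI error rate).
* `simulate_consensus_readset()` generates the post-consensus
  representation directly — one fragment-spanning consensus read per
  family — which is the natural level for caller experiments at depth
  several thousand. Its substitution errors are applied per *family*,
  emulating first-cycle PCR errors that survive consensus; they hit
  single-orientation families independently, so they are never coordinated
  across strands.
* Spikes: `duplex = TRUE` spikes emit every alternate molecule as two
  families with shared fragment coordinates, opposite orientations and
  distinct UMIs (a true double-stranded variant); `duplex = FALSE` spikes
  emulate single-strand artifacts, with all alternate families on one
  strand. Note that duplex spikes therefore contribute two families per
  molecule, which inflates the *observed* family-level VAF to about
  `2v / (1 + v)`.
* `simulate_coverage_tables()` draws negative-binomial per-target coverage
  (variance `mu + d mu^2`; `d = 0` degenerates to the exact expectation)
  with fold-changes applied to amplified genes in the case sample.

What the generators deliberately do **not** model: quality-by-cycle error
profiles, GC bias, mapping ambiguity, real indel alignment, or biological
fragment-length coupling to variant status. Green tests therefore
demonstrate the *algorithmic* correctness of grouping, filtering,
confirmation and profiling under the stated generative assumptions — not
performance on any particular instrument or cohort.

# Problem sizes and numerical choices

The test-suite and acceptance experiments use: 37-position panels at
consensus depth 3000 (≈ 111,000 consensus reads) for caller sensitivity
and specificity; 20 samples × 50,000 fragments for healthy-profile
consistency; and a few hundred targets for CNV fits — sizes chosen so the
full suite runs in about a minute while keeping the binomial/CDF oracles'
3-standard-deviation envelopes tight. Other numerical choices collected in
one place: consensus base-quality cap 60 and tie quality 2; SNR
denominator floor 0.5; log-ratio pseudo-count 0.5 coverage units scaled by
library size; EM variance floor 1e-4 and tolerance 1e-6; mixture-sd floor
1 bp; Wilcoxon two-sided doubling capped at 1; one-decimal rounding for
reported percentages.

# Known limitations

* Substitution variants only in the pileup; indels are accepted in the
  candidate container but not generated from alignments.
* No probabilistic duplex error model — confirmation is the combinatorial
  two-strand rule, which is stringent but discards true variants whose
  second strand was not recovered.
* The CNV module does not segment, estimate tumour fraction, or correct
  for GC; it reproduces only the null-distribution thresholding step.
* Alignment is accepted as input; the package does not run an aligner.
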