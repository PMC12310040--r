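---
title: "motifscape: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{motifscape: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the scientific models behind `motifscape`, the
parameters that matter, and the choices we made where the design was
genuinely open. It states no empirical result that the package's tests
and `scripts/acceptance.R` do not themselves compute.

## The problem

A ChIP-seq experiment for a transcription factor (TF) recovers every
DNA fragment the TF is cross-linked to, directly or indirectly. Motif
discovery on the peaks therefore returns a ranked list of position
weight matrices (PWMs) that mixes the motif the TF binds itself (its
*canonical* motif) with the motifs of partner TFs that co-occur in the
same peaks. Downstream questions — where a TF's binding sites lie
relative to genes, how often it is tethered rather than DNA-bound —
depend on getting the canonical motif right first.

## PWM model and similarity

A PWM is a column-stochastic 4 × w matrix of nucleotide probabilities
(rows A, C, G, T; 4 ≤ w ≤ 50; columns renormalised at construction and
validated to sum to 1 within 0.01). Information content per column is
`2 + Σ p log2 p` bits against a uniform background, with `0·log2 0 = 0`.

Two PWMs are compared by sliding one along the other over every
ungapped offset and both strands, and computing the Pearson correlation
(PCC) of the two flattened 4 × L overlapping sub-matrices. We return a
single scalar per pair — the maximum over alignments — because the
similarity criterion used throughout (similar ⇔ PCC ≥ 0.80) treats the
PCC as one number per PWM pair. Choices:

* **Flattened, not column-averaged.** The PCC is computed over the 4L
  overlapping cells at once. A column-averaged variant would weight
  low-information columns equally with sharp ones.
* **`min_overlap` defaults to `min(w_a, w_b, 5)`.** One- or two-column
  overlaps produce spuriously high correlations; five columns is the
  shortest overlap we consider interpretable for motifs of typical
  width 8–16.
* **Thresholds are ≥ 0.80 everywhere** (configurable). Using a strict
  `>` changes nothing in practice because exact ties at 0.80 occur with
  probability zero for continuous matrices.
* **Zero-variance overlaps get PCC 0.** A constant sub-matrix carries
  no motif information; correlation against it is undefined and calling
  it 0 keeps such alignments from ever winning.
* **Tie-breaking** is larger overlap, then + strand, then smaller
  |offset|, making the reported alignment deterministic.

## Scanning and exact p-values

Scanning uses the log-odds score `log2((p + ε·b) / ((1 + ε)·b))` per
cell (background b, pseudocount fraction ε = 0.01 so zero-probability
cells stay finite), summed over the window. P-values are exact: column
scores are discretised to 1/1000 bit and the null distribution of the
score of a random w-mer under the i.i.d. background is built by
convolving the per-column distributions. The discretisation error of a
word's score is bounded by w/1000 bits; the unit tests bracket the DP
p-values between exhaustive-enumeration p-values shifted by exactly
that slack. Sites are called at p ≤ 1e-4 — the conventional scanning
threshold for ChIP-seq motif presence — and the same integer score
scale is used for the table and the scan, so lookups are consistent by
construction.

The minus strand is scored with the reverse-complemented matrix and
reported on forward coordinates; under the default uniform background
the null distribution of both strands is identical. Windows containing
`N` are skipped. Both strands' hits at the same locus are kept;
de-duplication happens downstream by interval merging.

Peaks are summit-centred 200-bp windows (BED `[summit−100,
summit+100)`). With one experiment the top 500 peaks by signal are
used; with several, peaks are ranked by signal within each experiment
and merged by best rank (ties by signal) to the top 1000. This
best-rank merge is our documented surrogate for cross-experiment peak
prioritisation, isolated in `select_top_peaks()` so it can be swapped
out.

Internally all intervals are Bioconductor `GRanges` (1-based, closed),
the native currency of `findOverlaps`, `coverage` and
`distanceToNearest`; 0-based BED-style starts appear only in on-disk
tables. The summit-window invariant above is stated in BED coordinates
and holds exactly under the conversion.

## Canonical-motif inference

Per TF, inferred PWMs supported by fewer than 100 peaks are dropped
(the support filter is applied at classification, not at parse time, so
motif files round-trip losslessly). Then:

1. every PWM with PCC ≥ 0.80 to a same-family database canonical is
   canonical; the best-matching one is the representative;
2. otherwise, if the top-ranked PWM matches no database motif of any
   family, it is the *candidate canonical* (it may correspond to a
   motif not yet characterised);
3. otherwise the PWMs match only other families: they are recorded as
   co-occurring motifs and the TF has no canonical motif. Such TFs can
   fall back to the highest-information-content database canonical for
   binding-mode counting (`fallback_canonical()`).

**Sub-motif rejection.** A wider PWM sometimes embeds a canonical motif
plus extra informative sequence; it is then not itself canonical. Our
test: some window at the canonical's width reaches PCC ≥ 0.80, *and*
the full-length correlation — all query columns against the canonical
padded with uniform background at its best placement — stays below
0.80, *and* the flank has ≥ 3 columns with ≥ 0.5 bit. The padded
full-length comparison is the key numerical choice: correlation over
only the overlapping columns would always be ~1 for a true superset, so
"the whole PWM is not similar to the canonical" must be evaluated
against a background-padded reference. Uninformative flanks match the
uniform padding and keep the full-length correlation high, which is
exactly the case that should *not* be rejected.

**Split motifs.** When one long motif is recovered as two PWMs, their
hits co-occur at a nearly constant end-to-head gap. If a modal gap g
with 0 ≤ g ≤ 4 bp accounts for more than half of co-occurrences, the
halves are concatenated with g uniform spacer columns; otherwise the
merge is refused.

## Binding modes

Per TF: X = peaks containing only canonical-motif hits, Y = peaks with
only co-occurring-motif hits (tethered binding), Z = peaks with both
(co-binding). Presence, not multiplicity, is counted — a peak with two
canonical hits contributes once. The five groups follow strict
inequalities ((1) X > 0, Y = Z = 0; (2) X > Y > Z; (3) X > Z > Y; (4)
Y > X, Y > Z; (5) Z > X, Z > Y); tied configurations satisfy none of
them and are reported unclassified rather than forced, since the rules
are strict by construction. Co-occurring ("non-canonical") motifs are
restricted to families other than the TF's own.

Co-binding pairs are typed by shortest paths in an undirected
protein-interaction graph: the same TF twice is G3 (one TF binding two
nearby sites), a direct edge is G1, one intermediate co-factor is
G2(N=1), more than one is G2(N>1); pairs with no path or missing nodes
are reported untyped and excluded from group means. Motif spacing is
the end-to-head gap in coordinate order, strand-agnostic; overlapping
motifs yield negative gaps, which are retained and visible rather than
clipped. When a peak holds several hits of a motif, the top-scoring hit
represents the motif for spacing.

## Family core motifs

Within a family, canonical PWMs are clustered by single-linkage
connected components at PCC ≥ 0.80 — single linkage because the
criterion defines groups only through the pairwise threshold, with no
objective function to optimise. Clusters of ≥ 3 members yield a core
motif: the highest-IC member anchors an ungapped alignment, every other
member is placed at its best offset/strand, columns are averaged
unweighted (support-weighted averaging is available behind a flag), and
columns covered by fewer than 2 members are trimmed so a single
member's overhang cannot dominate the consensus ends. The consensus is
invariant to member order and to reverse-complementing any member.

## Positional analysis

* **Conservation.** A site's score is the mean of per-base track scores
  over its interval (bases absent from the track count 0); sites with
  score strictly > 0.5 are retained. The aggregation from per-base
  scores to one site score is a choice; mean is the default and max is
  available, since a site "detected in more than half the species" is
  most naturally a mean criterion.
* **Merging.** Sites overlapping by ≥ 90% of the shorter interval are
  unioned, TF annotations pooled, repeated to a fixpoint (idempotent).
  Measuring against the shorter interval is the default; a reciprocal
  mode exists.
* **TSS distance.** The site centre is located relative to the closest
  TSS over all genes; the sign is strand-aware (negative = upstream in
  gene orientation), ties break by gene name.
* **Region annotation** by site centre with precedence promoter >
  5'UTR > 3'UTR > exon > intron > TTS > intergenic; exon/intron
  ordinals are counted 5'→3' in gene orientation and binned 1..10,
  ">10". The promoter is −1000..+100 bp of the TSS (1100 bp,
  strand-aware); the −2000..+200 window is a separate reporting window
  for family quantiles, not an annotation class. The TTS class extends
  100 bp downstream of the TTS.
* **Enrichment.** Per region class, `log2(N / N_expected)` with
  `N_expected = n_sites × region_length / genome_length` over the
  merged region intervals; empty counts give −Inf, which PCA imputes to
  one below the column's smallest finite value so sentinels stay
  extreme without destroying the decomposition.
* **CTCF proximity.** A TF's percent abundance is 100 × (its sites
  within 200 bp of a CTCF site) / (CTCF sites with any nearby site);
  abundances of different TFs can legitimately sum above 100% because
  several TFs can flank one CTCF site.
* **PCA grouping.** TFs are embedded by `prcomp` on centred enrichment
  profiles; PC1's sign is fixed so the PLS loading is positive, making
  group labels deterministic. Cut-points are user-supplied or default
  to equal-count sextiles of PC1, because no canonical cut values exist
  for arbitrary data.
* **Quantiles** use the inverse-ECDF definition (type 1), so they equal
  sorted-array indexing exactly; families with ≤ 10 distinct TFs are
  pooled into "others" before reporting.
* **Random sites** follow the `bedtools random` model: chromosome drawn
  proportional to length, start uniform within bounds.

## The synthetic-data generator

The generator emulates the study's inputs with a planted ground truth:
an i.i.d. genome (GC 0.41, the human genome-wide value) with
non-overlapping multi-exon genes on both strands, PLS at promoters,
pELS within 2 kb, distal dELS, CTCF intervals partly near promoters; a
motif database with family labels; peaks of summit ± 100 bp whose
contents follow a per-TF binding-mode mixture of 0.6/0.3/0.1
(canonical-only / tethered / co-binding) with co-occurring spacing
drawn from Normal(40, 8) bp, the spacing scale reported for co-occurring
sites in ChIP-seq peaks; a conservation track elevated at planted sites
with probability 0.8; and a PPI network with planted direct edges,
one-co-factor and two-co-factor bridges plus leaf distractors that
provably cannot shorten planted paths.

Motif instances are *sampled from the PWM* column by column rather than
planted as consensus strings, so the scanner's p-value machinery is
exercised realistically. This makes detection probabilistic: the mean
score of a sampled instance equals the motif's information content
(under a uniform background), while the p ≤ 1e-4 threshold corresponds
to ≈ 13.3 bits. Database motifs therefore default to widths 12–16 with
20–26 bits — sharp, well-defined PWMs of the kind curated databases
hold for strong binders — giving ≥ 99% per-instance detection. We
measured the detection-versus-IC relationship by direct simulation
before freezing this default; at 14 bits detection would be ≈ 80% and
mixture recovery would be confounded by detection loss rather than by
the quantities under study.

All randomness flows from one master seed through named substreams
(genome / motifs / tfs / peaks / track / ppi), so each component is
reproducible in isolation.

What the generator does **not** emulate: real genomic sequence
composition (repeats, CpG islands, local GC structure), overlapping
genes and alternative TSSs, read-level noise or peak-calling artefacts,
correlated conservation outside planted sites, and biologically
structured PPI topology. Passing the recovery tests therefore shows the
*algorithms* are correct and well-calibrated under the stated
generative model, not that the biological conclusions transfer to real
data.

## Tied constants

The pipeline configuration carries the analysis constants in one
place: PCC threshold 0.80, scan p-value 1e-4, conservation 0.5, merge
overlap 0.9, support 100 peaks, CTCF window 200 bp, promoter
−1000..+100 bp. All are overridable per run; the defaults are the
values the analyses were designed around.

## Problem sizes in the test-suite

The tests run the full machinery at reduced scale: exhaustive p-value
enumeration at w = 5–6, similarity oracles on motifs of width 5–10,
synthetic genomes of 0.14–0.9 Mb with 6–40 genes, 60 TFs for
canonical-status recovery, and 2 TFs × 500 peaks for binding-mode and
spacing recovery. These sizes were chosen so each statistical check
retains conventional power (3σ binomial bands at n = 500, CLT bands at
n ≈ 80 pairs) while the whole suite remains quick to run. The
binding-mode recovery test compares recovered X/Y/Z fractions with the
*realized* planted composition of each TF's peaks — the generator's own
multinomial draw is part of the truth, not part of the measurement
error.

## Known limitations

* PCC-based similarity has no significance model (no E-values); the
  0.80 threshold is a convention, and for very short overlaps the PCC
  is noisy — hence the minimum-overlap floor.
* The DP p-value assumes an i.i.d. background; promoter-like
  composition (CpG bias) is not modelled, so genome-wide scans at
  p ≤ 1e-4 have locally varying false-positive density in real data.
* Tethered/co-binding tallies count motif presence, so a peak with an
  undetected weak canonical site is counted as tethered; detection
  probability depends on motif information content.
* The inter-experiment ranking surrogate reproduces the intent (favour
  consistently strong peaks) but not any specific published ranking
  scheme.
* `merge_tfbs` assumes approximate confluence of pairwise merging;
  pathological chains of marginal overlaps could in principle depend on
  merge order, though fixpoint iteration makes the result stable for
  the densities seen in practice.
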