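---
title: "Methods: piRNA loci, SV hotspots and TE activity with pirnasv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA loci, SV hotspots and TE activity with pirnasv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pirnasv)
```

# Scope and data model

`pirnasv` implements the computational half of a comparative-genomics
analysis of pachytene piRNA loci and structural variation: everything
downstream of read alignment and raw SV calling. Alignment, basecalling,
RepeatMasker annotation and BLAST execution are out of scope; their
outputs (collapsed reads with genomic mappings, SV call sets, hit tables,
conservation tracks) are the package's inputs.

All coordinates are 0-based half-open everywhere internally; the only
1-based interchange is the minimal VCF reader, which converts POS on
read. A minus-strand read's 5′ position is the *highest* genomic
coordinate it covers — required for the ping-pong overlap definition
below. Insertions anchor on a 1-bp interval at the insertion point,
matching VCF semantics and making "overlap with locus" well defined.
Species counts are real-valued, not integer, because oxidized-library
calibration rescales them.

# piRNA locus detection

Windows of 1 kb accumulate the 5′-end abundance of reads > 23 nt, with
multi-mapping species contributing count/n_mappings per mapping (the
source study does not state an apportionment rule; fractional weights
conserve totals exactly and are the common convention). The penalty is
the mean abundance of the top 5 % of windows genome-wide, encoding the
prior that piRNA clusters occupy at most 5 % of the genome. The scoring
recursion `s[i] = max(0, s[i-1] + a[i] - penalty)` is iterated: the
maximal score marks the last window of the current cluster; the first
window is the one after the most recent zero score (the recursion's reset
semantics make this the standard linear-chain traceback); the cluster's
windows are zeroed and the scores recomputed until all are zero.

Three choices were genuinely open:

* **Traceback.** "The maximum score indicates the largest cluster" leaves
  the start implicit; the window after the last reset is the unique start
  for which the extracted score equals the segment's penalized sum, and it
  makes the first extraction provably identical to the maximum-sum
  contiguous subarray of `a - penalty` (property-tested against
  exhaustive enumeration).
* **Per-base refinement threshold.** Boundaries are trimmed to the
  outermost base whose abundance exceeds `penalty / window` — the
  per-window mean converted to commensurate per-base units. If no base
  qualifies, the window-resolution interval is kept.
* **Clusters failing the ≥ 1 unique-read filter** are discarded *after*
  extraction but still consume their windows; otherwise the iteration
  could loop forever on a multimapper-only peak.

Ties for the maximal score are broken leftmost (then longest); with
real-valued abundances ties have probability zero.

# SV consensus and hotspots

Deletions, inversions and duplications must be corroborated: a same-type
record in the second call set with both breakpoints within 500 bp,
reciprocal size ratio ≥ 0.5 and score ≥ 10, while the primary record
needs ≥ 10 supporting reads. Insertions are taken from the primary caller
alone (long-read insertion calls rarely reproduce breakpoint-exactly
across callers). Records below 50 bp are rejected on input — by
definition they are not SVs.

Hotspot calling smooths SV midpoints (the event-point choice makes an SV
of any size one point; the alternative of using both breakpoints is not
stated in the source and would double-weight large events) with a
Gaussian kernel on a grid of step bw/10. Bandwidths follow the avian
chromosome classes: 2 kb for macrochromosomes (> 40 Mb) and intermediate
chromosomes, 200 bp for microchromosomes (< 20 Mb) and unassigned
contigs, 20 kb for sex chromosomes. `select_bandwidth()` re-derives the
verbal parsimony criterion as (SVs inside hotspots)/(hotspot bp),
maximized over the candidate set {200, 2 kb, 20 kb, 200 kb, 2 Mb}, ties
to the smaller bandwidth.

**The permutation null is family-wise.** Each of the 1000 trials
re-places the points uniformly and contributes its *maximum* density; a
grid point's empirical p is the fraction of trials whose maximum reaches
the observed density there. A literal pointwise comparison would flag ~1
grid point per chromosome on uniform data (each point has a 1/(T+1)
chance of beating all T trials, and there are thousands of points),
contradicting the required false-call behaviour; against the trial maxima,
uniform data yields a hotspot in roughly α of seeds, which the acceptance
suite verifies (≥ 99 % clean seeds at α = 0.001). Significant runs are
extended by bw/2 per side and merged; p = 0 is reported as "< 1/T".

# Shuffling tests

`shuffle_intervals()` re-places each query interval uniformly on its own
chromosome, length preserved, self-overlap permitted — the behaviour of
`bedtools shuffle -chrom`, which the analyses this package reproduces
relied on. Statistics: count of query elements in features (midpoint or
any-overlap, both exposed because the source uses both phrasings), number
of overlapping intervals, median nearest distance (gap between closest
ends of half-open intervals; overlap or shared boundary is 0), and median
per-interval mean of a score track.

Two p-values are reported side by side. The printed formula
`P = min{1, max{Pl, Pu}}` cannot fall below 0.5 — the larger of two
complementary tail fractions is at least 1/2 — yet the quantities it
accompanies are quoted as small (e.g. "< 1e-4"), which only the one-tailed
form `#(null at least as extreme)/T` can produce. The package computes
both and labels zero exceedances "< 1/T" rather than 0.

# Signatures

The ping-pong score S(k), k ∈ 1..30, sums products of plus- and
minus-strand species counts whose 5′ ends satisfy k = q − p + 1 on the
same chromosome (k = 10 ⟺ the two 5′ ends span exactly 10 bases, the
canonical register of piRNA-guided cleavage); 3′ heterogeneity is
ignored. Z₁₀ uses the background {1–9, 11–30} with a *population* sd —
the background is the full enumerated set, not a sample. Degenerate rule:
sd = 0 with S(10) equal to the background mean gives 0; sd = 0 with S(10)
above it gives +Inf, a flagged extreme. The production implementation
joins per-position count maps; an O(n²) pair enumeration is kept in the
test suite as the oracle.

Nucleotide periodicity aligns 26–32 nt uniquely mapping footprints to
each other per strand, forms the distance spectrum of summed count
products at 5′–5′ separations 0..D, and reports the squared-modulus DFT
of the mean-subtracted spectrum normalized to the first frequency. The
cited periodogram implementation's "clone" detail is not specified in the
source; mean subtraction + DFT is the declared stand-in, validated on a
3-nt comb (dominant relative power at frequency 1/3).

# TE classification and dating

Hits are filtered at e ≤ 1e-10 and by the 80-80-80 rule (> 80 % identity,
alignment > 80 % of *consensus* length — the ambiguous denominator is
read as consensus length — and < 20 % gaps). The length rule is waived
for LINE-class hits: target-primed reverse transcription habitually
truncates 5′ ends, and the classifier replaces it with the 3′-anchored
rule (the consensus 3′ terminus must align within 20 bp of an insertion
end, orientation-aware, with a ≥ 200 bp 3′ block). LTR/DNA elements must
be complete at both consensus termini; an LTR–internal–LTR arrangement is
an intact ERV unless its insertion site overlaps a reference solo LTR, in
which case the event is an ancestral deletion re-read as an insertion and
is rejected. Every insertion receives exactly one status; the cascade is
order-invariant (tested by permuting hits). `end_tol = 20` bp absorbs
ONT-scale breakpoint noise; the source states no tolerance.

Ages: per family, mean per-copy divergence p̄ from consensus (gaps
excluded) is JC69-corrected, K = −(3/4)ln(1 − 4p̄/3), and divided by a
neutral rate r = 1.9e-3 /site/My. K/r, not K/(2r): divergence from the
consensus proxies one lineage's divergence from the ancestral state, and
this scaling reproduces the ~21.6 My age at ~4 % divergence.

# Small-RNA statistics

Libraries are normalized to their miRNA totals (assumed constant across
samples); oxidized libraries are calibrated by the ratio of summed counts
over shared > 23 nt species — the sum, not a median of ratios, because it
is robust to zero counts and matches totals exactly, and it makes a
second calibration pass a no-op (factor 1, tested). Feature abundance
assigns a read to a feature when its 5′ base lies inside; ppm and rpkm
use total genome-mapping reads (all lengths) as denominator with a
pseudo-count of 0.001 added to both. Strand bias is the Watson fraction
w/(w+c) — the source names the quantity without a formula; the Watson
fraction is bounded and symmetric. Expression variance is the residual of
a LOESS fit (degree 2, span 0.75 by default) of CV = sd/mean on
log10(median + 0.001); the acceptance suite checks |Spearman ρ| < 0.1
between residual and median on 1000 synthetic features. Wootton–Federhen
complexity is evaluated via log-gamma, so long sequences cannot overflow
factorials.

# The synthetic world

Generators are pure functions of (config, seed); identical configs give
byte-identical FASTA output. Defaults are one stated world, not tuning
knobs:

* **Genome**: 60 Mb / 30 Mb / 5 Mb chromosomes — one representative of
  each avian size class (macro > 40 Mb, intermediate 20–40 Mb,
  micro < 20 Mb). Gene/repeat annotations at 5 and 50 per Mb.
* **SVs**: 200 per type, lengths 50–5000 bp, support and score uniform in
  10–30 (so defaults pass the consensus gates), 90 % dual-caller with
  ≤ 100 bp breakpoint jitter, and a 10× midpoint-rate excess over a
  100 kb hotspot. The planted hotspot share follows the closed form
  m·w/(L − w + m·w), which the tests assert as a binomial expectation.
* **piRNA reads**: collapsed species with mappings, never FASTQ —
  alignment is out of scope and the computations start from mapped reads.
  Cluster `depth` is expected 5′-end reads per bp; reads are 24–32 nt;
  a configured fraction of cluster reads is emitted as plus/minus pairs
  with 5′ ends exactly 10 nt apart; background 2e-6 reads/bp; 10 % of
  species receive a decoy second mapping. The miRNA pool (21–23 nt,
  1e5 reads over 50 species by default) exists purely to exercise the
  normalization rule.
* **TEs**: a 300 bp LTR, 5 kb internal and 4.6 kb CR1 consensus at 4 %
  per-copy divergence — i.i.d. per-site substitution to a uniformly
  chosen different base, matching the JC69 assumption used for dating,
  and ~4 % matching a recently invaded (~20 My) cohort at the stated
  neutral rate. Decoys are constructed to land in their designated
  rejected states: CR1 copies with the 3′ end internal (but still
  TE-bounded, so they exercise the 3′ rule rather than the boundedness
  rule) and intact ERVs planted on reference solo-LTR sites.

What a green test does *not* establish: sequence composition is uniform
random (no GC structure, no real repeat homology), breakpoints have no
microhomology, SV genotypes and population structure are absent, and
multi-mapping is a binary decoy rather than a repeat-driven ambiguity
profile. The calibration and recovery results therefore validate the
statistical machinery, not performance on any particular genome.

# Numerical and runtime choices

Empirical p-values use the trial-count denominator; zeros are labelled
"< 1/T" instead of 0. The KDE is computed by FFT convolution of binned
midpoints with the kernel spectrum precomputed per chromosome; kernel
support is truncated at ±4 bw. Degenerate inputs are handled explicitly:
all-zero windows are an error for penalty estimation ("no piRNA signal"),
an all-constant expression matrix short-circuits the LOESS (fitted = mean
CV), bandwidths at least the chromosome length skip the chromosome with a
warning, and chromosomes with fewer than two SVs are not evaluated.
Acceptance experiments run on 1–10 Mb chromosomes to stay inside the
runtime budget; all thresholds (Z > 3, p ≤ 0.001, ≥ 95 % / ≥ 99 % seed
fractions, 5–10 % recovery tolerances) are as stated, not scaled.

# Known limitations

The VCF reader is a deliberate minimal subset (SVTYPE/SVLEN/END/SEQ/RE).
The parsimony score for bandwidth selection is one reasonable
formalization of a verbal criterion. The shuffle engine does not support
GC-matched or blacklist-aware randomization. Distances ignore features on
other chromosomes (consistent with same-chromosome shuffling). The
periodicity transform is a plain periodogram, not the cited
implementation's exact internals.
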