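---
title: "Methods: GC-rich element discovery and Polycomb ChIP analysis with prc2scan"
author: "prc2scan maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GC-rich element discovery and Polycomb ChIP analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prc2scan)
```

## Scientific background

In embryonic stem (ES) cells, Polycomb repressive complex 2 (PRC2, whose
Ezh2 subunit deposits H3K27me3) localizes to thousands of developmental
loci, typically at CpG islands that also carry H3K4me3 — the "bivalent"
state. A productive working model is that *large GC-rich elements depleted
of activating transcription-factor motifs* are sufficient to recruit PRC2:
any CpG-island-like sequence that is not being actively transcribed tends
to acquire PRC2, whether it comes from a mammalian promoter or even from a
prokaryotic genome. `prc2scan` implements the computational side of testing
that model: it finds GC-rich elements, quantifies their motif content and
asymmetry, calls ChIP enrichment against a matched empirical null,
stratifies promoters by CpG class / expression / methylation, and
quantifies ChIP-qPCR — all exercisable end-to-end on synthetic data with
known ground truth.

## Coordinate and data conventions

All coordinates are **0-based, half-open** `[start, end)` everywhere inside
the package; conversion to 1-based conventions happens only at file
boundaries (e.g. fixed-step WIG). Sequences are uppercase A/C/G/T/N
character vectors; reads are (contig, 5′ position, strand) triples.

## Sequence statistics

For a window of sequence, the two discriminating statistics are

* **GC fraction**: (#G + #C) / (#non-N bases), and
* **CpG observed/expected**: `O/E = N_CpG · L / (N_C · N_G)` with `N_CpG`
  the count of literal `CG` dinucleotides inside the window (no wrap
  across window edges), `L` the non-N length. `O/E = 0` when `N_C` or
  `N_G` is zero; windows with more than 10% N are masked (assembly gaps
  would otherwise produce spurious ratios).

CpG islands are called with the classical mammalian convention —
GC ≥ 0.50, O/E ≥ 0.60, length ≥ 200 bp — which the analyses this package
reimplements invoke without restating thresholds; all three are
parameters. The scan runs a 200 bp window at 1 bp step, merges runs of
qualifying placements, trims non-G/C edge bases, and keeps merged spans
that still satisfy the criteria recomputed over their full length. Calls
are audited for self-consistency in the test suite
(`audit_island_calls()`).

**Element discovery** (`find_gc_rich_elements()`) is the prokaryote
selection procedure: score 1 kb windows for the island criteria, drop
windows containing more than `max_hits_per_window` activating-motif (AM)
hits (default 2; the original depletion threshold is not published, so
this is an explicit parameter, not a claim), and rank by O/E descending
with GC and coordinate as tie-breaks. The default step equals the window,
i.e. candidates tile the genome disjointly. This is a deliberate choice:
with a sliding step, windows straddling the *edge* of a motif-laden island
pass the island criteria while containing few motifs, and would be
reported alongside the genuinely depleted element. Disjoint candidate
segments match the way selected elements are used (cloned as intervals). A
sliding variant remains available through `step_bp`.

## Motif scanning

PWMs are per-position probability matrices with a pseudocount (all entries
strictly positive). A match at a position is scored as total log-odds in
bits against a background model, which defaults to the scanned sequence's
own base composition (MAST-style). Significance is a **per-position match
p-value**: the probability that a random background position scores at
least as high, computed from the exact score distribution obtained by
per-position convolution over scores discretized into 1/1000-bit bins
(`score_distribution()`; the absolute discretization error is at most
`motif_length/2000` bits and is reported). A hit is any position/strand
with p ≤ α; the conventional α is 5×10⁻⁵. This is *not* a sequence-level
E-value: it composes cleanly across sequences of different lengths and is
the conservative reading of "significance level". Overlapping self-hits
are all reported; no greedy masking.

Two consequences of this semantics are worth knowing. First, the smallest
attainable p-value for a motif equals the background probability of its
consensus word, so a composition-balanced 6-mer (min p ≈ 0.25⁶ ≈ 2×10⁻⁴)
can *never* be significant at 5×10⁻⁵ — short motifs need
composition-skewed consensus words to clear that bar. Second, in a low-GC
background every GC-rich *word* is individually rare, so near-consensus
words of a GC-rich motif may also clear α; the synthetic presets therefore
remove spurious hits using the scanner itself rather than exact word
matching.

**Asymmetry** within an island splits it at the midpoint, assigns each
overlapping hit to the half containing the hit's own midpoint (left on
ties), and reports a two-sided binomial p against Binomial(n, ½) — the
statistic behind "all the activating motifs sit in one half of this
island".

## ChIP-Seq enrichment against a randomized-read null

Window enrichment statistics count read **5′ positions** per window, for
both the observed data and the null. The null re-places all reads of a
dataset uniformly (contigs weighted by length), ten times by default, and
pools per-window counts over a disjoint tiling into an empirical
distribution; each dataset gets its own null so that sequencing depth is
matched. The empirical upper-tail p-value uses add-one smoothing,
`p = (#{null ≥ c} + 1)/(N + 1)`, capping resolution honestly at
`1/(N+1)` and making the test conservative rather than assuming any count
distribution.

A design note: an alternative convention counts *extended* reads
overlapping each window. We count 5′ positions because it keeps the null
mean exactly `total_reads × window / genome` (the Poisson expectation a
reader will check first) and puts the observed and null counts on
identical footing; read extension (default 200 bp, a fragment-length
proxy) is applied only when building density tracks for visualization
(`build_density()`, 25 bp bins, minus-strand reads extending
`[pos − ext, pos)`).

Genome-wide calling slides 1 kb windows at a 200 bp step and keeps
windows with p < 10⁻³ (strict; **no multiple-testing correction beyond
this fixed cutoff is applied — deliberately, to mirror the analysis being
reimplemented**). Enriched windows within 1 kb are merged transitively;
a region inherits the minimum member p-value, its width is the merged
span, and the summit is the midpoint of the highest-count window.

Promoter classification counts reads in TSS ± 1 kb (the original window
is inherited from its reference and not restated; ours is an explicit
parameter) against a null built for that window size, one null per mark.
Bivalent = K4me3⁺ ∧ K27me3⁺; the full mark-combination cross-tabulation
(Venn counts) is attached to the call table.

Heat-map matrices (`signal_matrix()`) take 20 kb rows centered on region
midpoints, partition rows by CpG-island overlap (overlapping group
first), and sort by enrichment width descending within groups,
coordinate-ordered on ties (the tie rule is our choice; the original is
silent). `spreading_extent()` walks measurement points outward from an
element boundary and reports the farthest point still at or above
threshold, stopping at the first sub-threshold point — spreading is
contiguous by definition.

## Expression, promoter classes and methylation

Promoter CpG classes use 500 bp sub-windows over a strand-oriented
−500..+2000 span around the TSS: HCP if any sub-window has GC ≥ 0.55 and
O/E ≥ 0.6; LCP if no sub-window reaches O/E 0.4; otherwise ICP. The
thresholds come from the standard promoter-class scheme (they are not
restated in the analysis being reimplemented) and are configurable. Note
that at bulk genomic O/E (~0.1–0.2) the LCP/ICP boundary is genuinely
stochastic at the 500 bp scale — a random CpG flurry can push one
sub-window over 0.4 — which is a property of the classifier, not a bug.

Expression scores concatenate a gene's exons into a virtual coordinate
and take the maximum read count in any 1 kb window of the concatenation
(whole span if shorter), normalized per million mapped reads ("read
density" is not given units in the original; per-million is ours). The
inactive-HCP stratification restricts to HCPs containing exactly one CpG
island, splits by Ezh2 call, and compares expression scores with a
two-sided rank-sum test; the "detectably transcribed" threshold is
data-driven (the maximum score among LCPs in the cohort) rather than
hard-coded, since only its definition, not its value, is published.

Methylation composites pool per-CpG levels (methylated/total) across
genes in sliding 200 bp windows over the 10 kb around TSSs,
strand-oriented; windows with no covered CpG are missing, and interval
summaries are coverage-weighted.

## ChIP-qPCR

Fold enrichment is ChIP/input on equal-mass quantities, or
`E^(input_Ct − chip_Ct)` with amplification efficiency E ∈ (1, 2]
(default 2). "Background subtracted by normalizing over a negative
genomic control" is implemented as **division** by the control amplicon's
enrichment (mapping the control to 1.0), per mark and per replicate:
division preserves the positivity of fold enrichments, whereas the
phrasing is ambiguous; an arithmetic-subtraction mode exists behind
`mode = "subtract"`. Because only K27me3 and Ezh2 are named for
normalization in the original protocol, normalization is opt-in per mark.
Replicate summaries report mean and SEM (sample sd/√n, absent at n = 1).

One statistical caveat the tests document: with n = 3 replicates, "the
mean lies within 3× the *sample* SEM of the truth" holds in only
P(|t₂| ≤ 3) ≈ 90% of runs — a property of the t distribution, not of the
estimator — so the ≥95% recovery check is run against the true
(noise-model) SEM of the mean, where coverage is ≈ 99.7%.

## Synthetic data: the stated world

Backgrounds are drawn from a **first-order Markov chain**, not i.i.d.
bases, because the discriminating statistic of the whole analysis is CpG
O/E, which must be controllable independently of GC. The chain's C-row
carries the CpG transition mass; a fixed-point calibration adjusts the
nominal parameters so the stationary statistics hit the targets.
Segment draws retry within the seeded stream (up to 50 draws) until
realized GC is within ±0.03 and O/E within ±0.1 of target — at 1 kb these
tolerances are about 1σ of the chain's sampling noise, so enforcement by
retry is what makes the contract reliable. Generators are pure functions
of (spec, seed) and always emit a serializable ground-truth record; tests
never re-infer truth from generated files.

Default background GC is 0.40 with O/E 0.20, planted islands are GC 0.65
with O/E 0.80–0.85; ChIP read sets mix a uniform background with extra
mass in enriched regions so the local rate is `fold ×` background;
methylation calls are Binomial(coverage, level); qPCR noise is
multiplicative lognormal. Four presets reproduce the study's test
configurations: a 44 kb BAC-like contig with one 1.7 kb island and 11
YY1-consensus motifs outside it; an inert 40 kb gene desert; a 20 kb
contig whose 1.8 kb island has all activating motifs in one half; and a
100 kb low-GC "prokaryote" with two grid-aligned qualifying 1 kb plants,
one motif-laden. The bundled YY1 and AM matrices are clearly labelled
example consensus PWMs — the original TRANSFAC matrix is not published in
the source analysis, and no identity is claimed.

What the generator does **not** emulate: mappability structure, PCR
duplicates, fragment-size distributions, nucleosome positioning,
bisulfite conversion failure, isoform structure. A green closed-loop test
therefore establishes that the algorithms recover what they are defined
to recover under their own noise model — not that they are robust to
every artifact of real libraries.

## Numerical and degenerate-input choices

* Score discretization 1/1000 bit; max error reported on the
  distribution object.
* Empirical p-values: add-one smoothing; floor `1/(N+1)`.
* `merge_regions` is idempotent and order-invariant; gap exactly equal to
  `gap_bp` merges.
* All-N windows, empty hit lists, zero-read sets, empty intervals and
  single-replicate SEM all return explicit missing values or empty
  tables, never silent drops; degenerate O/E (no C or no G) is 0 by
  convention.
* Elements/islands are re-audited from sequence in the test suite; island
  calls are invariant under reverse complement (coordinates reflected).

## Known limitations

* The enrichment caller is calibration-first, not sensitivity-first: no
  local background (MACS-style λ), no input-chromatin correction, no
  fragment-model deconvolution.
* Motif significance is per-position only; no E-values, no conservation
  filtering.
* The promoter window, read extension and AM-depletion threshold are
  explicit parameters whose original values are inherited from references
  and not restated there; defaults here are reasonable conventions, not
  reconstructions.
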