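---
title: "Methods: conserved uORF detection and analysis"
author: "uorfscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conserved uORF detection and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uorfscan)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage computes, which parameters matter and
why they default to what they do, what the synthetic-data generator does
and does not emulate, and the numerical conventions used throughout.

## Coordinates and sequence model

Internally all intervals are 0-based half-open; every user-facing table
(`uorf_table()`, TSV exports) is 1-based inclusive in the GenBank style.
Transcripts are sense-strand mRNA only. On ingest, sequences are
upper-cased, U is normalised to T, and IUPAC ambiguity codes other than N
collapse to N. N is retained and treated as a mismatch everywhere — in
alignment scoring, in the match sequence, and in codon filtering — so
ambiguity always depresses identity rather than inflating it.

GenBank CDS features `a..b` become `[a-1, b)`. A record whose CDS start is
fuzzy (`<1..`) or absent is flagged mORF-undefined; the database builder
excludes and counts such records, since without a defined mORF start the
notion of "upstream" is meaningless. When a multi-CDS record is
encountered the first CDS feature is used — a package choice, as mRNA
records essentially always carry a single CDS.

## uORF definition

The mORF is the annotated CDS when present; otherwise the longest
AUG-initiated, stop-terminated ORF in the three forward frames, ties
resolved toward the 5′-most start. A uORF is any AUG strictly 5′ of the
mORF start whose first in-frame stop codon occurs within the transcript
and at most `max_overlap_nt` nucleotides 3′ of the mORF start. Candidates
without an in-frame stop are excluded deliberately: such an ORF is an
N-terminal extension of the main protein, not a discrete upstream peptide.
Only AUG starts are recognised; near-cognate initiation (CUG/GUG) is a
documented non-goal. Nested uAUGs are reported as independent uORFs, each
with its own peptide.

`length_codons` counts coding codons including the initiator Met and
excluding the stop, i.e. the encoded peptide length. Defaults:
`min_len_codons = 10` (shorter peptides carry too little alignment signal
for the conservation statistics to be meaningful), `max_overlap_nt = 0`
(conservative: fully upstream uORFs only), no 5′ search limit. All three
are user-settable per search.

## Global alignment

Transcript pairs are aligned with exact affine-gap global alignment
(Needleman–Wunsch/Gotoh, via `Biostrings::pairwiseAlignment`). An anchored
heuristic aligner would also serve at transcript scale, but exact dynamic
programming is affordable below ~15 kb and makes the scoring contract
bit-exact: a gap run of length L costs `gap_open + gap_extend × (L − 1)`,
with defaults +5 match, −4 mismatch, gap opening 50 and no gap extension.
Terminal gaps are penalised like internal ones — a true global alignment —
so that UTR length differences appear as low-identity regions in the
heatmap instead of being silently absorbed. Where several alignments are
optimal the traceback is deterministic, and every structural invariant
(degapping recovers the inputs, no all-gap columns, the match-sequence
definition) holds for whichever optimum is returned; test oracles
therefore compare scores, which are unique.

## Windowed identity profile

From the aligned pair, the match sequence M marks each column 1 when the
two nucleotides are identical and neither is a gap or N. For a window of
w alignment columns (z = ⌊w/2⌋) centred on each non-gap query column i,
the profile value is the mean of M over the window clipped to the
alignment, `[i−z, i+z] ∩ [1, m]`, normalised by the clipped width. The
clipped-window form reproduces the edge normalisers 1/(z+i) and
1/(z+m−i+1) exactly where only one edge interferes, and generalises them
naturally when w exceeds the alignment (both edges clipped) — a case the
precondition w ≤ 2m−1 avoids by default. Two consequences of indexing
windows over alignment columns rather than query positions: gap columns
inside a window count as mismatches, so insertions and deletions depress
local identity, which is exactly what the heatmap should show; and the
profile still has one entry per ungapped query nucleotide, so strip length
always equals transcript length.

The default window, w = 21 nt, is a package choice: it must be odd for a
symmetric window, and ~7 codons of smoothing suppresses single-site noise
while leaving uORF-sized features (30–90 nt) sharply visible. The heatmap
uses a perceptually uniform gradient ("Viridis") over a fixed 0–100 %
scale with a scale bar always drawn, so images from different runs are
comparable. The raster is written pixel-exact (one cell per nucleotide,
colours computed, not plotted through a device), which makes rendering
byte-reproducible and lets tests assert on cell colours; PNG is the only
output format for that reason.

## Translated homology search

The search emulates a translated (tblastx-style) screen but compares the
already-extracted uORF peptides directly — uORF frame against uORF frame —
rather than all six reading frames of both nucleotide sequences. This is a
deliberate narrowing: the object of interest is the encoded peptide, the
uORF frames are known exactly on both sides, and frame-restricted
comparison avoids spurious out-of-frame hits while keeping the search
desk-scale. Scoring is classic protein-search practice: Smith–Waterman,
BLOSUM62, gap open 11 / extend 1 (a gap of length L costs 11 + L). Each
hit is reported with a bit-like score and a Karlin–Altschul expectation
E = K·m·n·exp(−λS) using the published gapped BLOSUM62 parameters
(λ = 0.267, K = 0.041) and the database residue count.

The default reporting threshold is derived from that expectation rather
than tuned: the smallest raw score whose expectation for a typical
15-residue uPEP against a 10,000-record database stays below 0.05
(`calibrate_min_score()`, giving 55). The test suite verifies the
calibration empirically with random peptides.

## Ka/Ks estimation

Codon alignments are read off the nucleotide alignment in query-frame
codon steps across the ORF (the ORF's own stop codon is not walked);
any codon column containing a gap, an N, a stop in either sequence, or
reference positions outside the reference ORF's coding span is dropped and
counted. Both estimators then work on clean sense-codon pairs.

**NG86.** Sites: at each codon position the three alternative bases are
classified synonymous/non-synonymous; mutations that would create a stop
codon are excluded and the position renormalised, so every position
contributes exactly one site and S + N = 3 × n_codons — which also keeps
the S+N bookkeeping invariant testable. Differences: codons differing at
k positions are resolved by averaging over all k! mutational pathways,
excluding pathways that pass through a stop codon (if every pathway is
blocked, all are used with steps through stops counted non-synonymous).
Proportions pS = Sd/S and pN = Nd/N receive the Jukes–Cantor correction;
p ≥ 3/4 is reported as a saturation flag, never an error.

**YN00.** Codon frequencies are estimated from both sequences by F3x4.
Site counting weights each candidate mutation by κ (transitions) and by
the target codon's frequency, normalised per position; base frequencies
are accumulated separately at synonymous and non-synonymous sites.
Differences are split into transitions and transversions within the same
pathway-averaging scheme as NG86 (equal pathway weights — a simplification
of the original's likelihood weighting, acceptable at the moderate
divergences the tool targets and cross-checked against NG86). Each site
class receives an F84-style multiple-hit correction with its own base
frequencies; the distance is computed through an algebraic form whose
Q = 0 limit is finite, and when a degenerate base composition at a site
class defeats the F84 correction far from saturation, the correction
falls back to K80 (equal frequencies) before flagging saturation. κ is
estimated iteratively: start at 2, re-count sites and re-correct distances
each round, update κ as the site-weighted mean of the per-class HKY
estimates, stop at |Δκ| < 1e−6 or 50 iterations (non-convergence is
flagged and the last iterate reported).

Both estimators are symmetric in their arguments, ratios with Ks = 0 are
reported as an undefined flag (never infinity), and only the standard
genetic code is supported. The simulation used to validate them is a
reversible 61-state codon chain (single-nucleotide steps, κ and ω
multipliers, spectral matrix exponential) — independent machinery from the
counting estimators. Divergence t is expressed in expected substitutions
per codon, the convention of the standard Ka/Ks tools. On the validation
grid (500 codons, t = 0.3, ω ∈ {0.1, 1.0}, 100 replicates) both
estimators recover ω to well within 15 % in the mean and correlate above
0.9; NG86's residual bias at ω = 1 (a few percent low) is the textbook
consequence of equal-weight site counting under transition bias and is
one reason YN00 is the default.

The paired report runs uORF and mORF through the same transcript
alignment and estimator; a side that fails (too few clean codons) is
flagged while the other side is still reported.

## Synthetic data generator

`make_transcript_pair()` builds a query transcript — random UTRs, a
random-sense-codon CDS, planted uORFs in the 5′UTR — and derives a
reference by mutation: UTR sites substituted to a target background
identity with transition bias κ = 2, coding codons mutated under a
synonymy-acceptance model (proposals that create stops are rejected;
non-synonymous proposals accepted with probability ω), short 1–3 nt indels
opened in non-coding regions only. Planted uORF conservation is controlled
either by the same ω model or by an exact amino-acid identity target
(`uorf_identity_aa`), which takes precedence when set. Stray upstream AUGs
are edited out of both sequences deterministically — preferring edits
outside coding regions, then synonymous in-uORF edits — so that the
planted uORFs are exactly the qualifying set and the generator's truth
records agree with the finder by construction.

Defaults describe a realistic mammalian-style comparison: 300 nt 5′UTR,
200-codon CDS, 200 nt 3′UTR, one 25-codon uORF, 60 % UTR background
identity (about human–mouse UTR divergence), 60 % uORF amino-acid
identity, ω = 0.1 for the uORF and 0.2 for the CDS, 2 % indel rate. The
generator deliberately does not emulate codon-usage bias, Kozak context,
CpG effects, alternative splicing or rate heterogeneity along the
sequence; passing tests therefore demonstrate correctness of the
algorithms under a clean substitution model, not performance on real
RefSeq data. Headline biological claims (how many uORFs are conserved
across which species) require a full RefSeq-scale screen and are outside
this package's validation scope.

`make_database()` surrounds planted homologue carriers with decoy
transcripts (each carrying its own random uORFs) and flags a stated
fraction as mORF-undefined to exercise the exclusion rule end to end.

## Determinism and problem sizes

Every stochastic component is seeded explicitly; the pipeline itself is
deterministic, and two runs on identical inputs produce byte-identical
summaries and images. The validation suite runs at deliberately moderate
sizes chosen to probe each property thoroughly while keeping a full run
interactive: 1,000 random profile instances and 1,000 random finder
fixtures against brute-force oracles, 500 random alignment pairs against
an independent DP implementation, the full 61×61 codon-pair grid against
pathway enumeration, 100 seeded search-recovery trials against 50 decoys
plus 200 random-peptide false-positive trials, and 2 × 100 simulation
replicates for estimator calibration.

## Known limitations

* Only AUG-initiated uORFs; no Kozak-context or reinitiation modelling.
* Frame-restricted peptide search will miss homology visible only in
  alternative frames of the transcript at large.
* BLAST bit-score/E-value numerics are emulated with published constants,
  not reproduced exactly.
* YN00 here uses equal pathway weights for multi-hit codons and F3x4
  frequencies; at high divergence or strong codon bias it will differ
  from maximum-likelihood estimates.
* The heatmap is a static PNG; there is no interactive viewer.
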