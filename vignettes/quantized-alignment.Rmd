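---
title: "Current-level quantized alignment: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Current-level quantized alignment: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalign)
```

## The model

A nanopore reads DNA through an ionic-current signal whose level at any
instant depends on the Q consecutive bases in and near the pore (Q = 6 for
R9.4 chemistry). The *Q-mer map* — one median current per possible 6-mer —
summarises this physics. Because the current levels of distinct Q-mers
overlap heavily, basecalling confuses current-similar Q-mers far more often
than chance, and two quite different nucleotide strings can be essentially
indistinguishable to the pore.

`quantalign` turns this into an alignment representation. A nucleotide
sequence of length n maps to the n − Q + 1 currents of its sliding Q-mers
(`current_sequence()`), which are hard-thresholded into a small alphabet
(`quantize_sequence()`; three levels by default, the *HQ3* code). No raw
signal is used anywhere: the only physics input is the Q-mer table. In the
quantized space, sequences the pore cannot distinguish become *identical*,
so edit distance there reflects what the instrument actually resolves.

Alignment is hybrid and two-step:

1. a coarse nucleotide alignment locates regions of interest (ROIs) on the
   reference;
2. each ROI is extended by `b = (1 − f + 0.25) n` (f the aligned fraction of
   the read, n the read length), the window and the read are quantized, and
   the quantized read *and its quantized reverse complement* are re-aligned
   to the window.

The reverse complement must be a separate query because complementation has
no image in symbol space — and it is exactly this double-orientation search
inside one window that lets inverted blocks align as opposite-strand split
segments of one read, the signature the SV extractor uses for inversions.

Both stages run on one alphabet-generic minimizer seed–chain–extend engine.
Anchors are exact minimizer matches; chains maximise anchor coverage minus a
gap cost `0.05 |Δt − Δq| + 0.5 log2(|Δt − Δq| + 1)`; chain gaps are closed
by banded dynamic programming and chain ends extended with a score-maximising
(x-drop-like) extension so chimeric tails soft-clip instead of forcing a bad
global alignment.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `Q` | 6 | bases | pore-model word length, fixed by the flow cell |
| `levels` | 3 | – | quantization alphabet size ("HQ3") |
| `k` (nucleotide) | 15 | symbols | minimizer length, stage 1 |
| `k` (quantized) | 18 | symbols | minimizer length, stage 2; the longer k compensates for the smaller alphabet's lower specificity |
| `w` | 10 | positions | minimizer window; ~2 seeds per w positions |
| `max_gap` | 5000 | bases | largest anchor gap chaining will bridge, which bounds the largest indel expressible inside one alignment |
| `band` | 64 | cells | initial half-width of banded DPs, doubled while a result cannot be certified exact |
| `min_chain_score` | 40 | – | unmapped threshold: roughly three consistent seeds |
| `refdist` | 500 | bases | maximum breakpoint score for an SV match |
| `pctsize` | 0.7 | – | minimum SV length similarity for a match (the standard benchmarking default) |

Quantizer thresholds are the equal-mass quantiles of the 4^Q model currents
(for three levels, the 1/3 and 2/3 lower empirical quantiles): the
maximum-entropy ternary code for the model at hand. The original method's
exact threshold values are not published; equal mass is this package's
documented choice, and `quantizer_config()` accepts any explicit thresholds.
A current exactly equal to a threshold falls in the lower bin — arbitrary,
fixed, tested.

## What the synthetic data emulates — and what it does not

`sim_config()` defines the study conditions used throughout the tests: a
200-kb i.i.d. genome at GC 0.5; 10 deletions, 10 insertions and 5 inversions
with lengths uniform on 50–2000 bases, rejection-placed at least 1 kb apart
(closer events produce truth intervals no matching convention resolves
cleanly); 20x coverage of log-normal reads (median 3 kb); and ~10% error
split 6% substitutions, 2% insertions, 2% deletions. The full-scale design
this miniaturises uses thousands of indels with lengths up to 10 kb and
reads with median 4.5 kb / mean 14 kb; the same knobs express it, the
desk scale simply keeps a complete run in minutes on one CPU.

The synthetic pore model is additive: each Q-mer's current is a
centre-weighted sum of per-base contributions plus a small idiosyncratic
term, with the four bases forming two current classes (A/T and C/G) whose
within-class contributions differ only slightly. Additivity and heavy
current overlap are what real pore tables show, and they are what makes
*confusable substitutions* exist at all: swapping a base for its
current-class partner shifts every overlapping window by the same small
amount, usually without crossing a quantization threshold. Substitution
errors in `simulate_reads()` pick, with probability `confusion_weight`
(default 0.8), the alternative base with the smallest total current
perturbation over all windows containing the position — the signal-induced
error bias — and a uniform alternative otherwise.

What passing tests on these data do **not** show: performance on real
basecaller error profiles (real confusions replace whole subsequences, not
independent bases, and include systematic homopolymer-length errors, which
are not modelled), on repetitive genomes (the i.i.d. genome has no VNTRs, the
hardest real substrate), or at whole-genome scale. The simulation
demonstrates the mechanism — quantization collapses signal-confusable errors
and the hybrid pipeline converts that into contiguous alignments and
recovered SVs — not field performance.

## Numerical choices and degenerate inputs

- **Exactness of banded edit distance.** A banded unit-cost alignment with
  band b is exact whenever its result is ≤ b (an optimal path with d edits
  never strays more than d cells off the diagonal), so bands double until
  that certificate holds. The oracle tests exploit this: banded results are
  compared against an independent full quadratic DP.
- **Affine gaps for CIGARs.** Unit-cost optimal paths scatter long indels
  through chance matches (a 1.5-kb deletion degrades into dozens of short
  runs), which destroys CIGAR-based SV evidence. Wherever a gap is SV-scale
  (length imbalance ≥ 50), base-level CIGARs come from a banded affine-gap
  (Gotoh) alignment with match 2, mismatch −4, gap open 16, extension 1; the
  high open cost keeps a long indel as one run unless ~9 consecutive chance
  matches interrupt it (probability ~4e-6 per position).
- **Chain splitting.** An inter-anchor gap whose edit cost far exceeds its
  length imbalance (excess > 0.3 of the balanced gap length, for gaps
  ≥ 200) is a foreign insert — typically an inverted block — not an indel;
  the chain splits there and each side becomes its own segment. The 0.3
  threshold separates noisy-but-true gaps (~0.1–0.2 excess at 10% error in
  either alphabet) from unrelated sequence (~0.4 in ternary space, ~0.5 in
  nucleotide space).
- **Extension scoring** (match 2, mismatch −6, gap −5, x-drop 100) is chosen
  so drift is clearly positive on 10%-error sequence and clearly negative on
  unrelated ternary sequence; with milder penalties, wide-band extensions
  walk straight across inverted blocks on chance matches.
- **Endpoint conventions.** Symbol interval `[a, b)` widens to nucleotides
  `[a, b + Q − 1)` when mapped back; terminal deletions left by that widening
  are trimmed off the re-derived CIGAR, and interval ends are polished by a
  short nucleotide-level extension, since quantized symbol ends are noisy.
- **Degenerate inputs.** Sequences shorter than Q (or k) are rejected or
  unmapped; non-ACGT characters must be split out first
  (`split_on_ambiguous()`), because Q-mer lookup is undefined on them;
  pore models with tied currents refuse threshold counts they cannot
  support; empty call sets give precision 0 with a warning.

## Design choices where the design was open

- **One ROI per step-1 placement, merged when extended windows overlap.**
  Extension by b routinely makes neighbouring secondary hits overlap;
  aligning each separately would duplicate alignments.
- **Fallback.** A read whose windows yield no quantized chain keeps its
  step-1 nucleotide alignment, flagged `stage = "fallback"` — the hybrid
  step never loses a read the coarse step mapped.
- **MAPQ** comes from quantized-stage chain competition:
  `clamp(round(40 (1 − s2/s1)) · min(1, anchors/10), 0, 60)`, 60 with no
  competitor. Only the consumer contract matters downstream (the
  well-aligned rule thresholds at > 20).
- **SV evidence aggregation.** Per read, nearby same-type CIGAR runs merge
  (long indels occasionally fragment); per cluster, evidence is aggregated
  one-read-one-vote before taking medians, so a read with fragmented runs
  cannot outvote clean spanning reads. Inversions take the *minority-strand*
  segment of a mixed-strand read: a forward read crossing an inversion is
  + with a − insert, a reverse-strand read is − with a + insert.
- **The matcher is a simplified Truvari**: same-type candidates within
  breakpoint score 500 and length similarity ≥ 0.7, assigned greedily by
  ascending breakpoint score. Genotypes are ignored throughout; none of the
  metrics use them.

## Limitations

The engine is a clear, testable re-implementation of the seed–chain–extend
idea, not a performance rival to production aligners; it is single-threaded
and keeps indexes in memory. The SV extractor is benchmarking plumbing with
a support threshold and median-based breakpoints, not a genotyping caller.
Quantization is hard (no per-Q-mer variance is used), ambiguous bases are
dropped rather than imputed, and duplications/translocations are out of
scope for the extractor. Real flow-cell tables can be loaded with
`load_qmer_model()`, but all shipped results use the synthetic additive
model described above.
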