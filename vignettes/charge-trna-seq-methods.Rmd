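---
title: "Measuring tRNA aminoacylation by charge tRNA-Seq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring tRNA aminoacylation by charge tRNA-Seq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tRNAcharge)
```

## The measurement

All mature tRNAs end in N-C-C-A, and the amino acid is esterified to the
terminal A. Periodate oxidation followed by amine-induced β-elimination
(the Whitfeld reaction) removes the 3'-terminal base of *deacylated* tRNA
only — the ester bond protects charged molecules. After sequencing, a
tRNA molecule that was charged reads out with a 3' `CCA` and an uncharged
one with `CC`. The aminoacylation charge of a tRNA species is therefore
estimated as

\[
\text{charge} = 100 \cdot \frac{n_{CCA}}{n_{CCA} + n_{CC}} .
\]

Charge uses raw read counts, not UMI-collapsed counts: it is a ratio
within a species, so molecule-level duplication cancels. Relative
expression (RPM) by contrast collapses reads with identical (sequence,
UMI) first, then normalizes counts to one million per sample. Reads whose
3' end is neither CCA nor CC (`other`) enter neither the charge numerator
nor the denominator but are kept for expression and modification
profiling.

### 3'-end classification

A read is called `CCA` when its final base aligns to the transcript's
final base, `CC` when it aligns to the penultimate base, and `other`
otherwise. Any 3' soft clip — even a single unaligned trailing base —
forces `other`: a read whose final base is unaligned gives no evidence
about the CCA/CC state, and a terminal mismatch is clipped by local
alignment anyway under the scoring used here. This is the one place where
the classification convention is ours; it is deliberately conservative.

## Alignment

Reads are aligned to every reference transcript with an exhaustive
Smith–Waterman dynamic program (no heuristic seeding — tRNAs are short,
similar, and heavily modified, so seed-based mappers lose exactly the
reads that matter). The primary scoring is match +1, mismatch −3, and a
score of 0 for a read base aligned to a masked reference position (`N`).
Gap costs follow BLAST-style `-G/-E` semantics: a gap of length $L$ costs
$6 + 3(L-1)$. A read is reported mapped when its best score reaches
`min_score` (default 15); a raw-score floor is used instead of an E-value
because it needs no composition model and is deterministic. All
transcripts tied at the best score are retained (up to three, flagged
beyond that), and uniqueness is tracked at three levels: transcript,
anticodon and amino acid. Transcript-level tables require a unique
transcript; anticodon ("codon-level") tables require only a unique
anticodon, and so on.

Determinism matters for reproducible misincorporation coordinates, so
ties inside the dynamic program are broken by a fixed rule: the end cell
with the smallest reference coordinate wins, and on the traceback a
diagonal step (mismatch) is preferred over a gap. Test fixtures built
from periodic sequences will therefore see alignments placed at the
leftmost equivalent position — a property, not a bug.

Misincorporation profiles are extracted from a *second* alignment of each
uniquely annotated read against its original, unmasked transcript under a
gentler scheme (match +1, mismatch −2, gap open 3, gap extend 2) so that
modification-driven mismatches stay inside the alignment instead of being
clipped. Per position the package reports UMI-collapsed coverage,
mismatch fraction, gap fraction (deletions at the position plus
insertions assigned to the 5'-adjacent position), and the RT-stop
percentage: the drop in coverage from position $p+1$ to $p$ — reverse
transcription runs 3'→5' — as a percentage of the transcript's maximum
coverage. The maximum-coverage denominator is our choice; a raw
"percentage drop" needs one, and maximum coverage proxies the number of
molecules that entered reverse transcription. Reads deleted at a position
still count as covering it, so the three fractions share one denominator.

## Reference masking

Base modifications cause systematic misincorporation during reverse
transcription. Against a plain reference these mismatches penalize the
true transcript's score, pushing reads toward the wrong member of a
similar family — often one with a different anticodon. The fix is to
convert positions with a high likelihood of mismatch to `N` (scoring 0)
so modifications stop distorting alignment. Masking is driven entirely by
the mismatch frequencies observed in the data; no external modification
catalog is consulted.

One masking iteration is: align → tally position-wise mismatch
frequencies → mask positions at or above `min_mut_freq` → share masks to
similar transcripts → apply. Frequencies are only trusted where a
transcript has at least 200 assigned reads and a position at least 100
covering reads. Only substitutions count toward masking; gaps are
reported separately but never trigger a mask. Frequencies are computed
against the retained original bases, so they stay defined at
already-masked coordinates across iterations. With `unique_anno = TRUE`
only uniquely annotated reads are counted; otherwise a read tied across
$k$ transcripts contributes $1/k$ to each — the fractional weighting is
our committed reading of the "float" counting variant, exposed as a
switch.

Mask *sharing* lets an abundant transcript donate its masked positions to
a highly similar but poorly covered transcript that likely carries the
same modifications: the pairwise alignment score of the two unmasked
sequences must reach `frac_max_score` times the larger of the two
self-alignment scores (this denominator bounds the fraction in [0, 1];
the alternative denominators are not well defined), the donor position
must map through that alignment to a position with the same nucleotide,
and the acceptor position must have fewer than 100 observations.

Masks accumulate monotonically across iterations — a masked position is
never unmasked — which is what makes the iteration converge to a fixed
point: annotations can change when the reference changes, but the mask
can only grow, and growth stops once frequencies stabilize.

The four tuning parameters (`unique_anno`, `min_mut_freq`,
`frac_max_score`, `iterations`) are chosen by grid search minimizing the
percentage of mapped reads assigned to tRNAs with multiple anticodons.
Minimizing multi-*transcript* assignment instead would reward masking only
one member of a similar family, handing truncated reads spurious unique
annotations; families of near-identical transcripts mostly share an
anticodon, which makes the anticodon objective robust. Ties are broken
toward fewer masked positions, then lexicographic parameter order. The
grid's candidate values are configuration input: sensible axes are
`unique_anno` ∈ {TRUE, FALSE}, `min_mut_freq` ∈ {0.1 … 0.5},
`frac_max_score` ∈ {0.8 … 1.0}, `iterations` ∈ {1, 2, 3}, and a
`min_mut_freq` above 1 serves as an explicit no-masking control.

## Preprocessing

The package consumes merged single-end reads laid out as
`[10 nt UMI][tRNA sequence][adapter barcode + splint context]`. Reads are
assigned to a barcode when a window near the 3' end matches the barcode
search sequence within Hamming distance 1 (the window spans the last
`length(search_seq) + 4` bases, taking the lowest-distance, most-3'
window, which tolerates small length variation left by upstream
trimming). Barcode sets must be pairwise separated by more than twice the
allowed distance or demultiplexing refuses to run. The matched substring
and everything 3' of it are trimmed; the 10 nt UMI is split off the 5'
end. Reads shorter than `min_len` after trimming are dropped (default 39
nt, the splint-ligation setting; use 25 for blunt-end libraries), and
samples above two million reads are downsampled to exactly that, under
the run seed. Base qualities are carried through but never used for
filtering. Counts are conserved: assigned + unassigned + ambiguous +
dropped equals the input.

### UMI occupancy QC

With $n$ reads and $k$ possible UMIs, the package evaluates the
occupancy expectation in both parameterizations:
$n\,[1-((n-1)/n)^k]$ (as published for this assay) and the standard
$k\,[1-((k-1)/k)^n]$. The two coincide at $n = k$ (at $n=k=4$ both equal
2.7344, which matches exhaustive enumeration of the $4^4$ assignments)
but diverge elsewhere, and the first exceeds the number of distinct UMIs
that are possible when $n \gg k$. The QC report prints the observed count
next to *both* expectations rather than choosing silently. The RT oligo's
UMI design — one random purine followed by nine random nucleotides —
spans $2 \cdot 4^9 = 524{,}288$ sequences.

## Titration model

Mixing intact RNA (A) with deacylated RNA (B) at $p$ percent intact
should give predictable charge, but a transcript's abundance can differ
between preparations (deacylation chemistry depletes fragile species).
With the concentration of transcript $i$ in B expressed as a factor $F_i$
of its concentration in A, the predicted charge of the mixture is

\[
T_i^{AB}(p) = \frac{p\,T_i^A + (100-p)\,T_i^B F_i}{p + (100-p)F_i},
\]

where $T_i^A$ and $T_i^B$ are replicate-mean charges of the pure
endpoints ($p = 100$ and $p = 0$), which are excluded from the fit.
$F_i$ is the only unknown; it is fitted by minimizing the sum of squared
differences between predicted and measured charge over the interior
mixing ratios with a bounded quasi-Newton optimizer (L-BFGS-B)
constrained to $[0.25, 4]$, multi-started from $F_0 \in \{0.5, 1, 2\}$
and polished with a golden-section/parabolic refinement so noiseless data
recovers $F$ to better than $10^{-6}$. When the endpoints are closer than
5 percentage points the curve is flat in $F$ and the fit returns `NA`
with an identifiability flag; estimates pinned at a bound are flagged
too. Residuals grouped by adapter barcode, with a bootstrap CI of each
mean, expose ligation bias. Fitting operates on transcript-level charge;
feeding codon-level tables works identically.

## Aminoacylation decay

Charge decays with first-order kinetics toward a small floor:

\[
N(t) = N_0 \left(\tfrac{1}{2}\right)^{t/t_{1/2}} + N_\infty ,
\]

with $N_\infty \in [0, 3.5]$ percent absorbing the residual CCA signal
after full deacylation, $N_0 \in [0, 100]$ and $t_{1/2} \in [1, 10^5]$
minutes. All timepoints and replicates are pooled into one SSE and
minimized with L-BFGS-B; because the surface has local minima in
$t_{1/2}$, the optimizer is multi-started from the log-spaced lattice
$t_{1/2} \in 10^{0..5}$. The default sampling grid is 0, 4, 8, 16, 32
minutes and 1, 2, 4, 8, 16, 40 hours. Fits with $t_{1/2}$ pinned at a
bound or $N_0$ near zero are flagged unidentifiable. Fitting is done per
anticodon group by default; transcript-level fitting is the same call on
a transcript-level table.

### Bootstrap confidence intervals, and why they are conservative

The 95% CI resamples $N = 1000$ synthetic time series: at every timepoint
one replicate is drawn uniformly at random (a switch shares the draw
across timepoints instead), the model is refitted from the point
estimate, and the 2.5/97.5 percentiles are reported. Note a structural
property of this design: each bootstrap series carries the measurement
noise of a *single* replicate series, while the point estimate pools all
replicates, so with $r$ replicates the bootstrap spread is roughly
$\sqrt{r}$ times the estimator's standard error. The resulting intervals
over-cover — simulation at the default design (4 replicates, σ = 1.5 pp)
shows essentially 100% coverage of the generating $t_{1/2}$ rather than
the nominal 95%. The intervals are honest upper bounds on uncertainty,
and the implementation reproduces the published procedure; narrower,
better-calibrated intervals would need a different resampling unit (e.g.
residual resampling), which is out of scope here.

## Synthetic data: what it does and does not emulate

Every stage is testable without downloads because `sim_reference()`,
`sim_reads()`, `sim_titration()` and `sim_decay()` generate inputs with
recorded ground truth, bit-reproducibly given a seed. `sim_reads()`
models the essentials of the assay: the CCA/CC split drawn from a
per-transcript charge, reverse transcription copying 3'→5' with
per-position substitution, deletion and stop probabilities, a UMI drawn
from its IUPAC pattern, and the barcode search sequence appended at the
3' end. It deliberately does *not* model sequencer base-call errors,
quality-score structure, PCR chimeras, or length-dependent ligation
efficiency — so green tests here demonstrate algorithmic correctness on
the assay's read structure, not robustness to every artifact of real
libraries. Real data additionally carries reference incompleteness
(absent isodecoders) that no simulation from the same reference can
expose.

Default study conditions used in the tests and the acceptance script:
20 transcripts with planted charges spanning 0.05–0.98 at 500 reads each
for charge recovery (binomial sampling error then predicts ≈95% of
estimates within two standard errors of truth); a seven-transcript
fixture with a two-site near-identical pair (one site hypermutated at 0.6
substitution probability, the ambiguity driver) plus ten singleton
modification sites at 0.5 for the masking search; six interior mixing
ratios × 4 replicates at σ = 1 pp for titration; the 11-point grid × 4
replicates at σ = 1.5 pp for decay, with 200 recovery simulations and 100
outer simulations × 1000 bootstrap draws for coverage. These sizes keep
the full suite in the minutes range on one CPU while leaving the binomial
and Monte-Carlo tolerances meaningful.

## Numerical and formatting choices

* Positions are 0-based internally, 1-based in every emitted table, and
  always counted on the transcript 5'→3'.
* Masked FASTA output writes `N` at masked positions; a TSV sidecar
  records the original base at each, so reading the pair reconstructs the
  reference exactly (round-trip identity, byte-stable across writes).
* Exact duplicate reference sequences collapse to one record under the
  lexicographically smallest id, with all ids kept as aliases; duplicate
  ids across files are fatal rather than silently renamed.
* GtRNAdb-style mature sequences may lack the post-transcriptional 3'
  CCA; it is appended at load time (with a warning) because every
  downstream charge call assumes it. tRNA-His's extra 5' G is not modeled;
  local alignment absorbs the overhang.
* The configuration file is YAML, one mapping per stage, unknown keys
  rejected. All randomness flows from the single `seed` entry; reruns are
  byte-identical.
* Insertions are assigned to the 5'-adjacent reference position in gap
  profiles; the alternative (3'-adjacent) is a coordinate convention with
  no downstream consequence beyond labeling.
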