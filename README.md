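# tRNAcharge

Processing and modeling for **charge tRNA-Seq**: estimating, per tRNA
species, what fraction of molecules carry their amino acid
(aminoacylation "charge"), alongside relative expression and
modification signatures, from barcoded, UMI-tagged sequencing reads.

The assay encodes charge in the last base of the read. Every mature tRNA
ends in N-C-C-A with the amino acid esterified to the terminal A; the
Whitfeld reaction (periodate oxidation + β-elimination) clips that
terminal base off *deacylated* molecules only. A charged molecule
therefore sequences with a 3' `CCA`, an uncharged one with `CC`, and

```
charge (%) = 100 · n_CCA / (n_CCA + n_CC)
```

computed on raw counts per transcript, anticodon, or amino acid.

What the package implements:

* **Preprocessing** — demultiplexing merged reads by 3' adapter barcode
  (Hamming distance ≤ 1, with a pairwise-separation guard), 5' UMI
  extraction, length filtering, seeded downsampling.
* **Alignment** — exhaustive Smith–Waterman of every read against every
  transcript (compiled; no heuristic seeding) under match +1 /
  mismatch −3 / gaps 6,3, with masked reference positions (`N`) scoring
  0; deterministic tie handling, up to three tied annotations, and
  CCA/CC/other 3'-end classification.
* **Reference masking** — positions with high misincorporation frequency
  (modification signatures) are converted to `N` so modifications stop
  misrouting reads between near-identical tRNAs; iterative, with mask
  sharing to similar low-coverage transcripts and a grid search over the
  four tuning parameters minimizing multi-anticodon read assignment.
* **Quantification** — charge tables, UMI-collapsed RPM tables
  (Σ = 10⁶ per sample), spike-in QC, and UMI occupancy QC against both
  occupancy expectations.
* **Modification signatures** — per-position mismatch, gap and RT-stop
  profiles from unmasked realignment (match +1 / mismatch −2 / gaps 3,2).
* **Titration model** — fits the per-transcript abundance correction
  factor `F ∈ [0.25, 4]` in
  `T(p) = (p·T_A + (100−p)·T_B·F) / (p + (100−p)·F)`
  by bounded quasi-Newton, with per-barcode error summaries.
* **Aminoacylation half-life** — fits first-order decay
  `N(t) = N0·(1/2)^(t/t½) + N∞` with bounds (N0 ∈ [0,100],
  t½ ∈ [1, 10⁵] min, N∞ ∈ [0, 3.5]) and bootstrap (N = 1000) confidence
  intervals.
* **Synthetic data** — seeded generators for references, reads (charge,
  misincorporation, RT stops, UMIs, barcodes), titration series and decay
  series, with ground-truth tables; `sim_study()` writes a complete
  miniature study.

See `vignettes/charge-trna-seq-methods.Rmd` for the models, parameter
semantics, and design choices.

## Worked example

Simulate a miniature study (8 transcripts × 3 barcodes, planted
per-transcript charges, a titration series with F = 1.5 and a decay
series with t½ = 120 min), then run the pipeline:

```r
library(tRNAcharge)

study <- "sim_study"; out <- "pipeline_out"
sim_study(study, seed = 42)

cfg <- load_config()
cfg$paths$reference        <- file.path(study, "reference.fasta")
cfg$paths$reads            <- file.path(study, "reads.fastq")
cfg$paths$sample_sheet     <- file.path(study, "samples.tsv")
cfg$paths$titration_design <- file.path(study, "titration_design.tsv")
cfg$paths$decay_design     <- file.path(study, "decay_design.tsv")
cfg$paths$out_dir          <- out
cfg$preprocess$min_len     <- 25L   # short synthetic transcripts
cfg$masking$iterations     <- 0L    # too few reads to earn a mask
run_pipeline(cfg)

read.table(file.path(out, "charge_transcript_sample1.tsv"),
           header = TRUE, sep = "\t")
```

```
     group_id n_cca n_cc charge_pct
1 Ala-CGC-3-1    33   27   55.00000
2 Arg-AGT-6-1    50   10   83.33333
3 Asp-AGA-5-1     7   53   11.66667
4 Cys-CTA-2-1    39   21   65.00000
...
```

The planted truths for those transcripts were 51.2%, 87.4%, 14.9% and
70.0% — each estimate sits within binomial sampling error of its truth
at 60 reads per transcript. The titration and decay fits land on their
generating parameters:

```
  transcript_id      F_i      sse at_bound identifiable
1    transcript 1.533517 29.54755    FALSE         TRUE       # truth F = 1.5

  group_id       N0   t_half    N_inf t_half_lo t_half_hi
1      all 94.54457 118.6744 1.827556  113.4528  124.5763     # truth t½ = 120
```

The same stages are callable individually (`demultiplex()`,
`align_all()`, `grid_search_masking()`, `charge_table()`,
`fit_titration()`, `fit_decay()`, …), and a thin command-line wrapper
ships at `inst/cli/trnacharge` (`simulate`, `run-all`, `mask`,
`titrate`, `halflife`).

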