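level_group <- function(annotations, level) {
  switch(level,
    transcript = annotations$transcript_ids,
    anticodon = annotations$anticodon,
    amino_acid = annotations$amino_acid,
    stop("unknown level: ", level,
         " (expected transcript, anticodon or amino_acid)"))
}

level_filter <- function(annotations, level) {
  switch(level,
    transcript = annotations$unique_transcript,
    anticodon = annotations$unique_anticodon,
    amino_acid = annotations$unique_amino_acid)
}

spike_in_ids <- function(ref) ref$transcripts$id[ref$transcripts$is_spike_in]

#' Aminoacylation charge table
#'
#' Charge per group is 100 * n_CCA / (n_CCA + n_CC) over raw (not
#' UMI-collapsed) read counts — charge is a ratio, so molecule-level
#' correction cancels. Reads must pass the level's uniqueness filter
#' (unique transcript at transcript level, unique anticodon at anticodon
#' level, unique amino acid at amino-acid level) and carry a CCA or CC end
#' call; `other` ends enter neither numerator nor denominator. Groups with
#' a zero denominator get `NA`. Spike-in transcripts are excluded (they are
#' controls, not biology; see [spike_in_qc()]).
#'
#' @param annotations [align_all()] output.
#' @param level "transcript", "anticodon" or "amino_acid".
#' @param ref The `masked_reference` (to identify spike-ins); optional.
#' @return Data frame: `group_id`, `n_cca`, `n_cc`, `charge_pct`.
#' @export
charge_table <- function(annotations, level = "transcript", ref = NULL) {
  keep <- annotations$mapped & level_filter(annotations, level) &
    annotations$end_class %in% c("CCA", "CC")
  ann <- annotations[keep, , drop = FALSE]
  if (!is.null(ref)) {
    spk <- spike_in_ids(ref)
    if (level == "transcript") ann <- ann[!(ann$transcript_ids %in% spk), ]
  }
  grp <- level_group(ann, level)
  cca <- tapply(ann$end_class == "CCA", grp, sum)
  cc <- tapply(ann$end_class == "CC", grp, sum)
  ids <- sort(unique(grp))
  n_cca <- as.integer(cca[ids]); n_cc <- as.integer(cc[ids])
  denom <- n_cca + n_cc
  data.frame(group_id = ids, n_cca = n_cca, n_cc = n_cc,
             charge_pct = ifelse(denom > 0, 100 * n_cca / denom, NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' UMI-collapse reads
#'
#' Reads with identical (sequence, UMI) within a sample are counted once:
#' they derive from the same molecule. Collapsing keys on the exact tRNA
#' read sequence plus the UMI, not on the annotation.
#'
#' @param reads Data frame with `seq` and `umi`.
#' @return The subset of reads with duplicate (seq, umi) pairs removed
#'   (first occurrence kept); idempotent.
#' @export
umi_collapse <- function(reads) {
  if (is.null(reads$umi)) stop("reads carry no 'umi' column")
  out <- reads[!duplicated(paste(reads$seq, reads$umi)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Relative expression (RPM) table
#'
#' Reads per million mapped reads after UMI collapsing: duplicate
#' (sequence, UMI) pairs count once, then counts per group at the chosen
#' level are scaled so they sum to 1e6 per sample. Spike-in transcripts are
#' excluded from the normalization total and from the table.
#'
#' @param annotations [align_all()] output.
#' @param reads The reads that were aligned (for `seq` and `umi`).
#' @param level "transcript", "anticodon" or "amino_acid".
#' @param ref Optional `masked_reference` for spike-in exclusion.
#' @return Data frame: `group_id`, `umi_collapsed_count`, `rpm`.
#' @export
rpm_table <- function(annotations, reads, level = "transcript", ref = NULL) {
  collapsed <- umi_collapse(reads)
  ann <- annotations[annotations$read_id %in% collapsed$read_id, ,
                     drop = FALSE]
  keep <- ann$mapped & level_filter(ann, level)
  ann <- ann[keep, , drop = FALSE]
  if (!is.null(ref)) {
    spk <- spike_in_ids(ref)
    drop_spk <- vapply(strsplit(ann$transcript_ids, ";"),
                       function(x) any(x %in% spk), logical(1))
    ann <- ann[!drop_spk, , drop = FALSE]
  }
  grp <- level_group(ann, level)
  cnt <- table(grp)
  ids <- sort(unique(grp))
  counts <- as.integer(cnt[ids])
  total <- sum(counts)
  data.frame(group_id = ids, umi_collapsed_count = counts,
             rpm = if (total > 0) 1e6 * counts / total else numeric(0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spike-in control QC
#'
#' CCA/CC counts and charge of the spike-in control transcripts (e.g. the
#' 50%-charge Lys control), reported separately from the biological tables.
#'
#' @param annotations [align_all()] output.
#' @param ref The `masked_reference`.
#' @return Data frame like [charge_table()] restricted to spike-ins.
#' @export
spike_in_qc <- function(annotations, ref) {
  spk <- spike_in_ids(ref)
  keep <- annotations$mapped & annotations$unique_transcript &
    annotations$transcript_ids %in% spk &
    annotations$end_class %in% c("CCA", "CC")
  ann <- annotations[keep, , drop = FALSE]
  cca <- tapply(ann$end_class == "CCA", ann$transcript_ids, sum)
  cc <- tapply(ann$end_class == "CC", ann$transcript_ids, sum)
  ids <- sort(unique(ann$transcript_ids))
  n_cca <- as.integer(cca[ids]); n_cc <- as.integer(cc[ids])
  data.frame(group_id = ids, n_cca = n_cca, n_cc = n_cc,
             charge_pct = ifelse(n_cca + n_cc > 0,
                                 100 * n_cca / (n_cca + n_cc), NA_real_),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expected number of unique UMIs
#'
#' `expected_unique_umis()` evaluates the published occupancy formula as
#' printed, E\[X\] = n \* (1 - ((n-1)/n)^k), with n the number of reads
#' and k the number of possible UMIs. Note that this swaps the
#' conventional roles of n and k relative to the standard occupancy
#' expectation E\[X\] = k \* (1 - ((k-1)/k)^n), provided as
#' `expected_unique_umis_standard()`; the two coincide at n = k. The QC
#' report computes both and leaves the choice to the reader.
#'
#' @param n Number of reads (>= 0).
#' @param k Number of possible UMI sequences (>= 1).
#' @return Expected number of distinct UMIs observed.
#' @export
expected_unique_umis <- function(n, k) {
  stopifnot(k >= 1)
  ifelse(n == 0, 0, n * (1 - ((n - 1) / n)^k))
}

#' @rdname expected_unique_umis
#' @export
expected_unique_umis_standard <- function(n, k) {
  stopifnot(k >= 1)
  ifelse(n == 0, 0, k * (1 - ((k - 1) / k)^n))
}

#' Size of a UMI design space
#'
#' Product over IUPAC pattern symbols of their alphabet sizes: N = 4,
#' R/Y/S/W/K/M = 2, fixed bases = 1. The RT-oligo design of one random
#' purine followed by nine random nucleotides ("RNNNNNNNNN") yields
#' 2 * 4^9 = 524,288 possible sequences.
#'
#' @param pattern IUPAC string, e.g. "RNNNNNNNNN".
#' @return Integer count of distinct sequences the pattern can produce.
#' @export
umi_space_size <- function(pattern) {
  sizes <- c(A = 1, C = 1, G = 1, T = 1, U = 1, R = 2, Y = 2, S = 2, W = 2,
             K = 2, M = 2, B = 3, D = 3, H = 3, V = 3, N = 4)
  syms <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(syms, names(sizes))
  if (length(bad) > 0L)
    stop("unknown pattern symbol(s): ", paste(unique(bad), collapse = ", "))
  prod(sizes[syms])
}

#' UMI occupancy QC
#'
#' Compares the observed number of distinct UMIs in a sample with the
#' expectation under both occupancy formulas (see
#' [expected_unique_umis()]).
#'
#' @param reads Data frame with a `umi` column.
#' @param umi_pattern IUPAC pattern of the UMI design (default
#'   "RNNNNNNNNN").
#' @return List: `n` reads, `k` possible UMIs, `observed_unique`,
#'   `expected_printed`, `expected_standard`.
#' @export
umi_qc <- function(reads, umi_pattern = "RNNNNNNNNN") {
  n <- nrow(reads)
  k <- umi_space_size(umi_pattern)
  list(n = n, k = k, observed_unique = length(unique(reads$umi)),
       expected_printed = expected_unique_umis(n, k),
       expected_standard = expected_unique_umis_standard(n, k))
}
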