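#' Realign a read against its unmasked transcript
#'
#' Misincorporation signals are extracted from a second Smith-Waterman
#' alignment of each uniquely annotated read against the original
#' (unmasked) transcript sequence, under a gentler scheme (match +1,
#' mismatch -2, gap open 3, gap extend 2) so that modification-driven
#' mismatches are retained inside the alignment instead of being clipped.
#'
#' @param read_seq Read sequence.
#' @param transcript_seq Original transcript sequence (no 'N's).
#' @param scheme Scoring scheme; defaults to [realign_scheme()].
#' @return A [local_align()] result.
#' @export
realign_unmasked <- function(read_seq, transcript_seq,
                             scheme = realign_scheme()) {
  local_align(read_seq, transcript_seq, scheme)
}

#' Per-position misincorporation profile
#'
#' For one transcript, computes from its uniquely annotated, UMI-collapsed
#' reads: span-based coverage, the fraction of covering reads with a
#' mismatch at each position, the fraction with a gap (deletions at the
#' position, plus insertions assigned to the 5'-adjacent position), and the
#' RT-stop percentage — the drop in coverage from position p+1 to p
#' (coverage runs 3' to 5' because reverse transcription primes at the 3'
#' adapter), as a percentage of the transcript's maximum coverage, clipped
#' at zero. A read deleted at p still counts as covering p, so the three
#' fractions share one denominator.
#'
#' @param reads Data frame with `seq` and `umi` of reads uniquely annotated
#'   to this transcript.
#' @param transcript_seq Original transcript sequence.
#' @param transcript_id Label carried into the output.
#' @param scheme Realignment scoring scheme.
#' @param collapse UMI-collapse the reads first (default TRUE).
#' @return Data frame of class `mod_profile`: `transcript_id`,
#'   `position_1based`, `ref_base`, `coverage`, `mismatch_fraction`,
#'   `gap_fraction`, `rt_stop_pct`; attribute `empty` flags a transcript
#'   with zero covering reads.
#' @export
mod_profile <- function(reads, transcript_seq, transcript_id = "transcript",
                        scheme = realign_scheme(), collapse = TRUE) {
  L <- nchar(transcript_seq)
  cov <- numeric(L); mm <- numeric(L); gap <- numeric(L)
  if (collapse && !is.null(reads$umi)) reads <- umi_collapse(reads)
  for (i in seq_len(nrow(reads))) {
    a <- realign_unmasked(reads$seq[i], transcript_seq, scheme)
    if (a$ref_end <= a$ref_start) next
    span <- (a$ref_start + 1L):a$ref_end
    cov[span] <- cov[span] + 1
    if (length(a$mismatch_pos) > 0L)
      mm[a$mismatch_pos + 1L] <- mm[a$mismatch_pos + 1L] + 1
    gpos <- unique(c(a$deletion_pos, a$insertion_pos))
    if (length(gpos) > 0L) gap[gpos + 1L] <- gap[gpos + 1L] + 1
  }
  max_cov <- max(cov)
  drop <- c(cov[-1L], 0) - cov  # coverage(p+1) - coverage(p), 3'->5' falloff
  drop[L] <- 0                  # no p+1 beyond the 3' terminus
  out <- data.frame(
    transcript_id = transcript_id, position_1based = seq_len(L),
    ref_base = strsplit(transcript_seq, "")[[1]], coverage = cov,
    mismatch_fraction = ifelse(cov > 0, mm / cov, NA_real_),
    gap_fraction = ifelse(cov > 0, gap / cov, NA_real_),
    rt_stop_pct = if (max_cov > 0) pmax(0, 100 * drop / max_cov) else
      rep(NA_real_, L),
    stringsAsFactors = FALSE)
  attr(out, "empty") <- max_cov == 0
  class(out) <- c("mod_profile", "data.frame")
  out
}

#' Misincorporation profiles for all transcripts of a sample
#'
#' @param annotations [align_all()] output.
#' @param reads The aligned reads (`read_id`, `seq`, `umi`).
#' @param ref The `masked_reference`.
#' @param scheme Realignment scheme.
#' @param min_reads Transcripts with fewer uniquely annotated reads are
#'   skipped (default 1).
#' @return Data frame stacking one [mod_profile()] per transcript.
#' @export
mod_profiles <- function(annotations, reads, ref, scheme = realign_scheme(),
                         min_reads = 1L) {
  tr <- ref$transcripts
  keep <- annotations$mapped & annotations$unique_transcript
  ann <- annotations[keep, , drop = FALSE]
  out <- list()
  for (id in sort(unique(ann$transcript_ids))) {
    rid <- ann$read_id[ann$transcript_ids == id]
    if (length(rid) < min_reads) next
    sub <- reads[reads$read_id %in% rid, , drop = FALSE]
    out[[id]] <- mod_profile(sub, tr$seq[match(id, tr$id)], id, scheme)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Compare two misincorporation profiles
#'
#' Position-aligned differences (a - b) of mismatch fraction, gap fraction
#' and RT-stop percentage, e.g. between samples processed with and without
#' periodate oxidation. Positions below the coverage floor in either
#' profile get `NA` deltas.
#'
#' @param a,b [mod_profile()] outputs for the same transcript.
#' @param min_coverage Coverage floor in both profiles (default 50).
#' @return Data frame: `position_1based`, `ref_base`,
#'   `d_mismatch_fraction`, `d_gap_fraction`, `d_rt_stop_pct`.
#' @export
compare_profiles <- function(a, b, min_coverage = 50L) {
  if (nrow(a) != nrow(b))
    stop("profiles have different lengths; same transcript required")
  ok <- a$coverage >= min_coverage & b$coverage >= min_coverage
  data.frame(
    position_1based = a$position_1based, ref_base = a$ref_base,
    d_mismatch_fraction = ifelse(ok, a$mismatch_fraction -
                                   b$mismatch_fraction, NA_real_),
    d_gap_fraction = ifelse(ok, a$gap_fraction - b$gap_fraction, NA_real_),
    d_rt_stop_pct = ifelse(ok, a$rt_stop_pct - b$rt_stop_pct, NA_real_),
    stringsAsFactors = FALSE)
}
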