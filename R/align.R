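#' Alignment scoring scheme
#'
#' The primary scheme scores match +1, mismatch -3, alignment to a masked
#' reference position (N) 0, with affine gap costs of 6 for the first gapped
#' base and 3 for each additional base (BLAST-style `-G 6 -E 3` semantics).
#' Reads whose best score falls below `min_score` are reported unmapped; a
#' raw-score floor replaces an E-value filter since it is deterministic and
#' needs no composition model.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score (<= 0).
#' @param n_score Score for a query base aligned to a masked 'N' position.
#' @param gap_open Cost of the first gapped base (positive penalty).
#' @param gap_extend Cost of each additional gapped base (positive penalty).
#' @param min_score Minimum best score for a read to count as mapped.
#' @return List of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1L, mismatch = -3L, n_score = 0L,
                           gap_open = 6L, gap_extend = 3L, min_score = 15L) {
  stopifnot(match > 0, mismatch <= 0, gap_open >= 0, gap_extend >= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 n_score = as.integer(n_score),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 min_score = as.integer(min_score)),
            class = "scoring_scheme")
}

#' Scheme used for unmasked realignment in misincorporation profiling
#' (match +1, mismatch -2, gap open 3, gap extend 2).
#' @rdname scoring_scheme
#' @export
realign_scheme <- function() {
  scoring_scheme(match = 1L, mismatch = -2L, n_score = 0L, gap_open = 3L,
                 gap_extend = 2L, min_score = 0L)
}

#' Optimal local alignment of one read against one reference sequence
#'
#' Exhaustive Smith-Waterman dynamic programming under affine gaps: the
#' guaranteed best local alignment, no heuristic seeding. A query base
#' aligned to a masked position ('N' in `ref`) contributes `n_score`. Among
#' co-optimal alignments the traceback is deterministic: the end cell with
#' the smallest reference coordinate is chosen and diagonal moves (mismatch)
#' are preferred over gaps.
#'
#' @param query Read sequence (A/C/G/T/N, 5'->3').
#' @param ref Reference sequence, possibly containing masked 'N' positions.
#' @param scheme A [scoring_scheme()].
#' @param ref_orig Optional original (unmasked) reference of equal length;
#'   match/mismatch calls in the reported path are made against it so that
#'   mismatch positions remain defined at masked coordinates. Defaults to
#'   `ref`.
#' @return List: `score`, `ref_start`/`ref_end` and `read_start`/`read_end`
#'   (half-open, 0-based), `mismatch_pos`, `deletion_pos`, `insertion_pos`
#'   (0-based reference coordinates; insertions are assigned to the
#'   5'-adjacent reference position), and `path` (one char per column:
#'   M match, X mismatch, D deletion, I insertion).
#' @export
local_align <- function(query, ref, scheme = scoring_scheme(),
                        ref_orig = NULL) {
  if (!nzchar(query) || !nzchar(ref)) stop("empty query or reference")
  if (is.null(ref_orig)) ref_orig <- ref
  .sw_align_full(query, ref, ref_orig, scheme$match, scheme$mismatch,
                 scheme$n_score, scheme$gap_open, scheme$gap_extend)
}

#' Align all reads against all reference transcripts
#'
#' Full all-against-all local alignment: every read is scored against every
#' transcript (masked sequences), the best score is kept, and all
#' transcripts tied at that score are collected. If more than three
#' transcripts tie, the read keeps the first three ids after a
#' deterministic lexicographic sort and is flagged `overflow_ties`. Reads
#' with best score below `scheme$min_score` are unmapped. Uniqueness flags
#' (`unique_transcript`, `unique_anticodon`, `unique_amino_acid`) are
#' computed from the retained ids, and the 3' end class (CCA/CC/other) from
#' the alignment to the first retained transcript.
#'
#' @param reads Data frame with `read_id`, `seq` (and whatever else —
#'   carried through by `read_id` joins downstream).
#' @param ref A `masked_reference`.
#' @param scheme A [scoring_scheme()].
#' @param keep_alignments Keep per-transcript alignment detail for the tied
#'   transcripts (needed by the masking stage); stored in attribute
#'   `alignments`.
#' @return Data frame with one row per read: `read_id`, `mapped`, `score`,
#'   `transcript_ids` (semicolon-joined), `n_tied`, `overflow_ties`,
#'   uniqueness flags, `amino_acid`, `anticodon` (of the retained set when
#'   unique, else NA), `ref_start`/`ref_end`/`read_start`/`read_end`
#'   (0-based half-open, first transcript), `end_class`.
#' @export
align_all <- function(reads, ref, scheme = scoring_scheme(),
                      keep_alignments = TRUE) {
  stopifnot(inherits(ref, "masked_reference"))
  tr <- ref$transcripts
  if (nrow(tr) == 0L) stop("empty reference")
  mseqs <- masked_sequences(ref)
  n <- nrow(reads)
  res <- vector("list", n)
  alns <- if (keep_alignments) vector("list", n) else NULL
  for (i in seq_len(n)) {
    q <- reads$seq[i]
    scores <- .sw_score_multi(q, unname(mseqs), scheme$match, scheme$mismatch,
                              scheme$n_score, scheme$gap_open,
                              scheme$gap_extend)
    best <- max(scores)
    if (best < scheme$min_score) {
      res[[i]] <- data.frame(
        read_id = reads$read_id[i], mapped = FALSE, score = best,
        transcript_ids = NA_character_, n_tied = 0L, overflow_ties = FALSE,
        unique_transcript = FALSE, unique_anticodon = FALSE,
        unique_amino_acid = FALSE, amino_acid = NA_character_,
        anticodon = NA_character_, ref_start = NA_integer_,
        ref_end = NA_integer_, read_start = NA_integer_,
        read_end = NA_integer_, end_class = NA_character_,
        stringsAsFactors = FALSE)
      next
    }
    tied <- sort(tr$id[scores == best])  # deterministic lexicographic sort
    overflow <- length(tied) > 3L
    kept <- utils::head(tied, 3L)
    rows <- match(kept, tr$id)
    acs <- tr$anticodon[rows]
    aas <- tr$amino_acid[rows]
    uniq_tr <- length(kept) == 1L && !overflow
    uniq_ac <- !anyNA(acs) && length(unique(acs)) == 1L && !overflow
    uniq_aa <- !anyNA(aas) && length(unique(aas)) == 1L && !overflow
    details <- lapply(rows, function(r)
      c(list(transcript_id = tr$id[r]),
        local_align(q, mseqs[[tr$id[r]]], scheme, ref_orig = tr$seq[r])))
    a1 <- details[[1L]]
    res[[i]] <- data.frame(
      read_id = reads$read_id[i], mapped = TRUE, score = best,
      transcript_ids = paste(kept, collapse = ";"), n_tied = length(tied),
      overflow_ties = overflow, unique_transcript = uniq_tr,
      unique_anticodon = uniq_ac, unique_amino_acid = uniq_aa,
      amino_acid = if (uniq_aa) aas[1L] else NA_character_,
      anticodon = if (uniq_ac) acs[1L] else NA_character_,
      ref_start = a1$ref_start, ref_end = a1$ref_end,
      read_start = a1$read_start, read_end = a1$read_end,
      end_class = classify_end(a1, nchar(tr$seq[rows[1L]]), nchar(q)),
      stringsAsFactors = FALSE)
    if (keep_alignments) alns[[i]] <- details
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (keep_alignments) {
    names(alns) <- reads$read_id
    attr(out, "alignments") <- alns
  }
  out
}

#' Classify the 3' end of an aligned read
#'
#' A read is called `CCA` when its final base aligns to the transcript's
#' final base (the terminal A of the 3' CCA), `CC` when its final base
#' aligns to the penultimate base (the second C), and `other` otherwise —
#' in particular when the read's 3' end is soft-clipped (its final base is
#' unaligned) or the alignment stops short of the CC. Charge is the
#' fraction of CCA calls among CCA + CC calls; `other` reads enter neither
#' the numerator nor the denominator but are retained for expression and
#' modification profiling.
#'
#' @param aln A [local_align()] result.
#' @param ref_len Transcript length.
#' @param read_len Read length.
#' @return One of "CCA", "CC", "other".
#' @export
classify_end <- function(aln, ref_len, read_len) {
  if (aln$read_end != read_len) return("other")  # 3' soft clip
  if (aln$ref_end == ref_len) return("CCA")
  if (aln$ref_end == ref_len - 1L) return("CC")
  "other"
}
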