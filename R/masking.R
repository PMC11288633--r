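#' Masking parameters
#'
#' The four tuning parameters controlling reference masking, plus the two
#' fixed eligibility floors: a transcript needs at least
#' `min_transcript_obs` assigned reads and a position at least
#' `min_pos_obs` covering reads before its mismatch frequency is trusted.
#'
#' @param unique_anno Count only reads with a unique transcript annotation
#'   when accumulating mismatch frequencies; when `FALSE`, multi-annotated
#'   reads contribute fractionally (1/k to each of the k retained
#'   transcripts).
#' @param min_mut_freq Minimum mismatch frequency to trigger masking.
#' @param frac_max_score Minimum fraction of the maximum alignment score
#'   between two reference sequences required to share a mask from one
#'   transcript to another; the denominator is the larger of the two
#'   self-alignment scores, bounding the fraction in \[0, 1\].
#' @param iterations Number of masking iterations (align, measure, mask).
#' @param min_transcript_obs Transcript observation floor (default 200).
#' @param min_pos_obs Position observation floor (default 100).
#' @return List of class `masking_params`.
#' @export
masking_params <- function(unique_anno = TRUE, min_mut_freq = 0.3,
                           frac_max_score = 0.9, iterations = 1L,
                           min_transcript_obs = 200L, min_pos_obs = 100L) {
  stopifnot(min_mut_freq >= 0, frac_max_score >= 0, frac_max_score <= 1,
            iterations >= 0L, min_transcript_obs >= 0L, min_pos_obs >= 0L)
  structure(list(unique_anno = isTRUE(unique_anno),
                 min_mut_freq = min_mut_freq,
                 frac_max_score = frac_max_score,
                 iterations = as.integer(iterations),
                 min_transcript_obs = as.integer(min_transcript_obs),
                 min_pos_obs = as.integer(min_pos_obs)),
            class = "masking_params")
}

#' Position-wise mismatch frequencies
#'
#' Accumulates, per (transcript, position), the weighted number of covering
#' reads and of reads whose base mismatches the original reference base
#' (substitutions only; gaps are tallied separately by the profiling stage
#' and never trigger masking). Coverage is span-based. Mismatches are
#' evaluated against the retained original bases, so frequencies stay
#' defined at already-masked coordinates across iterations.
#'
#' @param annotations [align_all()] output with alignment details attached.
#' @param ref The `masked_reference` the annotations were computed on.
#' @param unique_anno If `TRUE`, only reads with `unique_transcript` count
#'   (weight 1); otherwise every mapped read contributes 1/k to each of its
#'   k retained transcripts.
#' @param min_transcript_obs,min_pos_obs Eligibility floors; positions
#'   below either floor have `eligible = FALSE` and an `NA` fraction.
#' @return Data frame: `transcript_id`, `position` (0-based),
#'   `position_1based`, `ref_base`, `observations`, `mismatches`,
#'   `mismatch_fraction`, `eligible`.
#' @export
mismatch_frequencies <- function(annotations, ref, unique_anno = TRUE,
                                 min_transcript_obs = 200L,
                                 min_pos_obs = 100L) {
  alns <- attr(annotations, "alignments")
  if (is.null(alns))
    stop("annotations lack alignment details; rerun align_all with ",
         "keep_alignments = TRUE")
  tr <- ref$transcripts
  lens <- setNames(nchar(tr$seq), tr$id)
  cov <- lapply(lens, numeric)
  mm <- lapply(lens, numeric)
  tobs <- setNames(numeric(nrow(tr)), tr$id)
  for (i in seq_len(nrow(annotations))) {
    if (!annotations$mapped[i]) next
    if (unique_anno && !annotations$unique_transcript[i]) next
    details <- alns[[annotations$read_id[i]]]
    w <- 1 / length(details)
    for (d in details) {
      id <- d$transcript_id
      tobs[[id]] <- tobs[[id]] + w
      if (d$ref_end > d$ref_start) {
        span <- (d$ref_start + 1L):d$ref_end
        cov[[id]][span] <- cov[[id]][span] + w
      }
      if (length(d$mismatch_pos) > 0L)
        mm[[id]][d$mismatch_pos + 1L] <- mm[[id]][d$mismatch_pos + 1L] + w
    }
  }
  rows <- lapply(tr$id, function(id) {
    L <- lens[[id]]
    data.frame(transcript_id = id, position = 0:(L - 1L),
               position_1based = 1:L,
               ref_base = strsplit(tr$seq[match(id, tr$id)], "")[[1]],
               observations = cov[[id]], mismatches = mm[[id]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  t_ok <- tobs[out$transcript_id] >= min_transcript_obs
  p_ok <- out$observations >= min_pos_obs
  out$eligible <- unname(t_ok & p_ok)
  out$mismatch_fraction <- ifelse(out$eligible,
                                  out$mismatches / out$observations, NA_real_)
  rownames(out) <- NULL
  out
}

#' Positions to mask from a frequency table
#'
#' @param freqs A [mismatch_frequencies()] table.
#' @param min_mut_freq Minimum mismatch frequency to trigger masking.
#' @return Data frame `transcript_id`, `position` (0-based) of exactly the
#'   eligible positions at or above the threshold.
#' @export
build_mask <- function(freqs, min_mut_freq) {
  sel <- freqs$eligible & !is.na(freqs$mismatch_fraction) &
    freqs$mismatch_fraction >= min_mut_freq
  out <- freqs[sel, c("transcript_id", "position")]
  rownames(out) <- NULL
  out
}

#' Share masked positions between similar transcripts
#'
#' An abundant transcript donates its masked positions to highly similar
#' transcripts that lack the coverage to earn their own mask (they likely
#' carry the same modifications). A donor position propagates to an
#' acceptor transcript when (1) the pairwise alignment score of the two
#' unmasked sequences is at least `frac_max_score` times the larger of
#' their self-alignment scores, (2) the donor position maps through that
#' pairwise alignment to an acceptor position with the same nucleotide, and
#' (3) the acceptor position has fewer than `min_pos_obs` observations.
#'
#' @param mask Data frame `transcript_id`, `position` (the direct mask).
#' @param ref A `masked_reference` (original sequences are used).
#' @param freqs [mismatch_frequencies()] table (for acceptor observations).
#' @param frac_max_score Similarity threshold in \[0, 1\].
#' @param min_pos_obs Acceptor-position observation ceiling (default 100).
#' @param scheme Scoring scheme for the pairwise transcript alignments.
#' @return The expanded mask (superset of the input), with a `source`
#'   column: "direct" or "shared".
#' @export
share_mask <- function(mask, ref, freqs, frac_max_score,
                       min_pos_obs = 100L, scheme = scoring_scheme()) {
  tr <- ref$transcripts
  out <- if (NROW(mask) > 0L)
    data.frame(mask[, c("transcript_id", "position")], source = "direct",
               stringsAsFactors = FALSE)
  else
    data.frame(transcript_id = character(), position = integer(),
               source = character(), stringsAsFactors = FALSE)
  donors <- unique(out$transcript_id)
  if (length(donors) == 0L || nrow(tr) < 2L) return(out)
  obs <- setNames(freqs$observations,
                  paste(freqs$transcript_id, freqs$position))
  self_score <- scheme$match * nchar(tr$seq)
  for (don in donors) {
    di <- match(don, tr$id)
    dpos <- out$position[out$transcript_id == don & out$source == "direct"]
    for (ai in seq_len(nrow(tr))) {
      if (ai == di) next
      acc <- tr$id[ai]
      ceiling_score <- max(self_score[di], self_score[ai])
      pair <- local_align(tr$seq[di], tr$seq[ai], scheme)
      if (pair$score < frac_max_score * ceiling_score) next
      # map donor (query) coordinates to acceptor (ref) coordinates
      map <- rep(NA_integer_, nchar(tr$seq[di]))
      qi <- pair$read_start; rj <- pair$ref_start
      for (op in strsplit(pair$path, "")[[1]]) {
        if (op == "M" || op == "X") {
          map[qi + 1L] <- rj
          qi <- qi + 1L; rj <- rj + 1L
        } else if (op == "I") qi <- qi + 1L
        else rj <- rj + 1L  # "D"
      }
      for (p in dpos) {
        q <- map[p + 1L]
        if (is.na(q)) next
        if (substring(tr$seq[di], p + 1L, p + 1L) !=
            substring(tr$seq[ai], q + 1L, q + 1L)) next
        a_obs <- obs[paste(acc, q)]
        if (is.na(a_obs)) a_obs <- 0
        if (a_obs >= min_pos_obs) next
        out <- rbind(out, data.frame(transcript_id = acc, position = q,
                                     source = "shared",
                                     stringsAsFactors = FALSE))
      }
    }
  }
  out <- out[!duplicated(out[, c("transcript_id", "position")]), ]
  rownames(out) <- NULL
  out
}

#' Iterative reference masking
#'
#' Runs `iterations` rounds of: align all reads to the current (masked)
#' reference, measure position-wise mismatch frequencies, build the direct
#' mask, share it to similar low-coverage transcripts, and apply it. Masks
#' accumulate monotonically — a masked position is never unmasked — so the
#' procedure converges to a fixed point once the mask stops growing.
#'
#' @param reads Read data frame (`read_id`, `seq`).
#' @param ref A `masked_reference` (typically unmasked).
#' @param params A [masking_params()].
#' @param scheme Alignment scoring scheme.
#' @return The masked reference, with attribute `history`: per-iteration
#'   data frame of cumulative masked-position counts.
#' @export
iterate_masking <- function(reads, ref, params = masking_params(),
                            scheme = scoring_scheme()) {
  stopifnot(inherits(params, "masking_params"))
  history <- data.frame(iteration = integer(), n_masked = integer())
  if (params$iterations > 0L) for (it in seq_len(params$iterations)) {
    ann <- align_all(reads, ref, scheme, keep_alignments = TRUE)
    freqs <- mismatch_frequencies(ann, ref, params$unique_anno,
                                  params$min_transcript_obs,
                                  params$min_pos_obs)
    mask <- build_mask(freqs, params$min_mut_freq)
    mask <- share_mask(mask, ref, freqs, params$frac_max_score,
                       params$min_pos_obs, scheme)
    ref <- apply_mask(ref, mask)
    ref$iteration <- ref$iteration + 1L
    history <- rbind(history,
                     data.frame(iteration = ref$iteration,
                                n_masked = n_masked(ref)))
    attr(ref, "last_freqs") <- freqs
    attr(ref, "last_mask") <- mask
  }
  attr(ref, "history") <- history
  ref
}

#' Percentage of mapped reads without a unique anticodon
#'
#' The grid-search objective: reads assigned to tRNAs with multiple
#' anticodons, as a percentage of mapped reads.
#'
#' @param annotations [align_all()] output.
#' @return Percentage in \[0, 100\] (NaN when nothing maps).
#' @export
multi_anticodon_pct <- function(annotations) {
  mapped <- annotations$mapped
  100 * sum(mapped & !annotations$unique_anticodon) / sum(mapped)
}

#' Grid search over masking parameters
#'
#' Evaluates every combination in the grid: masks the reference under the
#' candidate parameters, realigns, and scores the percentage of mapped
#' reads assigned to tRNAs with multiple anticodons (minimized).
#' Minimizing multi-transcript assignment instead would reward masking only
#' one member of a highly similar family, so truncated reads gain spurious
#' unique annotations; families of similar transcripts mostly share an
#' anticodon, which makes the anticodon-level objective robust. Ties are
#' broken by fewest masked positions, then by lexicographic parameter
#' order.
#'
#' @param reads Read data frame.
#' @param ref Unmasked `masked_reference`.
#' @param grid Named list of candidate values for any of `unique_anno`,
#'   `min_mut_freq`, `frac_max_score`, `iterations`.
#' @param scheme Alignment scoring scheme.
#' @param min_transcript_obs,min_pos_obs Eligibility floors.
#' @return List: `best` ([masking_params()]), `table` (one row per
#'   combination: parameters, `objective_pct`, `n_masked`, `mapped_pct`),
#'   `ref` (reference masked under the best parameters).
#' @export
grid_search_masking <- function(reads, ref, grid, scheme = scoring_scheme(),
                                min_transcript_obs = 200L,
                                min_pos_obs = 100L) {
  if (length(grid) == 0L || any(lengths(grid) == 0L))
    stop("empty masking parameter grid")
  defaults <- list(unique_anno = TRUE, min_mut_freq = 0.3,
                   frac_max_score = 0.9, iterations = 1L)
  unknown <- setdiff(names(grid), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown grid parameter(s): ", paste(unknown, collapse = ", "))
  axes <- modifyList(defaults, grid)
  combos <- expand.grid(axes, stringsAsFactors = FALSE)
  combos <- combos[do.call(order, combos), , drop = FALSE]  # lexicographic
  rows <- vector("list", nrow(combos))
  refs <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    p <- masking_params(unique_anno = combos$unique_anno[i],
                        min_mut_freq = combos$min_mut_freq[i],
                        frac_max_score = combos$frac_max_score[i],
                        iterations = combos$iterations[i],
                        min_transcript_obs = min_transcript_obs,
                        min_pos_obs = min_pos_obs)
    mref <- iterate_masking(reads, ref, p, scheme)
    ann <- align_all(reads, mref, scheme, keep_alignments = FALSE)
    rows[[i]] <- data.frame(combos[i, , drop = FALSE],
                            objective_pct = multi_anticodon_pct(ann),
                            n_masked = n_masked(mref),
                            mapped_pct = 100 * mean(ann$mapped),
                            stringsAsFactors = FALSE)
    refs[[i]] <- mref
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  best_i <- order(tab$objective_pct, tab$n_masked)[1L]
  best <- masking_params(unique_anno = tab$unique_anno[best_i],
                         min_mut_freq = tab$min_mut_freq[best_i],
                         frac_max_score = tab$frac_max_score[best_i],
                         iterations = tab$iterations[best_i],
                         min_transcript_obs = min_transcript_obs,
                         min_pos_obs = min_pos_obs)
  list(best = best, table = tab, ref = refs[[best_i]])
}
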