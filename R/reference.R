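#' Load a tRNA transcript reference
#'
#' Reads mature tRNA transcript sequences from FASTA, parses amino-acid and
#' anticodon annotations from GtRNAdb-style names
#' (`<AminoAcid>-<Anticodon>-<family>-<copy>`), collapses exact duplicate
#' sequences, appends optional spike-in control sequences, and normalizes
#' every sequence to end in the universal 3' CCA. Genome-encoded (GtRNAdb)
#' mature sequences may lack the CCA tail that is added post-
#' transcriptionally; since reads derive from mature tRNA and charge calling
#' rests on the terminal CCA/CC distinction, a missing CCA is appended at
#' load time (with a warning naming the records).
#'
#' @param fasta_path Path to a multi-record FASTA of tRNA transcripts.
#' @param spike_in_fasta Optional FASTA of spike-in control sequences,
#'   appended after deduplication; annotation parsing is not required for
#'   spike-ins.
#' @return A `masked_reference` object with an empty mask: a list with
#'   `transcripts` (data frame: `id`, `seq`, `amino_acid`, `anticodon`,
#'   `is_spike_in`, `is_mito`, `aliases`), `mask` (named list of 0-based
#'   masked position vectors) and `iteration` (masking rounds applied, 0).
#' @export
load_reference <- function(fasta_path, spike_in_fasta = NULL) {
  main <- read_fasta_records(fasta_path)
  if (nrow(main) == 0L) stop("empty reference FASTA: ", fasta_path)
  main <- parse_trna_headers(main, spike_in = FALSE)
  main <- dedup_transcripts(main)
  if (!is.null(spike_in_fasta)) {
    spk <- read_fasta_records(spike_in_fasta)
    spk <- parse_trna_headers(spk, spike_in = TRUE)
    spk$aliases <- spk$id
    clash <- intersect(spk$id, main$id)
    if (length(clash) > 0L)
      stop("duplicate transcript id(s) across files: ",
           paste(clash, collapse = ", "))
    main <- rbind(main, spk)
  }
  main <- normalize_cca(main)
  rownames(main) <- NULL
  structure(
    list(transcripts = main,
         mask = setNames(vector("list", nrow(main)), main$id),
         iteration = 0L),
    class = "masked_reference")
}

read_fasta_records <- function(path) {
  if (!file.exists(path)) stop("FASTA not found: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  full <- names(ss)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  data.frame(id = id, desc = desc, seq = toupper(as.character(ss)),
             stringsAsFactors = FALSE)
}

# "Lys-TTT-3-1" -> amino_acid "Lys", anticodon "TTT"; mitochondrial entries
# are recognized by an mt/MT prefix token. Unparseable non-spike-in headers
# are rejected with a warning.
parse_trna_headers <- function(df, spike_in = FALSE) {
  ids <- df$id
  stripped <- sub("^(mt|MT|mito)[-_]", "", ids)
  m <- regmatches(stripped, regexec("^([A-Za-z]{3}|iMet|Und)-([ACGTN]{3})",
                                    stripped))
  aa <- vapply(m, function(x) if (length(x) == 3L) x[2] else NA_character_,
               character(1))
  ac <- vapply(m, function(x) if (length(x) == 3L) x[3] else NA_character_,
               character(1))
  is_mito <- grepl("^(mt|MT|mito)[-_]", ids)
  if (!spike_in) {
    bad <- is.na(aa)
    if (any(bad)) {
      warning("rejecting ", sum(bad), " record(s) with unparseable header: ",
              paste(utils::head(ids[bad], 5L), collapse = ", "))
      df <- df[!bad, , drop = FALSE]
      aa <- aa[!bad]; ac <- ac[!bad]; is_mito <- is_mito[!bad]
    }
  } else {
    aa[is.na(aa)] <- "Und"
  }
  bad_alpha <- grepl("[^ACGTN]", df$seq)
  if (any(bad_alpha)) {
    warning("rejecting ", sum(bad_alpha),
            " record(s) with non-ACGTN characters")
    keep <- !bad_alpha
    df <- df[keep, , drop = FALSE]
    aa <- aa[keep]; ac <- ac[keep]; is_mito <- is_mito[keep]
  }
  df$amino_acid <- aa
  df$anticodon <- ac
  df$is_spike_in <- spike_in
  df$is_mito <- is_mito
  df$desc <- NULL
  df
}

# Exact duplicate sequences collapse to one record; the lexicographically
# smallest id wins and all merged ids are retained as aliases.
dedup_transcripts <- function(df) {
  df <- df[order(df$id), , drop = FALSE]
  alias <- tapply(df$id, df$seq, function(x) paste(sort(x), collapse = ";"))
  keep <- !duplicated(df$seq)
  out <- df[keep, , drop = FALSE]
  out$aliases <- unname(alias[out$seq])
  out[order(out$id), , drop = FALSE]
}

normalize_cca <- function(df) {
  lacks <- !endsWith(df$seq, "CCA")
  if (any(lacks)) {
    warning("appended 3' CCA to ", sum(lacks), " record(s): ",
            paste(utils::head(df$id[lacks], 5L), collapse = ", "))
    df$seq[lacks] <- paste0(df$seq[lacks], "CCA")
  }
  df
}

#' Mask reference positions
#'
#' Adds positions to the reference mask. Masked positions are emitted as 'N'
#' (scoring 0 in alignment) while the original bases are retained internally
#' for unmasked realignment and for misincorporation-frequency computation.
#'
#' @param ref A `masked_reference`.
#' @param positions Data frame with columns `transcript_id` and `position`
#'   (0-based), or a list of `c(id, pos)` pairs.
#' @return The reference with the union of the prior and new mask.
#' @export
apply_mask <- function(ref, positions) {
  stopifnot(inherits(ref, "masked_reference"))
  if (is.list(positions) && !is.data.frame(positions)) {
    positions <- data.frame(
      transcript_id = vapply(positions, function(x) as.character(x[[1]]),
                             character(1)),
      position = vapply(positions, function(x) as.integer(x[[2]]),
                        integer(1)))
  }
  if (NROW(positions) == 0L) return(ref)
  tr <- ref$transcripts
  for (i in seq_len(nrow(positions))) {
    id <- positions$transcript_id[i]
    p <- as.integer(positions$position[i])
    row <- match(id, tr$id)
    if (is.na(row)) stop("unknown transcript in mask: ", id)
    len <- nchar(tr$seq[row])
    if (p < 0L || p >= len)
      stop("mask position out of bounds: ", id, " position ", p,
           " (0-based), length ", len)
    ref$mask[[id]] <- sort(unique(c(ref$mask[[id]], p)))
  }
  ref
}

#' Emitted (masked) sequences of a reference
#'
#' @param ref A `masked_reference`.
#' @return Named character vector of sequences with 'N' at masked positions.
#' @export
masked_sequences <- function(ref) {
  tr <- ref$transcripts
  out <- tr$seq
  for (i in seq_len(nrow(tr))) {
    pos <- ref$mask[[tr$id[i]]]
    if (length(pos) > 0L) {
      s <- strsplit(out[i], "")[[1]]
      s[pos + 1L] <- "N"
      out[i] <- paste(s, collapse = "")
    }
  }
  names(out) <- tr$id
  out
}

#' @export
print.masked_reference <- function(x, ...) {
  n_mask <- sum(lengths(x$mask))
  cat("masked_reference:", nrow(x$transcripts), "transcripts (",
      sum(x$transcripts$is_spike_in), "spike-in ),", n_mask,
      "masked positions,", x$iteration, "masking iteration(s)\n")
  invisible(x)
}

#' Count of masked positions
#' @param ref A `masked_reference`.
#' @return Integer total of masked positions across transcripts.
#' @export
n_masked <- function(ref) sum(lengths(ref$mask))

#' Write / read a masked reference
#'
#' The reference is serialized as a FASTA with 'N' at masked positions plus
#' a TSV sidecar `<path>.masked_positions.tsv` recording the original base at
#' each masked position (columns `transcript_id`, `position_1based`,
#' `original_base`), so that `read_reference(write_reference(ref))` is the
#' identity including the mask. Annotation fields are carried in the FASTA
#' description.
#'
#' @param ref A `masked_reference`.
#' @param path Output FASTA path.
#' @return `write_reference` returns `path` invisibly; `read_reference`
#'   returns a `masked_reference`.
#' @export
write_reference <- function(ref, path) {
  tr <- ref$transcripts
  seqs <- masked_sequences(ref)
  desc <- sprintf("aa=%s ac=%s spike=%d mito=%d aliases=%s iter=%d",
                  tr$amino_acid, tr$anticodon, as.integer(tr$is_spike_in),
                  as.integer(tr$is_mito), tr$aliases, ref$iteration)
  lines <- character(2L * nrow(tr))
  lines[c(TRUE, FALSE)] <- paste0(">", tr$id, " ", desc)
  lines[c(FALSE, TRUE)] <- unname(seqs)
  ok <- tryCatch({writeLines(lines, path); TRUE},
                 error = function(e) stop("failed writing ", path, ": ",
                                          conditionMessage(e)))
  side <- mask_table(ref)
  write.table(side, sidecar_path(path), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

sidecar_path <- function(path) paste0(path, ".masked_positions.tsv")

#' Mask as a table
#' @param ref A `masked_reference`.
#' @return Data frame `transcript_id`, `position_1based`, `original_base`.
#' @export
mask_table <- function(ref) {
  tr <- ref$transcripts
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    pos <- ref$mask[[tr$id[i]]]
    if (length(pos) == 0L) return(NULL)
    data.frame(transcript_id = tr$id[i], position_1based = pos + 1L,
               original_base = substring(tr$seq[i], pos + 1L, pos + 1L))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(transcript_id = character(), position_1based = integer(),
                      original_base = character())
  out
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  df <- read_fasta_records(path)
  if (nrow(df) == 0L) stop("empty reference FASTA: ", path)
  kv <- function(key) {
    m <- regmatches(df$desc, regexec(paste0(key, "=(\\S+)"), df$desc))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  tr <- data.frame(id = df$id, seq = df$seq, amino_acid = kv("aa"),
                   anticodon = kv("ac"),
                   is_spike_in = kv("spike") == "1",
                   is_mito = kv("mito") == "1",
                   aliases = kv("aliases"), stringsAsFactors = FALSE)
  tr$anticodon[tr$anticodon == "NA"] <- NA_character_
  iter <- suppressWarnings(as.integer(kv("iter")[1]))
  side_path <- sidecar_path(path)
  mask <- setNames(vector("list", nrow(tr)), tr$id)
  if (file.exists(side_path)) {
    side <- read.table(side_path, header = TRUE, sep = "\t",
                       colClasses = c("character", "integer", "character"))
    for (i in seq_len(nrow(side))) {
      id <- side$transcript_id[i]
      p <- side$position_1based[i]
      substring(tr$seq[match(id, tr$id)], p, p) <- side$original_base[i]
      mask[[id]] <- c(mask[[id]], p - 1L)
    }
    mask <- lapply(mask, function(x) sort(unique(x)))
  }
  structure(list(transcripts = tr, mask = mask,
                 iteration = if (is.na(iter)) 0L else iter),
            class = "masked_reference")
}
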