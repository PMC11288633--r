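# Hand-built fixture helpers: everything is generated in code at test time.

write_fasta_fixture <- function(ids, seqs, path = tempfile(fileext = ".fasta")) {
  lines <- character(2L * length(ids))
  lines[c(TRUE, FALSE)] <- paste0(">", ids)
  lines[c(FALSE, TRUE)] <- seqs
  writeLines(lines, path)
  path
}

# A minimal reference object without going through FASTA.
make_ref <- function(ids, seqs, anticodons = NULL, amino_acids = NULL,
                     spike = FALSE) {
  n <- length(ids)
  parse_tok <- function(i, k) {
    parts <- strsplit(ids[i], "-")[[1]]
    if (length(parts) >= 2L) parts[k] else NA_character_
  }
  tr <- data.frame(
    id = ids, seq = seqs,
    amino_acid = if (is.null(amino_acids))
      vapply(seq_len(n), parse_tok, character(1), 1L) else amino_acids,
    anticodon = if (is.null(anticodons))
      vapply(seq_len(n), parse_tok, character(1), 2L) else anticodons,
    is_spike_in = rep(spike, n), is_mito = FALSE, aliases = ids,
    stringsAsFactors = FALSE)
  ord <- order(tr$id)
  tr <- tr[ord, , drop = FALSE]
  rownames(tr) <- NULL
  structure(list(transcripts = tr,
                 mask = setNames(vector("list", n), tr$id),
                 iteration = 0L),
            class = "masked_reference")
}

# Reads data frame straight from sequences.
make_reads <- function(seqs, ids = sprintf("r%04d", seq_along(seqs)),
                       umi = NULL) {
  df <- data.frame(read_id = ids, seq = seqs,
                   qual = strrep("I", nchar(seqs)),
                   stringsAsFactors = FALSE)
  if (!is.null(umi)) df$umi <- umi
  df
}
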