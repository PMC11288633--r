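#' Read / write FASTQ
#'
#' Thin wrappers around Biostrings quality-aware FASTQ I/O returning a plain
#' data frame (`read_id`, `seq`, `qual`). Gzip-transparent on input.
#'
#' @param path FASTQ file path.
#' @return `read_fastq`: data frame with one row per read.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  ss <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  data.frame(read_id = sub("\\s.*$", "", names(ss)),
             seq = as.character(ss),
             qual = as.character(Biostrings::quality(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param reads Data frame with `read_id`, `seq` and optionally `qual`
#'   (constant 'I' used when absent).
#' @export
write_fastq <- function(reads, path) {
  qual <- if ("qual" %in% names(reads)) reads$qual else
    vapply(nchar(reads$seq), function(n) strrep("I", n), character(1))
  lines <- character(4L * nrow(reads))
  lines[c(TRUE, FALSE, FALSE, FALSE)] <- paste0("@", reads$read_id)
  lines[c(FALSE, TRUE, FALSE, FALSE)] <- reads$seq
  lines[c(FALSE, FALSE, TRUE, FALSE)] <- "+"
  lines[c(FALSE, FALSE, FALSE, TRUE)] <- qual
  writeLines(lines, path)
  invisible(path)
}

#' Barcode specifications
#'
#' A barcode spec couples a barcode id with the search sequence expected at
#' the read 3' end: the adapter barcode plus the splint-complementary
#' context, supplied by the user (library-design dependent). A read is
#' assigned to a barcode when a window near its 3' end matches the search
#' sequence within `max_hamming` substitutions.
#'
#' @param barcode_id Character vector of barcode names.
#' @param search_seq Character vector of search sequences (length >= 5).
#' @param max_hamming Maximum Hamming distance for a match (default 1).
#' @return Data frame of class `barcode_spec`.
#' @export
barcode_spec <- function(barcode_id, search_seq, max_hamming = 1L) {
  stopifnot(length(barcode_id) == length(search_seq))
  if (any(nchar(search_seq) < 5L))
    stop("barcode search_seq must be at least 5 nt")
  if (any(max_hamming >= nchar(search_seq)))
    stop("max_hamming must be smaller than the search sequence length")
  structure(data.frame(barcode_id = as.character(barcode_id),
                       search_seq = toupper(search_seq),
                       max_hamming = as.integer(max_hamming),
                       stringsAsFactors = FALSE),
            class = c("barcode_spec", "data.frame"))
}

# Pairwise separation check: unambiguous assignment needs all pairs of
# equal-length search sequences to differ at more than 2*max_hamming sites.
validate_barcode_separation <- function(specs) {
  n <- nrow(specs)
  if (n < 2L) return(invisible(TRUE))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    a <- specs$search_seq[i]; b <- specs$search_seq[j]
    if (nchar(a) != nchar(b)) next
    d <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    lim <- 2L * max(specs$max_hamming[c(i, j)])
    if (d <= lim)
      stop("barcodes '", specs$barcode_id[i], "' and '", specs$barcode_id[j],
           "' differ at only ", d, " position(s); need > ", lim,
           " for unambiguous assignment (use allow_close_barcodes to waive)")
  }
  invisible(TRUE)
}

#' Demultiplex reads by 3' adapter barcode
#'
#' Scans the last `len(search_seq) + slack` bases of each read for the
#' window with the lowest Hamming distance to each barcode search sequence
#' (ties broken by the most 3' window), assigns the read to a barcode when
#' the distance is within `max_hamming`, and trims the matched substring and
#' everything 3' of it. Reads matching no barcode go to the unassigned bin;
#' reads matching two or more (possible only when the separation
#' precondition is waived) go to an ambiguous bin.
#'
#' @param reads Data frame from [read_fastq()].
#' @param barcodes A [barcode_spec()] data frame.
#' @param slack Extra 3' bases scanned beyond the search-sequence length,
#'   tolerating small length variation from upstream trimming (default 4).
#' @param allow_close_barcodes Waive the pairwise-separation precondition.
#' @return List with `assigned` (named list of per-barcode read data
#'   frames, barcode-trimmed), `unassigned`, `ambiguous`, and `stats`
#'   (per-bin counts; conservation: bins sum to the input count).
#' @export
demultiplex <- function(reads, barcodes, slack = 4L,
                        allow_close_barcodes = FALSE) {
  stopifnot(is.data.frame(reads), nrow(barcodes) >= 1L)
  if (!allow_close_barcodes) validate_barcode_separation(barcodes)
  n <- nrow(reads)
  hits <- matrix(NA_integer_, nrow = n, ncol = nrow(barcodes))
  starts <- matrix(NA_integer_, nrow = n, ncol = nrow(barcodes))
  for (b in seq_len(nrow(barcodes))) {
    pat <- barcodes$search_seq[b]
    scan <- .barcode_scan(reads$seq, pat, nchar(pat) + as.integer(slack))
    hits[, b] <- scan[1, ]
    starts[, b] <- scan[2, ]
  }
  ok <- sweep(hits, 2L, barcodes$max_hamming, `<=`)
  n_ok <- rowSums(ok)
  assigned <- vector("list", nrow(barcodes))
  names(assigned) <- barcodes$barcode_id
  for (b in seq_len(nrow(barcodes))) {
    sel <- which(ok[, b] & n_ok == 1L)
    sub <- reads[sel, , drop = FALSE]
    if (nrow(sub) > 0L) {
      cut <- starts[sel, b]  # 0-based start of matched window
      sub$seq <- substr(sub$seq, 1L, cut)
      if ("qual" %in% names(sub)) sub$qual <- substr(sub$qual, 1L, cut)
      sub$barcode_id <- barcodes$barcode_id[b]
    }
    rownames(sub) <- NULL
    assigned[[b]] <- sub
  }
  unassigned <- reads[n_ok == 0L, , drop = FALSE]
  ambiguous <- reads[n_ok >= 2L, , drop = FALSE]
  rownames(unassigned) <- rownames(ambiguous) <- NULL
  stats <- c(setNames(vapply(assigned, nrow, integer(1)),
                      barcodes$barcode_id),
             unassigned = nrow(unassigned), ambiguous = nrow(ambiguous))
  list(assigned = assigned, unassigned = unassigned, ambiguous = ambiguous,
       stats = stats)
}

#' Extract the 5' UMI
#'
#' Splits off the first `umi_len` bases of each read as its UMI, leaving the
#' tRNA-derived sequence. Reads too short to contain a UMI plus a minimal
#' tRNA body are dropped and counted, not raised.
#'
#' @param reads Data frame with `seq` (post-demultiplexing).
#' @param umi_len UMI length in nt (default 10).
#' @param min_trna_len Minimal remaining tRNA sequence length for a read to
#'   be kept at this stage (default 1).
#' @return List with `reads` (columns plus `umi`, `seq` replaced by the
#'   trimmed tRNA sequence) and `n_dropped`.
#' @export
extract_umi <- function(reads, umi_len = 10L, min_trna_len = 1L) {
  keep <- nchar(reads$seq) >= umi_len + min_trna_len
  out <- reads[keep, , drop = FALSE]
  out$umi <- substr(out$seq, 1L, umi_len)
  out$seq <- substring(out$seq, umi_len + 1L)
  if ("qual" %in% names(out)) out$qual <- substring(out$qual, umi_len + 1L)
  rownames(out) <- NULL
  list(reads = out, n_dropped = sum(!keep))
}

#' Length filter
#'
#' Removes reads whose tRNA-derived sequence is shorter than `min_len`
#' (default 39 nt for splint-ligation libraries; 25 for blunt-end).
#'
#' @param reads Data frame with `seq`.
#' @param min_len Minimum surviving length.
#' @return List with `reads` and `n_removed`.
#' @export
length_filter <- function(reads, min_len = 39L) {
  keep <- nchar(reads$seq) >= min_len
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(reads = out, n_removed = sum(!keep))
}

#' Downsample reads to a cap
#'
#' Uniform random subset of exactly `cap` reads when the input exceeds the
#' cap; identity otherwise. Deterministic given `seed`.
#'
#' @param reads Data frame of reads.
#' @param cap Maximum read count retained (default 2e6).
#' @param seed Integer seed (required: reproducibility contract).
#' @return Data frame of retained reads (input order preserved).
#' @export
downsample <- function(reads, cap = 2e6, seed) {
  if (missing(seed)) stop("downsample requires an explicit seed")
  n <- nrow(reads)
  if (n <= cap) return(reads)
  sel <- withr::with_seed(as.integer(seed), sort(sample.int(n, cap)))
  out <- reads[sel, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a sample sheet
#'
#' TSV with columns `sample_id`, `barcode_id`, `search_seq` (and optional
#' design columns such as `p_percent` or `t_minutes` used by the titration
#' and half-life stages).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_sample_sheet <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "barcode_id", "search_seq")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("sample sheet missing column(s): ", paste(miss, collapse = ", "))
  df
}
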