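AA3 <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
         "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
         "Tyr", "Val")

rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

mutate_seq <- function(seq, n_mut, protect_tail = 3L) {
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  pos <- sample(seq_len(L - protect_tail), n_mut)
  for (p in pos) s[p] <- sample(setdiff(c("A", "C", "G", "T"), s[p]), 1L)
  paste(s, collapse = "")
}

#' Simulate a tRNA transcript reference with known family structure
#'
#' Generates random CCA-terminated transcript sequences: singletons plus
#' families of near-identical members produced by seeding one sequence and
#' applying a controlled number of substitutions. Families can share one
#' anticodon (the benign case for anticodon-level reporting) or split
#' anticodons (the case reference masking must disambiguate).
#'
#' @param n_singletons Number of unrelated transcripts.
#' @param families List of family specs, each a list with `size` (members),
#'   `mutations` (substitutions between members) and `share_anticodon`
#'   (logical).
#' @param length_range Transcript length range in nt (default 72..90,
#'   CCA included).
#' @param n_spike_ins Spike-in control sequences appended (default 0).
#' @param seed Integer seed (mandatory; generation is bit-reproducible).
#' @return List: `ref` (a `masked_reference`, mask empty), `truth` (data
#'   frame: `id`, `family`, `anticodon`, `amino_acid`).
#' @export
sim_reference <- function(n_singletons = 16L, families = list(),
                          length_range = c(72L, 90L), n_spike_ins = 0L,
                          seed) {
  if (missing(seed)) stop("sim_reference requires a seed")
  withr::with_seed(as.integer(seed), {
    rows <- list(); truth <- list()
    aas <- sample(AA3, n_singletons + length(families), replace =
                    n_singletons + length(families) > length(AA3))
    used_ac <- character()
    next_ac <- function() {
      repeat {
        ac <- rand_bases(3L)
        if (!(ac %in% used_ac)) { used_ac <<- c(used_ac, ac); return(ac) }
      }
    }
    for (i in seq_len(n_singletons)) {
      L <- sample(length_range[1]:length_range[2], 1L)
      ac <- next_ac()
      id <- sprintf("%s-%s-%d-1", aas[i], ac, i)
      rows[[id]] <- data.frame(id = id,
                               seq = paste0(rand_bases(L - 3L), "CCA"),
                               amino_acid = aas[i], anticodon = ac,
                               is_spike_in = FALSE, is_mito = FALSE,
                               aliases = id, stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(id = id, family = NA_character_,
                                anticodon = ac, amino_acid = aas[i],
                                stringsAsFactors = FALSE)
    }
    for (f in seq_along(families)) {
      fam <- families[[f]]
      aa <- aas[n_singletons + f]
      L <- sample(length_range[1]:length_range[2], 1L)
      base <- paste0(rand_bases(L - 3L), "CCA")
      ac <- next_ac()
      for (m in seq_len(fam$size)) {
        ac_m <- if (isTRUE(fam$share_anticodon) || m == 1L) ac else next_ac()
        id <- if (isTRUE(fam$share_anticodon))
          sprintf("%s-%s-%d-%d", aa, ac_m, n_singletons + f, m)
        else sprintf("%s-%s-%d-1", aa, ac_m, n_singletons + f)
        sq <- if (m == 1L) base else mutate_seq(base, fam$mutations)
        rows[[id]] <- data.frame(id = id, seq = sq, amino_acid = aa,
                                 anticodon = ac_m, is_spike_in = FALSE,
                                 is_mito = FALSE, aliases = id,
                                 stringsAsFactors = FALSE)
        truth[[id]] <- data.frame(id = id, family = paste0("fam", f),
                                  anticodon = ac_m, amino_acid = aa,
                                  stringsAsFactors = FALSE)
      }
    }
    for (s in seq_len(n_spike_ins)) {
      L <- sample(length_range[1]:length_range[2], 1L)
      id <- sprintf("spike-Lys-TTT-%d", s)
      rows[[id]] <- data.frame(id = id,
                               seq = paste0(rand_bases(L - 3L), "CCA"),
                               amino_acid = "Lys", anticodon = "TTT",
                               is_spike_in = TRUE, is_mito = FALSE,
                               aliases = id, stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(id = id, family = "spike",
                                anticodon = "TTT", amino_acid = "Lys",
                                stringsAsFactors = FALSE)
    }
    tr <- do.call(rbind, rows)
    tr <- tr[order(tr$id), , drop = FALSE]
    rownames(tr) <- NULL
    ref <- structure(list(transcripts = tr,
                          mask = setNames(vector("list", nrow(tr)), tr$id),
                          iteration = 0L),
                     class = "masked_reference")
    tt <- do.call(rbind, truth)
    rownames(tt) <- NULL
    list(ref = ref, truth = tt[order(tt$id), , drop = FALSE])
  })
}

sample_umi <- function(pattern) {
  alph <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), N = c("A", "C", "G", "T"))
  paste(vapply(strsplit(pattern, "")[[1]],
               function(s) sample(alph[[s]], 1L), character(1)),
        collapse = "")
}

#' Simulate charge tRNA-Seq reads with known ground truth
#'
#' Models the read-generating process: each read derives from one
#' transcript and ends in CCA (charged, aminoacyl-protected during
#' periodate oxidation) with the transcript's charge probability, else in
#' CC (the Whitfeld reaction cleaved the terminal A of the deacylated
#' molecule). Reverse transcription copies the template 3'->5', stopping
#' before position p with probability `stop_prob(p)` and planting
#' substitutions and deletions with the per-position probabilities
#' (modification-driven misincorporation). The cDNA-derived read is then
#' 5'-tagged with a UMI drawn from the design pattern and 3'-tagged with
#' the barcode search sequence; quality is constant 'I'.
#'
#' @param ref A `masked_reference` (original sequences are the templates).
#' @param charge Per-transcript charge as a named vector in \[0, 1\], or a
#'   single value recycled.
#' @param n_reads Reads per transcript (named vector or single value).
#' @param mods Optional data frame of planted modification effects:
#'   `transcript_id`, `position_1based`, `sub_prob`, `gap_prob`,
#'   `stop_prob` (absent columns default to 0).
#' @param umi_pattern UMI design (default "RNNNNNNNNN").
#' @param barcode A [barcode_spec()] row to append (NULL: no barcode, no
#'   UMI — raw tRNA sequences).
#' @param seed Integer seed (mandatory).
#' @return List: `reads` (data frame `read_id`, `seq`, `qual`), `truth`
#'   (per read: `read_id`, `transcript_id`, `end_truth`, `umi`,
#'   `barcode_id`, `start_1based`, `end_1based`).
#' @export
sim_reads <- function(ref, charge = 0.8, n_reads = 500L, mods = NULL,
                      umi_pattern = "RNNNNNNNNN", barcode = NULL, seed) {
  if (missing(seed)) stop("sim_reads requires a seed")
  tr <- ref$transcripts
  ids <- tr$id
  if (is.null(names(charge))) charge <- setNames(rep(charge, length(ids))[
    seq_along(ids)], ids)
  if (is.null(names(n_reads))) n_reads <- setNames(
    rep(as.integer(n_reads), length(ids))[seq_along(ids)], ids)
  probs <- lapply(seq_along(ids), function(i) {
    L <- nchar(tr$seq[i])
    m <- matrix(0, nrow = 3L, ncol = L,
                dimnames = list(c("sub", "gap", "stop"), NULL))
    if (!is.null(mods)) {
      sel <- mods$transcript_id == ids[i]
      for (j in which(sel)) {
        p <- mods$position_1based[j]
        if (!is.null(mods$sub_prob)) m["sub", p] <- mods$sub_prob[j]
        if (!is.null(mods$gap_prob)) m["gap", p] <- mods$gap_prob[j]
        if (!is.null(mods$stop_prob)) m["stop", p] <- mods$stop_prob[j]
      }
    }
    m
  })
  names(probs) <- ids
  withr::with_seed(as.integer(seed), {
    out_r <- list(); out_t <- list(); ridx <- 0L
    for (i in seq_along(ids)) {
      id <- ids[i]
      s <- strsplit(tr$seq[i], "")[[1]]
      L <- length(s)
      pm <- probs[[id]]
      stop_pos <- which(pm["stop", ] > 0)
      for (r in seq_len(n_reads[[id]])) {
        ridx <- ridx + 1L
        charged <- runif(1) < charge[[id]]
        end <- if (charged) L else L - 1L
        start <- 1L
        for (p in rev(stop_pos[stop_pos < end])) {
          # positions between p and end must have been reached first
          if (runif(1) < pm["stop", p]) { start <- p + 1L; break }
        }
        body <- s[start:end]
        rel <- seq.int(start, end)
        subm <- runif(length(rel)) < pm["sub", rel]
        for (j in which(subm))
          body[j] <- sample(setdiff(c("A", "C", "G", "T"), body[j]), 1L)
        gapm <- runif(length(rel)) < pm["gap", rel]
        if (any(gapm)) body <- body[!gapm]
        umi <- if (is.null(barcode)) "" else sample_umi(umi_pattern)
        bc_seq <- if (is.null(barcode)) "" else barcode$search_seq[1L]
        bc_id <- if (is.null(barcode)) NA_character_ else
          barcode$barcode_id[1L]
        read_id <- sprintf("sim_%s_%06d", bc_id, ridx)
        out_r[[ridx]] <- c(read_id, paste0(umi, paste(body, collapse = ""),
                                           bc_seq))
        out_t[[ridx]] <- data.frame(
          read_id = read_id, transcript_id = id,
          end_truth = if (charged) "CCA" else "CC",
          umi = umi, barcode_id = bc_id, start_1based = start,
          end_1based = end, stringsAsFactors = FALSE)
      }
    }
    seqs <- vapply(out_r, `[`, character(1), 2L)
    reads <- data.frame(read_id = vapply(out_r, `[`, character(1), 1L),
                        seq = seqs,
                        qual = strrep("I", nchar(seqs)),
                        stringsAsFactors = FALSE)
    list(reads = reads, truth = do.call(rbind, out_t))
  })
}

#' Simulate a charge titration series
#'
#' Evaluates the mixture model ([predicted_charge()]) on the design and
#' adds Gaussian noise clipped to \[0, 100\]; endpoint mixtures (p = 100,
#' p = 0) are generated too, since they define T_A and T_B downstream.
#'
#' @param T_A,T_B True endpoint charges (percent).
#' @param F_i True correction factor.
#' @param p_values Interior mixing percentages (default the 6-point
#'   design 85, 70, 55, 40, 25, 10).
#' @param replicates Barcode replicates per mixture (default 4).
#' @param noise_sd Gaussian noise SD in percentage points.
#' @param seed Integer seed (mandatory).
#' @param barcode_offsets Optional named per-barcode additive bias
#'   (percentage points), keyed "bc1".."bcN".
#' @return Data frame: `p_percent`, `replicate`, `barcode_id`,
#'   `charge_pct`; attribute `truth` records the generating parameters.
#' @export
sim_titration <- function(T_A, T_B, F_i,
                          p_values = c(85, 70, 55, 40, 25, 10),
                          replicates = 4L, noise_sd = 1, seed,
                          barcode_offsets = NULL) {
  if (missing(seed)) stop("sim_titration requires a seed")
  ps <- c(100, p_values, 0)
  withr::with_seed(as.integer(seed), {
    grid <- expand.grid(p_percent = ps, replicate = seq_len(replicates))
    grid$barcode_id <- paste0("bc", grid$replicate)
    mu <- predicted_charge(grid$p_percent, T_A, T_B, F_i)
    off <- if (is.null(barcode_offsets)) 0 else
      barcode_offsets[grid$barcode_id]
    grid$charge_pct <- pmin(100, pmax(0, mu + off +
                                        rnorm(nrow(grid), 0, noise_sd)))
    attr(grid, "truth") <- list(T_A = T_A, T_B = T_B, F_i = F_i)
    grid
  })
}

#' Simulate an aminoacylation decay series
#'
#' Evaluates the first-order decay model ([decay_model()]) on the
#' timepoint grid and adds Gaussian noise clipped to \[0, 100\].
#'
#' @param N0,t_half,N_inf True parameters.
#' @param timepoints Minutes (default the 11-point grid,
#'   [decay_timepoints()]).
#' @param replicates Replicates per timepoint (default 4).
#' @param noise_sd Gaussian noise SD in percentage points.
#' @param seed Integer seed (mandatory).
#' @return Data frame: `t_minutes`, `replicate`, `charge_pct`; attribute
#'   `truth` records the generating parameters.
#' @export
sim_decay <- function(N0 = 95, t_half = 120, N_inf = 2,
                      timepoints = decay_timepoints(), replicates = 4L,
                      noise_sd = 1.5, seed) {
  if (missing(seed)) stop("sim_decay requires a seed")
  withr::with_seed(as.integer(seed), {
    grid <- expand.grid(t_minutes = timepoints,
                        replicate = seq_len(replicates))
    mu <- decay_model(grid$t_minutes, N0, t_half, N_inf)
    grid$charge_pct <- pmin(100, pmax(0, mu + rnorm(nrow(grid), 0,
                                                    noise_sd)))
    attr(grid, "truth") <- list(N0 = N0, t_half = t_half, N_inf = N_inf)
    grid
  })
}

#' Simulate a complete miniature study
#'
#' Writes, under `dir`: a transcript reference FASTA (`reference.fasta`),
#' one merged FASTQ per barcode (`reads_<barcode>.fastq`) plus a combined
#' `reads.fastq`, a sample sheet (`samples.tsv`), a titration design
#' (`titration_design.tsv`), a decay design (`decay_design.tsv`), and
#' ground-truth tables (`truth_*.tsv`).
#'
#' @param dir Output directory (created).
#' @param seed Integer seed (mandatory).
#' @param n_barcodes Number of adapter barcodes (default 3).
#' @param reads_per_transcript Reads per transcript per barcode.
#' @return Invisibly, a named list of the written paths.
#' @export
sim_study <- function(dir, seed, n_barcodes = 3L,
                      reads_per_transcript = 60L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  simref <- sim_reference(n_singletons = 6L,
                          families = list(list(size = 2L, mutations = 3L,
                                               share_anticodon = FALSE)),
                          seed = seed)
  ref_path <- file.path(dir, "reference.fasta")
  write_reference(simref$ref, ref_path)
  barcodes <- sim_barcodes(n_barcodes)
  ids <- simref$ref$transcripts$id
  charge <- withr::with_seed(as.integer(seed) + 1L,
                             setNames(runif(length(ids), 0.1, 0.95), ids))
  paths <- list(reference = ref_path)
  all_reads <- list()
  for (b in seq_len(n_barcodes)) {
    sim <- sim_reads(simref$ref, charge = charge,
                     n_reads = reads_per_transcript,
                     barcode = barcodes[b, ], seed = seed + 10L + b)
    p <- file.path(dir, paste0("reads_", barcodes$barcode_id[b], ".fastq"))
    write_fastq(sim$reads, p)
    paths[[paste0("reads_", barcodes$barcode_id[b])]] <- p
    all_reads[[b]] <- sim$reads
    write.table(sim$truth,
                file.path(dir, paste0("truth_reads_",
                                      barcodes$barcode_id[b], ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  combined <- do.call(rbind, all_reads)
  paths$reads <- file.path(dir, "reads.fastq")
  write_fastq(combined, paths$reads)
  sheet <- data.frame(sample_id = paste0("sample", seq_len(n_barcodes)),
                      barcode_id = barcodes$barcode_id,
                      search_seq = barcodes$search_seq)
  paths$samples <- file.path(dir, "samples.tsv")
  write.table(sheet, paths$samples, sep = "\t", quote = FALSE,
              row.names = FALSE)
  tit <- sim_titration(T_A = 90, T_B = 5, F_i = 1.5, seed = seed + 100L)
  paths$titration <- file.path(dir, "titration_design.tsv")
  write.table(tit, paths$titration, sep = "\t", quote = FALSE,
              row.names = FALSE)
  dec <- sim_decay(seed = seed + 200L)
  paths$decay <- file.path(dir, "decay_design.tsv")
  write.table(dec, paths$decay, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(data.frame(transcript_id = ids, charge = charge[ids]),
              file.path(dir, "truth_charge.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Well-separated barcode specs for simulation
#'
#' @param n Number of barcodes (max 8).
#' @return A [barcode_spec()] data frame whose search sequences are
#'   pairwise Hamming distance > 2.
#' @export
sim_barcodes <- function(n = 3L) {
  pool <- c("ACGTACGTGG", "TGCATGCACC", "GATCGATCTT", "CTAGCTAGAA",
            "AAGGCCTTGC", "TTCCGGAACG", "GGTTAACCGT", "CCAATTGGTA")
  if (n > length(pool)) stop("at most ", length(pool), " barcodes")
  barcode_spec(paste0("bc", seq_len(n)), pool[seq_len(n)])
}
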