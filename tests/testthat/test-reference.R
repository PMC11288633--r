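test_that("loading parses annotations, deduplicates and CCA-normalizes", {
  seqs <- c("GGGCCCAAATTTGGGCCCAAACCA",      # duplicate pair, ends CCA
            "GGGCCCAAATTTGGGCCCAAACCA",
            "ACGTACGTACGTACGTACGT",          # lacks CCA
            "TTTTGGGGCCCCAAAATTTTCCA")
  fa <- write_fasta_fixture(c("Gly-GCC-1-2", "Gly-GCC-1-1",
                              "Lys-TTT-3-1", "Val-TAC-2-1"), seqs)
  expect_warning(ref <- load_reference(fa), "CCA")
  tr <- ref$transcripts
  # duplicates collapsed to the lexicographically smallest id with aliases
  expect_equal(sum(grepl("Gly", tr$id)), 1L)
  expect_equal(tr$id[grepl("Gly", tr$id)], "Gly-GCC-1-1")
  expect_equal(tr$aliases[tr$id == "Gly-GCC-1-1"],
               "Gly-GCC-1-1;Gly-GCC-1-2")
  # annotation parsing from the id
  expect_equal(tr$amino_acid[tr$id == "Lys-TTT-3-1"], "Lys")
  expect_equal(tr$anticodon[tr$id == "Lys-TTT-3-1"], "TTT")
  # CCA appended where missing, untouched where present
  expect_true(all(endsWith(tr$seq, "CCA")))
  expect_equal(tr$seq[tr$id == "Lys-TTT-3-1"],
               "ACGTACGTACGTACGTACGTCCA")
  expect_equal(tr$seq[tr$id == "Val-TAC-2-1"],
               "TTTTGGGGCCCCAAAATTTTCCA")
  # the multiset of distinct sequences is unchanged by deduplication
  expect_setequal(tr$seq, unique(paste0(sub("CCA$", "", seqs), "CCA")))
})

test_that("unparseable headers are rejected with a warning, empty is fatal", {
  fa <- write_fasta_fixture(c("Lys-TTT-3-1", "garbage_header"),
                            c("ACGTACGTACGTACGTCCA", "ACGTGGGGTTTTACGTCCA"))
  expect_warning(ref <- load_reference(fa), "unparseable")
  expect_equal(ref$transcripts$id, "Lys-TTT-3-1")
  empty <- tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(load_reference(empty))
})

test_that("CCA normalization is idempotent", {
  fa <- write_fasta_fixture("Lys-TTT-3-1", "ACGTACGTACGTACGTACGT")
  ref1 <- suppressWarnings(load_reference(fa))
  fa2 <- write_fasta_fixture("Lys-TTT-3-1", ref1$transcripts$seq)
  expect_silent(ref2 <- load_reference(fa2))
  expect_identical(ref1$transcripts$seq, ref2$transcripts$seq)
})

test_that("masking substitutes N, is idempotent, bounded, length-preserving", {
  ref <- make_ref(c("Lys-TTT-3-1", "Val-TAC-2-1"),
                  c(paste0(strrep("ACGT", 18), "TCCA"),  # 76 nt
                    paste0(strrep("GGCA", 17), "ACCA")))
  expect_identical(apply_mask(ref, list()), ref)  # empty mask identity
  m1 <- apply_mask(ref, data.frame(transcript_id = "Lys-TTT-3-1",
                                   position = 34L))
  s <- masked_sequences(m1)[["Lys-TTT-3-1"]]
  expect_equal(substring(s, 35, 35), "N")  # 0-based 34 -> 1-based 35
  expect_equal(nchar(s), 76L)
  # original base retained internally
  expect_equal(substring(m1$transcripts$seq[m1$transcripts$id ==
                                              "Lys-TTT-3-1"], 35, 35), "G")
  # idempotence
  m2 <- apply_mask(m1, data.frame(transcript_id = "Lys-TTT-3-1",
                                  position = 34L))
  expect_identical(masked_sequences(m2), masked_sequences(m1))
  expect_equal(n_masked(m2), 1L)
  # out of bounds is fatal and names the transcript
  expect_error(apply_mask(ref, data.frame(transcript_id = "Lys-TTT-3-1",
                                          position = 76L)),
               "Lys-TTT-3-1")
})

test_that("write/read round-trips the reference including the mask", {
  ref <- make_ref(c("Lys-TTT-3-1", "Val-TAC-2-1"),
                  c("ACGTACGTACGTACGTACGTCCA", "GGCAGGCAGGCAGGCAGGCACCA"))
  ref <- apply_mask(ref, data.frame(
    transcript_id = c("Lys-TTT-3-1", "Lys-TTT-3-1", "Val-TAC-2-1"),
    position = c(3L, 10L, 5L)))
  path <- tempfile(fileext = ".fasta")
  write_reference(ref, path)
  back <- read_reference(path)
  expect_identical(back$transcripts$seq, ref$transcripts$seq)
  expect_identical(back$transcripts$id, ref$transcripts$id)
  expect_identical(back$mask, ref$mask)
  expect_identical(masked_sequences(back), masked_sequences(ref))
  # sidecar lists exactly the masked positions
  side <- read.table(paste0(path, ".masked_positions.tsv"), header = TRUE,
                     sep = "\t")
  expect_equal(nrow(side), 3L)
  # deterministic serialization: two writes are byte-identical
  path2 <- tempfile(fileext = ".fasta")
  write_reference(ref, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("duplicate ids across main and spike-in files are fatal", {
  fa <- write_fasta_fixture("Lys-TTT-3-1", "ACGTACGTACGTACGTACGTCCA")
  spk <- write_fasta_fixture("Lys-TTT-3-1", "GGCAGGCAGGCAGGCAGGCACCA")
  expect_error(load_reference(fa, spk), "duplicate")
})

test_that("spike-ins are appended and flagged", {
  fa <- write_fasta_fixture("Lys-TTT-3-1", "ACGTACGTACGTACGTACGTCCA")
  spk <- write_fasta_fixture("Ecoli-Lys-control",
                             "GGCAGGCAGGCAGGCAGGCACCA")
  ref <- load_reference(fa, spk)
  expect_equal(sum(ref$transcripts$is_spike_in), 1L)
  expect_true("Ecoli-Lys-control" %in% ref$transcripts$id)
})
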