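quant_fixture <- function() {
  tseq <- paste0(strrep("ACGT", 18), "TCCA")  # 76 nt
  oseq <- paste0(strrep("GGCA", 18), "TCCA")
  ref <- make_ref(c("Lys-TTT-3-1", "Val-TAC-2-1"), c(tseq, oseq))
  cca <- substr(tseq, 1, 76)
  cc <- substr(tseq, 1, 75)
  short <- substr(tseq, 1, 60)
  ocva <- substr(oseq, 1, 76)
  reads <- make_reads(c(rep(cca, 75), rep(cc, 25), rep(short, 10),
                        rep(ocva, 40)),
                      umi = c(sprintf("AAAAAAAA%02d", c(seq_len(100),
                                                        seq_len(10))),
                              sprintf("CCCCCCCC%02d", seq_len(40))))
  ann <- align_all(reads, ref, scoring_scheme(), keep_alignments = FALSE)
  list(ref = ref, reads = reads, ann = ann)
}

test_that("charge is CCA / (CCA + CC) on raw counts, per level", {
  fx <- quant_fixture()
  ch <- charge_table(fx$ann, "transcript", fx$ref)
  lys <- ch[ch$group_id == "Lys-TTT-3-1", ]
  expect_equal(lys$n_cca, 75L)
  expect_equal(lys$n_cc, 25L)
  expect_equal(lys$charge_pct, 75)
  # `other`-ended reads are in neither numerator nor denominator
  expect_equal(lys$n_cca + lys$n_cc, 100L)
  val <- ch[ch$group_id == "Val-TAC-2-1", ]
  expect_equal(val$charge_pct, 100)
  # 0 CCA + 40 CC gives 0%
  ref1 <- make_ref("Gly-GCC-1-1", paste0(strrep("TGCA", 15), "CCA"))
  cc_only <- make_reads(rep(substr(ref1$transcripts$seq, 1, 62), 40))
  ann1 <- align_all(cc_only, ref1, scoring_scheme())
  expect_equal(charge_table(ann1, "transcript")$charge_pct, 0)
  expect_error(charge_table(fx$ann, "codon"), "unknown level")
})

test_that("anticodon and amino-acid levels group and filter correctly", {
  core <- strrep("GATTACAG", 6)
  ref <- make_ref(c("Gly-GCC-1-1", "Gly-GCC-2-1"),
                  c(paste0("AAAA", core, "CCA"),
                    paste0("GGGG", core, "CCA")))
  # read from the shared region: tied transcripts, same anticodon
  reads <- make_reads(c(paste0(core, "CCA"), paste0("AAAA", core, "CCA")))
  ann <- align_all(reads, ref, scoring_scheme())
  expect_false(ann$unique_transcript[1])
  tr_tab <- charge_table(ann, "transcript")
  ac_tab <- charge_table(ann, "anticodon")
  expect_equal(sum(tr_tab$n_cca + tr_tab$n_cc), 1L)  # only the unique read
  expect_equal(sum(ac_tab$n_cca + ac_tab$n_cc), 2L)  # both pass at codon level
  expect_equal(ac_tab$group_id, "GCC")
})

test_that("UMI collapsing counts identical (sequence, UMI) once", {
  reads <- make_reads(c("ACGTACGT", "ACGTACGT", "ACGTACGT", "TTTTACGT"),
                      umi = c("AAAAAAAAAA", "AAAAAAAAAA", "CCCCCCCCCC",
                              "AAAAAAAAAA"))
  col <- umi_collapse(reads)
  expect_equal(nrow(col), 3L)  # same seq+UMI collapsed; different UMI kept
  expect_identical(umi_collapse(col), col)  # idempotent
})

test_that("RPM sums to 1e6 and excludes spike-ins from normalization", {
  fx <- quant_fixture()
  rpm <- rpm_table(fx$ann, fx$reads, "transcript", fx$ref)
  expect_equal(sum(rpm$rpm), 1e6, tolerance = 1e-9)
  # single-transcript sample: rpm = 1e6
  ref1 <- make_ref("Gly-GCC-1-1", paste0(strrep("TGCA", 15), "CCA"))
  r1 <- make_reads(rep(substr(ref1$transcripts$seq, 1, 61), 3),
                   umi = c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"))
  a1 <- align_all(r1, ref1, scoring_scheme())
  expect_equal(rpm_table(a1, r1, "transcript")$rpm, 1e6)
  # spike-ins: excluded from the table, reported via spike_in_qc
  spk_ref <- make_ref(c("Gly-GCC-1-1", "spike-ctrl-1-1"),
                      c(paste0(strrep("TGCA", 15), "CCA"),
                        paste0(strrep("CTAG", 15), "CCA")))
  spk_ref$transcripts$is_spike_in <-
    spk_ref$transcripts$id == "spike-ctrl-1-1"
  reads <- make_reads(c(rep(paste0(strrep("TGCA", 15), "CCA"), 4),
                        rep(paste0(strrep("CTAG", 15), "CCA"), 2),
                        substr(paste0(strrep("CTAG", 15), "CCA"), 1, 62)),
                      umi = sprintf("AAAAAAAA%02d", 1:7))
  ann <- align_all(reads, spk_ref, scoring_scheme())
  rpm2 <- rpm_table(ann, reads, "transcript", spk_ref)
  expect_equal(rpm2$group_id, "Gly-GCC-1-1")
  expect_equal(rpm2$rpm, 1e6)
  qc <- spike_in_qc(ann, spk_ref)
  expect_equal(qc$group_id, "spike-ctrl-1-1")
  expect_equal(qc$n_cca, 2L)
  expect_equal(qc$n_cc, 1L)
})

test_that("charge is stable under subsampling in expectation", {
  fx <- quant_fixture()
  full <- charge_table(fx$ann, "transcript",
                       fx$ref)[1, "charge_pct"]
  sub_vals <- withr::with_seed(9, vapply(1:200, function(i) {
    idx <- sample(nrow(fx$ann), 100)
    charge_table(fx$ann[idx, ], "transcript",
                 fx$ref)[1, "charge_pct"]
  }, numeric(1)))
  expect_lt(abs(mean(sub_vals) - full), 1)
})

test_that("UMI occupancy expectations match enumeration and limits", {
  # printed formula: n = 1 gives 1 for any k
  expect_equal(expected_unique_umis(1, 7), 1)
  expect_equal(expected_unique_umis(0, 7), 0)
  # n = k: printed and standard formulas coincide; verified by exhaustive
  # enumeration of all 4^4 UMI assignments
  enum <- oracle_expected_unique(4, 4)
  expect_equal(enum, 2.734375)
  expect_equal(expected_unique_umis(4, 4), enum)
  expect_equal(expected_unique_umis_standard(4, 4), enum)
  # k -> infinity at fixed n: printed formula tends to n
  expect_equal(expected_unique_umis(10, 1e9), 10, tolerance = 1e-6)
  # the two formulas differ away from n = k (surfaced in QC, not hidden)
  expect_false(isTRUE(all.equal(expected_unique_umis(100, 10),
                                expected_unique_umis_standard(100, 10))))
})

test_that("UMI design space sizes", {
  expect_equal(umi_space_size("NNNNNNNNNN"), 4^10)
  expect_equal(umi_space_size("RNNNNNNNNN"), 524288)
  expect_equal(umi_space_size("ACGT"), 1)
  expect_error(umi_space_size("AXGT"), "unknown")
})

test_that("umi_qc reports observed and both expectations", {
  reads <- make_reads(rep("ACGTACGT", 5),
                      umi = c("AAAAAAAAAA", "AAAAAAAAAA", "CCCCCCCCCC",
                              "GGGGGGGGGG", "TTTTTTTTTT"))
  qc <- umi_qc(reads)
  expect_equal(qc$n, 5L)
  expect_equal(qc$k, 524288)
  expect_equal(qc$observed_unique, 4L)
  expect_equal(qc$expected_printed, expected_unique_umis(5, 524288))
  expect_equal(qc$expected_standard,
               expected_unique_umis_standard(5, 524288))
})
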