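test_that("mismatch frequencies: ratios, eligibility floors, NA below them", {
  tseq <- paste0(strrep("ACGT", 10), "TCA")  # 43 nt, ends TCA; fix to CCA
  tseq <- paste0(strrep("ACGT", 10), "CCA")
  ref <- make_ref("Lys-TTT-3-1", tseq)
  full <- tseq
  mut <- full
  substr(mut, 34, 34) <- "G"  # reference has C at 34
  trunc <- substring(full, 11)  # misses positions 1..10
  reads <- make_reads(c(rep(full, 60), rep(mut, 30), rep(trunc, 60)))
  ann <- align_all(reads, ref, scoring_scheme())
  fr <- mismatch_frequencies(ann, ref, unique_anno = TRUE,
                             min_transcript_obs = 100L, min_pos_obs = 100L)
  at34 <- fr[fr$position_1based == 34, ]
  expect_equal(at34$observations, 150)
  expect_equal(at34$mismatch_fraction, 30 / 150)
  # positions 1..10 have 90 observations (< 100): ineligible, NA fraction
  at5 <- fr[fr$position_1based == 5, ]
  expect_equal(at5$observations, 90)
  expect_false(at5$eligible)
  expect_true(is.na(at5$mismatch_fraction))
  # with a 200-transcript floor the whole transcript (150 reads) drops out
  fr2 <- mismatch_frequencies(ann, ref, unique_anno = TRUE,
                              min_transcript_obs = 200L,
                              min_pos_obs = 100L)
  expect_false(any(fr2$eligible))
})

test_that("build_mask selects exactly the positions at or above threshold", {
  fr <- data.frame(transcript_id = "t", position = 0:2,
                   position_1based = 1:3, ref_base = "A",
                   observations = 200, mismatches = c(10, 50, 120),
                   eligible = TRUE,
                   mismatch_fraction = c(0.05, 0.25, 0.60))
  expect_equal(nrow(build_mask(fr, 0.2)), 2L)
  expect_equal(build_mask(fr, 0.2)$position, 1:2)
  expect_equal(nrow(build_mask(fr, 1.01)), 0L)  # impossible threshold
})

test_that("planted high-mismatch sites are recovered by one iteration", {
  fx <- ambiguity_fixture()
  planted <- fx$mods[fx$mods$sub_prob >= 0.4, ]
  mref <- iterate_masking(fx$reads, fx$ref,
                          masking_params(unique_anno = TRUE,
                                         min_mut_freq = 0.3,
                                         frac_max_score = 1.0,
                                         iterations = 1L),
                          scoring_scheme())
  mt <- mask_table(mref)
  got <- paste(mt$transcript_id, mt$position_1based)
  want <- paste(planted$transcript_id, planted$position_1based)
  expect_gte(sum(want %in% got), ceiling(0.9 * length(want)))
})

test_that("mask sharing maps positions to similar low-coverage acceptors", {
  withr::with_seed(5, {
    donor <- paste0(paste(sample(c("A", "C", "G", "T"), 70,
                                 replace = TRUE), collapse = ""), "CCA")
  })
  acc <- strsplit(donor, "")[[1]]
  acc[c(10, 30, 60)] <- vapply(acc[c(10, 30, 60)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  ref <- make_ref(c("Gly-GCC-1-1", "Gly-GCC-2-1"),
                  c(donor, paste(acc, collapse = "")))
  # donor masked at 0-based 40 (a base shared by both); acceptor unseen
  mask <- data.frame(transcript_id = "Gly-GCC-1-1", position = 40L)
  freqs <- data.frame(transcript_id = "Gly-GCC-1-1", position = 0:72,
                      observations = 500)
  shared <- share_mask(mask, ref, freqs, frac_max_score = 0.8)
  expect_true(any(shared$transcript_id == "Gly-GCC-2-1" &
                    shared$position == 40L & shared$source == "shared"))
  # superset property
  expect_true(all(paste(mask$transcript_id, mask$position) %in%
                    paste(shared$transcript_id, shared$position)))
  # an acceptor position with >= 100 observations never receives a mask
  freqs2 <- rbind(freqs, data.frame(transcript_id = "Gly-GCC-2-1",
                                    position = 0:72, observations = 150))
  shared2 <- share_mask(mask, ref, freqs2, frac_max_score = 0.8)
  expect_false(any(shared2$source == "shared"))
  # frac_max_score = 1 with non-identical transcripts: nothing shared
  shared3 <- share_mask(mask, ref, freqs, frac_max_score = 1.0)
  expect_false(any(shared3$source == "shared"))
})

test_that("iterations compose, accumulate monotonically and reach a fixed point", {
  fx <- ambiguity_fixture(n_family = 300L, n_single = 250L)
  p1 <- masking_params(min_mut_freq = 0.3, frac_max_score = 1.0,
                       iterations = 1L)
  p2 <- masking_params(min_mut_freq = 0.3, frac_max_score = 1.0,
                       iterations = 2L)
  # iterations = 0 leaves the reference unmasked
  r0 <- iterate_masking(fx$reads, fx$ref,
                        masking_params(iterations = 0L))
  expect_equal(n_masked(r0), 0L)
  r1 <- iterate_masking(fx$reads, fx$ref, p1)
  r1b <- iterate_masking(fx$reads, r1, p1)
  r2 <- iterate_masking(fx$reads, fx$ref, p2)
  expect_identical(r2$mask, r1b$mask)  # two rounds == one 2-iteration run
  # monotone accumulation
  expect_true(all(paste(mask_table(r1)$transcript_id,
                        mask_table(r1)$position_1based) %in%
                    paste(mask_table(r2)$transcript_id,
                          mask_table(r2)$position_1based)))
  # fixed point: once the mask stops growing, iterations are no-ops
  r4 <- iterate_masking(fx$reads, fx$ref,
                        masking_params(min_mut_freq = 0.3,
                                       frac_max_score = 1.0,
                                       iterations = 4L))
  hist <- attr(r4, "history")
  expect_equal(hist$n_masked[4], hist$n_masked[3])
})

test_that("grid search lowers multi-anticodon assignment without hurting mapping", {
  fx <- ambiguity_fixture()
  gs <- grid_search_masking(fx$reads, fx$ref,
                            grid = list(min_mut_freq = c(0.3, 1.01),
                                        iterations = 1L),
                            min_transcript_obs = 200L, min_pos_obs = 100L)
  tab <- gs$table
  no_mask <- tab[tab$min_mut_freq > 1, ]
  best <- min(tab$objective_pct)
  expect_equal(no_mask$n_masked, 0L)
  expect_lt(best, no_mask$objective_pct)     # strictly reduced
  expect_equal(gs$best$min_mut_freq, 0.3)
  # no trade-off: mapping success never drops under the chosen mask
  expect_gte(tab$mapped_pct[tab$min_mut_freq == 0.3],
             no_mask$mapped_pct)
  # the masked reference resolves most of the planted ties
  ann <- align_all(fx$reads, gs$ref, scoring_scheme(),
                   keep_alignments = FALSE)
  expect_lt(multi_anticodon_pct(ann), no_mask$objective_pct / 2)
})

test_that("grid search degenerate cases", {
  fx <- ambiguity_fixture(n_family = 120L, n_single = 60L)
  one <- grid_search_masking(fx$reads, fx$ref,
                             grid = list(min_mut_freq = 1.01,
                                         iterations = 1L))
  expect_equal(nrow(one$table), 1L)
  expect_equal(one$best$min_mut_freq, 1.01)
  expect_error(grid_search_masking(fx$reads, fx$ref, grid = list()),
               "empty")
  # objective is 0 when every mapped read has a unique anticodon
  single_ref <- make_ref("Lys-TTT-3-1", paste0(strrep("ACGT", 15), "CCA"))
  reads <- make_reads(rep(paste0(strrep("ACGT", 15), "CCA"), 5))
  ann <- align_all(reads, single_ref, scoring_scheme())
  expect_equal(multi_anticodon_pct(ann), 0)
})

test_that("masking objective is invariant to read order", {
  fx <- ambiguity_fixture(n_family = 150L, n_single = 80L)
  ann1 <- align_all(fx$reads, fx$ref, scoring_scheme(),
                    keep_alignments = FALSE)
  perm <- withr::with_seed(3, sample(nrow(fx$reads)))
  ann2 <- align_all(fx$reads[perm, ], fx$ref, scoring_scheme(),
                    keep_alignments = FALSE)
  expect_equal(multi_anticodon_pct(ann1), multi_anticodon_pct(ann2))
})
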