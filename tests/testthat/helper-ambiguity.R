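# A transcript pair differing at two sites (d = 21, h = 41, 1-based) with a
# "modification" at h driving misincorporation: reads whose h base is
# misread as the sister transcript's base tie across both anticodons, and
# masking h resolves them.
ambiguity_fixture <- function(n_family = 500L, n_single = 300L, seed = 11) {
  withr::with_seed(seed, {
    base <- paste0(paste(sample(c("A", "C", "G", "T"), 73, replace = TRUE),
                         collapse = ""), "CCA")
    a <- strsplit(base, "")[[1]]
    b <- a
    b[21] <- setdiff(c("A", "C", "G", "T"), a[21])[1]
    b[41] <- setdiff(c("A", "C", "G", "T"), a[41])[1]
    singles <- replicate(5, paste0(paste(sample(c("A", "C", "G", "T"), 73,
                                                replace = TRUE),
                                         collapse = ""), "CCA"))
  })
  ids <- c("Glu-TTC-1-1", "Glu-CTC-1-1", sprintf("Ala-AG%s-%d-1",
                                                 c("A", "C", "G", "T", "N"),
                                                 3:7))
  ref <- make_ref(ids, c(base, paste(b, collapse = ""), singles),
                  anticodons = c("TTC", "CTC", "AGA", "AGC", "AGG", "AGT",
                                 "AGN"),
                  amino_acids = c("Glu", "Glu", rep("Ala", 5)))
  mods <- rbind(
    data.frame(transcript_id = c("Glu-TTC-1-1", "Glu-CTC-1-1"),
               position_1based = 41L, sub_prob = 0.6, gap_prob = 0,
               stop_prob = 0),
    data.frame(transcript_id = rep(sprintf("Ala-AG%s-%d-1",
                                           c("A", "C", "G", "T", "N"), 3:7),
                                   each = 2L),
               position_1based = rep(c(25L, 50L), 5L), sub_prob = 0.5,
               gap_prob = 0, stop_prob = 0))
  n_reads <- setNames(ifelse(grepl("Glu", ref$transcripts$id), n_family,
                             n_single), ref$transcripts$id)
  sim <- sim_reads(ref, charge = 0.9, n_reads = n_reads, mods = mods,
                   barcode = NULL, seed = seed + 1L)
  list(ref = ref, reads = sim$reads, truth = sim$truth, mods = mods)
}
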