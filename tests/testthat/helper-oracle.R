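# Independent alignment oracle: exhaustive affine-gap local DP that, unlike
# the production Gotoh implementation, maximizes explicitly over all gap
# lengths at every cell (O(n*m*(n+m))). Gap of length g costs
# open + (g-1)*ext. Returns the optimal score only.
oracle_sw_score <- function(query, ref, match = 1, mismatch = -3,
                            n_score = 0, open = 6, ext = 3) {
  qc <- strsplit(query, "")[[1]]
  rc <- strsplit(ref, "")[[1]]
  n <- length(qc); m <- length(rc)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (rc[j - 1L] == "N") n_score
        else if (qc[i - 1L] == rc[j - 1L]) match else mismatch
      cand <- H[i - 1L, j - 1L] + s
      gu <- seq_len(i - 1L)  # gap in ref direction (query consumed)
      up <- max(H[i - gu, j] - (open + (gu - 1L) * ext))
      gl <- seq_len(j - 1L)  # gap in query direction (ref consumed)
      left <- max(H[i, j - gl] - (open + (gl - 1L) * ext))
      H[i, j] <- max(0, cand, up, left)
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

oracle_sw_scheme <- function(query, ref, scheme) {
  oracle_sw_score(query, ref, scheme$match, scheme$mismatch, scheme$n_score,
                  scheme$gap_open, scheme$gap_extend)
}

# Exhaustive expectation of the number of distinct values when n draws are
# made uniformly from k values; enumerates all k^n assignments.
oracle_expected_unique <- function(n, k) {
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  mean(apply(grid, 1L, function(x) length(unique(x))))
}

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# Random (read, transcript) pair: half fully random, half a substring of
# the transcript with planted substitutions (realistic high-score case),
# optionally with masked reference positions.
random_pair <- function(max_read = 40L, max_ref = 90L, related = FALSE,
                        mask_n = 0L) {
  ref <- random_seq(sample(20:max_ref, 1L))
  if (related) {
    L <- nchar(ref)
    rl <- sample(10:min(max_read, L), 1L)
    st <- sample(seq_len(L - rl + 1L), 1L)
    q <- strsplit(substring(ref, st, st + rl - 1L), "")[[1]]
    nerr <- sample(0:3, 1L)
    for (p in sample(seq_along(q), min(nerr, length(q))))
      q[p] <- sample(c("A", "C", "G", "T"), 1L)
    query <- paste(q, collapse = "")
  } else {
    query <- random_seq(sample(5:max_read, 1L))
  }
  if (mask_n > 0L) {
    rc <- strsplit(ref, "")[[1]]
    rc[sample(seq_along(rc), min(mask_n, length(rc)))] <- "N"
    ref <- paste(rc, collapse = "")
  }
  list(query = query, ref = ref)
}
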