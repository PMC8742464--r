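# Shared fixtures and independent oracles used across test files.
# All fixtures are built in code; nothing is read from disk.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# a 100-bp toy genome: gene [10,40) with intron [20,30), tRNA [60,65)
toy_genome <- function() {
  set.seed(42)
  feats <- rbind(
    genome_feature("gene", "g1", 10, 40),
    genome_feature("intron", "g1i10g2", 20, 30, parent = "g1",
                   class_token = "g2"),
    genome_feature("tRNA", "trnX", 60, 65))
  annotated_genome("toy", random_dna(100), feats, circular = TRUE)
}

# ---- independent brute-force tandem-repeat oracle -------------------------
# Enumerates every (start, period, copies) block, scores it against the
# column consensus by direct tabulation, then applies the same canonical
# greedy selection (score desc, leftmost, fewest copies; non-overlapping
# within a period) that defines the reported set.
oracle_tandem <- function(seq, min_period, max_period, threshold,
                          mismatch_allowed = FALSE) {
  v <- strsplit(seq, "")[[1]]
  L <- length(v)
  out <- list()
  for (p in min_period:max_period) {
    if (2 * p > L) next
    cands <- list()
    for (a in 0:(L - 2 * p)) {
      kmax <- (L - a) %/% p
      if (kmax < 2) next
      for (k in 2:kmax) {
        block <- matrix(v[a + seq_len(k * p)], nrow = k, byrow = TRUE)
        sm <- sum(apply(block, 2, function(col) max(table(col))))
        score <- 2L * sm - k * p
        if (!mismatch_allowed && sm < k * p) next
        if (score >= threshold) {
          cands[[length(cands) + 1L]] <- c(a, p, k, score)
        }
      }
    }
    if (!length(cands)) next
    m <- do.call(rbind, cands)
    m <- m[order(-m[, 4], m[, 1], m[, 3]), , drop = FALSE]
    taken <- matrix(numeric(0), ncol = 2)
    for (i in seq_len(nrow(m))) {
      s <- m[i, 1]; e <- m[i, 1] + m[i, 3] * m[i, 2]
      if (nrow(taken) == 0L || all(e <= taken[, 1] | taken[, 2] <= s)) {
        taken <- rbind(taken, c(s, e))
        out[[length(out) + 1L]] <- m[i, ]
      }
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), period = integer(),
                      copies = integer(), score = integer()))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("start", "period", "copies", "score")
  df[order(df$start, df$period), ]
}

# all binary strings of length n over the given alphabet
all_strings <- function(n, alphabet = c("A", "T")) {
  grid <- do.call(expand.grid, rep(list(alphabet), n))
  apply(grid, 1, paste, collapse = "")
}

# ---- Smith-Waterman oracle (Biostrings) -----------------------------------
# Under the package's scheme a length-k gap costs open + k * extend,
# which is Biostrings' gapOpening/gapExtension convention.
oracle_sw_score <- function(a, b, match = 1, mismatch = -2,
                            gap_open = 5, gap_extend = 2) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "local",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  Biostrings::score(aln)
}

mutate_dna <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) chars[i] <- sample(setdiff(c("A", "C", "G", "T"),
                                            chars[i]), 1)
  paste(chars, collapse = "")
}
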