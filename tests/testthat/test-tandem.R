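test_that("perfect triplet repeat is found with the hand-computed score", {
  reps <- find_tandem_repeats("ACGACGACGACG", min_period = 3,
                              max_period = 3, threshold = 6)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$start, 0)
  expect_equal(reps$copies, 4)
  expect_equal(reps$span, 12)
  expect_equal(reps$score, 12)   # 12 matches, 0 mismatches
  expect_identical(reps$unit, "ACG")
})

test_that("one mismatching copy scores matches minus mismatches", {
  reps <- find_tandem_repeats("ACGTACGTACCT", min_period = 4,
                              max_period = 4, threshold = 6,
                              mismatch_allowed = TRUE)
  expect_equal(nrow(reps), 1)
  expect_equal(reps$copies, 3)
  expect_equal(reps$score, 10)   # 11 matches - 1 mismatch
  expect_equal(reps$mismatches, 1)
  expect_identical(reps$unit, "ACGT")
  # without mismatches only the two perfect copies remain
  reps2 <- find_tandem_repeats("ACGTACGTACCT", min_period = 4,
                               max_period = 4, threshold = 6,
                               mismatch_allowed = FALSE)
  expect_equal(reps2$copies, 2)
  expect_equal(reps2$score, 8)
})

test_that("structureless sequence yields no repeats above threshold", {
  set.seed(77)
  s <- random_dna(50)
  reps <- find_tandem_repeats(s, min_period = 2, max_period = 10,
                              threshold = 10, mismatch_allowed = FALSE)
  expect_equal(nrow(reps), 0)
  expect_error(find_tandem_repeats(s, min_period = 1), "min_period")
  expect_warning(find_tandem_repeats("ACG", min_period = 2,
                                     max_period = 4), "shorter")
})

test_that("detection equals the brute-force consensus oracle", {
  # exhaustive over all 2-letter strings of length 8, both modes
  for (s in all_strings(8)) {
    got <- find_tandem_repeats(s, 2, 4, threshold = 4,
                               mismatch_allowed = TRUE)
    want <- oracle_tandem(s, 2, 4, threshold = 4, mismatch_allowed = TRUE)
    expect_equal(as.data.frame(got[, c("start", "period", "copies",
                                       "score")]),
                 want, ignore_attr = TRUE, info = s)
  }
  # sampled longer 4-letter strings
  set.seed(123)
  for (rep in 1:150) {
    s <- random_dna(sample(12:20, 1))
    ma <- sample(c(TRUE, FALSE), 1)
    got <- find_tandem_repeats(s, 2, 6, threshold = 5,
                               mismatch_allowed = ma)
    want <- oracle_tandem(s, 2, 6, threshold = 5, mismatch_allowed = ma)
    expect_equal(as.data.frame(got[, c("start", "period", "copies",
                                       "score")]),
                 want, ignore_attr = TRUE, info = s)
  }
})

test_that("planted repeats are recovered at the same loci after rotation", {
  sim <- simulate_mitogenome(sim_config(seed = 21))
  g <- sim$genome
  L <- genome_length(g)
  r <- 5000L
  gr <- rotate_genome(g, r)
  reps <- dedupe_repeats(find_tandem_repeats(g))
  reps_r <- dedupe_repeats(find_tandem_repeats(gr))
  truth <- sim$truth$repeats
  found_at <- function(reps, start, period, L) {
    any(reps$period == period &
          circular_distance(reps$start, start, L) <= period)
  }
  for (k in seq_len(nrow(truth))) {
    expect_true(found_at(reps, truth$start[k], truth$period[k], L))
    expect_true(found_at(reps_r, (truth$start[k] - r) %% L,
                         truth$period[k], L))
  }
})

test_that("binning and density follow the definitions", {
  sim <- simulate_mitogenome(sim_config(seed = 8))
  part <- partition_regions(sim$genome)
  reps <- dedupe_repeats(find_tandem_repeats(sim$genome, partition = part))
  tab <- bin_repeats(reps)
  truth_bins <- table(cut(sim$truth$repeats$period,
                          c(1, 100, 200, 300, 400, 500),
                          labels = c("2-100", "101-200", "201-300",
                                     "301-400", "401-500")))
  expect_equal(as.vector(rowSums(tab)[names(truth_bins)]),
               as.vector(truth_bins))
  # all planted repeats sit in the intergenic LIR
  expect_true(all(reps$region_class == "intergenic"))
  d <- repeat_density(reps, part, "lir")
  expect_equal(d$count, nrow(reps))
  expect_equal(d$density, 1000 * d$count / (part$lir[2] - part$lir[1]))
  # direct arithmetic case: 5 repeats in a 2000-bp scope is 2.5/kbp
  expect_equal(1000 * 5 / 2000, 2.5)
  dg <- repeat_density(reps, scope = "genome")
  expect_equal(dg$length_bp, genome_length(sim$genome))
})

test_that("dedupe keeps the best-scoring repeat per overlap cluster", {
  # AAAA...: period 2 and period 3 reports overlap; after dedupe one stays
  s <- strrep("AT", 12)
  reps <- find_tandem_repeats(s, 2, 6, threshold = 6)
  expect_gt(nrow(reps), 1)
  dd <- dedupe_repeats(reps)
  expect_equal(nrow(dd), 1)
  expect_equal(dd$period, 2)
})
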