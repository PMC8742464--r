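test_that("gc_content matches hand counts and excludes N", {
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("GATTACA"), 2 / 7)
  expect_equal(gc_content("GCNNNN"), 1.0)
  expect_error(gc_content("NNN"), "unambiguous")
  g <- toy_genome()
  part <- partition_regions(g)
  # class-restricted GC equals GC of the extracted class positions
  pos <- which(REGION_CLASSES[part$labels] == "intergenic")
  manual <- gc_content(paste(strsplit(g$sequence, "")[[1]][pos],
                             collapse = ""))
  expect_equal(gc_content(g, region = "intergenic", partition = part),
               manual)
})

test_that("windowed skew reproduces single-window values and wraps", {
  expect_equal(windowed_gc_skew("GGGGGG", w = 6, s = 6)$skew, 1)
  expect_equal(windowed_gc_skew("CCCCCC", w = 6, s = 6)$skew, -1)
  expect_equal(windowed_gc_skew("GGGGCC", w = 6, s = 6)$skew, 1 / 3)
  # AT-only windows are flagged and contribute zero
  p <- windowed_gc_skew("ATATAT", w = 6, s = 6)
  expect_equal(p$skew, 0)
  expect_true(all(p$flagged_empty))
  # profile length on a circle is ceil(L/s) and windows wrap
  set.seed(10)
  s <- random_dna(103)
  p2 <- windowed_gc_skew(s, w = 20, s = 10)
  expect_length(p2$skew, ceiling(103 / 10))
  wrapped <- circular_subseq(s, 100, 120, TRUE)
  expect_equal(p2$skew[11],
               (sum(strsplit(wrapped, "")[[1]] == "G") -
                  sum(strsplit(wrapped, "")[[1]] == "C")) /
                 (sum(strsplit(wrapped, "")[[1]] %in% c("G", "C"))))
})

test_that("cumulative series is the prefix sum with extrema as stated", {
  prof <- structure(list(positions = 0:3, skew = c(1, 1, -1, -1),
                         flagged_empty = rep(FALSE, 4), w = 1L, s = 1L,
                         L = 4L, circular = TRUE, id = "t", gc = 0.5),
                    class = "skew_profile")
  pk <- cumulative_skew_and_peaks(prof)
  expect_equal(pk$cumulative, c(1, 2, 1, 0))
  expect_equal(which.max(pk$cumulative), 2)
  expect_equal(which.min(pk$cumulative), 4)
  # constant-zero skew reports no signal
  prof0 <- structure(list(positions = 0:3, skew = rep(0, 4),
                          flagged_empty = rep(TRUE, 4), w = 1L, s = 1L,
                          L = 4L, circular = TRUE, id = "t", gc = 0),
                     class = "skew_profile")
  expect_true(cumulative_skew_and_peaks(prof0)$no_signal)
})

test_that("skew is rotation-covariant and the origin maps to the same locus", {
  sim <- simulate_mitogenome(sim_config(seed = 31))
  g <- sim$genome
  L <- genome_length(g)
  s_step <- 25L
  r <- 400L * s_step          # rotation on the window grid
  prof <- windowed_gc_skew(g, 1000, s_step)
  prof_r <- windowed_gc_skew(rotate_genome(g, r), 1000, s_step)
  n <- length(prof$skew)
  shift <- r / s_step
  expect_equal(prof_r$skew, prof$skew[((seq_len(n) - 1 + shift) %% n) + 1])
  pk <- cumulative_skew_and_peaks(prof)
  pk_r <- cumulative_skew_and_peaks(prof_r)
  expect_equal((pk_r$origin_pred + r) %% L, pk$origin_pred)
  expect_equal((pk_r$terminus_pred + r) %% L, pk$terminus_pred)
})

test_that("reverse complement negates skew; predictions are strand-invariant", {
  sim <- simulate_mitogenome(sim_config(seed = 32))
  g <- sim$genome
  L <- genome_length(g)
  w <- 1000L; s_step <- 25L
  prof <- windowed_gc_skew(g, w, s_step)
  prof_rc <- windowed_gc_skew(revcomp_genome(g), w, s_step)
  # window [t, t+w) of the reverse complement covers [L-t-w, L-t)
  map <- ((L - prof_rc$positions - w) %% L) / s_step + 1
  expect_equal(prof_rc$skew, -prof$skew[map])
  # negation and coordinate reversal compose so that the detrended
  # cumulative series satisfies d_rc(i) = d(n - i): extrema keep their
  # roles and map to the same physical loci (a replication origin does
  # not move when the genome is read from the other strand)
  pk <- cumulative_skew_and_peaks(prof)
  pk_rc <- cumulative_skew_and_peaks(prof_rc)
  expect_lt(circular_distance((L - pk_rc$origin_pred - w) %% L,
                              pk$origin_pred, L), 2 * w)
  expect_lt(circular_distance((L - pk_rc$terminus_pred - w) %% L,
                              pk$terminus_pred, L), 2 * w)
})

test_that("non-overlapping window skews recombine to the genome-wide G-C", {
  set.seed(12)
  s <- random_dna(5000, gc = 0.3)
  prof <- windowed_gc_skew(s, w = 100, s = 100)
  b <- strsplit(s, "")[[1]]
  gmc <- sum(b == "G") - sum(b == "C")
  gpc_w <- vapply(prof$positions, function(t) {
    win <- strsplit(circular_subseq(s, t, t + 100, TRUE), "")[[1]]
    sum(win %in% c("G", "C"))
  }, numeric(1))
  expect_equal(sum(prof$skew * gpc_w), gmc)
})

test_that("planted origin is recovered within two window steps", {
  errs <- vapply(41:46, function(seed) {
    sim <- simulate_mitogenome(sim_config(seed = seed))
    prof <- windowed_gc_skew(sim$genome)
    pk <- cumulative_skew_and_peaks(prof)
    circular_distance(pk$origin_pred, sim$truth$ori_pos,
                      genome_length(sim$genome))
  }, numeric(1))
  expect_lte(median(errs), 0.02 * 40000)
})
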