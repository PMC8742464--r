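test_that("contexts are cut at the literal splice sites", {
  # exon(12) | intron GT...AG (14) | exon(12), plus strand
  left <- "AAAAAAAAAAAA"
  intr <- "GTCCCCCCCCCCAG"
  right <- "TTTTTTTTTTTT"
  seqs <- paste0(left, intr, right)
  feats <- rbind(
    genome_feature("gene", "g", 0, nchar(seqs)),
    genome_feature("CDS", "g",
                   segments = rbind(c(0, 12), c(26, 38))),
    genome_feature("intron", "gi12g2", 12, 26, parent = "g"))
  g <- annotated_genome("x", seqs, feats, circular = FALSE)
  ctx <- extract_splice_contexts(g)
  expect_equal(nrow(ctx), 1)
  expect_identical(ctx$donor_exon, "AAAAAAAAAA")
  expect_identical(ctx$donor_intron, "GTCCC")
  expect_identical(ctx$acceptor_intron, "CCCAG")
  expect_identical(ctx$acceptor_exon, "TTTTTTTTTT")
})

test_that("minus-strand contexts equal the reverse-complemented locus", {
  set.seed(17)
  core <- paste0("GT", random_dna(30), "AG")
  plus <- paste0(random_dna(15), core, random_dna(15))
  minus_seq <- dna_revcomp(plus)
  gp <- annotated_genome("p", plus, rbind(
    genome_feature("gene", "g", 0, 64),
    genome_feature("intron", "gi15g2", 15, 49, parent = "g")),
    circular = FALSE)
  L <- nchar(plus)
  gm <- annotated_genome("m", minus_seq, rbind(
    genome_feature("gene", "g", 0, 64, strand = "-"),
    genome_feature("intron", "gi15g2", L - 49, L - 15, strand = "-",
                   parent = "g")), circular = FALSE)
  cp <- extract_splice_contexts(gp)
  cm <- extract_splice_contexts(gm)
  for (slot in c("donor_exon", "donor_intron", "acceptor_intron",
                 "acceptor_exon")) {
    expect_identical(cm[[slot]], cp[[slot]], info = slot)
  }
})

test_that("short introns are skipped with a warning", {
  g <- annotated_genome("x", strrep("ACGT", 10), rbind(
    genome_feature("gene", "g", 0, 40),
    genome_feature("intron", "gi5g2", 5, 12, parent = "g")),
    circular = FALSE)
  expect_warning(ctx <- extract_splice_contexts(g), "skipped")
  expect_equal(nrow(ctx), 0)
})

test_that("PFM equals a hand tally and frequencies are proper", {
  ctx <- c("GTAAA", "GTAAC", "GAAAA", "CTAAA")
  pfm <- build_pfm(ctx)
  expect_equal(unname(pfm$counts[, 1]), c(0, 1, 3, 0))  # A C G T
  expect_equal(unname(pfm$counts[, 2]), c(1, 0, 0, 3))
  expect_equal(unname(pfm$counts[, 5]), c(3, 1, 0, 0))
  expect_equal(colSums(pfm$counts), setNames(rep(4, 5), colnames(pfm$counts)))
  expect_true(all(abs(colSums(pfm$freq) - 1) < 1e-12))
  expect_identical(pfm$dominant$base[1], "G")
  expect_equal(pfm$dominant$freq[1], 0.75)
  # invariant column
  pfm2 <- build_pfm(rep("GTAAA", 6))
  expect_true(all(pfm2$dominant$freq == 1))
  # dominant frequency can never drop below 1/4
  expect_true(all(pfm$dominant$freq >= 0.25))
})

test_that("PFMs add count-wise over context sets", {
  sim1 <- simulate_mitogenome(sim_config(seed = 14))
  sim2 <- simulate_mitogenome(sim_config(seed = 15))
  c1 <- extract_splice_contexts(sim1$genome)
  c2 <- extract_splice_contexts(sim2$genome)
  p1 <- build_pfm(c1, "donor_intron")
  p2 <- build_pfm(c2, "donor_intron")
  pc <- build_pfm(rbind(c1, c2), "donor_intron")
  expect_equal(pc$counts, p1$counts + p2$counts)
  expect_equal(pc$counts, pfm_add(p1, p2)$counts)
})

test_that("planted GT/AG termini give invariant donor and acceptor columns", {
  sim <- simulate_mitogenome(sim_config(seed = 16))
  ctx <- extract_splice_contexts(sim$genome)
  # one context per planted intron, twintron inner included
  expect_equal(nrow(ctx), nrow(sim$truth$introns))
  don <- build_pfm(ctx, "donor_intron")
  acc <- build_pfm(ctx, "acceptor_intron")
  expect_equal(don$freq["G", 1], 1.0)
  expect_equal(don$freq["T", 2], 1.0)
  expect_equal(acc$freq["A", 4], 1.0)
  expect_equal(acc$freq["G", 5], 1.0)
})
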