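test_that("per-gene decomposition follows exon/intron arithmetic", {
  set.seed(6)
  feats <- rbind(
    genome_feature("gene", "g", 10, 410),
    genome_feature("CDS", "g", segments = rbind(c(10, 60), c(360, 410))),
    genome_feature("intron", "gi50g2", 60, 360, parent = "g"),
    genome_feature("CDS", "h", 450, 500))
  g <- annotated_genome("x", random_dna(600), feats)
  dec <- decompose_genome(g)
  pg <- dec$per_gene
  expect_equal(pg$intron_fraction[pg$gene == "g"], 300 / 400)  # 0.75
  expect_equal(pg$gene_span[pg$gene == "g"],
               pg$exon_len[pg$gene == "g"] + pg$intron_len[pg$gene == "g"])
  expect_equal(pg$intron_fraction[pg$gene == "h"], 0)
  expect_equal(dec$n_introns, 1)
})

test_that("component lengths sum to L and IEPs are counted once", {
  sim <- simulate_mitogenome(sim_config(seed = 13))
  dec <- decompose_genome(sim$genome)
  expect_equal(dec$len_cds_orf + dec$len_intron + dec$len_intergenic +
                 dec$len_rrna + dec$len_trna, dec$L)
  expect_equal(dec$n_introns, nrow(sim$truth$introns))
  expect_equal(dec$n_ieps, nrow(sim$truth$orfs))
  expect_equal(dec$n_trnas, 6)
  # the twintron's inner span is not double-counted in its host gene
  tw_host <- "cox1"
  outer <- sim$truth$introns[sim$truth$introns$host == tw_host, ]
  outer <- outer[!grepl("ii", outer$name), ]
  expect_equal(dec$per_gene$intron_len[dec$per_gene$gene == tw_host],
               sum(outer$end - outer$start))
  # decomposition is invariant under rotation
  dec_r <- decompose_genome(rotate_genome(sim$genome, 7777))
  expect_equal(dec_r$per_gene[order(dec_r$per_gene$gene), ],
               dec$per_gene[order(dec$per_gene$gene), ],
               ignore_attr = TRUE)
})

test_that("genic intron share uses coding genes by default", {
  sim <- simulate_mitogenome(sim_config(seed = 13))
  dec <- decompose_genome(sim$genome)
  pg <- dec$per_gene
  coding <- pg$kind == "coding"
  expect_equal(dec$genic_intron_fraction,
               sum(pg$intron_len[coding]) / sum(pg$gene_span[coding]))
  dec2 <- decompose_genome(sim$genome, genic_includes_rna = TRUE)
  expect_gt(dec2$genic_len, dec$genic_len)
})

test_that("correlation equals the closed-form least squares", {
  # exact linear relation (lm warns about the perfect fit; that is the point)
  panel <- data.frame(L = c(2, 4, 6, 8), len_intron = c(1, 2, 3, 4))
  r <- suppressWarnings(correlate_genome_size(panel, "len_intron"))
  expect_equal(r$r2, 1.0)
  expect_equal(r$slope, 2.0)
  # hand OLS on {(1,2),(2,3),(3,5)}: r^2 = 27/28
  panel2 <- data.frame(L = c(2, 3, 5), len_intron = c(1, 2, 3))
  r2 <- correlate_genome_size(panel2, "len_intron")
  expect_equal(r2$r2, 27 / 28, tolerance = 1e-12)
  expect_equal(round(r2$r2, 4), 0.9643)
  # closed-form check on a noisy panel
  set.seed(30)
  x <- runif(12, 10, 50)
  y <- 3 * x + 7 + rnorm(12, sd = 2)
  panel3 <- data.frame(L = y, len_intron = x)
  r3 <- correlate_genome_size(panel3, "len_intron")
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  ss_res <- sum((y - alpha - beta * x)^2)
  ss_tot <- sum((y - mean(y))^2)
  expect_equal(r3$r2, 1 - ss_res / ss_tot, tolerance = 1e-12)
  expect_equal(r3$slope, beta, tolerance = 1e-12)
  # permutation invariance
  perm <- sample(12)
  r3p <- correlate_genome_size(panel3[perm, ], "len_intron")
  expect_equal(r3p$r2, r3$r2)
  # recovered slope is within 3 SE of the generating slope
  expect_lt(abs(r3$slope - 3), 3 * r3$slope_se)
  # degenerate predictor errors out
  expect_error(correlate_genome_size(
    data.frame(L = 1:4, len_intron = rep(2, 4)), "len_intron"),
    "variance")
  expect_error(correlate_genome_size(panel2[1:2, ], "len_intron"),
               "at least 3")
})
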