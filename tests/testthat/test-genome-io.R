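test_that("annotated_genome validates sequence and features", {
  expect_error(annotated_genome("x", ""), "non-empty")
  expect_error(annotated_genome("x", "ACGR"), "ambiguity")
  expect_error(annotated_genome("x", "ACGT", genetic_code = 2), "genetic_code")
  f <- genome_feature("intron", "i1", 0, 2)
  expect_error(annotated_genome("x", "ACGTACGT", f), "parent")
  f2 <- genome_feature("CDS", "g", 5, 20)
  expect_error(annotated_genome("x", "ACGTACGT", f2, circular = FALSE),
               "past sequence end")
})

test_that("extract_feature_sequence handles strand and origin wrap", {
  g <- annotated_genome("x", "ACGTTT",
                        genome_feature("CDS", "a", 0, 4), circular = TRUE)
  expect_identical(extract_feature_sequence(g, g$features[1, ]), "ACGT")
  gm <- annotated_genome("x", "ACGTTT",
                         genome_feature("CDS", "a", 0, 4, strand = "-"))
  # reverse complement of ACGT is itself
  expect_identical(extract_feature_sequence(gm, gm$features[1, ]), "ACGT")
  # wrapped segment [L-2, L+2) on circular AACCGG
  gw <- annotated_genome("x", "AACCGG",
                         genome_feature("CDS", "a", 4, 8), circular = TRUE)
  expect_identical(extract_feature_sequence(gw, gw$features[1, ]), "GGAA")
  # independent check of the minus-strand path against Biostrings
  set.seed(1)
  s <- random_dna(50)
  gg <- annotated_genome("x", s, genome_feature("CDS", "a", 7, 31,
                                                strand = "-"))
  expect_identical(extract_feature_sequence(gg, gg$features[1, ]),
                   as.character(Biostrings::reverseComplement(
                     Biostrings::DNAString(substr(s, 8, 31)))))
})

test_that("minimal GenBank record and location grammar parse correctly", {
  path <- tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       mini 30 bp DNA circular",
    "FEATURES             Location/Qualifiers",
    "     gene            1..30",
    "                     /gene=\"g\"",
    "ORIGIN",
    paste0("        1 ", tolower(strrep("acgtaa", 5))),
    "//"), path)
  g <- read_genbank(path)
  expect_equal(genome_length(g), 30)
  expect_true(g$circular)
  expect_equal(unname(g$features$segments[[1]]), cbind(0, 30))
  expect_identical(g$features$strand[1], "+")

  # join of complements: hand-converted to two minus segments [0,5), [9,20)
  writeLines(c(
    "LOCUS       mini2 30 bp DNA linear",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(complement(10..20),complement(1..5))",
    "                     /gene=\"g\"",
    "ORIGIN",
    paste0("        1 ", tolower(strrep("acgtaa", 5))),
    "//"), path)
  g2 <- read_genbank(path)
  expect_identical(g2$features$strand[1], "-")
  expect_equal(unname(g2$features$segments[[1]]),
               rbind(c(0, 5), c(9, 20)))

  # malformed coordinates are reported with the offending content
  writeLines(c(
    "LOCUS       bad 30 bp DNA linear",
    "FEATURES             Location/Qualifiers",
    "     gene            5..90",
    "ORIGIN",
    paste0("        1 ", tolower(strrep("acgtaa", 5))),
    "//"), path)
  expect_error(read_genbank(path), "outside sequence")
})

test_that("GenBank write/read round trip preserves the annotation", {
  sim <- simulate_mitogenome(sim_config(seed = 11))
  path <- tempfile(fileext = ".gb")
  write_genbank(sim$genome, path)
  g2 <- read_genbank(path)
  expect_identical(g2$sequence, sim$genome$sequence)
  expect_equal(nrow(g2$features), nrow(sim$genome$features))
  f1 <- sim$genome$features
  f2 <- g2$features
  for (i in seq_len(nrow(f1))) {
    j <- which(f2$kind == f1$kind[i] & f2$name == f1$name[i])
    expect_length(j, 1)
    expect_equal(unname(f1$segments[[i]]), unname(f2$segments[[j]]),
                 info = f1$name[i])
    expect_identical(f1$strand[i], f2$strand[j])
  }
  expect_identical(f1$parent[f1$kind == "intron"],
                   f2$parent[f2$kind == "intron"])
})

test_that("rotation and reverse complement transform coordinates correctly", {
  sim <- simulate_mitogenome(sim_config(seed = 5))
  g <- sim$genome
  L <- genome_length(g)
  r <- 1234L
  gr <- rotate_genome(g, r)
  i <- which(g$features$name == "cox1" & g$features$kind == "CDS")
  expect_identical(extract_feature_sequence(g, g$features[i, ]),
                   extract_feature_sequence(gr, gr$features[i, ]))
  grc <- revcomp_genome(g)
  expect_identical(extract_feature_sequence(g, g$features[i, ]),
                   extract_feature_sequence(grc, grc$features[i, ]))
  expect_identical(revcomp_genome(grc)$sequence, g$sequence)
})

test_that("intron nomenclature builds, parses and is injective", {
  expect_identical(name_intron("cob", 858, "g2",
                               inner = list(site = 2121, class = "g2")),
                   "cobi858g2ii2121g2")
  expect_identical(name_intron("cox1", 447, "g2",
                               inner = list(site = 1767, class = "g2")),
                   "cox1i447g2ii1767g2")
  expect_identical(name_intron("rnl", 1, "g2"), "rnli1g2")
  expect_error(name_intron("cob", 858, "g3"), "class")
  expect_error(name_intron("cob", 0, "g2"), "insertion_site")

  # parse is the inverse; names are unique over distinct arguments
  set.seed(9)
  args <- expand.grid(gene = c("cob", "cox1", "nad5", "rnl"),
                      site = c(1, 87, 858, 2121),
                      class = c("g1", "g2"),
                      stringsAsFactors = FALSE)
  names_plain <- mapply(name_intron, args$gene, args$site, args$class)
  expect_equal(anyDuplicated(names_plain), 0)
  for (k in seq_len(nrow(args))) {
    p <- parse_intron_name(names_plain[k])
    expect_identical(p$gene, args$gene[k])
    expect_equal(p$site, args$site[k])
    expect_identical(p$class, args$class[k])
  }
  p <- parse_intron_name("cobi858g2ii2121g2")
  expect_equal(p$inner$site, 2121)
  expect_identical(p$inner$class, "g2")
})
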