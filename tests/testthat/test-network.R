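make_nodes <- function(ids, seqs, lineage = NA_character_) {
  data.frame(id = ids, sequence = seqs, lineage = lineage,
             compartment = "MT", host_gene = NA_character_,
             stringsAsFactors = FALSE)
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
               replace = TRUE), collapse = "")
}

test_that("identical proteins connect; unrelated random ones do not", {
  set.seed(61)
  p <- random_protein(200)
  e <- all_vs_all(make_nodes(c("a", "b"), c(p, p)))
  expect_equal(nrow(e), 1)
  expect_equal(e$identity, 1.0)
  expect_lt(e$evalue, 1e-5)
  # null pairs: expect no edge for random unrelated proteins
  edgeless <- vapply(1:25, function(i) {
    nrow(all_vs_all(make_nodes(c("a", "b"),
                               c(random_protein(200),
                                 random_protein(200))))) == 0
  }, logical(1))
  expect_gte(mean(edgeless), 0.96)
})

test_that("shared-domain chimera links A-B and B-C but not A-C", {
  set.seed(62)
  dom1 <- random_protein(120)
  dom2 <- random_protein(120)
  a <- paste0(dom1, random_protein(60))
  b <- paste0(dom1, dom2)
  cc <- paste0(random_protein(60), dom2)
  e <- all_vs_all(make_nodes(c("A", "B", "C"), c(a, b, cc)))
  key <- paste(e$a, e$b)
  expect_setequal(key, c("A B", "B C"))
})

test_that("alignment scores are symmetric", {
  set.seed(63)
  p1 <- random_protein(150)
  p2 <- mutate_protein <- paste0(substr(p1, 1, 100), random_protein(50))
  e12 <- all_vs_all(make_nodes(c("x", "y"), c(p1, p2)),
                    evalue_cutoff = Inf, min_identity = 0)
  e21 <- all_vs_all(make_nodes(c("x", "y"), c(p2, p1)),
                    evalue_cutoff = Inf, min_identity = 0)
  expect_equal(e12$score, e21$score)
})

test_that("components, degrees and hubs follow graph arithmetic", {
  nodes <- make_nodes(c("A", "B", "C", "D"), rep("MKV", 4))
  edges <- data.frame(a = c("A", "B"), b = c("B", "C"),
                      score = c(10, 20), identity = c(1, 1),
                      evalue = c(1e-9, 1e-9))
  net <- components_and_hubs(edges, nodes)
  expect_equal(nrow(net$components), 2)   # {A,B,C} and isolated {D}
  comp_abc <- net$nodes$component[net$nodes$id == "A"]
  expect_equal(sum(net$nodes$component == comp_abc), 3)
  expect_equal(net$nodes$degree[net$nodes$id == "B"], 2)
  expect_identical(net$components$hub[net$components$size == 3], "B")
  # star: the center is the hub with degree 10
  star_nodes <- make_nodes(c("hub", paste0("leaf", 1:10)), rep("MKV", 11))
  star_edges <- data.frame(a = "hub", b = paste0("leaf", 1:10),
                           score = 1, identity = 1, evalue = 1e-9)
  star <- components_and_hubs(star_edges, star_nodes)
  expect_equal(nrow(star$components), 1)
  expect_identical(star$components$hub, "hub")
  expect_equal(star$components$hub_degree, 10)
})

test_that("planted families come out as separate lineage-pure components", {
  fam <- simulate_iep_families(n_families = 3, family_size = 3,
                               length_aa = 180, divergence = 0.25,
                               seed = 64)
  e <- all_vs_all(fam)
  net <- components_and_hubs(e, fam)
  expect_equal(nrow(net$components), 3)
  expect_setequal(net$components$majority_lineage,
                  c("family1", "family2", "family3"))
  # components partition the node set
  expect_equal(sum(net$components$size), nrow(fam))
  expect_false(any(is.na(net$nodes$component)))
  # graphml/tsv exports round-trip as files
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  expect_gt(file.info(gml)$size, 0)
})

test_that("empty protein sequences are rejected at load", {
  expect_error(all_vs_all(make_nodes(c("a", "b"), c("MKV", ""))), "empty")
})
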