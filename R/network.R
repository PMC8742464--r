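## Similarity network of intron-encoded proteins (IEPs): all-vs-all
## local protein alignment, thresholded edges, components and hubs.

#' Read protein nodes from a FASTA file with tagged headers
#'
#' Headers may carry `lineage=` and `compartment=` key-value tags, e.g.
#' `>orf563 lineage=red-algal compartment=MT`.
#'
#' @param path protein FASTA.
#' @return data frame with id, sequence, lineage, compartment, host_gene.
#' @export
read_protein_nodes <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  hdr <- names(ss)
  tag <- function(h, key) {
    m <- regmatches(h, regexec(paste0(key, "=([^ ]+)"), h))[[1]]
    if (length(m) < 2L) NA_character_ else m[2]
  }
  df <- data.frame(
    id = vapply(strsplit(hdr, " "), `[`, character(1), 1L),
    sequence = as.character(ss),
    lineage = vapply(hdr, tag, character(1), key = "lineage"),
    compartment = vapply(hdr, tag, character(1), key = "compartment"),
    host_gene = vapply(hdr, tag, character(1), key = "gene"),
    stringsAsFactors = FALSE, row.names = NULL)
  validate_protein_nodes(df)
}

validate_protein_nodes <- function(nodes) {
  bad <- nchar(nodes$sequence) == 0L
  if (any(bad)) stop("empty protein sequence for node(s): ",
                     paste(nodes$id[bad], collapse = ", "))
  nodes$sequence <- toupper(nodes$sequence)
  nodes
}

#' All-vs-all protein similarity edges
#'
#' Smith-Waterman optimal local alignment for every node pair (BLOSUM62,
#' affine gaps: a length-k gap costs open + k * extend).  Identity is
#' computed over aligned columns; pairs failing the E-value or identity
#' threshold are dropped.  The E-value search space is the pair's
#' sequence lengths scaled by the database size (total residue count of
#' the node set), in the spirit of a BLAST all-vs-all.
#'
#' @param nodes data frame with `id` and `sequence` (see
#'   [read_protein_nodes()]).
#' @param evalue_cutoff maximum E-value (default 1e-5).
#' @param min_identity minimum aligned-column identity (default 0.20).
#' @param gap_open,gap_extend affine gap parameters.
#' @param ka Karlin-Altschul parameters ([ka_params_protein()]).
#' @return data frame of class `network_edges`: a, b (a < b), score,
#'   identity, evalue.
#' @export
all_vs_all <- function(nodes, evalue_cutoff = 1e-5, min_identity = 0.20,
                       gap_open = 10, gap_extend = 1,
                       ka = ka_params_protein()) {
  nodes <- validate_protein_nodes(nodes)
  n <- nrow(nodes)
  if (n < 2L) stop("at least 2 nodes are required")
  db_len <- sum(nchar(nodes$sequence))
  data(list = "BLOSUM62", package = "Biostrings",
       envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    aln <- Biostrings::pairwiseAlignment(
      nodes$sequence[i], nodes$sequence[j], type = "local",
      substitutionMatrix = mat, gapOpening = gap_open,
      gapExtension = gap_extend)
    score <- Biostrings::score(aln)
    alen <- Biostrings::nchar(aln)
    matches <- Biostrings::nmatch(aln)
    identity <- if (alen > 0) matches / alen else 0
    ev <- ka_evalue(score, nchar(nodes$sequence[i]), db_len, ka)
    if (ev <= evalue_cutoff && identity >= min_identity) {
      ab <- sort(c(nodes$id[i], nodes$id[j]))
      rows[[length(rows) + 1L]] <- data.frame(
        a = ab[1], b = ab[2], score = score, identity = identity,
        evalue = ev, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(a = character(), b = character(), score = numeric(),
               identity = numeric(), evalue = numeric(),
               stringsAsFactors = FALSE)
  structure(out, class = c("network_edges", "data.frame"))
}

#' Connected components, degrees and hubs of the similarity network
#'
#' @param edges an [all_vs_all()] result.
#' @param nodes the node table (isolated nodes are kept as singleton
#'   components).
#' @return list of class `iep_network`: `graph` (igraph object),
#'   `nodes` (with `degree` and `component` columns), `components`
#'   (per-component size, majority lineage, hub node).
#' @export
components_and_hubs <- function(edges, nodes) {
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b"), drop = FALSE], directed = FALSE,
    vertices = nodes$id)
  if (nrow(edges) > 0L) {
    igraph::E(g)$weight <- edges$score
    igraph::E(g)$identity <- edges$identity
    igraph::E(g)$evalue <- edges$evalue
  }
  comp <- igraph::components(g)
  deg <- igraph::degree(g)
  nodes$degree <- deg[nodes$id]
  nodes$component <- comp$membership[nodes$id]
  comps <- do.call(rbind, lapply(seq_len(comp$no), function(k) {
    sel <- nodes$component == k
    lin <- nodes$lineage[sel]
    lin <- lin[!is.na(lin)]
    hub <- nodes$id[sel][which.max(nodes$degree[sel])]
    data.frame(component = k, size = sum(sel),
               majority_lineage = if (length(lin))
                 names(sort(table(lin), decreasing = TRUE))[1]
               else NA_character_,
               hub = hub, hub_degree = max(nodes$degree[sel]),
               stringsAsFactors = FALSE)
  }))
  structure(list(graph = g, nodes = nodes, components = comps),
            class = "iep_network")
}

#' @export
print.iep_network <- function(x, ...) {
  cat(sprintf("<iep_network> %d nodes, %d edges, %d components\n",
              nrow(x$nodes), igraph::ecount(x$graph),
              nrow(x$components)))
  print(x$components)
  invisible(x)
}

#' Export the network as GraphML
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}

#' Write the edge list as TSV
#' @export
write_edges_tsv <- function(edges, path) {
  write.table(as.data.frame(edges), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
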