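## Genome-size decomposition and cross-genome correlation.

#' Decompose a genome into architectural components
#'
#' Splits genome length into exon (CDS+ORF), intron, intergenic, rRNA
#' and tRNA totals (from the region partition, so they sum exactly to L)
#' and builds a per-gene table of span, exon length, intron length and
#' intron fraction.  `gene_span = exon_len + intron_len` for each gene;
#' intron-encoded proteins (IEPs) are ORF features fully contained in an
#' intron, counted once each.
#'
#' The "genic region" used for the genome-wide intron share is
#' exon + intron of protein-coding genes (CDS and free-standing ORF
#' hosts); set `genic_includes_rna = TRUE` to also count structural-RNA
#' genes and their introns.
#'
#' @param genome an [annotated_genome()].
#' @param partition matching [partition_regions()] result (computed if
#'   missing).
#' @param genic_includes_rna include rRNA/tRNA genes in the genic region.
#' @return object of class `genome_decomposition`.
#' @export
decompose_genome <- function(genome, partition = NULL,
                             genic_includes_rna = FALSE) {
  if (is.null(partition)) partition <- partition_regions(genome)
  L <- genome_length(genome)
  f <- genome$features
  cl <- partition$class_lengths

  ## per-gene table: any name owning CDS/rRNA/tRNA segments or introns
  exon_by_gene <- list()
  kind_by_gene <- list()
  coding <- f$kind %in% c("CDS", "exon")
  for (i in which(coding | f$kind %in% c("rRNA", "tRNA"))) {
    nm <- f$name[i]
    exon_by_gene[[nm]] <- sum(exon_by_gene[[nm]], segment_lengths(f$segments[[i]]))
    kind_by_gene[[nm]] <- if (coding[i]) "coding" else "rna"
  }
  intronic <- orf_in_intron(f)
  for (i in which(f$kind == "ORF" & !intronic)) {
    nm <- f$name[i]
    exon_by_gene[[nm]] <- sum(exon_by_gene[[nm]], segment_lengths(f$segments[[i]]))
    kind_by_gene[[nm]] <- "coding"
  }
  ## nested (twintron) introns are contained in their outer intron's
  ## segments, so summing raw intron feature lengths would double-count
  ## the inner span; use the union of intron positions per gene
  intron_by_gene <- intron_union_by_gene(f, L)

  genes <- union(names(exon_by_gene), names(intron_by_gene))
  per_gene <- do.call(rbind, lapply(genes, function(nm) {
    ex <- if (is.null(exon_by_gene[[nm]])) 0 else exon_by_gene[[nm]]
    it <- if (is.null(intron_by_gene[[nm]])) 0 else intron_by_gene[[nm]]
    data.frame(gene = nm,
               kind = if (is.null(kind_by_gene[[nm]])) "coding"
                      else kind_by_gene[[nm]],
               gene_span = ex + it, exon_len = ex, intron_len = it,
               intron_fraction = if (ex + it > 0) it / (ex + it) else NA,
               inconsistent = ex == 0 & it > 0,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(per_gene) && any(per_gene$inconsistent)) {
    warning("gene(s) with introns but zero exon length: ",
            paste(per_gene$gene[per_gene$inconsistent], collapse = ", "))
  }

  sel <- if (genic_includes_rna) rep(TRUE, NROW(per_gene))
         else per_gene$kind == "coding"
  genic_len <- sum(per_gene$gene_span[sel])
  genic_intron <- sum(per_gene$intron_len[sel])

  structure(list(
    id = genome$id, L = L,
    len_cds_orf = unname(cl[["exon"]]),
    len_intron = unname(cl[["intron"]]),
    len_intergenic = unname(cl[["intergenic"]]),
    len_rrna = unname(cl[["rRNA"]]), len_trna = unname(cl[["tRNA"]]),
    n_introns = sum(f$kind == "intron"),
    n_ieps = sum(f$kind == "ORF" & intronic),
    n_trnas = sum(f$kind == "tRNA"),
    genic_len = genic_len,
    genic_intron_fraction = if (genic_len > 0) genic_intron / genic_len
                            else NA_real_,
    per_gene = per_gene
  ), class = "genome_decomposition")
}

## per-gene union length of intron feature positions (handles nesting)
intron_union_by_gene <- function(f, L) {
  out <- list()
  for (nm in unique(f$parent[f$kind == "intron"])) {
    pos <- integer(0)
    for (i in which(f$kind == "intron" & f$parent == nm)) {
      seg <- f$segments[[i]]
      for (k in seq_len(nrow(seg))) {
        pos <- c(pos, seq.int(seg[k, 1], seg[k, 2] - 1L) %% L)
      }
    }
    out[[nm]] <- length(unique(pos))
  }
  out
}

#' @export
print.genome_decomposition <- function(x, ...) {
  cat(sprintf("<genome_decomposition> %s: %d bp\n", x$id, x$L))
  cat(sprintf("  CDS+ORF %d | intron %d | intergenic %d | rRNA %d | tRNA %d\n",
              x$len_cds_orf, x$len_intron, x$len_intergenic, x$len_rrna,
              x$len_trna))
  cat(sprintf("  introns %d, IEPs %d, tRNAs %d; intron share of genic region %.1f%%\n",
              x$n_introns, x$n_ieps, x$n_trnas,
              100 * x$genic_intron_fraction))
  invisible(x)
}

#' Correlate genome size against a component length across a panel
#'
#' Ordinary least squares of genome length on the predictor component;
#' r^2 = 1 - SS_res/SS_tot.
#'
#' @param panel list of [decompose_genome()] results (or a data frame
#'   with columns `L` and the predictor).
#' @param predictor one of `"len_cds_orf"`, `"len_intron"`,
#'   `"len_intergenic"`, `"len_rrna"`, `"len_trna"`, `"n_ieps"`,
#'   `"n_introns"`.
#' @return object of class `size_correlation`: list with `predictor`,
#'   `r2`, `slope`, `intercept`, `n`.
#' @export
correlate_genome_size <- function(panel, predictor = "len_intron") {
  if (is.data.frame(panel)) {
    x <- panel[[predictor]]
    y <- panel$L
  } else {
    x <- vapply(panel, function(d) as.numeric(d[[predictor]]), numeric(1))
    y <- vapply(panel, function(d) as.numeric(d$L), numeric(1))
  }
  n <- length(x)
  if (n < 3L) stop("panel must contain at least 3 genomes")
  if (stats::var(x) == 0) stop("zero variance in predictor '", predictor, "'")
  fit <- lm(y ~ x)
  structure(list(predictor = predictor,
                 r2 = summary(fit)$r.squared,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 slope_se = summary(fit)$coefficients[2, 2],
                 n = n),
            class = "size_correlation")
}

#' @export
print.size_correlation <- function(x, ...) {
  cat(sprintf("<size_correlation> L ~ %s: r^2 = %.4f, slope = %.3f (n = %d)\n",
              x$predictor, x$r2, x$slope, x$n))
  invisible(x)
}

#' Write the per-gene decomposition table as TSV
#' @export
write_decomposition_tsv <- function(decomp, path) {
  write.table(decomp$per_gene, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
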