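## Exhaustive region partition: every genome position gets exactly one
## label in {exon, intron, intergenic, tRNA, rRNA}.

#' Region class labels, in ascending painting precedence
#' @export
REGION_CLASSES <- c("intergenic", "tRNA", "rRNA", "intron", "exon")

#' Partition every genome position into a region class
#'
#' Label precedence when annotations collide is
#' exon > intron > rRNA > tRNA > intergenic.  The exon class is painted
#' from CDS/exon/ORF features; `gene` features act as a weak exon layer
#' (below introns) so that a gene annotated only as gene + introns still
#' yields its exonic remainder.  ORF features fully contained in an
#' intron are intron-encoded proteins and stay part of the intron class,
#' matching the convention that intron length includes its ORFs.
#'
#' The large intergenic region (LIR) is the longest maximal intergenic
#' run, allowed to wrap the coordinate origin on a circular genome.
#'
#' @param genome an [annotated_genome()].
#' @return an object of class `region_partition`: list with `labels`
#'   (integer vector of length L indexing `REGION_CLASSES`),
#'   `class_lengths`, `lir` (`c(start, end)`, 0-based half-open, `end`
#'   may exceed L when the run wraps; `NULL` when there is no intergenic
#'   position) and `genome_id`.
#' @export
partition_regions <- function(genome) {
  L <- genome_length(genome)
  lab <- rep.int(1L, L)  # intergenic
  f <- genome$features
  if (nrow(f) == 0L) {
    warning("genome has no features; whole genome labeled intergenic")
  }

  paint <- function(lab, rows, level) {
    for (i in rows) {
      seg <- f$segments[[i]]
      for (k in seq_len(nrow(seg))) {
        idx <- (seq.int(seg[k, 1], seg[k, 2] - 1L) %% L) + 1L
        lab[idx] <- level
      }
    }
    lab
  }

  intronic_orf <- orf_in_intron(f)
  ## weak exon layer first (coding genes only: a gene whose name also has
  ## an rRNA/tRNA feature is a structural-RNA gene), so that every other
  ## class can overpaint it; then ascending precedence
  rna_names <- f$name[f$kind %in% c("rRNA", "tRNA")]
  lab <- paint(lab, which(f$kind == "gene" & !f$name %in% rna_names), 5L)
  lab <- paint(lab, which(f$kind == "tRNA"), 2L)
  lab <- paint(lab, which(f$kind == "rRNA"), 3L)
  lab <- paint(lab, which(f$kind == "intron"), 4L)
  strong_exon <- which(f$kind %in% c("CDS", "exon") |
                         (f$kind == "ORF" & !intronic_orf))
  lab <- paint(lab, strong_exon, 5L)

  cls_len <- tabulate(lab, nbins = 5L)
  names(cls_len) <- REGION_CLASSES

  lir <- longest_run(lab == 1L, circular = genome$circular)

  structure(list(labels = lab, class_lengths = cls_len, lir = lir,
                 genome_id = genome$id, circular = genome$circular),
            class = "region_partition")
}

## TRUE for ORF features fully contained in some intron feature
orf_in_intron <- function(f) {
  out <- rep(FALSE, nrow(f))
  orfs <- which(f$kind == "ORF")
  introns <- which(f$kind == "intron")
  if (length(orfs) == 0L || length(introns) == 0L) return(out)
  for (i in orfs) {
    so <- f$segments[[i]]
    for (j in introns) {
      si <- f$segments[[j]]
      contained <- all(vapply(seq_len(nrow(so)), function(k) {
        any(si[, 1] <= so[k, 1] & so[k, 2] <= si[, 2])
      }, logical(1)))
      if (contained) { out[i] <- TRUE; break }
    }
  }
  out
}

## longest maximal run of TRUE, optionally wrapping the origin;
## returns c(start, end) 0-based half-open (end may exceed length) or NULL
longest_run <- function(x, circular = TRUE) {
  n <- length(x)
  if (!any(x)) return(NULL)
  if (all(x)) return(c(0, n))
  if (circular) {
    ## rotate so position 0 is FALSE, then runs cannot be split by the cut
    first_false <- which(!x)[1] - 1L
    xr <- x[((seq_len(n) - 1L + first_false) %% n) + 1L]
  } else {
    first_false <- 0L
    xr <- x
  }
  r <- rle(xr)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  s <- (starts[best] + first_false) %% n
  c(s, s + r$lengths[best])
}

#' @export
print.region_partition <- function(x, ...) {
  L <- length(x$labels)
  cat(sprintf("<region_partition> %s: %d bp\n", x$genome_id, L))
  for (cl in rev(REGION_CLASSES)) {
    cat(sprintf("  %-11s %8d bp (%5.1f%%)\n", cl, x$class_lengths[[cl]],
                100 * x$class_lengths[[cl]] / L))
  }
  if (!is.null(x$lir)) {
    cat(sprintf("  LIR: [%d, %d) length %d bp%s\n", x$lir[1], x$lir[2],
                x$lir[2] - x$lir[1],
                if (x$lir[2] > L) " (wraps origin)" else ""))
  }
  invisible(x)
}

#' Region class at given 0-based positions
#' @export
region_class_at <- function(partition, pos) {
  L <- length(partition$labels)
  REGION_CLASSES[partition$labels[(pos %% L) + 1L]]
}

#' Write the partition as a BED file (0-based half-open)
#' @export
write_partition_bed <- function(partition, path) {
  r <- rle(partition$labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  df <- data.frame(chrom = partition$genome_id, start = starts, end = ends,
                   name = REGION_CLASSES[r$values])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write per-class lengths as a TSV summary
#' @export
write_partition_tsv <- function(partition, path) {
  df <- data.frame(class = names(partition$class_lengths),
                   length_bp = as.integer(partition$class_lengths))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
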