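## Splice-site context extraction and position frequency matrices.

#' Extract exon/intron sequence contexts around every intron
#'
#' For each intron feature (twintron inner introns included) four
#' fixed-width blocks are taken on the coding strand of the host gene:
#' the last 10 bp of upstream exon, the first 5 bp of the intron, the
#' last 5 bp of the intron and the first 10 bp of downstream exon.
#' Blocks running past the gene/genome limits are N-padded and flagged;
#' introns shorter than 10 bp are skipped with a warning.
#'
#' @param genome an [annotated_genome()] (or list of genomes, whose
#'   contexts are concatenated).
#' @return data frame of class `splice_contexts` with columns
#'   `intron_id`, `genome_id`, `donor_exon`, `donor_intron`,
#'   `acceptor_intron`, `acceptor_exon`, `padded`.
#' @export
extract_splice_contexts <- function(genome) {
  if (!inherits(genome, "annotated_genome") && is.list(genome)) {
    out <- do.call(rbind, lapply(genome, extract_splice_contexts))
    class(out) <- c("splice_contexts", "data.frame")
    return(out)
  }
  f <- genome$features
  L <- genome_length(genome)
  rows <- list()
  for (i in which(f$kind == "intron")) {
    seg <- f$segments[[i]]
    a <- min(seg[, 1]); b <- max(seg[, 2])   # genomic extent
    if (b - a < 10L) {
      warning("intron ", f$name[i], " shorter than 10 bp; context skipped")
      next
    }
    strand <- f$strand[i]
    grab <- function(s, e) {
      ## clipped, N-padded extraction of [s, e) in genome coordinates
      if (genome$circular) {
        circular_subseq(genome$sequence, s %% L, (s %% L) + (e - s), TRUE)
      } else {
        left <- max(s, 0); right <- min(e, L)
        core <- if (right > left) substr(genome$sequence, left + 1, right) else ""
        paste0(strrep("N", left - s), core, strrep("N", e - right))
      }
    }
    if (strand == "+") {
      donor_exon <- grab(a - 10L, a)
      donor_intron <- grab(a, a + 5L)
      acceptor_intron <- grab(b - 5L, b)
      acceptor_exon <- grab(b, b + 10L)
    } else {
      donor_exon <- dna_revcomp(grab(b, b + 10L))
      donor_intron <- dna_revcomp(grab(b - 5L, b))
      acceptor_intron <- dna_revcomp(grab(a, a + 5L))
      acceptor_exon <- dna_revcomp(grab(a - 10L, a))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      intron_id = f$name[i], genome_id = genome$id,
      donor_exon = donor_exon, donor_intron = donor_intron,
      acceptor_intron = acceptor_intron, acceptor_exon = acceptor_exon,
      padded = grepl("N", paste0(donor_exon, acceptor_exon)),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(intron_id = character(), genome_id = character(),
               donor_exon = character(), donor_intron = character(),
               acceptor_intron = character(), acceptor_exon = character(),
               padded = logical(), stringsAsFactors = FALSE)
  class(out) <- c("splice_contexts", "data.frame")
  out
}

#' Build a position frequency matrix from splice contexts
#'
#' @param contexts a [extract_splice_contexts()] result (or any character
#'   vector of equal-length sequences).
#' @param slot which context block to tabulate: `"donor_exon"`,
#'   `"donor_intron"`, `"acceptor_intron"` or `"acceptor_exon"`.
#' @return object of class `pfm`: list with `counts` (4 x width matrix,
#'   rows A/C/G/T; N/pads excluded), `n` (number of contexts), `freq`
#'   (counts divided by per-column totals), `dominant` (data frame of
#'   per-position dominant base and frequency).
#' @export
build_pfm <- function(contexts, slot = c("donor_exon", "donor_intron",
                                         "acceptor_intron", "acceptor_exon")) {
  if (is.data.frame(contexts)) {
    slot <- match.arg(slot)
    seqs <- contexts[[slot]]
  } else {
    seqs <- as.character(contexts)
    slot <- "sequences"
  }
  if (length(seqs) == 0L) stop("at least one context is required")
  width <- unique(nchar(seqs))
  if (length(width) != 1L) stop("context sequences must be equal length")
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  counts <- sapply(seq_len(width), function(j) {
    col <- mat[, j]
    c(A = sum(col == "A"), C = sum(col == "C"),
      G = sum(col == "G"), T = sum(col == "T"))
  })
  counts <- matrix(counts, nrow = 4,
                   dimnames = list(c("A", "C", "G", "T"),
                                   paste0("p", seq_len(width))))
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1L), "/")
  dom <- apply(freq, 2, which.max)
  dominant <- data.frame(position = seq_len(width),
                         base = rownames(counts)[dom],
                         freq = freq[cbind(dom, seq_len(width))])
  structure(list(slot = slot, counts = counts, n = length(seqs),
                 freq = freq, dominant = dominant),
            class = "pfm")
}

#' @export
print.pfm <- function(x, digits = 3, ...) {
  cat(sprintf("<pfm> %s: %d contexts, width %d\n", x$slot, x$n,
              ncol(x$counts)))
  print(round(x$freq, digits))
  invisible(x)
}

#' Text sequence logo: per-position dominant base and frequency
#' @export
pfm_logo_text <- function(pfm) {
  paste(sprintf("%s(%.0f%%)", pfm$dominant$base, 100 * pfm$dominant$freq),
        collapse = " ")
}

#' Add two PFMs count-wise (same slot and width)
#' @export
pfm_add <- function(a, b) {
  stopifnot(identical(dim(a$counts), dim(b$counts)))
  counts <- a$counts + b$counts
  tot <- colSums(counts)
  freq <- sweep(counts, 2, pmax(tot, 1L), "/")
  dom <- apply(freq, 2, which.max)
  structure(list(slot = a$slot, counts = counts, n = a$n + b$n, freq = freq,
                 dominant = data.frame(position = seq_len(ncol(counts)),
                                       base = rownames(counts)[dom],
                                       freq = freq[cbind(dom, seq_len(ncol(counts)))])),
            class = "pfm")
}

#' Write a PFM (counts and frequencies) as TSV
#' @export
write_pfm_tsv <- function(pfm, path) {
  df <- data.frame(base = rownames(pfm$counts), pfm$counts,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
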