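## Core containers: annotated_genome and its features.
##
## Coordinates are 0-based half-open throughout the package; GenBank I/O
## converts to/from the 1-based inclusive convention at the boundary.  A
## segment may run past L (end <= start + L) to represent an interval that
## wraps the origin of a circular genome.

FEATURE_KINDS <- c("gene", "CDS", "ORF", "exon", "intron", "tRNA", "rRNA")

#' Construct an annotated circular genome
#'
#' @param id accession or label.
#' @param sequence nucleotide string over A, C, G, T, N (case-insensitive).
#' @param features data frame with columns `kind`, `name`, `strand`,
#'   `parent`, `class_token` and a list column `segments` of two-column
#'   matrices of 0-based half-open `[start, end)` intervals.  Use
#'   [genome_feature()] to build rows.
#' @param circular is the molecule circular?
#' @param genetic_code NCBI translation table id; 4 (mold/protozoan
#'   mitochondrial, TGA = Trp) is the default used for organelle ORFs.
#' @return an object of class `annotated_genome`.
#' @export
annotated_genome <- function(id, sequence, features = empty_features(),
                             circular = TRUE, genetic_code = 4L) {
  sequence <- toupper(as.character(sequence))
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty")
  bad <- gsub("[ACGTN]", "", sequence)
  if (nchar(bad) > 0L) {
    stop("sequence contains characters other than A/C/G/T/N: ",
         paste(unique(strsplit(bad, "")[[1]]), collapse = ", "),
         " (ambiguity codes are not supported)")
  }
  if (!genetic_code %in% c(1L, 4L, 11L)) {
    stop("genetic_code must be one of 1, 4, 11")
  }
  features <- validate_features(features, nchar(sequence), circular)
  structure(
    list(id = id, sequence = sequence, circular = isTRUE(circular),
         features = features, genetic_code = as.integer(genetic_code)),
    class = "annotated_genome"
  )
}

#' @export
genome_length <- function(genome) nchar(genome$sequence)

#' An empty feature table
#' @export
empty_features <- function() {
  data.frame(kind = character(), name = character(), strand = character(),
             parent = character(), class_token = character(),
             segments = I(list()), stringsAsFactors = FALSE)
}

#' Build a one-row feature table
#'
#' @param kind one of gene, CDS, ORF, exon, intron, tRNA, rRNA.
#' @param name feature name (gene symbol, `orfNNN`, intron name).
#' @param start,end 0-based half-open interval; ignored when `segments`
#'   is given.
#' @param strand "+" or "-".
#' @param segments optional two-column matrix of `[start, end)` rows for
#'   multi-segment (spliced or origin-spanning) features.
#' @param parent name of the parent feature (host gene for introns).
#' @param class_token intron class token, "g1" or "g2" (introns only).
#' @export
genome_feature <- function(kind, name, start = NULL, end = NULL,
                           strand = "+", segments = NULL,
                           parent = NA_character_,
                           class_token = NA_character_) {
  if (is.null(segments)) segments <- cbind(start, end)
  storage.mode(segments) <- "double"
  data.frame(kind = kind, name = name, strand = strand, parent = parent,
             class_token = class_token, segments = I(list(segments)),
             stringsAsFactors = FALSE)
}

validate_features <- function(features, L, circular) {
  if (nrow(features) == 0L) return(features)
  stopifnot(all(c("kind", "name", "strand", "segments") %in% names(features)))
  if (is.null(features$parent)) features$parent <- NA_character_
  if (is.null(features$class_token)) features$class_token <- NA_character_
  ok_kind <- features$kind %in% FEATURE_KINDS
  if (!all(ok_kind)) {
    stop("unknown feature kind(s): ",
         paste(unique(features$kind[!ok_kind]), collapse = ", "))
  }
  if (!all(features$strand %in% c("+", "-"))) stop("strand must be + or -")
  for (i in seq_len(nrow(features))) {
    seg <- features$segments[[i]]
    if (!is.matrix(seg) || ncol(seg) != 2L || nrow(seg) == 0L) {
      stop("feature ", features$name[i], ": segments must be a non-empty ",
           "two-column matrix")
    }
    if (any(seg[, 1] >= seg[, 2])) {
      stop("feature ", features$name[i], ": segment start must be < end")
    }
    if (any(seg[, 1] < 0) || any(seg[, 1] >= L)) {
      stop("feature ", features$name[i], ": segment start outside [0, L)")
    }
    wraps <- seg[, 2] > L
    if (any(wraps) && !circular) {
      stop("feature ", features$name[i], ": interval past sequence end on ",
           "a linear genome")
    }
    if (any(seg[, 2] - seg[, 1] > L)) {
      stop("feature ", features$name[i], ": segment longer than the genome")
    }
  }
  has_parent <- !is.na(features$parent)
  need_parent <- features$kind == "intron"
  if (any(need_parent & !has_parent)) {
    stop("intron feature(s) without a parent gene: ",
         paste(features$name[need_parent & !has_parent], collapse = ", "))
  }
  features
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %s bp, %s, code %d, %d features\n",
              x$id, format(genome_length(x), big.mark = ","),
              if (x$circular) "circular" else "linear",
              x$genetic_code, nrow(x$features)))
  if (nrow(x$features) > 0L) {
    tab <- table(x$features$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

## ---- sequence helpers -----------------------------------------------------

#' Reverse complement of a nucleotide string
#' @param x character string over A/C/G/T/N.
#' @export
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Extract `[start, end)` from a (possibly circular) sequence
#'
#' `end` may exceed the sequence length on a circular genome, in which
#' case the extraction wraps through the origin.
#' @export
circular_subseq <- function(sequence, start, end, circular = TRUE) {
  L <- nchar(sequence)
  if (start < 0 || start >= L || end <= start) {
    stop("invalid interval [", start, ", ", end, ")")
  }
  if (end <= L) return(substr(sequence, start + 1L, end))
  if (!circular) stop("interval wraps the origin of a linear sequence")
  if (end - start > L) stop("interval longer than the genome")
  paste0(substr(sequence, start + 1L, L), substr(sequence, 1L, end - L))
}

#' Extract the (spliced) sequence of a feature
#'
#' Segments are concatenated in order and the result is
#' reverse-complemented for minus-strand features, so the returned string
#' always reads 5' to 3' on the coding strand.
#'
#' @param genome an [annotated_genome()].
#' @param feature a one-row slice of `genome$features` (or any one-row
#'   feature table).
#' @export
extract_feature_sequence <- function(genome, feature) {
  seg <- feature$segments[[1]]
  parts <- vapply(seq_len(nrow(seg)), function(i) {
    circular_subseq(genome$sequence, seg[i, 1], seg[i, 2], genome$circular)
  }, character(1))
  out <- paste(parts, collapse = "")
  if (feature$strand == "-") out <- dna_revcomp(out) else out
}

#' Rotate a circular genome so that position `offset` becomes position 0
#'
#' Feature coordinates are shifted by `-offset` modulo L; features that
#' come to span the new origin are represented with a wrapped segment.
#' @export
rotate_genome <- function(genome, offset) {
  L <- genome_length(genome)
  if (!genome$circular) stop("cannot rotate a linear genome")
  offset <- offset %% L
  if (offset == 0) return(genome)
  seq2 <- paste0(substr(genome$sequence, offset + 1L, L),
                 substr(genome$sequence, 1L, offset))
  feats <- genome$features
  if (nrow(feats) > 0L) {
    feats$segments <- I(lapply(feats$segments, function(seg) {
      s <- (seg[, 1] - offset) %% L
      seg2 <- cbind(s, s + (seg[, 2] - seg[, 1]))
      dimnames(seg2) <- NULL
      seg2
    }))
  }
  annotated_genome(genome$id, seq2, feats, circular = TRUE,
                   genetic_code = genome$genetic_code)
}

#' Reverse-complement a genome, transforming its annotation
#' @export
revcomp_genome <- function(genome) {
  L <- genome_length(genome)
  feats <- genome$features
  if (nrow(feats) > 0L) {
    feats$strand <- ifelse(feats$strand == "+", "-", "+")
    feats$segments <- I(lapply(feats$segments, function(seg) {
      ## map [s, e) to [L - e, L - s); wrapped segments stay wrapped
      s2 <- (L - seg[, 2]) %% L
      seg2 <- cbind(s2, s2 + (seg[, 2] - seg[, 1]))
      seg2 <- seg2[rev(seq_len(nrow(seg2))), , drop = FALSE]
      dimnames(seg2) <- NULL
      seg2
    }))
  }
  annotated_genome(genome$id, dna_revcomp(genome$sequence), feats,
                   circular = genome$circular,
                   genetic_code = genome$genetic_code)
}

## interval span length, used in several modules
segment_lengths <- function(seg) sum(seg[, 2] - seg[, 1])
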