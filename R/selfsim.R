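## Genome self-similarity: seeded local alignment (dot-plot style),
## intron-intron homology and twintron detection.

#' Seed-and-extend local self-alignment of a genome
#'
#' Finds duplicated segments within a sequence: exact words of
#' `word_size` bp seed candidate region pairs on the forward and
#' reverse-complement strands; each candidate region pair is resolved by
#' an affine-gap Smith-Waterman alignment (match +1, mismatch -2, gap
#' open -5, gap extend -2) and hits scoring at least `min_score` are
#' reported with a Karlin-Altschul E-value.  The trivial full-length
#' self-diagonal is excluded and hits are canonically ordered
#' (q interval starts before s interval) so mirror duplicates are
#' suppressed.  Words occurring more than `max_word_occ` times are
#' masked as low-complexity (tandem arrays are the province of
#' [find_tandem_repeats()]).
#'
#' @param seq nucleotide string or [annotated_genome()].
#' @param word_size exact seed length (default 11).
#' @param min_score minimum alignment score to report (default 25).
#' @param max_word_occ seed multiplicity cap (default 100).
#' @param band diagonal clustering bandwidth in bp.
#' @param pad region padding around a seed cluster in bp.
#' @param ka Karlin-Altschul parameters, see [ka_params_dna()].
#' @return data frame of class `similarity_hits`: q_start, q_end,
#'   s_start, s_end (0-based half-open, forward-genome coordinates),
#'   strand ("forward"/"revcomp"), score, matches, align_len, identity,
#'   evalue.
#' @export
self_align <- function(seq, word_size = 11L, min_score = 25L,
                       max_word_occ = 100L, band = 50L, pad = 100L,
                       ka = ka_params_dna()) {
  if (inherits(seq, "annotated_genome")) seq <- seq$sequence
  seq <- toupper(seq)
  L <- nchar(seq)
  if (word_size < 4L) stop("word_size must be >= 4")
  if (L < word_size) stop("sequence shorter than word_size")
  qi <- dna_to_int(seq)
  ri <- dna_to_int(dna_revcomp(seq))

  hits_f <- align_seed_clusters(qi, qi, word_size, min_score, max_word_occ,
                                band, pad, self_mode = TRUE)
  hits_r <- align_seed_clusters(qi, ri, word_size, min_score, max_word_occ,
                                band, pad, self_mode = FALSE,
                                rc_self = TRUE)
  if (nrow(hits_r) > 0L) {
    ## map subject interval from revcomp coordinates back to the genome
    s2 <- L - hits_r$s_start
    s1 <- L - hits_r$s_end
    hits_r$s_start <- s1
    hits_r$s_end <- s2
    hits_r$strand <- "revcomp"
    ## canonical ordering + de-mirroring: q before s, drop self-overlaps
    swap <- hits_r$s_start < hits_r$q_start
    qs <- hits_r[swap, c("s_start", "s_end")]
    hits_r[swap, c("s_start", "s_end")] <- hits_r[swap, c("q_start", "q_end")]
    hits_r[swap, c("q_start", "q_end")] <- qs
    hits_r <- hits_r[!(hits_r$q_start == hits_r$s_start &
                         hits_r$q_end == hits_r$s_end), , drop = FALSE]
    hits_r <- unique(hits_r)
  }
  hits <- rbind(hits_f, hits_r)
  if (nrow(hits) > 0L) {
    hits$identity <- hits$matches / pmax(hits$align_len, 1L)
    hits$evalue <- ka_evalue(hits$score, L, L, ka)
    hits <- hits[order(hits$evalue, hits$q_start), , drop = FALSE]
    rownames(hits) <- NULL
  } else {
    hits$identity <- numeric(0)
    hits$evalue <- numeric(0)
  }
  class(hits) <- c("similarity_hits", "data.frame")
  attr(hits, "L") <- L
  hits
}

## shared machinery: seeds -> diagonal clusters -> windowed SW.
## rc_self marks a genome-vs-own-reverse-complement comparison: mirror
## seeds (subject locus at or before the query locus) are dropped and
## the palindromic anti-diagonal is excluded from the DP, so inverted
## duplications are reported once, as a pair of distinct loci.
align_seed_clusters <- function(qi, si, word_size, min_score, max_word_occ,
                                band, pad, self_mode, rc_self = FALSE) {
  empty <- data.frame(q_start = integer(), q_end = integer(),
                      s_start = integer(), s_end = integer(),
                      strand = character(), score = numeric(),
                      matches = integer(), align_len = integer(),
                      stringsAsFactors = FALSE)
  seeds <- .seed_hits(qi, si, as.integer(word_size), self_mode,
                      as.integer(max_word_occ))
  if (rc_self && nrow(seeds) > 0L) {
    L <- length(qi)
    keep <- (L - seeds[, 2] - word_size) > seeds[, 1]
    seeds <- seeds[keep, , drop = FALSE]
  }
  if (nrow(seeds) == 0L) return(empty)
  d <- seeds[, 2] - seeds[, 1]
  key <- round(d / band)
  rows <- list()
  max_side <- 4000L
  for (k in unique(key)) {
    sel <- which(key == k)
    o <- sel[order(seeds[sel, 1])]
    qpos <- seeds[o, 1]
    ## split a diagonal band at large gaps along q
    grp <- cumsum(c(1L, diff(qpos) > 5L * pad))
    for (g in unique(grp)) {
      idx <- o[grp == g]
      q1 <- max(0L, min(seeds[idx, 1]) - pad)
      q2 <- min(length(qi), max(seeds[idx, 1]) + word_size + pad)
      s1 <- max(0L, min(seeds[idx, 2]) - pad)
      s2 <- min(length(si), max(seeds[idx, 2]) + word_size + pad)
      if (q2 - q1 > max_side) q2 <- q1 + max_side
      if (s2 - s1 > max_side) s2 <- s1 + max_side
      aln <- .sw_align(qi[(q1 + 1L):q2], si[(s1 + 1L):s2],
                       1, -2, 5, 2,
                       use_forbid = self_mode,
                       forbid_delta = q1 - s1,
                       use_forbid_anti = rc_self,
                       forbid_anti = length(qi) + 1L - q1 - s1)
      if (aln$score < min_score) next
      rows[[length(rows) + 1L]] <- data.frame(
        q_start = q1 + aln$a_start, q_end = q1 + aln$a_end,
        s_start = s1 + aln$b_start, s_end = s1 + aln$b_end,
        strand = "forward", score = aln$score,
        matches = aln$matches, align_len = aln$align_len,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- unique(do.call(rbind, rows))
  ## collapse hits that are sub-alignments of an already-reported hit
  keep <- rep(TRUE, nrow(out))
  o <- order(-out$score)
  for (a in seq_along(o)) {
    i <- o[a]
    if (!keep[i]) next
    for (b in seq_along(o)) {
      if (b <= a) next
      j <- o[b]
      if (!keep[j]) next
      if (out$q_start[j] >= out$q_start[i] - 5 &&
          out$q_end[j] <= out$q_end[i] + 5 &&
          out$s_start[j] >= out$s_start[i] - 5 &&
          out$s_end[j] <= out$s_end[i] + 5) keep[j] <- FALSE
    }
  }
  out[keep, , drop = FALSE]
}

#' Align two sequences locally (affine-gap Smith-Waterman)
#'
#' Single optimal local alignment under the package's nucleotide
#' scoring; mainly a building block and oracle hook.
#' @export
local_align <- function(a, b, match = 1, mismatch = -2, gap_open = 5,
                        gap_extend = 2) {
  .sw_align(dna_to_int(a), dna_to_int(b), match, mismatch, gap_open,
            gap_extend)
}

#' Intron-intron homology pairs from self-alignment hits
#'
#' A pair of introns is reported when a hit passing the E-value cutoff
#' overlaps two distinct intron features, each by at least
#' `min_overlap` of the hit's span on that side.
#'
#' @param genome an [annotated_genome()] with intron features.
#' @param hits a [self_align()] result (computed if missing).
#' @param cutoff E-value cutoff (default 1e-10).
#' @param min_overlap minimum fractional overlap (default 0.5).
#' @return data frame with columns `intron_a`, `intron_b`, `evalue`,
#'   `score` (one row per intron pair, best hit kept).
#' @export
intron_homology <- function(genome, hits = NULL, cutoff = 1e-10,
                            min_overlap = 0.5) {
  if (is.null(hits)) hits <- self_align(genome)
  f <- genome$features
  introns <- which(f$kind == "intron")
  empty <- data.frame(intron_a = character(), intron_b = character(),
                      evalue = numeric(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (length(introns) == 0L || nrow(hits) == 0L) return(empty)
  hits <- hits[hits$evalue <= cutoff, , drop = FALSE]
  if (nrow(hits) == 0L) return(empty)
  iv <- t(vapply(introns, function(i) {
    seg <- f$segments[[i]]
    c(min(seg[, 1]), max(seg[, 2]))
  }, numeric(2)))
  nm <- f$name[introns]
  find_intron <- function(s, e) {
    ov <- pmin(iv[, 2], e) - pmax(iv[, 1], s)
    ok <- which(ov >= min_overlap * (e - s))
    if (length(ok) == 0L) return(NA_character_)
    nm[ok[which.max(ov[ok])]]
  }
  rows <- list()
  for (h in seq_len(nrow(hits))) {
    a <- find_intron(hits$q_start[h], hits$q_end[h])
    b <- find_intron(hits$s_start[h], hits$s_end[h])
    if (is.na(a) || is.na(b) || a == b) next
    pr <- sort(c(a, b))
    rows[[length(rows) + 1L]] <- data.frame(
      intron_a = pr[1], intron_b = pr[2], evalue = hits$evalue[h],
      score = hits$score[h], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$evalue), , drop = FALSE]
  out <- out[!duplicated(out[, c("intron_a", "intron_b")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect twintrons (introns nested inside introns)
#'
#' Nesting is inferred from coordinates: an intron whose genomic extent
#' lies strictly inside another intron's extent is an inner intron of a
#' twintron.  Each call is named with the intron nomenclature
#' ([name_intron()]); insertion sites are computed from the annotation
#' (exon bases of the host gene 5' of the outer intron; outer-intron
#' bases 5' of the inner intron).  Homologous introns (from
#' [intron_homology()]) are attached when supplied.
#'
#' @param genome an [annotated_genome()].
#' @param homology_pairs optional [intron_homology()] result.
#' @return data frame of class `twintron_calls` with columns
#'   `outer_intron`, `inner_intron`, `name`, `nested`, `homologs`.
#' @export
detect_twintrons <- function(genome, homology_pairs = NULL) {
  f <- genome$features
  introns <- which(f$kind == "intron")
  empty <- data.frame(outer_intron = character(), inner_intron = character(),
                      name = character(), nested = logical(),
                      homologs = character(), stringsAsFactors = FALSE)
  if (length(introns) < 2L) return(structure(empty,
                                             class = c("twintron_calls",
                                                       "data.frame")))
  ext <- t(vapply(introns, function(i) {
    seg <- f$segments[[i]]
    c(min(seg[, 1]), max(seg[, 2]))
  }, numeric(2)))
  rows <- list()
  for (a in seq_along(introns)) for (b in seq_along(introns)) {
    if (a == b) next
    ## partial overlap is an annotation inconsistency
    if (ext[a, 1] > ext[b, 1] && ext[a, 1] < ext[b, 2] &&
        ext[a, 2] > ext[b, 2]) {
      stop("intron ", f$name[introns[a]],
           " crosses the boundary of ", f$name[introns[b]])
    }
    ## inner a strictly inside outer b
    if (ext[a, 1] > ext[b, 1] && ext[a, 2] < ext[b, 2]) {
      io <- introns[b]; ii <- introns[a]
      gene <- f$parent[io]
      outer_site <- exon_bases_upstream(genome, gene, f$strand[io],
                                        ext[b, 1], ext[b, 2])
      inner_site <- if (f$strand[io] == "+") ext[a, 1] - ext[b, 1]
                    else ext[b, 2] - ext[a, 2]
      cls_o <- if (is.na(f$class_token[io])) "g2" else f$class_token[io]
      cls_i <- if (is.na(f$class_token[ii])) "g2" else f$class_token[ii]
      hm <- ""
      if (!is.null(homology_pairs) && nrow(homology_pairs) > 0L) {
        sel <- homology_pairs$intron_a %in% f$name[c(io, ii)] |
          homology_pairs$intron_b %in% f$name[c(io, ii)]
        partners <- setdiff(unique(c(homology_pairs$intron_a[sel],
                                     homology_pairs$intron_b[sel])),
                            f$name[c(io, ii)])
        hm <- paste(partners, collapse = ",")
      }
      rows[[length(rows) + 1L]] <- data.frame(
        outer_intron = f$name[io], inner_intron = f$name[ii],
        name = name_intron(gene, outer_site, cls_o,
                           inner = list(site = inner_site, class = cls_i)),
        nested = TRUE, homologs = hm, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  structure(out, class = c("twintron_calls", "data.frame"))
}

## number of exon (CDS) bases of `gene` strictly 5' of the intron
## occupying [a, b) -- the 1-based insertion site of the nomenclature
exon_bases_upstream <- function(genome, gene, strand, a, b) {
  f <- genome$features
  segs <- f$segments[f$kind %in% c("CDS", "exon") & f$name == gene]
  if (length(segs) == 0L) {
    ## fall back to the gene feature minus its introns
    gseg <- f$segments[f$kind == "gene" & f$name == gene]
    if (length(gseg) == 0L) stop("no exon annotation for gene ", gene)
    pos <- unlist(lapply(seq_len(nrow(gseg[[1]])), function(k) {
      seq.int(gseg[[1]][k, 1], gseg[[1]][k, 2] - 1L)
    }))
    ipos <- unlist(lapply(which(f$kind == "intron" & f$parent == gene),
                          function(i) {
      seg <- f$segments[[i]]
      unlist(lapply(seq_len(nrow(seg)), function(k) {
        seq.int(seg[k, 1], seg[k, 2] - 1L)
      }))
    }))
    exon_pos <- setdiff(pos, ipos)
  } else {
    exon_pos <- unlist(lapply(segs, function(seg) {
      unlist(lapply(seq_len(nrow(seg)), function(k) {
        seq.int(seg[k, 1], seg[k, 2] - 1L)
      }))
    }))
  }
  if (strand == "+") sum(exon_pos < a) else sum(exon_pos >= b)
}

#' Write similarity hits as a BLAST outfmt-6-like TSV
#' @export
write_hits_tsv <- function(hits, path) {
  write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
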