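## Tandem repeat detection, binning and density.

#' Tandem-repeat unit-length bins
#' @export
REPEAT_BINS <- c("2-100", "101-200", "201-300", "301-400", "401-500")

dna_to_int <- function(x) {
  v <- match(strsplit(toupper(x), "")[[1]], c("A", "C", "G", "T")) - 1L
  v[is.na(v)] <- -1L  # N never matches a consensus
  v
}

#' Find tandem repeats by consensus scoring
#'
#' ETANDEM-style detection: for every candidate period the sequence is
#' swept and copies of the unit are scored against their column
#' consensus; score = matches - mismatches.  Maximal non-overlapping runs
#' (per period) with score >= `threshold` and at least two full copies
#' are reported; runs of different periods may overlap (see
#' [dedupe_repeats()]).  On circular input the scan is run on the
#' sequence extended by its first `2 * max_period` bases and duplicates
#' mapping to the same circular locus are discarded.
#'
#' For long sequences a periodicity prefilter (first adjacent copy pair
#' must agree at >= 50% of sites) prunes the sweep; it is exact for the
#' near-perfect repeats the scorer is meant to find and is bypassed below
#' 2 kb, where the sweep is exhaustive.
#'
#' @param seq nucleotide string, or an [annotated_genome()].
#' @param min_period,max_period unit length range in bp (2 to 500).
#' @param threshold minimum score (EMBOSS etandem default 20).
#' @param mismatch_allowed if `FALSE` (the EMBOSS default, kept here),
#'   only perfect repeats (all copies identical) are reported; if `TRUE`
#'   copies may diverge from the consensus, each mismatch costing one
#'   score point against one gained per match.
#' @param circular treat the sequence as circular (default: taken from
#'   the genome, or `FALSE` for a bare string).
#' @param partition optional [partition_regions()] result used to attach
#'   the region class at each repeat midpoint.
#' @return data frame of class `tandem_repeats`: start (0-based), period,
#'   copies, span, score, mismatches, unit, bin, region_class.
#' @export
find_tandem_repeats <- function(seq, min_period = 2L, max_period = 500L,
                                threshold = 20L, mismatch_allowed = FALSE,
                                circular = NULL, partition = NULL) {
  if (inherits(seq, "annotated_genome")) {
    if (is.null(circular)) circular <- seq$circular
    seq <- seq$sequence
  }
  if (is.null(circular)) circular <- FALSE
  if (min_period < 2L) stop("min_period must be >= 2")
  if (max_period < min_period || max_period > 500L) {
    stop("require 2 <= min_period <= max_period <= 500")
  }
  if (threshold < 1L) stop("threshold must be positive")
  L <- nchar(seq)
  if (L < 2L * min_period) {
    warning("sequence shorter than twice min_period; no repeats possible")
    return(empty_repeats())
  }
  ext <- 0L
  scan_seq <- seq
  if (circular) {
    ext <- min(2L * max_period, L)
    scan_seq <- paste0(seq, substr(seq, 1L, ext))
  }
  df <- .etandem_scan(dna_to_int(scan_seq), as.integer(min_period),
                      as.integer(max_period), as.integer(threshold),
                      isTRUE(mismatch_allowed), TRUE)
  df$span <- df$period * df$copies
  if (circular && nrow(df) > 0L) {
    df <- df[df$start < L, , drop = FALSE]
    df <- dedupe_circular(df, L)
  }
  if (nrow(df) > 0L) {
    df <- df[order(df$start, df$period), , drop = FALSE]
    rownames(df) <- NULL
  }
  df$bin <- repeat_bin(df$period)
  df$region_class <- if (!is.null(partition)) {
    region_class_at(partition, (df$start + df$span %/% 2L))
  } else rep(NA_character_, nrow(df))
  class(df) <- c("tandem_repeats", "data.frame")
  attr(df, "L") <- L
  attr(df, "circular") <- circular
  df
}

empty_repeats <- function() {
  df <- data.frame(start = integer(), period = integer(), copies = integer(),
                   score = integer(), mismatches = integer(),
                   unit = character(), span = integer(), bin = character(),
                   region_class = character(), stringsAsFactors = FALSE)
  class(df) <- c("tandem_repeats", "data.frame")
  df
}

## drop repeats whose circular footprint is contained in a same-period
## repeat of higher (or equal, earlier-reported) score
dedupe_circular <- function(df, L) {
  if (nrow(df) < 2L) return(df)
  o <- order(-df$score, df$start)
  keep <- rep(TRUE, nrow(df))
  cover <- function(i) ((df$start[i] + seq_len(df$span[i]) - 1L) %% L)
  for (a in seq_along(o)) {
    i <- o[a]
    if (!keep[i]) next
    ci <- cover(i)
    for (b in seq_along(o)) {
      if (b <= a) next
      j <- o[b]
      if (!keep[j] || df$period[j] != df$period[i]) next
      if (all(cover(j) %in% ci)) keep[j] <- FALSE
    }
  }
  df[keep, , drop = FALSE]
}

repeat_bin <- function(period) {
  cut(period, breaks = c(1, 100, 200, 300, 400, 500), labels = REPEAT_BINS)
}

#' Collapse overlapping repeats of different periods
#'
#' Keeps the highest-scoring repeat in each cluster of mutually
#' overlapping reports; ties broken by smaller period, then leftmost
#' start.
#' @param repeats a [find_tandem_repeats()] result.
#' @export
dedupe_repeats <- function(repeats) {
  if (nrow(repeats) < 2L) return(repeats)
  o <- order(-repeats$score, repeats$period, repeats$start)
  keep <- logical(nrow(repeats))
  taken <- matrix(numeric(0), ncol = 2)
  for (i in o) {
    s <- repeats$start[i]; e <- s + repeats$span[i]
    if (nrow(taken) == 0L || all(e <= taken[, 1] | taken[, 2] <= s)) {
      keep[i] <- TRUE
      taken <- rbind(taken, c(s, e))
    }
  }
  out <- repeats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Histogram of repeats by length bin and region class
#'
#' Bins are by repeat unit length (period) by default; `by = "span"`
#' bins by the total repeat span instead.
#' @export
bin_repeats <- function(repeats, by = c("period", "span")) {
  by <- match.arg(by)
  val <- if (by == "period") repeats$period else repeats$span
  b <- cut(val, breaks = c(1, 100, 200, 300, 400, 500, Inf),
           labels = c(REPEAT_BINS, ">500"))
  rc <- factor(ifelse(is.na(repeats$region_class), "unassigned",
                      repeats$region_class),
               levels = c(REGION_CLASSES, "unassigned"))
  table(bin = b, region_class = rc)
}

#' Repeat density (repeats per kbp) in a scope
#'
#' Counts repeats whose midpoint lies in the scope and divides by the
#' scope length: density = 1000 * count / length.
#'
#' @param repeats a [find_tandem_repeats()] result.
#' @param partition the matching [partition_regions()] result (needed for
#'   scopes other than `"genome"`).
#' @param scope `"genome"`, `"lir"`, or a region class name.
#' @return list with `scope`, `count`, `length_bp`, `density`.
#' @export
repeat_density <- function(repeats, partition = NULL,
                           scope = c("genome", "lir", REGION_CLASSES)) {
  scope <- match.arg(scope)
  L <- attr(repeats, "L")
  mid <- (repeats$start + repeats$span %/% 2L) %% if (is.null(L)) Inf else L
  if (scope == "genome") {
    if (is.null(L)) stop("repeat set carries no genome length")
    count <- nrow(repeats)
    len <- L
  } else {
    if (is.null(partition)) stop("partition required for scope '", scope, "'")
    Lp <- length(partition$labels)
    if (scope == "lir") {
      if (is.null(partition$lir)) stop("partition has no LIR")
      lo <- partition$lir[1]; hi <- partition$lir[2]
      inside <- if (hi <= Lp) mid >= lo & mid < hi
                else mid >= lo | mid < (hi - Lp)
      len <- hi - lo
    } else {
      inside <- region_class_at(partition, mid) == scope
      len <- partition$class_lengths[[scope]]
    }
    if (len == 0) stop("scope '", scope, "' has zero length")
    count <- sum(inside)
  }
  list(scope = scope, count = count, length_bp = len,
       density = 1000 * count / len)
}

#' Write a repeat table as TSV
#' @export
write_repeats_tsv <- function(repeats, path) {
  write.table(as.data.frame(repeats), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
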