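## GC content, windowed GC skew, cumulative skew, origin/terminus calls.

#' GC content of a genome or a region of it
#'
#' (G+C)/(A+C+G+T); N is excluded from numerator and denominator.
#'
#' @param genome an [annotated_genome()] or a nucleotide string.
#' @param region optional: a `c(start, end)` 0-based half-open interval
#'   (`end` may wrap past L on a circular genome), or a region class name
#'   (requires `partition`).
#' @param partition a [partition_regions()] result, needed when `region`
#'   is a class name.
#' @return fraction in [0, 1].
#' @export
gc_content <- function(genome, region = NULL, partition = NULL) {
  circular <- TRUE
  if (inherits(genome, "annotated_genome")) {
    seq <- genome$sequence
    circular <- genome$circular
  } else {
    seq <- toupper(as.character(genome))
  }
  if (!is.null(region)) {
    if (is.character(region)) {
      if (is.null(partition)) stop("partition required for a class region")
      if (!region %in% REGION_CLASSES) stop("unknown region class: ", region)
      pos <- which(REGION_CLASSES[partition$labels] == region)
      if (length(pos) == 0L) stop("region '", region, "' is empty")
      b <- strsplit(seq, "")[[1]][pos]
      seq <- paste(b, collapse = "")
    } else {
      seq <- circular_subseq(seq, region[1], region[2], circular)
    }
  }
  if (nchar(seq) == 0L) stop("empty region")
  counts <- base_counts(seq)
  denom <- sum(counts)
  if (denom == 0L) stop("region contains no unambiguous bases")
  unname((counts["G"] + counts["C"]) / denom)
}

base_counts <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  c(A = sum(b == "A"), C = sum(b == "C"), G = sum(b == "G"),
    T = sum(b == "T"))
}

#' Windowed GC skew profile
#'
#' Computes (G-C)/(G+C) in windows of width `w` starting every `s` bp.
#' On a circular genome windows wrap the origin and the profile has
#' `ceiling(L/s)` entries; on a linear genome windows are truncated at
#' the sequence end.  Windows with no G or C get skew 0 and are flagged.
#'
#' @param genome an [annotated_genome()] or nucleotide string.
#' @param w window size in bp (default 1000).
#' @param s step size in bp (default 25).
#' @return object of class `skew_profile`: list with `positions` (window
#'   starts, 0-based), `skew`, `flagged_empty`, `w`, `s`, `L`,
#'   `circular`, `gc` (genome-wide GC fraction).
#' @export
windowed_gc_skew <- function(genome, w = 1000L, s = 25L) {
  circular <- TRUE
  id <- "sequence"
  if (inherits(genome, "annotated_genome")) {
    seq <- genome$sequence
    circular <- genome$circular
    id <- genome$id
  } else {
    seq <- toupper(as.character(genome))
  }
  L <- nchar(seq)
  if (w < 1L || s < 1L) stop("w and s must be >= 1")
  if (!circular && w > L) stop("window larger than a linear sequence")

  b <- strsplit(seq, "")[[1]]
  g <- as.integer(b == "G")
  cc <- as.integer(b == "C")
  if (circular) {
    ext <- min(w - 1L, L)
    g <- c(g, g[seq_len(ext)])
    cc <- c(cc, cc[seq_len(ext)])
    starts <- seq.int(0L, L - 1L, by = s)
  } else {
    starts <- seq.int(0L, L - w, by = s)
  }
  cg <- c(0L, cumsum(g))
  ccum <- c(0L, cumsum(cc))
  ends <- pmin(starts + w, length(g))
  nG <- cg[ends + 1L] - cg[starts + 1L]
  nC <- ccum[ends + 1L] - ccum[starts + 1L]
  tot <- nG + nC
  skew <- ifelse(tot > 0L, (nG - nC) / pmax(tot, 1L), 0)
  structure(list(positions = starts, skew = skew, flagged_empty = tot == 0L,
                 w = as.integer(w), s = as.integer(s), L = L,
                 circular = circular, id = id,
                 gc = gc_content(seq)),
            class = "skew_profile")
}

#' Cumulative GC skew and replication origin/terminus prediction
#'
#' The cumulative series is the running (prefix) sum of the per-window
#' skew.  Because a circular prefix sum depends on the arbitrary start
#' coordinate, extrema are located on the detrended series (the linear
#' trend `total * i/n` subtracted), which makes the predicted positions
#' invariant under genome rotation.  The global minimum is the predicted
#' replication origin and the global maximum the terminus.  A prominence
#' filter (extremum's deviation from the detrended baseline, as a
#' fraction of the detrended range, default 0.1) marks whether each peak
#' is distinct; a constant-zero profile yields a "no signal" call.
#'
#' @param profile a [windowed_gc_skew()] result.
#' @param lir optional LIR interval `c(start, end)` (from
#'   [partition_regions()]) used to flag whether each prediction falls
#'   inside the large intergenic region.
#' @param prominence minimum relative prominence for a distinct peak.
#' @return object of class `skew_peaks`: list with `cumulative`,
#'   `detrended`, `origin_pred`, `terminus_pred` (genome coordinates of
#'   the extremal windows), `origin_distinct`, `terminus_distinct`,
#'   `origin_in_lir`, `terminus_in_lir`, `no_signal`.
#' @export
cumulative_skew_and_peaks <- function(profile, lir = NULL,
                                      prominence = 0.1) {
  stopifnot(inherits(profile, "skew_profile"))
  cum <- cumsum(profile$skew)
  n <- length(cum)
  if (all(profile$skew == 0)) {
    return(structure(list(cumulative = cum, detrended = cum,
                          origin_pred = NA_real_, terminus_pred = NA_real_,
                          origin_distinct = FALSE, terminus_distinct = FALSE,
                          origin_in_lir = NA, terminus_in_lir = NA,
                          no_signal = TRUE, profile = profile),
                     class = "skew_peaks"))
  }
  trend <- cum[n] * seq_len(n) / n
  det <- cum - trend
  i_min <- which.min(det)
  i_max <- which.max(det)
  rng <- max(det) - min(det)
  origin_pred <- profile$positions[i_min]
  terminus_pred <- profile$positions[i_max]
  origin_distinct <- (0 - min(det)) >= prominence * rng
  terminus_distinct <- (max(det) - 0) >= prominence * rng
  in_lir <- function(pos) {
    if (is.null(lir)) return(NA)
    L <- profile$L
    if (lir[2] <= L) pos >= lir[1] && pos < lir[2]
    else pos >= lir[1] || pos < (lir[2] - L)
  }
  structure(list(cumulative = cum, detrended = det,
                 origin_pred = origin_pred, terminus_pred = terminus_pred,
                 origin_distinct = origin_distinct,
                 terminus_distinct = terminus_distinct,
                 origin_in_lir = in_lir(origin_pred),
                 terminus_in_lir = in_lir(terminus_pred),
                 no_signal = FALSE, profile = profile),
            class = "skew_peaks")
}

#' @export
print.skew_peaks <- function(x, ...) {
  if (x$no_signal) {
    cat("<skew_peaks> no signal (constant-zero skew)\n")
    return(invisible(x))
  }
  cat(sprintf("<skew_peaks> origin ~ %d%s, terminus ~ %d%s\n",
              x$origin_pred,
              if (isTRUE(x$origin_in_lir)) " (in LIR)" else "",
              x$terminus_pred,
              if (isTRUE(x$terminus_in_lir)) " (in LIR)" else ""))
  cat(sprintf("  distinct: origin %s, terminus %s\n",
              x$origin_distinct, x$terminus_distinct))
  invisible(x)
}

#' Write a skew profile (position, skew, cumulative) as TSV
#' @export
write_skew_tsv <- function(profile, path) {
  df <- data.frame(position = profile$positions, skew = profile$skew,
                   cumulative = cumsum(profile$skew))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Circular distance between two positions
#' @export
circular_distance <- function(a, b, L) {
  d <- abs(a - b) %% L
  pmin(d, L - d)
}
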