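## GenBank flat-file input/output.
##
## Only the parts of the format needed for annotated organelle genomes are
## supported: LOCUS (length + topology), the FEATURES table with
## join/complement locations, and ORIGIN.  GenBank's 1-based inclusive
## coordinates are converted to the package's 0-based half-open convention
## on the way in and back on the way out.

GB_FEATURE_KEYS <- c(gene = "gene", CDS = "CDS", intron = "intron",
                     tRNA = "tRNA", rRNA = "rRNA", exon = "exon")

#' Read an annotated genome from a GenBank flat file
#'
#' Parses LOCUS, FEATURES and ORIGIN sections.  `join(...)` locations
#' become multi-segment features, `complement(...)` sets the minus strand,
#' and two-part joins that meet at the sequence origin of a circular
#' record are fused into a single wrapped segment.  CDS features whose
#' `/gene` qualifier looks like `orfNNN` are classed as ORF; `/note`
#' qualifiers mentioning "group I"/"group II" set the intron class token.
#'
#' @param path path to a GenBank flat file.
#' @return an [annotated_genome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0L) stop("empty GenBank file: ", path)

  locus_i <- grep("^LOCUS", lines)[1]
  if (is.na(locus_i)) stop("malformed GenBank record: no LOCUS line")
  locus <- strsplit(trimws(lines[locus_i]), "[[:space:]]+")[[1]]
  if (length(locus) < 3L || is.na(suppressWarnings(as.integer(locus[3])))) {
    stop("malformed LOCUS line: ", lines[locus_i])
  }
  id <- locus[2]
  L <- as.integer(locus[3])
  circular <- any(grepl("circular", locus, ignore.case = TRUE))

  feat_i <- grep("^FEATURES", lines)
  orig_i <- grep("^ORIGIN", lines)
  if (length(orig_i) == 0L) stop("malformed GenBank record: no ORIGIN section")
  orig_i <- orig_i[1]

  ## ---- sequence ----
  end_i <- grep("^//", lines)
  end_i <- if (length(end_i)) end_i[length(end_i)] else length(lines) + 1L
  seq_lines <- lines[seq(orig_i + 1L, end_i - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) != L) {
    stop("ORIGIN sequence length (", nchar(sequence),
         ") disagrees with LOCUS length (", L, ")")
  }

  ## ---- features ----
  feats <- empty_features()
  if (length(feat_i) > 0L) {
    ftab <- lines[seq(feat_i[1] + 1L, orig_i - 1L)]
    feats <- parse_feature_table(ftab, L, circular, feat_i[1])
  }

  annotated_genome(id, sequence, feats, circular = circular)
}

parse_feature_table <- function(ftab, L, circular, offset) {
  recs <- list()  # each: list(key, location, quals)
  i <- 1L
  n <- length(ftab)
  while (i <= n) {
    line <- ftab[i]
    if (grepl("^ {5}\\S", line)) {
      key <- sub("^ {5}(\\S+).*$", "\\1", line)
      loc <- trimws(substring(line, 22L))
      j <- i + 1L
      ## location continuation lines (long joins end with "," mid-line or
      ## leave an unbalanced parenthesis)
      unbalanced <- function(x) {
        lengths(regmatches(x, gregexpr("\\(", x))) >
          lengths(regmatches(x, gregexpr("\\)", x)))
      }
      while (j <= n && grepl("^ {21}", ftab[j]) &&
             !grepl("^ {21}/", ftab[j]) &&
             (endsWith(loc, ",") || unbalanced(loc))) {
        loc <- paste0(loc, trimws(ftab[j]))
        j <- j + 1L
      }
      ## qualifiers
      quals <- character()
      while (j <= n && grepl("^ {21}", ftab[j]) && !grepl("^ {5}\\S", ftab[j])) {
        q <- trimws(ftab[j])
        if (startsWith(q, "/")) {
          quals <- c(quals, q)
        } else if (length(quals)) {
          quals[length(quals)] <- paste0(quals[length(quals)], q)
        }
        j <- j + 1L
      }
      recs[[length(recs) + 1L]] <- list(key = key, location = loc,
                                        quals = quals, line = offset + i)
      i <- j
    } else {
      i <- i + 1L
    }
  }

  rows <- list()
  for (r in recs) {
    if (!r$key %in% names(GB_FEATURE_KEYS)) next
    parsed <- tryCatch(parse_gb_location(r$location, L, circular),
                       error = function(e) {
                         stop("bad location at line ", r$line, " (", r$key,
                              " ", r$location, "): ", conditionMessage(e))
                       })
    gene <- gb_qual(r$quals, "gene")
    if (is.na(gene)) gene <- gb_qual(r$quals, "locus_tag")
    if (is.na(gene)) gene <- gb_qual(r$quals, "product")
    note <- gb_qual(r$quals, "note")
    kind <- r$key
    name <- gene
    parent <- NA_character_
    class_token <- NA_character_
    if (kind == "CDS" && !is.na(gene) && grepl("^orf[0-9]+$", gene)) {
      kind <- "ORF"
    }
    if (kind == "intron") {
      parent <- gene
      if (!is.na(note) && grepl("group II", note)) class_token <- "g2"
      else if (!is.na(note) && grepl("group I", note)) class_token <- "g1"
      nm <- gb_qual(r$quals, "standard_name")
      name <- if (!is.na(nm)) nm else paste0(gene, "-intron")
    }
    if (is.na(name)) name <- paste0(tolower(kind), "_", r$line)
    rows[[length(rows) + 1L]] <- genome_feature(
      kind = kind, name = name, strand = parsed$strand,
      segments = parsed$segments, parent = parent, class_token = class_token)
  }
  if (length(rows) == 0L) return(empty_features())
  do.call(rbind, rows)
}

gb_qual <- function(quals, what) {
  pat <- paste0("^/", what, "=")
  hit <- quals[startsWith(quals, paste0("/", what, "="))]
  if (length(hit) == 0L) return(NA_character_)
  v <- sub(pat, "", hit[1])
  gsub("^\"|\"$", "", v)
}

#' Parse a GenBank location string
#'
#' Handles `a..b`, `a`, `complement(...)`, `join(...)`, `order(...)` and
#' `<`/`>` partial markers.  Returns 0-based half-open segments plus the
#' strand; a two-part join meeting at the origin of a circular sequence is
#' fused into one wrapped segment, and minus-strand multi-segment
#' locations are stored in ascending genomic order (the spliced product is
#' reconstructed by concatenation followed by reverse complement).
#' @keywords internal
parse_gb_location <- function(loc, L, circular = TRUE) {
  loc <- gsub("[[:space:]<>]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^(join|order)\\(", loc)) {
    loc <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
  }
  parts <- strsplit(loc, ",")[[1]]
  segs <- t(vapply(parts, function(p) {
    minus <- grepl("^complement\\(", p)
    p <- sub("^complement\\((.*)\\)$", "\\1", p)
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      ab <- as.numeric(strsplit(p, "\\.\\.")[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      ab <- c(as.numeric(p), as.numeric(p))
    } else {
      stop("unparseable location element '", p, "'")
    }
    if (ab[1] > ab[2]) stop("start > end in '", p, "'")
    c(ab[1] - 1, ab[2], as.numeric(minus))
  }, numeric(3)))
  dimnames(segs) <- NULL
  if (any(segs[, 3] == 1)) {
    if (!all(segs[, 3] == 1)) stop("mixed-strand join is not supported")
    strand <- "-"
  }
  segs <- segs[, 1:2, drop = FALSE]
  if (any(segs[, 2] > L)) stop("feature outside sequence (length ", L, ")")
  ## fuse a join that meets at the origin into one wrapped segment
  if (circular && nrow(segs) >= 2L) {
    k <- nrow(segs)
    if (segs[k - 1L, 2] == L && segs[k, 1] == 0) {
      segs <- rbind(segs[seq_len(k - 2L), , drop = FALSE],
                    c(segs[k - 1L, 1], L + segs[k, 2]))
    }
  }
  if (strand == "-" && nrow(segs) > 1L) {
    segs <- segs[order(segs[, 1]), , drop = FALSE]
  }
  list(segments = segs, strand = strand)
}

## ---- writing --------------------------------------------------------------

#' Write an annotated genome as a GenBank flat file
#'
#' @param genome an [annotated_genome()].
#' @param path output path.
#' @export
write_genbank <- function(genome, path) {
  L <- genome_length(genome)
  topo <- if (genome$circular) "circular" else "linear"
  out <- sprintf("LOCUS       %-16s %d bp    DNA     %s UNA 01-JAN-2026",
                 genome$id, L, topo)
  out <- c(out, sprintf("DEFINITION  %s synthetic annotated genome.",
                        genome$id),
           sprintf("ACCESSION   %s", genome$id),
           "FEATURES             Location/Qualifiers",
           sprintf("     source          1..%d", L),
           sprintf("                     /organism=\"synthetic construct\""),
           sprintf("                     /mol_type=\"genomic DNA\""))
  f <- genome$features
  for (i in seq_len(nrow(f))) {
    key <- if (f$kind[i] == "ORF") "CDS" else f$kind[i]
    loc <- format_gb_location(f$segments[[i]], f$strand[i], L)
    out <- c(out, sprintf("     %-15s %s", key, loc))
    out <- c(out, sprintf("                     /gene=\"%s\"",
                          if (f$kind[i] == "intron") f$parent[i] else f$name[i]))
    if (f$kind[i] == "intron") {
      cls <- if (!is.na(f$class_token[i]) && f$class_token[i] == "g1")
        "group I intron" else "group II intron"
      out <- c(out, sprintf("                     /note=\"%s\"", cls),
               sprintf("                     /standard_name=\"%s\"", f$name[i]))
    }
  }
  out <- c(out, "ORIGIN")
  s <- genome$sequence
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    groups <- substring(chunk, seq(1L, nchar(chunk), 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    out <- c(out, sprintf("%9d %s", p, tolower(paste(groups, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}

format_gb_location <- function(seg, strand, L) {
  fmt1 <- function(s, e) {
    if (e <= L) sprintf("%d..%d", s + 1, e)
    else sprintf("%d..%d,1..%d", s + 1, L, e - L)  # wrapped segment
  }
  parts <- unlist(lapply(seq_len(nrow(seg)), function(i) {
    strsplit(fmt1(seg[i, 1], seg[i, 2]), ",")[[1]]
  }))
  loc <- if (length(parts) > 1L) paste0("join(", paste(parts, collapse = ","), ")")
         else parts
  if (strand == "-") paste0("complement(", loc, ")") else loc
}

#' Read a bare FASTA sequence as an unannotated genome
#' @param path FASTA file (first record used).
#' @param circular topology flag for the resulting genome.
#' @export
read_fasta_genome <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  annotated_genome(names(ss)[1], as.character(ss[[1]]), circular = circular)
}

#' Write the genome sequence as FASTA
#' @export
write_fasta_genome <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
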