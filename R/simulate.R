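## Seeded synthetic mitogenome generator with planted truth.
##
## Emulates the architecture of an AT-rich, intron-rich circular
## mitogenome: protein-coding genes interrupted by group II introns (GT/AG
## termini) that may carry stop-free ORFs (IEPs) and may nest (twintrons),
## two rRNAs (one with an intron) and a handful of tRNAs, a large
## intergenic region densely planted with tandem repeats, and a
## strand-compositional switch (G/C bias) between a planted replication
## origin and terminus.  Every planted element is recorded in a truth
## table so downstream detectors can be scored by parameter recovery.

#' Default simulation configuration
#'
#' Defaults are a scaled-down image of the architecture this package is
#' aimed at: a 40 kb AT-rich circular genome (GC 25%), five coding genes
#' carrying seven group II introns (13.5 kb total) of which four hold
#' IEP ORFs, one twintron, one intron planted as a diverged copy of
#' another (self-proliferation), an 11 kb LIR carrying ten tandem-repeat
#' arrays spanning unit sizes 6-450 bp with >= 3 copies each, and a GC
#' skew amplitude of 0.3 switching at the origin (mid-LIR) and terminus.
#'
#' @param seed integer seed driving the single RNG stream.
#' @param L target genome length (bp); the layout is packed to exactly L.
#' @param gc_background background GC fraction.
#' @param skew_amplitude relative G/C excess on the leading arc, in
#'   [0, 1]; 0 disables the compositional switch.
#' @param lir_length length of the large intergenic region (bp).
#' @param lir_repeats data frame with columns `unit_len` and `copies`.
#' @param genes,rnas,trnas,introns advanced overrides of the gene/intron
#'   catalog; see the function body for the expected shapes.
#' @param copy_divergence substitution rate applied to the planted
#'   intron copy.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, L = 40000L, gc_background = 0.25,
                       skew_amplitude = 0.3, lir_length = 11000L,
                       lir_repeats = NULL, genes = NULL, rnas = NULL,
                       trnas = NULL, introns = NULL,
                       copy_divergence = 0.05) {
  if (skew_amplitude < 0 || skew_amplitude > 1) {
    stop("skew_amplitude must be in [0, 1]")
  }
  if (is.null(genes)) {
    genes <- data.frame(
      name = c("cox1", "cob", "atp6", "atp9", "nad5"),
      exon_len = c(1500L, 1150L, 750L, 230L, 1900L),
      strand = c("+", "+", "-", "+", "+"),
      stringsAsFactors = FALSE)
  }
  if (is.null(rnas)) {
    rnas <- data.frame(name = c("rnl", "rns"),
                       exon_len = c(2800L, 1500L),
                       strand = c("+", "-"), stringsAsFactors = FALSE)
  }
  if (is.null(trnas)) {
    trnas <- data.frame(name = paste0("trn", LETTERS[1:6]),
                        exon_len = rep(72L, 6),
                        strand = c("+", "+", "-", "+", "-", "+"),
                        stringsAsFactors = FALSE)
  }
  if (is.null(introns)) {
    introns <- list(
      list(host = "cox1", site = 447L, length = 2500L, has_orf = TRUE,
           inner = list(site = 1767L, length = 900L)),
      list(host = "cox1", site = 963L, length = 1800L, has_orf = TRUE),
      list(host = "cob", site = 441L, copy_of = "cox1i963g2"),
      list(host = "cob", site = 858L, length = 2200L, has_orf = TRUE),
      list(host = "atp9", site = 87L, length = 1200L, has_orf = FALSE),
      list(host = "nad5", site = 750L, length = 1600L, has_orf = TRUE),
      list(host = "rnl", site = 1200L, length = 1500L, has_orf = FALSE))
  }
  if (is.null(lir_repeats)) {
    lir_repeats <- data.frame(
      unit_len = c(6L, 11L, 17L, 25L, 40L, 60L, 150L, 250L, 350L, 450L),
      copies = c(8L, 5L, 4L, 4L, 3L, 3L, 3L, 3L, 3L, 3L))
  }
  structure(list(seed = as.integer(seed), L = as.integer(L),
                 gc_background = gc_background,
                 skew_amplitude = skew_amplitude,
                 lir_length = as.integer(lir_length),
                 lir_repeats = lir_repeats, genes = genes, rnas = rnas,
                 trnas = trnas, introns = introns,
                 copy_divergence = copy_divergence),
            class = "sim_config")
}

#' Simulate an annotated circular mitogenome with planted truth
#'
#' Deterministic given `config$seed` (one RNG stream, draws in a fixed
#' order: layout spacers, background bases, repeat units, ORF codons,
#' intron-copy mutations).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (an [annotated_genome()]) and `truth`
#'   (planted repeats, introns, twintrons, ORFs, origin/terminus, LIR and
#'   per-class lengths).
#' @export
simulate_mitogenome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$L
  BASES <- c("A", "C", "G", "T")

  ## ---- gene-internal layout (coding-strand coordinates) ----
  units <- build_gene_layouts(config)
  fixed_len <- sum(vapply(units, function(u) u$glen, numeric(1)))
  n_spacers <- length(units) - 1L  # between units; LIR abuts the last unit
  free <- L - fixed_len - config$lir_length
  if (free < 100L * n_spacers) {
    stop("infeasible packing: genes + introns + LIR leave ", free,
         " bp for ", n_spacers, " intergenic spacers")
  }
  ## spacer lengths: random split of the free pool (draw 1)
  w <- stats::runif(n_spacers, 0.5, 1.5)
  spacer <- floor(free * w / sum(w))
  spacer[n_spacers] <- free - sum(spacer[-n_spacers])

  ## ---- genome layout: units + spacers, LIR last ----
  pos <- 0L
  for (i in seq_along(units)) {
    units[[i]]$g0 <- pos
    pos <- pos + units[[i]]$glen +
      if (i <= n_spacers) spacer[i] else 0L
  }
  lir <- c(pos, pos + config$lir_length)
  stopifnot(lir[2] == L)
  ori_pos <- floor((lir[1] + lir[2]) / 2)
  ter_pos <- (ori_pos + floor(L / 2)) %% L

  ## ---- background sequence with compositional switch (draw 2) ----
  gc <- config$gc_background
  amp <- config$skew_amplitude
  on_leading <- arc_membership(L, ori_pos, ter_pos)
  pG <- ifelse(on_leading, gc / 2 * (1 + amp), gc / 2 * (1 - amp))
  pC <- gc - pG
  u <- stats::runif(L)
  genome_seq <- ifelse(u < pG, "G",
                ifelse(u < pG + pC, "C",
                ifelse(u < pG + pC + (1 - gc) / 2, "A", "T")))

  ## ---- plant tandem repeats in the LIR (draw 3) ----
  reps <- config$lir_repeats
  total_span <- sum(reps$unit_len * reps$copies)
  gap_pool <- config$lir_length - total_span - 200L
  if (gap_pool < nrow(reps)) stop("infeasible packing: LIR too small for ",
                                  "the planted repeats")
  gw <- stats::runif(nrow(reps) + 1L)
  gaps <- floor(gap_pool * gw / sum(gw))
  truth_rep <- list()
  p <- lir[1] + 100L
  for (i in seq_len(nrow(reps))) {
    p <- p + gaps[i]
    ulen <- reps$unit_len[i]
    unit <- sample_bases(ulen, pG[(p %% L) + 1L], pC[(p %% L) + 1L], gc)
    arr <- strrep(unit, reps$copies[i])
    substr_assign <- seq.int(p, p + nchar(arr) - 1L) + 1L
    genome_seq[substr_assign] <- strsplit(arr, "")[[1]]
    truth_rep[[i]] <- data.frame(start = p, period = ulen,
                                 copies = reps$copies[i], unit = unit,
                                 stringsAsFactors = FALSE)
    p <- p + nchar(arr)
  }
  truth_rep <- do.call(rbind, truth_rep)

  ## ---- write gene content: ORFs, intron copies, GT/AG (draws 4-5) ----
  ## write coding-strand `str` at coding offset t1 of unit u; the
  ## minus-strand mapping is coding [t1, t2) -> genome
  ## [g0 + glen - t2, g0 + glen - t1), reverse-complemented
  place <- function(u, t1, str) {
    chars <- strsplit(str, "")[[1]]
    if (u$strand == "+") {
      idx <- u$g0 + t1 + seq_along(chars)
      genome_seq[idx] <<- chars
    } else {
      t2 <- t1 + length(chars)
      idx <- u$g0 + u$glen - t2 + seq_along(chars)
      genome_seq[idx] <<- rev(chartr("ACGT", "TGCA", chars))
    }
  }
  read_coding <- function(u, t1, t2) {
    if (u$strand == "+") {
      paste(genome_seq[u$g0 + seq.int(t1 + 1L, t2)], collapse = "")
    } else {
      s <- paste(genome_seq[u$g0 + u$glen - t2 + seq_len(t2 - t1)],
                 collapse = "")
      dna_revcomp(s)
    }
  }
  unit_by_name <- setNames(seq_along(units),
                           vapply(units, `[[`, character(1), "name"))

  ## ORF codon streams (AT-rich codon usage, stop-free under table 4)
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    for (o in u$orfs) {
      place(u, o$rel[1], orf_sequence((o$rel[2] - o$rel[1]) / 3L, gc))
    }
  }
  ## planted intron copy (after its source is final)
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    for (iv in u$introns) {
      if (is.null(iv$copy_of)) next
      src <- find_intron_rel(units, iv$copy_of)
      src_seq <- read_coding(units[[src$unit]], src$rel[1], src$rel[2])
      place(u, iv$rel[1], mutate_seq(src_seq, config$copy_divergence))
    }
  }
  ## GT/AG termini for every intron (outer termini flank the full extent)
  for (ui in seq_along(units)) {
    u <- units[[ui]]
    for (iv in u$introns) {
      place(u, iv$rel[1], "GT")
      place(u, iv$rel[2] - 2L, "AG")
      if (!is.null(iv$inner)) {
        place(u, iv$inner$rel[1], "GT")
        place(u, iv$inner$rel[2] - 2L, "AG")
      }
    }
  }

  genome_sequence <- paste(genome_seq, collapse = "")

  ## ---- features + truth ----
  built <- build_features(units, L)
  genome <- annotated_genome(sprintf("SIM%06d", config$seed),
                             genome_sequence, built$features,
                             circular = TRUE, genetic_code = 4L)
  truth <- list(seed = config$seed, L = L, ori_pos = ori_pos,
                ter_pos = ter_pos, lir = lir, repeats = truth_rep,
                introns = built$introns, twintrons = built$twintrons,
                orfs = built$orfs,
                class_lengths = built$class_lengths_of(L, config))
  list(genome = genome, truth = truth)
}

arc_membership <- function(L, ori, ter) {
  ## TRUE for positions on the ori -> ter arc (increasing coordinate)
  i <- seq_len(L) - 1L
  if (ori <= ter) i >= ori & i < ter else i >= ori | i < ter
}

sample_bases <- function(n, pg, pc, gc) {
  u <- stats::runif(n)
  paste(ifelse(u < pg, "G",
        ifelse(u < pg + pc, "C",
        ifelse(u < pg + pc + (1 - gc) / 2, "A", "T"))), collapse = "")
}

## stop-free ORF under translation table 4 (stops TAA/TAG; TGA = Trp),
## codons sampled with AT-rich usage matching the genome composition
orf_sequence <- function(n_codons, gc) {
  pb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  codons <- as.vector(outer(outer(names(pb), names(pb), paste0),
                            names(pb), paste0))
  wts <- as.vector(outer(outer(pb, pb), pb))
  keep <- !codons %in% c("TAA", "TAG")
  body <- sample(codons[keep], n_codons - 2L, replace = TRUE,
                 prob = wts[keep] / sum(wts[keep]))
  paste0("ATG", paste(body, collapse = ""), "TAA")
}

mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

## ---- layout helpers -------------------------------------------------------

## Resolve each gene/rna/trna into coding-strand relative intervals:
## exon chunks, introns (with nesting and ORFs), total length.
build_gene_layouts <- function(config) {
  catalog <- rbind(
    data.frame(name = config$genes$name, exon_len = config$genes$exon_len,
               strand = config$genes$strand, kind = "coding",
               stringsAsFactors = FALSE),
    data.frame(name = config$rnas$name, exon_len = config$rnas$exon_len,
               strand = config$rnas$strand, kind = "rRNA",
               stringsAsFactors = FALSE),
    data.frame(name = config$trnas$name, exon_len = config$trnas$exon_len,
               strand = config$trnas$strand, kind = "tRNA",
               stringsAsFactors = FALSE))

  ## resolve copy_of lengths first
  specs <- config$introns
  by_name <- list()
  for (s in specs) {
    if (is.null(s$copy_of)) {
      nm <- name_intron(s$host, s$site, "g2")
      by_name[[nm]] <- s
    }
  }
  for (k in seq_along(specs)) {
    s <- specs[[k]]
    if (!is.null(s$copy_of)) {
      src <- by_name[[s$copy_of]]
      if (is.null(src)) stop("copy_of target not found: ", s$copy_of)
      specs[[k]]$length <- src$length
      specs[[k]]$has_orf <- FALSE
      if (!is.null(src$inner)) specs[[k]]$inner <- src$inner
    }
  }

  units <- list()
  for (gi in seq_len(nrow(catalog))) {
    g <- catalog[gi, ]
    gin <- Filter(function(s) s$host == g$name, specs)
    gin <- gin[order(vapply(gin, `[[`, integer(1), "site"))]
    sites <- vapply(gin, `[[`, integer(1), "site")
    if (any(sites < 1L | sites > g$exon_len)) {
      stop("intron site outside exon for gene ", g$name)
    }
    if (anyDuplicated(sites)) stop("duplicate intron sites in ", g$name)
    exons <- list(); introns <- list(); orfs <- list()
    cursor <- 0L; consumed <- 0L
    bounds <- c(sites, g$exon_len)
    prev <- 0L
    for (k in seq_along(bounds)) {
      chunk <- bounds[k] - prev
      exons[[length(exons) + 1L]] <- c(cursor, cursor + chunk)
      cursor <- cursor + chunk
      prev <- bounds[k]
      if (k <= length(gin)) {
        s <- gin[[k]]
        extent <- s$length + if (!is.null(s$inner)) s$inner$length else 0L
        iv <- list(rel = c(cursor, cursor + extent), site = s$site,
                   length = s$length, has_orf = isTRUE(s$has_orf),
                   copy_of = s$copy_of, inner = NULL)
        if (!is.null(s$inner)) {
          if (s$inner$site < 1L || s$inner$site > s$length - 1L) {
            stop("inner intron site outside outer intron in ", g$name)
          }
          iv$inner <- list(
            rel = c(cursor + s$inner$site,
                    cursor + s$inner$site + s$inner$length),
            site = s$inner$site, length = s$inner$length)
        }
        if (iv$has_orf) {
          orf_len <- 3L * floor(min(0.6 * s$length, s$length - 240L) / 3L)
          orf_start <- cursor + 120L
          if (!is.null(iv$inner) && orf_start + orf_len > iv$inner$rel[1]) {
            orf_len <- 3L * floor((iv$inner$rel[1] - orf_start - 30L) / 3L)
          }
          if (orf_len >= 90L) {
            orfs[[length(orfs) + 1L]] <- list(
              rel = c(orf_start, orf_start + orf_len),
              name = paste0("orf", orf_len / 3L),
              intron_site = s$site)
          }
        }
        introns[[length(introns) + 1L]] <- iv
        cursor <- cursor + extent
      }
    }
    units[[length(units) + 1L]] <- list(
      name = g$name, kind = g$kind, strand = g$strand,
      exon_len = g$exon_len, glen = cursor, exons = exons,
      introns = introns, orfs = orfs, g0 = NA_integer_)
  }
  units
}

find_intron_rel <- function(units, name) {
  parsed <- parse_intron_name(name)
  for (ui in seq_along(units)) {
    if (units[[ui]]$name != parsed$gene) next
    for (iv in units[[ui]]$introns) {
      if (iv$site == parsed$site) return(list(unit = ui, rel = iv$rel))
    }
  }
  stop("intron not found: ", name)
}

## map a coding-relative [t1, t2) interval of unit u to genome coordinates
map_rel <- function(u, t1, t2) {
  if (u$strand == "+") c(u$g0 + t1, u$g0 + t2)
  else c(u$g0 + u$glen - t2, u$g0 + u$glen - t1)
}

build_features <- function(units, L) {
  feats <- list()
  introns_truth <- list(); twintrons_truth <- list(); orfs_truth <- list()
  for (u in units) {
    gseg <- map_rel(u, 0L, u$glen)
    if (u$kind == "tRNA") {
      feats[[length(feats) + 1L]] <- genome_feature(
        "tRNA", u$name, gseg[1], gseg[2], strand = u$strand)
      next
    }
    feats[[length(feats) + 1L]] <- genome_feature(
      "gene", u$name, gseg[1], gseg[2], strand = u$strand)
    exon_segs <- do.call(rbind, lapply(u$exons, function(e) {
      map_rel(u, e[1], e[2])
    }))
    exon_segs <- exon_segs[exon_segs[, 2] > exon_segs[, 1], , drop = FALSE]
    exon_segs <- exon_segs[order(exon_segs[, 1]), , drop = FALSE]
    feats[[length(feats) + 1L]] <- genome_feature(
      if (u$kind == "coding") "CDS" else "rRNA", u$name,
      segments = exon_segs, strand = u$strand)
    for (iv in u$introns) {
      iseg <- map_rel(u, iv$rel[1], iv$rel[2])
      nm <- name_intron(u$name, iv$site, "g2")
      if (!is.null(iv$inner)) {
        tw_nm <- name_intron(u$name, iv$site, "g2",
                             inner = list(site = iv$inner$site,
                                          class = "g2"))
        inner_seg <- map_rel(u, iv$inner$rel[1], iv$inner$rel[2])
        feats[[length(feats) + 1L]] <- genome_feature(
          "intron", nm, iseg[1], iseg[2], strand = u$strand,
          parent = u$name, class_token = "g2")
        feats[[length(feats) + 1L]] <- genome_feature(
          "intron", tw_nm, inner_seg[1], inner_seg[2], strand = u$strand,
          parent = u$name, class_token = "g2")
        twintrons_truth[[length(twintrons_truth) + 1L]] <- data.frame(
          name = tw_nm, outer = nm, inner = tw_nm, stringsAsFactors = FALSE)
        introns_truth[[length(introns_truth) + 1L]] <- data.frame(
          name = tw_nm, host = u$name, start = inner_seg[1],
          end = inner_seg[2], strand = u$strand, stringsAsFactors = FALSE)
      } else {
        feats[[length(feats) + 1L]] <- genome_feature(
          "intron", nm, iseg[1], iseg[2], strand = u$strand,
          parent = u$name, class_token = "g2")
      }
      introns_truth[[length(introns_truth) + 1L]] <- data.frame(
        name = nm, host = u$name, start = iseg[1], end = iseg[2],
        strand = u$strand, stringsAsFactors = FALSE)
    }
    for (o in u$orfs) {
      oseg <- map_rel(u, o$rel[1], o$rel[2])
      feats[[length(feats) + 1L]] <- genome_feature(
        "ORF", o$name, oseg[1], oseg[2], strand = u$strand)
      orfs_truth[[length(orfs_truth) + 1L]] <- data.frame(
        name = o$name, start = oseg[1], end = oseg[2], strand = u$strand,
        host = u$name, stringsAsFactors = FALSE)
    }
  }
  features <- do.call(rbind, feats)
  bindr <- function(x) if (length(x)) do.call(rbind, x) else NULL
  class_lengths_of <- function(L, config) {
    exon <- sum(config$genes$exon_len)
    rrna <- sum(config$rnas$exon_len)
    trna <- sum(config$trnas$exon_len)
    gl <- sum(vapply(units, function(u) u$glen, numeric(1)))
    intron <- gl - exon - rrna - trna
    c(exon = exon, intron = intron, rRNA = rrna, tRNA = trna,
      intergenic = L - gl)
  }
  list(features = features, introns = bindr(introns_truth),
       twintrons = bindr(twintrons_truth), orfs = bindr(orfs_truth),
       class_lengths_of = class_lengths_of)
}

#' Simulate protein families for network testing
#'
#' Generates `n_families` unrelated ancestral amino-acid sequences and,
#' for each, `family_size` diverged members (i.i.d. substitutions at
#' `divergence`), labeled with the family as lineage.  Unrelated
#' families share no detectable similarity, so the expected component
#' structure of the IEP network equals the family structure.
#'
#' @export
simulate_iep_families <- function(n_families = 3L, family_size = 4L,
                                  length_aa = 250L, divergence = 0.25,
                                  seed = 1L) {
  set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  rows <- list()
  for (f in seq_len(n_families)) {
    anc <- sample(aa, length_aa, replace = TRUE)
    for (m in seq_len(family_size)) {
      s <- anc
      hit <- which(stats::runif(length_aa) < divergence)
      s[hit] <- sample(aa, length(hit), replace = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("fam%d_m%d", f, m), sequence = paste(s, collapse = ""),
        lineage = paste0("family", f), compartment = "MT",
        host_gene = NA_character_, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a simulation's truth table as JSON
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
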