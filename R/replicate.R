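## End-to-end analysis of the three deposited Porphyridium-type
## mitogenome records.  The GenBank flat files are not bundled (they are
## full 56-132 kb genome records); download MT483995, MT483996 and
## MT483997 from NCBI and point `dir` at them.

#' Run the full architecture analysis on the reference genome records
#'
#' For each record: region partition and LIR, genome decomposition
#' (per-gene intron fractions, genic intron share), GC content, tandem
#' repeats (unit sizes 2-500, consensus score threshold 20) with LIR
#' counts and densities, GC skew origin/terminus calls, splice-site
#' PFMs, and twintron detection.
#'
#' @param dir directory containing `<accession>.gb` GenBank flat files.
#' @param accessions record basenames to analyse.
#' @param max_period largest tandem-repeat unit size to scan.
#' @return named list of per-genome result bundles plus a pooled
#'   splice-context PFM set.
#' @export
replicate_reference_analysis <- function(dir,
                                         accessions = c("MT483995",
                                                        "MT483996",
                                                        "MT483997"),
                                         max_period = 500L) {
  paths <- file.path(dir, paste0(accessions, ".gb"))
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("reference record(s) not found: ",
         paste(paths[missing], collapse = ", "),
         ". Download the GenBank flat files from NCBI first.")
  }
  out <- list()
  all_ctx <- list()
  for (k in seq_along(accessions)) {
    g <- read_genbank(paths[k])
    part <- partition_regions(g)
    dec <- decompose_genome(g, part)
    reps <- find_tandem_repeats(g, max_period = max_period,
                                partition = part)
    reps_d <- dedupe_repeats(reps)
    prof <- windowed_gc_skew(g, w = 1000L, s = 25L)
    peaks <- cumulative_skew_and_peaks(prof, lir = part$lir)
    tw <- detect_twintrons(g)
    ctx <- extract_splice_contexts(g)
    all_ctx[[k]] <- ctx
    out[[accessions[k]]] <- list(
      genome = g, partition = part, decomposition = dec,
      repeats = reps, repeats_deduped = reps_d,
      lir_density = if (!is.null(part$lir))
        repeat_density(reps_d, part, "lir") else NULL,
      gc = gc_content(g), skew = prof, peaks = peaks,
      twintrons = tw, contexts = ctx)
  }
  pooled <- do.call(rbind, all_ctx)
  out$pooled_pfms <- lapply(
    setNames(nm = c("donor_exon", "donor_intron", "acceptor_intron",
                    "acceptor_exon")),
    function(slot) build_pfm(pooled, slot))
  out
}
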