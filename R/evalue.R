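## Karlin-Altschul E-value estimates.
##
## E = K * m * n * exp(-lambda * S) for an alignment of score S between
## sequences of (effective) lengths m and n.  For the nucleotide scheme
## used here (+1 match / -2 mismatch) the ungapped lambda has the closed
## form log((3 + sqrt(21)) / 2) at uniform base composition; K is taken
## from the standard BLASTN tables for that scheme.  For gapped protein
## alignments with BLOSUM62 the standard gapped constants are used as
## defaults.  All constants are configurable.

#' Karlin-Altschul parameters for the package's nucleotide scoring
#' @export
ka_params_dna <- function() {
  list(lambda = log((3 + sqrt(21)) / 2), K = 0.621)
}

#' Karlin-Altschul parameters for gapped BLOSUM62 protein alignment
#' @export
ka_params_protein <- function() {
  list(lambda = 0.267, K = 0.041)
}

#' Karlin-Altschul E-value
#' @param score alignment score.
#' @param m,n search-space sequence lengths.
#' @param params list with `lambda` and `K`.
#' @export
ka_evalue <- function(score, m, n, params = ka_params_dna()) {
  params$K * as.numeric(m) * as.numeric(n) * exp(-params$lambda * score)
}
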