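## Intron nomenclature: <gene>i<site><class>[ii<site><class>] — e.g.
## cobi858g2 for a group II intron inserted after exon position 858 of cob,
## and cobi858g2ii2121g2 for a twintron whose inner intron sits after
## position 2121 of the outer intron.

#' Build an intron (or twintron) name
#'
#' @param gene host gene symbol.
#' @param insertion_site 1-based exon position after which the intron is
#'   inserted.
#' @param class intron class token, `"g1"` or `"g2"`.
#' @param inner for twintrons, a `list(site =, class =)` describing the
#'   inner intron's insertion position within the outer intron.
#' @return the nomenclature string.
#' @examples
#' name_intron("cob", 858, "g2", inner = list(site = 2121, class = "g2"))
#' @export
name_intron <- function(gene, insertion_site, class = "g2", inner = NULL) {
  check_tok <- function(x) {
    if (!is.character(x) || length(x) != 1L || !x %in% c("g1", "g2")) {
      stop("unknown intron class token: ", deparse(x))
    }
  }
  if (insertion_site < 1) stop("insertion_site must be >= 1")
  check_tok(class)
  nm <- paste0(gene, "i", as.integer(insertion_site), class)
  if (!is.null(inner)) {
    if (inner$site < 1) stop("inner insertion site must be >= 1")
    check_tok(inner$class)
    nm <- paste0(nm, "ii", as.integer(inner$site), inner$class)
  }
  nm
}

#' Parse an intron name back into its components
#'
#' Inverse of [name_intron()].
#' @param name an intron or twintron name.
#' @return list with `gene`, `site`, `class` and (for twintrons) `inner`.
#' @export
parse_intron_name <- function(name) {
  pat <- "^(.*?)i([0-9]+)(g[12])(?:ii([0-9]+)(g[12]))?$"
  m <- regmatches(name, regexec(pat, name, perl = TRUE))[[1]]
  if (length(m) == 0L || m[2] == "") stop("unparseable intron name: ", name)
  out <- list(gene = m[2], site = as.integer(m[3]), class = m[4])
  if (m[5] != "") out$inner <- list(site = as.integer(m[5]), class = m[6])
  out
}
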