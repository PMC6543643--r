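#' The nine arsenic resistance and metabolism marker genes
#'
#' Canonical ordering of the gene families profiled by this package:
#' arsenite efflux pumps (\code{acr3}, \code{arsB}), cytoplasmic arsenate
#' reductases (\code{arsC_grx}, \code{arsC_trx}), the regulator/chaperone
#' \code{arsD}, the arsenite methyltransferase \code{arsM}, and the
#' energy-metabolism genes \code{aioA} (arsenite oxidase), \code{arrA}
#' (respiratory arsenate reductase) and \code{arxA} (alternative arsenite
#' oxidase). The ordering is canonical: it is used as a deterministic
#' tie-break in ORF deduplication.
#'
#' @return Character vector of the nine gene names.
#' @export
#' @examples
#' arsenic_genes()
arsenic_genes <- function() {
  c("acr3", "aioA", "arrA", "arsB", "arsC_grx", "arsC_trx", "arsD",
    "arsM", "arxA")
}

#' Genes subject to the elevated bit-score threshold
#'
#' Homologs of other molybdopterin oxidoreductases produce spurious
#' high-scoring hits for the arsenic energy-metabolism genes, so these three
#' families are screened at a higher bit-score floor (default 1000 bits
#' rather than 100).
#'
#' @return Character vector: \code{aioA}, \code{arrA}, \code{arxA}.
#' @export
elevated_genes <- function() c("aioA", "arrA", "arxA")

#' Detoxification versus metabolism gene grouping
#'
#' Detoxification genes protect the cell (efflux, cytoplasmic reduction,
#' methylation support); metabolism genes couple arsenic redox chemistry to
#' energy conservation. Used when contrasting abundance of the two guilds.
#'
#' @param group Either \code{"detoxification"} or \code{"metabolism"}.
#' @return Character vector of gene names.
#' @export
gene_group <- function(group = c("detoxification", "metabolism")) {
  group <- match.arg(group)
  if (group == "detoxification") {
    c("acr3", "arsB", "arsC_grx", "arsC_trx", "arsD")
  } else {
    c("aioA", "arrA", "arsM", "arxA")
  }
}

# reference protein lengths used by the synthetic generator: transporter-like
# families get 150 aa, the small reductases 120 aa
gene_protein_length <- function(gene) {
  ifelse(gene %in% c("arsC_grx", "arsC_trx", "arsD"), 120L, 150L)
}
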