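#' Build a genome x gene x location genotype matrix
#'
#' Tallies screened, deduplicated, annotated hits into per-genome copy
#' counts, split by genomic location (chromosome vs plasmid). Genomes with
#' no retained hits are kept as all-zero rows: absence of a genotype is
#' itself a result.
#'
#' @param hits Annotated hit table (see [process_hits()]).
#' @param genomes Genome metadata (\code{genome_id}, \code{phylum}); defines
#'   the full genome set, including hit-free genomes.
#' @return A \code{genotype_matrix}: list with integer matrices
#'   \code{chromosome} and \code{plasmid} (genomes x genes), and
#'   \code{phylum}, a named character vector over genomes.
#' @export
#' @examples
#' g <- generate_genomes(n_genomes = 30, seed = 4)
#' gm <- build_genotype_matrix(process_hits(g$hits, g$genomes)$hits, g$genomes)
#' gm
build_genotype_matrix <- function(hits, genomes) {
  assert_cols(genomes, c("genome_id", "phylum"), "genome metadata")
  if (anyDuplicated(genomes$genome_id)) stop_("duplicate genome ids in metadata")
  validate_hit_table(hits)
  unknown <- setdiff(hits$genome_id, genomes$genome_id)
  if (length(unknown)) {
    stop_("hits reference genomes absent from metadata: ",
          paste(utils::head(unknown, 5L), collapse = ", "))
  }
  genome_ids <- genomes$genome_id
  genes <- arsenic_genes()
  tally <- function(loc) {
    h <- hits[hits$replicon_type == loc, , drop = FALSE]
    m <- table(factor(h$genome_id, levels = genome_ids),
               factor(h$gene, levels = genes))
    m <- matrix(as.integer(m), nrow = length(genome_ids),
                dimnames = list(genome_ids, genes))
    m
  }
  structure(list(chromosome = tally("chromosome"),
                 plasmid = tally("plasmid"),
                 phylum = stats::setNames(genomes$phylum, genome_ids)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tot <- x$chromosome + x$plasmid
  carriers <- rowSums(tot) > 0
  cat(sprintf("Genotype matrix: %d genomes x %d genes\n",
              nrow(tot), ncol(tot)))
  cat(sprintf("  copies: %d chromosomal, %d plasmid-borne\n",
              sum(x$chromosome), sum(x$plasmid)))
  cat(sprintf("  genomes with >= 1 gene: %d (%.1f%%); none: %d (%.1f%%)\n",
              sum(carriers), 100 * mean(carriers),
              sum(!carriers), 100 * mean(!carriers)))
  invisible(x)
}

#' @export
as.data.frame.genotype_matrix <- function(x, ...) {
  genes <- colnames(x$chromosome)
  long <- expand.grid(genome_id = rownames(x$chromosome), gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  long$chromosome <- as.vector(x$chromosome)
  long$plasmid <- as.vector(x$plasmid)
  long$phylum <- unname(x$phylum[long$genome_id])
  long
}

#' Genomes carrying no profiled gene
#'
#' @param matrix A \code{genotype_matrix}.
#' @return List with \code{count} (all-zero genomes) and \code{proportion}
#'   (count / total genomes).
#' @export
none_fraction <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  tot <- matrix$chromosome + matrix$plasmid
  if (nrow(tot) == 0L) stop_("empty genotype matrix")
  n_none <- sum(rowSums(tot) == 0)
  list(count = n_none, proportion = n_none / nrow(tot))
}

#' Phylum composition of gene carriers
#'
#' For each gene, counts carrier genomes (>= 1 copy on chromosome or
#' plasmid) per phylum and the carrier proportion each phylum contributes.
#' Genes with no carriers are listed in the \code{"genes_without_carriers"}
#' attribute rather than as rows.
#'
#' @param matrix A \code{genotype_matrix}.
#' @return \code{data.frame} with \code{gene}, \code{phylum},
#'   \code{carriers}, \code{proportion}; per gene the proportions sum to 1.
#' @export
phylum_gene_proportions <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  tot <- matrix$chromosome + matrix$plasmid
  genes <- colnames(tot)
  pieces <- lapply(genes, function(g) {
    carriers <- matrix$phylum[tot[, g] > 0]
    if (!length(carriers)) return(NULL)
    tab <- table(carriers)
    data.frame(gene = g, phylum = names(tab),
               carriers = as.integer(tab),
               proportion = as.numeric(tab) / sum(tab),
               stringsAsFactors = FALSE)
  })
  empty <- genes[vapply(pieces, is.null, logical(1))]
  out <- do.call(rbind, pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(gene = character(), phylum = character(),
                      carriers = integer(), proportion = numeric())
  }
  rownames(out) <- NULL
  attr(out, "genes_without_carriers") <- empty
  out
}

#' Per-genome total copy-number histogram
#'
#' Total copies per genome per gene (chromosomal + plasmid copies from the
#' same organism), tabulated over carrier genomes.
#'
#' @param matrix A \code{genotype_matrix}.
#' @return \code{data.frame} with \code{gene}, \code{total_copies},
#'   \code{n_genomes}; per gene, \code{n_genomes} sums to the carrier count.
#' @export
copy_number_histogram <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  tot <- matrix$chromosome + matrix$plasmid
  pieces <- lapply(colnames(tot), function(g) {
    copies <- tot[, g]
    copies <- copies[copies > 0]
    if (!length(copies)) return(NULL)
    tab <- table(copies)
    data.frame(gene = g, total_copies = as.integer(names(tab)),
               n_genomes = as.integer(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  if (is.null(out)) {
    out <- data.frame(gene = character(), total_copies = integer(),
                      n_genomes = integer())
  }
  rownames(out) <- NULL
  out
}

#' Plasmid-borne share of a gene's copies
#'
#' Fraction of a gene's retained hit copies found on plasmids (copies, not
#' carrier genomes: mobile copies are the unit of interest for horizontal
#' transfer).
#'
#' @param matrix A \code{genotype_matrix}.
#' @param gene One of [arsenic_genes()].
#' @return Proportion in [0, 1].
#' @export
plasmid_fraction <- function(matrix, gene) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  gene <- match.arg(gene, arsenic_genes())
  pl <- sum(matrix$plasmid[, gene])
  ch <- sum(matrix$chromosome[, gene])
  if (pl + ch == 0L) stop_("no retained hits for gene ", gene)
  pl / (pl + ch)
}

#' Binary presence/absence traits from a genotype matrix
#'
#' Extracts, for one gene and genomic location, the 0/1 presence vector over
#' the tips of a tree, in tip order: the trait consumed by [signal_test()].
#'
#' @param matrix A \code{genotype_matrix}.
#' @param gene One of [arsenic_genes()].
#' @param location \code{"chromosome"}, \code{"plasmid"}, or \code{"any"}.
#' @param tree An \code{ape::phylo}; tips must be genomes of the matrix.
#' @return Named integer vector of 0/1 over \code{tree$tip.label}.
#' @export
genotype_trait <- function(matrix, gene,
                           location = c("chromosome", "plasmid", "any"),
                           tree) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  gene <- match.arg(gene, arsenic_genes())
  location <- match.arg(location)
  counts <- switch(location,
                   chromosome = matrix$chromosome[, gene],
                   plasmid = matrix$plasmid[, gene],
                   any = matrix$chromosome[, gene] + matrix$plasmid[, gene])
  missing <- setdiff(tree$tip.label, names(counts))
  if (length(missing)) {
    stop_("tree tip(s) absent from genotype matrix: ",
          paste(utils::head(missing, 5L), collapse = ", "))
  }
  x <- as.integer(counts[tree$tip.label] > 0)
  names(x) <- tree$tip.label
  x
}
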