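#' Read a homology-search hit table
#'
#' Reads the tab-separated hit table produced by an hmmsearch post-processing
#' step (or by [generate_genomes()]): one row per hit of a gene model against
#' an ORF on a replicon, with bit score and percent alignment (100 x aligned
#' model positions / model length). All rows are validated; a malformed row
#' is a hard error naming the row, never a silent drop.
#'
#' @param path Path to a UTF-8, tab-separated file with header columns
#'   \code{genome_id}, \code{replicon_id}, \code{replicon_type},
#'   \code{orf_id}, \code{gene}, \code{score}, \code{percent_alignment}.
#' @return A \code{data.frame} hit table in file order.
#' @seealso [write_hit_table()], [screen_hits()]
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop_("hit table not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  assert_cols(df, hit_table_columns(), "hit table")
  df <- df[, hit_table_columns()]
  df$score <- suppressWarnings(as.numeric(df$score))
  df$percent_alignment <- suppressWarnings(as.numeric(df$percent_alignment))
  validate_hit_table(df)
  df
}

hit_table_columns <- function() {
  c("genome_id", "replicon_id", "replicon_type", "orf_id", "gene",
    "score", "percent_alignment")
}

#' Validate a hit table against its invariants
#'
#' Checks column presence, the replicon-type and gene vocabularies, finite
#' scores and percent alignment in [0, 100]. Errors name the first offending
#' rows.
#'
#' @param hits A hit table \code{data.frame}.
#' @return \code{hits}, invisibly, if valid.
#' @export
validate_hit_table <- function(hits) {
  assert_cols(hits, hit_table_columns(), "hit table")
  bad_row <- function(test, msg) {
    idx <- which(test)
    if (length(idx)) {
      stop_("invalid hit table: ", msg, " in row(s) ",
            paste(utils::head(idx, 5L), collapse = ", "),
            if (length(idx) > 5L) sprintf(" (and %d more)", length(idx) - 5L))
    }
  }
  bad_row(!hits$replicon_type %in% c("chromosome", "plasmid"),
          "replicon_type not in {chromosome, plasmid}")
  bad_row(!hits$gene %in% arsenic_genes(), "unknown gene name")
  bad_row(!is.finite(hits$score), "non-finite or malformed score")
  bad_row(!is.finite(hits$percent_alignment) |
            hits$percent_alignment < 0 | hits$percent_alignment > 100,
          "percent_alignment outside [0, 100]")
  invisible(hits)
}

#' Write a hit table
#'
#' Writes tab-separated, UTF-8, Unix newlines, no quoting; the canonical
#' on-disk form, so \code{write_hit_table(read_hit_table(f))} is stable under
#' further round trips.
#'
#' @param hits A validated hit table.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  validate_hit_table(hits)
  write_tsv(hits[, hit_table_columns()], path)
}

# shared TSV writer: tab-separated, no quotes, Unix newlines
write_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE)
}

#' Read and validate a phylogenetic tree
#'
#' Parses a newick file into an \code{ape} \code{phylo} object and enforces
#' the contract downstream phylogenetic-signal computations rely on: every
#' branch carries a non-negative length and tip labels are unique.
#' Polytomies are allowed and preserved (the trait covariance matrix they
#' imply is unambiguous).
#'
#' @param path Path to a newick file.
#' @return An \code{ape::phylo} tree.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop_("tree file not found: ", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_("could not parse newick in ", path)
  validate_tree(tree)
  tree
}

#' @rdname read_tree
#' @param tree An \code{ape::phylo} object.
#' @export
validate_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop_("not a phylo object")
  n_edge <- nrow(tree$edge)
  if (is.null(tree$edge.length) || length(tree$edge.length) != n_edge ||
      anyNA(tree$edge.length)) {
    stop_("tree has missing branch lengths")
  }
  if (any(tree$edge.length < 0)) stop_("tree has negative branch lengths")
  if (anyDuplicated(tree$tip.label)) {
    stop_("duplicate tip labels: ",
          paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                collapse = ", "))
  }
  invisible(tree)
}

#' Write a tree to newick
#'
#' @param tree An \code{ape::phylo} object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tree <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read assembled protein variants with their abundances
#'
#' Loads gene-targeted-assembly output: a protein FASTA of assembled variant
#' sequences (OTUs) plus a tab-separated abundance file mapping each sequence
#' id to its gene, site and coverage-adjusted abundance. Every sequence must
#' have exactly one abundance row and vice versa; sequences are validated
#' against the 20-residue amino-acid alphabet plus X.
#'
#' @param path Protein FASTA path.
#' @param abundance_path TSV with columns \code{variant_id}, \code{gene},
#'   \code{site_id}, \code{abundance}.
#' @return A \code{data.frame} of variant records: \code{variant_id},
#'   \code{gene}, \code{site_id}, \code{sequence}, \code{abundance}.
#' @export
read_variant_fasta <- function(path, abundance_path) {
  if (!file.exists(path)) stop_("FASTA not found: ", path)
  seqs <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop_("duplicate sequence ids in FASTA")
  seq_chr <- as.character(seqs)
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), seq_chr)
  if (any(bad)) {
    stop_("illegal residue in sequence(s): ",
          paste(utils::head(ids[bad], 5L), collapse = ", "))
  }
  if (any(nchar(seq_chr) == 0L)) stop_("empty sequence in FASTA")
  ab <- read_tsv(abundance_path)
  assert_cols(ab, c("variant_id", "gene", "site_id", "abundance"),
              "abundance table")
  if (anyDuplicated(ab$variant_id)) stop_("duplicate variant_id in abundance table")
  missing_ab <- setdiff(ids, ab$variant_id)
  if (length(missing_ab)) {
    stop_("sequence(s) without abundance row: ",
          paste(utils::head(missing_ab, 5L), collapse = ", "))
  }
  missing_seq <- setdiff(ab$variant_id, ids)
  if (length(missing_seq)) {
    stop_("abundance row(s) without sequence: ",
          paste(utils::head(missing_seq, 5L), collapse = ", "))
  }
  if (!all(ab$gene %in% arsenic_genes() | ab$gene == "rplB")) {
    stop_("unknown gene name in abundance table")
  }
  ab$abundance <- as.numeric(ab$abundance)
  if (any(!is.finite(ab$abundance) | ab$abundance < 0)) {
    stop_("abundances must be finite and non-negative")
  }
  out <- ab[match(ids, ab$variant_id),
            c("variant_id", "gene", "site_id", "abundance")]
  out$sequence <- unname(seq_chr)
  rownames(out) <- NULL
  out[, c("variant_id", "gene", "site_id", "sequence", "abundance")]
}

#' Write protein variants and abundances
#'
#' Inverse of [read_variant_fasta()]: FASTA wrapped at 80 columns plus the
#' abundance TSV.
#'
#' @param variants Variant record \code{data.frame}.
#' @param path Output FASTA path.
#' @param abundance_path Output abundance TSV path.
#' @return \code{path}, invisibly.
#' @export
write_variant_fasta <- function(variants, path, abundance_path) {
  assert_cols(variants, c("variant_id", "gene", "site_id", "sequence",
                          "abundance"), "variant table")
  seqs <- Biostrings::AAStringSet(variants$sequence)
  names(seqs) <- variants$variant_id
  Biostrings::writeXStringSet(seqs, path, width = 80L)
  write_tsv(variants[, c("variant_id", "gene", "site_id", "abundance")],
            abundance_path)
  invisible(path)
}
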