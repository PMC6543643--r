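#' Quality-screen homology-search hits
#'
#' Applies the retention cascade used for searches against complete genomes:
#' a hit is kept iff \code{score > base_score_min} AND
#' \code{percent_alignment > alignment_min} AND, for the elevated-threshold
#' genes (arsenite oxidases and respiratory arsenate reductase, which
#' attract spurious molybdopterin-oxidoreductase homologs),
#' \code{score > elevated_score_min}. All inequalities are strict. Input
#' order is preserved and rejected rows are counted per rule (a row failing
#' several rules is attributed to the first in score / alignment / elevated
#' order, so counts partition the input).
#'
#' @param hits A validated hit table (see [read_hit_table()]).
#' @param base_score_min Bit-score floor for all genes (default 100).
#' @param alignment_min Percent-alignment floor (default 90).
#' @param elevated A character vector of genes screened at the elevated
#'   floor (default [elevated_genes()]).
#' @param elevated_score_min Bit-score floor for \code{elevated} genes
#'   (default 1000).
#' @return A list with \code{hits} (the retained rows, original order) and
#'   \code{report}, a \code{screen_report} with per-rule rejection counts.
#' @export
#' @examples
#' g <- generate_genomes(n_genomes = 20, seed = 1)
#' sc <- screen_hits(g$hits)
#' sc$report
screen_hits <- function(hits, base_score_min = 100, alignment_min = 90,
                        elevated = elevated_genes(),
                        elevated_score_min = 1000) {
  validate_hit_table(hits)
  fail_score <- !(hits$score > base_score_min)
  fail_align <- !(hits$percent_alignment > alignment_min)
  fail_elev <- hits$gene %in% elevated & !(hits$score > elevated_score_min)
  keep <- !(fail_score | fail_align | fail_elev)
  report <- structure(
    list(input = nrow(hits),
         rejected_score = sum(fail_score),
         rejected_alignment = sum(fail_align & !fail_score),
         rejected_elevated = sum(fail_elev & !fail_score & !fail_align),
         retained = sum(keep),
         thresholds = list(base_score_min = base_score_min,
                           alignment_min = alignment_min,
                           elevated = elevated,
                           elevated_score_min = elevated_score_min)),
    class = "screen_report")
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(hits = out, report = report)
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Hit screening report\n")
  cat(sprintf("  input rows:          %d\n", x$input))
  cat(sprintf("  rejected (score <= %g):     %d\n",
              x$thresholds$base_score_min, x$rejected_score))
  cat(sprintf("  rejected (alignment <= %g): %d\n",
              x$thresholds$alignment_min, x$rejected_alignment))
  cat(sprintf("  rejected (%s score <= %g): %d\n",
              paste(x$thresholds$elevated, collapse = "/"),
              x$thresholds$elevated_score_min, x$rejected_elevated))
  cat(sprintf("  retained:            %d\n", x$retained))
  invisible(x)
}

#' Keep the best hit per open reading frame
#'
#' When one ORF matches several gene models, only the highest-scoring hit is
#' biologically meaningful; lower-scoring hits on the same
#' (genome, ORF) are removed. Score ties are broken deterministically by the
#' canonical gene ordering of [arsenic_genes()], so the result is invariant
#' to input row order.
#'
#' @param hits A screened hit table.
#' @return The deduplicated hit table, at most one row per
#'   (\code{genome_id}, \code{orf_id}), in input order of the survivors; the
#'   number of removed rows is attached as attribute \code{"removed"}.
#' @export
dedup_orfs <- function(hits) {
  validate_hit_table(hits)
  if (nrow(hits) == 0L) {
    attr(hits, "removed") <- 0L
    return(hits)
  }
  key <- paste(hits$genome_id, hits$orf_id, sep = "\r")
  gene_rank <- match(hits$gene, arsenic_genes())
  # order within ORF: score desc, then canonical gene order; stable pick
  ord <- order(key, -hits$score, gene_rank, method = "radix")
  first_of_key <- !duplicated(key[ord])
  keep_rows <- sort(ord[first_of_key])
  out <- hits[keep_rows, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- nrow(hits) - nrow(out)
  out
}

#' Attach taxonomy to retained hits
#'
#' Joins the genome metadata table onto a hit table, adding \code{phylum}
#' and \code{taxonomy}. Every genome in the hits must be present in the
#' metadata; missing genomes are a hard error listing the ids.
#'
#' @param hits A hit table.
#' @param genomes Genome metadata with columns \code{genome_id},
#'   \code{phylum}, and optionally \code{taxonomy}.
#' @return The hit table with \code{phylum} and \code{taxonomy} columns.
#' @export
annotate_hits <- function(hits, genomes) {
  validate_hit_table(hits)
  assert_cols(genomes, c("genome_id", "phylum"), "genome metadata")
  idx <- match(hits$genome_id, genomes$genome_id)
  if (anyNA(idx)) {
    missing <- unique(hits$genome_id[is.na(idx)])
    stop_("genome id(s) missing from metadata: ",
          paste(utils::head(missing, 10L), collapse = ", "))
  }
  hits$phylum <- genomes$phylum[idx]
  hits$taxonomy <- if ("taxonomy" %in% names(genomes)) {
    genomes$taxonomy[idx]
  } else {
    genomes$phylum[idx]
  }
  hits
}

#' Run the full screening cascade
#'
#' Convenience wrapper: [screen_hits()], [dedup_orfs()], [annotate_hits()],
#' with the deduplication count folded into the report.
#'
#' @inheritParams screen_hits
#' @inheritParams annotate_hits
#' @return A list with \code{hits} (screened, deduplicated, annotated) and
#'   \code{report}.
#' @export
process_hits <- function(hits, genomes, base_score_min = 100,
                         alignment_min = 90, elevated = elevated_genes(),
                         elevated_score_min = 1000) {
  sc <- screen_hits(hits, base_score_min, alignment_min, elevated,
                    elevated_score_min)
  dd <- dedup_orfs(sc$hits)
  sc$report$rejected_dedup <- attr(dd, "removed")
  sc$report$retained <- nrow(dd)
  list(hits = annotate_hits(dd, genomes), report = sc$report)
}
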