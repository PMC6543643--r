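#' Percent identity between two protein sequences
#'
#' Global (Needleman-Wunsch) alignment with guide scores match = +1,
#' mismatch = 0, gap open = -5, gap extend = -1, then identity computed as
#' 100 x matches / alignment columns, excluding terminal-gap columns
#' (overhangs) from the denominator so ragged assembly ends are tolerated
#' while internal indels are penalized. Symmetric in its arguments.
#'
#' @param a,b Non-empty protein sequences (character scalars).
#' @return Percent identity in [0, 100].
#' @export
#' @examples
#' pairwise_identity("MKVLAT", "MKVLAT")
pairwise_identity <- function(a, b) {
  stopifnot(is.character(a), is.character(b),
            length(a) == 1L, length(b) == 1L)
  if (nchar(a) == 0L || nchar(b) == 0L) stop_("empty sequence")
  pairwise_identity_many(a, b)
}

# vectorized core: identity of each element of `patterns` against `subject`
pairwise_identity_many <- function(patterns, subject) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(patterns), Biostrings::AAString(subject),
    type = "global", substitutionMatrix = identity_matrix(),
    gapOpening = 5, gapExtension = 1)
  # global alignments cover both sequences end to end, so the gapped
  # pattern/subject views are the full aligned strings
  p <- unname(as.character(Biostrings::pattern(aln)))
  s <- unname(as.character(Biostrings::subject(aln)))
  vapply(seq_along(p), function(i) {
    aligned_identity(strsplit(p[i], "")[[1]], strsplit(s[i], "")[[1]])
  }, numeric(1))
}

# identity from one aligned pair, excluding terminal-gap columns
aligned_identity <- function(pc, sc) {
  n <- length(pc)
  gap <- pc == "-" | sc == "-"
  lead_p <- cumsum(pc != "-") == 0
  lead_s <- cumsum(sc != "-") == 0
  trail_p <- rev(cumsum(rev(pc) != "-") == 0)
  trail_s <- rev(cumsum(rev(sc) != "-") == 0)
  keep <- !(lead_p | lead_s | trail_p | trail_s)
  if (!any(keep)) return(0)
  100 * sum(pc[keep] == sc[keep] & !gap[keep]) / sum(keep)
}

identity_matrix <- function() {
  m <- diag(1L, length(AA_ALPHABET))
  dimnames(m) <- list(AA_ALPHABET, AA_ALPHABET)
  storage.mode(m) <- "integer"
  m
}

#' Dereplicate exact-duplicate variant sequences
#'
#' Within each gene, merges records with identical residue strings at the
#' same site, summing their coverage-adjusted abundances; the lexicographic
#' first variant id of each merged group is kept. Total abundance is
#' conserved.
#'
#' @param variants Variant record \code{data.frame} (\code{variant_id},
#'   \code{gene}, \code{site_id}, \code{sequence}, \code{abundance}).
#' @return Dereplicated variant records, one per
#'   (\code{gene}, \code{site_id}, \code{sequence}).
#' @export
dereplicate <- function(variants) {
  assert_cols(variants, c("variant_id", "gene", "site_id", "sequence",
                          "abundance"), "variant table")
  if (!nrow(variants)) return(variants)
  key <- paste(variants$gene, variants$site_id, variants$sequence,
               sep = "\r")
  ord <- order(key, variants$variant_id, method = "radix")
  v <- variants[ord, , drop = FALSE]
  k <- key[ord]
  first <- !duplicated(k)
  sums <- tapply(v$abundance, k, sum)
  out <- v[first, , drop = FALSE]
  out$abundance <- as.numeric(sums[k[first]])
  out <- out[order(out$gene, out$site_id, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy centroid clustering of protein variants
#'
#' UCLUST-style clustering within each gene: sequences are processed in
#' order of decreasing total (cross-site) abundance, ties broken by longer
#' sequence then lexicographic id; each sequence joins the first existing
#' centroid (in founding order) with [pairwise_identity()] at or above the
#' threshold, otherwise it founds a new cluster. Deterministic, and every
#' pair of centroids compared at founding time sits below the threshold.
#'
#' @param variants Dereplicated variant records.
#' @param identity_threshold Percent identity threshold (default 90).
#' @return A \code{variant_clusters} object: list with \code{clusters}
#'   (\code{cluster_id}, \code{gene}, \code{centroid_id}, \code{n_members},
#'   \code{occupancy}, \code{total_abundance}), \code{members}
#'   (\code{variant_id} -> \code{cluster_id} with gene/site/abundance) and
#'   \code{site_abundance} (\code{cluster_id} x \code{site_id} summed
#'   abundance, long form).
#' @export
greedy_cluster <- function(variants, identity_threshold = 90) {
  assert_cols(variants, c("variant_id", "gene", "site_id", "sequence",
                          "abundance"), "variant table")
  stopifnot(is.numeric(identity_threshold), identity_threshold > 0,
            identity_threshold <= 100)
  members_all <- list()
  clusters_all <- list()
  for (g in unique(variants$gene)) {
    v <- variants[variants$gene == g, , drop = FALSE]
    # one representative row per distinct sequence, ranked by total abundance
    tot <- tapply(v$abundance, v$sequence, sum)
    seqs <- names(tot)
    ord <- order(-as.numeric(tot), -nchar(seqs),
                 vapply(seqs, function(s) {
                   min(v$variant_id[v$sequence == s])
                 }, character(1)), method = "radix")
    seqs <- seqs[ord]
    centroid_seq <- character(0)
    centroid_id <- character(0)
    assign_cluster <- integer(length(seqs))
    for (i in seq_along(seqs)) {
      hit <- 0L
      if (length(centroid_seq)) {
        ident <- pairwise_identity_many(centroid_seq, seqs[i])
        ok <- which(ident >= identity_threshold)
        if (length(ok)) hit <- ok[1L]
      }
      if (hit == 0L) {
        centroid_seq <- c(centroid_seq, seqs[i])
        centroid_id <- c(centroid_id,
                         sprintf("%s_cl%03d", g, length(centroid_seq)))
        hit <- length(centroid_seq)
      }
      assign_cluster[i] <- hit
    }
    m <- v
    m$cluster_id <- centroid_id[assign_cluster[match(m$sequence, seqs)]]
    members_all[[g]] <- m
    occ <- tapply(m$site_id, m$cluster_id,
                  function(s) length(unique(s)))
    ab <- tapply(m$abundance, m$cluster_id, sum)
    nm <- tapply(m$variant_id, m$cluster_id, length)
    cent_of <- function(cid) {
      s <- centroid_seq[match(cid, centroid_id)]
      min(m$variant_id[m$sequence == s])
    }
    clusters_all[[g]] <- data.frame(
      cluster_id = centroid_id, gene = g,
      centroid_id = vapply(centroid_id, cent_of, character(1)),
      centroid_sequence = centroid_seq,
      n_members = as.integer(nm[centroid_id]),
      occupancy = as.integer(occ[centroid_id]),
      total_abundance = as.numeric(ab[centroid_id]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  members <- do.call(rbind, members_all)
  rownames(members) <- NULL
  clusters <- do.call(rbind, clusters_all)
  rownames(clusters) <- NULL
  site_ab <- stats::aggregate(list(abundance = members$abundance),
                              members[, c("cluster_id", "gene", "site_id")],
                              FUN = sum)
  structure(list(clusters = clusters, members = members,
                 site_abundance = site_ab,
                 identity_threshold = identity_threshold),
            class = "variant_clusters")
}

#' @export
print.variant_clusters <- function(x, ...) {
  cat(sprintf("Variant clusters at %.0f%% identity: %d clusters, %d members, %d gene(s)\n",
              x$identity_threshold, nrow(x$clusters), nrow(x$members),
              length(unique(x$clusters$gene))))
  invisible(x)
}

#' Classify clusters as endemic or cosmopolitan
#'
#' A cluster is endemic when present (summed coverage-adjusted abundance
#' > 0) at fewer than \code{min_cosmopolitan_sites} distinct sites,
#' cosmopolitan otherwise.
#'
#' @param clusters A \code{variant_clusters} object.
#' @param min_cosmopolitan_sites Occupancy at which a cluster stops being
#'   endemic (default 3: endemic means fewer than three sites).
#' @return List with \code{clusters} (the cluster table plus
#'   \code{endemic}), \code{endemic_count}, \code{cosmopolitan_count},
#'   \code{endemic_proportion}, and \code{cosmopolitan_composition} (share
#'   of cosmopolitan clusters per gene).
#' @export
classify_occupancy <- function(clusters, min_cosmopolitan_sites = 3) {
  stopifnot(inherits(clusters, "variant_clusters"),
            is_count(min_cosmopolitan_sites))
  cl <- clusters$clusters
  cl$endemic <- cl$occupancy < min_cosmopolitan_sites
  cosmo <- cl[!cl$endemic, , drop = FALSE]
  comp <- if (nrow(cosmo)) {
    tab <- table(cosmo$gene)
    data.frame(gene = names(tab), n_clusters = as.integer(tab),
               share = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(), n_clusters = integer(), share = numeric())
  }
  list(clusters = cl,
       endemic_count = sum(cl$endemic),
       cosmopolitan_count = sum(!cl$endemic),
       endemic_proportion = mean(cl$endemic),
       cosmopolitan_composition = comp)
}

#' Rank sites by mean normalized gene abundance
#'
#' Orders sites by decreasing mean rplB-normalized abundance over their
#' detected genes (conservative convention: not-detected genes do not enter
#' a site's mean); ties broken by site id.
#'
#' @param profile A \code{site_profile} from [rplb_normalize()].
#' @return \code{data.frame} of per-site per-gene normalized abundances
#'   with \code{site_rank} (1 = most abundant site) and \code{site_mean};
#'   rows ordered by rank then gene.
#' @export
rank_abundance <- function(profile) {
  assert_cols(profile, c("site_id", "gene", "normalized", "detected"),
              "site profile")
  det <- profile[profile$detected, , drop = FALSE]
  if (!nrow(det)) stop_("no detected genes to rank")
  means <- tapply(det$normalized, det$site_id, mean)
  ord <- order(-as.numeric(means), names(means))
  rank_of <- stats::setNames(seq_along(ord), names(means)[ord])
  det$site_mean <- as.numeric(means[det$site_id])
  det$site_rank <- as.integer(rank_of[det$site_id])
  out <- det[order(det$site_rank, det$gene),
             c("site_id", "gene", "normalized", "site_mean", "site_rank")]
  rownames(out) <- NULL
  out
}
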