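#' Cultivation-weighted gene abundance
#'
#' Estimates the environmental abundance of each gene from cultivable
#' genomes: the expected copies per genome under each sample's inferred
#' organism abundances,
#' \eqn{\hat A(s, g) = \sum_k w_{sk} \, c_{kg}}, where \eqn{w_{sk}} is the
#' 16S-inferred relative abundance of genome k in sample s (summing to 1)
#' and \eqn{c_{kg}} its total copy count (chromosome + plasmid). The
#' estimator is linear in the weights, so soil-order means of per-sample
#' estimates equal estimates under order-averaged weights.
#'
#' @param matrix A \code{genotype_matrix}.
#' @param weights Long weight table (\code{sample_id}, \code{soil_order},
#'   \code{genome_id}, \code{weight}); per-sample weights must sum to 1
#'   within 1e-6 and reference genomes in the matrix.
#' @param use_presence Use presence/absence (0/1) instead of copy counts.
#' @return List with \code{per_sample} (\code{sample_id}, \code{soil_order},
#'   \code{gene}, \code{estimate}) and \code{per_soil_order} (mean over the
#'   order's samples).
#' @export
cultivation_weighted_abundance <- function(matrix, weights,
                                           use_presence = FALSE) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  assert_cols(weights, c("sample_id", "soil_order", "genome_id", "weight"),
              "weight table")
  copies <- matrix$chromosome + matrix$plasmid
  if (use_presence) copies <- (copies > 0) + 0L
  unknown <- setdiff(weights$genome_id, rownames(copies))
  if (length(unknown)) {
    stop_("weight table references unknown genome(s): ",
          paste(utils::head(unknown, 5L), collapse = ", "))
  }
  sums <- tapply(weights$weight, weights$sample_id, sum)
  bad <- names(sums)[abs(sums - 1) > 1e-6]
  if (length(bad)) {
    stop_("weights do not sum to 1 for sample(s): ",
          paste(utils::head(bad, 5L), collapse = ", "))
  }
  samples <- unique(weights$sample_id)
  # weight matrix samples x genomes, absent genomes weighted 0
  W <- matrix(0, nrow = length(samples), ncol = nrow(copies),
              dimnames = list(samples, rownames(copies)))
  W[cbind(match(weights$sample_id, samples),
          match(weights$genome_id, rownames(copies)))] <- weights$weight
  est <- W %*% copies
  order_of <- weights$soil_order[match(samples, weights$sample_id)]
  per_sample <- data.frame(
    sample_id = rep(samples, times = ncol(est)),
    soil_order = rep(order_of, times = ncol(est)),
    gene = rep(colnames(est), each = nrow(est)),
    estimate = as.vector(est), stringsAsFactors = FALSE)
  per_order <- stats::aggregate(list(estimate = per_sample$estimate),
                                per_sample[, c("soil_order", "gene")],
                                FUN = mean)
  list(per_sample = per_sample, per_soil_order = per_order)
}

#' Normalize per-site gene counts to the rplB single-copy marker
#'
#' Divides each site's coverage-adjusted gene count by the site's total
#' rplB count, giving an approximate per-genome frequency that is invariant
#' to sequencing depth. Sites where a gene was not assembled are kept as
#' explicit not-detected rows (\code{detected = FALSE}, \code{normalized =
#' NA}): absence of assembly evidence is not a zero.
#'
#' @param gene_counts \code{data.frame} (\code{site_id}, \code{gene},
#'   \code{count}) of coverage-adjusted per-site totals.
#' @param sites Site table with \code{site_id}, \code{rplb_total} (> 0) and
#'   optionally coordinates, carried through.
#' @return \code{site_profile} data.frame: one row per site x gene with
#'   \code{count}, \code{rplb_total}, \code{normalized}, \code{detected},
#'   plus any coordinate columns present in \code{sites}.
#' @export
rplb_normalize <- function(gene_counts, sites) {
  assert_cols(gene_counts, c("site_id", "gene", "count"), "gene counts")
  assert_cols(sites, c("site_id", "rplb_total"), "site table")
  if (any(sites$rplb_total <= 0)) {
    stop_("rplB total must be positive for every site: ",
          paste(sites$site_id[sites$rplb_total <= 0], collapse = ", "))
  }
  unknown <- setdiff(gene_counts$site_id, sites$site_id)
  if (length(unknown)) {
    stop_("counts reference unknown site(s): ",
          paste(unknown, collapse = ", "))
  }
  if (any(gene_counts$count < 0)) stop_("counts must be non-negative")
  genes <- sort(unique(gene_counts$gene))
  grid <- expand.grid(site_id = sites$site_id, gene = genes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  idx <- match(paste(grid$site_id, grid$gene),
               paste(gene_counts$site_id, gene_counts$gene))
  grid$count <- gene_counts$count[idx]
  grid$rplb_total <- sites$rplb_total[match(grid$site_id, sites$site_id)]
  grid$detected <- !is.na(grid$count) & grid$count > 0
  grid$normalized <- ifelse(grid$detected, grid$count / grid$rplb_total,
                            NA_real_)
  for (col in intersect(c("latitude", "longitude"), names(sites))) {
    grid[[col]] <- sites[[col]][match(grid$site_id, sites$site_id)]
  }
  class(grid) <- c("site_profile", "data.frame")
  grid
}

#' Summed per-site per-gene counts from variant records
#'
#' Convenience tally feeding [rplb_normalize()]: sums coverage-adjusted
#' variant abundances per (site, gene).
#'
#' @param variants Variant record \code{data.frame}.
#' @return \code{data.frame} with \code{site_id}, \code{gene}, \code{count}.
#' @export
site_gene_counts <- function(variants) {
  assert_cols(variants, c("site_id", "gene", "abundance"), "variant table")
  out <- stats::aggregate(list(count = variants$abundance),
                          variants[, c("site_id", "gene")], FUN = sum)
  out[order(out$site_id, out$gene), , drop = FALSE]
}

#' Relative composition of detected genes at each site
#'
#' Per-site proportions of rplB-normalized abundance over the genes detected
#' there (summing to 1 per site).
#'
#' @param profile A \code{site_profile} from [rplb_normalize()].
#' @return \code{data.frame}: \code{site_id}, \code{gene},
#'   \code{proportion}.
#' @export
relative_gene_composition <- function(profile) {
  stopifnot(inherits(profile, "data.frame"))
  assert_cols(profile, c("site_id", "gene", "normalized", "detected"),
              "site profile")
  det <- profile[profile$detected, , drop = FALSE]
  if (!nrow(det)) stop_("no genes detected at any site")
  empty <- setdiff(unique(profile$site_id), unique(det$site_id))
  if (length(empty)) {
    stop_("no genes detected at site(s): ", paste(empty, collapse = ", "))
  }
  tot <- tapply(det$normalized, det$site_id, sum)
  det$proportion <- det$normalized / as.numeric(tot[det$site_id])
  out <- det[order(det$site_id, det$gene),
             c("site_id", "gene", "proportion")]
  rownames(out) <- NULL
  out
}

#' Per-genome normalized gene abundance in a genome collection
#'
#' Total copies of each gene divided by the number of genomes: the
#' cultivation-dependent analogue of rplB normalization (each complete
#' genome contributes exactly one marker copy).
#'
#' @param matrix A \code{genotype_matrix}.
#' @return Named numeric vector over genes.
#' @export
refsoil_normalized_abundance <- function(matrix) {
  stopifnot(inherits(matrix, "genotype_matrix"))
  tot <- matrix$chromosome + matrix$plasmid
  if (nrow(tot) == 0L) stop_("empty genotype matrix")
  colSums(tot) / nrow(tot)
}

#' Per-site community structure from rplB counts
#'
#' Converts phylum-labeled rplB counts into per-site proportions and flags
#' the six most abundant phyla per site; warns if those six cover less than
#' 75\% of a community.
#'
#' @param rplb_otus \code{data.frame} (\code{site_id}, \code{phylum},
#'   \code{count}).
#' @param n_top Number of top phyla to flag (default 6).
#' @param min_coverage Warn if flagged phyla sum below this (default 0.75).
#' @return \code{data.frame}: \code{site_id}, \code{phylum}, \code{count},
#'   \code{proportion}, \code{top_phylum}.
#' @export
community_structure <- function(rplb_otus, n_top = 6, min_coverage = 0.75) {
  assert_cols(rplb_otus, c("site_id", "phylum", "count"), "rplB OTU table")
  if (any(rplb_otus$count < 0)) stop_("counts must be non-negative")
  pieces <- lapply(split(rplb_otus, rplb_otus$site_id), function(d) {
    tot <- sum(d$count)
    if (tot == 0) stop_("all-zero community at site ", d$site_id[1])
    d$proportion <- d$count / tot
    ord <- order(-d$proportion, d$phylum)
    d$top_phylum <- seq_len(nrow(d)) %in% ord[seq_len(min(n_top, nrow(d)))] &
      d$proportion > 0
    cover <- sum(d$proportion[d$top_phylum])
    if (cover < min_coverage) {
      warning(sprintf("top %d phyla cover only %.1f%% of site %s",
                      n_top, 100 * cover, d$site_id[1]), call. = FALSE)
    }
    d
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
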