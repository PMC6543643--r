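#' Default planted genotype prevalences
#'
#' Unconditional per-gene carrier probabilities used by
#' [generate_genomes()]: cytoplasmic arsenate reductase (grx) most common,
#' efflux pumps intermediate, arsenic energy-metabolism genes rare. These
#' echo the qualitative ranking seen across complete soil genomes.
#'
#' @return Named numeric vector over [arsenic_genes()].
#' @export
default_genotype_prevalence <- function() {
  c(acr3 = 0.30, aioA = 0.04, arrA = 0.015, arsB = 0.12, arsC_grx = 0.45,
    arsC_trx = 0.30, arsD = 0.10, arsM = 0.052, arxA = 0.01)
}

#' Generate synthetic complete genomes with planted arsenic genotypes
#'
#' Emulates a replicon-resolved collection of complete soil genomes searched
#' with gene HMMs. Each genome gets a phylum, one chromosome, 0-3 plasmids,
#' and a planted genotype; each planted gene copy becomes exactly one true
#' hit in the emitted hit table, with bit scores drawn strictly inside the
#' retention band (uniform 150-2500; for the elevated-threshold genes
#' uniform 1100-2500) and percent alignment uniform on 92-100. Decoy hits
#' that must fail screening (score uniform 20-99, alignment uniform 10-89,
#' or, for elevated genes, score uniform 110-999) are added at rate
#' \code{decoy_rate} per genome. Score bands are disjoint from the
#' thresholds, so planted-genotype recovery is exact, not statistical; an
#' \code{adversarial} mode instead places hits exactly at the 100 and 1000
#' bit thresholds and at 90 percent alignment to pin the strict-inequality
#' behavior.
#'
#' @param n_genomes Number of genomes.
#' @param n_phyla Number of phylum labels to spread genomes over.
#' @param genotype_prevalence Named unconditional carrier probability per
#'   gene (default [default_genotype_prevalence()]).
#' @param none_fraction Expected fraction of genomes carrying no profiled
#'   gene (default 0.143).
#' @param decoy_rate Expected decoys per genome (default 0.3).
#' @param adversarial Add boundary hits exactly at the thresholds.
#' @param seed Integer seed; identical arguments and seed give identical
#'   output.
#' @return List with \code{genomes} (metadata: \code{genome_id},
#'   \code{phylum}, \code{taxonomy}, \code{n_plasmids}), \code{hits} (a hit
#'   table), and \code{truth}: \code{genotype} ledger (\code{genome_id},
#'   \code{gene}, \code{replicon_type}, \code{copies}), realized
#'   \code{none_count} / \code{none_fraction}, and \code{n_decoys}.
#' @export
#' @examples
#' g <- generate_genomes(n_genomes = 50, seed = 42)
#' head(g$hits)
#' g$truth$none_fraction
generate_genomes <- function(n_genomes, n_phyla = 25,
                             genotype_prevalence = default_genotype_prevalence(),
                             none_fraction = 0.143, decoy_rate = 0.3,
                             adversarial = FALSE, seed) {
  stopifnot(is_count(n_genomes), is_count(n_phyla))
  genes <- arsenic_genes()
  if (!all(genes %in% names(genotype_prevalence))) {
    stop_("genotype_prevalence must name all nine genes")
  }
  prev <- genotype_prevalence[genes]
  if (any(prev < 0 | prev > 1) || none_fraction < 0 || none_fraction > 1) {
    stop_("probabilities must lie in [0, 1]")
  }
  p_carrier <- 1 - none_fraction
  if (p_carrier == 0 && any(prev > 0)) {
    stop_("none_fraction 1 is infeasible with positive gene prevalence")
  }
  cond_prev <- if (p_carrier > 0) prev / p_carrier else prev
  if (max(cond_prev) > 1) {
    stop_("infeasible: none_fraction ", none_fraction,
          " plus max prevalence ", max(prev),
          " requires conditional prevalence > 1")
  }
  with_seed(seed, {
    phyla <- sprintf("Phylum%02d", seq_len(n_phyla))
    genome_ids <- sprintf("G%04d", seq_len(n_genomes))
    phylum <- sample(phyla, n_genomes, replace = TRUE)
    n_plasmids <- sample(0:3, n_genomes, replace = TRUE,
                         prob = c(0.45, 0.30, 0.15, 0.10))
    hit_rows <- vector("list", n_genomes)
    truth_rows <- vector("list", n_genomes)
    n_decoys <- 0L
    for (i in seq_len(n_genomes)) {
      gid <- genome_ids[i]
      orf_counter <- 0L
      next_orf <- function() {
        orf_counter <<- orf_counter + 1L
        sprintf("%s_ORF%03d", gid, orf_counter)
      }
      replicons <- c(sprintf("%s_chr", gid),
                     if (n_plasmids[i] > 0) {
                       sprintf("%s_p%d", gid, seq_len(n_plasmids[i]))
                     })
      rep_type <- c("chromosome", rep("plasmid", n_plasmids[i]))
      carrier <- stats::runif(1) < p_carrier
      planted <- if (carrier) {
        got <- stats::runif(length(genes)) < cond_prev
        if (!any(got) && any(cond_prev > 0)) {
          got[sample(length(genes), 1, prob = cond_prev)] <- TRUE
        }
        genes[got]
      } else {
        character()
      }
      rows <- list()
      truths <- list()
      for (g in planted) {
        copies <- 1L + stats::rbinom(1L, 2L, 0.1)
        for (k in seq_len(copies)) {
          on_plasmid <- n_plasmids[i] > 0 && stats::runif(1) < 0.1
          ridx <- if (on_plasmid) 1L + sample.int(n_plasmids[i], 1L) else 1L
          score <- if (g %in% elevated_genes()) {
            stats::runif(1, 1100, 2500)
          } else {
            stats::runif(1, 150, 2500)
          }
          rows[[length(rows) + 1L]] <- data.frame(
            genome_id = gid, replicon_id = replicons[ridx],
            replicon_type = rep_type[ridx], orf_id = next_orf(), gene = g,
            score = round(score, 1),
            percent_alignment = round(stats::runif(1, 92, 100), 1),
            stringsAsFactors = FALSE)
          truths[[length(truths) + 1L]] <- data.frame(
            genome_id = gid, gene = g, replicon_type = rep_type[ridx],
            stringsAsFactors = FALSE)
        }
      }
      for (d in seq_len(stats::rpois(1, decoy_rate))) {
        n_decoys <- n_decoys + 1L
        g <- sample(genes, 1)
        ridx <- sample.int(length(replicons), 1L)
        modes <- if (g %in% elevated_genes()) 3L else 2L
        mode <- sample.int(modes, 1L)
        if (mode == 1L) {          # fails base score
          score <- stats::runif(1, 20, 99)
          pct <- stats::runif(1, 92, 100)
        } else if (mode == 2L) {   # fails alignment
          score <- stats::runif(1, 150, 999)
          pct <- stats::runif(1, 10, 89)
        } else {                   # elevated gene, fails elevated score
          score <- stats::runif(1, 110, 999)
          pct <- stats::runif(1, 92, 100)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          genome_id = gid, replicon_id = replicons[ridx],
          replicon_type = rep_type[ridx], orf_id = next_orf(), gene = g,
          score = round(score, 1), percent_alignment = round(pct, 1),
          stringsAsFactors = FALSE)
      }
      hit_rows[[i]] <- if (length(rows)) do.call(rbind, rows) else NULL
      truth_rows[[i]] <- if (length(truths)) do.call(rbind, truths) else NULL
    }
    hits <- do.call(rbind, hit_rows[!vapply(hit_rows, is.null, logical(1))])
    if (is.null(hits)) {
      hits <- data.frame(genome_id = character(), replicon_id = character(),
                         replicon_type = character(), orf_id = character(),
                         gene = character(), score = numeric(),
                         percent_alignment = numeric())
    }
    if (adversarial) {
      bound <- data.frame(
        genome_id = genome_ids[1],
        replicon_id = sprintf("%s_chr", genome_ids[1]),
        replicon_type = "chromosome",
        orf_id = sprintf("%s_ADV%03d", genome_ids[1], 1:3),
        gene = c("acr3", "aioA", "arsB"),
        score = c(100, 1000, 500),
        percent_alignment = c(95, 95, 90),
        stringsAsFactors = FALSE)
      hits <- rbind(hits, bound)
    }
    rownames(hits) <- NULL
    truth <- do.call(rbind,
                     truth_rows[!vapply(truth_rows, is.null, logical(1))])
    if (is.null(truth)) {
      genotype <- data.frame(genome_id = character(), gene = character(),
                             replicon_type = character(), copies = integer())
    } else {
      agg <- stats::aggregate(list(copies = rep(1L, nrow(truth))),
                              truth[, c("genome_id", "gene", "replicon_type")],
                              FUN = sum)
      genotype <- agg[order(agg$genome_id, agg$gene, agg$replicon_type), ]
      rownames(genotype) <- NULL
    }
    carriers <- unique(genotype$genome_id)
    genomes <- data.frame(
      genome_id = genome_ids, phylum = phylum,
      taxonomy = paste("Bacteria", phylum, sep = ";"),
      n_plasmids = n_plasmids, stringsAsFactors = FALSE)
    list(genomes = genomes, hits = hits,
         truth = list(genotype = genotype,
                      none_count = n_genomes - length(carriers),
                      none_fraction = (n_genomes - length(carriers)) / n_genomes,
                      n_decoys = n_decoys),
         params = list(n_genomes = n_genomes, n_phyla = n_phyla,
                       genotype_prevalence = prev,
                       none_fraction = none_fraction,
                       decoy_rate = decoy_rate, adversarial = adversarial,
                       seed = seed))
  })
}

#' Simulate binary traits on a tree
#'
#' Positive and negative controls for the phylogenetic-signal test.
#' \code{brownian_threshold} simulates Brownian motion on the tree and
#' thresholds the continuous trait at the prevalence quantile (a binary
#' trait that inherits phylogenetic signal); \code{clustered} turns on the
#' clade whose tip fraction is closest to the prevalence (maximal signal);
#' \code{random} is i.i.d. Bernoulli (no signal).
#'
#' @param tree A valid \code{ape::phylo} with at least 4 tips.
#' @param mode \code{"brownian_threshold"}, \code{"clustered"} or
#'   \code{"random"}.
#' @param prevalence Target fraction of positive tips, strictly in (0, 1).
#' @param seed Integer seed.
#' @return Named 0/1 integer vector over \code{tree$tip.label}.
#' @export
simulate_traits_on_tree <- function(tree,
                                    mode = c("brownian_threshold",
                                             "clustered", "random"),
                                    prevalence = 0.5, seed) {
  mode <- match.arg(mode)
  validate_tree(tree)
  n <- length(tree$tip.label)
  if (n < 4L) stop_("tree must have at least 4 tips")
  if (!is.numeric(prevalence) || prevalence <= 0 || prevalence >= 1) {
    stop_("prevalence must lie strictly in (0, 1); boundary traits are degenerate")
  }
  x <- with_seed(seed, {
    switch(mode,
      brownian_threshold = {
        V <- phylo_vcv(tree)
        z <- drop(crossprod(chol(V + diag(1e-10, n)), stats::rnorm(n)))
        k <- min(max(round(prevalence * n), 1L), n - 1L)
        as.integer(rank(-z, ties.method = "first") <= k)
      },
      random = stats::rbinom(n, 1L, prevalence),
      clustered = {
        internal <- (n + 1L):(n + tree$Nnode)
        fracs <- vapply(internal, function(nd) {
          length(tip_descendants(tree, nd)) / n
        }, numeric(1))
        best <- internal[which.min(abs(fracs - prevalence))]
        out <- integer(n)
        out[tip_descendants(tree, best)] <- 1L
        out
      })
  })
  names(x) <- tree$tip.label
  x
}

# tip indices descending from an internal node
tip_descendants <- function(tree, node) {
  n <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  out <- integer(0)
  while (length(kids)) {
    out <- c(out, kids[kids <= n])
    kids <- tree$edge[tree$edge[, 1] %in% kids[kids > n], 2]
  }
  sort(out)
}

#' Generate synthetic soil sites with planted variant clusters
#'
#' Emulates gene-targeted assembly output across soil sites. Each gene gets
#' a set of planted sequence clusters: local clusters occur at exactly one
#' site, shared-pool clusters at three or more sites with the identical
#' residue string at each. Cluster ancestor sequences are mutated from a
#' per-gene root and redrawn until every between-cluster pairwise difference
#' is at least \code{divergence} per residue, while cluster members differ
#' from their ancestor by at most \code{within_divergence / 2}; the identity
#' bands are therefore disjoint with margin and a 90\% identity clustering
#' recovers the planted partition exactly. Per-site marker totals (rplB) are
#' drawn uniformly on 50-500 and site coordinates uniformly from five
#' continental bounding boxes.
#'
#' @param n_sites Number of sites.
#' @param genes Genes to plant (default: the seven families assembled
#'   site-by-site, excluding \code{arrA}/\code{arxA}).
#' @param shared_variant_fraction Fraction of clusters drawn from the shared
#'   (cosmopolitan) pool; default 0.007.
#' @param variants_per_gene_site Local clusters planted per gene per site.
#' @param divergence Minimum between-cluster difference per residue
#'   (>= 0.12; default 0.25).
#' @param within_divergence Maximum within-cluster pairwise difference per
#'   residue (<= 0.05; default 0.02).
#' @param seed Integer seed.
#' @return List with \code{sites} (metadata: \code{site_id},
#'   \code{latitude}, \code{longitude}, \code{rplb_total}),
#'   \code{variants} (variant records), \code{rplb_community} (per-site
#'   phylum-labeled rplB counts) and \code{truth}: per-variant cluster
#'   assignments, per-cluster occupancy and endemic flag, the realized
#'   \code{endemic_proportion}, total planted abundance, and per
#'   (site, gene) abundance sums.
#' @export
generate_sites <- function(n_sites, genes = setdiff(arsenic_genes(),
                                                    c("arrA", "arxA")),
                           shared_variant_fraction = 0.007,
                           variants_per_gene_site = 2,
                           divergence = 0.25, within_divergence = 0.02,
                           seed) {
  stopifnot(is_count(n_sites), is_count(variants_per_gene_site))
  genes <- match.arg(genes, arsenic_genes(), several.ok = TRUE)
  if (shared_variant_fraction < 0 || shared_variant_fraction >= 1) {
    stop_("shared_variant_fraction must lie in [0, 1)")
  }
  if (within_divergence >= divergence) {
    stop_("divergence bands overlap: within-cluster divergence (",
          within_divergence, ") must be below between-cluster divergence (",
          divergence, ")")
  }
  if (divergence < 0.12) stop_("between-cluster divergence must be >= 0.12")
  if (within_divergence > 0.05) {
    stop_("within-cluster divergence must be <= 0.05")
  }
  if (shared_variant_fraction > 0 && n_sites < 3L) {
    stop_("shared clusters need at least 3 sites")
  }
  with_seed(seed, {
    site_ids <- sprintf("S%02d", seq_len(n_sites))
    boxes <- list(c(25, 50, -125, -70),    # North America
                  c(-35, 5, -80, -40),     # South America
                  c(36, 60, -10, 30),      # Europe
                  c(5, 55, 60, 140),       # Asia
                  c(-40, -12, 113, 153))   # Australia
    box <- boxes[(seq_len(n_sites) - 1L) %% length(boxes) + 1L]
    lat <- vapply(box, function(b) stats::runif(1, b[1], b[2]), numeric(1))
    lon <- vapply(box, function(b) stats::runif(1, b[3], b[4]), numeric(1))
    rplb_total <- sample(50:500, n_sites, replace = TRUE)
    sites <- data.frame(site_id = site_ids, latitude = round(lat, 4),
                        longitude = round(lon, 4), rplb_total = rplb_total,
                        stringsAsFactors = FALSE)

    n_local_total <- length(genes) * n_sites * variants_per_gene_site
    n_shared_total <- round(shared_variant_fraction /
                              (1 - shared_variant_fraction) * n_local_total)
    shared_gene <- if (n_shared_total > 0) {
      sample(genes, n_shared_total, replace = TRUE)
    } else {
      character()
    }

    variant_rows <- list()
    cluster_rows <- list()
    summary_rows <- list()
    for (g in genes) {
      L <- gene_protein_length(g)
      n_local <- n_sites * variants_per_gene_site
      n_shared <- sum(shared_gene == g)
      k <- n_local + n_shared
      root <- sample(AA_ALPHABET[1:20], L, replace = TRUE)
      ancestors <- plant_ancestors(root, k, divergence)
      m_within <- floor(within_divergence * L / 2)
      cl_ids <- sprintf("%s_C%03d", g, seq_len(k))
      # local clusters: sites cycle so every site gets its quota
      local_site <- rep(site_ids, each = variants_per_gene_site)
      for (j in seq_len(k)) {
        shared <- j > n_local
        csites <- if (shared) {
          sort(sample(site_ids, sample(3:n_sites, 1)))
        } else {
          local_site[j]
        }
        canonical <- paste(ancestors[[j]], collapse = "")
        for (s in csites) {
          vid <- sprintf("%s_%s_v%d", cl_ids[j], s, 1L)
          variant_rows[[length(variant_rows) + 1L]] <- data.frame(
            variant_id = vid, gene = g, site_id = s, sequence = canonical,
            abundance = round(stats::rlnorm(1, meanlog = 1, sdlog = 1), 4),
            stringsAsFactors = FALSE)
          cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
            variant_id = vid, cluster_id = cl_ids[j], gene = g, site_id = s,
            stringsAsFactors = FALSE)
        }
        if (!shared && m_within > 0) {
          # minor within-cluster variants at the same site
          for (extra in seq_len(stats::rbinom(1, 2, 0.3))) {
            mut <- mutate_sequence(ancestors[[j]],
                                   sample.int(m_within, 1L))
            vid <- sprintf("%s_%s_v%d", cl_ids[j], csites, extra + 1L)
            variant_rows[[length(variant_rows) + 1L]] <- data.frame(
              variant_id = vid, gene = g, site_id = csites,
              sequence = paste(mut, collapse = ""),
              abundance = round(stats::rlnorm(1, meanlog = 0, sdlog = 1), 4),
              stringsAsFactors = FALSE)
            cluster_rows[[length(cluster_rows) + 1L]] <- data.frame(
              variant_id = vid, cluster_id = cl_ids[j], gene = g,
              site_id = csites, stringsAsFactors = FALSE)
          }
        }
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          cluster_id = cl_ids[j], gene = g, occupancy = length(csites),
          endemic = length(csites) < 3L, stringsAsFactors = FALSE)
      }
    }
    variants <- do.call(rbind, variant_rows)
    rownames(variants) <- NULL
    clusters <- do.call(rbind, cluster_rows)
    cluster_summary <- do.call(rbind, summary_rows)

    # per-site rplB community structure over ten phyla
    phyla <- sprintf("Phylum%02d", 1:10)
    comm <- do.call(rbind, lapply(seq_len(n_sites), function(i) {
      p <- stats::rgamma(length(phyla), shape = 0.8)
      counts <- drop(stats::rmultinom(1, rplb_total[i], p / sum(p)))
      data.frame(site_id = site_ids[i], phylum = phyla,
                 count = as.integer(counts), stringsAsFactors = FALSE)
    }))

    gsc <- stats::aggregate(list(count = variants$abundance),
                            variants[, c("site_id", "gene")], FUN = sum)
    list(sites = sites, variants = variants, rplb_community = comm,
         truth = list(clusters = clusters, cluster_summary = cluster_summary,
                      n_clusters = nrow(cluster_summary),
                      endemic_proportion = mean(cluster_summary$endemic),
                      total_abundance = sum(variants$abundance),
                      gene_site_counts = gsc),
         params = list(n_sites = n_sites, genes = genes,
                       shared_variant_fraction = shared_variant_fraction,
                       variants_per_gene_site = variants_per_gene_site,
                       divergence = divergence,
                       within_divergence = within_divergence, seed = seed))
  })
}

# draw k cluster ancestors from a root sequence, rejecting draws until all
# pairwise per-residue differences are >= divergence (guaranteed margins
# beat expected ones: recovery tests are exact, not statistical)
plant_ancestors <- function(root, k, divergence) {
  L <- length(root)
  min_diff <- ceiling(divergence * L)
  q <- min(0.9, 1.6 * divergence)    # per-position mutation probability
  ancestors <- vector("list", k)
  for (j in seq_len(k)) {
    for (try in seq_len(200L)) {
      cand <- root
      hit <- which(stats::runif(L) < q)
      if (length(hit)) cand <- mutate_at(cand, hit)
      ok <- TRUE
      for (prev in ancestors[seq_len(j - 1L)]) {
        if (sum(cand != prev) < min_diff) { ok <- FALSE; break }
      }
      if (ok) { ancestors[[j]] <- cand; break }
    }
    if (is.null(ancestors[[j]])) {
      stop_("could not place ", k, " clusters at divergence ", divergence,
            " on a length-", L, " protein")
    }
  }
  ancestors
}

mutate_sequence <- function(seq_vec, n_mut) {
  mutate_at(seq_vec, sample.int(length(seq_vec), n_mut))
}

mutate_at <- function(seq_vec, pos) {
  aa <- AA_ALPHABET[1:20]
  for (p in pos) {
    seq_vec[p] <- sample(setdiff(aa, seq_vec[p]), 1L)
  }
  seq_vec
}

#' Generate per-sample organism abundance weights
#'
#' Emulates 16S-inferred environmental abundances of cultivable organisms:
#' for each sample, a Dirichlet-distributed weight vector over the genomes
#' (summing to 1 within 1e-9), labeled with a soil order.
#'
#' @param genomes Genome metadata from [generate_genomes()].
#' @param n_samples Number of samples (>= \code{n_soil_orders}).
#' @param n_soil_orders Number of soil-order labels to cycle through.
#' @param concentration Dirichlet concentration parameter (default 1, a
#'   flat Dirichlet).
#' @param seed Integer seed.
#' @return Long \code{data.frame}: \code{sample_id}, \code{soil_order},
#'   \code{genome_id}, \code{weight}.
#' @export
generate_organism_weights <- function(genomes, n_samples,
                                      n_soil_orders = 6, concentration = 1,
                                      seed) {
  assert_cols(genomes, "genome_id", "genome metadata")
  stopifnot(is_count(n_samples), is_count(n_soil_orders))
  if (n_samples < n_soil_orders) {
    stop_("need at least one sample per soil order")
  }
  orders <- c("Mollisol", "Alfisol", "Ultisol", "Spodosol", "Andisol",
              "Gelisol", "Histosol", "Inceptisol", "Vertisol", "Aridisol",
              "Oxisol", "Entisol")[seq_len(min(n_soil_orders, 12L))]
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(n_samples), function(i) {
      w <- stats::rgamma(nrow(genomes), shape = concentration)
      data.frame(sample_id = sprintf("EMP%03d", i),
                 soil_order = orders[(i - 1L) %% length(orders) + 1L],
                 genome_id = genomes$genome_id, weight = w / sum(w),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Write a synthetic genome collection to disk
#'
#' Emits the hit table, genome metadata and machine-readable truth ledgers
#' as TSVs under \code{dir} (ledgers under \code{dir/truth/}).
#'
#' @param x Result of [generate_genomes()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_genomes <- function(x, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_hit_table(x$hits, file.path(dir, "hits.tsv"))
  write_tsv(x$genomes, file.path(dir, "genomes.tsv"))
  write_tsv(x$truth$genotype, file.path(dir, "truth", "genotype.tsv"))
  write_tsv(data.frame(none_count = x$truth$none_count,
                       none_fraction = x$truth$none_fraction,
                       n_decoys = x$truth$n_decoys),
            file.path(dir, "truth", "summary.tsv"))
  invisible(dir)
}

#' Write a synthetic site collection to disk
#'
#' Emits variant FASTA + abundance TSV, site metadata, rplB community table
#' and truth ledgers under \code{dir}.
#'
#' @param x Result of [generate_sites()].
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_synthetic_sites <- function(x, dir) {
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  write_variant_fasta(x$variants, file.path(dir, "variants.faa"),
                      file.path(dir, "abundance.tsv"))
  write_tsv(x$sites, file.path(dir, "sites.tsv"))
  write_tsv(x$rplb_community, file.path(dir, "rplb_community.tsv"))
  write_tsv(x$truth$clusters, file.path(dir, "truth", "clusters.tsv"))
  write_tsv(x$truth$cluster_summary,
            file.path(dir, "truth", "cluster_summary.tsv"))
  invisible(dir)
}
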