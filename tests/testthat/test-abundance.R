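two_genome_matrix <- function(copies1, copies2, gene = "acr3") {
  genomes <- data.frame(genome_id = c("G1", "G2"), phylum = "P1",
                        stringsAsFactors = FALSE)
  mk <- function(genome, n) {
    if (n == 0) return(NULL)
    data.frame(genome_id = genome, replicon_id = paste0(genome, "_chr"),
               replicon_type = "chromosome",
               orf_id = sprintf("%s_O%d", genome, seq_len(n)), gene = gene,
               score = 500, percent_alignment = 95, stringsAsFactors = FALSE)
  }
  hits <- rbind(mk("G1", copies1), mk("G2", copies2))
  if (is.null(hits)) hits <- mk("G1", 1)[0, ]
  build_genotype_matrix(hits, genomes)
}

test_that("cultivation-weighted abundance is the weighted copy expectation", {
  gm <- two_genome_matrix(1, 0)
  w <- data.frame(sample_id = "s1", soil_order = "Mollisol",
                  genome_id = c("G1", "G2"), weight = c(0.5, 0.5))
  est <- cultivation_weighted_abundance(gm, w)
  expect_equal(est$per_sample$estimate[est$per_sample$gene == "acr3"], 0.5)
  # all weight on the zero-copy genome
  w0 <- transform(w, weight = c(0, 1))
  est0 <- cultivation_weighted_abundance(gm, w0)
  expect_equal(est0$per_sample$estimate[est0$per_sample$gene == "acr3"], 0)
  # unnormalized weights are rejected
  expect_error(cultivation_weighted_abundance(gm, transform(w, weight = 0.4)),
               "sum to 1")
  expect_error(cultivation_weighted_abundance(
    gm, transform(w, genome_id = c("G1", "GX"))), "unknown genome")
})

test_that("weighted estimates equal per-sample dot products and are linear", {
  g <- generate_genomes(40, seed = 8)
  gm <- build_genotype_matrix(process_hits(g$hits, g$genomes)$hits,
                              g$genomes)
  w <- generate_organism_weights(g$genomes, n_samples = 6, n_soil_orders = 3,
                                 seed = 9)
  est <- cultivation_weighted_abundance(gm, w)
  copies <- gm$chromosome + gm$plasmid
  for (s in unique(w$sample_id)[1:3]) {
    ws <- w[w$sample_id == s, ]
    for (gene in c("acr3", "arsC_grx")) {
      manual <- sum(ws$weight * copies[ws$genome_id, gene])
      expect_equal(est$per_sample$estimate[est$per_sample$sample_id == s &
                                             est$per_sample$gene == gene],
                   manual, tolerance = 1e-12)
    }
  }
  # linearity: mixing two weight tables mixes the estimates identically
  w1 <- w[w$sample_id == "EMP001", ]
  w2 <- transform(w1, weight = rev(weight))
  mix <- transform(w1, weight = 0.3 * w1$weight + 0.7 * w2$weight)
  e1 <- cultivation_weighted_abundance(gm, w1)$per_sample$estimate
  e2 <- cultivation_weighted_abundance(gm, w2)$per_sample$estimate
  em <- cultivation_weighted_abundance(gm, mix)$per_sample$estimate
  expect_equal(em, 0.3 * e1 + 0.7 * e2, tolerance = 1e-12)
})

test_that("rplB normalization divides by marker totals and is depth-invariant", {
  counts <- data.frame(site_id = c("S1", "S1", "S2"),
                       gene = c("acr3", "arsM", "acr3"),
                       count = c(5, 2, 3))
  sites <- data.frame(site_id = c("S1", "S2"), rplb_total = c(10, 6))
  pr <- rplb_normalize(counts, sites)
  expect_equal(pr$normalized[pr$site_id == "S1" & pr$gene == "acr3"], 0.5)
  # undetected is an explicit marker, distinct from zero
  nd <- pr[pr$site_id == "S2" & pr$gene == "arsM", ]
  expect_false(nd$detected)
  expect_true(is.na(nd$normalized))
  # scaling all counts and rplB by 7 leaves normalized values unchanged
  pr7 <- rplb_normalize(transform(counts, count = count * 7),
                        transform(sites, rplb_total = rplb_total * 7))
  expect_equal(pr7$normalized, pr$normalized)
  expect_error(rplb_normalize(counts, transform(sites, rplb_total = c(10, 0))),
               "positive")
})

test_that("normalized site profiles match the generator ledger", {
  s <- generate_sites(5, seed = 14)
  counts <- site_gene_counts(s$variants)
  pr <- rplb_normalize(counts, s$sites)
  led <- s$truth$gene_site_counts
  for (i in seq_len(nrow(led))) {
    row <- pr[pr$site_id == led$site_id[i] & pr$gene == led$gene[i], ]
    expect_equal(row$normalized,
                 led$count[i] /
                   s$sites$rplb_total[s$sites$site_id == led$site_id[i]],
                 tolerance = 1e-12)
  }
})

test_that("relative gene composition sums to one over detected genes", {
  counts <- data.frame(site_id = "S1", gene = c("acr3", "arsM"),
                       count = c(3, 1))
  sites <- data.frame(site_id = "S1", rplb_total = 10)
  comp <- relative_gene_composition(rplb_normalize(counts, sites))
  expect_equal(comp$proportion, c(0.75, 0.25))
  one <- rplb_normalize(data.frame(site_id = "S1", gene = "acr3", count = 2),
                        sites)
  expect_equal(relative_gene_composition(one)$proportion, 1)
  none <- rplb_normalize(data.frame(site_id = "S1", gene = "acr3", count = 0),
                         sites)
  expect_error(relative_gene_composition(none), "no genes detected")
})

test_that("per-genome normalized abundance is copies over genome count", {
  gm <- two_genome_matrix(3, 2)
  ab <- refsoil_normalized_abundance(gm)
  expect_equal(unname(ab["acr3"]), 2.5)
  expect_equal(unname(ab["arsM"]), 0)
})

test_that("community structure flags top phyla and their coverage", {
  # seven equal phyla: top six cover 6/7 >= 0.75, no warning
  otus <- data.frame(site_id = "S1", phylum = paste0("P", 1:7), count = 10)
  expect_no_warning(cs <- community_structure(otus))
  expect_equal(sum(cs$top_phylum), 6L)
  expect_equal(sum(cs$proportion), 1)
  # single phylum
  one <- community_structure(data.frame(site_id = "S1", phylum = "P1",
                                        count = 4))
  expect_equal(one$proportion, 1)
  expect_true(one$top_phylum)
  # a long flat tail drops coverage below 75% and warns
  flat <- data.frame(site_id = "S1", phylum = paste0("P", 1:20), count = 1)
  expect_warning(community_structure(flat), "cover only")
  expect_error(community_structure(data.frame(site_id = "S1", phylum = "P1",
                                              count = 0)), "all-zero")
  # proportions equal a brute-force group-by on a generated fixture
  s <- generate_sites(4, seed = 31)
  cs2 <- community_structure(s$rplb_community)
  for (site in unique(cs2$site_id)) {
    sub <- s$rplb_community[s$rplb_community$site_id == site, ]
    expect_equal(cs2$proportion[cs2$site_id == site][
      match(sub$phylum, cs2$phylum[cs2$site_id == site])],
      sub$count / sum(sub$count))
  }
})
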