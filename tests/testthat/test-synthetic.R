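test_that("genome generation is seed-deterministic and honors prevalences", {
  a <- generate_genomes(10, none_fraction = 0.2, seed = 7)
  b <- generate_genomes(10, none_fraction = 0.2, seed = 7)
  expect_identical(a, b)
  c <- generate_genomes(10, none_fraction = 0.2, seed = 8)
  expect_false(identical(a$hits, c$hits))

  # zero prevalence: only decoys, and every one of them fails screening
  z <- generate_genomes(60, genotype_prevalence = stats::setNames(
    rep(0, 9), arsenic_genes()), seed = 5)
  expect_equal(nrow(z$truth$genotype), 0L)
  expect_equal(nrow(z$hits), z$truth$n_decoys)
  expect_equal(nrow(screen_hits(z$hits)$hits), 0L)
})

test_that("realized none fraction falls in its binomial confidence band", {
  g <- generate_genomes(200, none_fraction = 0.143, seed = 11)
  ci <- qbinom(c(0.025, 0.975), 200, 0.143) / 200
  expect_gte(g$truth$none_fraction, ci[1])
  expect_lte(g$truth$none_fraction, ci[2])
  # ledger agrees with the emitted hit table after exact screening
  pr <- process_hits(g$hits, g$genomes)
  gm <- build_genotype_matrix(pr$hits, g$genomes)
  expect_equal(none_fraction(gm)$proportion, g$truth$none_fraction)
})

test_that("infeasible none fraction + prevalence combinations error", {
  prev <- default_genotype_prevalence()
  prev["arsC_grx"] <- 0.95
  expect_error(generate_genomes(10, genotype_prevalence = prev,
                                none_fraction = 0.2, seed = 1),
               "infeasible")
})

test_that("trait simulation modes have their designed properties", {
  tree <- balanced_tree16()
  # clustered traits form a clade by construction
  tr <- simulate_traits_on_tree(tree, "clustered", prevalence = 0.25,
                                seed = 1)
  expect_equal(sum(tr), 4L)
  pos <- which(tr == 1)
  mrca <- ape::getMRCA(tree, names(tr)[pos])
  clade_tips <- ape::extract.clade(tree, mrca)$tip.label
  expect_setequal(clade_tips, names(tr)[pos])

  # random traits hit the prevalence within a binomial band
  set.seed(2)
  big <- ape::rcoal(64)
  ones <- vapply(1:30, function(i) {
    sum(simulate_traits_on_tree(big, "random", 0.5, seed = i))
  }, integer(1))
  expect_gt(mean(ones), qbinom(0.005, 64, 0.5))
  expect_lt(mean(ones), qbinom(0.995, 64, 0.5))

  # Brownian-threshold traits carry more signal than random ones
  V <- phylo_vcv(big)
  Kb <- vapply(1:50, function(i) {
    blomberg_K(simulate_traits_on_tree(big, "brownian_threshold", 0.5,
                                       seed = i), V)
  }, numeric(1))
  Kr <- vapply(1:50, function(i) {
    blomberg_K(simulate_traits_on_tree(big, "random", 0.5, seed = 100 + i),
               V)
  }, numeric(1))
  expect_gt(mean(Kb), mean(Kr))

  expect_error(simulate_traits_on_tree(tree, "random", prevalence = 0,
                                       seed = 1), "prevalence")
  expect_error(simulate_traits_on_tree(tree, "random", prevalence = 1,
                                       seed = 1), "prevalence")
})

test_that("site generation plants disjoint identity bands and honest ledgers", {
  s <- generate_sites(6, variants_per_gene_site = 1, seed = 13)
  # every within-cluster pair >= 95% identity, between-cluster pairs <= 88%
  d <- dereplicate(s$variants)
  cl_of <- s$truth$clusters$cluster_id[match(d$variant_id,
                                             s$truth$clusters$variant_id)]
  for (g in unique(d$gene)[1:2]) {
    idx <- which(d$gene == g)
    for (i in idx) {
      others <- setdiff(idx, i)
      ident <- vapply(others, function(j) {
        pairwise_identity(d$sequence[i], d$sequence[j])
      }, numeric(1))
      same <- cl_of[others] == cl_of[i]
      if (any(same)) expect_true(all(ident[same] >= 95))
      if (any(!same)) expect_true(all(ident[!same] <= 88))
    }
  }
  # shared clusters occupy >= 3 sites, local clusters exactly 1
  cs <- s$truth$cluster_summary
  expect_true(all(cs$occupancy[cs$endemic] <= 2))
  expect_true(all(cs$occupancy[!cs$endemic] >= 3))

  # no shared pool at all: every cluster occupies exactly one site
  s0 <- generate_sites(5, shared_variant_fraction = 0, seed = 3)
  expect_true(all(s0$truth$cluster_summary$occupancy == 1L))
  expect_equal(s0$truth$endemic_proportion, 1)

  # overlapping divergence bands are rejected
  expect_error(generate_sites(4, divergence = 0.13, within_divergence = 0.2,
                              seed = 1), "divergence")
  # seed determinism extends to the FASTA bytes
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  write_synthetic_sites(generate_sites(4, seed = 9), dir1)
  write_synthetic_sites(generate_sites(4, seed = 9), dir2)
  f1 <- file.path(dir1, "variants.faa")
  f2 <- file.path(dir2, "variants.faa")
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("organism weights are Dirichlet rows summing to one", {
  g <- generate_genomes(25, seed = 2)
  w <- generate_organism_weights(g$genomes, n_samples = 8,
                                 n_soil_orders = 4, seed = 6)
  sums <- tapply(w$weight, w$sample_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_equal(length(unique(w$soil_order)), 4L)
  w2 <- generate_organism_weights(g$genomes, n_samples = 8,
                                  n_soil_orders = 4, seed = 6)
  expect_identical(w, w2)
  expect_error(generate_organism_weights(g$genomes, n_samples = 2,
                                         n_soil_orders = 4, seed = 1),
               "soil order")
})
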