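test_that("pairwise identity counts matches over non-terminal-gap columns", {
  a <- random_protein(100, seed = 51)
  expect_equal(pairwise_identity(a, a), 100)
  # ten substitutions, no gaps
  av <- strsplit(a, "")[[1]]
  bv <- av
  idx <- seq(5, 95, by = 10)
  for (i in idx) bv[i] <- setdiff(c("A", "C", "D"), av[i])[1]
  expect_equal(pairwise_identity(a, paste(bv, collapse = "")), 90)
  # symmetry
  b <- random_protein(90, seed = 52)
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  expect_error(pairwise_identity(a, ""), "empty")
})

test_that("alignment scores equal an independent Gotoh DP oracle", {
  set.seed(53)
  for (i in 1:8) {
    la <- sample(30:60, 1)
    a <- random_protein(la)
    if (i <= 4) {
      # equal length, substitutions only: unique gapless optimum
      bv <- strsplit(a, "")[[1]]
      nmut <- sample(1:10, 1)
      pos <- sample(la, nmut)
      for (p in pos) bv[p] <- sample(setdiff(LETTERS[LETTERS %in% c("A", "C",
        "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S",
        "T", "V", "W", "Y")], bv[p]), 1)
      b <- paste(bv, collapse = "")
    } else {
      # internal deletion
      cut <- sort(sample(5:(la - 5), 2))
      b <- paste(strsplit(a, "")[[1]][-(cut[1]:cut[2])], collapse = "")
    }
    oracle <- gotoh_align(a, b)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAStringSet(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = resistome:::identity_matrix(), gapOpening = 5,
      gapExtension = 1)
    expect_equal(Biostrings::score(aln), oracle$score, tolerance = 1e-9)
    if (i <= 4) {
      # unambiguous alignments: identity agrees with the oracle too
      expect_equal(pairwise_identity(a, b),
                   oracle_identity(oracle$a, oracle$b), tolerance = 1e-9)
    }
  }
})

test_that("dereplication merges identical sequences and conserves abundance", {
  v <- data.frame(
    variant_id = c("v1", "v2", "v3"),
    gene = "acr3", site_id = c("S1", "S1", "S2"),
    sequence = c("MKVL", "MKVL", "MKVL"),
    abundance = c(2, 3, 4), stringsAsFactors = FALSE)
  d <- dereplicate(v)
  expect_equal(nrow(d), 2L)
  expect_equal(d$abundance[d$site_id == "S1"], 5)
  expect_equal(sum(d$abundance), sum(v$abundance))
  # no duplicates: unchanged rows
  v2 <- transform(v, sequence = c("MKVL", "MKVA", "MKVC"))
  expect_equal(nrow(dereplicate(v2)), 3L)
  # ledger conservation on a generated fixture
  s <- generate_sites(5, seed = 44)
  expect_equal(sum(dereplicate(s$variants)$abundance),
               s$truth$total_abundance, tolerance = 1e-9)
})

test_that("greedy clustering separates below-threshold pairs", {
  base <- random_protein(100, seed = 61)
  bv <- strsplit(base, "")[[1]]
  change <- function(x, pos) {
    for (p in pos) x[p] <- setdiff(c("A", "C", "D", "E"), x[p])[1]
    paste(x, collapse = "")
  }
  # 11 substitutions in 100 -> 89% identity: two clusters at the 90% line
  far <- change(bv, 1:11)
  v <- data.frame(variant_id = c("v1", "v2"), gene = "acr3",
                  site_id = "S1", sequence = c(base, far),
                  abundance = c(5, 1), stringsAsFactors = FALSE)
  cl <- greedy_cluster(v, 90)
  expect_equal(nrow(cl$clusters), 2L)
  # 10 substitutions -> exactly 90%: joins at a >= threshold
  near <- change(bv, 1:10)
  v2 <- transform(v, sequence = c(base, near))
  expect_equal(nrow(greedy_cluster(v2, 90)$clusters), 1L)
  # all identical sequences: one cluster
  v3 <- transform(v, sequence = base)
  expect_equal(nrow(greedy_cluster(v3, 90)$clusters), 1L)
})

test_that("clustering recovers the planted partition and conserves abundance", {
  s <- generate_sites(6, variants_per_gene_site = 1, seed = 71)
  d <- dereplicate(s$variants)
  cl <- greedy_cluster(d, 90)
  truth <- s$truth$clusters
  planted <- truth$cluster_id[match(cl$members$variant_id,
                                    truth$variant_id)]
  tab <- table(planted, cl$members$cluster_id)
  expect_equal(nrow(cl$clusters), s$truth$n_clusters)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_true(all(colSums(tab > 0) == 1))
  expect_equal(sum(cl$clusters$total_abundance), s$truth$total_abundance,
               tolerance = 1e-9)
  # partition property: every input sequence in exactly one cluster
  expect_setequal(cl$members$variant_id, d$variant_id)
  expect_equal(anyDuplicated(cl$members$variant_id), 0L)
  # raising the threshold never merges clusters
  n90 <- nrow(cl$clusters)
  n95 <- nrow(greedy_cluster(d, 95)$clusters)
  expect_gte(n95, n90)
})

test_that("occupancy classification pins the endemic boundary at 3 sites", {
  mk_clusters <- function(occupancies) {
    v <- do.call(rbind, lapply(seq_along(occupancies), function(i) {
      seqv <- random_protein(60, seed = 80 + i)
      data.frame(variant_id = sprintf("c%d_s%d", i,
                                      seq_len(occupancies[i])),
                 gene = "acr3",
                 site_id = sprintf("S%02d", seq_len(occupancies[i])),
                 sequence = seqv, abundance = 1, stringsAsFactors = FALSE)
    }))
    greedy_cluster(v, 90)
  }
  cl <- mk_clusters(c(1, 2, 3, 4))
  res <- classify_occupancy(cl)
  occ <- res$clusters$occupancy
  expect_equal(res$clusters$endemic, occ < 3)
  expect_equal(res$endemic_count, 2L)
  expect_equal(res$cosmopolitan_count, 2L)
  expect_equal(res$endemic_count + res$cosmopolitan_count,
               nrow(res$clusters))
  # single-site dataset: everything endemic
  s1 <- generate_sites(1, shared_variant_fraction = 0, seed = 5)
  res1 <- classify_occupancy(greedy_cluster(dereplicate(s1$variants), 90))
  expect_equal(res1$endemic_proportion, 1)
})

test_that("sites rank by mean normalized abundance with stable ties", {
  pr <- data.frame(site_id = rep(c("S1", "S2", "S3"), each = 1),
                   gene = "acr3", count = c(1, 3, 2),
                   rplb_total = 10, detected = TRUE,
                   normalized = c(0.1, 0.3, 0.2))
  rk <- rank_abundance(pr)
  expect_equal(rk$site_id, c("S2", "S3", "S1"))
  expect_equal(rk$site_rank, 1:3)
  one <- rank_abundance(pr[1, ])
  expect_equal(one$site_rank, 1L)
  # brute-force ordering on a generated fixture
  s <- generate_sites(6, seed = 88)
  prof <- rplb_normalize(site_gene_counts(s$variants), s$sites)
  rk2 <- rank_abundance(prof)
  det <- prof[prof$detected, ]
  means <- sort(tapply(det$normalized, det$site_id, mean), decreasing = TRUE)
  expect_equal(unique(rk2$site_id), names(means))
})
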