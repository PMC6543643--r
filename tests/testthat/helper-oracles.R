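# Independent oracles used to check the package implementations.
# Each is coded directly from first principles and shares no code with R/.

# Gotoh global alignment with affine gaps (match +1, mismatch 0, gap cost
# open + ext * length). Returns the optimal score and one optimal alignment.
gotoh_align <- function(a, b, match = 1, mismatch = 0, open = 5, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in aligned pair
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in b (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in a (B consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -(open + ext * (i - 1))
  for (j in 2:(m + 1)) Y[1, j] <- -(open + ext * (j - 1))
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  score <- max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  # traceback (prefer M, then X, then Y on ties)
  pa <- character(0); pb <- character(0)
  i <- n + 1; j <- m + 1
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  while (i > 1 || j > 1) {
    if (state == 1L) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      pa <- c(A[i - 1], pa); pb <- c(B[j - 1], pb)
      prev <- c(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      state <- which.max(prev)
      i <- i - 1; j <- j - 1
    } else if (state == 2L) {
      pa <- c(A[i - 1], pa); pb <- c("-", pb)
      state <- if (isTRUE(all.equal(X[i, j], M[i - 1, j] - open - ext)) &&
                   M[i - 1, j] - open - ext >= X[i - 1, j] - ext) 1L else 2L
      i <- i - 1
    } else {
      pa <- c("-", pa); pb <- c(B[j - 1], pb)
      state <- if (isTRUE(all.equal(Y[i, j], M[i, j - 1] - open - ext)) &&
                   M[i, j - 1] - open - ext >= Y[i, j - 1] - ext) 1L else 3L
      j <- j - 1
    }
    if (i == 1 && state == 2L) state <- 3L
    if (j == 1 && state == 3L && i > 1) state <- 2L
  }
  list(score = score, a = pa, b = pb)
}

# identity of an aligned pair, excluding terminal-gap columns, coded
# independently of the package version
oracle_identity <- function(pa, pb) {
  first <- max(min(which(pa != "-")), min(which(pb != "-")))
  last <- min(max(which(pa != "-")), max(which(pb != "-")))
  cols <- first:last
  100 * sum(pa[cols] == pb[cols]) / length(cols)
}

# score of an aligned pair under the guide scores (to compare optima)
alignment_score <- function(pa, pb, match = 1, mismatch = 0, open = 5,
                            ext = 1) {
  sc <- 0
  in_gap <- FALSE
  for (k in seq_along(pa)) {
    if (pa[k] == "-" || pb[k] == "-") {
      sc <- sc - ext - if (in_gap) 0 else open
      in_gap <- TRUE
    } else {
      sc <- sc + if (pa[k] == pb[k]) match else mismatch
      in_gap <- FALSE
    }
  }
  sc
}

# two-sided Mann-Whitney p by full enumeration of group assignments
mw_enum_p <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  N <- length(pool)
  u_of <- function(idx) {
    xs <- pool[idx]; ys <- pool[-idx]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  mid <- n1 * (N - n1) / 2
  combs <- utils::combn(N, n1)
  us <- apply(combs, 2, u_of)
  mean(abs(us - mid) >= abs(u_obs - mid) - 1e-12)
}

# one-sided Mantel p by enumeration over all relabelings
mantel_enum <- function(d1, d2) {
  n <- nrow(d1)
  ut <- upper.tri(d1)
  perms <- rbind(1:n)
  # all permutations via recursion
  grow <- function(p) {
    if (length(p) == n) return(list(p))
    rest <- setdiff(1:n, p)
    unlist(lapply(rest, function(r) grow(c(p, r))), recursive = FALSE)
  }
  allp <- grow(integer(0))
  r_obs <- cor(d1[ut], d2[ut])
  rs <- vapply(allp, function(p) cor(d1[ut], d2[p, p][ut]), numeric(1))
  list(r = r_obs, p = mean(rs >= r_obs - 1e-12))
}

# brute-force tip covariance via root-to-tip and tip-to-tip path lengths:
# V[i,j] = (depth(i) + depth(j) - d(i,j)) / 2
vcv_bruteforce <- function(tree) {
  n <- length(tree$tip.label)
  dn <- ape::dist.nodes(tree)
  root <- n + 1L
  depth <- dn[root, seq_len(n)]
  D <- dn[seq_len(n), seq_len(n)]
  V <- (outer(depth, depth, "+") - D) / 2
  dimnames(V) <- list(tree$tip.label, tree$tip.label)
  V
}

# naive direct-formula Blomberg K (explicit sums, no shared code)
K_direct <- function(x, V) {
  n <- length(x)
  Vi <- solve(V)
  a <- sum(Vi %*% x) / sum(Vi)
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Vi %*% (x - a)) / (n - 1)
  expected <- (sum(diag(V)) - n / sum(Vi)) / (n - 1)
  (mse0 / mse) / expected
}

# a balanced 16-tip tree with unit branch lengths, used by several tests
balanced_tree16 <- function() {
  ape::compute.brlen(ape::stree(16, type = "balanced"), 1)
}

star_tree <- function(n, len = 2) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(len, nrow(tr$edge))
  tr
}

random_hit_table <- function(n, seed) {
  set.seed(seed)
  data.frame(
    genome_id = sprintf("G%04d", sample(200, n, TRUE)),
    replicon_id = "r",
    replicon_type = sample(c("chromosome", "plasmid"), n, TRUE),
    orf_id = sprintf("O%05d", seq_len(n)),
    gene = sample(arsenic_genes(), n, TRUE),
    score = round(runif(n, 0, 2600), 1),
    percent_alignment = round(runif(n, 0, 100), 1),
    stringsAsFactors = FALSE)
}

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
                 "P", "Q", "R", "S", "T", "V", "W", "Y"), len, TRUE),
        collapse = "")
}
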