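#' Phylogenetic variance-covariance matrix
#'
#' Tip x tip matrix of shared branch length: \code{V[i, j]} is the root-to-
#' most-recent-common-ancestor path length of tips i and j, \code{V[i, i]}
#' the root-to-tip depth. Under Brownian motion this is the trait covariance
#' implied by the tree; polytomies define it unambiguously.
#'
#' @param tree A valid \code{ape::phylo} with branch lengths (see
#'   [read_tree()]).
#' @return Symmetric positive semi-definite matrix with tip labels as
#'   dimnames.
#' @export
phylo_vcv <- function(tree) {
  validate_tree(tree)
  if (sum(tree$edge.length) == 0) stop_("tree has zero total branch length")
  V <- ape::vcv.phylo(tree)
  V[tree$tip.label, tree$tip.label]
}

#' Blomberg's K for a tip trait
#'
#' Ratio of the observed to the Brownian-expected contrast between the
#' phylogenetically naive and phylogenetically corrected mean squared
#' errors. With phylogenetic GLS mean
#' \eqn{\hat a = (1'V^{-1}1)^{-1} 1'V^{-1}x},
#' \eqn{MSE_0 = \sum_i (x_i-\hat a)^2/(n-1)} and
#' \eqn{MSE = (x-\hat a)'V^{-1}(x-\hat a)/(n-1)},
#' \deqn{K = \frac{MSE_0/MSE}{[\mathrm{tr}(V) - n/\sum_{ij}(V^{-1})_{ij}]/(n-1)}.}
#' K is about 1 when trait variation accumulates as Brownian motion on the
#' tree, near 0 when the trait is phylogenetically random, and > 1 when
#' close relatives are even more similar than Brownian motion predicts.
#' Binary presence/absence traits are analyzed with this continuous-trait
#' statistic directly.
#'
#' @param trait Numeric (or 0/1) vector over tips; if named, reordered to
#'   match \code{V}'s dimnames.
#' @param V Tip covariance matrix from [phylo_vcv()].
#' @return K (non-negative scalar).
#' @export
blomberg_K <- function(trait, V) {
  x <- align_trait(trait, V)
  if (stats::var(x) == 0) stop_("trait has zero variance")
  n <- length(x)
  Vi <- solve_vcv(V)
  ones <- rep(1, n)
  s <- sum(Vi)                       # 1' V^-1 1
  a_hat <- sum(Vi %*% x) / s
  dev <- x - a_hat
  mse0 <- sum(dev^2) / (n - 1)
  mse <- drop(crossprod(dev, Vi %*% dev)) / (n - 1)
  expected <- (sum(diag(V)) - n / s) / (n - 1)
  (mse0 / mse) / expected
}

align_trait <- function(trait, V) {
  x <- as.numeric(trait)
  if (length(x) != nrow(V)) stop_("trait length does not match tree tip count")
  if (!is.null(names(trait))) {
    if (!setequal(names(trait), rownames(V))) {
      stop_("trait names do not match tree tips")
    }
    x <- as.numeric(trait[rownames(V)])
  }
  if (anyNA(x)) stop_("trait contains missing values")
  x
}

# invert V, adding a small ridge if numerically singular
solve_vcv <- function(V) {
  tryCatch(solve(V), error = function(e) {
    message("covariance matrix singular; adding 1e-8 ridge")
    solve(V + diag(1e-8 * mean(diag(V)), nrow(V)))
  })
}

#' Permutation test for phylogenetic signal
#'
#' Computes Blomberg's K for a binary (or continuous) tip trait and a
#' permutation p-value: tip values are reshuffled across tips
#' \code{n_permutations} times and the phylogenetically corrected mean
#' squared error (smaller = more signal) is compared with the observed one,
#' \eqn{p = (1 + \#\{MSE_{perm} \le MSE_{obs}\})/(n_{perm}+1)}.
#' Constant traits are untestable: flagged, K and p set to \code{NA}, and
#' excluded from the FDR family by [fdr_adjust()].
#'
#' @param trait Trait vector over tips (named or in tip order).
#' @param tree A valid \code{ape::phylo}.
#' @param n_permutations Number of trait permutations (default 999).
#' @param seed Integer seed; the test is deterministic given it.
#' @param name Trait label carried into the result.
#' @return A one-row \code{data.frame} of class \code{signal_result}:
#'   \code{trait}, \code{n_positive}, \code{K}, \code{p}, \code{p_adjusted}
#'   (NA until [fdr_adjust()]), \code{n_permutations}, \code{seed},
#'   \code{testable}, \code{low_power} (fewer than 5 tips in either state).
#' @export
#' @examples
#' tree <- ape::rcoal(32)
#' tr <- simulate_traits_on_tree(tree, mode = "clustered", prevalence = 0.25,
#'                               seed = 1)
#' signal_test(tr, tree, seed = 1)
signal_test <- function(trait, tree, n_permutations = 999L, seed,
                        name = "trait") {
  validate_tree(tree)
  stopifnot(is_count(n_permutations))
  V <- phylo_vcv(tree)
  x <- align_trait(trait, V)
  n <- length(x)
  n_pos <- sum(x == max(x))
  testable <- stats::var(x) > 0
  if (!testable) {
    res <- data.frame(trait = name, n_positive = NA_integer_, K = NA_real_,
                      p = NA_real_, p_adjusted = NA_real_,
                      n_permutations = as.integer(n_permutations),
                      seed = as.integer(seed), testable = FALSE,
                      low_power = NA)
    class(res) <- c("signal_result", "data.frame")
    return(res)
  }
  Vi <- solve_vcv(V)
  s <- sum(Vi)
  vi_rows <- rowSums(Vi)             # 1' V^-1, as a vector
  mse_of <- function(X) {
    # X: n x m matrix of trait columns; (n-1) MSE per column
    q <- colSums(X * (Vi %*% X))
    b <- colSums(vi_rows * X)
    q - b^2 / s
  }
  obs <- mse_of(matrix(x, ncol = 1))
  perms <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) sample(x), numeric(n))
  })
  p <- (1 + sum(mse_of(perms) <= obs)) / (n_permutations + 1)
  n_ones <- sum(x > min(x))
  res <- data.frame(trait = name, n_positive = n_ones,
                    K = blomberg_K(x, V), p = p, p_adjusted = NA_real_,
                    n_permutations = as.integer(n_permutations),
                    seed = as.integer(seed), testable = TRUE,
                    low_power = min(n_ones, n - n_ones) < 5)
  class(res) <- c("signal_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjustment over a family of signal tests
#'
#' Combines [signal_test()] results (e.g. one per gene x genomic location)
#' and applies the Benjamini-Hochberg step-up over the testable traits only;
#' untestable rows keep \code{NA}.
#'
#' @param results A \code{signal_result} or list of them.
#' @return A \code{signal_result} data.frame with \code{p_adjusted} filled.
#' @export
fdr_adjust <- function(results) {
  if (is.list(results) && !is.data.frame(results)) {
    results <- do.call(rbind, results)
  }
  stopifnot(inherits(results, "data.frame"))
  if (!any(results$testable)) stop_("no testable traits in family")
  idx <- which(results$testable)
  results$p_adjusted[idx] <- stats::p.adjust(results$p[idx], method = "BH")
  class(results) <- c("signal_result", "data.frame")
  results
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("Phylogenetic signal tests (%d trait(s), %d permutations)\n",
              nrow(x), x$n_permutations[1]))
  df <- as.data.frame(x)
  df$K <- round(df$K, 3)
  df$p <- signif(df$p, 3)
  df$p_adjusted <- signif(df$p_adjusted, 3)
  print.data.frame(df[, c("trait", "n_positive", "K", "p", "p_adjusted",
                          "low_power")], row.names = FALSE)
  invisible(x)
}
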