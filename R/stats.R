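#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. The U statistic counts
#' pairs with \eqn{x_i > y_j} plus half the ties. The p-value is exact
#' (full null enumeration of rank assignments) when both samples have at
#' most 10 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return An object of class \code{htest} with \code{statistic} (U),
#'   \code{p.value}, sample sizes in \code{parameter}, and \code{method}
#'   recording whether the p-value was exact.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y) {
  if (!length(x) || !length(y)) stop_("both samples must be non-empty")
  if (anyNA(x) || anyNA(y)) stop_("samples must not contain NA")
  n1 <- length(x)
  n2 <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- n1 <= 10 && n2 <= 10 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  structure(list(statistic = c(U = U),
                 parameter = c(n1 = n1, n2 = n2),
                 p.value = wt$p.value,
                 method = sprintf("Mann-Whitney U test (%s)",
                                  if (exact) "exact" else "normal_approx"),
                 alternative = "two.sided",
                 data.name = paste(deparse1(substitute(x)), "and",
                                   deparse1(substitute(y)))),
            class = "htest")
}

#' Great-circle distances between sites
#'
#' Haversine distance matrix (km, Earth radius 6371 km) over site
#' coordinates.
#'
#' @param sites \code{data.frame} with \code{site_id}, \code{latitude}
#'   (degrees, [-90, 90]) and \code{longitude} (degrees, [-180, 180]).
#' @return Symmetric zero-diagonal matrix (km) with site ids as dimnames.
#' @export
geographic_distance <- function(sites) {
  assert_cols(sites, c("site_id", "latitude", "longitude"), "site table")
  if (any(abs(sites$latitude) > 90)) stop_("latitude outside [-90, 90]")
  if (any(abs(sites$longitude) > 180)) stop_("longitude outside [-180, 180]")
  p <- cbind(sites$longitude, sites$latitude)
  n <- nrow(p)
  D <- matrix(0, n, n, dimnames = list(sites$site_id, sites$site_id))
  for (i in seq_len(n)) {
    if (i < n) {
      j <- (i + 1):n
      d <- geosphere::distHaversine(p[i, , drop = FALSE],
                                    p[j, , drop = FALSE], r = 6371)
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}

#' Between-site gene-content dissimilarity
#'
#' Bray-Curtis (default), Jaccard or Euclidean dissimilarity on the site x
#' gene matrix of rplB-normalized abundances. Genes not detected at a site
#' enter as 0 here (dissimilarities need complete vectors), unlike the
#' conservative per-gene summaries.
#'
#' @param profile A \code{site_profile} from [rplb_normalize()].
#' @param metric \code{"braycurtis"}, \code{"jaccard"} or
#'   \code{"euclidean"}.
#' @return Symmetric zero-diagonal dissimilarity matrix over sites.
#' @export
gene_content_distance <- function(profile,
                                  metric = c("braycurtis", "jaccard",
                                             "euclidean")) {
  metric <- match.arg(metric)
  assert_cols(profile, c("site_id", "gene", "normalized"), "site profile")
  sites <- unique(profile$site_id)
  genes <- unique(profile$gene)
  if (length(sites) < 2) stop_("need at least 2 sites")
  M <- matrix(0, length(sites), length(genes),
              dimnames = list(sites, genes))
  vals <- ifelse(is.na(profile$normalized), 0, profile$normalized)
  M[cbind(match(profile$site_id, sites),
          match(profile$gene, genes))] <- vals
  zero <- rowSums(M) == 0
  if (any(zero)) {
    stop_("all-zero gene vector at site(s): ",
          paste(sites[zero], collapse = ", "))
  }
  vm <- switch(metric, braycurtis = "bray", jaccard = "jaccard",
               euclidean = "euclidean")
  as.matrix(vegan::vegdist(M, method = vm))
}

#' Mantel test of matrix association
#'
#' Pearson correlation r of the upper-triangle entries of two distance
#' matrices, with a one-sided (positive association) permutation p-value
#' obtained by relabeling the rows/columns of the second matrix:
#' \eqn{p = (1 + \#\{r_{perm} \ge r_{obs}\})/(n_{perm}+1)}. When the number
#' of possible relabelings n! does not exceed \code{n_permutations}, all of
#' them are enumerated instead and the p-value is exact
#' (\eqn{\#\{r_{perm} \ge r_{obs}\}/n!}, the identity included).
#'
#' @param d1,d2 Symmetric zero-diagonal distance matrices over the same
#'   sites in the same order, at least 4 x 4.
#' @param n_permutations Number of random relabelings (default 999).
#' @param seed Integer seed (used only when sampling).
#' @return A \code{mantel_result} list: \code{r}, \code{p},
#'   \code{n_permutations} (actual count used), \code{exact}, \code{seed}.
#' @export
mantel <- function(d1, d2, n_permutations = 999L, seed = 1L) {
  check_dist <- function(d, name) {
    if (!is.matrix(d) || nrow(d) != ncol(d)) stop_(name, " must be square")
    if (nrow(d) < 4) stop_("need at least 4 sites")
    if (any(abs(d - t(d)) > 1e-12)) stop_(name, " must be symmetric")
    if (any(abs(diag(d)) > 1e-12)) stop_(name, " must have zero diagonal")
  }
  check_dist(d1, "d1")
  check_dist(d2, "d2")
  if (nrow(d1) != nrow(d2)) stop_("matrices must have the same dimension")
  if (!is.null(rownames(d1)) && !is.null(rownames(d2)) &&
      !identical(rownames(d1), rownames(d2))) {
    stop_("matrices must cover the same sites in the same order")
  }
  n <- nrow(d1)
  ut <- upper.tri(d1)
  v1 <- d1[ut]
  if (stats::sd(v1) == 0 || stats::sd(d2[ut]) == 0) {
    stop_("constant distance matrix: correlation undefined")
  }
  r_obs <- stats::cor(v1, d2[ut])
  r_perm_of <- function(perm) stats::cor(v1, d2[perm, perm][ut])
  n_fact <- factorial(n)
  if (n_fact <= n_permutations) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1L, r_perm_of)
    p <- sum(r_perm >= r_obs - 1e-12) / n_fact
    used <- n_fact
    exact <- TRUE
  } else {
    r_perm <- with_seed(seed, {
      vapply(seq_len(n_permutations),
             function(i) r_perm_of(sample.int(n)), numeric(1))
    })
    p <- (1 + sum(r_perm >= r_obs - 1e-12)) / (n_permutations + 1)
    used <- n_permutations
    exact <- FALSE
  }
  structure(list(r = r_obs, p = p, n_permutations = used, exact = exact,
                 seed = seed, n_sites = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat("Mantel test (one-sided, positive association)\n")
  cat(sprintf("  r = %.5f, p = %.4g (%s, %d relabelings, %d sites)\n",
              x$r, x$p, if (x$exact) "exact" else "permutation",
              x$n_permutations, x$n_sites))
  invisible(x)
}

# all n! permutations, rows of a matrix (n small; used for exact Mantel p)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}
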