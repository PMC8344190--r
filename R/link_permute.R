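#' Permutation of one vector to attain a target correlation with another
#'
#' Single-pass construction of a permutation index `iy` such that
#' `cor(x, y[iy])` is approximately `rho`, while the multiset of values of
#' `y` is preserved exactly. Both vectors are sorted; a noisy copy
#' `z = sort(y) + e` with `e ~ N(0, S_y^2 (1 - rho^2) / rho^2)` sets how
#' strongly the sorted pairing is scrambled; the index
#' `order(y)[order(z)]` is then re-ordered by `rank(x)` so that `x` itself
#' stays untouched. Accuracy improves with `n` and does not require
#' normality (integer or zero-inflated `y` work).
#'
#' `rho = 0` degenerates to an unconstrained random shuffle (the noise
#' variance is infinite there); `rho = 1` co-sorts exactly. Ties are broken
#' by first occurrence so results are deterministic under a fixed seed.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @param rho target correlation in `[0, 1]`.
#' @return An integer permutation of `seq_along(y)`.
#' @export
sortcor <- function(x, y, rho) {
  n <- length(y)
  if (length(x) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (!is.finite(rho) || rho < 0 || rho > 1) stop("rho must be in [0, 1]")
  if (rho == 0) return(sample.int(n))
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("x and y must have nonzero variance when rho > 0")
  }
  oy <- order(y)
  if (rho == 1) {
    iy <- oy
  } else {
    ysort <- y[oy]
    e <- stats::rnorm(n, 0, sqrt(stats::var(y) * (1 - rho^2) / rho^2))
    iy <- oy[order(ysort + e)]
  }
  iy[rank(x, ties.method = "first")]
}

#' Cluster taxa by abundance profile
#'
#' Agglomerative hierarchical clustering (Ward D2 linkage on Euclidean
#' distances between per-taxon log-TSS profiles), cut into exactly `K`
#' clusters. Profiles are centered and scaled before the distance is
#' computed, making squared Euclidean distance proportional to
#' `1 - cor(taxon_i, taxon_j)`, so clusters collect correlated taxa rather
#' than taxa of similar mean abundance. Co-permuting whole clusters instead
#' of single taxa preserves the between-taxon covariance structure when
#' abundances are rearranged.
#'
#' @param a an [abundance_matrix()] with a `logtss` view.
#' @param K number of clusters (default 500, capped at the number of taxa).
#' @return A `cluster_assignment` list with `labels` (per-taxon integer
#'   cluster id) and `n_clusters`.
#' @export
cluster_taxa <- function(a, K = 500) {
  stopifnot(inherits(a, "abundance_matrix"))
  if (is.null(a$logtss)) stop("abundance matrix lacks the log-TSS view; run tss_log_transform() first")
  k <- ncol(a$logtss)
  if (K > k) stop("K must not exceed the number of taxa (", k, ")")
  if (K == k) {
    labels <- seq_len(k)
  } else {
    prof <- scale(a$logtss)
    prof[, !is.finite(colSums(prof))] <- 0  # constant taxa: zero profile
    hc <- stats::hclust(stats::dist(t(prof)), method = "ward.D2")
    labels <- stats::cutree(hc, k = K)
  }
  names(labels) <- a$taxon_ids
  structure(list(labels = as.integer(labels), n_clusters = as.integer(K)),
            class = "cluster_assignment")
}

#' Link one taxon's abundance to a genetic value by cluster co-permutation
#'
#' Computes the [sortcor()] permutation that makes the causative taxon's
#' abundance correlate at `target_rho` with its genetic value, then applies
#' that same row permutation to every taxon in the causative taxon's
#' cluster. Marginal distributions of all taxa are preserved exactly, as are
#' within-cluster correlations; clusters not containing the causative taxon
#' are untouched.
#'
#' @param a an [abundance_matrix()] with a `logtss` view.
#' @param genetic_value length-`n` numeric vector (the simulated genetic
#'   value for the taxon's log abundance).
#' @param taxon_index column index of the causative taxon.
#' @param target_rho desired correlation in `[0, 1]` (the square root of the
#'   abundance heritability).
#' @param clusters a `cluster_assignment` from [cluster_taxa()].
#' @return The `abundance_matrix` with the causative cluster's rows
#'   co-permuted; the permutation used is attached as attribute
#'   `"permutation"`.
#' @export
link_abundance_to_genome <- function(a, genetic_value, taxon_index,
                                     target_rho, clusters) {
  stopifnot(inherits(a, "abundance_matrix"),
            inherits(clusters, "cluster_assignment"))
  if (is.null(a$logtss)) stop("abundance matrix lacks the log-TSS view")
  k <- ncol(a$logtss)
  if (taxon_index < 1 || taxon_index > k) stop("invalid taxon_index")
  x_k <- a$logtss[, taxon_index]
  if (target_rho > 0 && stats::var(x_k) == 0) {
    stop("constant abundance column cannot attain a nonzero correlation")
  }
  iy <- sortcor(genetic_value, x_k, target_rho)
  members <- which(clusters$labels == clusters$labels[taxon_index])
  a$raw[, members] <- a$raw[iy, members, drop = FALSE]
  a$logtss[, members] <- a$logtss[iy, members, drop = FALSE]
  attr(a, "permutation") <- iy
  a
}
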