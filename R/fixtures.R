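#' Specification for synthetic genotype/abundance fixtures
#'
#' Describes the scale and dependence structure of a synthetic dataset that
#' emulates a livestock genotype panel plus a rumen-like taxon abundance
#' table: a U-shaped allele-frequency spectrum with local linkage
#' disequilibrium (LD) for genotypes, and zero-inflated, highly leptokurtic
#' abundances organized in correlated taxon clusters.
#'
#' @param n individuals.
#' @param p SNPs.
#' @param k taxa.
#' @param zero_fraction target fraction of zero abundance cells in `[0, 1)`.
#' @param n_clusters number of correlated taxon blocks (`<= k`).
#' @param ld_block_len SNPs per LD block.
#' @param within_block_r latent correlation between adjacent SNPs inside an
#'   LD block, in `[0, 1)`.
#' @param within_cluster_r latent correlation between taxa sharing a cluster,
#'   in `[0, 1)`.
#' @param depth mean sequencing depth per sample used to scale counts.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n = 300, p = 3000, k = 800, zero_fraction = 0.5,
                         n_clusters = 100, ld_block_len = 10,
                         within_block_r = 0.9, within_cluster_r = 0.6,
                         depth = 5e4) {
  stopifnot(n > 0, p > 0, k > 0, n_clusters >= 1, n_clusters <= k,
            within_block_r >= 0, within_block_r < 1,
            within_cluster_r >= 0, within_cluster_r < 1)
  if (zero_fraction >= 1 || zero_fraction < 0) {
    stop("zero_fraction must be in [0, 1)")
  }
  structure(list(n = n, p = p, k = k, zero_fraction = zero_fraction,
                 n_clusters = n_clusters, ld_block_len = ld_block_len,
                 within_block_r = within_block_r,
                 within_cluster_r = within_cluster_r, depth = depth),
            class = "fixture_spec")
}

# latent haplotype field: AR(1) correlation within LD blocks, blocks independent
.latent_ld <- function(n, p, block_len, r) {
  m <- matrix(stats::rnorm(n * p), n, p)
  if (r > 0 && block_len > 1L) {
    w <- sqrt(1 - r^2)
    for (j in seq_len(p)[-1L]) {
      if ((j - 1L) %% block_len != 0L) m[, j] <- r * m[, j - 1L] + w * m[, j]
    }
  }
  m
}

#' Generate synthetic genotypes
#'
#' Allele frequencies are drawn from a Beta(0.5, 0.5) spectrum truncated to
#' `[0.01, 0.99]`; two latent Gaussian haplotype fields with AR(1) block
#' correlation `within_block_r` are thresholded at the allele-frequency
#' quantile, giving Hardy-Weinberg genotypes with local LD.
#'
#' @param spec a [fixture_spec()].
#' @param seed optional integer seed.
#' @return A [genotype_matrix()] with dosages coded 0/1/2 and no missing
#'   values.
#' @export
gen_genotypes <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  freq <- stats::qbeta(stats::runif(spec$p,
                                    stats::pbeta(0.01, 0.5, 0.5),
                                    stats::pbeta(0.99, 0.5, 0.5)), 0.5, 0.5)
  thr <- stats::qnorm(1 - freq)
  h1 <- .latent_ld(spec$n, spec$p, spec$ld_block_len, spec$within_block_r)
  h2 <- .latent_ld(spec$n, spec$p, spec$ld_block_len, spec$within_block_r)
  d <- sweep(h1, 2L, thr, ">") + sweep(h2, 2L, thr, ">")
  storage.mode(d) <- "double"
  genotype_matrix(d)
}

#' Planted cluster labels of a fixture
#'
#' Taxa are assigned to `n_clusters` contiguous blocks of near-equal size;
#' [gen_abundances()] uses the same assignment, so these labels are the
#' ground truth for clustering tests.
#'
#' @param spec a [fixture_spec()].
#' @return Integer vector of length `k`.
#' @export
fixture_cluster_labels <- function(spec) {
  sort(rep_len(seq_len(spec$n_clusters), spec$k))
}

#' Generate synthetic taxon abundances
#'
#' A latent multivariate Gaussian with common-factor correlation
#' `within_cluster_r` inside each planted taxon cluster is exponentiated to
#' log-normal counts (per-taxon log-scale mean and dispersion are themselves
#' heterogeneous) and zeroed below a per-taxon quantile so that the overall
#' zero fraction matches `zero_fraction`. Raw columns are strongly
#' leptokurtic; the log-TSS view is much less so.
#'
#' @param spec a [fixture_spec()].
#' @param seed optional integer seed.
#' @return An [abundance_matrix()] (raw counts only; apply
#'   [tss_log_transform()] for the log view).
#' @export
gen_abundances <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n; k <- spec$k
  labels <- fixture_cluster_labels(spec)
  r <- spec$within_cluster_r
  lat <- matrix(stats::rnorm(n * k), n, k)
  if (r > 0) {
    fac <- matrix(stats::rnorm(n * spec$n_clusters), n, spec$n_clusters)
    lat <- sqrt(r) * fac[, labels, drop = FALSE] + sqrt(1 - r) * lat
  }
  # heterogeneous log-normal marginals: taxon base abundance spans orders of
  # magnitude, dispersion 1-2.5 on the log scale
  mu <- stats::rnorm(k, mean = log(spec$depth) - 6, sd = 1.5)
  sig <- stats::runif(k, 1, 2.5)
  counts <- round(exp(sweep(sweep(lat, 2L, sig, "*"), 2L, mu, "+")))
  # zero the smallest values per taxon; per-taxon zero fraction varies around
  # the target so the realized overall fraction matches it
  zf <- spec$zero_fraction
  if (zf > 0) {
    half <- min(zf, 1 - zf, 0.3)
    taxon_zf <- pmin(0.98, pmax(0, stats::runif(k, zf - half, zf + half)))
    for (j in seq_len(k)) {
      nz <- round(taxon_zf[j] * n)
      if (nz > 0) counts[order(counts[, j])[seq_len(nz)], j] <- 0
    }
  }
  a <- abundance_matrix(counts)
  a$planted_clusters <- labels
  a
}
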