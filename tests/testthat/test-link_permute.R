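test_that("sortcor handles the exact limits rho = 1 and rho = 0", {
  set.seed(1)
  x <- rnorm(500); y <- rgamma(500, 2)
  iy <- sortcor(x, y, 1)
  expect_equal(cor(x, y[iy]), cor(sort(x), sort(y)))  # exact co-sorting
  expect_gt(cor(x, y[iy]), 0.9)  # skewed y caps the attainable correlation

  iy0 <- sortcor(x, y, 0)
  expect_lt(abs(cor(x, y[iy0])), 2 / sqrt(500) * 2)
  expect_error(sortcor(x, y, -0.1), "rho")
  expect_error(sortcor(x, y, 1.2), "rho")
  expect_error(sortcor(x, rep(1, 500), 0.5), "variance")
})

test_that("sortcor attains intermediate targets and preserves the multiset", {
  set.seed(2)
  err <- replicate(50, {
    x <- rnorm(2000); y <- rnorm(2000)
    cor(x, y[sortcor(x, y, 0.6)]) - 0.6
  })
  expect_lt(abs(mean(err)), 0.05)

  # multiset preservation, including heavy ties
  y <- c(rep(0, 800), rpois(1200, 3))
  x <- rnorm(2000)
  iy <- sortcor(x, y, 0.5)
  expect_identical(sort(y[iy]), sort(y))
  expect_identical(length(unique(iy)), 2000L)
})

test_that("sortcor works on non-normal vectors and improves with n", {
  set.seed(3)
  pois_err <- replicate(30, {
    x <- rnorm(1500); y <- rpois(1500, 2)
    abs(cor(x, y[sortcor(x, y, 0.5)]) - 0.5)
  })
  expect_lt(mean(pois_err), 0.05)

  abserr <- function(n) mean(replicate(40, {
    x <- rnorm(n); y <- rnorm(n)
    abs(cor(x, y[sortcor(x, y, 0.5)]) - 0.5)
  }))
  e <- vapply(c(200, 1000, 5000), abserr, numeric(1))
  expect_gt(e[1], e[2])
  expect_gt(e[2], e[3])
})

test_that("Ward clustering recovers planted blocks and honors K", {
  fx <- small_fixture()
  cl <- fx$cl
  expect_identical(cl$n_clusters, 30L)
  expect_identical(length(cl$labels), 150L)

  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(cl$labels,
                                   fixture_cluster_labels(fx$spec))
  expect_gt(ari, 0.8)

  # duplicated taxon joins its twin before anything else
  a2 <- abundance_matrix(cbind(fx$a$raw, dup = fx$a$raw[, 1]))
  a2 <- tss_log_transform(a2)
  cl2 <- cluster_taxa(a2, K = ncol(a2$raw) - 1L)
  expect_identical(cl2$labels[1], cl2$labels[ncol(a2$raw)])

  # K = k: everyone their own cluster; K > k: error
  clk <- cluster_taxa(fx$a, K = 150)
  expect_identical(sort(clk$labels), 1:150)
  expect_error(cluster_taxa(fx$a, K = 151), "must not exceed")

  # clusters are tight: intra-cluster correlation beats random pairs
  cm <- cor(fx$a$logtss)
  intra <- vapply(unique(cl$labels), function(l) {
    idx <- which(cl$labels == l)
    if (length(idx) < 2) return(NA_real_)
    mean(cm[idx, idx][upper.tri(cm[idx, idx])])
  }, numeric(1))
  rand <- cm[upper.tri(cm)]
  expect_gt(quantile(intra, 0.25, na.rm = TRUE), quantile(rand, 0.75))
})

test_that("cluster co-permutation links the causative taxon and nothing else", {
  fx <- small_fixture()
  set.seed(11)
  gv <- rnorm(150)
  taxon <- which(fx$cl$labels == fx$cl$labels[5])[1]
  linked <- link_abundance_to_genome(fx$a, gv, taxon, 0.6, fx$cl)

  achieved <- cor(gv, linked$logtss[, taxon])
  expect_lt(abs(achieved - 0.6), 0.15)

  members <- which(fx$cl$labels == fx$cl$labels[taxon])
  # marginals exactly preserved for every taxon
  for (j in seq_len(10)) {
    expect_identical(sort(unname(linked$raw[, j])),
                     sort(unname(fx$a$raw[, j])))
  }
  # within-cluster correlations untouched (same permutation applied)
  if (length(members) >= 2) {
    expect_equal(cor(linked$logtss[, members]), cor(fx$a$logtss[, members]))
  }
  # other clusters bitwise untouched
  outside <- which(fx$cl$labels != fx$cl$labels[taxon])
  expect_identical(linked$raw[, outside], fx$a$raw[, outside])

  const <- fx$a
  const$logtss[, taxon] <- 1
  expect_error(link_abundance_to_genome(const, gv, taxon, 0.5, fx$cl),
               "constant")
})

test_that("linking a handful of clusters leaves the global structure intact", {
  # proportions as in the study design: few causative clusters among many
  spec <- fixture_spec(n = 300, p = 50, k = 800)
  a0 <- tss_log_transform(gen_abundances(spec, seed = 4))
  cl <- cluster_taxa(a0, K = 500)
  set.seed(13)
  a <- a0
  for (l in sample(unique(cl$labels), 5)) {
    taxon <- which(cl$labels == l)[1]
    a <- link_abundance_to_genome(a, rnorm(300), taxon, 0.6, cl)
  }
  p0 <- prcomp(a0$logtss, scale. = TRUE)$rotation[, 1]
  p1 <- prcomp(a$logtss, scale. = TRUE)$rotation[, 1]
  expect_gt(abs(cor(p0, p1)), 0.95)
})
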