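test_that("scenario configurations enforce the grid-table consistency rules", {
  cfg <- scenario_config("Joint", r2 = 0.5)
  expect_equal(cfg$n_qtn, 100)
  expect_equal(cfg$n_otu, 25)
  expect_equal(cfg$h2, 0.25)
  expect_equal(cfg$b2, 0.25)

  expect_error(scenario_config("Genome", n_otu = 25), "n_otu = 0")
  expect_error(scenario_config("Microbiome", n_qtn = 10), "h2 = 0")
  expect_error(scenario_config("Joint", h2 = 0.3, b2 = 0.3, r2 = 0.5),
               "h2 \\+ b2")
  expect_error(scenario_config("Recursive", n_otu = 10, n_otu_g = 11),
               "n_otu_g")
  null <- scenario_config("Null")
  expect_equal(null$h2 + null$b2 + null$n_qtn + null$n_otu, 0)
})

test_that("effect magnitudes follow the configured gamma laws", {
  set.seed(4)
  alpha <- holosim:::.signed_gamma(1e5, c(0.2, 5))
  omega <- holosim:::.signed_gamma(1e5, c(1.4, 3.8))
  expect_lt(abs(mean(abs(alpha)) - 0.2 * 5), 0.05)
  expect_lt(abs(mean(abs(omega)) - 1.4 * 3.8), 0.06)
  # signs balanced
  expect_lt(abs(mean(sign(alpha))), 0.02)

  h <- holosim:::.rtrunc_gamma(1e4, c(2, 0.125))
  expect_true(all(h > 0.01 & h < 0.9))
})

test_that("causative features respect scenario structure", {
  fx <- small_fixture()
  set.seed(5)
  effG <- sample_effects(scenario_config("Genome", r2 = 0.5), fx$g, fx$a, fx$cl)
  expect_length(effG$otu_idx, 0)
  expect_length(effG$omega, 0)
  expect_length(effG$qtn_idx, 100)

  effR <- sample_effects(scenario_config("Recursive", r2 = 0.5, n_otu = 20,
                                         n_otu_g = 20),
                         fx$g, fx$a, fx$cl)
  # causative taxa in distinct clusters
  expect_identical(anyDuplicated(fx$cl$labels[effR$otu_idx]), 0L)
  expect_length(effR$beta, 20)
  expect_true(all(effR$h_k2 > 0.01 & effR$h_k2 < 0.9))

  expect_error(sample_effects(scenario_config("Microbiome", n_otu = 31),
                              fx$g, fx$a, fx$cl),
               "exceeds the number of taxon clusters")
})

test_that("abundance-genome linking attains the per-taxon heritabilities", {
  fx <- small_fixture()
  cfg <- scenario_config("Recursive", r2 = 0.5, n_otu = 10, n_otu_g = 10)
  set.seed(6)
  eff <- sample_effects(cfg, fx$g, fx$a, fx$cl)
  lk <- simulate_abundance_genetics(eff, fx$g, fx$a, fx$cl)
  achieved <- vapply(seq_along(lk$effects$otu_g_idx), function(i) {
    cor(lk$genetic_values[, i],
        lk$abundances$logtss[, lk$effects$otu_g_idx[i]])
  }, numeric(1))
  target <- sqrt(lk$effects$h_k2)
  expect_lt(mean(abs(achieved - target)), 0.15)
  expect_gt(cor(achieved, target), 0.6)
  # marginals unchanged by the whole linking step
  for (j in seq_len(ncol(fx$a$raw))) {
    expect_identical(sort(unname(lk$abundances$raw[, j])),
                     sort(unname(fx$a$raw[, j])))
  }
  # no genetic control requested: input returned untouched
  effJ <- sample_effects(scenario_config("Joint"), fx$g, fx$a, fx$cl)
  expect_identical(simulate_abundance_genetics(effJ, fx$g, fx$a, fx$cl)$abundances,
                   fx$a)
})

test_that("variance bookkeeping is exact and targets are met in expectation", {
  fx <- small_fixture()
  for (scn in c("Null", "Genome", "Microbiome", "Joint", "Recursive")) {
    cfg <- scenario_config(scn, r2 = 0.5,
                           n_otu = if (scn %in% c("Genome", "Null")) 0 else 10,
                           n_otu_g = if (scn == "Recursive") 10 else 0)
    for (r in 1:3) {
      sim <- simulate_dataset(cfg, fx$g, fx$a, fx$cl, seed = 100 * r + match(scn, c("Null", "Genome", "Microbiome", "Joint", "Recursive")))
      total <- sim$realized_h2 + sim$realized_b2 + sim$realized_gb_cov +
        sim$realized_resid
      expect_lt(abs(total - 1), 1e-6)
      expect_equal(sd(sim$y), 1, tolerance = 1e-10)
    }
  }
  # Joint: realized fractions close to the targets
  h2s <- replicate(10, {
    sim <- simulate_dataset(scenario_config("Joint", r2 = 0.5, n_otu = 10),
                            fx$g, fx$a, fx$cl)
    c(sim$realized_h2, sim$realized_b2)
  })
  expect_lt(abs(mean(h2s[1, ]) - 0.25), 0.03)
  expect_lt(abs(mean(h2s[2, ]) - 0.25), 0.03)
  # Null: pure standard-normal noise
  sim0 <- simulate_dataset(scenario_config("Null"), fx$g, fx$a, fx$cl, seed = 8)
  expect_equal(sim0$realized_h2, 0)
  expect_equal(sim0$realized_b2, 0)
})

test_that("phenotypes are invariant to rescaling all effects", {
  fx <- small_fixture()
  cfg <- scenario_config("Joint", r2 = 0.5, n_otu = 10)
  set.seed(31)
  eff <- sample_effects(cfg, fx$g, fx$a, fx$cl)
  eff2 <- eff
  eff2$alpha <- 2 * eff$alpha
  eff2$omega <- 2 * eff$omega
  set.seed(77); sim1 <- simulate_phenotype(eff, fx$g, fx$a, cfg)
  set.seed(77); sim2 <- simulate_phenotype(eff2, fx$g, fx$a, cfg)
  expect_equal(sim1$y, sim2$y)
})

test_that("Recursive and Joint phenotypes share the same marginal law", {
  fx <- small_fixture()
  pool <- function(scn) {
    unlist(lapply(1:30, function(r) {
      cfg <- scenario_config(scn, r2 = 0.5, n_otu = 10,
                             n_otu_g = if (scn == "Recursive") 10 else 0)
      simulate_dataset(cfg, fx$g, fx$a, fx$cl, seed = 5000 + r)$y
    }))
  }
  ks <- suppressWarnings(ks.test(pool("Joint"), pool("Recursive")))
  expect_gt(ks$p.value, 0.01)
})

test_that("threshold binarization marks exactly the top quantile", {
  fx <- small_fixture()
  set.seed(41)
  eff <- sample_effects(scenario_config("Microbiome", n_otu = 5),
                        fx$g, fx$a, fx$cl)
  x <- binarize_threshold(fx$a, eff, exceed_frac = 0.25)
  n <- nrow(fx$a$logtss)
  for (j in eff$otu_idx) {
    expect_equal(sum(x[, j]), ceiling(0.25 * n))
    expect_true(all(x[, j] %in% c(0, 1)))
  }
  # deterministic function of the continuous column
  x2 <- binarize_threshold(fx$a, eff, exceed_frac = 0.25)
  expect_identical(x, x2)
  # untouched non-causative columns
  neutral <- setdiff(seq_len(ncol(x)), eff$otu_idx)[1]
  expect_identical(x[, neutral], fx$a$logtss[, neutral])
  expect_error(binarize_threshold(fx$a, eff, exceed_frac = 1), "exceed_frac")
})
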