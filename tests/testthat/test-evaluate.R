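test_that("holdout masking is deterministic under a fixed seed", {
  fx <- small_fixture()
  cfg <- scenario_config("Microbiome", r2 = 0.5, n_otu = 10)
  sim <- simulate_dataset(cfg, fx$g, fx$a, fx$cl, seed = 12)
  inputs <- analysis_inputs(fx$g, fx$a)
  mc <- mcmc_settings(1500, 300, 3)
  cv1 <- cv_accuracy(sim, inputs, "Cb", mcmc = mc, seed = 99)
  cv2 <- cv_accuracy(sim, inputs, "Cb", mcmc = mc, seed = 99)
  expect_identical(cv1$test_idx, cv2$test_idx)
  expect_equal(cv1$accuracy, cv2$accuracy)
  expect_length(cv1$test_idx, round(0.1 * length(sim$y)))
})

test_that("bias tables report mean and relative bias against targets", {
  cfg <- scenario_config("Joint", r2 = 0.5)
  fits <- list(
    structure(list(h2_post = c(mean = 0.2), b2_post = c(mean = 0.30)),
              class = "fit_result"),
    structure(list(h2_post = c(mean = 0.3), b2_post = c(mean = 0.40)),
              class = "fit_result"))
  tab <- vc_bias(fits, cfg)
  b2row <- tab[tab$parameter == "b2", ]
  expect_equal(b2row$mean_estimate, 0.35)
  expect_equal(b2row$rel_bias, 0.4)  # (0.35 - 0.25) / 0.25
  h2row <- tab[tab$parameter == "h2", ]
  expect_equal(h2row$bias, 0)
  expect_error(vc_bias(fits[1], cfg), "at least 2")
})

test_that("association p-values are uniform when no genetic link exists", {
  fx <- small_fixture()
  cfg <- scenario_config("Recursive", r2 = 0.5, n_otu = 10, n_otu_g = 10)
  set.seed(13)
  eff <- sample_effects(cfg, fx$g, fx$a, fx$cl)
  # abundances never linked: every SNP-taxon pair is null
  scan <- gwas_abundances(fx$a, fx$g, eff)
  pn <- scan$pvalues[scan$neutral_mask, ]
  ks <- suppressWarnings(ks.test(pn, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(length(pn), 1000)
  # the empirical threshold sits near the nominal 5% quantile
  expect_lt(abs(scan$empirical_threshold - 0.05), 0.02)
})

test_that("MWAS power is at chance when the phenotype carries no signal", {
  fx <- small_fixture()
  cfg <- scenario_config("Microbiome", r2 = 0.5, n_otu = 25)
  set.seed(14)
  pow <- replicate(20, {
    sim <- simulate_dataset(cfg, fx$g, fx$a, fx$cl)
    sim$y <- rnorm(length(sim$y))  # sever the abundance-phenotype link
    mwas_power(sim)$power
  })
  m <- ceiling(0.05 * 150)
  chance <- m / 150
  expect_lt(abs(mean(pow) - chance), 0.05)

  simN <- simulate_dataset(scenario_config("Null"), fx$g, fx$a, fx$cl, seed = 3)
  expect_error(mwas_power(simN), "b2 > 0")
})

test_that("MWAS ranks causative taxa under a microbiome signal", {
  fx <- small_fixture()
  cfg <- scenario_config("Microbiome", r2 = 0.5, n_otu = 10)
  set.seed(15)
  pow <- replicate(5, {
    sim <- simulate_dataset(cfg, fx$g, fx$a, fx$cl)
    mwas_power(sim)$power
  })
  expect_gt(mean(pow), 0.2)
})

test_that("inclusion recovery summarizes Bayes C inclusion frequencies", {
  incl <- rep(0.01, 100)
  incl[c(3, 7, 11)] <- c(0.9, 0.8, 0.005)
  fit <- structure(list(inclusion_prob = list(b = incl)), class = "fit_result")
  eff <- list(otu_idx = c(3, 7, 11))
  rec <- inclusion_recovery(fit, eff, top_frac = 0.05)
  expect_equal(rec$mean_inclusion, mean(c(0.9, 0.8, 0.005)))
  expect_equal(rec$top_recovery, 2 / 3)  # top-5 contains taxa 3 and 7 only
  expect_error(inclusion_recovery(structure(list(inclusion_prob = NULL),
                                            class = "fit_result"), eff),
               "Bayes C")
})

test_that("abundance heritability estimates shrink toward zero", {
  fx <- small_fixture()
  cfg <- scenario_config("Recursive", r2 = 0.5, n_otu = 8, n_otu_g = 8)
  sim <- simulate_dataset(cfg, fx$g, fx$a, fx$cl, seed = 16)
  caus <- sim$effects$otu_g_idx
  neutral <- setdiff(seq_len(150), caus)[1:8]
  set.seed(17)
  spec <- abundance_h2_spectrum(sim$abundances_linked, fx$g,
                                taxa = c(caus, neutral),
                                mcmc = mcmc_settings(1500, 300, 3))
  est_caus <- spec$h2_hat[seq_along(caus)]
  est_neut <- spec$h2_hat[-seq_along(caus)]
  # shrinkage direction: estimates do not exceed the simulated values on average
  expect_lt(mean(est_caus), mean(sim$effects$h_k2) + 0.05)
  # neutral taxa concentrate near zero, below the causative ones
  expect_lt(mean(est_neut), 0.2)
  expect_gt(mean(est_caus), mean(est_neut))
})
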