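# Small shared fixture for unit tests; built once per test run.
.fixture_cache <- new.env(parent = emptyenv())

small_fixture <- function() {
  if (is.null(.fixture_cache$small)) {
    set.seed(424242)
    spec <- fixture_spec(n = 150, p = 400, k = 150, n_clusters = 30,
                         ld_block_len = 5)
    g <- gen_genotypes(spec)
    a <- tss_log_transform(gen_abundances(spec))
    cl <- cluster_taxa(a, K = 30)
    .fixture_cache$small <- list(spec = spec, g = g, a = a, cl = cl)
  }
  .fixture_cache$small
}

# Full-scale fixture shared by the acceptance-style tests.
study_fixture <- function() {
  if (is.null(.fixture_cache$study)) {
    set.seed(20260920)
    spec <- fixture_spec()  # n = 300, p = 3000, k = 800
    g <- gen_genotypes(spec)
    a <- tss_log_transform(gen_abundances(spec))
    cl <- cluster_taxa(a, K = 500)
    inputs <- analysis_inputs(g, a)
    .fixture_cache$study <- list(spec = spec, g = g, a = a, cl = cl,
                                 inputs = inputs)
  }
  .fixture_cache$study
}

# chain length used throughout the scaled-down experiments
test_mcmc <- function() mcmc_settings(5000, 500, 5)

excess_kurtosis <- function(x) mean((x - mean(x))^4) / stats::var(x)^2 - 3
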