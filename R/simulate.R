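#' Causal scenario configuration
#'
#' Defines one of the six causal architectures relating host genome (G),
#' microbiome (B) and phenotype (y):
#' \describe{
#'   \item{Null}{neither G nor B affects y.}
#'   \item{Genome}{only SNPs affect y (`b2 = 0`, no causative taxa).}
#'   \item{Microbiome}{only taxon abundances affect y (`h2 = 0`).}
#'   \item{Indirect}{G affects y only through genetically controlled
#'     abundances (`h2 = 0`, all causative taxa heritable).}
#'   \item{Joint}{G and B act on y independently (`h2 = b2 = r2/2`).}
#'   \item{Recursive}{G acts on y directly and through genetically
#'     controlled abundances (`h2 = b2 = r2/2`).}
#' }
#' Scenario-specific zeroing is enforced: e.g. a Genome configuration cannot
#' carry causative taxa, and `h2 + b2` must equal `r2`.
#'
#' @param scenario one of `"Null"`, `"Genome"`, `"Microbiome"`,
#'   `"Indirect"`, `"Joint"`, `"Recursive"`.
#' @param r2 total variance fraction `h2 + b2` (0.25 or 0.50 in the default
#'   grids).
#' @param n_qtn number of SNPs with a direct effect on y.
#' @param n_otu number of causative taxa.
#' @param n_otu_g number of causative taxa under genetic control (subset of
#'   `n_otu`).
#' @param n_qtn_per_otu QTNs controlling each heritable abundance.
#' @param h2,b2 heritability and microbiability; scenario defaults follow
#'   the standard grid (`r2/2` each for Joint/Recursive, `r2`/0 for
#'   Genome, 0/`r2` for Microbiome and Indirect).
#' @param effect_alpha,effect_beta gamma (shape, scale) for SNP effect
#'   magnitudes on phenotype and on abundances; default `c(0.2, 5)`.
#' @param effect_omega gamma (shape, scale) for abundance effect magnitudes
#'   on phenotype; default `c(1.4, 3.8)`.
#' @param h2_otu_law gamma (shape, scale) for abundance heritabilities,
#'   truncated to `(0.01, 0.9)`; default `c(2, 0.125)`.
#' @param threshold_mode if `TRUE`, causative abundances act on the
#'   phenotype through a 0/1 threshold indicator rather than linearly.
#' @param exceed_frac fraction of observations above the threshold when
#'   `threshold_mode` is on (default 0.25).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario = c("Null", "Genome", "Microbiome",
                                         "Indirect", "Joint", "Recursive"),
                            r2 = 0.5, n_qtn = NULL, n_otu = NULL,
                            n_otu_g = NULL, n_qtn_per_otu = 10,
                            h2 = NULL, b2 = NULL,
                            effect_alpha = c(0.2, 5),
                            effect_beta = c(0.2, 5),
                            effect_omega = c(1.4, 3.8),
                            h2_otu_law = c(2, 0.125),
                            threshold_mode = FALSE, exceed_frac = 0.25) {
  scenario <- match.arg(scenario)
  if (scenario == "Null") r2 <- 0
  if (r2 < 0 || r2 > 1) stop("r2 must be in [0, 1]")
  defaults <- switch(scenario,
    Null       = list(n_qtn = 0,   n_otu = 0,  n_otu_g = 0,  h2 = 0,    b2 = 0),
    Genome     = list(n_qtn = 100, n_otu = 0,  n_otu_g = 0,  h2 = r2,   b2 = 0),
    Microbiome = list(n_qtn = 0,   n_otu = 25, n_otu_g = 0,  h2 = 0,    b2 = r2),
    Indirect   = list(n_qtn = 0,   n_otu = 25, n_otu_g = 25, h2 = 0,    b2 = r2),
    Joint      = list(n_qtn = 100, n_otu = 25, n_otu_g = 0,  h2 = r2/2, b2 = r2/2),
    Recursive  = list(n_qtn = 100, n_otu = 25, n_otu_g = 25, h2 = r2/2, b2 = r2/2))
  if (is.null(n_qtn)) n_qtn <- defaults$n_qtn
  if (is.null(n_otu)) n_otu <- defaults$n_otu
  if (is.null(n_otu_g)) n_otu_g <- defaults$n_otu_g
  if (is.null(h2)) h2 <- defaults$h2
  if (is.null(b2)) b2 <- defaults$b2
  if (scenario == "Null" && (h2 != 0 || b2 != 0 || n_qtn != 0 || n_otu != 0)) {
    stop("Null scenario requires h2 = b2 = 0 and no causative features")
  }
  if (scenario == "Genome" && (b2 != 0 || n_otu != 0)) {
    stop("Genome scenario requires b2 = 0 and n_otu = 0")
  }
  if (scenario %in% c("Microbiome", "Indirect") && (h2 != 0 || n_qtn != 0)) {
    stop(scenario, " scenario requires h2 = 0 and n_qtn = 0 (no direct SNP effects)")
  }
  if (scenario == "Microbiome" && n_otu_g != 0) {
    stop("Microbiome scenario has no genetically controlled taxa")
  }
  if (scenario %in% c("Indirect", "Recursive") && n_otu_g < 1) {
    stop(scenario, " scenario requires n_otu_g >= 1")
  }
  if (abs(h2 + b2 - r2) > 1e-12) stop("h2 + b2 must equal r2")
  if (n_otu_g > n_otu) stop("n_otu_g must not exceed n_otu")
  if (threshold_mode && (exceed_frac <= 0 || exceed_frac >= 1)) {
    stop("exceed_frac must be in (0, 1)")
  }
  structure(list(scenario = scenario, r2 = r2, h2 = h2, b2 = b2,
                 n_qtn = n_qtn, n_otu = n_otu, n_otu_g = n_otu_g,
                 n_qtn_per_otu = n_qtn_per_otu,
                 effect_alpha = effect_alpha, effect_beta = effect_beta,
                 effect_omega = effect_omega, h2_otu_law = h2_otu_law,
                 threshold_mode = threshold_mode, exceed_frac = exceed_frac),
            class = "scenario_config")
}

# gamma magnitudes with independent random signs
.signed_gamma <- function(n, shape_scale) {
  if (n == 0) return(numeric(0))
  stats::rgamma(n, shape = shape_scale[1], scale = shape_scale[2]) *
    sample(c(-1, 1), n, replace = TRUE)
}

# truncated gamma via rejection; law is (shape, scale), bounds (0.01, 0.9)
.rtrunc_gamma <- function(n, shape_scale, lo = 0.01, hi = 0.9) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rgamma(2L * (n - length(out)) + 10L,
                       shape = shape_scale[1], scale = shape_scale[2])
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

#' Sample causative features and their effects
#'
#' Draws the QTN set with direct phenotype effects (`alpha`), the causative
#' taxa and their phenotype effects (`omega`), and, for scenarios with
#' genetically controlled abundances, each controlled taxon's QTN set
#' (`beta`) and abundance heritability. Effect magnitudes follow the
#' configured gamma laws with independent random signs. Causative taxa are
#' sampled from distinct clusters, and abundance QTN sets are drawn
#' independently of the direct-effect QTNs.
#'
#' @param config a [scenario_config()].
#' @param g a [genotype_matrix()].
#' @param a an [abundance_matrix()].
#' @param clusters a `cluster_assignment` from [cluster_taxa()].
#' @return An `effect_set` list with `qtn_idx`, `alpha`, `otu_idx`, `omega`,
#'   `otu_g_idx`, `beta` (list per controlled taxon with `qtn` and `beta`),
#'   and `h_k2`.
#' @export
sample_effects <- function(config, g, a, clusters) {
  stopifnot(inherits(config, "scenario_config"),
            inherits(g, "genotype_matrix"),
            inherits(a, "abundance_matrix"),
            inherits(clusters, "cluster_assignment"))
  p <- ncol(g$dosages); k <- ncol(a$raw)
  if (config$n_otu > clusters$n_clusters) {
    stop("n_otu exceeds the number of taxon clusters")
  }
  qtn_idx <- if (config$n_qtn > 0) sort(sample.int(p, config$n_qtn)) else integer(0)
  alpha <- .signed_gamma(config$n_qtn, config$effect_alpha)
  otu_idx <- integer(0)
  if (config$n_otu > 0) {
    chosen <- sample(unique(clusters$labels), config$n_otu)
    otu_idx <- vapply(chosen, function(cl) {
      members <- which(clusters$labels == cl)
      members[sample.int(length(members), 1L)]
    }, integer(1))
  }
  omega <- .signed_gamma(config$n_otu, config$effect_omega)
  otu_g_idx <- if (config$n_otu_g > 0) otu_idx[seq_len(config$n_otu_g)] else integer(0)
  beta <- NULL
  h_k2 <- NULL
  if (config$n_otu_g > 0) {
    beta <- lapply(seq_len(config$n_otu_g), function(i) {
      list(qtn = sample.int(p, config$n_qtn_per_otu),
           beta = .signed_gamma(config$n_qtn_per_otu, config$effect_beta))
    })
    names(beta) <- as.character(otu_g_idx)
    h_k2 <- .rtrunc_gamma(config$n_otu_g, config$h2_otu_law)
    names(h_k2) <- as.character(otu_g_idx)
  }
  structure(list(qtn_idx = qtn_idx, alpha = alpha, otu_idx = otu_idx,
                 omega = omega, otu_g_idx = otu_g_idx, beta = beta,
                 h_k2 = h_k2),
            class = "effect_set")
}

# centered -1/0/1 coding from raw dosages
.centered_dosage <- function(g) {
  d <- g$dosages
  if (min(d, na.rm = TRUE) >= 0) d - 1 else d
}

#' Link genetically controlled abundances to the genome
#'
#' For each controlled taxon `k`, computes the genetic value
#' `gamma_k = sum_j beta_jk z_ij` from that taxon's QTN set, then rearranges
#' the taxon's cluster ([link_abundance_to_genome()]) so that
#' `cor(gamma_k, x_k)` equals `sqrt(h_k2)`. The abundance marginals are
#' unchanged. A monomorphic QTN draw (zero-variance genetic value) triggers
#' a resample of that taxon's QTN set with a warning.
#'
#' @param effects an `effect_set` from [sample_effects()].
#' @param g a [genotype_matrix()].
#' @param a an [abundance_matrix()] with a `logtss` view.
#' @param clusters a `cluster_assignment`.
#' @return A list: `abundances` (the linked [abundance_matrix()]),
#'   `genetic_values` (n-by-`n_otu_g` matrix of `gamma_k`), and `effects`
#'   (with any resampled QTN sets).
#' @export
simulate_abundance_genetics <- function(effects, g, a, clusters) {
  stopifnot(inherits(effects, "effect_set"))
  n_g <- length(effects$otu_g_idx)
  if (n_g == 0) {
    return(list(abundances = a, genetic_values = NULL, effects = effects))
  }
  z <- .centered_dosage(g)
  gv <- matrix(0, nrow(z), n_g,
               dimnames = list(g$sample_ids, as.character(effects$otu_g_idx)))
  for (i in seq_len(n_g)) {
    b <- effects$beta[[i]]
    gam <- as.vector(z[, b$qtn, drop = FALSE] %*% b$beta)
    tries <- 0L
    while (stats::var(gam) == 0 && tries < 20L) {
      warning("zero-variance genetic value for taxon ", effects$otu_g_idx[i],
              "; resampling its QTN set")
      b <- list(qtn = sample.int(ncol(z), length(b$qtn)),
                beta = .signed_gamma(length(b$qtn), c(0.2, 5)))
      gam <- as.vector(z[, b$qtn, drop = FALSE] %*% b$beta)
      tries <- tries + 1L
    }
    effects$beta[[i]] <- b
    gv[, i] <- gam
    a <- link_abundance_to_genome(a, gam, effects$otu_g_idx[i],
                                  sqrt(effects$h_k2[i]), clusters)
  }
  list(abundances = a, genetic_values = gv, effects = effects)
}

#' Threshold (binarized) effect inputs
#'
#' Replaces each causative taxon's log abundance by a 0/1 indicator of
#' exceeding its upper `exceed_frac` empirical quantile, so that exactly
#' `ceiling(exceed_frac * n)` observations are 1 (ties broken by stable
#' order). Used to generate phenotypes under a threshold (liability-style)
#' abundance-phenotype relationship while the analysis side still sees the
#' continuous log abundances.
#'
#' @param a an [abundance_matrix()] with a `logtss` view.
#' @param effects an `effect_set` (its `otu_idx` columns are binarized).
#' @param exceed_frac fraction of observations above the threshold.
#' @return The n-by-k matrix of phenotype-generating inputs.
#' @export
binarize_threshold <- function(a, effects, exceed_frac = 0.25) {
  stopifnot(exceed_frac > 0, exceed_frac < 1)
  x <- a$logtss
  n <- nrow(x)
  m <- ceiling(exceed_frac * n)
  for (j in effects$otu_idx) {
    top <- order(x[, j], decreasing = TRUE)[seq_len(m)]
    col <- numeric(n)
    col[top] <- 1
    if (stats::var(col) == 0) {
      warning("binarized column ", j, " is degenerate (zero variance)")
    }
    x[, j] <- col
  }
  x
}

#' Simulate a phenotype under a causal scenario
#'
#' Builds the direct genetic value `G_i = sum_j alpha_j z_ij` and the
#' microbiome value `M_i = sum_k omega_k x_ik` (terms dropped per scenario),
#' rescales them so `Var(G) = h2` and `Var(M) = b2` exactly, draws a
#' residual orthogonalized against `G` and `M` with `Var = 1 - r2`, and
#' returns the standardized phenotype. In the Recursive scenario `G` and
#' `M` are correlated through the genetically controlled abundances; that
#' cross-covariance is part of the simulated biology and is reported, not
#' removed, so the exact variance decomposition is
#' `h2 + b2 + 2 cov(G, M) + (1 - r2) = Var(y)`.
#'
#' @param effects an `effect_set`.
#' @param g a [genotype_matrix()].
#' @param a_linked an [abundance_matrix()] (already linked for
#'   Recursive/Indirect scenarios).
#' @param config a [scenario_config()].
#' @return A `simulated_dataset` list with `y` (standardized), the linked
#'   abundances, `genetic_value_direct`, `microbiome_value`, `residual`,
#'   realized variance fractions (`realized_h2`, `realized_b2`,
#'   `realized_gb_cov`, `realized_resid`), `effects` and `config`.
#' @export
simulate_phenotype <- function(effects, g, a_linked, config) {
  stopifnot(inherits(effects, "effect_set"), inherits(config, "scenario_config"))
  n <- nrow(g$dosages)
  z <- .centered_dosage(g)
  x <- if (config$threshold_mode) {
    binarize_threshold(a_linked, effects, config$exceed_frac)
  } else {
    a_linked$logtss
  }
  G <- numeric(n); M <- numeric(n)
  if (config$h2 > 0 && length(effects$qtn_idx) > 0) {
    raw <- as.vector(z[, effects$qtn_idx, drop = FALSE] %*% effects$alpha)
    G <- sqrt(config$h2) * (raw - mean(raw)) / stats::sd(raw)
  }
  if (config$b2 > 0 && length(effects$otu_idx) > 0) {
    raw <- as.vector(x[, effects$otu_idx, drop = FALSE] %*% effects$omega)
    M <- sqrt(config$b2) * (raw - mean(raw)) / stats::sd(raw)
  }
  eps <- stats::rnorm(n)
  basis <- cbind(1, G, M)
  eps <- stats::lm.fit(basis, eps)$residuals
  eps <- sqrt(1 - config$r2) * eps / stats::sd(eps)
  y_raw <- G + M + eps
  vy <- stats::var(y_raw)
  ds <- structure(list(
    y = (y_raw - mean(y_raw)) / stats::sd(y_raw),
    abundances_linked = a_linked,
    genetic_value_direct = G,
    microbiome_value = M,
    residual = eps,
    realized_h2 = stats::var(G) / vy,
    realized_b2 = stats::var(M) / vy,
    realized_gb_cov = 2 * stats::cov(G, M) / vy,
    realized_resid = stats::var(eps) / vy,
    effects = effects,
    config = config
  ), class = "simulated_dataset")
  ds
}

#' One-call scenario simulation
#'
#' Runs [sample_effects()], [simulate_abundance_genetics()] (for scenarios
#' with heritable abundances) and [simulate_phenotype()] in sequence.
#'
#' @param config a [scenario_config()].
#' @param g a [genotype_matrix()].
#' @param a an [abundance_matrix()] with a `logtss` view.
#' @param clusters a `cluster_assignment`.
#' @param seed optional integer seed.
#' @return A `simulated_dataset`; for linked scenarios the element
#'   `genetic_values` holds the per-taxon genetic values used in the link.
#' @export
simulate_dataset <- function(config, g, a, clusters, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  eff <- sample_effects(config, g, a, clusters)
  gv <- NULL
  if (config$n_otu_g > 0) {
    lk <- simulate_abundance_genetics(eff, g, a, clusters)
    a <- lk$abundances
    eff <- lk$effects
    gv <- lk$genetic_values
  }
  ds <- simulate_phenotype(eff, g, a, config)
  ds$genetic_values <- gv
  ds
}
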