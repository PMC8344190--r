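#' Holdout predictive accuracy
#'
#' Masks a random 10% of phenotypes (the cross-validation protocol: fit on
#' the remaining 90%, predict the masked records) and returns the Pearson
#' correlation between observed and predicted phenotypes on the holdout.
#'
#' @param sim a `simulated_dataset`.
#' @param inputs an [analysis_inputs()] list (built from the same genotype
#'   matrix and the simulation's linked abundances).
#' @param model_tag analysis model tag, see [fit_model()].
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_settings()].
#' @param test_frac holdout fraction (default 0.10).
#' @param seed optional seed controlling the mask draw.
#' @return A `cv_result` list with `accuracy`, `test_idx`, `model_tag` and
#'   the underlying `fit`.
#' @export
cv_accuracy <- function(sim, inputs, model_tag, priors = prior_config(),
                        mcmc = mcmc_settings(), test_frac = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(sim$y)
  if (n < 20) stop("need at least 20 individuals for holdout validation")
  mask <- sort(sample.int(n, round(test_frac * n)))
  fit <- fit_model(sim$y, inputs, model_tag, priors, mcmc, mask)
  pred <- fit$yhat_test
  if (stats::sd(pred) == 0) {
    warning("zero variance in predictions; accuracy undefined")
    acc <- NA_real_
  } else {
    acc <- stats::cor(sim$y[mask], pred)
  }
  structure(list(accuracy = acc, test_idx = mask, model_tag = model_tag,
                 fit = fit),
            class = "cv_result")
}

#' Variance-component bias table
#'
#' Summarizes posterior-mean heritability and microbiability across
#' replicate fits against the simulated targets.
#'
#' @param fits list of `fit_result` objects (replicates of one scenario and
#'   model).
#' @param config the [scenario_config()] that generated the data.
#' @return A data.frame with one row per parameter: simulated value, mean
#'   estimate, absolute and relative bias (relative bias is `NA` when the
#'   simulated value is zero; the absolute column is then the quantity to
#'   read).
#' @export
vc_bias <- function(fits, config) {
  if (length(fits) < 2) stop("need at least 2 replicate fits")
  grab <- function(el) vapply(fits, function(f)
    if (is.null(f[[el]])) NA_real_ else f[[el]]["mean"], numeric(1))
  est <- list(h2 = grab("h2_post"), b2 = grab("b2_post"))
  target <- c(h2 = config$h2, b2 = config$b2)
  do.call(rbind, lapply(names(est), function(nm) {
    m <- mean(est[[nm]])
    data.frame(parameter = nm, simulated = target[[nm]], mean_estimate = m,
               bias = m - target[[nm]],
               rel_bias = if (target[[nm]] > 0) (m - target[[nm]]) / target[[nm]] else NA_real_,
               n_replicates = length(fits))
  }))
}

# vectorized per-pair simple-regression p-values via correlations
.cor_pvals <- function(A, B) {
  n <- nrow(A)
  r <- stats::cor(A, B)
  r <- pmin(pmax(r, -1 + 1e-15), 1 - 1e-15)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(tt), df = n - 2)
}

#' GWAS of genetically controlled abundances
#'
#' Regresses each controlled taxon's log abundance on each SNP (simple
#' linear regression; two-sided t-test p-values) and evaluates the fraction
#' of true abundance QTNs that pass the 5% empirical significance threshold
#' derived from the neutral-SNP p-value distribution. Monomorphic SNPs get
#' p = 1 with a warning.
#'
#' @param a_linked linked [abundance_matrix()] from a Recursive/Indirect
#'   simulation.
#' @param g a [genotype_matrix()].
#' @param effects the simulation's `effect_set`.
#' @param neutral_quantile quantile of the neutral p-values used as the
#'   empirical threshold (default 0.05).
#' @return An `association_scan` list: `pvalues` (SNPs x controlled taxa),
#'   `neutral_mask`, `empirical_threshold`, and `causative_hit_rate` (the
#'   fraction of causative QTN pairs more significant than the threshold).
#' @export
gwas_abundances <- function(a_linked, g, effects, neutral_quantile = 0.05) {
  if (length(effects$otu_g_idx) == 0) {
    stop("no genetically controlled taxa; GWAS of abundances needs Recursive/Indirect data")
  }
  d <- g$dosages
  v <- apply(d, 2L, stats::var)
  mono <- v == 0
  if (any(mono)) warning(sum(mono), " monomorphic SNP(s); their p-values set to 1")
  X <- a_linked$logtss[, effects$otu_g_idx, drop = FALSE]
  P <- matrix(1, ncol(d), ncol(X),
              dimnames = list(g$snp_ids, as.character(effects$otu_g_idx)))
  P[!mono, ] <- .cor_pvals(d[, !mono, drop = FALSE], X)
  causative_snps <- unique(unlist(lapply(effects$beta, `[[`, "qtn")))
  neutral_mask <- !(seq_len(ncol(d)) %in% causative_snps)
  thr <- stats::quantile(P[neutral_mask, ], neutral_quantile, names = FALSE)
  hits <- vapply(seq_along(effects$beta), function(i) {
    P[effects$beta[[i]]$qtn, i] <= thr
  }, logical(length(effects$beta[[1]]$qtn)))
  structure(list(pvalues = P, neutral_mask = neutral_mask,
                 empirical_threshold = thr,
                 causative_hit_rate = mean(hits)),
            class = "association_scan")
}

#' Microbiome-wide association power
#'
#' Regresses the phenotype on each taxon's log abundance and computes power
#' as the fraction of true causative taxa among the top 5% (smallest
#' p-values; ties broken by stable order).
#'
#' @param sim a `simulated_dataset` with `b2 > 0`.
#' @param top_frac fraction of taxa declared significant (default 0.05).
#' @return A list with `power`, `pvalues` and `top_idx`.
#' @export
mwas_power <- function(sim, top_frac = 0.05) {
  if (sim$config$b2 <= 0) stop("MWAS power needs a scenario with b2 > 0")
  X <- sim$abundances_linked$logtss
  v <- apply(X, 2L, stats::var)
  p <- rep(1, ncol(X))
  p[v > 0] <- as.vector(.cor_pvals(X[, v > 0, drop = FALSE],
                                   matrix(sim$y, ncol = 1)))
  m <- ceiling(top_frac * ncol(X))
  top <- order(p)[seq_len(m)]
  list(power = length(intersect(top, sim$effects$otu_idx)) /
         length(sim$effects$otu_idx),
       pvalues = p, top_idx = top)
}

#' Recovery of causative taxa from Bayes C inclusion frequencies
#'
#' @param fit a Bayes C `fit_result` with a taxon block.
#' @param effects the simulation's `effect_set`.
#' @param top_frac fraction of top-ranked taxa considered (default 0.05).
#' @return A list: `mean_inclusion` (average inclusion probability over
#'   causative taxa), `top_recovery` (fraction of causative taxa inside the
#'   top `top_frac` by inclusion frequency).
#' @export
inclusion_recovery <- function(fit, effects, top_frac = 0.05) {
  if (is.null(fit$inclusion_prob) || !"b" %in% names(fit$inclusion_prob)) {
    stop("fit is not a Bayes C fit with a taxon block")
  }
  incl <- fit$inclusion_prob$b
  caus <- effects$otu_idx
  m <- ceiling(top_frac * length(incl))
  top <- order(incl, decreasing = TRUE)[seq_len(m)]
  list(mean_inclusion = mean(incl[caus]),
       top_recovery = length(intersect(top, caus)) / length(caus))
}

#' Per-taxon abundance heritability spectrum
#'
#' Fits a single-kernel RKHS (GBLUP) model with weakly informative variance
#' priors to each requested taxon's log abundance and returns the posterior
#' mean heritability. The genomic kernel is eigendecomposed once and shared
#' across taxa.
#'
#' @param a_linked linked [abundance_matrix()].
#' @param g a [genotype_matrix()].
#' @param taxa taxon column indices to fit (default: all; fitting all taxa
#'   of a large table is expensive - pass a subset).
#' @param mcmc an [mcmc_settings()].
#' @param priors a [prior_config()]; forced to weakly informative.
#' @return A data.frame with `taxon` and `h2_hat`.
#' @export
abundance_h2_spectrum <- function(a_linked, g, taxa = NULL,
                                  mcmc = mcmc_settings(5000, 500, 5),
                                  priors = prior_config(weakly_informative = TRUE)) {
  priors$weakly_informative <- TRUE
  if (is.null(taxa)) taxa <- seq_len(ncol(a_linked$logtss))
  Z <- analysis_inputs(g, a_linked)$Z
  Kg <- build_kernels(Z = Z)$G
  eig <- .kernel_eigen(Kg)
  h2 <- vapply(taxa, function(j) {
    x <- a_linked$logtss[, j]
    if (stats::var(x) == 0) return(NA_real_)
    x <- (x - mean(x)) / stats::sd(x)
    res <- .rkhs_gibbs(x, list(G = eig), priors, mcmc)
    mean(res$share_trace[, 1])
  }, numeric(1))
  data.frame(taxon = taxa, h2_hat = h2)
}
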