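#' MCMC settings
#'
#' Chain length defaults follow the analysis protocol of the package's
#' experiment layer: 50,000 iterations with 500 burn-in and thinning every
#' 5 (9900 kept samples). Tests and the scaled-down experiments use
#' `mcmc_settings(5000, 500, 5)`.
#'
#' @param iters total iterations.
#' @param burnin burn-in iterations (`< iters`).
#' @param thin thinning interval.
#' @return An `mcmc_settings` list with an extra `kept` element.
#' @export
mcmc_settings <- function(iters = 50000, burnin = 500, thin = 5) {
  stopifnot(iters >= 1, thin >= 1, burnin >= 0)
  if (burnin >= iters) stop("burnin must be smaller than iters")
  structure(list(iters = as.integer(iters), burnin = as.integer(burnin),
                 thin = as.integer(thin),
                 kept = (as.integer(iters) - as.integer(burnin)) %/% as.integer(thin)),
            class = "mcmc_settings")
}

#' Prior configuration for the Gibbs samplers
#'
#' Bayes C inclusion priors: `pi ~ Beta(a, b)` with `a = pi0 * p0`,
#' `b = (1 - pi0) * p0`, i.e. mean `pi0` and variance
#' `pi0 (1 - pi0) / (p0 + 1)`. The default (`pi0 = 0.001`, `p0 = 5`) is a
#' sparse prior; `alt_flat = TRUE` switches to the more liberal
#' (`pi0 = 0.01`, `p0 = 2`). Variance components (slab, kernel and residual)
#' get scaled-inverse-chi-square priors with `df = 5` and scales set so the
#' prior mode matches an equal split of a prior R2 of 0.5 across fitted
#' components; `weakly_informative = TRUE` uses `df = 3` with a near-zero
#' scale to mimic a REML-like estimator (used for per-taxon abundance
#' heritability).
#'
#' @param pi0 prior expected inclusion probability.
#' @param p0 prior counts of the Beta prior.
#' @param alt_flat use the liberal flat prior (`p0 = 2`, `pi0 = 0.01`).
#' @param df prior degrees of freedom for variance components.
#' @param prior_r2 prior fraction of variance explained by all fitted
#'   components jointly.
#' @param weakly_informative near-flat variance priors (`df = 3`, tiny
#'   scale).
#' @return A `prior_config` list.
#' @export
prior_config <- function(pi0 = 0.001, p0 = 5, alt_flat = FALSE,
                         df = 5, prior_r2 = 0.5, weakly_informative = FALSE) {
  if (alt_flat) { pi0 <- 0.01; p0 <- 2 }
  stopifnot(pi0 > 0, pi0 < 1, p0 > 0, prior_r2 > 0, prior_r2 < 1)
  if (weakly_informative) df <- 3
  structure(list(pi0 = pi0, p0 = p0, df = df, prior_r2 = prior_r2,
                 weakly_informative = weakly_informative),
            class = "prior_config")
}

#' Genomic, microbiome and interaction kernels
#'
#' Builds similarity matrices from standardized feature matrices:
#' `G = Z Z' / p` (SNPs), `B = W W' / n_b` (log abundances), each divided by
#' its feature count so the average diagonal is about 1, and the Hadamard
#' interaction kernel `GxB = G * B` (elementwise), the analogue of the
#' additive-by-additive epistatic covariance structure.
#'
#' @param Z,W standardized feature matrices (individuals in rows); either
#'   may be `NULL` if unused.
#' @return A `kernel_set` list with elements `G`, `B`, `GxB` (those that can
#'   be formed).
#' @export
build_kernels <- function(Z = NULL, W = NULL) {
  out <- list()
  if (!is.null(Z)) out$G <- tcrossprod(Z) / ncol(Z)
  if (!is.null(W)) out$B <- tcrossprod(W) / ncol(W)
  if (!is.null(out$G) && !is.null(out$B)) out$GxB <- out$G * out$B
  structure(out, class = "kernel_set")
}

# eigendecomposition of a kernel, dropping near-null dimensions
.kernel_eigen <- function(K, tol = 1e-8) {
  K <- K + diag(1e-8, nrow(K))
  ee <- eigen(K, symmetric = TRUE)
  if (min(ee$values) < -1e-6 * max(ee$values)) {
    stop("kernel is not positive semi-definite")
  }
  keep <- ee$values > tol * max(ee$values)
  list(U = ee$vectors[, keep, drop = FALSE], d = ee$values[keep])
}

# scaled-inv-chi-square scale with prior mode at `target`
.sichisq_scale <- function(target, df) target * (df + 2) / df

#' Fit a multi-kernel Bayesian RKHS (GBLUP) model
#'
#' Gibbs sampler for `y = mu + sum_c u_c + e` with `u_c ~ N(0, sigma2_c K_c)`
#' for each selected kernel and `e ~ N(0, sigma2_e I)`. Each kernel is
#' eigendecomposed once and its effects are block-updated in the eigenbasis.
#' Masked phenotypes are imputed by data augmentation each iteration;
#' predictions are posterior means of the linear predictor (excluding the
#' residual). Per kept iteration the sampler records
#' `Var(u_c) / Var(y)` for each component - the heritability,
#' microbiability, and interaction-share draws.
#'
#' @param y phenotype vector.
#' @param kernels a [build_kernels()] `kernel_set`.
#' @param which kernels to fit, subset of `c("G", "B", "GxB")` (model menu
#'   Rgbx = all three, Rgb = G+B, Rg = G, Rb = B).
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_settings()].
#' @param mask indices of phenotypes to hold out (treated as missing).
#' @param fixed_variances optional named list
#'   `list(components = c(...), residual = ...)` freezing all variance
#'   components (no variance updates); used for validation against the
#'   closed-form mixed-model solution.
#' @return A `fit_result`.
#' @export
fit_rkhs <- function(y, kernels, which = c("G", "B"),
                     priors = prior_config(), mcmc = mcmc_settings(),
                     mask = NULL, fixed_variances = NULL) {
  stopifnot(inherits(kernels, "kernel_set"))
  missing_k <- setdiff(which, names(kernels))
  if (length(missing_k)) stop("kernel(s) not available: ", paste(missing_k, collapse = ", "))
  if (length(which) < 1) stop("select at least one kernel")
  eigs <- lapply(kernels[which], .kernel_eigen)
  res <- .rkhs_gibbs(y, eigs, priors, mcmc, mask, fixed_variances)
  shares <- res$share_trace
  colnames(shares) <- which
  post <- function(nm) {
    if (!nm %in% colnames(shares)) return(NULL)
    c(mean = mean(shares[, nm]), sd = stats::sd(shares[, nm]))
  }
  structure(list(
    method = "rkhs", which = which,
    h2_post = post("G"), b2_post = post("B"), ixn_post = post("GxB"),
    abscov_post = NULL, inclusion_prob = NULL,
    yhat = res$yhat, yhat_test = if (length(mask)) res$yhat[mask] else NULL,
    mask = mask,
    chain_summaries = data.frame(shares, sigma2_e = res$sigma2_e_trace,
                                 check.names = FALSE),
    u_post = res$u_post, mu_post = res$mu_post,
    mcmc = mcmc, priors = priors
  ), class = "fit_result")
}

# core RKHS sampler on precomputed eigendecompositions
.rkhs_gibbs <- function(y, eigs, priors, mcmc, mask = NULL,
                        fixed_variances = NULL) {
  n <- length(y)
  nc <- length(eigs)
  if (!is.null(mask) && length(mask) >= n) stop("mask covers all individuals")
  miss <- if (is.null(mask)) integer(0) else as.integer(mask)
  obs <- setdiff(seq_len(n), miss)
  var_y_ref <- stats::var(y[obs])
  y[miss] <- mean(y[obs])

  fixed <- !is.null(fixed_variances)
  if (priors$weakly_informative) {
    S_c <- rep(1e-4, nc); S_e <- 1e-4
  } else {
    S_c <- rep(.sichisq_scale(var_y_ref * priors$prior_r2 / nc, priors$df), nc)
    S_e <- .sichisq_scale(var_y_ref * (1 - priors$prior_r2), priors$df)
  }
  sigma2_c <- if (fixed) fixed_variances$components else
    rep(var_y_ref * priors$prior_r2 / nc, nc)
  sigma2_e <- if (fixed) fixed_variances$residual else
    var_y_ref * (1 - priors$prior_r2)

  delta <- lapply(eigs, function(e) numeric(length(e$d)))
  u <- matrix(0, n, nc)
  mu <- mean(y)

  nkeep <- mcmc$kept
  share_tr <- matrix(0, nkeep, nc)
  s2e_tr <- numeric(nkeep)
  yhat_sum <- numeric(n)
  u_sum <- matrix(0, n, nc)
  mu_sum <- 0
  kept <- 0L

  for (it in seq_len(mcmc$iters)) {
    r <- y - rowSums(u)
    mu <- mean(r) + stats::rnorm(1) * sqrt(sigma2_e / n)
    for (cdx in seq_len(nc)) {
      ee <- eigs[[cdx]]
      ytil <- y - mu - rowSums(u[, -cdx, drop = FALSE])
      rj <- crossprod(ee$U, ytil)[, 1L]
      prec <- 1 / sigma2_e + 1 / (sigma2_c[cdx] * ee$d)
      m <- (rj / sigma2_e) / prec
      delta[[cdx]] <- m + stats::rnorm(length(m)) / sqrt(prec)
      u[, cdx] <- ee$U %*% delta[[cdx]]
      if (!fixed) {
        ss <- sum(delta[[cdx]]^2 / ee$d)
        sigma2_c[cdx] <- (ss + priors$df * S_c[cdx]) /
          stats::rchisq(1, priors$df + length(ee$d))
      }
    }
    e <- y - mu - rowSums(u)
    if (!fixed) {
      sigma2_e <- (sum(e^2) + priors$df * S_e) /
        stats::rchisq(1, priors$df + n)
    }
    if (!is.finite(sigma2_e) || sigma2_e <= 0) {
      stop("non-finite residual variance in RKHS chain")
    }
    if (length(miss)) {
      fitted <- mu + rowSums(u[miss, , drop = FALSE])
      y[miss] <- fitted + stats::rnorm(length(miss)) * sqrt(sigma2_e)
    }
    if (it > mcmc$burnin && (it - mcmc$burnin) %% mcmc$thin == 0) {
      kept <- kept + 1L
      share_tr[kept, ] <- apply(u, 2L, stats::var) / var_y_ref
      s2e_tr[kept] <- sigma2_e
      yhat_sum <- yhat_sum + mu + rowSums(u)
      u_sum <- u_sum + u
      mu_sum <- mu_sum + mu
    }
  }
  list(share_trace = share_tr[seq_len(kept), , drop = FALSE],
       sigma2_e_trace = s2e_tr[seq_len(kept)],
       yhat = yhat_sum / kept, u_post = u_sum / kept, mu_post = mu_sum / kept)
}

#' Fit a Bayes C spike-slab regression
#'
#' Gibbs sampler for `y = mu + Z g + W b + e` in which each feature's effect
#' is zero with probability `1 - pi` and drawn from a normal slab otherwise.
#' The SNP block and the taxon block keep separate inclusion probabilities
#' and slab variances, so the heritability/microbiability split is not
#' confounded by pooling. Per kept iteration the sampler records
#' `Var(Z g)/Var(y)` and `Var(W b)/Var(y)` (the heritability and
#' microbiability draws), the absolute covariance share
#' `|cov(Z g, W b)|/Var(y)`, and each feature's inclusion indicator.
#'
#' @param y phenotype vector.
#' @param Z standardized genotype matrix (or `NULL` for microbiome-only
#'   models).
#' @param W standardized log-abundance matrix (or `NULL` for genome-only
#'   models).
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_settings()].
#' @param mask indices of phenotypes to hold out.
#' @return A `fit_result` with posterior summaries `h2_post`, `b2_post`,
#'   `abscov_post`, per-feature `inclusion_prob` (`$g` for SNPs, `$b` for
#'   taxa), `yhat_test` predictions and thinned `chain_summaries`.
#' @export
fit_bayesc <- function(y, Z = NULL, W = NULL, priors = prior_config(),
                       mcmc = mcmc_settings(), mask = NULL) {
  blocks <- list()
  labels <- character(0)
  if (!is.null(Z)) { blocks <- c(blocks, list(Z)); labels <- c(labels, "g") }
  if (!is.null(W)) { blocks <- c(blocks, list(W)); labels <- c(labels, "b") }
  if (!length(blocks)) stop("provide at least one of Z, W")
  n <- length(y)
  if (!is.null(mask) && length(mask) >= n) stop("mask covers all individuals")
  miss <- if (is.null(mask)) integer(0) else as.integer(mask)
  obs <- setdiff(seq_len(n), miss)
  var_y_ref <- stats::var(y[obs])
  y0 <- y
  y0[miss] <- mean(y[obs])

  nb <- length(blocks)
  r2c <- priors$prior_r2 / nb
  S_b <- vapply(blocks, function(X) {
    .sichisq_scale(var_y_ref * r2c / (priors$pi0 * ncol(X)), priors$df)
  }, numeric(1))
  S_e <- .sichisq_scale(var_y_ref * (1 - priors$prior_r2), priors$df)

  res <- .bayesc_gibbs(y0, miss_idx = miss - 1L, blocks = blocks,
                       pi0 = rep(priors$pi0, nb), p0 = rep(priors$p0, nb),
                       df_b = priors$df, S_b = S_b,
                       df_e = priors$df, S_e = S_e, var_y_ref = var_y_ref,
                       niter = mcmc$iters, burnin = mcmc$burnin,
                       thin = mcmc$thin)
  shares <- res$share_trace
  colnames(shares) <- labels
  incl <- stats::setNames(lapply(res$inclusion, as.vector), labels)
  post <- function(nm) {
    if (!nm %in% labels) return(NULL)
    c(mean = mean(shares[, nm]), sd = stats::sd(shares[, nm]))
  }
  structure(list(
    method = "bayesc", which = labels,
    h2_post = post("g"), b2_post = post("b"), ixn_post = NULL,
    abscov_post = if (nb == 2) c(mean = mean(res$abscov_trace),
                                 sd = stats::sd(res$abscov_trace)) else NULL,
    inclusion_prob = incl,
    yhat = res$yhat, yhat_test = if (length(miss)) res$yhat[miss] else NULL,
    mask = mask,
    chain_summaries = data.frame(shares, sigma2_e = res$sigma2_e_trace,
                                 check.names = FALSE),
    mcmc = mcmc, priors = priors
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result (%s, components: %s)\n", x$method,
              paste(x$which, collapse = "+")))
  fmt <- function(nm, v) if (!is.null(v))
    cat(sprintf("  %-8s %.3f (sd %.3f)\n", nm, v["mean"], v["sd"]))
  fmt("h2", x$h2_post); fmt("b2", x$b2_post); fmt("g x b", x$ixn_post)
  fmt("|cov|", x$abscov_post)
  invisible(x)
}

#' Analysis inputs from raw data
#'
#' Standardizes the genotype and log-abundance matrices (mean 0, SD 1 per
#' column; monomorphic SNPs dropped with a message) and builds the kernels.
#' Precomputing this once lets many model fits share the same inputs.
#'
#' @param g a [genotype_matrix()].
#' @param a an [abundance_matrix()] with a `logtss` view.
#' @return A list with `Z`, `W`, and `kernels`.
#' @export
analysis_inputs <- function(g, a) {
  d <- g$dosages
  v <- apply(d, 2L, stats::var)
  if (any(v == 0)) {
    message(sum(v == 0), " monomorphic SNP(s) dropped before standardization")
    d <- d[, v > 0, drop = FALSE]
  }
  Z <- standardize_columns(d)
  w <- a$logtss
  vw <- apply(w, 2L, stats::var)
  if (any(vw == 0)) {
    message(sum(vw == 0), " constant taxa dropped before standardization")
    w <- w[, vw > 0, drop = FALSE]
  }
  W <- standardize_columns(w)
  list(Z = Z, W = W, kernels = build_kernels(Z, W))
}

#' Fit a model by menu tag
#'
#' Dispatch over the seven-model analysis menu: RKHS models `Rgbx`
#' (G + B + interaction), `Rgb`, `Rg`, `Rb`, and Bayes C models `Cgb`,
#' `Cg`, `Cb`.
#'
#' @param y phenotype vector.
#' @param inputs an [analysis_inputs()] list.
#' @param model_tag one of `"Rgbx"`, `"Rgb"`, `"Rg"`, `"Rb"`, `"Cgb"`,
#'   `"Cg"`, `"Cb"`.
#' @param priors a [prior_config()].
#' @param mcmc an [mcmc_settings()].
#' @param mask holdout indices.
#' @return A `fit_result`.
#' @export
fit_model <- function(y, inputs, model_tag, priors = prior_config(),
                      mcmc = mcmc_settings(), mask = NULL) {
  switch(model_tag,
    Rgbx = fit_rkhs(y, inputs$kernels, c("G", "B", "GxB"), priors, mcmc, mask),
    Rgb  = fit_rkhs(y, inputs$kernels, c("G", "B"), priors, mcmc, mask),
    Rg   = fit_rkhs(y, inputs$kernels, "G", priors, mcmc, mask),
    Rb   = fit_rkhs(y, inputs$kernels, "B", priors, mcmc, mask),
    Cgb  = fit_bayesc(y, inputs$Z, inputs$W, priors, mcmc, mask),
    Cg   = fit_bayesc(y, inputs$Z, NULL, priors, mcmc, mask),
    Cb   = fit_bayesc(y, NULL, inputs$W, priors, mcmc, mask),
    stop("unknown model tag: ", model_tag)
  )
}
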