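#' Validate and normalize a scenario-grid configuration
#'
#' Reads a YAML configuration describing a simulation/analysis grid and
#' returns normalized components. Scenario blocks use the grid-table column
#' names (`N_QTN`, `N_OTU`, `N_OTU_g`, `r2`, `h2`, `b2`); consistency rules
#' (`h2 + b2 = r2`, scenario-specific zeroing) are enforced with messages
#' naming the offending field.
#'
#' @param config a file path to a YAML config, or an equivalent list.
#' @return A list with `fixture` (a [fixture_spec()]), `scenarios` (list of
#'   [scenario_config()]), `models`, `replicates`, `clusters_K`, `mcmc` and
#'   `seed`.
#' @export
validate_config <- function(config) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$scenarios) || !length(cfg$scenarios)) {
    stop("config field 'scenarios' is missing or empty")
  }
  fx <- do.call(fixture_spec, as.list(cfg$fixture %||% list()))
  scenarios <- lapply(seq_along(cfg$scenarios), function(i) {
    s <- cfg$scenarios[[i]]
    if (is.null(s$scenario)) stop("scenarios[", i, "]: field 'scenario' is required")
    args <- list(scenario = s$scenario)
    map <- c(N_QTN = "n_qtn", N_OTU = "n_otu", N_OTU_g = "n_otu_g",
             r2 = "r2", h2 = "h2", b2 = "b2", N_QTN_per_OTU = "n_qtn_per_otu",
             threshold_mode = "threshold_mode", exceed_frac = "exceed_frac")
    for (nm in names(map)) if (!is.null(s[[nm]])) args[[map[[nm]]]] <- s[[nm]]
    tryCatch(do.call(scenario_config, args),
             error = function(e) stop("scenarios[", i, "] (", s$scenario, "): ",
                                      conditionMessage(e), call. = FALSE))
  })
  models <- cfg$models %||% c("Rgb", "Cgb")
  bad <- setdiff(models, c("Rgbx", "Rgb", "Rg", "Rb", "Cgb", "Cg", "Cb"))
  if (length(bad)) stop("config field 'models': unknown tag(s) ", paste(bad, collapse = ", "))
  mc <- cfg$mcmc %||% list()
  mcmc <- mcmc_settings(mc$iters %||% 5000, mc$burnin %||% 500, mc$thin %||% 5)
  list(fixture = fx, scenarios = scenarios, models = models,
       replicates = as.integer(cfg$replicates %||% 2L),
       clusters_K = as.integer(cfg$clusters_K %||% fx$n_clusters),
       mcmc = mcmc, seed = as.integer(cfg$seed %||% 1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run a scenario-by-model grid
#'
#' Generates (or loads) the input data, then executes every scenario x
#' model x replicate cell: simulate a phenotype, hold out 10% of records,
#' fit the model, and record holdout accuracy plus posterior variance
#' shares. Results are written as a tidy TSV
#' (`scenario, model_tag, replicate, metric, value`) together with a JSON
#' manifest recording every seed. A failed cell is logged and the remaining
#' cells continue.
#'
#' @param config a file path or list, see [validate_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the results data.frame.
#' @export
run_scenario_grid <- function(config, out_dir) {
  cfg <- validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  set.seed(cfg$seed)
  g <- gen_genotypes(cfg$fixture)
  a <- tss_log_transform(gen_abundances(cfg$fixture))
  clusters <- cluster_taxa(a, K = cfg$clusters_K)
  inputs0 <- analysis_inputs(g, a)
  rows <- list()
  errors <- character(0)
  for (si in seq_along(cfg$scenarios)) {
    sc <- cfg$scenarios[[si]]
    for (rep in seq_len(cfg$replicates)) {
      cell_seed <- cfg$seed + 1000L * si + rep
      res <- tryCatch({
        sim <- simulate_dataset(sc, g, a, clusters, seed = cell_seed)
        inputs <- if (sc$n_otu_g > 0) {
          analysis_inputs(g, sim$abundances_linked)
        } else inputs0
        out <- list()
        for (tag in cfg$models) {
          cv <- cv_accuracy(sim, inputs, tag, mcmc = cfg$mcmc,
                            seed = cell_seed)
          add <- function(metric, value) {
            data.frame(scenario = sc$scenario, model_tag = tag,
                       replicate = rep, metric = metric, value = value)
          }
          out[[tag]] <- rbind(
            add("accuracy", cv$accuracy),
            if (!is.null(cv$fit$h2_post)) add("h2_hat", cv$fit$h2_post[["mean"]]),
            if (!is.null(cv$fit$b2_post)) add("b2_hat", cv$fit$b2_post[["mean"]]),
            add("realized_h2", sim$realized_h2),
            add("realized_b2", sim$realized_b2))
        }
        do.call(rbind, out)
      }, error = function(e) {
        errors <<- c(errors, sprintf("%s rep %d: %s", sc$scenario, rep,
                                     conditionMessage(e)))
        NULL
      })
      if (!is.null(res)) rows[[length(rows) + 1L]] <- res
    }
  }
  results <- do.call(rbind, rows)
  utils::write.table(results, file.path(out_dir, "results.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(
    seed = cfg$seed,
    cell_seeds = lapply(seq_along(cfg$scenarios), function(si)
      cfg$seed + 1000L * si + seq_len(cfg$replicates)),
    models = cfg$models,
    mcmc = unclass(cfg$mcmc)[c("iters", "burnin", "thin")],
    fixture = unclass(cfg$fixture),
    errors = errors,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(errors)) {
    writeLines(errors, file.path(out_dir, "errors.log"))
  }
  invisible(results)
}
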