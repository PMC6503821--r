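#' Run the full ABC analysis pipeline from a configuration
#'
#' Configuration-driven orchestration of every stage: read VCF + popmap,
#' filter loci, subsample to a complete matrix, compute observed statistics,
#' build (or resume) per-model reference tables, run model selection with
#' both classifiers at the configured tolerances, estimate parameters for
#' supported models, cross-validate, and run posterior predictive checks.
#' Every output lands under `outdir` together with a provenance manifest
#' (config, seeds, package version) from which the run can be reproduced.
#'
#' Config keys (YAML file or list): `analysis`, `vcf`, `popmap`,
#' `model_set` (path to a model-set YAML), `n_reps` (per model), `n_loci`
#' (`NULL` = match the observed panel), `subsample_fraction` (default 0.8),
#' `min_callrate` (default 0.8), `min_pops` (default: all populations),
#' `select_tolerances` (default `c(0.005, 0.001)`), `estimate_tolerances`
#' (default `c(0.01, 0.05)`), `support_threshold` (default 0.25; models at
#' or above it get parameter estimation), `cv_pods` (default 0 = skip),
#' `ppc_sims` (default 0 = skip), `seed`, `outdir`.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @return Invisibly, a result bundle of class `abc_run`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("pipeline stage 'config': file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(
    list(analysis = "analysis", subsample_fraction = 0.8, min_callrate = 0.8,
         min_pops = NULL, n_loci = NULL,
         select_tolerances = c(0.005, 0.001),
         estimate_tolerances = c(0.01, 0.05),
         support_threshold = 0.25, cv_pods = 0L, ppc_sims = 0L,
         n_trees = 1000L, seed = 1L, outdir = tempfile("abc_run_")),
    config)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", cfg$analysis, "] stage: ", name)
    tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           "\n  (fix the cause and rerun; finished reference-table chunks",
           " under outdir are reused)", call. = FALSE))
  }

  set.seed(cfg$seed)
  for (key in c("vcf", "popmap", "model_set"))
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
      stop("pipeline stage 'inputs' failed: missing ", key, " file")

  ds <- stage("read", read_genotypes(cfg$vcf, cfg$popmap))
  min_pops <- if (is.null(cfg$min_pops)) length(populations(ds)) else cfg$min_pops
  ds_f <- stage("filter", filter_loci(ds, cfg$min_callrate, min_pops))
  pm <- population_map(ds_f, fraction = cfg$subsample_fraction)
  ds_c <- stage("subsample", subsample_complete(ds_f, pm))
  ms <- stage("models", load_model_set(cfg$model_set))
  pop_order <- names(ms$models[[1L]]$sampling)
  observed <- stage("observed_stats", build_stat_vector(ds_c, pop_order))
  write_stat_vector(observed, file.path(cfg$outdir, "observed_stats.tsv"))

  n_loci <- if (is.null(cfg$n_loci)) nrow(ds_c$genotypes) else cfg$n_loci
  table_seeds <- sample.int(.Machine$integer.max - 1L, length(ms$models))
  tables <- stage("reference_tables", {
    lapply(seq_along(ms$models), function(k) {
      base <- file.path(cfg$outdir, paste0("reftable_", names(ms$models)[k]))
      if (file.exists(paste0(base, ".tsv"))) return(read_reference_table(base))
      rt <- build_reference_table(ms$models[[k]], cfg$n_reps, n_loci,
                                  seed = table_seeds[k])
      write_reference_table(rt, base)
      rt
    })
  })

  selection <- stage("model_selection", {
    out <- list()
    for (tol in cfg$select_tolerances)
      out[[paste0("neural_net_tol", tol)]] <-
        nn_model_posterior(tables, observed, tolerance = tol)
    out$random_forest <- rf_model_posterior(
      tables, observed, n_trees = cfg$n_trees,
      seed = sample.int(.Machine$integer.max - 1L, 1L))
    out
  })
  support <- colMeans(do.call(rbind, lapply(selection, `[[`, "posterior_prob")))
  supported <- names(support)[support >= cfg$support_threshold]
  if (!length(supported)) supported <- names(which.max(support))

  estimates <- stage("parameter_estimation", {
    out <- list()
    for (m in supported)
      for (tol in cfg$estimate_tolerances) {
        tab <- tables[[which(names(ms$models) == m)]]
        post <- nn_adjust_params(tab, observed, tolerance = tol)
        out[[paste0(m, "_tol", tol)]] <- post
      }
    out
  })

  cv <- NULL
  if (cfg$cv_pods > 0L)
    cv <- stage("cross_validation",
                cv_model_selection(tables, n_pods_per_model = cfg$cv_pods,
                                   method = "rejection",
                                   tolerance = min(cfg$select_tolerances) * 5))
  ppc <- NULL
  if (cfg$ppc_sims > 0L)
    ppc <- stage("posterior_predictive", {
      m <- supported[1L]
      posterior_predictive(ms$models[[m]],
                           estimates[[paste0(m, "_tol", min(cfg$estimate_tolerances))]],
                           observed, n_sims = cfg$ppc_sims, n_loci = n_loci)
    })

  summaries <- lapply(estimates, function(p)
    apply(posterior_summary(p), 1L, function(r)
      sprintf("median %.4g, 95%% HDI %.4g-%.4g", r[1L], r[2L], r[3L])))
  manifest <- list(
    analysis = cfg$analysis,
    package_version = as.character(utils::packageVersion("invabc")),
    config = cfg[setdiff(names(cfg), "outdir")],
    table_seeds = as.integer(table_seeds),
    n_loci_simulated = n_loci,
    observed_panel = nrow(ds_c$genotypes),
    supported_models = supported,
    model_posteriors = lapply(selection, function(s) as.list(s$posterior_prob)),
    rf_oob_error = selection$random_forest$oob_error,
    parameter_summaries = summaries)
  yaml::write_yaml(manifest, file.path(cfg$outdir, "manifest.yaml"))

  invisible(structure(list(config = cfg, observed = observed, tables = tables,
                           selection = selection, estimates = estimates,
                           cv = cv, ppc = ppc, manifest = manifest),
                      class = "abc_run"))
}

#' @export
print.abc_run <- function(x, ...) {
  cat("abc_run:", x$config$analysis, "\n")
  cat("  supported models:",
      paste(x$manifest$supported_models, collapse = ", "), "\n")
  for (nm in names(x$selection)) {
    cat("  ", nm, ": ", sep = "")
    pp <- x$selection[[nm]]$posterior_prob
    best <- which.max(pp)
    cat(sprintf("best %s (Pr = %.3f)\n", names(pp)[best], pp[best]))
  }
  invisible(x)
}
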