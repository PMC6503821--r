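#' Leave-one-out cross-validation of ABC model selection
#'
#' Rows of the reference tables serve as pseudo-observed datasets (PODS):
#' each sampled POD is classified by the chosen method against the reference
#' table with its own row excluded, giving a confusion matrix and per-model
#' misclassification rates.  An optional `grouping` map (model -> shared
#' colonization process) attributes each model's misclassification to models
#' representing the same process versus a different one, the pattern
#' characteristic of scenario sets that share a route but differ in source.
#'
#' The `"randomforest"` method uses a single forest and classifies each POD
#' with the trees for which that row was out of bag, the standard
#' forest-internal estimate; `"rejection"` and `"neuralnet"` redo the
#' accept/classify step per POD.
#'
#' @param tables list of `ref_table`s, one per candidate model.
#' @param n_pods_per_model PODS sampled per model (default 100).
#' @param method `"rejection"`, `"neuralnet"` or `"randomforest"`.
#' @param tolerance accepted fraction (rejection/neuralnet).
#' @param grouping optional named character vector: model -> process label.
#' @param n_trees forest size for `"randomforest"`.
#' @param ... passed to [nn_model_posterior()] for `"neuralnet"`.
#' @return Object of class `abc_cv`: `confusion` (models x models counts),
#'   `misclassification` per model, and `attribution` (same-process vs
#'   other-process misclassified fractions) when `grouping` is given.
#' @export
cv_model_selection <- function(tables, n_pods_per_model = 100L,
                               method = c("rejection", "neuralnet", "randomforest"),
                               tolerance = 0.01, grouping = NULL,
                               n_trees = 500L, ...) {
  method <- match.arg(method)
  pool <- pool_tables(tables)
  models <- levels(pool$labels)
  K <- length(models)
  n <- nrow(pool$stats)
  per_model <- table(pool$labels)
  if (any(n_pods_per_model > per_model))
    stop("n_pods_per_model exceeds the per-model table size")
  scaling <- abc_standardize(pool$stats)
  Z <- apply_scaling(pool$stats, scaling)

  pods <- unlist(lapply(models, function(m)
    sample(which(pool$labels == m), n_pods_per_model)))
  truth <- pool$labels[pods]

  pred <- character(length(pods))
  if (method == "randomforest") {
    df <- as.data.frame(Z)
    names(df) <- make.names(names(df))
    df$.model <- pool$labels
    fit <- ranger::ranger(dependent.variable.name = ".model", data = df,
                          num.trees = n_trees, num.threads = 1L,
                          keep.inbag = TRUE,
                          seed = sample.int(.Machine$integer.max - 1L, 1L))
    inbag <- matrix(unlist(fit$inbag.counts), nrow = n)
    all_pred <- stats::predict(fit, data = df[pods, , drop = FALSE],
                               predict.all = TRUE, num.threads = 1L)$predictions
    for (k in seq_along(pods)) {
      oob <- inbag[pods[k], ] == 0L
      votes <- tabulate(all_pred[k, oob], nbins = K)
      pred[k] <- models[which.max(votes)]
    }
  } else {
    n_acc <- ceiling(tolerance * (n - 1L))
    for (k in seq_along(pods)) {
      i <- pods[k]
      d <- sqrt(rowSums(sweep(Z, 2L, Z[i, ], "-")^2))
      d[i] <- Inf  # leave-one-out: exclude the POD's own row
      acc <- order(d, seq_along(d))[seq_len(n_acc)]
      if (method == "rejection") {
        tab <- table(pool$labels[acc])
        pred[k] <- names(tab)[which.max(tab)]
      } else {
        # single-class accepted sets are routine for well-separated PODS;
        # the absent-model warning is informative for end users, noise here
        sel <- suppressWarnings(
          nn_model_posterior(list(stats = pool$stats[-i, , drop = FALSE],
                                  labels = pool$labels[-i]),
                             pool$stats[i, ], tolerance = tolerance, ...))
        pred[k] <- names(which.max(sel$posterior_prob))
      }
    }
  }

  confusion <- table(factor(truth, levels = models),
                     factor(pred, levels = models))
  mis <- 1 - diag(confusion) / rowSums(confusion)
  attribution <- NULL
  if (!is.null(grouping)) {
    attribution <- data.frame(model = models,
                              misclassification = as.numeric(mis),
                              same_process = NA_real_, other_process = NA_real_)
    for (r in seq_len(K)) {
      wrong <- confusion[r, ] / rowSums(confusion)[r]
      wrong[r] <- 0
      same <- grouping[models] == grouping[models[r]]
      attribution$same_process[r] <- sum(wrong[same])
      attribution$other_process[r] <- sum(wrong[!same])
    }
  }
  structure(list(confusion = confusion, misclassification = mis,
                 attribution = attribution, method = method,
                 tolerance = if (method == "randomforest") NULL else tolerance,
                 n_pods_per_model = n_pods_per_model),
            class = "abc_cv")
}

#' @export
print.abc_cv <- function(x, ...) {
  cat("ABC model-selection cross-validation (", x$method, ", ",
      x$n_pods_per_model, " PODS/model)\n", sep = "")
  cat("per-model misclassification:\n")
  print(round(x$misclassification, 3))
  cat("confusion matrix (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

#' Prediction error of parameter estimates from PODS cross-validation
#'
#' For each sampled POD row, the parameter posterior is estimated against
#' the table with that row excluded and summarized by its (weighted) median;
#' the scaled prediction error per parameter is
#' \deqn{E_p = \sum_i (\hat\theta_i - \theta_i)^2 / (n \,\mathrm{Var}(\theta))}
#' over the PODS (the cv4abc convention): 0 means perfect point estimation,
#' values near 1 mean the statistics carry no information about the
#' parameter beyond its prior.
#'
#' @param table a `ref_table` (single model).
#' @param n_pods number of PODS (default 100).
#' @param tolerance accepted fraction.
#' @param method `"rejection"` or `"neuralnet"` (regression-adjusted).
#' @param ... passed to [nn_adjust_params()] for `"neuralnet"`.
#' @return Object of class `abc_prederr`: named `error` vector plus the
#'   `estimates` and `truth` matrices.
#' @export
cv_parameters <- function(table, n_pods = 100L, tolerance = 0.01,
                          method = c("rejection", "neuralnet"), ...) {
  method <- match.arg(method)
  n <- nrow(table$stats)
  if (n_pods >= n) stop("n_pods must be smaller than the table size")
  vt <- apply(table$params, 2L, stats::var)
  if (any(vt == 0))
    stop("degenerate prior: zero variance for ",
         paste(colnames(table$params)[vt == 0], collapse = ", "))
  pods <- sample.int(n, n_pods)
  est <- matrix(NA_real_, n_pods, ncol(table$params),
                dimnames = list(NULL, colnames(table$params)))
  for (k in seq_along(pods)) {
    i <- pods[k]
    sub <- structure(list(model = table$model,
                          params = table$params[-i, , drop = FALSE],
                          stats = table$stats[-i, , drop = FALSE],
                          n_loci = table$n_loci), class = "ref_table")
    post <- if (method == "rejection")
      rejection_params(sub, table$stats[i, ], tolerance)
    else nn_adjust_params(sub, table$stats[i, ], tolerance, ...)
    est[k, ] <- posterior_summary(post)[colnames(est), "median"]
  }
  truth <- table$params[pods, , drop = FALSE]
  err <- colSums((est - truth)^2) / (n_pods * apply(truth, 2L, stats::var))
  structure(list(error = err, estimates = est, truth = truth,
                 method = method, tolerance = tolerance),
            class = "abc_prederr")
}

#' @export
print.abc_prederr <- function(x, ...) {
  cat("parameter prediction error (", x$method, ", ",
      nrow(x$estimates), " PODS, tolerance ", x$tolerance, ")\n", sep = "")
  print(round(x$error, 3))
  invisible(x)
}

#' Posterior predictive check
#'
#' Simulates `n_sims` datasets with parameter vectors drawn (with
#' replacement, weighted) from the posterior, recomputes the statistic
#' battery on each, and reports a per-statistic posterior predictive
#' p-value.  With `sides = 2` (default), `p = 2 min(Pr(sim <= obs),
#' Pr(sim >= obs))` capped at 1, ties counting toward both; `sides = 1`
#' gives the one-sided `min(Pr(sim <= obs), Pr(sim >= obs))`.  Statistics
#' with `p < 0.05` are flagged.
#'
#' @param model a `scenario_model`.
#' @param posterior an `abc_posterior` for that model.
#' @param observed observed statistic vector.
#' @param n_sims posterior predictive simulations (default 1,000).
#' @param n_loci loci per simulated dataset.
#' @param sides 1 or 2.
#' @return Object of class `abc_ppc` with `p_values`, `flagged`, `observed`
#'   and the simulated statistic matrix `sims`.
#' @export
posterior_predictive <- function(model, posterior, observed, n_sims = 1000L,
                                 n_loci, sides = 2L) {
  if (nrow(posterior$adjusted) < 1L) stop("empty posterior")
  draws <- sample.int(nrow(posterior$adjusted), n_sims, replace = TRUE,
                      prob = posterior$weights)
  pops <- names(model$sampling)
  csamp <- cumsum(model$sampling)
  idx <- stats::setNames(mapply(function(a, b) seq.int(a, b),
                                c(1L, utils::head(csamp, -1L) + 1L), csamp,
                                SIMPLIFY = FALSE), pops)
  sn <- stat_names(pops)
  sims <- matrix(NA_real_, n_sims, length(sn), dimnames = list(NULL, sn))
  for (k in seq_len(n_sims)) {
    inst <- scenario_instance(model, posterior$adjusted[draws[k], ])
    sims[k, ] <- simulate_stats(inst, n_loci, idx)
  }
  obs <- observed[sn]
  ple <- colMeans(sweep(sims, 2L, obs, "<=") * 1)
  pge <- colMeans(sweep(sims, 2L, obs, ">=") * 1)
  p <- if (sides == 2L) 2 * pmin(ple, pge) else pmin(ple, pge)
  p[p > 1] <- 1
  structure(list(p_values = p, flagged = names(p)[p < 0.05],
                 observed = obs, sims = sims, sides = sides),
            class = "abc_ppc")
}

#' @export
print.abc_ppc <- function(x, ...) {
  cat("posterior predictive check:", length(x$p_values), "statistics,",
      length(x$flagged), "flagged (p < 0.05,", x$sides, "sided)\n")
  if (length(x$flagged)) cat("  flagged:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}
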