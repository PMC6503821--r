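# ---- standardization ----------------------------------------------------

#' Robust standardization of summary statistics
#'
#' Centers on the column median and scales by the median absolute deviation
#' (MAD), which is robust to the heavy-tailed count statistics in the
#' battery.  Columns whose MAD is zero fall back to the standard deviation;
#' columns with zero variance are dropped and recorded.  The observed vector
#' must always be standardized with the *reference* scales, never its own.
#'
#' @param stats numeric matrix of reference statistics (rows = replicates).
#' @return Object of class `abc_scaling` with `center`, `scale`, `keep`
#'   (retained column names) and `dropped`.
#' @export
abc_standardize <- function(stats) {
  center <- apply(stats, 2L, stats::median)
  scale <- apply(stats, 2L, stats::mad)
  sds <- apply(stats, 2L, stats::sd)
  scale[scale == 0] <- sds[scale == 0]
  keep <- is.finite(scale) & scale > 0
  if (!any(keep)) stop("all statistic columns are degenerate")
  structure(list(center = center[keep], scale = scale[keep],
                 keep = colnames(stats)[keep],
                 dropped = colnames(stats)[!keep]),
            class = "abc_scaling")
}

apply_scaling <- function(x, scaling) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L, dimnames = list(NULL, names(x)))
  x <- x[, scaling$keep, drop = FALSE]
  sweep(sweep(x, 2L, scaling$center, "-"), 2L, scaling$scale, "/")
}

# ---- rejection ----------------------------------------------------------

#' ABC rejection step
#'
#' Retains the `ceiling(tolerance * n)` reference rows with smallest
#' Euclidean distance to the observed vector on standardized statistics;
#' ties are broken deterministically by row index.
#'
#' @param stats reference statistic matrix (pooled over models if used for
#'   model selection).
#' @param observed observed statistic vector (raw scale).
#' @param tolerance accepted fraction, in (0, 1].
#' @param scaling optional precomputed [abc_standardize()] result; default
#'   computes it from `stats`.
#' @return Object of class `abc_rejection`: `index` (accepted row indices in
#'   distance order), `distance`, `tolerance`, `scaling`.
#' @export
abc_reject <- function(stats, observed, tolerance, scaling = NULL) {
  if (!(tolerance > 0 && tolerance <= 1)) stop("tolerance must be in (0, 1]")
  if (is.null(scaling)) scaling <- abc_standardize(stats)
  z <- apply_scaling(stats, scaling)
  zo <- apply_scaling(observed, scaling)
  d <- sqrt(rowSums(sweep(z, 2L, zo[1L, ], "-")^2))
  n_acc <- ceiling(tolerance * nrow(z))
  ord <- order(d, seq_along(d))[seq_len(n_acc)]
  structure(list(index = ord, distance = d[ord], tolerance = tolerance,
                 scaling = scaling), class = "abc_rejection")
}

# Epanechnikov weights on accepted distances (abc-regression convention)
epanechnikov_w <- function(d) {
  dmax <- max(d)
  if (dmax == 0) return(rep(1, length(d)))
  w <- 1 - (d / dmax)^2
  w[w <= 0] <- min(w[w > 0], 1e-8)  # keep the boundary row usable
  w
}

# ---- model selection ----------------------------------------------------

new_selection <- function(method, tolerance, prob, votes = NULL,
                          oob_error = NULL, n_accepted = NULL) {
  structure(list(method = method, tolerance = tolerance,
                 posterior_prob = prob, votes = votes, oob_error = oob_error,
                 n_accepted = n_accepted),
            class = "abc_model_selection")
}

#' @export
print.abc_model_selection <- function(x, ...) {
  cat("ABC model selection (", x$method, ")\n", sep = "")
  if (!is.null(x$tolerance)) cat("  tolerance:", x$tolerance, "\n")
  if (!is.null(x$oob_error))
    cat("  out-of-bag error:", format(x$oob_error, digits = 3), "\n")
  pp <- sort(x$posterior_prob, decreasing = TRUE)
  for (m in names(pp)) cat(sprintf("  %-20s %.4f\n", m, pp[m]))
  invisible(x)
}

pool_tables <- function(tables) {
  if (inherits(tables, "ref_table")) tables <- list(tables)
  stats_m <- do.call(rbind, lapply(tables, `[[`, "stats"))
  labels <- factor(unlist(lapply(tables, function(t)
    rep(t$model, nrow(t$stats)))),
    levels = vapply(tables, `[[`, character(1), "model"))
  list(stats = stats_m, labels = labels)
}

# minimal multilayer perceptron classifier (softmax output, tanh hidden),
# trained by BFGS on the penalized cross-entropy; used only for the
# multi-hidden-layer topology that no installed package provides.
mlp_fit <- function(X, Y, hidden, decay = 5e-3, maxit = 300) {
  sizes <- c(ncol(X), hidden, ncol(Y))
  n_w <- sum((sizes[-length(sizes)] + 1L) * sizes[-1L])
  unpack <- function(par) {
    out <- vector("list", length(sizes) - 1L)
    o <- 0L
    for (l in seq_along(out)) {
      nin <- sizes[l] + 1L; nout <- sizes[l + 1L]
      out[[l]] <- matrix(par[o + seq_len(nin * nout)], nin, nout)
      o <- o + nin * nout
    }
    out
  }
  fwd <- function(W) {
    A <- X
    acts <- list()
    for (l in seq_along(W)) {
      Z <- cbind(1, A) %*% W[[l]]
      A <- if (l < length(W)) tanh(Z) else Z
      acts[[l]] <- A
    }
    E <- exp(A - apply(A, 1L, max))
    P <- E / rowSums(E)
    list(P = P, acts = acts)
  }
  loss <- function(par) {
    W <- unpack(par)
    P <- fwd(W)$P
    -sum(Y * log(pmax(P, 1e-12))) / nrow(X) + decay * sum(par^2)
  }
  grad <- function(par) {
    W <- unpack(par)
    f <- fwd(W)
    delta <- (f$P - Y) / nrow(X)
    g <- vector("list", length(W))
    for (l in rev(seq_along(W))) {
      Ain <- if (l == 1L) X else f$acts[[l - 1L]]
      g[[l]] <- t(cbind(1, Ain)) %*% delta
      if (l > 1L)
        delta <- (delta %*% t(W[[l]][-1L, , drop = FALSE])) *
          (1 - f$acts[[l - 1L]]^2)
    }
    unlist(g) + 2 * decay * par
  }
  par <- stats::runif(n_w, -0.5, 0.5)
  fit <- stats::optim(par, loss, grad, method = "BFGS",
                      control = list(maxit = maxit))
  W <- unpack(fit$par)
  function(newX) {
    A <- newX
    for (l in seq_along(W)) {
      Z <- cbind(1, A) %*% W[[l]]
      A <- if (l < length(W)) tanh(Z) else Z
    }
    E <- exp(A - apply(A, 1L, max))
    E / rowSums(E)
  }
}

#' Neural-network ABC model posterior
#'
#' Classical regression-classification ABC model selection: rejection at the
#' given tolerance on the pooled reference table, then a feed-forward
#' classifier (multinomial output) fitted to the accepted rows' standardized
#' statistics, evaluated at the observed vector.  The default topology is a
#' single hidden layer of 5 units (via `nnet`); `hidden` may be a vector
#' (e.g. `rep(5, 5)`) for a deeper multilayer perceptron.  An ensemble of
#' random restarts is averaged to damp initialization noise.  A candidate
#' model absent from the accepted rows is assigned probability 0 with a
#' warning.
#'
#' @param tables list of `ref_table`s (one per candidate model, equal row
#'   counts for equal model priors), or a pooled list with `stats`/`labels`.
#' @param observed observed statistic vector.
#' @param tolerance accepted fraction of the pooled table.
#' @param hidden hidden-layer sizes; scalar = single hidden layer.
#' @param ensemble number of restarts averaged.
#' @param decay weight decay (default 0.5: accepted sets are small relative
#'   to the network size, so fairly strong shrinkage toward uniform class
#'   probabilities is the safer default; genuinely separated models still
#'   reach near-certain support).
#' @param maxit training iterations.
#' @return An `abc_model_selection` with `method = "neural_net"`.
#' @export
nn_model_posterior <- function(tables, observed, tolerance = 0.01,
                               hidden = 5L, ensemble = 5L, decay = 0.5,
                               maxit = 500L) {
  pool <- if (is.list(tables) && !is.null(tables$stats)) tables
          else pool_tables(tables)
  if (nlevels(pool$labels) < 2L) stop("model selection needs >= 2 models")
  rej <- abc_reject(pool$stats, observed, tolerance)
  lab <- droplevels(pool$labels[rej$index])
  missing <- setdiff(levels(pool$labels), levels(lab))
  if (length(missing))
    warning("model(s) absent from accepted rows (probability 0): ",
            paste(missing, collapse = ", "))
  Z <- apply_scaling(pool$stats[rej$index, , drop = FALSE], rej$scaling)
  zo <- apply_scaling(observed, rej$scaling)
  w <- epanechnikov_w(rej$distance)

  probs <- matrix(0, ensemble, nlevels(lab),
                  dimnames = list(NULL, levels(lab)))
  if (nlevels(lab) == 1L) {
    probs[, 1L] <- 1
  } else if (length(hidden) == 1L) {
    Y <- nnet::class.ind(lab)
    for (e in seq_len(ensemble)) {
      fit <- nnet::nnet(Z, Y, size = hidden, decay = decay, maxit = maxit,
                        weights = w, softmax = TRUE, trace = FALSE)
      probs[e, ] <- stats::predict(fit, zo)[1L, ]
    }
  } else {
    Y <- nnet::class.ind(lab)
    for (e in seq_len(ensemble)) {
      pred <- mlp_fit(Z, Y, hidden, decay = decay)
      probs[e, ] <- pred(zo)[1L, ]
    }
  }
  pp <- colMeans(probs)
  full <- stats::setNames(rep(0, nlevels(pool$labels)), levels(pool$labels))
  full[names(pp)] <- pp
  full <- full / sum(full)
  new_selection("neural_net", tolerance, full, n_accepted = length(rej$index))
}

#' Random-forest ABC model posterior
#'
#' Classification forest over the full reference table (no rejection step, as
#' in random-forest ABC): model support at the observed vector is the
#' proportion of trees voting for each model; the forest's out-of-bag
#' misclassification rate is recorded.
#'
#' @inheritParams nn_model_posterior
#' @param n_trees number of trees (default 1,000).
#' @param seed optional seed passed to the forest for reproducible votes.
#' @return An `abc_model_selection` with `method = "random_forest"`, per-model
#'   `votes` and `oob_error`.
#' @export
rf_model_posterior <- function(tables, observed, n_trees = 1000L, seed = NULL) {
  pool <- if (is.list(tables) && !is.null(tables$stats)) tables
          else pool_tables(tables)
  if (nlevels(pool$labels) < 2L) stop("model selection needs >= 2 models")
  scaling <- abc_standardize(pool$stats)
  df <- as.data.frame(apply_scaling(pool$stats, scaling))
  names(df) <- make.names(names(df))
  df$.model <- pool$labels
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1L, 1L)
  fit <- ranger::ranger(dependent.variable.name = ".model", data = df,
                        num.trees = n_trees, seed = seed, num.threads = 1L,
                        respect.unordered.factors = TRUE)
  obs <- as.data.frame(apply_scaling(observed, scaling))
  names(obs) <- make.names(names(obs))
  pred <- stats::predict(fit, data = obs, predict.all = TRUE,
                         num.threads = 1L)$predictions
  votes <- tabulate(pred[1L, ], nbins = nlevels(pool$labels))
  names(votes) <- levels(pool$labels)
  new_selection("random_forest", NULL, votes / n_trees, votes = votes,
                oob_error = fit$prediction.error)
}

#' Pairwise Bayes factors from model posterior probabilities
#'
#' Under equal model priors, `BF[a, b] = Pr(a) / Pr(b)`.  Support with
#' `BF >= 3` is flagged "strong" (Jeffreys' convention); a zero denominator
#' yields `Inf`.
#'
#' @param result an `abc_model_selection`.
#' @return Matrix of class `abc_bayes_factors` with a `strong` attribute.
#' @export
bayes_factors <- function(result) {
  p <- result$posterior_prob
  bf <- outer(p, p, function(a, b) ifelse(b == 0, Inf, a / b))
  diag(bf) <- 1
  structure(bf, strong = bf >= 3 & !diag(length(p)),
            class = c("abc_bayes_factors", "matrix"))
}

#' @export
print.abc_bayes_factors <- function(x, ...) {
  cat("Bayes factors (row vs column); * = strong (BF >= 3)\n")
  m <- format(round(unclass(x), 2))
  m[attr(x, "strong")] <- paste0(m[attr(x, "strong")], "*")
  print(m, quote = FALSE)
  invisible(x)
}

# ---- parameter estimation ----------------------------------------------

default_transforms <- function(pnames) {
  tr <- ifelse(grepl("^SEV_", pnames), "logit",
               ifelse(grepl("^(Ne_|HYP_|MIG_)", pnames), "log", "identity"))
  stats::setNames(tr, pnames)
}

tr_fun <- function(kind) {
  switch(kind,
         log = list(f = log, inv = exp),
         logit = list(f = function(x) stats::qlogis(pmin(pmax(x, 1e-12), 1 - 1e-12)),
                      inv = stats::plogis),
         identity = list(f = identity, inv = identity))
}

#' Neural-network regression-adjusted parameter posterior
#'
#' Rejection at the given tolerance, then for each parameter a nonlinear
#' (single-hidden-layer) regression of the transformed parameter on the
#' standardized accepted statistics; the fitted conditional expectation
#' transports the accepted draws to the observed vector by residual
#' adjustment, `theta* = m(s_obs) + (theta - m(s))`.  Effective sizes and
#' migration rates are log-transformed and bottleneck severities
#' logit-transformed before adjustment, so back-transformed draws always
#' respect the parameter support.  Accepted draws carry Epanechnikov
#' distance weights.  If a regression fails the raw rejection posterior is
#' returned for that parameter with a warning.
#'
#' @param table a `ref_table` (single model).
#' @param observed observed statistic vector.
#' @param tolerance accepted fraction.
#' @param transforms named character vector (`"log"`, `"logit"`,
#'   `"identity"`) per parameter; default chosen from canonical name
#'   prefixes.
#' @param hidden hidden-layer size for the regressions.
#' @param ensemble restarts averaged for the conditional-mean fits.
#' @param maxit,decay `nnet` training controls.  The decay default (0.5) is
#'   deliberately strong: accepted sets are typically around 100 rows against
#'   a network with more weights than that, and weaker shrinkage lets the
#'   conditional-mean fit absorb residual spread, collapsing the adjusted
#'   posterior and ruining interval coverage.
#' @return Object of class `abc_posterior`: raw accepted draws, adjusted
#'   draws, normalized weights, transforms, tolerance.
#' @export
nn_adjust_params <- function(table, observed, tolerance = 0.01,
                             transforms = NULL, hidden = 5L, ensemble = 3L,
                             maxit = 500L, decay = 0.5) {
  rej <- abc_reject(table$stats, observed, tolerance)
  if (length(rej$index) < 50L)
    stop("fewer than 50 accepted rows; increase the tolerance or table size")
  raw <- table$params[rej$index, , drop = FALSE]
  Z <- apply_scaling(table$stats[rej$index, , drop = FALSE], rej$scaling)
  zo <- apply_scaling(observed, rej$scaling)
  w <- epanechnikov_w(rej$distance)
  if (is.null(transforms)) transforms <- default_transforms(colnames(raw))

  adj <- raw
  for (p in colnames(raw)) {
    tf <- tr_fun(transforms[[p]])
    y <- tf$f(raw[, p])
    if (stats::var(y) == 0) { adj[, p] <- raw[, p]; next }
    pred_obs <- 0; pred_acc <- 0; ok <- TRUE
    for (e in seq_len(ensemble)) {
      fit <- try(nnet::nnet(Z, y, size = hidden, linout = TRUE,
                            decay = decay, maxit = maxit, weights = w,
                            trace = FALSE), silent = TRUE)
      if (inherits(fit, "try-error")) { ok <- FALSE; break }
      pred_obs <- pred_obs + stats::predict(fit, zo)[1L, 1L] / ensemble
      pred_acc <- pred_acc + stats::predict(fit, Z)[, 1L] / ensemble
    }
    if (!ok) {
      warning("regression failed for ", p, "; returning unadjusted draws")
      adj[, p] <- raw[, p]
    } else {
      adj[, p] <- tf$inv(pred_obs + (y - pred_acc))
    }
  }
  structure(list(params = colnames(raw), raw = raw, adjusted = adj,
                 weights = w / sum(w), transforms = transforms,
                 tolerance = tolerance, distance = rej$distance),
            class = "abc_posterior")
}

#' Rejection-only parameter posterior
#'
#' The accepted draws themselves, with Epanechnikov distance weights and no
#' regression adjustment.
#'
#' @inheritParams nn_adjust_params
#' @return An `abc_posterior` whose adjusted draws equal the raw draws.
#' @export
rejection_params <- function(table, observed, tolerance = 0.01) {
  rej <- abc_reject(table$stats, observed, tolerance)
  raw <- table$params[rej$index, , drop = FALSE]
  w <- epanechnikov_w(rej$distance)
  structure(list(params = colnames(raw), raw = raw, adjusted = raw,
                 weights = w / sum(w),
                 transforms = default_transforms(colnames(raw)),
                 tolerance = tolerance, distance = rej$distance),
            class = "abc_posterior")
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("abc_posterior:", nrow(x$adjusted), "weighted draws,",
      length(x$params), "parameters (tolerance", x$tolerance, ")\n")
  print(posterior_summary(x))
  invisible(x)
}

weighted_median <- function(x, w) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  x[o][which(cw >= 0.5)[1L]]
}

hdi_weighted <- function(x, w, level = 0.95) {
  o <- order(x)
  x <- x[o]; w <- w[o] / sum(w)
  cw <- cumsum(w)
  n <- length(x)
  best <- c(x[1L], x[n])
  best_len <- x[n] - x[1L]
  j <- 1L
  for (i in seq_len(n)) {
    lo_mass <- if (i > 1L) cw[i - 1L] else 0
    while (j < n && cw[j] - lo_mass < level) j <- j + 1L
    if (cw[j] - lo_mass >= level) {
      len <- x[j] - x[i]
      if (len < best_len) { best_len <- len; best <- c(x[i], x[j]) }
    }
    if (j == n && cw[n] - lo_mass < level) break
  }
  best
}

#' Posterior medians and highest-density intervals
#'
#' Weighted medians and the shortest interval containing `level` posterior
#' mass (computed on the weighted adjusted draws).
#'
#' @param posterior an `abc_posterior`.
#' @param level HDI mass (default 0.95).
#' @return Matrix with columns `median`, `hdi_lower`, `hdi_upper` and one row
#'   per parameter.
#' @export
posterior_summary <- function(posterior, level = 0.95) {
  out <- matrix(NA_real_, length(posterior$params), 3L,
                dimnames = list(posterior$params,
                                c("median", "hdi_lower", "hdi_upper")))
  for (p in posterior$params) {
    x <- posterior$adjusted[, p]
    out[p, 1L] <- weighted_median(x, posterior$weights)
    out[p, 2:3] <- hdi_weighted(x, posterior$weights, level)
  }
  out
}

#' @export
summary.abc_posterior <- function(object, level = 0.95, ...)
  posterior_summary(object, level)
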