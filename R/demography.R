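#' Prior specification
#'
#' Uniform or log-uniform prior over a bounded interval.  Log-uniform priors
#' require a strictly positive lower bound.
#'
#' @param dist `"uniform"` or `"loguniform"`.
#' @param lower,upper bounds, with `lower < upper`.
#' @return Object of class `prior_spec`.
#' @export
prior_spec <- function(dist = c("uniform", "loguniform"), lower, upper) {
  dist <- match.arg(dist)
  if (!(is.numeric(lower) && is.numeric(upper) && lower < upper))
    stop("prior bounds must satisfy lower < upper")
  if (dist == "loguniform" && lower <= 0)
    stop("log-uniform priors require lower > 0")
  structure(list(dist = dist, lower = lower, upper = upper),
            class = "prior_spec")
}

#' Draw from a prior
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @return Numeric vector of draws.
#' @export
draw_prior <- function(spec, n = 1L) {
  if (spec$dist == "uniform") stats::runif(n, spec$lower, spec$upper)
  else exp(stats::runif(n, log(spec$lower), log(spec$upper)))
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("%s(%g, %g)\n", x$dist, x$lower, x$upper))
  invisible(x)
}

as_prior <- function(x, where = "prior") {
  if (inherits(x, "prior_spec")) return(x)
  if (is.list(x) && !is.null(x$dist))
    return(prior_spec(x$dist, x$lower, x$upper))
  stop("cannot interpret ", where, " as a prior specification")
}

#' Candidate invasion scenario
#'
#' A scenario is a set of demes with contemporary effective sizes (priors or
#' references to shared hyperpriors), diploid sampling sizes, founding events
#' (each derived deme founded exactly once, forming a tree rooted in an
#' unfounded source deme), and optional continuous migration edges.  Founding
#' events carry a bottleneck: backward in time, at the event time the derived
#' deme's size becomes `severity x contemporary Ne` for `duration`
#' generations, after which all remaining lineages transfer to the source
#' deme.  Event times are in generations before sampling; with recent
#' invasions they are typically fixed constants derived from first-detection
#' years divided by the generation time.
#'
#' Severity classes (`SF` for shipping-assisted foundings, `RF` for inland
#' river foundings) let a single class-level prior be shared across all
#' events of that class (`severity = "RF"` refers to `class_priors$RF`,
#' giving one pooled severity parameter per class and draw); an inline
#' [prior_spec()] instead gives the event its own parameter.
#'
#' Deme effective sizes may reference a hyperprior:
#' `ne = list(hyper = "name")` sets the deme's conditional location to the
#' hyperprior draw, optionally scattered multiplicatively via
#' `scatter = prior_spec(...)`.
#'
#' @param name model name.
#' @param demes named list: deme label -> `ne` specification (a
#'   [prior_spec()], a plain list with `dist`/`lower`/`upper`, or a
#'   `list(hyper=, scatter=)` reference).
#' @param sampling named integer vector of diploid sample sizes per deme
#'   (every deme sampled at a positive size).
#' @param events list of founding events, each a list with `time`, `derived`,
#'   `source`, `severity` (prior or class name), optional `class`, optional
#'   `duration` (default 1 generation).
#' @param migration list of edges, each `list(from=, to=, rate=, start=, end=)`
#'   with `rate` a prior; the rate is the per-generation backward probability
#'   that a lineage currently in `from` traces its ancestry to `to`.
#' @param hyperpriors named list of [prior_spec()]s.
#' @param class_priors named list of [prior_spec()]s keyed by severity class.
#' @param generation_time generations per year bookkeeping constant
#'   (years/generation; default 2), stored for provenance.
#' @param validate stop on invariant violations (default `TRUE`).
#' @return Object of class `scenario_model`.
#' @export
scenario_model <- function(name, demes, sampling, events,
                           migration = list(), hyperpriors = list(),
                           class_priors = list(), generation_time = 2,
                           validate = TRUE) {
  demes <- lapply(demes, function(d) {
    if (is.list(d) && !is.null(d$hyper)) {
      d$scatter <- if (!is.null(d$scatter)) as_prior(d$scatter, "scatter")
      d
    } else as_prior(d, "deme ne")
  })
  hyperpriors <- lapply(hyperpriors, as_prior, where = "hyperprior")
  class_priors <- lapply(class_priors, as_prior, where = "class prior")
  events <- lapply(events, function(e) {
    e$duration <- if (is.null(e$duration)) 1 else e$duration
    if (!is.character(e$severity)) e$severity <- as_prior(e$severity, "severity")
    e
  })
  migration <- lapply(migration, function(m) {
    m$rate <- as_prior(m$rate, "migration rate")
    m$start <- if (is.null(m$start)) 0 else m$start
    m$end <- if (is.null(m$end)) Inf else m$end
    m
  })
  sampling <- vapply(sampling, as.integer, integer(1))
  obj <- structure(list(name = name, demes = demes, sampling = sampling,
                        events = events, migration = migration,
                        hyperpriors = hyperpriors, class_priors = class_priors,
                        generation_time = generation_time),
                   class = "scenario_model")
  if (validate) {
    v <- validate_scenario(obj)
    if (length(v$violations))
      stop("invalid scenario '", name, "':\n  ",
           paste(v$violations, collapse = "\n  "))
  }
  obj
}

#' Validate a scenario
#'
#' Checks the structural invariants: positive event times, each derived deme
#' founded exactly once, a founding graph that is a tree rooted in a single
#' unfounded deme, severity prior support inside (0, 1], sources that remain
#' active when their derived demes merge into them, known deme references,
#' and positive sampling sizes.  Event times beyond the invasion window are
#' reported as warnings, not violations.
#'
#' @param model a `scenario_model` (possibly built with `validate = FALSE`).
#' @param invasion_window generations; events older than this draw a warning
#'   (default 30).
#' @return List with character vectors `violations` and `warnings`.
#' @export
validate_scenario <- function(model, invasion_window = 30) {
  v <- character()
  w <- character()
  labels <- names(model$demes)
  if (is.null(labels) || anyDuplicated(labels))
    v <- c(v, "demes must be a uniquely named list")
  if (!setequal(names(model$sampling), labels))
    v <- c(v, "sampling must cover exactly the deme labels")
  if (any(model$sampling <= 0L))
    v <- c(v, "every deme must be sampled at a positive size")
  for (d in labels) {
    ne <- model$demes[[d]]
    if (is.list(ne) && !is.null(ne$hyper) &&
        !(ne$hyper %in% names(model$hyperpriors)))
      v <- c(v, sprintf("deme %s references unknown hyperprior '%s'", d, ne$hyper))
  }
  founded <- vapply(model$events, function(e) e$derived, character(1))
  if (anyDuplicated(founded))
    v <- c(v, sprintf("deme(s) founded more than once: %s",
                      paste(unique(founded[duplicated(founded)]), collapse = ", ")))
  merge_time <- stats::setNames(rep(Inf, length(labels)), labels)
  for (e in model$events) {
    if (!(e$derived %in% labels) || !(e$source %in% labels)) {
      v <- c(v, sprintf("event references unknown deme (%s -> %s)",
                        e$source, e$derived))
      next
    }
    if (e$derived == e$source)
      v <- c(v, sprintf("deme %s founded from itself", e$derived))
    if (!is.numeric(e$time) || e$time <= 0)
      v <- c(v, sprintf("founding time of %s must be positive", e$derived))
    else if (e$time > invasion_window)
      w <- c(w, sprintf("founding of %s at %g generations exceeds the invasion window (%g)",
                        e$derived, e$time, invasion_window))
    if (is.character(e$severity)) {
      if (!(e$severity %in% names(model$class_priors)))
        v <- c(v, sprintf("event %s references unknown severity class '%s'",
                          e$derived, e$severity))
    } else if (e$severity$lower <= 0 || e$severity$upper > 1) {
      v <- c(v, sprintf("severity prior of event %s outside (0,1]", e$derived))
    }
    if (e$duration < 0)
      v <- c(v, sprintf("negative bottleneck duration for %s", e$derived))
    merge_time[e$derived] <- e$time + e$duration
  }
  for (cp in model$class_priors)
    if (cp$lower <= 0 || cp$upper > 1) {
      v <- c(v, "class severity prior outside (0,1]")
      break
    }
  roots <- setdiff(labels, founded)
  if (length(labels) && length(roots) != 1L)
    v <- c(v, sprintf("founding graph must be a tree with one root (found %d unfounded demes)",
                      length(roots)))
  for (e in model$events)
    if (e$source %in% labels && is.finite(merge_time[e$source]) &&
        merge_time[e$source] < e$time + e$duration)
      v <- c(v, sprintf("source %s is extinguished before absorbing %s",
                        e$source, e$derived))
  for (m in model$migration) {
    if (!(m$from %in% labels) || !(m$to %in% labels))
      v <- c(v, sprintf("migration edge references unknown deme (%s -> %s)",
                        m$from, m$to))
    if (m$rate$lower < 0)
      v <- c(v, "migration rates must be non-negative")
  }
  list(violations = v, warnings = w)
}

#' @export
print.scenario_model <- function(x, ...) {
  cat("scenario_model:", x$name, "-", length(x$demes), "demes,",
      length(x$events), "founding events,",
      length(x$migration), "migration edges\n")
  for (e in x$events)
    cat(sprintf("  %s -> %s at t=%g (class %s)\n", e$source, e$derived,
                e$time, if (is.null(e$class)) "-" else e$class))
  invisible(x)
}

sev_param_name <- function(e) {
  if (is.character(e$severity)) paste0("SEV_", e$severity)
  else paste0("SEV_", e$derived)
}

#' Parameter names of a scenario
#' @param model a `scenario_model`.
#' @return Character vector: `HYP_*`, `Ne_*`, `SEV_*`, `MIG_*` in canonical order.
#' @export
param_names <- function(model) {
  hyp <- if (length(model$hyperpriors)) paste0("HYP_", names(model$hyperpriors))
  nev <- paste0("Ne_", names(model$demes))
  sev <- unique(vapply(model$events, sev_param_name, character(1)))
  mig <- vapply(model$migration,
                function(m) paste0("MIG_", m$from, "_", m$to), character(1))
  c(hyp, nev, sev, unique(mig))
}

#' Draw a concrete parameter instance from a scenario's priors
#'
#' Hyperprior draws come first; deme sizes referencing a hyperprior are drawn
#' conditionally on it (size = hyper draw x scatter draw, scatter defaulting
#' to exactly 1 so referencing demes share their conditional location).
#' Class-level severities are drawn once per class and shared by all events
#' of that class.
#'
#' @param model a `scenario_model`.
#' @return Object of class `scenario_instance`: the model plus a flat named
#'   parameter vector `$params` (the reference-table row prefix).
#' @export
draw_instance <- function(model) {
  p <- numeric(0)
  for (h in names(model$hyperpriors))
    p[paste0("HYP_", h)] <- draw_prior(model$hyperpriors[[h]])
  for (d in names(model$demes)) {
    ne <- model$demes[[d]]
    val <- if (is.list(ne) && !is.null(ne$hyper)) {
      sc <- if (!is.null(ne$scatter)) draw_prior(ne$scatter) else 1
      p[[paste0("HYP_", ne$hyper)]] * sc
    } else draw_prior(ne)
    p[paste0("Ne_", d)] <- val
  }
  for (e in model$events) {
    nm <- sev_param_name(e)
    if (nm %in% names(p)) next  # class severity shared across events
    p[nm] <- if (is.character(e$severity))
      draw_prior(model$class_priors[[e$severity]])
    else draw_prior(e$severity)
  }
  for (m in model$migration) {
    nm <- paste0("MIG_", m$from, "_", m$to)
    if (is.na(p[nm])) p[nm] <- draw_prior(m$rate)
  }
  structure(list(model = model, params = p), class = "scenario_instance")
}

#' Bind a parameter vector to a scenario
#'
#' Inverse of extracting `$params` from [draw_instance()]: builds a
#' `scenario_instance` from an explicit named parameter vector (e.g. a
#' reference-table row, a posterior draw, or known synthetic truth).
#'
#' @param model a `scenario_model`.
#' @param params named numeric vector matching [param_names()] (extra names
#'   ignored).
#' @return A `scenario_instance`.
#' @export
scenario_instance <- function(model, params) {
  need <- setdiff(param_names(model), names(params))
  if (length(need))
    stop("missing parameter(s): ", paste(need, collapse = ", "))
  structure(list(model = model, params = params[param_names(model)]),
            class = "scenario_instance")
}

#' @export
print.scenario_instance <- function(x, ...) {
  cat("scenario_instance of", x$model$name, "\n")
  print(signif(x$params, 4))
  invisible(x)
}

#' Ordered set of candidate scenarios for one analysis
#'
#' All models in a set must share deme labels and sampling configuration so
#' their simulated statistic vectors have identical layout.
#'
#' @param name analysis name.
#' @param models list of [scenario_model()]s.
#' @return Object of class `model_set`.
#' @export
model_set <- function(name, models) {
  if (length(models) < 1L) stop("empty model set")
  nm <- vapply(models, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("duplicate model names in set")
  ref <- models[[1L]]
  for (m in models[-1L]) {
    if (!setequal(names(m$demes), names(ref$demes)))
      stop("model ", m$name, " has different deme labels than ", ref$name)
    if (!identical(m$sampling[names(ref$sampling)], ref$sampling))
      stop("model ", m$name, " has a different sampling configuration")
  }
  structure(list(name = name, models = stats::setNames(models, nm)),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat("model_set:", x$name, "-", length(x$models), "candidate models\n")
  cat(" ", paste(names(x$models), collapse = ", "), "\n")
  invisible(x)
}

prior_to_list <- function(p) list(dist = p$dist, lower = p$lower, upper = p$upper)

model_to_list <- function(m) {
  list(name = m$name,
       generation_time = m$generation_time,
       demes = lapply(m$demes, function(d) {
         if (is.list(d) && !is.null(d$hyper)) {
           out <- list(hyper = d$hyper)
           if (!is.null(d$scatter)) out$scatter <- prior_to_list(d$scatter)
           out
         } else prior_to_list(d)
       }),
       hyperpriors = lapply(m$hyperpriors, prior_to_list),
       class_priors = lapply(m$class_priors, prior_to_list),
       sampling = as.list(m$sampling),
       events = lapply(m$events, function(e) {
         out <- list(time = e$time, derived = e$derived, source = e$source,
                     duration = e$duration)
         if (!is.null(e$class)) out$class <- e$class
         out$severity <- if (is.character(e$severity)) e$severity
                         else prior_to_list(e$severity)
         out
       }),
       migration = lapply(m$migration, function(mm)
         list(from = mm$from, to = mm$to, rate = prior_to_list(mm$rate),
              start = mm$start,
              end = if (is.finite(mm$end)) mm$end else "Inf")))
}

model_from_list <- function(l) {
  mig <- lapply(l$migration, function(mm) {
    mm$end <- if (identical(mm$end, "Inf")) Inf else mm$end
    mm
  })
  scenario_model(name = l$name, demes = l$demes,
                 sampling = unlist(l$sampling),
                 events = l$events, migration = mig,
                 hyperpriors = if (is.null(l$hyperpriors)) list() else l$hyperpriors,
                 class_priors = if (is.null(l$class_priors)) list() else l$class_priors,
                 generation_time = if (is.null(l$generation_time)) 2 else l$generation_time)
}

#' Load / save a model set from a YAML configuration file
#'
#' The schema mirrors [scenario_model()]: a top-level `analysis` name and a
#' `models` list.  Worked example configurations for the shipped analyses
#' live under `system.file("extdata/models", package = "invabc")`; they are
#' reconstructions of named colonization hypotheses (stepping-stone versus
#' single-jump-then-downstream, east-west orderings, single versus multiple
#' introductions) with desk-scale priors, and are labelled as such in their
#' headers.
#'
#' @param path YAML file path.
#' @return A [model_set()].
#' @export
load_model_set <- function(path) {
  if (!file.exists(path)) stop("model-set file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$analysis) || is.null(cfg$models))
    stop("model-set config must have 'analysis' and 'models' keys")
  model_set(cfg$analysis, lapply(cfg$models, model_from_list))
}

#' @rdname load_model_set
#' @param ms a `model_set`.
#' @export
write_model_set <- function(ms, path) {
  yaml::write_yaml(list(analysis = ms$name,
                        models = lapply(unname(ms$models), model_to_list)),
                   path)
  invisible(path)
}
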