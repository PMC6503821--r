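# Compile a scenario_instance into the numeric configuration consumed by the
# C++ simulator: deme indices, sizes, the scheduled founding events (resize at
# t, merge at t+duration) and migration edges with their active intervals.
sim_config <- function(instance) {
  m <- instance$model
  p <- instance$params
  labels <- names(m$demes)
  di <- stats::setNames(seq_along(labels) - 1L, labels)
  ne <- unname(p[paste0("Ne_", labels)])
  if (any(!is.finite(ne) | ne <= 0)) stop("non-positive effective size in instance")
  ev <- matrix(0, nrow = length(m$events), ncol = 5L)
  for (k in seq_along(m$events)) {
    e <- m$events[[k]]
    sev <- p[[sev_param_name(e)]]
    if (!is.finite(sev) || sev <= 0 || sev > 1)
      stop("severity outside (0,1] in instance")
    ev[k, ] <- c(e$time, di[[e$derived]], di[[e$source]], sev, e$duration)
  }
  mg <- matrix(0, nrow = length(m$migration), ncol = 5L)
  for (k in seq_along(m$migration)) {
    mm <- m$migration[[k]]
    mg[k, ] <- c(di[[mm$from]], di[[mm$to]],
                 p[[paste0("MIG_", mm$from, "_", mm$to)]],
                 mm$start, if (is.finite(mm$end)) mm$end else 1e18)
  }
  list(copies = 2L * unname(m$sampling[labels]), ne = ne,
       events = ev, migration = mg, labels = labels,
       sampling = m$sampling[labels])
}

#' Simulate a genealogy under a scenario instance
#'
#' Standard backward-in-time coalescent with continuous-time approximation:
#' within each deme, any pair of lineages coalesces at rate 1/(2Ne(t)) per
#' generation; migration moves lineages between demes at their backward
#' rates; at a founding event's time the derived deme's lineages experience
#' the bottleneck size for the event's duration and then merge into the
#' source deme.
#'
#' @param instance a `scenario_instance` (from [draw_instance()] or
#'   [scenario_instance()]).
#' @return Object of class `genealogy`: `parent` (1-based, root = `NA`),
#'   `time` (node times in generations, tips at 0), `n_tips`, and `tip_deme`.
#' @export
simulate_genealogy <- function(instance) {
  cfg <- sim_config(instance)
  g <- .sim_genealogy_cpp(cfg$copies, cfg$ne, cfg$events, cfg$migration)
  parent <- g$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(parent = parent, time = g$time, n_tips = g$n_tips,
                 tip_deme = rep(cfg$labels, cfg$copies)),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", x$n_tips, "tips, TMRCA =",
      format(max(x$time), digits = 4), "generations\n")
  invisible(x)
}

#' Place one SNP on a genealogy
#'
#' One mutation is placed on a branch chosen proportional to branch length;
#' tips below the branch carry the derived allele, so the site is polymorphic
#' in the pooled sample by construction (SNP-mode ascertainment).  Gene
#' copies are paired into diploids within demes.
#'
#' @param genealogy a `genealogy`.
#' @return Integer vector of diploid genotype codes (derived-allele counts),
#'   with the deme labels as names.
#' @export
place_snp <- function(genealogy) {
  parent0 <- genealogy$parent - 1L
  parent0[is.na(parent0)] <- -1L
  der <- .place_mutation_cpp(parent0, genealogy$time, genealogy$n_tips)
  gt <- der[seq(1L, genealogy$n_tips, by = 2L)] +
    der[seq(2L, genealogy$n_tips, by = 2L)]
  names(gt) <- genealogy$tip_deme[seq(1L, genealogy$n_tips, by = 2L)]
  gt
}

#' Simulate a complete SNP genotype dataset
#'
#' `n_loci` independent genealogies, each contributing one pooled-polymorphic
#' SNP.  Sample sizes per deme are the instance's sampling configuration; the
#' output has no missing data.
#'
#' @param instance a `scenario_instance`.
#' @param n_loci number of SNP loci.
#' @return A complete [genotype_dataset()].
#' @export
simulate_dataset <- function(instance, n_loci) {
  cfg <- sim_config(instance)
  geno <- .sim_dataset_cpp(as.integer(n_loci), cfg$copies, cfg$ne,
                           cfg$events, cfg$migration)  # loci x individuals
  pops <- rep(cfg$labels, cfg$sampling)
  ids <- paste0(pops, "_", unlist(lapply(cfg$sampling, seq_len)))
  genotype_dataset(geno, locus_ids = sprintf("L%05d", seq_len(n_loci)),
                   individual_ids = ids,
                   pop_of = stats::setNames(pops, ids))
}

# fast path used by the reference-table builder: raw stats, no object wrap
simulate_stats <- function(instance, n_loci, idx_template) {
  cfg <- sim_config(instance)
  geno <- .sim_dataset_cpp(as.integer(n_loci), cfg$copies, cfg$ne,
                           cfg$events, cfg$migration)
  stat_vector_core(geno, idx_template)
}

#' Build a per-model reference table
#'
#' Each row is one replicate: parameters drawn from the model's priors, a
#' dataset simulated under them, and the canonical statistic vector computed.
#' Generation is chunked with per-chunk seeds derived deterministically from
#' `seed`, so a table can be (re)built chunk by chunk and concatenated:
#' running two chunks of 50 under the recorded seed schedule equals one run
#' of 100.
#'
#' @param model a `scenario_model`.
#' @param n_reps number of replicates (rows).
#' @param n_loci SNP loci per replicate (match the observed panel size of the
#'   analysis).
#' @param chunk_size replicates per chunk.
#' @param seed optional master seed; per-chunk seeds are derived from it.
#' @return Object of class `ref_table` with `params` and `stats` matrices,
#'   the model name, `n_loci` and the chunk seed schedule.
#' @export
build_reference_table <- function(model, n_reps, n_loci,
                                  chunk_size = 1000L, seed = NULL) {
  if (n_reps < 1L) stop("n_reps must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  n_chunks <- ceiling(n_reps / chunk_size)
  chunk_seeds <- sample.int(.Machine$integer.max - 1L, n_chunks)
  sizes <- rep(chunk_size, n_chunks)
  sizes[n_chunks] <- n_reps - chunk_size * (n_chunks - 1L)
  chunks <- vector("list", n_chunks)
  for (k in seq_len(n_chunks))
    chunks[[k]] <- build_reference_chunk(model, sizes[k], n_loci, chunk_seeds[k])
  out <- do.call(combine_reference_tables, chunks)
  out$chunk_seeds <- chunk_seeds
  out
}

#' @rdname build_reference_table
#' @param chunk_seed seed for this chunk.
#' @export
build_reference_chunk <- function(model, n_reps, n_loci, chunk_seed) {
  set.seed(chunk_seed)
  pn <- param_names(model)
  pops <- names(model$sampling)
  sn <- stat_names(pops)
  params <- matrix(NA_real_, n_reps, length(pn), dimnames = list(NULL, pn))
  stats_m <- matrix(NA_real_, n_reps, length(sn), dimnames = list(NULL, sn))
  csamp <- cumsum(model$sampling)
  idx <- stats::setNames(mapply(function(a, b) seq.int(a, b),
                                c(1L, utils::head(csamp, -1L) + 1L), csamp,
                                SIMPLIFY = FALSE), pops)
  for (r in seq_len(n_reps)) {
    inst <- draw_instance(model)
    params[r, ] <- inst$params[pn]
    stats_m[r, ] <- simulate_stats(inst, n_loci, idx)
  }
  structure(list(model = model$name, params = params, stats = stats_m,
                 n_loci = n_loci, chunk_seeds = chunk_seed),
            class = "ref_table")
}

#' Concatenate reference tables of the same model
#' @param ... `ref_table` objects with identical layouts.
#' @return A single `ref_table`.
#' @export
combine_reference_tables <- function(...) {
  parts <- list(...)
  ref <- parts[[1L]]
  for (p in parts[-1L]) {
    if (!identical(p$model, ref$model) ||
        !identical(colnames(p$stats), colnames(ref$stats)) ||
        !identical(colnames(p$params), colnames(ref$params)))
      stop("reference tables have incompatible layouts")
  }
  structure(list(model = ref$model,
                 params = do.call(rbind, lapply(parts, `[[`, "params")),
                 stats = do.call(rbind, lapply(parts, `[[`, "stats")),
                 n_loci = ref$n_loci,
                 chunk_seeds = unlist(lapply(parts, `[[`, "chunk_seeds"))),
            class = "ref_table")
}

#' @export
print.ref_table <- function(x, ...) {
  cat("ref_table:", x$model, "-", nrow(x$stats), "replicates x",
      ncol(x$stats), "statistics (", ncol(x$params), "parameters,",
      x$n_loci, "loci/replicate )\n")
  invisible(x)
}

#' Write / read a reference table (TSV + YAML manifest sidecar)
#'
#' @param rt a `ref_table`.
#' @param path base path; writes `<path>.tsv` and `<path>.manifest.yaml`.
#' @return `write_reference_table` invisibly returns the base path;
#'   `read_reference_table` returns the `ref_table`.
#' @export
write_reference_table <- function(rt, path) {
  df <- data.frame(rt$params, rt$stats, check.names = FALSE)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  yaml::write_yaml(list(model = rt$model, n_reps = nrow(rt$stats),
                        n_loci = rt$n_loci,
                        n_params = ncol(rt$params),
                        param_names = colnames(rt$params),
                        stat_names = colnames(rt$stats),
                        chunk_seeds = as.integer(rt$chunk_seeds),
                        layout_version = 1L),
                   paste0(path, ".manifest.yaml"))
  invisible(path)
}

#' @rdname write_reference_table
#' @export
read_reference_table <- function(path) {
  man <- yaml::read_yaml(paste0(path, ".manifest.yaml"))
  df <- utils::read.table(paste0(path, ".tsv"), header = TRUE, sep = "\t",
                          check.names = FALSE)
  structure(list(model = man$model,
                 params = as.matrix(df[, man$param_names, drop = FALSE]),
                 stats = as.matrix(df[, man$stat_names, drop = FALSE]),
                 n_loci = man$n_loci,
                 chunk_seeds = man$chunk_seeds),
            class = "ref_table")
}
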