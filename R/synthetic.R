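#' Default study-shaped scenario
#'
#' An 18-population layout emulating the shape of a Great Lakes invasion
#' survey: ten lake/bay "source" locations whose contemporary effective
#' sizes share a hyperprior, plus three inland river chains behind dispersal
#' barriers (a three-step reservoir chain founded from a bay; two impounded
#' river segments founded separately plus one downstream segment; and a
#' two-lake east-to-west chain).  Source foundings are shipping-assisted
#' (`SF` severity class), inland foundings are river foundings (`RF`), and
#' all founding times are recent (4-12 generations before sampling,
#' consistent with a <20-generation invasion window at 2 years per
#' generation).
#'
#' @param n_individuals diploid sample size per population (default 25).
#' @return A [scenario_model()].
#' @export
default_study_model <- function(n_individuals = 25L) {
  sources <- c("ALP", "CBR", "GTB", "LKE", "LTB", "MGL", "PWL", "RGC", "SAB")
  inland <- c("HWR", "MTL", "BML", "FCP", "CDP", "FDP", "MLL", "BTL")
  demes <- c(list(STC = list(hyper = "gl_ne")),
             stats::setNames(rep(list(list(hyper = "gl_ne")), length(sources)),
                             sources),
             stats::setNames(rep(list(prior_spec("loguniform", 10, 1000)),
                                 length(inland)), inland))
  sampling <- stats::setNames(rep(n_individuals, length(demes)), names(demes))
  ev <- function(t, der, src, cl) list(time = t, derived = der, source = src,
                                       severity = cl, class = cl)
  events <- c(lapply(sources, function(s) ev(12, s, "STC", "SF")),
              list(ev(10, "HWR", "SAB", "RF"), ev(6, "MTL", "HWR", "RF"),
                   ev(4, "BML", "MTL", "RF"),
                   ev(9, "FCP", "SAB", "RF"), ev(9, "CDP", "SAB", "RF"),
                   ev(5, "FDP", "CDP", "RF"),
                   ev(8, "MLL", "CBR", "RF"), ev(5, "BTL", "MLL", "RF")))
  scenario_model(
    name = "study_shaped",
    demes = demes, sampling = sampling, events = events,
    hyperpriors = list(gl_ne = prior_spec("loguniform", 500, 5000)),
    class_priors = list(SF = prior_spec("uniform", 0.05, 0.5),
                        RF = prior_spec("uniform", 0.005, 0.3)))
}

#' Default ground-truth parameters for the study-shaped scenario
#'
#' Truth values sit in the regime recent-invasion analyses report: large
#' source effective sizes (~10^3), inland sizes ~10^2, strong river-founding
#' bottlenecks (3% of contemporary Ne) and milder shipping-assisted ones
#' (15%), so recovery tests probe the relevant corner of parameter space.
#'
#' @param model the scenario (default [default_study_model()]).
#' @return Named numeric parameter vector.
#' @export
default_study_truth <- function(model = default_study_model()) {
  p <- stats::setNames(numeric(0), character(0))
  p["HYP_gl_ne"] <- 1000
  inland_ne <- c(HWR = 70, MTL = 200, BML = 250, FCP = 150, CDP = 150,
                 FDP = 150, MLL = 250, BTL = 400)
  for (d in names(model$demes)) {
    ne <- model$demes[[d]]
    p[paste0("Ne_", d)] <- if (is.list(ne) && !is.null(ne$hyper)) 1000
                           else unname(inland_ne[d])
  }
  p["SEV_SF"] <- 0.15
  p["SEV_RF"] <- 0.03
  p
}

#' Specification for a synthetic observed study
#'
#' Bundles the true scenario, the true parameter values, the panel size and
#' the per-population call-rate schedule under which a synthetic "observed"
#' dataset is generated.  Call rates must stay at or above the downstream
#' filter threshold, otherwise dataset generation refuses to proceed.
#'
#' @param model true scenario (default [default_study_model()]).
#' @param truth named parameter vector (default [default_study_truth()]).
#' @param n_loci SNP panel size (default 2,312).
#' @param call_rates per-population call rates in `[min_callrate, 1]`;
#'   default an evenly spaced schedule over 0.85-0.98.
#' @param min_callrate downstream filter floor the schedule must respect.
#' @param seed RNG seed for the whole generation step.
#' @return Object of class `synthetic_study_spec`.
#' @export
synthetic_study_spec <- function(model = default_study_model(),
                                 truth = default_study_truth(model),
                                 n_loci = 2312L, call_rates = NULL,
                                 min_callrate = 0.8, seed = 1L) {
  pops <- names(model$sampling)
  if (is.null(call_rates))
    call_rates <- stats::setNames(seq(0.85, 0.98, length.out = length(pops)), pops)
  call_rates <- call_rates[pops]
  if (anyNA(call_rates)) stop("call_rates must cover every population")
  if (any(call_rates < min_callrate) || any(call_rates > 1))
    stop("call-rate schedule incompatible with downstream filters: ",
         "rates must lie in [", min_callrate, ", 1]")
  structure(list(model = model, truth = truth, n_loci = as.integer(n_loci),
                 call_rates = call_rates, min_callrate = min_callrate,
                 seed = as.integer(seed)),
            class = "synthetic_study_spec")
}

#' Generate a synthetic observed study (VCF + popmap + truth manifest)
#'
#' Simulates a complete dataset under the true scenario instance, injects
#' missingness uniformly at random within each population according to the
#' call-rate schedule, and writes standard files: a plain-text VCF, a
#' two-column population map, and a YAML truth manifest recording the model,
#' parameters, seed and schedule.  Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_study_spec()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a list with `vcf`, `popmap`, `truth` paths and the
#'   truth parameter vector.
#' @export
generate_study <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  set.seed(spec$seed)
  inst <- scenario_instance(spec$model, spec$truth)
  ds <- simulate_dataset(inst, spec$n_loci)
  geno <- ds$genotypes
  for (p in names(spec$call_rates)) {
    r <- spec$call_rates[[p]]
    if (r >= 1) next
    cols <- which(ds$pop_of == p)
    drop <- matrix(stats::runif(nrow(geno) * length(cols)) > r,
                   nrow(geno), length(cols))
    geno[, cols][drop] <- NA_integer_
  }
  ds_m <- genotype_dataset(geno, locus_ids = ds$locus_ids,
                           individual_ids = ds$individual_ids,
                           pop_of = ds$pop_of)
  paths <- list(vcf = file.path(dir, "genotypes.vcf"),
                popmap = file.path(dir, "popmap.txt"),
                truth = file.path(dir, "truth.yaml"))
  write_genotypes(ds_m, paths$vcf, paths$popmap)
  yaml::write_yaml(list(model = spec$model$name,
                        seed = spec$seed,
                        n_loci = spec$n_loci,
                        call_rates = as.list(spec$call_rates),
                        truth = as.list(spec$truth)),
                   paths$truth)
  invisible(c(paths, list(params = spec$truth)))
}

#' Separable two-model toy fixture
#'
#' Two single-founding scenarios that differ only in bottleneck severity
#' (severe, ~1%, versus mild, ~90% of contemporary Ne, over a 3-generation
#' founding bottleneck), whose statistic distributions are far apart (their
#' clusters sit several pooled SDs apart on the derived-deme diversity
#' statistics): the workhorse fixture for exercising classifier-based model
#' selection and cross-validation with a known answer.  The observed vector
#' is simulated from the severe model and the truth is recorded in the
#' returned manifest.
#'
#' @param n_per_model reference-table rows per model.
#' @param n_loci loci per replicate.
#' @param seed optional seed.
#' @return List with `tables` (two `ref_table`s), `observed` (statistic
#'   vector), `truth` (name of the generating model) and `instance` (the
#'   generating instance).
#' @export
make_separable_fixture <- function(n_per_model = 1000L, n_loci = 150L,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  base <- function(name, sev_lo, sev_hi)
    scenario_model(
      name = name,
      demes = list(SRC = prior_spec("loguniform", 500, 2000),
                   DER = prior_spec("loguniform", 100, 400)),
      sampling = c(SRC = 10L, DER = 10L),
      events = list(list(time = 10, derived = "DER", source = "SRC",
                         severity = prior_spec("uniform", sev_lo, sev_hi),
                         class = "RF", duration = 3)))
  m_severe <- base("severe_bottleneck", 0.005, 0.015)
  m_mild <- base("mild_bottleneck", 0.85, 0.95)
  seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  t1 <- build_reference_table(m_severe, n_per_model, n_loci, seed = seeds[1L])
  t2 <- build_reference_table(m_mild, n_per_model, n_loci, seed = seeds[2L])
  set.seed(seeds[3L])
  inst <- draw_instance(m_severe)
  obs <- build_stat_vector(simulate_dataset(inst, n_loci),
                           names(m_severe$sampling))
  list(tables = list(t1, t2), observed = obs,
       truth = "severe_bottleneck", instance = inst)
}
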