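#' SNP genotype dataset
#'
#' Container for a loci x individuals matrix of biallelic genotype codes
#' (number of ALT-allele copies, 0/1/2, `NA` = missing) together with a
#' population assignment for every individual.  This is the common currency of
#' the whole pipeline: observed data read from VCF, subsampled complete
#' matrices, and coalescent-simulated datasets all use it.
#'
#' Allele orientation carries no meaning downstream: every summary statistic
#' is folded (minor-allele based), so codes count ALT alleles purely as a
#' storage convention.
#'
#' @param genotypes integer matrix, loci in rows, individuals in columns;
#'   entries in `{0, 1, 2, NA}`.
#' @param locus_ids unique locus identifiers (default `rownames(genotypes)`).
#' @param individual_ids unique individual identifiers (default column names).
#' @param pop_of named character vector mapping every individual id to a
#'   population label; at least two populations are required.
#' @return An object of class `genotype_dataset`.
#' @export
genotype_dataset <- function(genotypes, locus_ids = rownames(genotypes),
                             individual_ids = colnames(genotypes), pop_of) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(locus_ids)) locus_ids <- sprintf("L%05d", seq_len(nrow(genotypes)))
  if (is.null(individual_ids)) individual_ids <- sprintf("ind%04d", seq_len(ncol(genotypes)))
  locus_ids <- as.character(locus_ids)
  individual_ids <- as.character(individual_ids)
  if (anyDuplicated(locus_ids)) stop("locus ids must be unique")
  if (anyDuplicated(individual_ids)) stop("individual ids must be unique")
  if (length(locus_ids) != nrow(genotypes)) stop("locus_ids length mismatch")
  if (length(individual_ids) != ncol(genotypes)) stop("individual_ids length mismatch")
  bad <- genotypes[!is.na(genotypes)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("genotype codes must be 0, 1, 2 or NA")
  pop_of <- pop_of[individual_ids]
  if (anyNA(pop_of))
    stop("individuals missing from the population map: ",
         paste(individual_ids[is.na(pop_of)], collapse = ", "))
  pop_of <- stats::setNames(as.character(pop_of), individual_ids)
  if (length(unique(pop_of)) < 2L)
    stop("a genotype_dataset needs at least 2 populations")
  dimnames(genotypes) <- list(locus_ids, individual_ids)
  structure(list(genotypes = genotypes, locus_ids = locus_ids,
                 individual_ids = individual_ids, pop_of = pop_of),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  nm <- sum(is.na(x$genotypes))
  cat("genotype_dataset:", nrow(x$genotypes), "loci x",
      ncol(x$genotypes), "individuals,",
      length(unique(x$pop_of)), "populations\n")
  cat(sprintf("  missing genotypes: %d (%.1f%%)\n", nm,
              100 * nm / length(x$genotypes)))
  tb <- table(x$pop_of)
  cat("  populations:", paste(sprintf("%s(%d)", names(tb), tb), collapse = " "), "\n")
  invisible(x)
}

#' Population labels of a dataset
#' @param ds a `genotype_dataset`.
#' @return Character vector of population labels in order of first appearance.
#' @export
populations <- function(ds) unique(unname(ds$pop_of))

pop_indices <- function(ds, pop_order = populations(ds)) {
  lapply(stats::setNames(pop_order, pop_order),
         function(p) which(ds$pop_of == p))
}

#' Read SNP genotypes from a VCF file and a population map
#'
#' Consumes only the GT field of a VCF v4.x file.  Genotype codes count ALT
#' alleles; half-missing diploid calls (e.g. `0/.`) are treated as missing;
#' phasing is ignored (`0|1` equals `0/1`).  Multiallelic records are a hard
#' error unless `skip_multiallelic = TRUE`, in which case they are dropped
#' with a message.  Depth-based filtering is an upstream (genotyper)
#' responsibility; the VCF is taken at face value.
#'
#' @param vcf path to a VCF file (plain or bgzipped).
#' @param popmap path to a two-column whitespace/tab-delimited text file:
#'   individual id, population label.  Every VCF sample must appear.
#' @param skip_multiallelic drop multiallelic records instead of erroring.
#' @return A [genotype_dataset()].
#' @export
read_genotypes <- function(vcf, popmap, skip_multiallelic = FALSE) {
  v <- vcfR::read.vcfR(vcf, verbose = FALSE)
  samples <- colnames(v@gt)[-1]
  pm <- utils::read.table(popmap, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "pop"))
  missing <- setdiff(samples, pm$id)
  if (length(missing))
    stop("VCF sample(s) absent from the population map: ",
         paste(missing, collapse = ", "))

  alt <- v@fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE) | is.na(alt) | alt == "."
  if (any(multi)) {
    if (!skip_multiallelic)
      stop(sum(multi), " multiallelic/invalid site(s) found; ",
           "set skip_multiallelic = TRUE to drop them")
    message("dropping ", sum(multi), " multiallelic site(s)")
    v <- v[!multi, ]
  }

  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  code <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  geno <- matrix(code[gt], nrow = nrow(gt), ncol = ncol(gt))

  ids <- v@fix[, "ID"]
  pos_ids <- paste0(v@fix[, "CHROM"], "_", v@fix[, "POS"])
  ids <- ifelse(is.na(ids) | ids == ".", pos_ids, ids)
  if (anyDuplicated(ids)) ids <- make.unique(ids)

  genotype_dataset(geno, locus_ids = ids, individual_ids = samples,
                   pop_of = stats::setNames(pm$pop, pm$id))
}

#' Write a genotype dataset to VCF and population-map files
#'
#' Emits a minimal plain-text VCF v4.2 (GT field only) plus the matching
#' two-column population map; [read_genotypes()] on the output recovers the
#' same genotype codes.
#'
#' @param ds a `genotype_dataset`.
#' @param vcf,popmap output paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_genotypes <- function(ds, vcf, popmap) {
  gt_str <- matrix(c("0/0", "0/1", "1/1")[ds$genotypes + 1L],
                   nrow = nrow(ds$genotypes))
  gt_str[is.na(ds$genotypes)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              "##source=invabc",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ds$individual_ids), collapse = "\t"))
  body <- paste("1", seq_len(nrow(gt_str)), ds$locus_ids, "A", "G", ".",
                "PASS", ".", "GT",
                apply(gt_str, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf)
  utils::write.table(data.frame(ds$individual_ids, unname(ds$pop_of)),
                     popmap, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(vcf = vcf, popmap = popmap))
}

#' Filter loci on per-population call rate
#'
#' Retains exactly those loci for which the number of populations with a
#' per-population call rate of at least `min_callrate` is at least
#' `min_pops`; locus order is preserved.  The defaults mirror a common
#' RAD-seq inclusion rule: genotyped in 80% of individuals within a
#' population, in at least 15 of 18 populations.
#'
#' @param ds a `genotype_dataset`.
#' @param min_callrate minimum within-population call rate, in (0, 1].
#' @param min_pops minimum number of populations meeting `min_callrate`;
#'   must not exceed the number of populations in `ds`.
#' @return The filtered `genotype_dataset`.
#' @export
filter_loci <- function(ds, min_callrate = 0.8, min_pops = 15L) {
  if (!(min_callrate > 0 && min_callrate <= 1))
    stop("min_callrate must be in (0, 1]")
  idx <- pop_indices(ds)
  if (min_pops > length(idx))
    stop("min_pops exceeds the number of populations (", length(idx), ")")
  cr <- vapply(idx, function(ix)
    rowMeans(!is.na(ds$genotypes[, ix, drop = FALSE])), numeric(nrow(ds$genotypes)))
  keep <- rowSums(cr >= min_callrate) >= min_pops
  if (!any(keep))
    stop("no locus passes the call-rate filter; ",
         "relax min_callrate or min_pops")
  genotype_dataset(ds$genotypes[keep, , drop = FALSE],
                   locus_ids = ds$locus_ids[keep],
                   individual_ids = ds$individual_ids, pop_of = ds$pop_of)
}

#' Population map with subsampling targets
#'
#' Records, per population, which individuals belong to it and how many
#' genotypes to draw per locus when building a complete matrix.  The default
#' target is `floor(fraction * sample size)`: taking the floor guarantees
#' feasibility when loci were filtered at exactly the same call-rate
#' threshold.
#'
#' @param ds a `genotype_dataset`.
#' @param fraction subsampling fraction, in (0, 1].
#' @param target_n optional named integer vector overriding the computed
#'   targets (names = population labels).
#' @return An object of class `population_map` with fields `labels`,
#'   `members` and `target_n`.
#' @export
population_map <- function(ds, fraction = 0.8, target_n = NULL) {
  labels <- populations(ds)
  members <- lapply(stats::setNames(labels, labels),
                    function(p) ds$individual_ids[ds$pop_of == p])
  if (is.null(target_n)) {
    target_n <- vapply(members, function(m) as.integer(floor(fraction * length(m))),
                       integer(1))
  } else {
    target_n <- vapply(stats::setNames(labels, labels),
                       function(p) as.integer(target_n[[p]]), integer(1))
  }
  if (any(target_n < 2L))
    stop("subsampling target below 2 for population(s): ",
         paste(labels[target_n < 2L], collapse = ", "))
  structure(list(labels = labels, members = members, target_n = target_n),
            class = "population_map")
}

#' @export
print.population_map <- function(x, ...) {
  cat("population_map:", length(x$labels), "populations\n")
  for (p in x$labels)
    cat(sprintf("  %s: %d individuals, target %d\n", p,
                length(x$members[[p]]), x$target_n[[p]]))
  invisible(x)
}

#' Subsample genotypes into a complete (no-missing) matrix
#'
#' For every locus and population, draws exactly `target_n` non-missing
#' genotypes without replacement.  Sampling is independent across loci: the
#' procedure deliberately breaks within-individual associations between loci
#' (only per-locus allele counts and frequencies feed the downstream
#' statistics, so nothing the pipeline uses is affected).  Columns of the
#' output are therefore pseudo-individuals.  Identical RNG state gives
#' identical output.
#'
#' @param ds a `genotype_dataset` (typically after [filter_loci()]).
#' @param pm a [population_map()] for `ds`.
#' @return A complete `genotype_dataset` with `sum(target_n)` columns.
#' @export
subsample_complete <- function(ds, pm) {
  idx <- pop_indices(ds, pm$labels)
  n_loci <- nrow(ds$genotypes)
  out_cols <- sum(pm$target_n)
  out <- matrix(NA_integer_, n_loci, out_cols)
  col0 <- 0L
  new_pop <- character(out_cols)
  for (p in pm$labels) {
    cols <- idx[[p]]
    tn <- pm$target_n[[p]]
    sub <- ds$genotypes[, cols, drop = FALSE]
    ok <- !is.na(sub)
    n_ok <- rowSums(ok)
    if (any(n_ok < tn)) {
      l <- which(n_ok < tn)[1L]
      stop("locus ", ds$locus_ids[l], " has only ", n_ok[l],
           " non-missing genotypes in population ", p,
           " (need ", tn, "); run filter_loci with compatible thresholds")
    }
    for (l in seq_len(n_loci)) {
      avail <- which(ok[l, ])
      pick <- if (length(avail) == tn) sample(avail) else
        sample(avail, tn)
      out[l, col0 + seq_len(tn)] <- sub[l, pick]
    }
    new_pop[col0 + seq_len(tn)] <- p
    col0 <- col0 + tn
  }
  ids <- paste0(new_pop, "_", unlist(lapply(pm$target_n, seq_len)))
  genotype_dataset(out, locus_ids = ds$locus_ids, individual_ids = ids,
                   pop_of = stats::setNames(new_pop, ids))
}

is_complete <- function(ds) !anyNA(ds$genotypes)
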