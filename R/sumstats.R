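#' @useDynLib invabc, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# ---- internal fast paths -----------------------------------------------
# All statistics operate on a complete genotype matrix (loci x individuals)
# plus a list of column indices per population.  The user-facing operations
# wrap these with validation; the reference-table builder calls them directly.

pop_alt_counts <- function(geno, idx) {
  m <- vapply(idx, function(ix) rowSums(geno[, ix, drop = FALSE]),
              numeric(nrow(geno)))
  if (nrow(geno) == 1L) m <- matrix(m, nrow = 1L,
                                    dimnames = list(NULL, names(idx)))
  m
}

freq_matrix <- function(geno, idx) {
  n <- vapply(idx, length, integer(1))
  sweep(pop_alt_counts(geno, idx), 2L, 2 * n, "/")
}

gst_from_freqs <- function(p) {
  # Nei's multilocus G_ST as a ratio of across-locus averages, unweighted
  # population contributions; clamped to [0, 1].
  hs <- rowMeans(2 * p * (1 - p))
  pbar <- rowMeans(p)
  ht <- 2 * pbar * (1 - pbar)
  mht <- mean(ht)
  if (mht == 0) return(0)
  min(max((mht - mean(hs)) / mht, 0), 1)
}

#' Canonical summary-statistic layout
#'
#' The statistic vector layout is a pure function of the ordered population
#' label list, so observed and simulated vectors are directly comparable.
#' Blocks, in order: per-population segregating-site counts `S_<pop>`,
#' private-site counts `pS_<pop>`, expected heterozygosities `He_<pop>`;
#' cross-population aggregates `S_mean`, `S_sd`, `pS_mean`, `pS_sd`,
#' `pS_total`, `He_all`; pairwise `Gst_<i>_<j>` for unordered pairs (i < j in
#' `pop_order`); `Gst_all`; then ordered-pair jSFS axis counts
#' `jSFSn_<i>_<j>` and mean private minor-allele frequencies `jSFSf_<i>_<j>`.
#'
#' @param pop_order ordered character vector of population labels.
#' @return Character vector of canonical statistic names.
#' @export
stat_names <- function(pop_order) {
  K <- length(pop_order)
  pairsU <- utils::combn(pop_order, 2L)
  ord <- expand.grid(j = pop_order, i = pop_order, stringsAsFactors = FALSE)
  ord <- ord[ord$i != ord$j, c("i", "j")]
  c(paste0("S_", pop_order), paste0("pS_", pop_order), paste0("He_", pop_order),
    "S_mean", "S_sd", "pS_mean", "pS_sd", "pS_total", "He_all",
    paste0("Gst_", pairsU[1L, ], "_", pairsU[2L, ]), "Gst_all",
    paste0("jSFSn_", ord$i, "_", ord$j),
    paste0("jSFSf_", ord$i, "_", ord$j))
}

ordered_pairs <- function(pop_order) {
  ord <- expand.grid(j = seq_along(pop_order), i = seq_along(pop_order))
  ord <- ord[ord$i != ord$j, c("i", "j")]
  as.matrix(ord)
}

stat_vector_core <- function(geno, idx) {
  K <- length(idx)
  p <- freq_matrix(geno, idx)
  poly <- p > 0 & p < 1
  S <- colSums(poly)
  pS <- colSums(poly & rowSums(poly) == 1L)
  he_loc <- 2 * p * (1 - p)
  He <- colMeans(he_loc)

  n <- vapply(idx, length, integer(1))
  ptot <- rowSums(pop_alt_counts(geno, idx)) / (2 * sum(n))
  He_all <- mean(2 * ptot * (1 - ptot))

  pairsU <- utils::combn(seq_len(K), 2L)
  gst <- numeric(ncol(pairsU))
  for (k in seq_len(ncol(pairsU)))
    gst[k] <- gst_from_freqs(p[, pairsU[, k], drop = FALSE])
  gst_all <- gst_from_freqs(p)

  ord <- ordered_pairs(names(idx))
  A <- numeric(nrow(ord))
  f <- numeric(nrow(ord))
  for (k in seq_len(nrow(ord))) {
    i <- ord[k, "i"]; j <- ord[k, "j"]
    pbar <- (p[, i] + p[, j]) / 2
    minor_alt <- pbar <= 0.5          # tie at 0.5 -> ALT designated minor
    qi <- ifelse(minor_alt, p[, i], 1 - p[, i])
    qj <- ifelse(minor_alt, p[, j], 1 - p[, j])
    axis <- qi > 0 & qj == 0
    A[k] <- sum(axis)
    f[k] <- if (A[k] > 0) mean(qi[axis]) else 0
  }

  c(S, pS, He,
    mean(S), stats::sd(S), mean(pS), stats::sd(pS), sum(pS), He_all,
    gst, gst_all, A, f)
}

# ---- user-facing operations --------------------------------------------

check_complete <- function(ds) {
  if (!inherits(ds, "genotype_dataset")) stop("expected a genotype_dataset")
  if (!is_complete(ds))
    stop("dataset contains missing genotypes; run subsample_complete() first")
}

#' Per-population per-locus ALT allele frequencies
#'
#' @param ds a complete `genotype_dataset`.
#' @param pop_order population order (default: order of first appearance).
#' @return Numeric matrix, loci x populations, of ALT-allele frequencies.
#' @export
allele_freqs <- function(ds, pop_order = populations(ds)) {
  check_complete(ds)
  p <- freq_matrix(ds$genotypes, pop_indices(ds, pop_order))
  rownames(p) <- ds$locus_ids
  p
}

#' Expected heterozygosity per population and overall
#'
#' Per locus, He = 2p(1-p); per population, the mean over all retained loci
#' (monomorphic loci contribute 0, which keeps He comparable across
#' populations with different numbers of segregating sites).  The overall
#' value uses pooled-sample allele frequencies.
#'
#' @inheritParams allele_freqs
#' @return List with `He` (named per-population vector) and `He_all`.
#' @export
expected_het <- function(ds, pop_order = populations(ds)) {
  check_complete(ds)
  idx <- pop_indices(ds, pop_order)
  p <- freq_matrix(ds$genotypes, idx)
  n <- vapply(idx, length, integer(1))
  ptot <- rowSums(pop_alt_counts(ds$genotypes, idx)) / (2 * sum(n))
  list(He = colMeans(2 * p * (1 - p)),
       He_all = mean(2 * ptot * (1 - ptot)))
}

#' Segregating (polymorphic) locus counts per population
#'
#' A locus counts toward `S_i` iff its frequency in population i is strictly
#' between 0 and 1.  The across-population SD uses the n-1 denominator and is
#' `NA` for a single population.
#'
#' @inheritParams allele_freqs
#' @return List with `S` (per population), `mean` and `sd`.
#' @export
count_segregating <- function(ds, pop_order = populations(ds)) {
  check_complete(ds)
  p <- freq_matrix(ds$genotypes, pop_indices(ds, pop_order))
  S <- colSums(p > 0 & p < 1)
  list(S = S, mean = mean(S), sd = stats::sd(S))
}

#' Private polymorphic site counts per population
#'
#' A locus is private to population i when it is polymorphic in i and
#' monomorphic in every other population.
#'
#' @inheritParams allele_freqs
#' @return List with `pS` (per population), `mean`, `sd` and `total`.
#' @export
count_private <- function(ds, pop_order = populations(ds)) {
  check_complete(ds)
  p <- freq_matrix(ds$genotypes, pop_indices(ds, pop_order))
  poly <- p > 0 & p < 1
  pS <- colSums(poly & rowSums(poly) == 1L)
  list(pS = pS, mean = mean(pS), sd = stats::sd(pS), total = sum(pS))
}

#' Pairwise and total multilocus G_ST
#'
#' Nei's heterozygosity-based differentiation measure,
#' \eqn{G_{ST} = (\bar H_T - \bar H_S)/\bar H_T}, computed as a ratio of
#' across-locus averages with unweighted population contributions (sample
#' sizes are near-equal after subsampling, and the same estimator is applied
#' to observed and simulated data, so small-sample bias cancels in the ABC
#' distance).  Values are clamped to the unit interval; a pair jointly monomorphic at
#' every locus yields 0 with a warning.
#'
#' @inheritParams allele_freqs
#' @return List with `Gst` (named vector over unordered pairs `i_j`) and
#'   `Gst_all` over all populations.
#' @export
pairwise_gst <- function(ds, pop_order = populations(ds)) {
  check_complete(ds)
  p <- freq_matrix(ds$genotypes, pop_indices(ds, pop_order))
  pairsU <- utils::combn(seq_along(pop_order), 2L)
  gst <- numeric(ncol(pairsU))
  for (k in seq_len(ncol(pairsU))) {
    sub <- p[, pairsU[, k], drop = FALSE]
    pbar <- rowMeans(sub)
    if (all(2 * pbar * (1 - pbar) == 0))
      warning("populations ", pop_order[pairsU[1L, k]], " and ",
              pop_order[pairsU[2L, k]],
              " are jointly monomorphic at all loci; G_ST reported as 0")
    gst[k] <- gst_from_freqs(sub)
  }
  names(gst) <- paste0(pop_order[pairsU[1L, ]], "_", pop_order[pairsU[2L, ]])
  list(Gst = gst, Gst_all = gst_from_freqs(p))
}

#' Joint-SFS axis statistics for ordered population pairs
#'
#' For each ordered pair (i, j) the minor allele is defined per locus from
#' the pooled pair (unweighted mean frequency; a tie at 0.5 designates the
#' ALT allele minor, keeping vectors deterministic).  A locus counts toward
#' the axis count `A_ij` iff its minor allele segregates in i (frequency > 0)
#' and is absent from j (frequency exactly 0); `f_ij` is the mean minor-allele
#' frequency in i over those loci (0 when `A_ij = 0`).  These statistics carry
#' directional information about gene flow between the pair.
#'
#' @inheritParams allele_freqs
#' @return Data frame with columns `from`, `to`, `A` and `f`.
#' @export
jsfs_axis_stats <- function(ds, pop_order = populations(ds)) {
  check_complete(ds)
  p <- freq_matrix(ds$genotypes, pop_indices(ds, pop_order))
  ord <- ordered_pairs(pop_order)
  out <- data.frame(from = pop_order[ord[, "i"]], to = pop_order[ord[, "j"]],
                    A = 0, f = 0, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(ord))) {
    i <- ord[k, "i"]; j <- ord[k, "j"]
    pbar <- (p[, i] + p[, j]) / 2
    minor_alt <- pbar <= 0.5
    qi <- ifelse(minor_alt, p[, i], 1 - p[, i])
    qj <- ifelse(minor_alt, p[, j], 1 - p[, j])
    axis <- qi > 0 & qj == 0
    out$A[k] <- sum(axis)
    out$f[k] <- if (any(axis)) mean(qi[axis]) else 0
  }
  out
}

#' Build the canonical summary-statistic vector
#'
#' Concatenates every statistic of the battery in the canonical order given
#' by [stat_names()].  Using the same `pop_order` on observed and simulated
#' data yields directly comparable vectors.
#'
#' @param ds a complete `genotype_dataset`.
#' @param pop_order ordered population labels; must cover exactly the
#'   populations present in `ds`.
#' @return Named numeric vector of class `stat_vector`.
#' @export
build_stat_vector <- function(ds, pop_order = populations(ds)) {
  check_complete(ds)
  have <- populations(ds)
  if (!setequal(pop_order, have) || length(pop_order) != length(have))
    stop("pop_order does not match the populations in the dataset")
  v <- stat_vector_core(ds$genotypes, pop_indices(ds, pop_order))
  structure(stats::setNames(v, stat_names(pop_order)),
            class = c("stat_vector", "numeric"), pop_order = pop_order)
}

#' Write / read a statistic vector as single-row TSV
#'
#' @param sv a named statistic vector.
#' @param path output path.
#' @return `write_stat_vector` invisibly returns `path`; `read_stat_vector`
#'   returns the named numeric vector.
#' @export
write_stat_vector <- function(sv, path) {
  df <- as.data.frame(as.list(unclass(sv)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stat_vector
#' @export
read_stat_vector <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  unlist(df[1L, , drop = TRUE])
}

#' Group means and standard deviations of per-population values
#'
#' Unweighted group means with n-1 standard deviations; singleton groups get
#' `NA` SD.  Used, e.g., to aggregate per-location expected heterozygosity
#' into basin-level summaries.
#'
#' @param values named numeric vector of per-population values.
#' @param grouping named character vector mapping population label to group.
#' @return Data frame with columns `group`, `n`, `mean`, `sd`.
#' @export
summarize_diversity <- function(values, grouping) {
  g <- grouping[names(values)]
  if (anyNA(g)) stop("grouping missing for: ",
                     paste(names(values)[is.na(g)], collapse = ", "))
  groups <- unique(unname(g))
  out <- data.frame(group = groups, n = NA_integer_,
                    mean = NA_real_, sd = NA_real_)
  for (k in seq_along(groups)) {
    x <- values[g == groups[k]]
    out$n[k] <- length(x)
    out$mean[k] <- mean(x)
    out$sd[k] <- stats::sd(x)
  }
  out
}
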