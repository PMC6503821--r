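make_ds <- function(geno, pops) {
  ids <- paste0(pops, "_", seq_along(pops))
  genotype_dataset(geno, individual_ids = ids, pop_of = setNames(pops, ids))
}

test_that("allele frequencies are ALT-allele fractions per population", {
  # pop of 2 diploids with codes (1, 2) -> p = 0.75
  geno <- rbind(c(1L, 2L, 0L, 0L), c(0L, 0L, 2L, 2L), c(0L, 0L, 0L, 0L))
  ds <- make_ds(geno, c("A", "A", "B", "B"))
  p <- allele_freqs(ds)
  expect_equal(unname(p[, "A"]), c(0.75, 0, 0))
  expect_equal(unname(p[, "B"]), c(0, 1, 0))
  # missing data must be rejected with a pointer to subsampling
  geno[1, 1] <- NA
  dsm <- make_ds(geno, c("A", "A", "B", "B"))
  expect_error(allele_freqs(dsm), "subsample_complete")
})

test_that("expected heterozygosity matches hand computation and pooled overall", {
  # single locus p = 0.5 -> He = 0.5 (symmetry maximum)
  geno <- rbind(c(1L, 1L, 1L, 1L))
  expect_equal(unname(expected_het(make_ds(geno, c("A", "A", "B", "B")))$He),
               c(0.5, 0.5))
  # loci with p = (0.25, 0) in A -> He_A = mean(0.375, 0) = 0.1875
  geno2 <- rbind(c(1L, 0L, 2L, 2L), c(0L, 0L, 1L, 1L))
  he <- expected_het(make_ds(geno2, c("A", "A", "B", "B")))
  expect_equal(unname(he$He["A"]), 0.1875)
  # overall uses pooled-sample frequencies
  pt <- c(sum(geno2[1, ]) / 8, sum(geno2[2, ]) / 8)
  expect_equal(he$He_all, mean(2 * pt * (1 - pt)))
})

test_that("segregating and private site counts follow their definitions", {
  # A freqs over 3 loci: 0, 0.3, 1 -> S_A = 1; B segregates only at locus 1
  geno <- rbind(c(0L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L),
                c(1L, 1L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),
                c(2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L, 2L))
  pops <- rep(c("A", "B"), each = 5)
  cs <- count_segregating(make_ds(geno, pops))
  expect_equal(unname(cs$S), c(1, 1))
  # mean/SD across populations use the n-1 denominator: S = (2, 4)
  geno2 <- rbind(c(1L, 0L, 1L, 0L), c(1L, 0L, 1L, 0L),
                 c(0L, 0L, 1L, 0L), c(0L, 0L, 1L, 0L))
  cs2 <- count_segregating(make_ds(geno2, c("A", "A", "B", "B")))
  expect_equal(cs2$mean, 3)
  expect_equal(cs2$sd, sqrt(2))
  # all-monomorphic dataset
  cs3 <- count_segregating(make_ds(matrix(0L, 3, 4), c("A", "A", "B", "B")))
  expect_equal(unname(cs3$S), c(0, 0))

  # private sites: polymorphic in exactly one population
  geno3 <- rbind(c(1L, 0L, 0L, 0L, 0L, 0L),   # private to A
                 c(1L, 0L, 1L, 0L, 0L, 0L),   # polymorphic in A and B
                 c(0L, 0L, 0L, 0L, 2L, 2L))   # monomorphic everywhere
  cp <- count_private(make_ds(geno3, rep(c("A", "B", "C"), each = 2)))
  expect_equal(unname(cp$pS), c(1, 0, 0))
  expect_equal(cp$total, sum(cp$pS))
})

test_that("pairwise G_ST equals Nei's ratio-of-averages hand computations", {
  # one locus, p_A = 0.2, p_B = 0.8: H_S = 0.32, H_T = 0.5, Gst = 0.36
  geno <- rbind(c(1L, 1L, 0L, 0L, 0L, 2L, 2L, 2L, 1L, 1L))
  pops <- rep(c("A", "B"), each = 5)
  g <- pairwise_gst(make_ds(geno, pops))
  expect_equal(unname(g$Gst["A_B"]), 0.36)
  # adding a (0.5, 0.5) locus: Gst = (0.5 - 0.41) / 0.5 = 0.18
  geno2 <- rbind(geno, c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L))
  g2 <- pairwise_gst(make_ds(geno2, pops))
  expect_equal(unname(g2$Gst["A_B"]), 0.18)
  # identical frequency vectors -> no differentiation
  geno3 <- rbind(c(1L, 0L, 1L, 0L), c(2L, 0L, 2L, 0L))
  expect_equal(unname(pairwise_gst(make_ds(geno3, c("A", "A", "B", "B")))$Gst["A_B"]), 0)
  # jointly monomorphic pair -> 0 with a warning
  expect_warning(g4 <- pairwise_gst(make_ds(matrix(0L, 2, 4), c("A", "A", "B", "B"))),
                 "monomorphic")
  expect_equal(unname(g4$Gst["A_B"]), 0)
})

test_that("adding a locus fixed for different alleles strictly increases pairwise G_ST", {
  set.seed(7)
  ds <- random_dataset(30, c("A", "B"), 6, maf = 0.4)
  g0 <- pairwise_gst(ds)$Gst["A_B"]
  geno2 <- rbind(ds$genotypes, fixed = c(rep(0L, 6), rep(2L, 6)))
  g1 <- pairwise_gst(make_ds(geno2, rep(c("A", "B"), each = 6)))$Gst["A_B"]
  expect_gt(g1, g0)
})

test_that("jSFS axis statistics follow the pooled-pair minor-allele definition", {
  # locus 1: minor allele freq 0.1 in A, absent in B
  # locus 2: minor allele segregating in both -> interior cell
  geno <- rbind(c(1L, 0L, 0L, 0L, 0L, rep(0L, 5)),
                c(1L, 0L, 0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L))
  pops <- rep(c("A", "B"), each = 5)
  j <- jsfs_axis_stats(make_ds(geno, pops))
  ab <- j[j$from == "A" & j$to == "B", ]
  ba <- j[j$from == "B" & j$to == "A", ]
  expect_equal(ab$A, 1)
  expect_equal(ab$f, 0.1)
  expect_equal(ba$A, 0)
  expect_equal(ba$f, 0)
  # pooled frequency exactly 0.5: ALT designated minor deterministically
  geno3 <- rbind(c(2L, 2L, 2L, 2L, 2L, rep(0L, 5)))  # p_A = 1, p_B = 0 -> pooled 0.5 tie
  j3 <- jsfs_axis_stats(make_ds(geno3, pops))
  # ALT minor: q_A = 1 > 0, q_B = 0 -> counts toward A axis
  expect_equal(j3[j3$from == "A" & j3$to == "B", "A"], 1)
})

test_that("every statistic equals the brute-force oracle on small random matrices", {
  set.seed(17)
  for (rep in 1:8) {
    K <- sample(2:3, 1)
    pops <- LETTERS[seq_len(K)]
    n_per <- sample(2:4, 1)
    ds <- random_dataset(sample(3:5, 1), pops, n_per, maf = runif(1, 0.2, 0.6))
    o <- oracle_stats(ds$genotypes, unname(ds$pop_of))
    sv <- build_stat_vector(ds)
    expect_equal(unname(sv[paste0("S_", pops)]), unname(o$S))
    expect_equal(unname(sv[paste0("pS_", pops)]), unname(o$pS))
    expect_equal(unname(sv[paste0("He_", pops)]), unname(o$He))
    expect_equal(unname(sv["He_all"]), o$He_all)
    expect_equal(unname(sv["S_mean"]), mean(o$S))
    expect_equal(unname(sv["S_sd"]), sd(o$S))
    expect_equal(unname(sv["pS_total"]), sum(o$pS))
    expect_equal(unname(sv[paste0("Gst_", names(o$Gst))]), unname(o$Gst))
    expect_equal(unname(sv["Gst_all"]), o$Gst_all)
    expect_equal(unname(sv[paste0("jSFSn_", names(o$A))]), unname(o$A))
    expect_equal(unname(sv[paste0("jSFSf_", names(o$f))]), unname(o$f))
    # pS_i <= S_i always
    expect_true(all(o$pS <= o$S))
  }
})

test_that("the canonical layout has the documented length and is order-stable", {
  set.seed(19)
  ds <- random_dataset(10, c("P1", "P2"), 4)
  sv <- build_stat_vector(ds)
  expect_length(sv, 18L)  # 6 per-pop + 6 aggregate + 1 + 1 + 2 + 2
  expect_identical(names(sv), stat_names(c("P1", "P2")))
  expect_error(build_stat_vector(ds, c("P1", "P3")), "pop_order")
  # permuting individuals within a population leaves the vector unchanged
  perm <- c(sample(1:4), sample(5:8))
  ds2 <- genotype_dataset(ds$genotypes[, perm], ds$locus_ids,
                          ds$individual_ids[perm], ds$pop_of[perm])
  expect_equal(build_stat_vector(ds2, c("P1", "P2")), sv)
  # duplicating loci doubles counts but leaves He / Gst / f unchanged
  dup <- genotype_dataset(rbind(ds$genotypes, ds$genotypes),
                          c(ds$locus_ids, paste0(ds$locus_ids, "b")),
                          ds$individual_ids, ds$pop_of)
  svd <- build_stat_vector(dup, c("P1", "P2"))
  expect_equal(unname(svd["S_P1"]), 2 * unname(sv["S_P1"]))
  expect_equal(unname(svd["He_P1"]), unname(sv["He_P1"]))
  expect_equal(unname(svd["Gst_P1_P2"]), unname(sv["Gst_P1_P2"]))
  expect_equal(unname(svd["jSFSf_P1_P2"]), unname(sv["jSFSf_P1_P2"]))
})

test_that("relabeling populations permutes the statistic vector consistently", {
  set.seed(23)
  ds <- random_dataset(20, c("A", "B", "C"), 4, maf = 0.3)
  sv1 <- build_stat_vector(ds, c("A", "B", "C"))
  sv2 <- build_stat_vector(ds, c("C", "A", "B"))
  expect_equal(unname(sv2["He_A"]), unname(sv1["He_A"]))
  expect_equal(unname(sv2["Gst_C_A"]), unname(sv1["Gst_A_C"]))
  expect_equal(unname(sv2["jSFSn_B_C"]), unname(sv1["jSFSn_B_C"]))
  expect_equal(unname(sv2["Gst_all"]), unname(sv1["Gst_all"]))
})

test_that("stat vectors round-trip through the single-row TSV format", {
  set.seed(29)
  sv <- build_stat_vector(random_dataset(15, c("A", "B"), 4))
  f <- tempfile(fileext = ".tsv")
  write_stat_vector(sv, f)
  back <- read_stat_vector(f)
  expect_equal(back, setNames(as.numeric(sv), names(sv)))
})

test_that("summarize_diversity gives unweighted group means with n-1 SDs", {
  vals <- c(FDP = 0.190, CDP = 0.189, FCP = 0.196, BML = 0.137, MTL = 0.137,
            HWR = 0.116)
  grp <- c(FDP = "AuSable", CDP = "AuSable", FCP = "AuSable",
           BML = "Flint", MTL = "Flint", HWR = "Flint")
  out <- summarize_diversity(vals, grp)
  flint <- out[out$group == "Flint", ]
  expect_equal(round(flint$mean, 3), 0.130)
  expect_equal(round(flint$sd, 3), 0.012)
  # group of identical values -> SD 0; singleton group -> NA SD
  out2 <- summarize_diversity(c(a = 1, b = 1, c = 2),
                              c(a = "g1", b = "g1", c = "g2"))
  expect_equal(out2$sd[out2$group == "g1"], 0)
  expect_true(is.na(out2$sd[out2$group == "g2"]))
})
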