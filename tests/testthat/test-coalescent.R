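test_that("pairwise coalescence time has mean 2N in a constant-size deme", {
  set.seed(101)
  m2 <- scenario_model("pair",
                       demes = list(A = prior_spec("uniform", 1000 - 1e-4, 1000 + 1e-4)),
                       sampling = c(A = 1L), events = list())
  inst2 <- draw_instance(m2)
  tmrca <- replicate(10000, max(simulate_genealogy(inst2)$time))
  # E[T2] = 2N generations; exponential, SE = 2N / sqrt(reps)
  se <- 2000 / sqrt(10000)
  expect_lt(abs(mean(tmrca) - 2000), 3 * se)
})

test_that("a severity ~1, duration-0 founding event is a null event for root times", {
  set.seed(103)
  null_ev <- panmictic_model(500, 5L, 5L)
  single <- scenario_model("single",
                           demes = list(A = prior_spec("uniform", 500 - 1e-4, 500 + 1e-4)),
                           sampling = c(A = 10L), events = list())
  i1 <- draw_instance(null_ev)
  i2 <- draw_instance(single)
  t1 <- replicate(1000, max(simulate_genealogy(i1)$time))
  t2 <- replicate(1000, max(simulate_genealogy(i2)$time))
  expect_gt(ks.test(t1, t2)$p.value, 0.01)
})

test_that("no cross-deme coalescence predates the founding time without migration", {
  m <- divergence_model(N = 300, t_split = 10, n_dip = 5L)
  set.seed(107)
  inst <- draw_instance(m)
  for (r in 1:50) {
    g <- simulate_genealogy(inst)
    n <- g$n_tips
    # earliest common ancestor of tips from different demes must be >= 10
    anc_times <- function(tip) {
      v <- tip; out <- integer(0)
      while (!is.na(g$parent[v])) { v <- g$parent[v]; out <- c(out, v) }
      out
    }
    a_anc <- unique(unlist(lapply(which(g$tip_deme == "A"), anc_times)))
    b_anc <- unique(unlist(lapply(which(g$tip_deme == "B"), anc_times)))
    shared <- intersect(a_anc, b_anc)
    expect_gte(min(g$time[shared]), 10)
  }
})

test_that("genealogies are binary, ultrametric from tips and rootward-increasing", {
  m <- inland_migration_model(n_dip = 4L)
  set.seed(109)
  for (r in 1:20) {
    g <- simulate_genealogy(draw_instance(m))
    n <- g$n_tips
    expect_equal(sum(is.na(g$parent)), 1L)          # single root
    expect_equal(tabulate(g$parent[!is.na(g$parent)]),
                 c(rep(0L, n), rep(2L, n - 1L)))    # binary internal nodes
    expect_true(all(g$time[seq_len(n)] == 0))       # tips contemporary
    internal <- g$parent[!is.na(g$parent)]
    expect_true(all(g$time[internal] >
                      g$time[which(!is.na(g$parent))] - 1e-12))
  }
})

test_that("single mutations give polymorphic sites; terminal branches give singletons", {
  m <- divergence_model(N = 200, t_split = 5, n_dip = 3L)
  set.seed(113)
  inst <- draw_instance(m)
  for (r in 1:200) {
    gt <- place_snp(simulate_genealogy(inst))
    total <- sum(gt)
    expect_gt(total, 0)
    expect_lt(total, 2 * length(gt))
  }
})

test_that("the conditional site frequency spectrum for n = 4 copies is (6,3,2)/11", {
  m <- panmictic_model(1000, 1L, 1L)  # 2 + 2 = 4 gene copies, panmictic
  set.seed(127)
  inst <- draw_instance(m)
  ds <- simulate_dataset(inst, 10000)
  counts <- table(factor(rowSums(ds$genotypes), levels = 1:3)) / 10000
  expected <- c(6, 3, 2) / 11
  # binomial 99% CI half-widths at 1e4 sites
  hw <- qnorm(0.995) * sqrt(expected * (1 - expected) / 10000)
  expect_true(all(abs(as.numeric(counts) - expected) < hw + 1e-9))
})

test_that("every simulated dataset is complete, polymorphic and seed-reproducible", {
  m <- inland_migration_model(n_dip = 5L)
  set.seed(131)
  inst <- draw_instance(m)
  ds <- simulate_dataset(inst, 300)
  expect_equal(nrow(ds$genotypes), 300L)
  expect_false(anyNA(ds$genotypes))
  pooled <- rowMeans(ds$genotypes) / 2
  expect_true(all(pooled > 0 & pooled < 1))
  expect_equal(sort(unique(unname(ds$pop_of))), c("INL1", "INL2", "SRC"))
  set.seed(77); d1 <- simulate_dataset(inst, 50)
  set.seed(77); d2 <- simulate_dataset(inst, 50)
  expect_identical(d1$genotypes, d2$genotypes)
})

test_that("a strong founding bottleneck depresses derived-deme heterozygosity", {
  set.seed(137)
  strong <- founding_model(0.0099, 0.0101, n_dip = 8L)
  inst <- draw_instance(strong)
  diffs <- replicate(100, {
    he <- expected_het(simulate_dataset(inst, 80))$He
    he[["DER"]] - he[["SRC"]]
  })
  tt <- t.test(diffs, alternative = "less")
  expect_lt(tt$p.value, 0.01)
})

test_that("derived-source differentiation grows as bottleneck severity drops", {
  set.seed(139)
  mean_gst <- vapply(c(0.9, 0.1, 0.01), function(s) {
    inst <- draw_instance(founding_model(s - 1e-4, s + 1e-4, n_dip = 8L))
    mean(replicate(100, pairwise_gst(simulate_dataset(inst, 60))$Gst[["SRC_DER"]]))
  }, numeric(1))
  expect_true(all(diff(mean_gst) > 0))
})

test_that("reference tables have the declared layout and chunked builds concatenate", {
  m <- founding_model(0.01, 0.3, n_dip = 4L)
  rt <- build_reference_table(m, 100, 30, seed = 5)
  expect_equal(nrow(rt$stats), 100L)
  expect_equal(colnames(rt$params), param_names(m))
  expect_identical(colnames(rt$stats), stat_names(c("SRC", "DER")))
  # chunked generation under the same master seed reproduces the one-shot run
  rt_chunked <- build_reference_table(m, 100, 30, chunk_size = 50L, seed = 5)
  set.seed(5)
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  c1 <- build_reference_chunk(m, 50, 30, seeds[1])
  c2 <- build_reference_chunk(m, 50, 30, seeds[2])
  manual <- combine_reference_tables(c1, c2)
  expect_identical(rt_chunked$stats, manual$stats)
  expect_identical(rt_chunked$params, manual$params)
})

test_that("reference tables round-trip through the TSV + manifest format", {
  m <- founding_model(0.01, 0.3, n_dip = 4L)
  rt <- build_reference_table(m, 20, 20, seed = 9)
  base <- tempfile()
  write_reference_table(rt, base)
  back <- read_reference_table(base)
  expect_equal(back$stats, rt$stats)
  expect_equal(back$params, rt$params)
  expect_equal(back$model, rt$model)
})

test_that("statistic distributions separate strong from absent bottlenecks", {
  set.seed(149)
  weak <- build_reference_table(founding_model(0.90, 0.95, n_dip = 6L), 100, 50)
  strong <- build_reference_table(founding_model(0.01, 0.05, n_dip = 6L), 100, 50)
  tt <- t.test(weak$stats[, "He_DER"], strong$stats[, "He_DER"])
  expect_lt(tt$p.value, 0.01)
})

test_that("mean pairwise G_ST matches an independent coalescent simulator", {
  # two-deme divergence model cross-checked against msprime/tskit (SNP mode)
  oracle <- system.file("oracle/msprime_gst.py", package = "invabc")
  out <- suppressWarnings(
    system2("python", c(oracle, "500", "50", "10", "100", "400", "11"),
            stdout = TRUE, stderr = FALSE))
  expect_gt(length(out), 0)
  ref <- as.numeric(out[length(out)])
  expect_false(is.na(ref))
  m <- divergence_model(N = 500, t_split = 50, n_dip = 10L)
  set.seed(151)
  inst <- draw_instance(m)
  ours <- mean(replicate(400, pairwise_gst(simulate_dataset(inst, 100))$Gst_all))
  expect_lt(abs(ours - ref) / ref, 0.10)
})

test_that("lineages stranded in an isolated deme raise a scenario error", {
  # two demes, no events, no migration: can never find a common ancestor
  m <- scenario_model("broken",
                      demes = list(A = prior_spec("uniform", 99, 100),
                                   B = prior_spec("uniform", 99, 100)),
                      sampling = c(A = 2L, B = 2L), events = list(),
                      validate = FALSE)
  set.seed(157)
  expect_error(simulate_genealogy(draw_instance(m)), "stranded")
})
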