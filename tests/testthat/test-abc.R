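toy_stats <- function(n, shift = 0, sd = 1, ncol = 4) {
  m <- matrix(rnorm(n * ncol, shift, sd), n, ncol)
  colnames(m) <- paste0("stat", seq_len(ncol))
  m
}

test_that("robust standardization has unit MAD, drops constants, reuses reference scales", {
  set.seed(201)
  m <- cbind(toy_stats(500), const = 1)
  sc <- abc_standardize(m)
  expect_identical(sc$dropped, "const")
  z <- invabc:::apply_scaling(m, sc)
  expect_equal(unname(apply(z, 2, mad)), rep(1, 4), tolerance = 1e-10)
  expect_equal(unname(apply(z, 2, median)), rep(0, 4), tolerance = 1e-10)
  # observed vector standardized with the reference scales, not its own
  obs <- c(stat1 = 100, stat2 = 0, stat3 = 0, stat4 = 0, const = 1)
  zo <- invabc:::apply_scaling(obs, sc)
  expect_equal(unname(zo[1, "stat1"]), (100 - sc$center[["stat1"]]) / sc$scale[["stat1"]])
  expect_error(abc_standardize(matrix(1, 10, 2,
                                      dimnames = list(NULL, c("a", "b")))),
               "degenerate")
})

test_that("rejection keeps the nearest tolerance fraction with index tie-breaks", {
  set.seed(203)
  m <- toy_stats(100)
  obs <- setNames(rep(0, 4), colnames(m))
  rej <- abc_reject(m, obs, 0.05)
  expect_length(rej$index, 5L)
  # they really are the 5 smallest standardized distances
  sc <- abc_standardize(m)
  z <- invabc:::apply_scaling(m, sc)
  zo <- invabc:::apply_scaling(obs, sc)
  d <- sqrt(rowSums(sweep(z, 2, zo[1, ], "-")^2))
  expect_setequal(rej$index, order(d)[1:5])
  # tolerance 1 accepts everything (posterior = prior)
  expect_length(abc_reject(m, obs, 1)$index, 100L)
  expect_error(abc_reject(m, obs, 0), "tolerance")
})

test_that("rejection at tolerance 1 reproduces prior marginals", {
  set.seed(205)
  fix <- separable_small()
  rt <- fix$tables[[1]]
  post <- rejection_params(rt, fix$observed, tolerance = 1)
  expect_equal(nrow(post$adjusted), nrow(rt$params))
  # accepted-draw marginals match fresh, independent draws from the same priors
  fresh_sev <- draw_prior(prior_spec("uniform", 0.005, 0.015), 2000)
  fresh_ne <- draw_prior(prior_spec("loguniform", 100, 400), 2000)
  expect_gt(ks.test(post$adjusted[, "SEV_DER"], fresh_sev)$p.value, 0.01)
  expect_gt(ks.test(post$adjusted[, "Ne_DER"], fresh_ne)$p.value, 0.01)
})

test_that("neural-net model selection resolves the separable fixture and sums to one", {
  set.seed(207)
  fix <- separable_small()
  # wide tolerance keeps both classes among the accepted rows
  sel <- nn_model_posterior(fix$tables, fix$observed, tolerance = 0.7)
  expect_equal(sum(sel$posterior_prob), 1, tolerance = 1e-6)
  expect_equal(names(which.max(sel$posterior_prob)), fix$truth)
  expect_gt(sel$posterior_prob[[fix$truth]], 0.9)
})

test_that("the deep multilayer topology is available and agrees on the winner", {
  set.seed(209)
  fix <- separable_small()
  sel <- suppressWarnings(
    nn_model_posterior(fix$tables, fix$observed, tolerance = 0.05,
                       hidden = rep(5L, 5L), ensemble = 2L))
  expect_equal(sum(sel$posterior_prob), 1, tolerance = 1e-6)
  expect_equal(names(which.max(sel$posterior_prob)), fix$truth)
})

test_that("two identical simulators get symmetric neural-net posteriors", {
  set.seed(211)
  m <- founding_model(0.1, 0.3, n_dip = 5L)
  t1 <- build_reference_table(m, 400, 40)
  t2 <- build_reference_table(m, 400, 40)
  t2$model <- "clone"
  # observed vectors simulated fresh, so they sit in neither reference table
  probs <- replicate(6, {
    obs <- build_stat_vector(simulate_dataset(draw_instance(m), 40),
                             c("SRC", "DER"))
    sel <- nn_model_posterior(list(t1, t2), obs, tolerance = 0.2, ensemble = 3L)
    sel$posterior_prob[[1]]
  })
  expect_lt(abs(mean(probs) - 0.5), 0.1)
})

test_that("random-forest selection returns votes, OOB error and is seed-stable", {
  set.seed(213)
  fix <- separable_small()
  sel1 <- rf_model_posterior(fix$tables, fix$observed, n_trees = 300, seed = 5)
  sel2 <- rf_model_posterior(fix$tables, fix$observed, n_trees = 300, seed = 5)
  expect_identical(sel1$votes, sel2$votes)
  expect_equal(sum(sel1$votes), 300)
  expect_equal(sel1$posterior_prob[[fix$truth]],
               sel1$votes[[fix$truth]] / 300)
  expect_gt(sel1$posterior_prob[[fix$truth]], 0.9)
  expect_lt(sel1$oob_error, 0.05)
})

test_that("Bayes factors follow Pr ratios with the strong-support flag at 3", {
  sel <- invabc:::new_selection("neural_net", 0.01,
                                c(m1 = 0.41, m2 = 0.205, m3 = 0.385))
  bf <- bayes_factors(sel)
  expect_equal(bf["m1", "m2"], 2)
  expect_false(attr(bf, "strong")["m1", "m2"])
  expect_equal(bf["m1", "m1"], 1)
  sel0 <- invabc:::new_selection("neural_net", 0.01, c(m1 = 1, m2 = 0))
  expect_equal(bayes_factors(sel0)["m1", "m2"], Inf)
})

test_that("regression adjustment concentrates on a noiseless linear relationship", {
  # parameter = linear function of one statistic + small noise
  set.seed(215)
  n <- 2000
  s1 <- runif(n, 0, 1)
  stats_m <- cbind(s1 = s1, s2 = rnorm(n), s3 = rnorm(n))
  params <- cbind(Ne_X = exp(2 + 3 * s1 + rnorm(n, 0, 0.02)))
  rt <- structure(list(model = "toy", params = params, stats = stats_m,
                       n_loci = NA), class = "ref_table")
  obs <- c(s1 = 0.5, s2 = 0, s3 = 0)
  post <- nn_adjust_params(rt, obs, tolerance = 0.1, ensemble = 3L)
  truth <- exp(2 + 3 * 0.5)
  med <- posterior_summary(post)["Ne_X", "median"]
  expect_lt(abs(med - truth) / truth, 0.05)
})

test_that("statistics carrying no information leave the posterior at the prior", {
  set.seed(217)
  n <- 3000
  stats_m <- cbind(s1 = rnorm(n), s2 = rnorm(n))
  params <- cbind(MIG_A_B = exp(runif(n, log(1e-3), log(1e-1))))
  rt <- structure(list(model = "toy", params = params, stats = stats_m,
                       n_loci = NA), class = "ref_table")
  post <- nn_adjust_params(rt, c(s1 = 0, s2 = 0), tolerance = 0.2, ensemble = 2L)
  expect_gt(ks.test(post$adjusted[, 1], params[sample(n, 500), 1])$p.value, 0.01)
})

test_that("adjusted draws always respect parameter support", {
  set.seed(219)
  fix <- separable_small()
  rt <- fix$tables[[1]]
  post <- nn_adjust_params(rt, fix$observed, tolerance = 0.2)
  sev <- post$adjusted[, "SEV_DER"]
  ne <- post$adjusted[, grep("^Ne_", colnames(post$adjusted))]
  expect_true(all(sev > 0 & sev <= 1))
  expect_true(all(ne > 0))
  expect_true(all(post$weights >= 0))
  expect_equal(sum(post$weights), 1)
})

test_that("weighted HDIs are shortest intervals: analytic, point-mass and bimodal cases", {
  set.seed(221)
  x <- runif(10000)
  w <- rep(1 / 10000, 10000)
  hdi <- invabc:::hdi_weighted(x, w, 0.95)
  expect_lt(abs(diff(hdi) - 0.95), 0.02)
  # point mass collapses to a zero-length interval at the atom
  hdi0 <- invabc:::hdi_weighted(rep(2, 50), rep(1 / 50, 50), 0.95)
  expect_equal(diff(hdi0), 0)
  expect_equal(hdi0[1], 2)
  # symmetric bimodal: HDI beats the equal-tailed interval; brute-force scan oracle
  xb <- c(rnorm(5000, -3, 0.3), rnorm(5000, 3, 0.3))
  wb <- rep(1 / 10000, 10000)
  hdib <- invabc:::hdi_weighted(xb, wb, 0.95)
  eq <- quantile(xb, c(0.025, 0.975))
  expect_lt(diff(hdib), diff(eq))
  xs <- sort(xb)
  k <- ceiling(0.95 * length(xs))
  widths <- xs[k:length(xs)] - xs[1:(length(xs) - k + 1)]
  expect_equal(unname(diff(hdib)), min(widths), tolerance = 1e-9)
})

test_that("weighted medians respect the weights", {
  expect_equal(invabc:::weighted_median(c(1, 2, 10), c(0.5, 0.3, 0.2)), 1)
  expect_equal(invabc:::weighted_median(c(1, 2, 10), c(0.2, 0.2, 0.6)), 10)
  x <- rnorm(999)
  expect_equal(invabc:::weighted_median(x, rep(1, 999)), median(x))
})
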