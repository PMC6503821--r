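# Brute-force reference implementations of every summary statistic, written
# independently of the package internals (explicit loops, no shared code),
# used to check the vectorized fast paths on small matrices.

oracle_freqs <- function(geno, pop) {
  pops <- unique(pop)
  out <- matrix(NA_real_, nrow(geno), length(pops),
                dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- which(pop == p)
    for (l in seq_len(nrow(geno))) {
      tot <- 0
      for (j in cols) tot <- tot + geno[l, j]
      out[l, p] <- tot / (2 * length(cols))
    }
  }
  out
}

oracle_stats <- function(geno, pop) {
  pops <- unique(pop)
  K <- length(pops)
  p <- oracle_freqs(geno, pop)
  S <- pS <- He <- numeric(K); names(S) <- names(pS) <- names(He) <- pops
  for (k in seq_len(K)) {
    for (l in seq_len(nrow(geno))) {
      poly_here <- p[l, k] > 0 && p[l, k] < 1
      if (poly_here) {
        S[k] <- S[k] + 1
        if (all(!(p[l, -k] > 0 & p[l, -k] < 1))) pS[k] <- pS[k] + 1
      }
      He[k] <- He[k] + 2 * p[l, k] * (1 - p[l, k]) / nrow(geno)
    }
  }
  ptot <- numeric(nrow(geno))
  for (l in seq_len(nrow(geno))) ptot[l] <- sum(geno[l, ]) / (2 * ncol(geno))
  He_all <- mean(2 * ptot * (1 - ptot))

  gst_pair <- function(cols) {
    hs <- ht <- numeric(nrow(geno))
    for (l in seq_len(nrow(geno))) {
      hl <- 0
      for (k in cols) hl <- hl + 2 * p[l, k] * (1 - p[l, k]) / length(cols)
      hs[l] <- hl
      pb <- mean(p[l, cols])
      ht[l] <- 2 * pb * (1 - pb)
    }
    if (mean(ht) == 0) 0 else min(max((mean(ht) - mean(hs)) / mean(ht), 0), 1)
  }
  gst <- c()
  for (i in seq_len(K - 1)) for (j in seq((i + 1), K))
    gst[paste0(pops[i], "_", pops[j])] <- gst_pair(c(i, j))
  gst_all <- gst_pair(seq_len(K))

  A <- f <- c()
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    nm <- paste0(pops[i], "_", pops[j])
    cnt <- 0; fsum <- 0
    for (l in seq_len(nrow(geno))) {
      pb <- (p[l, i] + p[l, j]) / 2
      qi <- if (pb <= 0.5) p[l, i] else 1 - p[l, i]
      qj <- if (pb <= 0.5) p[l, j] else 1 - p[l, j]
      if (qi > 0 && qj == 0) { cnt <- cnt + 1; fsum <- fsum + qi }
    }
    A[nm] <- cnt
    f[nm] <- if (cnt > 0) fsum / cnt else 0
  }
  list(S = S, pS = pS, He = He, He_all = He_all, Gst = gst,
       Gst_all = gst_all, A = A, f = f)
}

# small random complete dataset
random_dataset <- function(n_loci, pops, n_per_pop, maf = 0.5) {
  ids <- paste0(rep(pops, each = n_per_pop), "_", seq_len(n_per_pop))
  geno <- matrix(rbinom(n_loci * length(ids), 2, maf), n_loci)
  genotype_dataset(geno, individual_ids = ids,
                   pop_of = setNames(rep(pops, each = n_per_pop), ids))
}

# two-deme scenario whose second deme merges into the first at t ~ 0 with
# severity ~ 1: panmictic-equivalent, used for single-population checks
panmictic_model <- function(N, n_dip_a, n_dip_b = 1L) {
  scenario_model("panmictic",
                 demes = list(A = prior_spec("uniform", N - 1e-4, N + 1e-4),
                              B = prior_spec("uniform", N - 1e-4, N + 1e-4)),
                 sampling = c(A = n_dip_a, B = n_dip_b),
                 events = list(list(time = 1e-9, derived = "B", source = "A",
                                    severity = prior_spec("uniform", 1 - 1e-9, 1),
                                    duration = 0)))
}

divergence_model <- function(N = 500, t_split = 50, n_dip = 10L) {
  scenario_model("divergence",
                 demes = list(A = prior_spec("uniform", N - 1e-4, N + 1e-4),
                              B = prior_spec("uniform", N - 1e-4, N + 1e-4)),
                 sampling = c(A = n_dip, B = n_dip),
                 events = list(list(time = t_split, derived = "B", source = "A",
                                    severity = prior_spec("uniform", 1 - 1e-9, 1),
                                    duration = 0)))
}

# source + bottlenecked derived deme, point-mass-ish priors except severity
founding_model <- function(sev_lo, sev_hi, N_src = 1000, N_der = 200,
                           t_found = 10, n_dip = 10L) {
  scenario_model("founding",
                 demes = list(SRC = prior_spec("uniform", N_src - 1e-4, N_src + 1e-4),
                              DER = prior_spec("uniform", N_der - 1e-4, N_der + 1e-4)),
                 sampling = c(SRC = n_dip, DER = n_dip),
                 events = list(list(time = t_found, derived = "DER", source = "SRC",
                                    severity = prior_spec("uniform", sev_lo, sev_hi),
                                    class = "RF")))
}

# the reconstructed 3-deme inland invasion scenario with a migration-rate
# parameter (source bay + two-step inland chain behind barriers)
inland_migration_model <- function(n_dip = 20L) {
  scenario_model("inland",
                 demes = list(SRC = prior_spec("loguniform", 500, 5000),
                              INL1 = prior_spec("loguniform", 10, 1000),
                              INL2 = prior_spec("loguniform", 10, 1000)),
                 sampling = c(SRC = n_dip, INL1 = n_dip, INL2 = n_dip),
                 events = list(list(time = 12, derived = "INL1", source = "SRC",
                                    severity = "RF", class = "RF"),
                               list(time = 8, derived = "INL2", source = "INL1",
                                    severity = "RF", class = "RF")),
                 class_priors = list(RF = prior_spec("uniform", 0.005, 0.3)),
                 migration = list(list(from = "INL2", to = "INL1",
                                       rate = prior_spec("loguniform", 1e-4, 1e-2))))
}
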