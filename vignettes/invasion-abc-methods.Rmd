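---
title: "Reconstructing recent invasion histories with coalescent ABC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing recent invasion histories with coalescent ABC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(invabc)
```

# The inference problem

A recently arrived invader has been sampled at 15--20 locations: several
large, old "source" populations (lakes, bays) and a handful of young inland
populations separated by dams.  Each candidate history of the invasion is a
*scenario*: a population tree in which every inland deme was founded exactly
once, at a known or assumed time, from some source, through a founding
bottleneck, possibly with continuous migration afterwards.  Competing
scenarios differ in which source founded which deme and in which order.
Given a SNP panel (thousands of biallelic RAD-seq loci), we want posterior
probabilities over the scenarios, posterior distributions for their
parameters, and an honest account of what is and is not identifiable this
soon after founding.

Because the likelihood of a SNP panel under such a demography is
intractable, everything runs through approximate Bayesian computation:
simulate datasets under each candidate, reduce observed and simulated data
to the same summary-statistic vector, and treat proximity in statistic space
as likelihood.

# Data preparation

`read_genotypes()` consumes only the GT field of a VCF v4.x file; genotype
codes count ALT alleles, half-missing diploid calls (`0/.`) are missing,
phasing is ignored.  Depth and quality filtering are regarded as the
genotyper's job.  `filter_loci()` applies the panel inclusion rule (default:
call rate at least 0.8 within a population, in at least `min_pops`
populations).  `subsample_complete()` then draws, for each locus and
population, exactly `floor(0.8 x sample size)` non-missing genotypes without
replacement.  The floor guarantees feasibility when the filter threshold and
the subsampling fraction coincide.  Sampling independently per locus
deliberately destroys between-locus associations within individuals; every
downstream statistic depends only on per-locus allele counts, so nothing the
pipeline uses is affected, and simulating missingness patterns is avoided
entirely.  No linkage-based statistics are computed anywhere for the same
reason.

# The statistic battery

For populations in a fixed order (the layout is a pure function of that
order; see `stat_names()`):

* per population: number of segregating loci $S_i$, number of private
  polymorphic sites $pS_i$ (polymorphic in $i$, monomorphic everywhere
  else), expected heterozygosity $He_i = \overline{2p(1-p)}$ averaged over
  *all* retained loci, so monomorphic loci contribute zero --- this keeps
  $He$ comparable between populations with different $S$;
* aggregates: mean and SD (sample SD, $n-1$) of $S_i$; mean, SD, and total
  of $pS_i$; overall $He$ from pooled-sample frequencies;
* per unordered pair: Nei's multilocus
  $G_{ST} = (\bar H_T - \bar H_S)/\bar H_T$ with $\bar H_S$ the across-locus
  mean of the unweighted average within-population heterozygosity and
  $\bar H_T$ the across-locus mean of $2\bar p(1-\bar p)$, $\bar p$ the
  unweighted mean frequency; a ratio of averages, not an average of ratios,
  which is the stable multilocus form for low-diversity loci.  No
  small-sample correction is applied: sample sizes are near-equal after
  subsampling and the same estimator is applied to observed and simulated
  data, so the bias cancels in ABC distances.  Also the total $G_{ST}$ over
  all populations in the supplied order;
* per ordered pair $(i,j)$: the number of loci whose minor allele (defined
  from the pooled pair; a tie at frequency 0.5 designates the ALT allele
  minor, keeping vectors deterministic) segregates in $i$ but is absent from
  $j$ --- loci on the axes of the pairwise joint site frequency spectrum ---
  and the mean frequency of those private minor alleles.  These carry the
  directional signal that distinguishes, say, upstream stepping-stone
  spread from a jump followed by downstream dispersal.

All components are checked in the test suite against an independent
brute-force enumeration on small matrices.

# Scenario models and priors

`scenario_model()` holds demes (contemporary $N_e$ priors, or references to
a shared hyperprior for source populations, so that "all big-lake sources
are large, with one common scale" costs one hyperparameter), diploid
sampling sizes, founding events, and migration edges.  Priors are uniform or
log-uniform.  Severity classes let several events of the same kind (SF =
shipping-assisted founding, RF = river founding) share a single severity
parameter per draw, mirroring the pooled treatment of bottleneck classes in
invasion analyses.

Founding-event semantics, backward in time: at the event time the derived
deme's size becomes `severity x contemporary Ne` for `duration` generations
(default 1), after which all remaining lineages transfer to the source deme.
This is the instantaneous-resize-plus-lineage-move construction standard in
coalescent simulators.  Event times are fixed constants by default, derived
from first-detection records divided by a generation time (default 2
years/generation); they may be given priors instead.  Migration is a
per-generation, per-lineage backward rate over an active interval; the
shipped configurations use it downstream-only across dams, since upstream
passage is blocked.  Worked configurations reconstructing named competing
hypotheses (stepping-stone versus single-jump-then-downstream for a
three-reservoir chain; east-west orderings for a two-lake chain; single
versus multiple introductions) ship under `inst/extdata/models/`; they are
labelled reconstructions with desk-scale priors, not archived analysis
files.

# Coalescent simulation and SNP ascertainment

The simulator (C++, driven by R's RNG so every result is seed-reproducible)
is a continuous-time multi-deme coalescent: within a deme of size $N_e(t)$
each lineage pair coalesces at rate $1/(2N_e)$ per generation; migration
moves single lineages at their backward rates; scheduled events resize demes
and merge them rootward.  The continuous-time approximation is standard and
accurate here even though events are recent, because the per-generation
coalescence probabilities involved are small except inside bottlenecks,
where the approximation errs on the side of slightly smoothing an already
extreme collapse.  Two structural checks anchor the implementation: mean
pairwise coalescence time $2N$ within Monte-Carlo error, and agreement of
pairwise $G_{ST}$ with an independent simulator (msprime/tskit) on a
two-deme divergence model.

Each locus is one biallelic SNP from its own genealogy.  A dataset of
$L$ loci is simulated as $L$ independent genealogies over which the $L$
segregating sites are allocated multinomially, proportional to total branch
length, with each site's mutation placed uniformly on its genealogy's
branches.  This reproduces the infinite-sites mutation process conditional
on the total number of segregating sites: the pooled conditional site
frequency spectrum is proportional to $1/i$, which the test suite verifies
against the exact $n=4$ law $(6,3,2)/11$.  The obvious simpler scheme ---
exactly one uniformly placed mutation per genealogy --- yields a subtly
different ("fixed-S") law that over-represents singletons, because it
ignores the length-biased sampling of genealogies by mutations; it is *not*
used for datasets.  The allocation means a few sites can share a genealogy
(mild linkage); no linkage statistics exist in the battery, and the same
generative law applies to reference tables and synthetic observed data, so
ABC distances compare like with like.  `place_snp()` on a single genealogy
retains the one-uniform-mutation contract for genealogy-level work.

There is no mutation-rate parameter anywhere: simulation is
polymorphism-conditional, so $\theta$ is not estimable and not part of any
model, and the number of simulated loci should simply match the observed
panel of the analysis.

# The ABC engine

Statistics are standardized by column median and MAD (falling back to the
SD when the MAD is zero, dropping genuinely constant columns); MAD scaling
is robust to the heavy-tailed count statistics.  Rejection keeps the
`ceiling(tolerance x n)` rows nearest the observed vector in Euclidean
distance, with deterministic index tie-breaks.

**Model selection.**  Two routes, intended to be compared:

* a feed-forward classifier (single hidden layer of 5 units via `nnet`)
  fitted to the accepted rows, ensemble-averaged over random restarts, read
  out at the observed point.  A deeper 5x5 topology is available
  (`hidden = rep(5, 5)`, a small hand-written MLP), because the phrase
  "five hidden layers" is ambiguous between five *units* and five *layers*
  in parts of the ABC literature; the single-layer-of-5 reading is the
  convention of the upstream neural-net ABC implementation and is the
  default.
* a random-forest classifier over the full reference table (no rejection
  step), 1,000 trees, with support read as the proportion of tree votes at
  the observed point and the forest's out-of-bag misclassification recorded.

The classifier weight decay defaults to 0.5.  This is deliberately strong:
accepted sets are often ~100-200 rows against ~100+ network weights, and
with weak decay the classifier manufactures certainty from noise --- two
models with *identical* simulators should score near (0.5, 0.5), and do so
only under strong shrinkage, while genuinely separated models still reach
near-certain support.  Bayes factors are posterior-probability ratios under
the equal model priors implied by equal replicate counts, flagged "strong"
at 3.

**Parameter estimation.**  Neural-network regression adjustment: regress
each transformed parameter on the standardized accepted statistics
(Epanechnikov-weighted by distance), then transport the accepted draws to
the observed point by residual adjustment
$\theta^* = m(s_{obs}) + (\theta - m(s))$.  $N_e$ and migration rates are
log-transformed, severities logit-transformed, so back-transformed draws
always respect their support.  The regression decay also defaults high
(0.5): calibration probes on the synthetic inland scenario showed that weak
decay lets the conditional-mean fit absorb the residual spread, collapsing
the adjusted posterior to near-zero width and destroying interval coverage
(severity HDI coverage rose from 1/12 at decay 0.01 to 18/20 at 0.5, at
equal prediction error).  Summaries are weighted medians and 95% highest
density intervals (shortest weighted interval, two-pointer scan over the
sorted draws).

# Validation

* `cv_model_selection()`: reference rows serve as pseudo-observed datasets
  (PODS); each sampled POD is classified with its own row excluded.
  Re-simulation is unnecessary at these table sizes, so leave-one-out means
  exactly that.  For the forest, each POD is classified by the trees in
  which it was out of bag.  An optional model-to-process grouping splits
  each model's misclassification into same-process and other-process parts
  --- the diagnostic for scenario sets that share a route but differ in
  source, which is where identifiability typically fails.
* `cv_parameters()`: prediction error
  $\sum_i(\hat\theta_i - \theta_i)^2 / (n\,\mathrm{Var}(\theta))$ with
  posterior medians as point estimates; ~0 means sharp estimation, ~1 means
  the statistics add nothing beyond the prior.
* `posterior_predictive()`: simulate from posterior draws, compare each
  statistic's simulated distribution to the observed value.  "More extreme"
  is read two-sided by default, $p = 2\min(\Pr(\le), \Pr(\ge))$ with ties
  counted both ways (one-sided available via `sides = 1`): the two-sided
  reading flags both diversity deficits and excesses, at the cost of being
  conservative for heavily tied count statistics.

# The synthetic-data generator

`generate_study()` emulates the shape of the motivating surveys: by default
18 populations of 25 diploids, a 2,312-locus panel, per-population call
rates on an even 0.85--0.98 schedule (missingness uniform within a
population --- real call-rate structure beyond the floor is unknowable, and
per-individual weights are an optional extension), and ground truth near the
regime such studies report: source $N_e \sim 10^3$ under a shared
hyperparameter, inland $N_e \sim 10^2$, river-founding severity 3%,
shipping-assisted severity 15%.  The truth manifest (YAML) records model,
seed, schedule, and every parameter.  What the generator does *not* emulate:
genotyping error, allele dropout, depth variation, linked loci, or
population structure within sampling locations --- so green end-to-end tests
certify the inference machinery, not robustness to RAD-seq artefacts.

`make_separable_fixture()` builds the two-model toy (severe ~1% versus mild
~90% founding severity over a 3-generation bottleneck) whose statistic
clusters sit several pooled SDs apart; it anchors the classifier power
tests.

# Scales used by the shipped checks

The test-suite simulation studies run at desk scale, chosen so the whole
suite completes in a few minutes while leaving each check statistically
decisive: classifier power at 10,000 reference rows per model and 150 loci;
the migration-unidentifiability and severity-recovery cross-validations at
a 10,000-row table of 500-locus replicates with 20 diploids per deme, 100
PODS, tolerance 0.01.  Production analyses of the kind the package targets
use on the order of $10^6$ rows per model and the full observed panel;
`build_reference_table()` is chunked and seed-scheduled precisely so that
scale is a matter of patience, not code changes.  The reconstructed inland
scenario used by those checks (one source bay, a two-step dam-fragmented
chain, shared RF severity, downstream-only migration with a log-uniform
prior spanning 1e-4 to 1e-2 per generation) reflects rare dam passage; at
such rates migration is expected to be unidentifiable from this statistic
battery --- and measuring *that* is the point of the check.

# Known limitations

* Continuous-time coalescent, not generation-by-generation Wright-Fisher:
  inside single-generation bottlenecks of a handful of founders the
  approximation is coarse, though both observed-emulating and reference
  simulations share it.
* The statistic battery is folded and frequency-based; haplotype or
  linkage signal, which could add power at these timescales, is out of
  scope by design.
* Posterior predictive checks inherit the pairwise-heavy composition of the
  battery: with many more pairwise than per-population statistics, fit
  assessments weight differentiation more than diversity.
* Scenario configuration deliberately refuses cyclic founding graphs and
  twice-founded demes; admixture pulses must be expressed as founding
  events.
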