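# invabc

Coalescent ABC reconstruction of recent invasion histories from SNP data.

## The problem

When an invasive fish (or any recently established invader) turns up in a
chain of inland lakes and impoundments, managers want to know three things:
where the founders came from, which way the invasion moved through the
system (upstream stepping-stone? a single long jump followed by downstream
spread? several separate introductions?), and how many individuals founded
each population.  Only a few generations after founding, allele-frequency
signal is faint, but panels of thousands of RAD-seq SNPs genotyped in 15-20
populations carry enough information to compare explicit demographic models.

`invabc` implements that comparison as a likelihood-free (approximate
Bayesian computation, ABC) pipeline for exactly this setting: populations of
20-25 diploids, 2,000-4,000 biallelic SNPs, founding events fewer than 20
generations ago, effective sizes from tens (fresh founders) to thousands
(source populations).

## What it does

1. **Genotype handling** — reads a multi-sample VCF (GT field) plus a
   two-column population map; filters loci on per-population call rate
   (e.g. genotyped in 80% of individuals in at least 15 of 18 populations);
   subsamples to a *complete* matrix by drawing, per locus and population,
   a fixed number of non-missing genotypes without replacement.
2. **Summary statistics** — a fixed-order vector per dataset: segregating
   sites S and private sites pS per population (plus means/SDs/total),
   expected heterozygosity He per population and overall, Nei's multilocus
   G<sub>ST</sub> = (H̄<sub>T</sub> − H̄<sub>S</sub>)/H̄<sub>T</sub> for
   every pair and overall, and for every ordered pair the number of loci on
   the axes of the joint site frequency spectrum together with the mean
   private minor-allele frequency (directional gene-flow signal).
3. **Scenario simulation** — candidate invasion models are population trees
   with founding events: backward in time, a derived deme drifts at its
   contemporary N<sub>e</sub> until its founding time, passes through a
   bottleneck of severity s (founder N<sub>e</sub> = s × contemporary
   N<sub>e</sub>) for a configurable duration, then merges into its source.
   Severity classes (SF shipping-assisted, RF river founding) can share one
   prior; source-deme sizes can hang off a common hyperprior; continuous
   backward migration edges are supported.  A compiled (Rcpp) multi-deme
   coalescent simulates SNP datasets under any scenario instance.
4. **ABC machinery** — reference tables of (drawn parameters, statistics);
   MAD-standardized Euclidean rejection; model selection by neural-network
   classifier on accepted rows and by random-forest votes over the full
   table (1,000 trees, out-of-bag error); Bayes factors; parameter
   estimation by neural-network regression adjustment on log/logit scales
   with weighted medians and 95% highest-density intervals.
5. **Validation** — leave-one-out cross-validation on pseudo-observed
   datasets (misclassification rates, confusion matrices, shared-process
   attribution), cv4abc-style prediction errors
   Σ(est − true)² / (n · Var(true)), and posterior predictive checks with
   per-statistic p-values.
6. **Synthetic data** — a generator that emulates the study shape (18
   populations, 2,312 loci, per-population call-rate schedule, known truth
   manifest) so the whole pipeline is testable end to end without any
   download.

## Worked example

Two candidate colonization models that differ only in founding-bottleneck
severity (~1% versus ~90% of contemporary N<sub>e</sub>), with the observed
data simulated under the severe model:

```r
library(invabc)
fix <- make_separable_fixture(n_per_model = 2000, n_loci = 150, seed = 7)

nn_model_posterior(fix$tables, fix$observed, tolerance = 0.01)
#> ABC model selection (neural_net)
#>   tolerance: 0.01
#>   severe_bottleneck    1.0000
#>   mild_bottleneck      0.0000

rf_model_posterior(fix$tables, fix$observed, n_trees = 1000, seed = 7)
#> ABC model selection (random_forest)
#>   out-of-bag error: 0
#>   severe_bottleneck    1.0000
#>   mild_bottleneck      0.0000

post <- nn_adjust_params(fix$tables[[1]], fix$observed, tolerance = 0.05)
round(posterior_summary(post), 4)
#>           median hdi_lower hdi_upper
#> Ne_SRC  858.1905  551.0505 1846.5450
#> Ne_DER  140.1548  100.6884  212.9831
#> SEV_DER   0.0060    0.0044    0.0085
```

Both classifiers give the generating model all support.  The generating
truth for this seed was N<sub>e,SRC</sub> = 647, N<sub>e,DER</sub> = 111 and
severity 0.0059: the posterior median severity (0.0060) lands on the truth
and every 95% HDI covers it.  `run_pipeline()` strings all stages together
from a single YAML config (see the vignette and
`inst/scripts/run_pipeline.R`); worked scenario configurations for three
river-system analyses ship under `inst/extdata/models/`.

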