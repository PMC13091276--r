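# microstrat

Multi-kingdom microbiome stratification and association networks for
clinical cohorts, as a tidyverse-native R package.

Gut microbiome studies of gastrointestinal disease increasingly combine
bacterial (16S) and fungal (ITS) profiling and ask not just *which taxa
differ* but *how the community is organised*: which community type a
person carries, which metabolic niche dominates, and how fragile the
cross-kingdom interaction network is. `microstrat` implements that
analysis stack end to end for genus-level count tables:

* **Enterotyping** by Dirichlet-multinomial mixtures (DMM). The mixture
  density is $\sum_k \pi_k \,\mathrm{DM}(x \mid \alpha_k)$ with
  $\log \mathrm{DM}(x \mid \alpha) = \log\Gamma(A) - \log\Gamma(N+A) +
  \sum_j[\log\Gamma(x_j+\alpha_j) - \log\Gamma(\alpha_j)]$. EM fitting
  with a weighted Minka fixed-point M-step; model selection by BIC, AIC
  and a Laplace approximation; genus contribution scores between the
  K-component and 1-component fits.
* **Succinotyping** from succinate-utilizer genera: with
  $r_D = n_D/(n_D+n_P)$ over *Dialister* and *Phascolarctobacterium*
  reads, samples are D-type ($r_D > 0.9$), P-type ($r_D < 0.1$), mixed,
  or unclassified ($n_D + n_P < 10$), with Fisher-exact association
  tests against host categories.
* **Diversity**: richness/Shannon/Pielou, Bray-Curtis and Jaccard
  distances, PERMANOVA variance partitioning ($R^2$ per factor) with
  marginal covariate adjustment and pairwise comparisons under BH
  correction (vegan backend).
* **Differential abundance**: prevalence-filtered Wilcoxon rank-sum
  screens with BH control, calprotectin/symptom/age-tertile
  stratification, and the Basidiomycota/Ascomycota dysbiosis ratio.
* **Association networks**: graphical lasso on CLR-transformed
  abundances (own RcppArmadillo solver) with StARS stability selection
  (80% subsampling, 50 repetitions, instability threshold 0.05), signed
  edge weights as partial correlations, Leiden-based signed community
  detection ($Q^+ - Q^-$), keystone taxa (top 5% by combined z-scored
  centralities), and targeted-attack robustness curves with AUC and R50.
* **Synthetic cohorts**: a seeded generator
  (`generate_cohort()`) that emulates a four-group IBS/UC/CD cohort
  (9/29/31/30 samples) with known enterotype labels, succinotype
  classes (43/30/18/9% targets), fungal phylum structure and a sparse
  latent precision matrix — the ground truth every stage is validated
  against.

## Worked example

```r
library(microstrat)

co <- generate_cohort(synth_config(seed = 7))

# succinotype calls and prevalence
calls <- classify_cohort(co$bacterial, co$bact_taxonomy)
table(calls$label)
#>    D mixed     P unclassified
#>   52    21    19            7

# enterotypes: fit K = 1..3 and select
sel <- select_k(rarefy_counts(co$bacterial, 3000, seed = 1), k_range = 1:3, seed = 1)
sel$best
#>     bic     aic laplace
#>       2       3       3

# beta diversity and variance partitioning
d <- beta_distance(co$bacterial, "bray_curtis")
permanova(d, co$metadata, "group", n_perm = 999, seed = 1)

# a signed association network with keystones and robustness
net <- infer_network(list(bacterial = co$bacterial, fungal = co$fungal), seed = 1)
rep <- network_report(net, resolution = 0.5, seed = 1)
rep$robustness_targeted
#> Robustness curve (targeted_betweenness)
#>   AUC: 0.1664  R50: 0.1993
```

`table(calls$label)` reports how many samples fall in each succinotype
(the generator's targets are 43% D / 30% P / 18% mixed / 9%
unclassified, so counts near 43/30/18/9 out of 99 are expected up to
binomial noise). `sel$best` gives the component count chosen by each
information criterion: BIC recovers the generating two components,
while the weaker-penalty criteria (AIC, Laplace) absorb some of the
cohort's residual latent covariance into a third component — the
behaviour to expect on real, overdispersed data. The robustness printout gives the area under the
largest-connected-component curve during a betweenness-targeted attack
(lower = more fragile) and the node fraction whose removal halves the
component.

The whole pipeline runs from one call:

```r
bundle <- run_pipeline(pipeline_config(seed = 42), out_dir = "run1")
writeLines(make_report(bundle))
```

which writes every stage table plus a checksummed manifest; identical
config and seed reproduce the directory byte for byte.

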