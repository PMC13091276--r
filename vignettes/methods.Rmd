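---
title: "Methods: multi-kingdom stratification and association networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-kingdom stratification and association networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`microstrat` analyses paired bacterial (16S) and fungal (ITS) genus-level
count tables from a clinical cohort along four axes: community *types*
(enterotypes via Dirichlet-multinomial mixtures and succinotypes via
succinate-utilizer ratios), *diversity* (alpha metrics and PERMANOVA
variance partitioning on Bray-Curtis/Jaccard distances), *differential
abundance* (Wilcoxon screening with Benjamini-Hochberg control), and
*association networks* (graphical lasso with StARS stability selection,
followed by signed community detection, keystone scoring and
attack-robustness analysis). This vignette documents the models, their
assumptions, the tunable parameters, and the numerical choices the
package makes where a published description leaves the design open.

## The synthetic cohort generator

All validation runs on seeded synthetic cohorts with recorded ground
truth (`generate_cohort()`). Defaults emulate a four-group
gastrointestinal cohort: 9 controls, 29 IBS, 31 ulcerative colitis and
30 Crohn's disease participants; two Bacteroides-dominant enterotype
mixture components (component 2 enriched ten-fold in
Escherichia/Streptococcus-like genera and depleted in
Faecalibacterium/Alistipes-like ones); succinotype target prevalences of
43% *Dialister*-dominant (D), 30% *Phascolarctobacterium*-dominant (P),
18% mixed and 9% unclassified; and a fungal table whose phylum labels
give an expected Basidiomycota/Ascomycota mass ratio near 2.

Bacterial counts are drawn from a mixture logistic-normal-multinomial:
the latent log-mean is the sample's enterotype component profile and the
latent covariance is the inverse of a known sparse precision matrix
(band, block, or preferential-attachment topology), so a single cohort
carries both enterotype and network ground truth. The succinate-utilizer
genus columns are then redrawn per sample to realise the target
succinotype class under the classification rule itself (unclassified
samples are generated by forcing fewer than 10 combined reads).

Sequencing depths are lognormal with medians 5,000 (16S) and 3,000
(ITS). These are desk-scale stand-ins: the statistical structure, not
the absolute depth, is what the downstream stages consume, and small
depths keep the full pipeline fast. Genus abundances decay as
$j^{-1.3}$, a heavy tail that yields realistic dominance structure but
*less* sparsity than real stool tables; passing tests therefore
demonstrate correctness of the machinery, not field performance on
sparse real data. Within-group compositional effect sizes are free
parameters of the generator, not calibrated to any cohort. Host
metadata (age, calprotectin, symptoms, *Blastocystis* carriage) are
drawn independently of microbial structure by default, giving a testable
null; a single odds parameter can link calprotectin to enterotype 2.

## Count-table preprocessing

* **Rare-taxon filter** (`rare_asv_filter()`, default fraction 0.001):
  "relative abundance below 0.1% of the mean sequencing depth" mixes a
  proportion with a depth, so two interpretations are offered. The
  default drops taxa whose *total* count falls below 0.001 x mean
  per-sample depth (plus all singletons); `mode = "per_sample"` instead
  thresholds the mean relative abundance.
* **Prevalence filters** use strict below-threshold removal: a taxon
  present in exactly 10% of samples survives a 10% filter. The
  differential-abundance stage uses 10%, network inference 20%.
* **Rarefaction** subsamples without replacement (hypergeometric
  marginals) to an even depth and excludes shallower samples; the
  pipeline default depth is the 10th percentile of sample depths, which
  retains about 90% of samples.
* **CLR transform** adds a pseudocount of 1 (simplest documented
  choice), logs, and centres each sample; rows sum to zero exactly, so
  CLR covariance matrices are singular by construction — relevant
  wherever they are inverted (see the network section).
* ASVs with an unassigned genus are pooled as
  `unassigned_<nearest assigned parent>` rather than dropped, so
  aggregation conserves per-sample totals exactly.

## Diversity and PERMANOVA

Alpha diversity reports observed richness, Shannon entropy (natural
log; $0 \log 0 := 0$) and Pielou's evenness ($H / \ln S$, defined 0 for
one taxon). Beta diversity uses Bray-Curtis on counts and Jaccard on
presence/absence (vegan's implementations). PERMANOVA is vegan's
`adonis2`: sequential partitions when no covariates are given (term and
residual $R^2$ sum to 1) and marginal tests when adjusting for a
covariate such as disease group. Permutation p-values use the
add-one convention $(1 + \#\{F^* \ge F\})/(1 + n_{perm})$ and never
report zero; the default is 999 permutations (unspecified in typical
reports; chosen once). Pairwise group comparisons run one PERMANOVA per
level pair with BH adjustment across pairs.

## Enterotypes: Dirichlet-multinomial mixtures

The mixture density for a count row $x$ with total $N$ is
$\sum_k \pi_k \, \mathrm{DM}(x \mid \alpha_k)$ with
$\log \mathrm{DM}(x \mid \alpha) = \log\Gamma(A) - \log\Gamma(N + A) +
\sum_j [\log\Gamma(x_j + \alpha_j) - \log\Gamma(\alpha_j)]$, $A = \sum_j
\alpha_j$. Fitting is EM: exact E-step responsibilities, and an M-step
that updates $\pi$ by responsibility means and each $\alpha_k$ by a
responsibility-weighted Minka fixed point (five inner sweeps per EM
iteration — a generalized EM, so the observed-data log-likelihood is
still monotone, which the tests assert at tolerance $10^{-6}$).
Responsibilities are initialised from k-means on CLR counts plus
jitter; three random restarts guard against local optima, and the best
restart by log-likelihood is returned. Degenerate fits (duplicated
components or a vanishing weight) are legal outputs and are penalised
by the information criteria rather than patched.

Model selection compares BIC, AIC and a Laplace score across K. The
parameter count is $K \cdot G + (K - 1)$, stated explicitly so scores
are comparable across K. The Laplace score is the negative
log-likelihood at the mode plus half the log-determinant of a
*diagonal* curvature approximation (trigamma terms of the expected
complete-data Hessian) minus $\tfrac{npar}{2}\log 2\pi$ — an
approximation in the spirit of the classical mixture-evidence
treatment, not a claim of equivalence to any particular package.

Genus contributions to the multi-component structure compare component
mean profiles $\alpha_k / A_k$ between the K-component and
single-component fits, summing absolute differences per genus. The
default space is CLR of the mean profiles, with proportion space as the
alternative; both are exposed because verbal descriptions of this
statistic vary between "mean absolute differences" and "CLR-transformed
differences". Assignment is argmax responsibility with ties broken
toward the lowest component index and logged.

## Succinotypes

With $n_D$ and $n_P$ the genus-aggregated read counts of *Dialister*
and *Phascolarctobacterium*, $r_D = n_D / (n_D + n_P)$. Samples are
unclassified when $n_D + n_P < 10$, D-type when $r_D > 0.9$, P-type
when $r_D < 0.1$, and mixed otherwise. All inequalities are strict;
boundary ratios are mixed. "Mixed" is defined as the classifiable
remainder because published rules define only D/P and the exclusion,
yet cohorts report a mixed class. Genus matching is exact on taxonomy
strings with an optional alias map (no silent substring matches). For
subjects with repeated samples, clear calls (D or P) are prioritised
over mixed, and mixed over unclassified. Prevalences are always
reported under both normalizations (within group and over the cohort),
since published figures mix the two. Associations with host categories
use two-sided Fisher's exact tests (probability-mass definition; empty
margins give p = 1 by convention) with BH adjustment across the family.

## Differential abundance

Pairwise Wilcoxon rank-sum tests on relative abundances within each
stratum, exact for combined n <= 20 without ties and the tie-corrected
normal approximation otherwise; all-identical inputs give p = 1. BH
correction is applied within each (comparison, stratum) family,
mirroring per-panel reporting, rather than one global family. Age
strata are empirical tertiles with ties assigned to the lower tertile.
Bias-corrected compositional methods (e.g. ANCOM-BC2) are deliberately
not re-implemented; `attach_external_da()` records externally computed
results alongside the screen. The fungal dysbiosis indicator is the
per-sample Basidiomycota/Ascomycota count ratio (natural log for
display); a zero Ascomycota count triggers a +0.5 continuity correction
on both phyla and a flag, and a sample with neither phylum is undefined.

## Association networks

`infer_network()` chains: per-kingdom 20% prevalence filter, CLR,
column concatenation over shared samples (cross-kingdom mode),
covariance, StARS-selected graphical lasso, and edge extraction. The
graphical lasso maximises $\log\det\Theta - \mathrm{tr}(S\Theta) -
\lambda \lVert\Theta\rVert_{1,\mathrm{off}}$ by block coordinate
descent (RcppArmadillo; inactive coordinates cost O(1) via a maintained
residual); the reported duality gap
$\mathrm{tr}(S\Theta) + \lambda\lVert\Theta\rVert_{1,\mathrm{off}} - p$
measures remaining suboptimality. Edge weights are partial correlations
$\rho_{ij} = -\Theta_{ij} / \sqrt{\Theta_{ii}\Theta_{jj}}$; published
figures typically show only signs, so the magnitude is an extension of
this package, documented as such.

StARS draws 50 subsamples of 80% of samples, fits the path of 30
log-spaced penalties from $\lambda_{max} = \max |S_{ij}|$ down to
$\lambda_{max}/100$, and computes per penalty the all-pairs edge
instability $\bar D(\lambda) = \mathrm{mean}_{i<j}\, 2\hat\theta_{ij}(1
- \hat\theta_{ij})$. The monotonized statistic (running maximum from
the sparse end) selects the smallest penalty still at or below
$\beta = 0.05$ (the original StARS default; subsampling fraction and
repetition count follow common practice in this literature, and the
threshold is stated because published pipelines rarely state theirs).
Two numerical choices matter. First, because the monotonized
instability cannot decrease, the path is abandoned at the first penalty
exceeding $\beta$ — an exact shortcut, not an approximation. Second,
duplicate subsamples (inevitable when n is small: at n = 9 there are
only 36 distinct 80% subsamples) are fitted once and counted by
multiplicity. Subsample fits use a looser convergence tolerance
($10^{-3}$) than the final full-data refit ($10^{-4}$), since only
their edge sets are consumed.

Two regimes deserve caution. At very small n (a 9-sample control
group), subsamples overlap almost completely, the instability is
underestimated, and the selected graphs can be implausibly dense —
mirroring the published caveat that small-group networks are
underpowered and should be read only at the level of global
organisation. Conversely on true *null* data the selected network
retains a false-edge count consistent with $\beta$ itself (roughly
$\beta$-level instability spread over all pairs, i.e. around 5–15
spurious partial correlations at p = 30); StARS at its default
threshold controls edge *stability*, not the family-wise false-edge
count, and the package documents rather than hides this behaviour.

## Network statistics

Isolated vertices are always removed before metrics; components of two
or fewer nodes are additionally removed only from visualization
exports. Path-based metrics (betweenness, harmonic closeness, average
path length, diameter) use $1/|w|$ edge lengths so strong associations
are short; eigen-centrality and hub scores use $|w|$ (identical up to
scale on undirected graphs — both are reported because both appear in
the field's metric vocabulary). Degree is the unweighted count.

Community detection runs Leiden (modularity objective) on the
positive-edge layer at resolution 0.5, then greedily relocates single
nodes while the signed modularity $Q^+ - Q^-$ (positive-layer
modularity at the chosen resolution minus negative-layer modularity)
strictly improves. This convention for "incorporating both positive
and negative edges" is one of several defensible ones and is fixed
here; it guarantees negatively linked cliques are never merged.

Keystones are the top 5% of nodes (ceiling) by the sum of z-scored
degree, betweenness, closeness and eigen-centrality; a zero-variance
metric contributes zeros, and ties at the cutoff are all included and
flagged (on a vertex-transitive graph every node ties at score zero and
the selection degenerates, by design).

Robustness curves remove nodes from the largest connected component —
either adaptively by current betweenness (recomputed after each
removal; static ranking available) or uniformly at random (averaged
over 50 orders, computed by reverse union-find) — recording the LCC
fraction of the *initial* LCC at removal fractions $0, 1/n, \dots, 1$.
AUC is the trapezoidal integral over the removal fraction; R50 is the
smallest fraction at which the LCC falls to half. On the complete graph
$K_{20}$ the targeted curve is exactly linear with AUC = 1/2, and on a
21-node star the first (hub) removal collapses the LCC to 1/21 — both
serve as exact test oracles. Published absolute values of weighted path
lengths and diameters depend on unstated weighting conventions;
reproduction of those exact numbers is not claimed.

## Pipeline and problem sizes

`run_pipeline()` executes preprocess → diversity → enterotype →
succinotype → differential abundance → networks (cross-kingdom per
group, bacterial-only per succinotype) → network statistics, writing
every table plus a manifest with MD5 checksums. Stage seeds are derived
by hashing the stage name against the master seed, so adding a stage
never shifts another stage's random stream; identical config and seed
give byte-identical outputs. The validation suite exercises desk-scale
problem sizes chosen once: a 99-sample, 250 + 150-genus cohort for the
end-to-end run; n = 200, G = 40 for mixture recovery; p = 30, n = 200
for network recovery; 1000 null datasets of n = 40 for PERMANOVA size;
and brute-force graph oracles at up to 12 nodes.

## Known limitations

* The generator's taxa are less sparse and less zero-inflated than real
  stool profiles, and metadata effects are linear-in-odds toggles; the
  suite validates machinery, not clinical effect sizes.
* StARS edge stability does not bound the absolute false-edge count
  (see above); small-n networks can be dense and should be read
  globally, not edge-wise.
* The marginal PERMANOVA permutes raw labels holding covariates fixed
  (no residual-permutation scheme).
* The Laplace score uses a diagonal curvature approximation; with very
  small or very collinear genus sets it can rank models differently
  from a full-Hessian evidence estimate.
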