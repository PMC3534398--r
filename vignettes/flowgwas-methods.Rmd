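---
title: "Marker-effect estimation for sire-based dairy traits: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker-effect estimation for sire-based dairy traits: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowgwas)
```

# The problem

Milkability traits (total milking time, ascending time, time at plateau,
descending time, maximum and average flow) are recorded on cows but selected
on through progeny-tested sires.  A GWAS for such traits therefore regresses
a *pseudo-phenotype* for each genotyped sire — his de-regressed breeding
value — on his SNP genotypes.  Two features make this setting statistically
delicate: the number of markers far exceeds the number of sires, and the
sires are strongly related, so naive single-marker tests confound family
structure with marker effects.

`flowgwas` implements the complete pipeline for this design: marker quality
control, de-regression of breeding values, a Bayesian LASSO regression that
fits **all markers simultaneously** together with a pedigree-based polygenic
effect, significance declaration by within-chain permutation, a Bayes C-pi
mixture cross-check of the null-marker proportion, marker-window region
analysis against literature QTL intervals, and direct-genomic-value (DGV)
prediction analytics.  A gene-dropping population simulator generates data
with the same statistical structure, so the entire pipeline is testable
without proprietary data.

# The core model

For sire $i$ with de-regressed proof $y_i$,

$$y_i = \mu + S_i + \sum_{j=1}^p x_{ij}\,\beta_j + e_i,$$

where $x_{ij} \in \{-1, 0, 1\}$ is the genotype at marker $j$ (mean-imputed
after QC), $\beta_j$ the allele substitution effect,
$S \sim N(0, \mathbf{A}\sigma^2_s)$ a polygenic effect with $\mathbf{A}$ the
pedigree-expected numerator relationship matrix (tabular method,
`build_numerator_relationship()`), and $e \sim N(0, \mathbf{I}\sigma^2_e)$.
The polygenic term absorbs family structure and the background polygenes
that the marker panel does not tag, protecting against spurious
associations.

Marker effects carry the Bayesian LASSO (double-exponential) prior in its
conditional hierarchy:

$$\beta_j \mid \tau^2_j \sim N(0, \tau^2_j\,\sigma^2_e), \qquad
  \tau^2_j \sim \text{Exp}(\lambda^2/2),$$

so that marginally $\beta_j$ has a Laplace distribution and small effects
are shrunk hard while large effects escape.  Gibbs updates are standard:
each $\beta_j$ from its normal full conditional, $1/\tau^2_j$
inverse-Gaussian, the polygenic vector jointly in the eigenbasis of
$\mathbf{A}$ (where its full-conditional precision is diagonal — one
$O(n^2)$ matrix product per iteration instead of an $O(n^3)$ factorisation),
and the variances from scaled inverse-chi-square conditionals; because the
$\beta$ prior scales with $\sigma^2_e$, the residual-variance update
includes $\sum_j \beta_j^2/\tau^2_j$ and $p$ extra degrees of freedom.  The
sampler is written in C++ (Rcpp/RcppArmadillo) and driven by R's RNG, so a
seed makes chains bit-reproducible.

## Chain protocol and the shrinkage parameter

Defaults in `blasso_control()` follow the long-chain protocol used for this
kind of analysis: 100,000 iterations, 30,000 burn-in, every 30th sample
stored (2,333 stored samples, `n_stored_samples()`).  $\lambda$ is *fixed*
in the final chain at the average of five exploratory chains (50,000
iterations each by default) in which $\lambda^2$ is sampled under a diffuse
Gamma(0.1, 0.1) hyperprior (`estimate_lambda()`).  Fixing $\lambda$ removes
a slowly-mixing hyperparameter from the production chain; the exploratory
average is robust to individual-chain noise and a crude convergence screen
flags (but still returns) discordant chains.  Variance priors are scaled
inverse-chi-square with 4 degrees of freedom and scales set from the
response variance — proper but weak; both are configurable.

Test-suite and acceptance-script runs use shorter chains (2,000–80,000
iterations depending on the check) and panels of 800–2,030 markers on
400–1,400 animals; these sizes were chosen so every posterior quantity
asserted is estimated with Monte-Carlo error far below its test tolerance.

## De-regression

EBVs are shrunken predictors that mix the sire's own information with his
parents'; regressing them directly on genotypes double-counts family
information.  `deregress()` implements the Garrick–Taylor–Fernando
parent-average-removal system: the information content ($Z'Z$, in
residual-variance units) of the parent average and of the animal are
recovered from their reliabilities via

$$\alpha = \frac{1}{0.5 - r^2_{PA}}, \quad
  \delta = \frac{0.5 - r^2_{PA}}{1 - r^2_i}, \quad
  Z'Z_{PA} = \lambda(0.5\alpha - 4) + 0.5\lambda\sqrt{\alpha^2 + 16/\delta},$$
$$Z'Z_i = \delta\,Z'Z_{PA} + 2\lambda(2\delta - 1), \qquad
  \lambda = (1 - h^2)/h^2,$$

the mixed-model right-hand sides are reconstructed from the EBVs, and the
animal's own equation is solved free of the parent average.  For animals
with unknown parents the system reduces to the classical single-animal
de-regression $y = \text{EBV}/r^2$.  Records whose own information content
is essentially nil (de-regressed reliability below ~5%) are flagged and
excluded.  Reliabilities are clamped to [0.01, 0.99] and a parent-average
reliability is capped at 0.49 (it cannot reach 0.5).  Record weights
$(1-h^2)/[(c + (1-r^2_{DRP})/r^2_{DRP})h^2]$ are returned but the default
analysis uses unweighted residuals, matching the homogeneous residual in
the core model; $c$ (the genomic-variance fraction not captured by markers)
defaults to 0.5.

## Significance by within-chain permutation

`run_permuted_chain()` runs the same Gibbs sampler while re-permuting the
response against the genotype rows every $h$ iterations ($h = 3$ by
default; $h = L$ is ordinary across-chain permutation).  The permutation
moves $y$ jointly with its polygenic index, so the $y$–$\mathbf{A}$ linkage
is preserved and only the genotype–phenotype link is broken.  The stored
marker-effect draws form the null sample; `critical_values()` reads the
$0.25\alpha$ and $1 - 0.25\alpha$ percentiles (per marker by default,
pooled across markers optionally — the underlying report does not say which
it used), and a marker is declared significant when its posterior mean
falls outside its interval.

**A calibration caveat discovered during validation.**  Under a *global
null* (no genetic signal at all) this declaration rule is conservative: the
null draws have variance equal to the across-permutation variance of the
posterior mean *plus* the average posterior variance, so they are always
wider than the spread of the observed posterior means they are compared
with — empirically 1.7–6 times wider across shrinkage regimes, giving a
realised type-I rate of roughly 0.1% at nominal $\alpha = 0.05$ rather than
5%.  This is a property of comparing a posterior *mean* against quantiles
of posterior *draws*, not of the permutation schedule: within-chain
($h = 3$) and across-chain ($h = L$) null draws have matching spread, as
exchangeability requires.  On data with genuine polygenic signal the band
behaves as intended — markers carrying real variance escape it, and the
declared fraction moves together with the Bayes C-pi estimate of the
non-null proportion (an agreement the test suite checks).  Users should
read the permutation band as a conservative screen, not an exact
$\alpha$-level test.

## Bayes C-pi cross-check

`run_bayescpi()` fits the mixture model in which $\beta_j = 0$ with
probability $\pi$ and $\beta_j \sim N(0, \sigma^2_\beta)$ (one common slab
variance) otherwise, with $\pi \sim U(0,1)$ estimated from the data.
Inclusion indicators are sampled with the effect integrated out; $\pi$ gets
a Beta update from the inclusion counts.  The posterior mean of $\pi$
estimates the proportion of null markers and its complement should track
the permutation method's significant fraction across datasets — the
cross-check the original analysis used.  A response carrying no information
leaves $\pi$ at its uniform prior; this is detected (posterior SD near the
prior's 0.289) and flagged.

## Regions and QTL annotation

The markers with the largest absolute effects (top 100 by default,
deterministic ties by map order) are chained into regions: two selected
markers join one region when they sit on the same chromosome within 20
panel positions of each other, with transitive closure
(`group_regions()`).  A region's variance share is the variance across
animals of its region-restricted DGV divided by the all-marker DGV
variance.  Regions are tagged with every literature QTL class whose
interval overlaps them (closed intervals, 1-based base pairs); a curated
fixture of milking-speed (MSPD), udder (UT), somatic-cell/mastitis
(SCS/SCC/CM) and milk-yield (MY) intervals on the Btau 4.0 assembly ships
in `inst/extdata/qtl_intervals_btau4.tsv`.

## Genomic prediction

Sires split at EBV reliability 0.60 (strictly greater = discovery; the
paper's convention) into discovery and prediction sets.  Marker effects are
estimated on the discovery set; `dgv_table()` builds per-animal DGVs from
nested subsets of the largest effects (25, 50, 100, 300, 3,000, 10,000,
capped at the panel) plus the full panel, and optionally from significant
and genic-significant marker sets.  `correlation_recovery()` reports the
Pearson correlation between EBV and each subset DGV on the prediction set
and the fraction of the full-panel correlation each subset recovers;
`genomic_variance_proportions()` reports each subset's share of the
all-marker DGV variance (exactly 1 for the full panel).  Markers within
genes or their 500-kb flanks (`flag_gene_region_markers()`, via
GenomicRanges overlap on GFF3 gene features) define the genic subsets;
`gene_dgv_proportion()` summarises, per animal, how much of the selected-
marker DGV the genic markers reproduce, as the median of per-animal ratios
(with a floor on tiny denominators).  The ratio median is sensitive to the
DGV location — on panels whose genotype means are far from zero the raw
ratios drift from the variance split — so a variance-ratio alternative is
exposed; the underlying report's definition is ambiguous between the two.

# The synthetic population generator

`simulate_population()` emulates the study conditions at desk scale:

* **Pedigree** — `n_founders` unrelated animals; each later generation
  pairs the previous one at random and every pair leaves
  `offspring_per_mating` offspring.  Defaults (300 founders, 4 generations,
  2 offspring per mating) give ~1,200 animals, the order of the ~1,351
  genotyped sires emulated.  Random mating is a simplification: real sire
  pedigrees descend from selection, so real relationship structure is
  denser.
* **Marker map** — 29 autosomes x 100 markers by default (a scaled-down
  33,074-SNP panel), uniform positions, and ~30% of markers flagged genic
  in contiguous blocks, matching the reported fraction of SNPs within genes
  or 500-kb regulatory flanks at panel scale.
* **Genotypes** — founders drawn from Hardy–Weinberg at frequencies in
  `maf_range` (default 0.05–0.5); descendants by gene dropping, one allele
  transmitted per parent per marker.  Markers segregate independently:
  linkage disequilibrium beyond co-segregation within families is *not*
  modelled, so LD-based fine-mapping behaviour of real 50k panels is
  outside what passing tests demonstrate.
* **QTL** — `n_qtl` markers receive additive effects scaled so that
  $\sum_j 2q_j(1-q_j)\beta_j^2$ equals `qtl_variance * h2 *
  phenotypic_variance` exactly (the marker-variance identity used
  throughout; a garbled rendering of this relation in the source material
  was resolved to this standard form).  Defaults (10 QTL, 30% of genetic
  variance) encode the "mostly polygenic with a minority of moderate QTL"
  architecture; the remaining genetic variance is polygenic, bred down the
  pedigree with Mendelian-sampling variance $\sigma^2_{poly}/2$ (inbreeding
  ignored at this scale).
* **EBV proxies** — per-animal reliability $r^2$ drawn from
  `reliability_range` (default 0.38–0.60, the span of published
  trait-mean reliabilities; prediction-split experiments widen it to 0.90
  so the >0.60 discovery set is populated) and
  $\text{EBV} = \overline{\text{TBV}} + \sigma_{TBV}\,(r\,z_{TBV} +
  \sqrt{1 - r^2}\,\epsilon)$, which reproduces the marginal accuracy
  structure ($\text{cor}^2(\text{EBV},\text{TBV}) \approx \bar{r}^2$)
  without modelling the multi-trait evaluation that produced real EBVs.
  Heritability defaults to 0.25, inside the 0.02–0.42 span of the milk-flow
  traits; six traits are emulated as six independent runs since no in-scope
  computation needs their genetic correlations.

Every stage draws from its own seed offset, so identical configurations are
bit-reproducible and stages can be re-run independently.

# Numerical choices

* $\mathbf{A}$ is eigendecomposed once per fit; eigenvalues are clamped at
  zero and a matrix with eigenvalues below $-10^{-6}\,\lambda_{max}$ is
  rejected as non-PSD.  Relationship eigenvalues below $10^{-10}$
  contribute no polygenic variance.
* Genotype columns are mean-centred and the response is handled with a
  sampled intercept; neither changes the marker-effect posterior.
* The inverse-Gaussian mean in the $\tau^2$ update is capped at $10^8$ and
  latent scales floored at $10^{-12}$ to keep the chain finite when an
  effect collapses to zero; variances are floored at $10^{-12}$.
* Monomorphic markers (zero genotype variance) keep $\beta_j = 0$.
* HWE uses the 1-df chi-square against expectations at the sample allele
  frequency; monomorphic markers get statistic 0, p = 1.  The QC
  significance level defaults to $10^{-6}$ (the source analysis names the
  test but not its level; this is standard GWAS practice), and filters are
  applied in the order call rate, MAF, HWE on unfiltered statistics with
  first-failure attribution.
* Allele frequencies in QC are computed from all non-missing entries, so
  mean-imputed dosages leave them unchanged and filtering is idempotent.
* DGV subset additivity (`DGV(all) = DGV(S) + DGV(S^c)`) holds exactly up
  to IEEE summation round-off — floating-point addition is not
  associative, so the identity cannot be bitwise for arbitrary effect
  values; tests assert it at $10^{-12}$ relative tolerance.  Identities
  that are exact in floating point (full-panel variance proportion = 1,
  stored-sample counts, percentile ranks, region counts) are asserted
  exactly.
* Ties in $|\hat\beta|$ rankings break by marker map order; region tables
  are reported in genome order.

# Known limitations

* The permutation band is conservative under a global null (see above);
  its nominal level is an upper bound on the realised type-I rate.
* Random mating, no selection, no LD, and single-trait simulation mean the
  generator validates the *machinery*, not the population-genetic realism
  of any particular cattle breed.
* De-regression parameterisation (weights, the value of $c$) follows the
  Garrick system; the source analysis cites its method without equations,
  so exact numerical equivalence with the original pipeline is not claimed.
* The Bayes C-pi null proportion on the default mostly-polygenic synthetic
  trait is much higher than the 59–67% reported on real data, where dense
  LD lets many markers tag polygenic variance — with 10 planted QTL and
  LD-free markers, most simulated markers really are null.
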