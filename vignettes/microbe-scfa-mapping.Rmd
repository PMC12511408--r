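---
title: "Mapping microbe-SCFA associations with transit-conditioned ordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping microbe-SCFA associations with transit-conditioned ordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scfamap)
```

## The scientific problem

Stool short-chain fatty acids (SCFAs: acetate, butyrate, propionate) are the
main end products of bacterial fibre fermentation in the colon, and shifts in
their output are implicated in functional bowel disorders such as irritable
bowel syndrome (IBS). Relating SCFA concentrations to metagenome composition
is confounded by colonic transit time: transit shapes both the community
(washout, substrate exposure) and the measured metabolite pool, so a naive
taxon-SCFA correlation mixes genuine metabolic coupling with shared transit
dependence. `scfamap` implements an analysis chain built around that problem:

1. **Compositional preprocessing** — closure to relative abundances, an
   additive log-ratio (ALR) transform, a high-abundance/prevalence filter
   (relative abundance at least 0.1% in at least 2 specimens within at least
   one clinical group), and a fold-change screen (3-fold on group means).
2. **Partial canonical correspondence analysis (pCCA)** of the abundance
   matrix on the SCFA concentrations, *conditioned on transit time*, with a
   reduced-model permutation test (999 permutations by default).
3. **Projection-score ranking**: each taxon's species-score vector is
   projected onto an SCFA arrow in the biplot plane; taxa within a 60-degree
   cone around the axis line and with absolute projection at least 0.5 are
   retained and ranked. The sign of the projection encodes the direction of
   association.
4. **Bootstrap-consensus Gaussian Bayesian network** over retained taxa,
   SCFAs and transit (500 resamples, 50% edge retention by default) as an
   orthogonal validation: taxa flagged by projection should reappear as
   direct or indirect SCFA neighbours.
5. **Group-level statistics**: Kruskal-Wallis with Dunn's post hoc and
   Bonferroni correction for quantitative traits; covariate-adjusted linear
   models for ALR taxa and for KO (KEGG orthogroup) abundances aggregated
   into gut metabolic modules (GMMs).

A synthetic cohort generator with planted, signed "driver" taxa and a real
transit confounder provides ground truth for every stage.

## The ordination model

Let $Y$ be the $n \times p$ abundance matrix, $P = Y / \sum Y$, with row
masses $r$ and column masses $c$. The chi-square residual matrix is

$$\bar{Q}_{ij} = \frac{P_{ij} - r_i c_j}{\sqrt{r_i c_j}},$$

and its total sum of squares is the total inertia. Conditioning variables
$Z$ (transit) and constraints $X$ (SCFA concentrations) are centred with
weights $r$; constraints are additionally standardised to weighted unit
variance so arrow lengths are comparable across SCFAs with different units.
$\bar{Q}$ and $X$ are residualised on $Z$ by $r$-weighted least squares (the
removed variance is the *conditional* inertia); the residual $\bar{Q}$ is
projected onto the span of the residualised constraints, and the fitted
matrix is decomposed by SVD. Squared singular values are the constrained
eigenvalues; what remains is residual inertia, and the partition

$$\text{total} = \text{conditional} + \text{constrained} + \text{residual}$$

holds to machine precision (tested to $10^{-8}$). The reported
$R^2 = \text{constrained} / (\text{total} - \text{conditional})$ is the raw
(unadjusted) share of transit-adjusted inertia explained by the SCFA set.

Significance uses the pseudo-F

$$F = \frac{\text{constrained}/q}{\text{residual}/(n - q - z - 1)}$$

with $q$ constraint axes and $z$ condition columns, under reduced-model
residual permutation: the chi-square residuals left after removing the
conditions are row-permuted and the fit recomputed, so transit stays
attached to its sample. This is the conservative scheme for testing
constraints in the presence of conditions; the test is calibrated on the
generator's confounded null (rejection rate statistically indistinguishable
from 0.05 at $\alpha = 0.05$) precisely because permuting raw rows instead
would break the transit linkage and inflate the size.

### Scaling and sign conventions

Species scores are reported in the community-ecology "species" scaling:
unit right-singular vectors divided by $\sqrt{c}$ and multiplied by the
axis singular value. Biplot arrows are the $r$-weighted correlations of
each (standardised) constraint with the site scores. Both conventions were
verified against an independent constrained-ordination implementation to
$10^{-6}$ on shared inputs; the 0.5 projection cutoff therefore lives on
the familiar scale of published CCA biplots. Because an SVD determines axes
only up to sign, each axis is oriented so that the constraint with the
largest absolute arrow component on that axis points positive; all
downstream geometry (angles, absolute projections, retained sets) is
invariant to this choice, which exists purely to make outputs reproducible.

### One joint model or one model per SCFA?

Both modes are provided. The joint model (all SCFAs plus the
acetate:butyrate ratio as constraints) summarises the shared structure, and
its omnibus permutation test is the headline significance statement. For
*ranking taxa against an individual SCFA* the package defaults to the
single-constraint mode in `rank_by_group()` examples and acceptance
checks: with one constraint (plus conditions) there is exactly one
constrained axis, the axis *is* the SCFA direction, and the cone degenerates
to the sign distinction with only the 0.5 magnitude threshold active — the
1-D fallback built into `project_taxa()`. In the joint model the biplot
plane holds only the first two of up to four constrained axes, so drivers
of an SCFA whose arrow loads on later axes are geometrically invisible;
the per-SCFA mode has no such blind spot.

## The projection-score statistic

In the plane of the first two constrained axes, let $u$ be the unit vector
along the chosen SCFA arrow and $v$ a taxon's species-score vector. The
angle to the axis *line*, $\theta = \arccos(|\langle v, u\rangle| / \|v\|)$,
treats positive and negative associations symmetrically; a taxon is
retained iff $\theta \le 30^\circ$ and $|\langle v, u\rangle| \ge 0.5$, and
the signed projection $\langle v, u\rangle$ is the ranking statistic. Ties
in absolute score are broken lexicographically by feature identifier so the
ranking is deterministic. The geometry is invariant under joint rotation of
scores and arrows (tested to $10^{-10}$), and tightening either threshold
can only shrink the retained set.

## The consensus network

`learn_structure()` performs greedy hill climbing from the empty graph over
single-edge additions, deletions and reversals, maximising the Gaussian BIC
network score (per-node log-likelihood given parents minus
$\tfrac{k}{2}\log n$). The search is deterministic: equal-score moves break
lexicographically by (operation, source, target). Two numerically identical
implementations ship — a compiled search used by default and a pure-R
reference — and the test suite asserts they produce the same graph move for
move. Scores are computed from the covariance matrix with a $10^{-8}$
relative ridge so bootstrap resamples with duplicated rows and strongly
co-occurring taxa remain well-posed, and the number of parents per node is
capped at $\max(3, n/10)$ to prevent small resamples from overfitting
near-collinear variables.

`bootstrap_consensus()` learns a structure on each of `n_boot` (default 500)
row resamples; an undirected edge is retained when it appears (in either
direction) in at least 50% of resamples, its direction is the majority
direction (ties flagged undirected), residual directed cycles are broken by
dropping the weakest edge, and every retained edge carries the sign of its
partial regression coefficient. A claim in the underlying procedure about
including associations by partial-correlation sign is ambiguous as printed;
the package therefore *annotates* each edge with the sign instead of
filtering on it. The network stage of `run_pipeline()` takes as nodes the
projection-retained taxa, the SCFA quantities and transit: these are the
variables the network is meant to cross-validate, and keeping the node set
focused makes a 500-resample ensemble honest rather than nominal.

## The synthetic cohort and what it does (not) show

`cohort_config()` defaults define the study conditions for all calibration
and power statements:

* **Design**: three clinical groups (healthy volunteers, IBS with
  constipation, IBS with diarrhea) of 17/15/26 samples; 100 species-level
  taxa.
* **Composition**: logistic-normal — a power-law log-abundance skeleton
  ($\propto -1.2\log\text{rank}$), per-taxon Gaussian dispersion
  $\sigma = 2$ on the log scale (realistic species-level overdispersion,
  which also sets the chi-square inertia, and hence the species-score
  magnitudes, on the scale published biplots show), softmax closure. An
  optional multinomial count layer adds sequencing-depth noise.
* **Transit**: log-normal per group with medians 1.4 / 1.5 / 0.9 days and
  log-SD 0.55.
* **Confounding**: ten taxa (ranks 31-40) respond to transit with
  alternating log-slopes $\pm 0.8$ per day, and each SCFA carries a direct
  transit slope (−1.5, −0.6, −0.6 µg/mg per day), so taxa and SCFA are
  marginally correlated with *no* direct coupling — the structure the pCCA
  conditioning must, and in tests does, remove.
* **Drivers**: taxa 2-11 (the dominant taxa after the reference; dominant
  fermenters shaping SCFA output is the natural reading) carry signed
  loadings $\pm 2$ µg/mg per unit log-ratio onto acetate (4), butyrate (4)
  and propionate (2). Two structural choices matter and are easy to miss:
  loadings are **sign-balanced within each SCFA**, because with a shared
  ALR reference an unbalanced set leaks reference noise into every taxon's
  marginal association and cancels the minority-sign driver's signal; and
  same-SCFA, same-direction drivers co-occur as a **producer guild**
  (latent correlation 0.8), mirroring cross-feeding consortia — without it
  the marginal correlation of each of $m$ independent equal drivers is
  capped at $1/\sqrt{m}$ regardless of effect size.
* **SCFA scale**: intercepts 8/6/6 µg/mg dry weight with measurement noise
  SD 0.4 and zero-truncation by noise resampling (no point mass at zero).
  Typical synthetic totals sit near 20 µg/mg, the upper quartile of
  clinically reported values; the intercepts are kept high relative to the
  driver variance so the truncation mass stays small and planted linear
  effects remain identifiable.
* **Extras**: age/sex/BMI/diet covariates, group-dependent stool bile acid
  totals with a threshold-derived bile-acid-malabsorption flag — all
  synthetic conveniences for exercising the covariate-adjusted stages, not
  calibrated biology.

Effect sizes are deliberately strong: the generator exists to verify that
the machinery recovers *known* structure with high probability at cohort
sizes of tens of samples, not to mimic the modest effects of real cohorts.
Passing tests therefore show correctness of the statistical machinery under
a favourable, known-truth regime. They do not show that real stool
metagenomes satisfy the logistic-normal model, that real microbe-SCFA
couplings are log-linear, nor that transit confounding in patients is fully
linear — on real data the conditioning removes only the linear transit
component, and zero-inflation beyond pseudocounting is not modelled.

## Numerical choices and degenerate inputs

* ALR reference defaults to the taxon with the highest minimum relative
  abundance (most consistently present); pseudocount defaults to half the
  smallest nonzero relative abundance; both are overridable. The 0.1%
  abundance filter is applied per sample within group (the stricter of the
  two plausible readings).
* Constraints that are entirely absorbed by the conditions (zero residual
  norm) are dropped with a warning rather than fitted as numerical noise;
  if all are absorbed the ordination returns a zero-axis fit with
  constrained inertia 0. Genuinely collinear constraints are an error that
  names the offending columns.
* Permutation p-values use the add-one convention
  $p = (1 + \#\{F^* \ge F\})/(1 + n_\text{perm})$, so the smallest
  attainable p at 999 permutations is exactly 0.001.
* PERMANOVA uses sequential (Type I) sums of squares with covariates before
  group, Gower centring without negative-eigenvalue correction, free row
  permutation without covariates and Freedman-Lane residual permutation
  with them.
* Per-trait comparisons drop missing values for that endpoint only and
  never impute; fully tied traits return a flagged degenerate result with
  p = 1. Per-feature linear models apply no multiplicity correction by
  default (optional Bonferroni/Benjamini-Hochberg flags), matching the
  exploratory framing of the analysis they implement.

## A worked run

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(
  generator = cohort_config(),   # study-sized synthetic cohort
  n_perm = 999, n_boot = 500, seed = 1,
  out_dir = "scfamap-results")
run <- run_pipeline(cfg)
run
glance(run$pcca_test)
attr(run$rankings, "counts")
autoplot(run$pcca_test$fit)
plot_projection_ranking(run$rankings)
autoplot(run$network)
```

Problem sizes used by the shipped verification suite: oracle equivalence on
fifty 10-sample tables; calibration on 200 null cohorts of 20 samples at
199 permutations; power on 100 cohorts of 60 samples; driver recovery on 50
cohorts of 180 samples; chain recovery on 25 linear-Gaussian systems of 500
observations at 100 bootstrap resamples; cross-method concordance on
study-sized cohorts with a 50-resample consensus over the top-ranked taxa.

## Known limitations

* The ALR transform depends on the reference; rankings are stable under
  reasonable references in the synthetic regime but this is not guaranteed
  for arbitrary data.
* Hill climbing finds a local BIC optimum; the bootstrap consensus, not any
  single learned graph, is the supported output. Gaussian BIC on ALR data
  assumes approximate multivariate normality.
* The 0.5 projection threshold is meaningful on the species-focused scaling
  only; both the threshold and the scaling are configurable, and rankings
  produced under other scalings should not be compared against it.
* Covariate *selection* is out of scope: covariates are supplied
  explicitly, never chosen by the package.
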