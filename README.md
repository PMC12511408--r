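# scfamap

Mapping microbe–metabolite relationships in stool metagenomes: which
bacterial species shape short-chain fatty acid (SCFA) output, once the
confounding effect of colonic transit time is removed?

`scfamap` is an R package for clinical microbiome studies — IBS subtyping
being the motivating case — in which paired data are available per
participant: a species-level relative-abundance table, stool SCFA
concentrations (acetate, butyrate, propionate), colonic transit time, a
clinical group label and baseline covariates. It provides a tested,
reusable implementation of a transit-conditioned microbe–SCFA association
pipeline, together with a synthetic cohort generator with planted ground
truth against which every stage is validated.

## The method at its core

The engine is partial canonical correspondence analysis (pCCA) with a
biplot projection-score ranking:

- Form the chi-square residual matrix of the composition,
  `Q̄_ij = (P_ij − r_i c_j) / √(r_i c_j)`; its sum of squares is the total
  inertia.
- Remove the variance explained by the conditioning variable (transit) by
  weighted least squares, then project what remains onto the SCFA
  constraints; the SVD of the fitted part yields constrained eigenvalues
  and the inertia partition `total = conditional + constrained + residual`.
- Test the constrained fraction with the pseudo-F
  `F = (constrained/q) / (residual/(n − q − z − 1))` under reduced-model
  residual permutation (transit stays attached to its sample).
- Rank taxa per SCFA by the signed projection `⟨v, u⟩` of each species
  score `v` onto the SCFA arrow direction `u` in the biplot, keeping taxa
  within a 60° cone around the axis line with `|⟨v, u⟩| ≥ 0.5`.
- Cross-validate with a bootstrap-consensus Gaussian Bayesian network
  (greedy hill climbing on the BIC network score; edges retained when they
  appear in ≥ 50% of resamples): projection-ranked taxa should reappear as
  direct or indirect SCFA neighbours.

Around the engine: Bray-Curtis / Euclidean-on-ALR PERMANOVA with covariate
adjustment (Freedman-Lane), the 0.1%-abundance / 2-specimen prevalence
filter, a 3-fold differential-abundance screen, Kruskal-Wallis + Dunn +
Bonferroni trait comparisons, covariate-adjusted per-taxon linear models,
and gut-metabolic-module (KEGG orthogroup) association models.

## Worked example

```r
library(scfamap)

cfg <- pipeline_config(
  generator = cohort_config(),   # synthetic cohort: 17 HV / 15 IBS-C / 26 IBS-D
  n_perm = 199, n_boot = 100, seed = 1)
run <- run_pipeline(cfg)
run
#> scfamap pipeline run
#>   stage n_samples n_features
#>   input        58        100
#>  filter        58        100
#>    pcca        58        100
#> PERMANOVA (unadjusted): F = 0.886, p = 0.675
#> pCCA: F = 1.565, p = 0.02, R2 = 0.1075
#> retained taxa per group x SCFA:
#>  group_id                scfa_id n_retained n_features
#>        HV                acetate         32         98
#>  ...
#>   overall                acetate         11        100
```

The pCCA line is the headline statistic: after conditioning on transit,
the four SCFA constraints explain 10.8% of the remaining community inertia
(`R2 = 0.1075`) and the association is significant by permutation
(`p = 0.02` at 199 permutations). The per-group table counts the taxa
whose projection scores survive the 60°/0.5 retention rules — the "number
of ranked bacteria" readout per clinical group and SCFA.

```r
dplyr::filter(run$rankings, group_id == "overall", scfa_id == "acetate", retained)
#>   group_id scfa_id feature_id projection_score angle_deg retained
#> 1  overall acetate  taxon_002           1.108      0.005     TRUE
#> 2  overall acetate  taxon_084           0.951     20.868     TRUE
#> 3  overall acetate  taxon_004           0.890      9.884     TRUE
#> ...
```

`taxon_002` and `taxon_004` are two of the generator's planted positive
acetate drivers, recovered at the top of the ranking with the correct
sign; `projection_score` is the signed projection onto the acetate arrow
and `angle_deg` the angle to the axis line. The consensus network
(`tidy(run$network)`) independently attaches driver taxa to their SCFAs:

```r
generics::tidy(run$network)
#>        from         to frequency direction sign
#> 1 taxon_002  taxon_004      1.00   forward    1
#> 2 taxon_011 propionate      1.00   forward   -1
#> 3 taxon_010 propionate      0.99   forward    1
#> ...
```

`autoplot(run$pcca_test$fit)` draws the biplot,
`plot_projection_ranking(run$rankings)` the signed ranking bars, and
`autoplot(run$network)` the consensus graph. All result types have
broom-style `tidy()`/`glance()` methods and export to TSV via
`write_result_tables()`.

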