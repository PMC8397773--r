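# gutnet

Social networks and gut-microbiota transmission in wild rodent
populations.

Gut symbionts can spread between hosts through social contact, but in
species that do not live in groups the social signal is hard to separate
from shared space, shared kin and shared time.  gutnet is for ecologists
and microbiome researchers who track free-living animals with passive
loggers (RFID/PIT-tag stations) and profile their gut communities with
16S amplicon sequencing.  It implements the full inference chain from
raw detections to the two headline questions:

1. **Does social association predict microbiota similarity?**  Dyadic
   regression of pairwise Jaccard similarity on social association
   strength, controlling for spatial distance, sampling interval,
   kinship, and sex/age similarity, with permutation-based inference.
2. **Does network position predict microbiota diversity?**  Covariate-
   adjusted models of asymptotic richness on six centrality metrics with
   node-permutation tests.

## The model

Social networks are built from (night, logger) co-occurrence *instances*
under sliding association windows (12 h down to 2 min).  Association
strength is the lifespan-adjusted Simple Ratio Index

```
I = X / (X + y_AB + y_A + y_B)
```

with `X` the instances a dyad was associated (detections within the
window at the same logger-night), `y_AB` instances with both observed but
not associated, and `y_A`, `y_B` instances with one observed while the
other was alive but unobserved — the denominator restricted to nights
inside both lifespans.

Microbiota similarity is the Jaccard Index (shared ASV proportion;
Bray–Curtis as an abundance-weighted check), modelled on the logit scale.
Inference is permutation-based throughout: node-label permutations for
the dyadic and centrality models, Double-Semi-Partialing MRQAP, Mantel
tests, and PERMANOVA; diversity uses Chao1 and Chao–Jost asymptotic
estimators.  Robustness procedures include a density-matched
edge-thinning null and a leave-one-bacterial-family-out dropout analysis.
A synthetic-data generator with known transmission ground truth
(`simulate_study()`) emulates all five inputs — logger records,
individual and sample metadata, ASV counts with taxonomy, kinship — so
every stage is testable without field data.  See the methods vignette
(`vignettes/gutnet-methods.Rmd`) for the full model description.

## Worked example

```r
library(gutnet)

params <- sim_params(n_individuals = 20, n_nights = 40, seed = 42)
study  <- simulate_study(params)

events   <- detect_associations(study$records, study$individuals,
                                window_minutes = c(2, 720))
sri_2min <- adjusted_sri(events[["2"]])
network_summary(sri_2min)
#>   n_individuals n_edges density mean_weight sd_weight kind  window_minutes
#> 1            20      40   0.211      0.0458    0.0522 SRI                2

community  <- filter_community(study$community)
#> Filtered 33 ASV(s): 2 singleton(s), 0 in excluded taxa, 31 unobserved; 167 ASV(s) retained.
similarity <- jaccard_similarity(community)
dyads <- build_dyad_table(similarity, sri_2min,
                          spatial_summary(study$records),
                          study$kinship, study$individuals, study$samples)
fit <- fit_dyadic_model(dyads, n_perm = 999, seed = 1)
fit
#> <dyadic_fit 'main': 1710 dyads, 20 individuals, 999 permutations, seed 1>
#>   term              estimate p_perm  conf_low conf_high
#> 1 social_strength    5.54     0.001  2.85       8.14
#> 2 spatial_distance  -0.441    0.067 -0.898      0.0256
#> 3 kinship            0.524    0.022  0.0221     0.937
#> 4 sex_same          -0.0137   0.905 -0.211      0.143
#> 5 age_same           0.0650   0.633 -0.206      0.284
#> 6 sampling_interval  0.00362  0.578 -0.000171   0.00845
```

The social slope (5.54 on the logit scale, permutation p = 0.001) is the
generator's injected transmission signal recovered from the 2-min
network; spatial distance trends negative (nearer pairs more similar) and
the other covariates are near zero.  Centrality then predicts richness:

```r
cent <- centrality_suite(sri_2min)
diversity_model(cent, alpha_diversity(community), study$samples,
                "degree", n_perm = 1000, seed = 1, always_permute = TRUE)
#>   metric response estimate  p_model  p_perm n_individuals
#> 1 degree richness     3.02  1.9e-04 9.99e-04            20
```

Well-connected individuals carry ~3 more asymptotic ASVs per additional
social partner — the diversifying effect of social transmission.
`autoplot()` methods draw coefficient plots, thinning-null comparisons
and family-dropout panels; `tidy()`/`glance()` return tibbles.

A thin command-line front end with subcommands (`simulate`, `network`,
`diversity`, `dyadic`, `centrality`, `null-thinning`, `dropout`) is
installed at `inst/scripts/gutnet-cli.R`; it reads a YAML run
configuration, writes TSV results and a JSON manifest per stage.

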