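---
title: "Methods: social networks and gut-microbiota transmission with gutnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: social networks and gut-microbiota transmission with gutnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gutnet implements an end-to-end analysis of social transmission of gut
symbionts in a tracked wild rodent population: from raw spatiotemporal
logger detections, through social-network construction, to the two headline
inferences that (i) dyadic social association strength predicts
gut-microbiota similarity, controlling for space, time, kinship and host
attributes, and (ii) social network centrality predicts microbiota
richness.  Because suitable field data are rarely public, the package ships
a synthetic-data generator with known transmission ground truth, so the
whole pipeline is testable end to end.

# From logger records to a social network

The raw material is a table of time-stamped detections of PIT-tagged
individuals at fixed logger stations.  Nocturnal rodents are active between
`night_start_hour` (default 18:00) and `night_end_hour` (default 06:00);
a *night* spans that window and an *instance* is a (night, logger)
combination — the sampling unit of association.

Two individuals are *associated* at an instance when any detection of one
lies within `window_minutes` of any detection of the other at that logger
that night (boundary inclusive; multiple qualifying pairs within one
instance count once).  Sliding the window from 12 h down to 2 min (720,
240, 60, 30, 10, 2 min) produces a family of networks with increasingly
intimate edge definitions: a 12 h edge means "used the same place the same
night", a 2 min edge implies close spatiotemporal coincidence.

Association strength is the lifespan-adjusted Simple Ratio Index

$$I \;=\; \frac{X}{X + y_{AB} + y_A + y_B},$$

where $X$ counts instances with the dyad associated, $y_{AB}$ instances
where both members were observed that night but not associated, and $y_A$,
$y_B$ instances where one member was observed while the other was alive
(between its first and last observation) but unobserved.  Restricting the
denominator to nights inside both lifespans lets individuals with partial
study-period overlap coexist in one static network without penalising
dyads that could never have met.  When every lifespan covers the whole
study period the index reduces to the classical Simple Ratio Index, and
the test suite verifies this equivalence against an instance-by-instance
brute-force oracle.

Two bookkeeping details are not fully determined by the index's verbal
definition, and both are explicit, flagged conventions:

* **Same-night, different-logger co-observations.** Under the default
  `yab_convention = "per_logger"`, every logger-night at which exactly one
  member appears while the other was observed elsewhere that night
  increments $y_{AB}$ once; `"per_night"` collapses these to one increment
  per night.
* **Same logger, outside the window.** Counted in $y_{AB}$ (both observed,
  not associated), not in the single-observation terms.

Timestamp comparison is pairwise by default; a `chain = TRUE` flag
switches to single-linkage chaining (A 9 min from C, C 9 min from B links
A to B under a 10-min window) for sensitivity checks.  Binary networks
(`binary_index()`) record only whether a dyad was ever associated.

# Microbiota processing and diversity

The community data enter as a samples-by-ASVs integer count table with a
taxonomy through the family rank, i.e. downstream of standard 16S
amplicon denoising.  `filter_community()` removes table-wide singleton
ASVs (total count 1; a per-sample variant is available by flag), ASVs
assigned to non-gut taxa (Cyanobacteria, Mitochondria — chloroplast and
host signal), and never-observed ASVs, with full accounting messages.
`normalise_community()` converts to within-sample proportions.

Beta diversity uses two complementary metrics, both delegated to vegan's
distance machinery and cross-checked in the tests against per-pair
brute-force oracles:

* **Jaccard Index** — the proportion of shared ASVs between two samples
  ($|A \cap B|/|A \cup B|$ on presence sets; 1 minus the binary Jaccard
  distance).  Presence/absence is the natural scale for transmission:
  acquiring a taxon changes support regardless of its abundance.
* **Bray–Curtis dissimilarity** — abundance-weighted, less sensitive to
  low-abundance artefacts, used as a robustness check.

Alpha diversity corrects for unseen taxa at finite depth:
Chao1 asymptotic richness ($S_{obs} + f_1^2/2f_2$ when doubletons exist,
else $S_{obs} + f_1(f_1-1)/2$) and the Chao–Jost asymptotic Shannon
entropy, whose observed part uses the digamma identity
$\sum_{k=x}^{n-1} 1/k = \psi(n) - \psi(x)$ and whose unseen-species
correction uses the singleton/doubleton coverage estimator.  These closed
forms are implemented directly; the suite pins them to hand-computed cases
and to the $\ln 4$ limit for a deep uniform 4-ASV sample.  Optional
rarefaction (`rarefy_community()`, default depth 90% of the smallest
retained sample) guards the beta-diversity results against read-depth
variation.

# Dyadic inference by permutation

`build_dyad_table()` assembles one row per unordered between-individual
sample pair: the similarity response plus social association strength,
spatial distance between mean logger coordinates, sampling interval in
days, kinship, sex- and age-similarity, and the dyad sex category (FF, MF,
MM).  Spatial distance and sampling interval are min–max scaled to [0, 1]
over the analysed table so all coefficients are comparable; the remaining
covariates are naturally in [0, 1].

The response is a proportion, so models are fit on the logit scale with a
clamp $\varepsilon$ (default $10^{-6}$, configurable up to 0.01) keeping 0
and 1 finite.  Coefficients are ordinary least squares; *inference* is by
**node-label permutation**: individual identities are permuted jointly
across every individual-level pairwise structure (social, spatial,
kinship, sex, age) while the response and the sample-level sampling
interval stay fixed, and the model is refit per permutation.  Because a
permutation moves a whole individual — with all its samples and all its
dyads — the procedure respects the dyadic dependence and repeat-sampling
structure that random-effect formulations absorb, while keeping the
artifact free of MCMC machinery.  Two-sided p-values use +1 smoothing,
$p = (1 + \#\{|\beta^*| \ge |\hat\beta|\})/(n_{perm}+1)$, and 95%
intervals are the 2.5/97.5 percentiles of
$\hat\beta - (\beta^* - \bar\beta^*)$.  A fixed-slope model with
permutation uncertainty is reported rather than a random-slope analogue,
which has no exact permutation counterpart; this is a documented
difference from hierarchical-Bayesian formulations of the same question.

The sex-interaction variant gives social association one slope per dyad
sex category (plus category main effects), so sex-dependent transmission
appears directly as category-specific slopes; categories with fewer than
two dyads are flagged inestimable.

Three standard complements triangulate the main model:

* **MRQAP** (Double-Semi-Partialing): each predictor matrix is
  residualised on the others, the residual matrix's rows and columns are
  permuted jointly, and the |t| statistic is compared across permutations.
  `mrqap_microbiota()` applies it to an individual-level response built
  from one random sample per individual, repeated over several seeded
  draws with the median p reported, so no single arbitrary draw decides.
* **Mantel tests** for kinship (and for comparing networks across edge
  definitions).
* **PERMANOVA** (vegan `adonis2`, marginal or sequential) for
  individual-level predictors of composition — month, age, sex, and the
  repeatability of individual identity.

Degenerate inputs are handled deterministically: constant covariates are
reported with estimate 0, p = 1 and a `"constant"` flag; a constant
response or a collinear covariate pair (|r| > 0.999) is an error naming
the offender.

# Centrality and diversity

`centrality_suite()` computes six node metrics capturing different
transmission-relevant aspects of connectedness: degree, weighted degree
(strength), eigenvector centrality (scaled to max 1), betweenness on
weighted shortest paths with distance = 1/weight (unnormalised, the
standard treatment for association indices), Stephenson–Zelen information
centrality, and bridge propensity.  Two of these require conventions:

* **Information centrality** uses the resistance formulation: with
  weighted Laplacian $L$ and $C = (L + J)^{-1}$,
  $I_i = 1/(C_{ii} + (\mathrm{tr}\,C - 2\sum_j C_{ij})/n)$, equal to $n$
  over the node's summed resistance distances.  It is computed per
  connected component (isolated nodes get 0) and tested against an
  independent pseudoinverse-based resistance oracle on exhaustively
  enumerated small graphs.
* **Bridge propensity** has no canonical formula; it is defined here as
  the mean over a node's partners of one minus their neighbourhood
  overlap, $\mathrm{overlap}(i,j) = |N(i) \cap N(j)| / |N(i) \cup N(j)
  \setminus \{i,j\}|$ (empty unions count as overlap 0).  A hub whose
  partners share no other neighbours scores 1; a clique member scores 0.

`diversity_model()` regresses individual-mean asymptotic richness (or
Shannon) on screened covariates plus one centrality metric and reports
both the model-based p and a node-permutation p obtained by shuffling
centrality values across individuals (1000 permutations by default).
Following a two-stage rule, the permutation p is computed only when the
model p is below 0.05, unless forced.  `covariate_screen()` implements the
preliminary simplification step, retaining covariates with p < 0.1.

# Sensitivity analyses

**Density-matched thinning null.**  More intimate edge definitions give
sparser networks, so a stronger effect in the 2-min network could in
principle reflect density alone.  `thin_network()` removes the weakest
edges of the 12 h network until it has exactly the edge count of each
comparison network (ties at the cutoff broken by a seeded draw; retained
weights unchanged), and `thinning_null_analysis()` refits the dyadic model
with the thinned network as predictor.  A real intimacy gradient vanishes
in these nulls.

**Family dropout.**  `family_dropout()` recomputes the Jaccard response
with each bacterial family excluded in turn and refits the dyadic model
per network, logging each family's ASV richness.  Families whose exclusion
attenuates the social effect are candidate socially transmitted taxa.  The
same permutation seed is reused for every family so differences between
families reflect composition, not Monte-Carlo noise; a family whose
removal empties a sample's support is flagged and the affected samples
dropped.

# The synthetic-data generator

`simulate_study()` produces all five pipeline inputs with known ground
truth.  Its defaults are the package's study conditions, chosen once to
emulate a semi-social nocturnal rodent population on a small monitored
woodland plot:

| parameter | default | rationale |
|---|---|---|
| `n_individuals` | 40 | a season's tracked cohort |
| `n_loggers` | 9 | 3×3 grid over the plot |
| `grid_extent` | 150 m | ~2.25 ha plot |
| `n_nights` | 60 | one field season of logging |
| `home_range_sd` | 15 m | nearest-neighbour spacing of a few–10 m |
| `visit_rate` | 3/night | several station visits per active night |
| `affinity_density` | 0.05 | ~2 strong associates per individual |
| `covisit_rate` | 0.5/night at affinity 1 | regular but not nightly co-visits |
| `transmission_strength` | 0.2/contact | probable transfer over a season of repeated contact |
| `spatial_strength` | 0.02/night at source | environmental uptake near a source |
| `drift_rate` | 0.01/night | slow community turnover |
| `n_asvs`, `n_families` | 200, 10 | desk-scale community, 5 contact-only + 5 environmental families |
| `baseline_richness` | 40 | tens of core taxa per host |
| `samples_per_individual` | 3 | repeat faecal sampling |

Individuals get uniform home-range centres, Bernoulli(0.5) sexes,
lifespans covering overlapping night subsets, and kinship from a
two-generation synthetic pedigree (full sibs 0.5, half sibs 0.25) that is
deliberately independent of social affinity — so the tests can confirm
the kinship covariate does not absorb the social effect.  Each night,
individuals visit loggers under a Gaussian kernel around their centre;
affiliated dyads additionally make synchronized co-visits (same logger,
within 2 min).  These injected events are the ground-truth contact
structure, which means shorter association windows carry a stronger true
signal — the mechanism behind the window-gradient recovery test.

Community dynamics are presence/absence: transmission transfers support,
it does not move abundance, matching the Jaccard-centred analysis.
Contact-only-guild ASVs transfer at contact events with probability
`transmission_strength` (females transfer nothing to females under
`sexdep = "male_biased"`); environmental-guild ASVs colonise from fixed
spatial sources; resident ASVs drop out at `drift_rate`.  Faecal samples
are multinomial draws at log-normal depth (~10^4 reads) from lognormal
abundance weights over the present ASVs.  Sampling dates are spread over
the final two thirds of each lifespan: the generator starts from asocial
baseline communities, so a burn-in period is required before sampled
communities reflect accumulated transmission history, whereas a wild
population is sampled at quasi-steady state from the outset.

Two generator behaviours discovered during design are worth recording
because they constrain the defaults.  First, transmission intensity has an
interior optimum for *dyadic* signal: stronger or denser transmission
homogenises the population through multi-step chains and flattens the
dose–response between a dyad's own contact rate and its similarity.  The
default affinity density of 0.05 keeps the affiliation graph sparse enough
that direct partnerships, not chains, dominate — which is also what makes
the male-male slope recoverable under male-biased transmission.  Second,
with a shared heavy-tailed abundance distribution, baseline communities of
different individuals already overlap substantially; the family-structured
individual preferences (Dirichlet-style weights) keep baseline Jaccard
moderate so a transmission contrast is measurable.

What the generator does *not* emulate: 16S read-level artefacts (chimeras,
sequencing error — counts are drawn at the ASV level), seasonal diet
shifts, age structure in communities, or abundance-mediated transmission.
Passing recovery tests therefore demonstrates that the pipeline detects
the designed presence/absence transmission structure at field-realistic
scale; it does not certify performance under real-data artefacts absent
from the generator.

# Numerical choices and test scale

* Logit clamp $\varepsilon = 10^{-6}$; covariate min–max scaling is
  recomputed per analysed table (so subset analyses are internally
  scaled).
* All permutation p-values use +1 smoothing and are two-sided; the
  smallest achievable p is $1/(n_{perm}+1)$.
* Thinning tie-breaks, rarefaction, sample-per-individual draws and every
  simulation stage are seeded; rerunning any stage with the same seed is
  bit-identical, and result objects and manifests carry seed and
  permutation counts.
* The test suite sizes simulations for a single CPU: calibration checks
  use 500 null replicates at 199 permutations with 15–30 units;
  ground-truth recovery uses 25–50 replicates at the full study conditions
  (40 individuals, 60 nights) and a graded-transmission sweep at 25
  individuals × 30 nights.  Formula oracles run on exhaustively enumerated
  graphs and tables of at most 6 nodes / 8 ASVs.

# Known limitations

* The adjusted-SRI denominator conventions for co-observation instances
  are reasonable readings of an under-specified verbal definition; both
  are implemented and flagged, but results can differ slightly between
  them on sparse data.
* Node-label permutation tests exchangeability of individuals; it is
  robust to dyadic dependence but, like MRQAP, approximate under strong
  heteroscedasticity across individuals.
* Bridge propensity is a package convention, not a literature-standard
  formula; treat cross-study comparisons accordingly.
* The asymptotic Shannon estimator assumes the sample is representative
  of the individual's community at collection time; very low-coverage
  samples are flagged rather than dropped.
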