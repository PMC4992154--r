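---
title: "Modelling island extirpations of threatened vertebrates: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling island extirpations of threatened vertebrates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data

Invasive mammals are the leading driver of vertebrate extinctions on
islands. This package models the *extirpation* — the post-1500 loss of one
species from one island — of highly threatened and extinct terrestrial
vertebrates, as a function of island conditions (area, precipitation,
human presence, topography), native-species traits (taxonomic class
combined with flight ability: six "class/volancy" groups), and the
presence of twelve groups of invasive mammals. The analysis unit is one
island population (one species on one island); the cluster unit is the
island, because unmeasured island-level events (storms, disease, invasion
history) correlate the fates of co-occurring populations.

Two tables drive everything: an island table (one row per island, with
abiotic covariates, human presence, and presence plus eradication flags
for each invasive group) and a population table (one row per island
population, with class/volancy and the binary outcome extirpated =
1 / persists = 0). `read_dataset()` validates both and enforces
referential integrity. Missing invasive-group information is coded as
*absent* — the conservative convention for patchy invasion records — and
eradicated invaders are coded *present* for model fitting (they were
present long enough to do damage) but *absent* for prediction of current
and future risk. This two-flag convention (`use_historical_presence` in
`build_design()`) is central: the model is trained on historical
exposure and predicts under current exposure.

## The regression model

The outcome is binary and heavily asymmetric (roughly three quarters of
populations persist), so the mean model uses the complementary log-log
link,

$$\Pr(y_{ij} = 1) = \mu_{ij} = 1 - \exp\{-\exp(\mathbf{x}_{ij}^\top
\boldsymbol\beta)\},$$

for population $j$ on island $i$. Coefficients are estimated by
generalized estimating equations (GEE): the population-averaged score

$$\sum_i \mathbf{D}_i^\top \mathbf{V}_i^{-1} (\mathbf{y}_i -
\boldsymbol\mu_i) = \mathbf{0}$$

is solved by iteratively reweighted updates, with working covariance
$\mathbf{V}_i = \phi \mathbf{A}_i^{1/2} \mathbf{R}(\alpha)
\mathbf{A}_i^{1/2}$ and an *exchangeable* working correlation
$\mathbf{R}(\alpha)$: every pair of populations on the same island shares
one correlation $\alpha$. Both $\phi$ and $\alpha$ are re-estimated each
iteration by the standard moment estimators from Pearson residuals, with
the parameter-count correction ($n - p$ and $\sum_i n_i(n_i-1)/2 - p$
denominators). Inference uses the robust sandwich covariance
$\mathbf{B}^{-1}\mathbf{M}\mathbf{B}^{-1}$, which stays valid when the
exchangeable working correlation is wrong.

Numerical choices, all exposed as arguments of `fit_gee()`:

* convergence at max $|\Delta\beta| < 10^{-8}$ within 200 iterations,
  followed by a short polish phase that drives the estimating-equation
  norm below about $10^{-8}$ (small coefficient steps do not by
  themselves guarantee a small score);
* initialisation from an independence GLM fit;
* the exchangeable inverse is applied in closed form (a rank-one update),
  so one iteration costs a handful of grouped matrix products — this is
  what makes all-subsets selection and repeated cross-validation
  affordable;
* linear predictors are clamped to $[-30, 30]$ and fitted risks to
  $[10^{-10}, 1-10^{-10}]$ during fitting; a fit with more than 2% of
  risks pinned at a boundary raises a separation warning, and
  non-convergence is flagged on the result rather than raised;
* $\phi$ is estimated rather than fixed at 1 (configurable), matching
  common GEE practice for binary data;
* with no within-cluster pairs (all islands hosting one population)
  $\alpha$ is inestimable and set to 0.

Model fit is summarised by QICu $= -2\,QL + 2p$, with $QL$ the
independence binomial quasi-likelihood at the fitted values — an AIC
analogue for estimating-equation fits sharing one correlation structure —
and by the Brier score (`fit_mse()`), since GEE fits carry no deviance.

## Covariate preparation and screening

Area, maximum elevation, temperature seasonality and body mass are
right-skewed and enter on the natural-log scale; precipitation enters
untransformed, in mm (so its coefficient is per-mm and comparisons are
made between fully specified covariate profiles rather than per-unit).
Elevation is strongly collinear with area (Pearson $r > 0.7$), so the
model uses the residual of $\log(\text{elevation}+1)$ on $\log$ area —
the size-independent part of topographic relief. The $+1$ offset keeps
zero-elevation atolls in the data.

`covariate_screen()` reports all high-correlation pairs, flags invasive
groups present on fewer than 10% of islands (too rare for stable global
effects), and flags covariates above a missingness ceiling (body mass in
practice). Rows with remaining missing covariates are dropped, not
imputed: imputation of island attributes belongs upstream with the
GIS/climate processing, which is out of scope here.

`cooccurrence_ordination()` embeds the invasive groups in two dimensions
from the Euclidean distances between their presence/absence profiles
across islands, as a diagnostic for strong co-occurrence clusters. It
initialises with classical (metric) MDS and refines by stress
majorization (the SMACOF Guttman transform), whose raw stress is
non-increasing by construction; Kruskal stress-1 is reported. A
rank-optimising non-metric view of the same distances is available from
`MASS::isoMDS()` and is used as a cross-check in the test suite; a
diffuse embedding under either view supports keeping all groups.

## Model selection

Selection reproduces a three-stage procedure:

1. **Order-wise all-subsets QICu ranking.** For each model order $k$,
   every $k$-subset of the candidate main effects is fit and ranked by
   QICu (`all_subsets_rank()`); all subsets are fit on the complete-case
   rows of the full candidate design, since information criteria are
   only comparable on identical data. Models within 2 QICu of the best
   form the top set; their coefficients are combined with weights
   $w \propto \exp(-\Delta/2)$, zero-filled over absent terms
   (`average_top_models()`). Zero-filled (full) rather than conditional
   averaging was chosen because it shrinks terms with weak support
   toward zero, which is the conservative direction for prediction; a
   different convention would only matter when top models disagree
   substantially, in which case the order curve flags instability anyway.
2. **Order choice by MSE.** The Brier score of the averaged model is
   traced across orders and the smallest order is chosen at which the
   relative improvement to the next order falls below `rel_tol`
   (default 0.5%) — a diminishing-returns rule
   (`order_curve_and_choice()`).
3. **Interaction screening and forced terms.** Starting from the top
   model at the chosen order, candidate interactions are tested
   *sequentially* in their listed order, retained iff they decrease QICu
   by more than 10 (a deliberately conservative improvement limit);
   retained terms stay in the model for later tests. Finally, term sets
   of special *a priori* interest (rats and rat-by-area, given rats'
   global notoriety and their dominance of eradication practice) are
   added jointly iff they improve QICu by more than 20
   (`screen_and_force()`). Sequential-cumulative screening reflects a
   narrative, ordered protocol; simultaneous screening can be emulated
   by calling `screen_and_force()` once per candidate against the fixed
   base.

Every decision is appended to an audit log, from which the final model
can be reconstructed (this is a test). Candidate fits that fail to
converge are excluded from rankings rather than imputed — a criterion
evaluated at a non-solution is meaningless.

## Validation

`cross_validate()` performs island-level K-fold cross-validation
(default $K = 10$): islands, never rows, are partitioned, so no island
ever straddles training and test. Each repeat-fold refit scores its
held-out rows with four error statistics (mean error, mean absolute
error, SD of error, MSE) and the ROC AUC; each fold is one validation
run, so $R$ repeats give $10R$ runs. AUC uses the Mann–Whitney rank
formulation with midrank ties — exact and $O(n \log n)$ — and is checked
against an $O(n^2)$ concordance count in the tests. Test folds that
contain a single outcome class have no defined AUC; they are recorded
and excluded from AUC aggregates with a reported count, rather than
resampled, which would bias the partition law.

`cluster_influence()` provides deletion diagnostics by *exact* refits
with each island removed (warm-started from the full fit), summarised by
a Cook-type form $\Delta\beta^\top \Sigma_{\text{robust}}^{-1}
\Delta\beta$, with row-level deletions inside the most influential
islands. Exact refits are affordable at this data scale and avoid the
approximation error of one-step methods.

## Thresholding, scenarios, and extinction debt

`choose_threshold()` converts risks to binary predictions: among all
thresholds achieving a true-positive rate of at least the target
(default 80%), it returns the one with the best true-negative rate (ties
to the larger threshold). The asymmetric target encodes the conservation
cost structure: missing a real extirpation is worse than a false alarm.
Alternate, more specific thresholds are tabulated for sensitivity
analysis; the most conservative of these serves as a worst-case bound on
predicted-extirpation counts.

`apply_scenario()` builds the counterfactual: the managed invasive
groups are set absent on the islands hosting extant threatened
populations (the input dataset is never mutated). `scenario_benefit()`
then compares baseline and managed risk for every extant population —
both computed under *current* presence, i.e. with real-world
eradications applied. A predicted extirpation is *preventable* when the
baseline classifies it extirpated and the managed scenario does not. The
per-population *extinction debt* is the risk difference
baseline − managed: the share of a population's extirpation risk
attributable to the managed invaders. Debts can be negative if a managed
group carries a protective coefficient; they are reported as-is.

Because the link is complementary log-log, exponentiated coefficients
are *not* odds ratios; `odds_ratio()` therefore compares two fully
specified covariate profiles through the fitted model, and
`risk_profile()` sweeps one covariate across a range for several
invasive-mammal combinations with everything else held at a reference
profile (e.g. median precipitation, median inhabited area).

## The synthetic-data generator

Real island-biodiversity tables cannot be redistributed with the
package, so every stage is exercised against `sim_params()` /
`simulate_dataset()`, a generative model with known ground truth:

* log-normal island areas ($\ln$ area $\sim N(\ln 9.7,\ 3.8^2)$);
* human presence Bernoulli with logistic probability increasing in
  $\ln$ area (intercept −3.214, slope 1.2);
* precipitation normal in $\ln$ area (964 + 150·$\ln$ area, SD 620 mm),
  truncated at 0;
* log elevation tracking log area with noise (slope 0.5, SD 0.7), which
  intentionally reproduces the area–elevation collinearity the
  screening stage must catch;
* per-group logistic invasive occupancy in human presence and
  $\ln$ area (`default_occupancy_model()`);
* a zero-truncated geometric number of threatened populations per
  island (mean 2.6) with classes drawn from a fixed class/volancy mix;
* outcomes with marginal risk $1-\exp\{-\exp(\mathbf{x}^\top
  \boldsymbol\beta_{\text{true}})\}$ and within-island dependence from a
  Gaussian copula with exchangeable latent correlation.

The copula gives exact marginals with tunable dependence — the
estimating-equation formulation specifies only a working correlation,
not a generative mechanism, so a concrete mechanism had to be chosen.
The latent correlation is root-found (via the bivariate-normal orthant
probability) so that the implied pairwise outcome correlation matches
the requested value at the mean marginal risk; the mapping is monotone
and is verified against brute-force integration in the tests. Because
the calibration is done at the *mean* risk, datasets with strongly
heterogeneous risks realise slightly different pairwise correlations —
acceptable for a working-correlation model whose inference is robust to
exactly this kind of misspecification.

Default parameters were calibrated once against the published
descriptive statistics of the global threatened-island dataset: ~54%
of islands uninhabited, uninhabited islands smaller and drier (median
areas ~1 vs ~150 km², median precipitation ~990 vs ~1,750 mm, overall
medians ~9.7 km² and ~1,326 mm), ~73% of islands with at least one
invasive group, uninhabited islands mostly invasive-free (~46%) or
rat/cat-only (~45%), four groups rare (<10% of islands), and ~25%
extirpation prevalence over ~2,600 populations on ~1,000 islands. The
true coefficient vector (`default_true_beta()`) uses moderate,
ecologically signed effects (harmful rats, cats, pigs,
mustelids/mongooses and humans; a negative rat-by-area interaction) with
the intercept set for 25% prevalence.

What the generator does *not* emulate: spatial or archipelago structure,
phylogenetic relatedness of species, temporal dynamics (no extirpation
dates), detection error in invasion records, and any dependence of
occupancy on precipitation or temperature. Passing tests therefore
demonstrate the correctness and calibration of the *methods* under a
plausible data-generating process, not the ecological conclusions of
any particular real dataset.

## Problem sizes used by the tests and the acceptance script

Test and script problem sizes were chosen as the smallest that give the
relevant statistics stable behaviour: parameter recovery uses 200
replicates of 1,000 islands (~5,000 records at 5 populations per island
on average, copula correlation 0.2); selection-rule error rates use 100
simulations of 400 islands; cross-validation checks use 10×10-fold runs;
the acceptance script runs the full pipeline on the ~1,000-island
paper-like dataset with 100 repeats of 10-fold cross-validation (1,000
validation runs) and an all-subsets scan over nine candidate main
effects. The fold-level definition of a validation run (each fold is one
run) was chosen because repeats × folds is the natural unit at which the
AUC's spread is reported.

## Known limitations

* The exchangeable working correlation is a modelling convenience;
  robust (sandwich) standard errors guard inference, but efficiency is
  lost if the true dependence is more structured.
* QICu shares AIC's tendency to admit weak extra terms; the >10/>20
  improvement thresholds for interactions and forced terms are
  deliberately conservative but still heuristic.
* Influence diagnostics refit per deleted island; at much larger scales
  than ~1,000 islands the one-step approximation would be preferable.
* Separation (e.g. an empty class-by-invader cell) can defeat the
  cloglog fit at small sample sizes; the fit flags it rather than
  penalising its way out, and the practical remedy is a coarser model.
* Odds ratios computed between profiles inherit the model's
  extrapolation behaviour at extreme covariate values; profiles should
  stay inside the data's support.
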