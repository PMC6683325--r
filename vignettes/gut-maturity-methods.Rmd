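---
title: "Methods: microbiota maturity, proteome response and ingredient screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: microbiota maturity, proteome response and ingredient screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gutmaturity quantifies how far a child's gut microbial community has
progressed along the program of normal early-life development, and how host
biology and candidate complementary foods respond to nutritional
intervention. This vignette explains the models and procedures the package
implements, the choices made where the methodology was genuinely open, and
what its synthetic cohorts do and do not establish about real data.

## The microbiota-age model and MAZ

Healthy infants acquire gut bacteria in a reproducible succession: taxa
adapted to a milk diet dominate the first months and recede through weaning,
while weaning-phase taxa rise toward a more adult-like community by roughly
the second birthday. Because this succession is reproducible, community
composition predicts chronological age in healthy children, and the
*prediction error* becomes a biomarker: a child whose community resembles
that of younger healthy children has an "immature" microbiota.

The package operationalizes this with a random-forest regression of
chronological age (months) on relative feature abundances, fitted to a
healthy reference cohort (`fit_age_model()`). Features may be taxa
(OTUs/strains) or functional pathway modules; both run through the same code
path, so taxonomic maturity and functional maturity differ only in the input
table.

Three refinements matter:

* **Subject-grouped cross-validation.** Longitudinal cohorts contribute many
  samples per child. All cross-validation in the package assigns whole
  subjects to folds, so a model is never evaluated on samples from a child
  it trained on; with repeated sampling, row-wise CV would leak identity and
  overstate accuracy.
* **Sparsification** (`sparsify()`). Features are ranked by out-of-bag
  permutation importance (ties broken lexicographically, so rankings are
  reproducible). Nested models on the top-*n* features are scored by
  grouped-CV mean absolute error over a grid of *n*, and the smallest *n*
  within one standard error of the minimum is selected — the usual
  parsimony rule for nested model grids. The default ceiling of 30 features
  mirrors the size at which sparse community-maturity models of this kind
  are conventionally reported. Note that the one-SE rule optimizes
  predictive parsimony, not feature recovery: when many informative
  trajectories are mutually redundant, the selected set is deliberately
  smaller than the full informative set (see "Known limitations").
* **Calibration** (`calibrate()`). MAZ needs reference statistics for
  healthy children at each age. Out-of-fold predictions for the healthy
  cohort are binned by chronological age — monthly bins, merged left to
  right until each holds at least 10 samples — and the per-bin median and SD
  of predicted age are stored. Out-of-fold rather than resubstitution
  predictions are used because resubstitution SDs are optimistically small
  and would inflate MAZ magnitudes. A floor of 0.25 months on the bin SD
  prevents a near-degenerate bin from exploding the z-scores; binning
  granularity, the merge threshold and the floor are declared conventions,
  exposed as arguments.

Scoring (`microbiota_age()`, `maz()`) then computes, per sample,

* microbiota age — the forest prediction;
* relative maturity = microbiota age − healthy median microbiota age at the
  same chronological age (months);
* MAZ = relative maturity / healthy SD of microbiota age at that age.

Samples outside the calibrated age range are flagged and left unscored
rather than extrapolated. Model features missing from a scored table are
zero-filled with a warning (an undetected taxon is a zero relative
abundance); abundances are fractions of the *whole* community and are
deliberately not renormalized to the sparse subset, which would distort the
scale the model was trained on. If more than half the model's features are
missing, the table is treated as mismatched and scoring errors.

## The synthetic cohort generator

No suitable reference cohort is distributable with the package, so the
generator provides cohorts with known ground truth.

Each taxon follows a two-parameter logistic trajectory in log abundance
(`taxon_trajectories()`): milk-phase taxa decline with age, weaning-phase
taxa rise, neutral taxa are flat. Trajectory midpoints are drawn uniformly
over 4–20 months and per-month logit rates over 0.4–1.2, spreading
transitions across the observation window the way milk- and weaning-phase
organisms spread theirs; the logistic swing is 4 log units, giving roughly
50-fold dynamic range between a taxon's young and old expected abundance.
The community composition at age *a* is the softmax of the per-taxon log
abundances, and an observed sample is a Dirichlet draw centred on that
composition with concentration `dispersion` × expected proportions
(default 300, putting per-taxon sampling noise in the range typical of
relative-abundance estimates from moderate-depth amplicon sequencing).
Dirichlet noise was chosen over a logistic-normal because its moments are
closed-form, which keeps the noise-free and infinite-dispersion limits
exactly checkable.

Immaturity is modeled as multiplicative age compression: a cohort with
factor *c* < 1 sampled at chronological age *a* is drawn from the healthy
generative law at effective age *c·a* (`generate_immature_cohort()`).
A multiplicative rather than additive lag keeps behavior sensible near
birth (an additive lag would demand samples from negative ages).
The standard study-scale conditions are 25 subjects sampled monthly over
months 1–24, 60 taxa of which 30 are age-discriminatory — the scale of the
healthy reference birth cohorts these models are built on.

The proteome generator (`generate_proteome()`) emulates an aptamer-panel
experiment: 1305 proteins, a healthy and a SAM reference group of 30
subjects each, and per treatment arm 30 subjects with paired pre/post
visits. Healthy and SAM means differ by ±1 log2 unit on 50 planted proteins
per direction; each arm reverses a configured fraction of that shift
post-intervention. The total per-observation noise SD is 0.5 on the log2
scale, split evenly between a per-subject intercept (shared by paired
visits) and visit-level noise, so paired contrasts gain the efficiency
pairing should give.

The diet screen generator (`generate_diet_design()`) produces 14 diets as
random ingredient-inclusion profiles over 12 ingredients fed to a 14-strain
consortium, with planted (ingredient, strain) slopes on the log-abundance
scale, closed to relative abundances by a softmax.

What the generator does **not** emulate: phylogenetic correlation among
taxa, inter-subject variance structure (subjects are exchangeable draws
around a common trajectory — the real inter-subject covariance of these
cohorts is not characterized well enough to claim fidelity), breastfeeding
and antibiotic covariates, sequencing error, and batch effects. Passing
recovery tests on these cohorts therefore demonstrates that the estimators
are correct under their assumed data-generating law — not that the law is
an adequate model of any particular population.

## Moderated differential abundance

Protein panels have many features and few samples, so per-protein variance
estimates are noisy. The package uses the empirical-Bayes moderated t:
per-protein residual variances s² (on d degrees of freedom) are shrunk
toward a prior s₀² with weight d₀,

s²_post = (d₀·s₀² + d·s²)/(d₀ + d),

and the contrast is referenced to d₀ + d degrees of freedom. The prior
(d₀, s₀²) is estimated by method-of-moments on log s²: a scaled chi-square
has known log-mean and log-variance, so matching the observed mean and
variance of the log variances identifies both parameters (the trigamma
inverse is computed by Newton's method). At d₀ = 0 the statistic reduces
exactly to the pooled-variance two-sample t — a limit the tests assert
numerically — and the implementation is cross-checked against the
established eBayes implementation on heteroskedastic panels. Unpaired
healthy-vs-SAM contrasts use the two-sample form; pre/post contrasts use
the one-sample form on within-subject differences. Constant proteins get a
floored variance and a flag rather than an error.

Downstream conventions, each a declared choice where the field's practice
varies:

* Panel values are analyzed on the log2 scale (RFU-like measurements are
  positive and right-skewed); `read_proteome_panel(log2_transform = TRUE)`
  transforms linear input on load.
* Discriminatory sets: top 50 per direction by fold difference among
  proteins passing raw p < 10⁻⁷. The threshold is interpreted as raw
  because set construction pre-selects by rank anyway; it is exposed as an
  argument.
* Treatment-effect maps: per arm, the mean within-subject post−pre log2
  change per protein, normalized per protein by subtracting the across-arm
  mean, so normalized values sum to zero across arms and a single arm's
  shift is read relative to the others.
* Category labels: within caller-supplied annotation categories (e.g. GO
  sets from a GMT file), proteins with linear fold-difference strictly
  above 1.3 (30%) and BH-FDR q < 0.05 are labeled by direction. Set
  *enrichment* itself is out of scope: categories come from the caller.
* Multiple testing is Benjamini-Hochberg throughout, applied once per
  screen.

## Rank-correlation screens

`spearman_screen()` correlates every column of one table against every
column of another (pairwise-complete, average ranks for ties). For n ≤ 9
paired observations the two-sided p-value is exact, from full enumeration
of all n! permutations; beyond that the t approximation on the rank
correlation is used. FDR is applied once across the whole screen rather
than per row, matching how ingredient-by-strain screens are read as a
single heatmap. Constant columns yield missing estimates and are excluded
from the FDR family rather than poisoning it.

## Numerical and reproducibility choices

* All randomness in a generator or fit flows from one integer seed;
  distinct operations draw from sub-streams derived by hashing the
  operation name, so adding an operation does not reshuffle another's
  draws. Identical config + seed reproduces bit-identical tables, models
  and score files (forests are single-threaded with fixed seeds).
* Importance ties break lexicographically by feature id.
* Abundance rows must sum to 1 within 10⁻³ (renormalized with a message
  within that band, rejected beyond it, naming the offending samples).
* Writers emit a `#`-comment header with package version and seed and write
  atomically (temp file + rename).

The study-scale problem sizes used throughout the tests — 600-sample
reference cohorts, 1305-protein panels with 30 subjects per group, 200-panel
null calibrations, 5-seed recovery averages — were chosen to match the
scale of the cohorts and assays this class of analysis is applied to while
keeping a full verification run on a laptop comfortable.

## Known limitations

* The one-SE sparsification rule selects for parsimony. On communities
  where many discriminatory trajectories are mutually redundant, the
  selected sparse set stabilizes around 20–25 features even when 30 taxa
  truly carry age information, and compositional closure lets a few neutral
  taxa rank among the informative ones. Recovery of the *full* planted set
  within the *selected* set is therefore structurally bounded below 100%;
  the importance ranking itself recovers planted taxa well (~90% in the top
  30). Fixing the sparse size at `max_features` instead (as fixed-size
  30-taxon models in the literature effectively do) is possible by passing
  `grid = max_features`.
* Random forests do not extrapolate: microbiota ages saturate near the
  training range's ends, compressing MAZ at the youngest and oldest
  calibrated ages.
* Calibration bins are step functions; a spline reference would be smoother
  but is deliberately out of scope.
* The moderated-t prior assumes variances are exchangeable across proteins;
  strongly structured heteroskedasticity (e.g. intensity-dependent) is not
  modeled.
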