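---
title: "Sparse two-domain PLS for triple-network connectivity and phenotype association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sparse two-domain PLS for triple-network connectivity and phenotype association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnmpls)
```

## The scientific problem

The triple network model (TNM) of psychopathology holds that the salience
network (SN) regulates switching between the frontoparietal control
network (FPN), which supports externally directed cognition, and the
default mode network (DMN), which supports internally directed mental
activity. Disruption of this three-way balance is a candidate substrate
for a range of clinical conditions, including alcohol use disorder (AUD).
`tnmpls` implements a pipeline that asks, for a cohort of participants
with resting-state fMRI and a battery of AUD-related measures: *which
patterns of functional coupling within and between the SN, FPN and DMN
co-vary with which combinations of phenotypes?*

The two data domains are:

* **Connectivity domain** `X` (subjects × edges): Pearson correlations of
  mean regional BOLD time series, restricted to the regions of the three
  TNM networks under the Yeo 17-subnetwork scheme (Ventral Attention A/B
  → SN; Control A/B/C → FPN; Default A/B/C → DMN), vectorized from the
  strict upper triangle. Direct FPN–DMN couplings are removed before
  modelling: under the TNM, FPN–DMN communication is mediated by the SN,
  so only within-network edges and the SN–FPN, SN–DMN blocks enter.
* **Phenotype domain** `Y` (subjects × 8): Sex, Age, Education,
  family-history density of AUD (FHD), AUD symptom count, and three
  composite scores — Drinking (first principal component of five
  log-transformed consumption measures), Urgency (first PC of positive
  and negative urgency) and Alcohol seeking (first PC of the
  alcohol-versus-water work contrasts from two self-administration
  sessions). Every column is z-scored.

## Phenotype derivation

*FHD.* Each affected parent or full sibling contributes 0.5, each
affected grandparent or parent's sibling 0.25, unaffected relatives 0;
the score is the weight sum divided by the number of counted relatives,
so it lies in [0, 0.5]. An empty pedigree is an error (the density is
undefined), and only the four weighted relationship categories are
counted.

*Drinking measures.* Consumption variables are heavily right skewed, so
they are transformed elementwise by `log(1 + x)`. The offset of one is a
documented choice: drinking-days-per-week can legitimately be zero, the
transform maps 0 to 0, is monotone, and is indistinguishable from a plain
logarithm at the large values where the skew lives.

*Alcohol preference.* Within each session condition (neutral, aversive),
preference is the completed-trial contrast `cwa − cww`; positive values
mean more work for alcohol than water.

*PCA compression.* Each variable group is z-scored and decomposed through
the eigenstructure of its correlation matrix; components with eigenvalue
greater than one are retained (Kaiser rule) and each is oriented so the
sum of its loadings is positive, which removes the eigenvector sign
indeterminacy. Only the first retained component feeds the 8-variable
table; further retained components are exposed in the provenance slot.
For a two-variable group with correlation `r` the first eigenvalue is
`1 + |r|` and its explained-variance fraction `(1 + |r|)/2` exactly,
which the tests use as a closed-form oracle. When no eigenvalue exceeds
one the group carries no shared component and the function errors rather
than guessing — the caller should use a raw variable instead.

*Conventions.* Sex is coded female = 0, male = 1 before z-scoring (any
affine coding yields the same column up to sign); z-scoring uses the
sample (n − 1) denominator throughout. Both are recorded in the output
provenance so results are bit-reproducible.

## The sparse PLS model

Partial least squares finds paired weight vectors `(u, v)` maximizing the
covariance between latent scores `φ = Xu` and `ψ = Yv`. For centered
domains this is the leading singular pair of the cross-covariance
`M = XᵀY`, and successive components are fitted on deflated residuals.

The regularized variant constrains each domain's weights to the
intersection of the unit Euclidean sphere and an L1 ball of radius
`λ_D`:

* `‖u‖₂ = 1, ‖u‖₁ ≤ λ_C` (connectivity domain, `1 ≤ λ_C ≤ p`),
* `‖v‖₂ = 1, ‖v‖₁ ≤ λ_P` (phenotype domain, `1 ≤ λ_P ≤ q`).

`λ_D = 1` forces a single nonzero coefficient (maximal regularization);
radii at or above `√|D|` cannot bind for a unit-norm vector and are
accepted but vacuous. The subproblem "maximize `zᵀw` over this set" has
the closed-form solution `w = S(z, δ)/‖S(z, δ)‖₂`, with `S` elementwise
soft-thresholding and `δ ≥ 0` the smallest threshold at which the L1
bound holds; `δ` is found by bisection to 1e-10. Exact ties at the
maximum absolute coordinate are broken toward the lowest index, making
the solver fully deterministic.

Each component is fitted by alternating these projections,
`u ← P(Mv, λ_C)`, `v ← P(Mᵀu, λ_P)`, starting from the leading right
singular vector of `M` (a deterministic warm start that makes the
unregularized fit *exactly* the SVD solution from the first iteration).
Iteration stops when the max-norm weight change drops below 1e-6
(default) or after 500 iterations, in which case the component carries a
`converged = FALSE` flag and a warning — never a silent failure. The
component sign is fixed by flipping `(u, v, φ, ψ)` jointly so the
largest-magnitude phenotype coefficient is positive.

*Deflation.* Both domains are projected onto the orthocomplement of
their own latent score vectors. The choice guarantees that within-domain
latent scores are pairwise orthogonal across components — a property the
tests check directly — and reduces to classical PLS-SVD behaviour in the
unregularized case.

*Standardization.* Both domains are column z-scored before fitting by
default. Standardizing the connectivity columns puts all edges on the
same scale so that coefficients are comparable across edges; the
alternative (centering only) is available via `scale_x = FALSE` and is
the right choice when edge variances are themselves meaningful (the
noiseless-recovery tests use it, because rescaling near-zero-variance
noise edges back to unit variance would manufacture signal out of
nothing).

## Choosing the regularization radii

Both rules operate on the first component only; the selected pair is
then reused for every component.

* **Phenotype feature cap** (`select_lambda_phenotype`): scan
  `λ_P ∈ {1, 1.1, …, q}` and return the *largest* radius (i.e. the least
  regularization) at which the first component has at most
  `max_features` (default 3) nonzero phenotype coefficients.
* **Connectivity density rule** (`select_lambda_connectivity`): scan 100
  log-spaced radii in `[1, √p]` and return the one whose nonzero
  fraction is closest to `target_density` (default 0.5, i.e. keep half
  of the dense solution); ties go to the smaller radius.

### Two estimator subtleties worth knowing

**Boundary leakage.** A `k`-sparse unit-L2 vector has `‖v‖₁ ≤ √k`. A
two-variable association therefore has `‖v‖₁ ≤ √2 ≈ 1.414`, and any
radius above that — for example 1.5 — leaves slack that the exact
boundary solution fills with small spurious coefficients whose *total*
L1 mass is pinned by the constraint (≈ 0.12 at `λ_P = 1.5`) but whose
*count* depends on how the sample noise spectrum falls near the
threshold. Consequently a fixed radius of 1.5 caps the feature count at
three only when the underlying association genuinely spreads over three
or more variables (`√3 ≈ 1.73 > 1.5` makes the constraint bind inside
the support); over cohorts with two-variable planted factors the count
at `λ_P = 1.5` ranges from 3 to about 6. When a hard feature count is
the goal, the feature-cap selection rule — not a fixed radius — is the
right tool.

**Non-monotone support along the path.** The nonzero count of the first
component is non-decreasing in `λ_P` in the overwhelming majority of
datasets, but it is not a theorem: at an L1-boundary transition the
optimum can redistribute its mass over a *different, larger* support as
the budget tightens. The acceptance suite retains a verified
counterexample (global optimum 3-sparse at `λ_P = 1.3` but 2-sparse at
`λ_P = 1.4`, confirmed by restarting the solver from every one-hot
initialization); we observed roughly one affected dataset per forty
random instances. The selection rules are robust to this because they
scan the whole grid rather than assuming monotonicity.

## Network-level inference

For a fitted component, the edge coefficients are grouped into the five
TNM blocks (SN–SN, FPN–FPN, DMN–DMN, SN–FPN, SN–DMN). Each block's
observed contribution is the sum of absolute coefficients; the null
ensemble shuffles the coefficient values uniformly over all edge
positions (block memberships fixed, so each block's null respects its
size) 1000 times, and a block is significant when its observed
contribution strictly exceeds the 99th percentile
(linear-interpolation sample quantile) of its own ensemble. The shuffle
seed is mandatory and recorded, and the full null ensemble is returned
for audit. No multiple-testing correction is applied across the five
blocks; results should be read accordingly. With exchangeable
coefficients the per-block flag rate is ≈ 1% by construction, which the
acceptance suite verifies by Monte-Carlo.

Because the null redistributes the *global* coefficient pool, a small
block can only be flagged when its coefficients are extreme within that
pool — block size alone never produces significance.

*Signed strengths and substrates.* Rebuilding the coefficient vector
into a symmetric matrix (zeros on the diagonal and at excluded FPN–DMN
positions), each region's positive strength is the sum of positive
coefficients in its row and its negative strength the sum of negative
ones. Since every edge appears in two rows, net strengths sum to exactly
twice the summed edge coefficients — a conservation identity tested to
1e-12. The top fraction (default 5%, `k = ceiling(fraction · N)`, ties
by region index) of regions by absolute net strength forms the
component's regional substrate, reported with the strength threshold.

*Circuit summary.* Significant blocks are drawn onto the TNM graph with
directionality imposed by the model — arrows run SN→FPN and SN→DMN,
never the reverse, and within-network blocks are self-loops — while the
sign (increased/decreased) comes from the block's signed coefficient
sum, the natural signed companion of the absolute-sum test statistic.

## Leave-one-out stability

`loocv_fit` refits the model once per held-out subject with the radii
fixed at their full-cohort selection (per-fold reselection would answer
a different question: stability of the *rule*, not of the *solution*).
Standardization is recomputed inside each fold by default. Because the
solver is deterministic, each fold is bitwise identical to an
independent fit on the same subset — the tests assert this literally.
Components are aligned to the full-cohort reference by index (deflation
order is stable for well-separated factors; a diagnostic warns when a
run correlates more strongly with a different reference component), with
a sign flip whenever the connectivity weights correlate negatively.
Variability is summarized as the per-variable coefficient distribution
(min/quartiles/max across folds, for box plots) and the per-edge
population-SD (n denominator) per component.

## The synthetic cohort generator

No participant data ship with the package; every pipeline stage is
instead exercised against cohorts with *planted, known* cross-domain
structure. `simulate_cohort` draws `K` standard-normal latent factors
per subject and embeds them in both domains:

* **Phenotype side.** Each factor loads on a named support of at most
  three of the eight variables (defaults mirror the associations the
  pipeline is designed to detect: Drinking+Age, FHD+Urgency,
  AlcoholSeeking+Sex). Supported target columns are factor plus noise;
  unsupported columns are pure noise. Targets are then pushed out to
  *raw instrument scales* so the full derivation path is exercised:
  five log-normal consumption variables (via `expm1`, so the pipeline's
  `log1p` recovers the target exactly), integer urgency scores clamped
  to the 4–16 instrument range, paired work counts whose contrasts
  recover the seeking target, a binary sex split at the target median,
  and pedigrees of two parents plus four grandparents whose affected
  counts are quantile-matched to a right-skewed density target. With
  six counted relatives the attainable FHD grid spans [0, 1/3].
* **Connectivity side.** Each factor has a sparse edge-loading vector
  (default support 5% of all allowed edges) confined to designated
  blocks (defaults again mirror the target associations), never touching
  the excluded FPN–DMN block. Edge values are a block-dependent baseline
  (0.25 within-network, 0.10 between — typical resting-state coupling
  magnitudes) plus the factor signal plus Gaussian noise of SD 0.1 on
  the correlation scale. With the time-series toggle, per-subject
  regional series are instead drawn from the planted correlation matrix
  (baseline plus that subject's edge deviations, repaired to the nearest
  positive-definite correlation matrix by eigenvalue flooring at 1e-6
  and diagonal renormalization), and the pipeline's own `compute_fc`
  closes the loop.

*Signal calibration.* Factor strength is set so the leading singular
value of the planted cross-covariance is `snr` times (default 3) the
expected leading noise singular value, using the random-matrix
approximation `σ₁(noise) ≈ σ_x √n (√p + √q)` for unit-variance
phenotype columns. The default makes recovery achievable but not
trivial. Because the signal scale is *relative* to `noise_sd_x`, a
noiseless cohort is obtained by raising `snr`, not by shrinking the
noise SD.

*What the generator does not emulate.* BOLD autocorrelation and
hemodynamics, motion artifacts, site or session effects, realistic
inter-variable phenotype correlations beyond the planted factors, and
the empirical spatial covariance of real connectomes. Passing recovery
tests therefore demonstrate correctness of the estimator under the
generative model, not performance guarantees on real cohorts. Two
derived columns are information-limited by design: Sex is binarized
(correlation with its continuous target ≈ 0.8) and FHD is quantized to
the 6-relative pedigree grid (≈ 0.88); the six continuous-mapped
columns track their targets at ≥ 0.9 for raw-noise SD ≤ 0.1.

*Recovery scoring.* `recovery_report` greedily matches fitted components
to planted factors on absolute latent-score correlation and reports
support precision/recall/F1 in both domains, score correlations, and
loading cosines. In the recovery studies the radii are matched to the
planted sparsity (feature cap = planted phenotype support size, density
target = planted edge fraction): the question those studies answer is
whether the estimator finds a structure of the size that exists, not
whether a selection heuristic guesses that size. Under the default
calibration (n = 55, ~800 edges, one factor, 20 seeds) we observe
phenotype support F1 = 1.0 on every seed, mean edge F1 ≈ 0.85 and mean
latent correlation ≈ 0.995.

## Orchestration and reproducibility

`run_pipeline` drives the full analysis from a single `run_config`
(defaults: 4 components, density target 0.5, feature cap 3, 1000
permutations at the 99th percentile, top 5% regions): phenotype
derivation, radius selection (phenotype cap first with the connectivity
constraint vacuous, then the density rule at the selected phenotype
radius), unregularized and regularized fits, block tests, strengths, top
regions, circuit summaries, and optional leave-one-out stability. Every
output table carries a hash of the configuration, stage boundaries log
row/column counts so silent misalignment is impossible, subject-id
mismatches between domains are an error listing the offenders, and every
stochastic step takes an explicit seed — the report is byte-identical
across reruns of the same config and seed, which the tests assert
file-by-file.

Test and validation problem sizes are deliberately modest — cohorts of
12–55 subjects on 100–800 edges, with single large-cohort checks at the
full 145-region space (~7,900 edges) — chosen so the full suite documents
every property in well under half an hour while remaining faithful to
the target regime of many more edges than subjects.

## Known limitations

* PLS associations are correlational; nothing here supports causal
  directionality claims beyond what the TNM assumes a priori.
* The feature count at a *fixed* phenotype radius is not a reliable
  sparsity dial near the L1 boundary (see the leakage discussion); use
  the selection rules.
* Block-level inference tests a sum statistic; it says nothing about
  individual edges, and no correction is applied across blocks.
* The 145-region TNM space depends on an externally supplied
  parcellation lookup; the package validates and restricts whatever
  lookup it is given rather than shipping an atlas.
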