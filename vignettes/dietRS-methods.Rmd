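---
title: "dietRS: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{dietRS: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietRS)
```

dietRS implements the statistical pipeline of a two-diet,
repeated-measures feeding trial comparing fecal microbiomes and
metabolomes. The motivating setting is a feline study of dietary
resistant starch (RS): two groups of cats are fed identically
formulated foods that differ in retained RS ("LRS" low, "HRS" high),
feces are collected at weeks 3 and 6 with up to two replicate
collections per cat, and the samples are profiled by 16S sequencing
(genus-level OTU counts), untargeted metabolomics, and targeted panels
(short-chain fatty acids, IgA, ammonia, proximate analysis). This
vignette explains each method, the assumptions behind it, the tunable
parameters, and the design choices made where the analysis was
genuinely open.

## Study design and data containers

`StudyDesign` stores one row per collected sample: subject, group
(LRS/HRS), week (3/6), and collection number (1/2). Cats fail to
produce stool at some visits; missing collections are represented by
absent rows and never imputed. Stages that need both collections per
subject fall back to single-collection behavior automatically (the
per-week test switches from a mixed model to a t-test), and subjects
with no samples at all are simply absent from the design.

`CountTable` holds genus-level counts with phylum/family/genus
annotation. OTUs whose genus is unknown are kept: community structure
(diversity) is assessed on *all* taxa, while univariate differential
testing and PLS-DA use only taxa identified at the genus level
(`countsToClr(x, identifiedOnly = TRUE)`). `FeatureMatrix` carries
metabolite (or transformed microbiome) values with an explicit scale
tag — `raw`, `log2` or `clr` — so a stage can refuse input on the wrong
scale instead of silently double-transforming.

## Diversity: Hill numbers and 1 − CqN profiles

Alpha diversity is computed per sample on count proportions (never on
CLR values) as Hill numbers
$^qD = \left(\sum_i p_i^q\right)^{1/(1-q)}$: richness $S$ at $q = 0$,
the exponential Shannon index at $q = 1$ (limit form), and the inverse
Simpson index at $q = 2$. Pielou's evenness is $J = H / \ln S$, left
missing for single-taxon samples where it is undefined. Profiles are
evaluated on the open grid $0 < q < 10$ in steps of 0.05 (richness is
reported separately by `alphaSummary`), and any $q$ within $10^{-9}$
of 1 is routed to the entropy limit so the profile is continuous
through $q = 1$.

Beta diversity pools $N$ samples with equal weights. Gamma diversity
is the Hill number of the mean composition; assemblage alpha is
$\frac{1}{N}\bigl[\sum_{ij} (p_{ij}/N)^q\bigr]^{1/(1-q)}$; their ratio
$\beta_q \in [1, N]$ is converted to the overlap measure

$$C_{qN} = \frac{(1/\beta_q)^{q-1} - (1/N)^{q-1}}{1 - (1/N)^{q-1}},$$

with the $q = 1$ case handled analytically as
$1 - \ln\beta_1 / \ln N$. The reported dissimilarity is
$^q\beta = 1 - C_{qN}$. At $q = 0$ this reduces to one minus the
Sørensen similarity and at $q = 2$ to one minus Morisita–Horn, which
the test suite verifies against independently coded classical
formulas. Because the originating analysis used a custom script whose
pooling convention is not published, the equal-weight pooled
decomposition above is fixed here as *the* convention and beta
profiles are stratified by group × week by default (`by = "group"`
pools across weeks); both conventions are exposed rather than guessed.

```{r diversity-example}
cts <- rbind(s1 = c(10, 0), s2 = c(5, 5))
colnames(cts) <- c("taxonA", "taxonB")
betaProfile(cts, qGrid = 2)  # beta = 1.2, C2N = 2/3, qbeta = 1/3
```

## Compositional treatment: CZM zero replacement and CLR

Counts are compositional; before log-ratio analysis, zeros are imputed
by the Bayesian-multiplicative count-zero-multiplicative (CZM)
treatment: in sample $i$ with total $n_i$, each zero receives
$\delta_i = f \cdot \tfrac{1}{n_i + 1}$ on the proportion scale and
nonzero proportions are rescaled multiplicatively so the row sums to
one. The default fraction $f = 0.65$ and detection limit
$1/(n_i+1)$ follow the defaults of the reference implementation of
this treatment; both are configurable, and parity with that
implementation is a test goal rather than a guarantee. The CLR
transform is then
$\mathrm{clr}_{ij} = \ln p_{ij} - \overline{\ln p_{i\cdot}}$, computed
on proportions (equivalent to counts by scale invariance). CLR is
applied to the pooled sample set by default; transforming per
timepoint instead is possible by subsetting first, but pooling keeps
week-3 and week-6 values on a common scale for the across-study mixed
models, which is why it is the default. Row sums of a CLR matrix are
asserted to be 0 within 1e-8, compositions within 1e-9.

## The differential-testing cascade

The cascade mirrors a sequential testing strategy: (1) class-level
joint tests ask whether the diet shifts a biochemical class at a
week; (2) per-feature tests at each week identify the members driving
it; (3) an across-study mixed model tests for an effect over the
whole feeding period; (4) Storey q-values control the false discovery
rate over each p-value vector; and (5) a feature is declared
significant only under the dual criterion $p \le 0.05$ **and**
$q \le 0.1$ (both inclusive). Metabolite tests run on log2 values,
microbiome tests on CLR values.

Per-week tests are pooled-variance independent t-tests when each cat
contributed one sample at the week, and random-intercept mixed models
(subject as random factor) when replicate collections are available.
The pooled-variance choice matches the default "independent t-test"
of the statistical platform this pipeline emulates; Welch's correction
is deliberately not the default. Across the study the model is
`value ~ group + (1|subject)` with `(1|collection)` added when
replicate collections exist, fit by REML with variance components
constrained nonnegative. The p-value uses a Wald t statistic on
*containment* degrees of freedom — $n_\text{subjects} - 2$ for the
between-subject group effect — chosen over Satterthwaite approximation
for determinism and implementability; this is a documented deviation
risk relative to software that defaults to Satterthwaite. When the
design degenerates to one observation per subject the random intercept
is unidentifiable and the model is collapsed analytically to ordinary
least squares, making the t-test equivalence exact rather than
approximate. Non-converging fits yield a missing p-value and a
`converged = FALSE` flag, never a silent zero.

Storey's $\pi_0$ is estimated by evaluating
$\pi_0(\lambda) = \#\{p > \lambda\} / (m(1-\lambda))$ on the grid
$\lambda = 0.05, \dots, 0.95$ (step 0.05), smoothing with a cubic
smoothing spline (3 effective degrees of freedom) and reading off the
value at $\lambda = 0.95$, clamped to $(0, 1]$. With fewer than 10
p-values $\pi_0$ is pinned at 1, which makes the q-values identical
to Benjamini–Hochberg — the conservative limit. Derived ratios (e.g.
hydroxyl:oxo redox pairs) are flagged `derived` and excluded from
every q-value input vector, since they are arithmetic combinations of
features already in the vector; they receive NA q-values and NA
significance rather than a fabricated call.

Whether the headline "fraction changed" should use per-week q-values
or across-study mixed-model q-values is ambiguous in this kind of
design; the cascade computes both (`q_w3`, `q_w6`, `q`) and the
default `qInput = "mixed"` designates the across-study test, with
`"week"` as the alternative. Subject exclusions (e.g. recorded
statistical outliers in a targeted panel) are taken from an explicit
configuration list and never inferred from the data.

## PLS-DA, VIP, and cross-validation

PLS-DA is fit by NIPALS on a single centered 0/1 group code
(equivalent to a two-column indicator for two classes), with X
column-centered and autoscaled to unit variance by default. Feature
scaling is the main source of divergence from other PLS
implementations, so a centering-only mode (`scale = FALSE`) is
provided. Up to 15 factors are searched (capped at the matrix rank;
extraction stops early when residual X or y variance falls below
1e-12). Each weight vector's largest-magnitude element is forced
positive so fits are sign-deterministic. VIP scores use
$\mathrm{VIP}_j = \sqrt{p \sum_a \mathrm{SSY}_a w_{ja}^2 /
\sum_a \mathrm{SSY}_a}$, normalized so the mean squared VIP is 1.
Factor choice uses stratified 7-fold cross-validation with
deterministic seeded fold assignment: the chosen factor count
minimizes the root mean predictive residual sum of squares, and
$Q^2(A) = 1 - \mathrm{PRESS}(A)/\mathrm{SSY}$ is reported per factor.
The NIPALS scores are tested against an independent SVD-based PLS
computation (agreement within 1e-6 up to sign).

## The synthetic-data generator

The generator exists so every stage is testable with known ground
truth; its defaults are the emulated study's conditions. Design: 20
subjects per group (the trial enrolled 40 and lost 4 that never
produced stool; per-row missingness at rate 0.1 emulates unreliable
stool production, and the acceptance analyses use the realized 17/19
group sizes directly). Metabolome: 736 features on the log2 scale,
`value = baseline + effect·1[HRS] + subject intercept + residual`,
with baseline ~ N(10, 2), subject-intercept sd 0.3 and residual sd
0.5 — stated assumptions, not fitted values, since the trial publishes
no within-subject correlation estimates. The planted effect structure
defaults to 36% of features up and 11% down (47% affected) at ±1
log2 unit, the fraction the emulated study reports. Counts: 252 taxa
with log-normal baseline logits, per-sample composition
`softmax(base + shift·1[HRS] + subject noise + sample noise)` and
multinomial sampling at a library size uniform in [20000, 60000].
The logit-scale Gaussian noise plays the overdispersion role of a
Dirichlet–multinomial while keeping the generative model consistent
with the CLR analysis assumptions; this is a deliberate simplification,
documented as the generative model. A single global seed fans out to
fixed per-stage child seeds so stages can be re-run independently.

What the generator does *not* emulate: compositional zero patterns
tied to taxon phylogeny, longitudinal drift beyond two fixed
timepoints, heavy-tailed platform noise, or batch effects. Passing
tests therefore demonstrate the statistical machinery is correct under
the stated model, not that real data meet that model.

```{r generator-example}
design <- simulateDesign(c(5, 5), missingRate = 0, seed = 1)
truth <- syntheticTruth(nFeatures = 40, seed = 1)
metab <- simulateMetabolome(design, truth, nFeatures = 40, seed = 1)
metab
```

## Targeted summaries

SCFA totals are per-sample sums (acetate + propionate + butyrate;
isobutyrate + 2-methylbutyrate + isovalerate for BCFA) and the
SCFA/BCFA ratio is computed per sample *then* averaged over a group —
by Jensen-type non-linearity this differs from the ratio of group-mean
totals, and the package keeps the two quantities clearly apart
(`scfaTotals` / `scfaGroupTable` versus `scfaMeanTable`). Group deltas
are always computed from unrounded means; printed tables that round
before differencing can disagree in the last digit, so a rounded view
is a display concern, not a computation. The proximate formulas are
NFE = 100 − (crude fiber + protein + fat + ash + moisture), percent
cook = gelatinized/total starch × 100, apparent digestibility =
(consumed − fecal)/consumed, and organic dry matter =
100 − (moisture + ash); all are pure functions with validated input
ranges. Ordinal 5-point stool scores are treated as continuous and
routed through the same group-summary and t-test machinery, matching
the approximation used in this trial design.

## Problem sizes and numerical tolerances in the test suite

The test and acceptance suites run the cascade at the emulated trial's
size (736 features, 17/19 subjects, 20 independent null replicates)
and verify: dual-criterion false-positive fraction ≤ 5% on null data;
power ≥ 0.9 with perfect sign agreement for planted ±1 log2 effects at
residual sd 0.5; q-values identical (1e-12) to a brute-force
min-over-thresholds oracle for vectors up to length 12; mixed-model /
t-test agreement within 1e-6 under model collapse; Hill profiles
monotone over 1000 random compositions; CqN against Sørensen and
Morisita–Horn oracles at 1e-12; and NIPALS against an SVD oracle at
1e-6. Monte-Carlo sizes were chosen so each check is statistically
decisive at these tolerances while the whole suite remains quick to
run on one CPU.

## Known limitations

- Containment degrees of freedom are conservative for unbalanced
  designs relative to Satterthwaite; p-values near the threshold can
  differ from software using other approximations.
- The q = 7-fold CV fold assignment, while stratified and seeded, is
  one of many defensible schemes; Q² values depend on it.
- The CZM default fraction (0.65) is a convention, not an estimate;
  analyses with many structural zeros should examine sensitivity.
- Real-data headline quantities of the motivating trial (the observed
  fraction of metabolites changed, its regression statistics, and all
  taxon-level results) depend on per-sample data that are not public;
  the package reproduces the trial's printed *table arithmetic*
  exactly and re-enacts the metabolome-wide analysis on synthetic data
  with the same design sizes and planted effect fractions.
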