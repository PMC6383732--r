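---
title: "Estimating the evolutionary potential of larval tolerance to ocean acidification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the evolutionary potential of larval tolerance to ocean acidification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Ocean acidification raises the mortality of marine fish larvae, but
populations may adapt if tolerance of low-pH / high-pCO2 seawater is
heritable. `oaquant` implements a quantitative-genetic analysis of that
question for a crossed breeding design of the kind used with beach-spawning
fishes: wild adults are strip-spawned in full factorial sets (each of three
sires crossed with each of three dams), the resulting full-sib families are
reared as groups of 50 larvae per tank under ambient and acidified
treatments within replicated temporal blocks (spawning events), and
per-tank mortality and growth are recorded over a 14-day larval period.

Four analysis traits are defined: daily mortality rate and growth (change
in mean standard length, mm) in each environment. Each tank observes
exactly the two traits of its own treatment, so the four-trait data are
structurally incomplete by design. Tolerance of acidification is
quantified through (i) heritabilities of the traits in each environment
and (ii) the cross-environment genetic correlation $r_G$: with $r_G > 0$,
selection acting today (under ambient conditions) produces a correlated
response that pre-adapts the population to conditions it has not yet
experienced.

## The model

The phenotypic (co)variance of the four traits is partitioned as

$$\mathbf{P} = \mathbf{G} + \mathbf{M} + \mathbf{B} + \mathbf{R},$$

where $\mathbf{G}$ is the additive genetic covariance (structured across
tanks by the pedigree numerator relationship matrix $\mathbf{A}$:
full sibs share $0.5\,\mathbf{G}$, half sibs $0.25\,\mathbf{G}$),
$\mathbf{M}$ the maternal-effect covariance (shared by tanks with the same
dam), $\mathbf{B}$ the among-block covariance (spawning events), and
$\mathbf{R}$ the residual among-tank covariance. The only fixed effects
are the four trait means. Each tank is represented as a pedigree
pseudo-individual whose parents are the family's sire and dam, so
replicate tanks of one family are distinct full sibs; this is the only
pedigree encoding consistent with group-level records and the
sib-similarity coefficients above.

Derived quantities are computed per posterior sample and then summarized:
heritability $h^2_t = G_{tt} / P_{tt}$, component proportions
$G_{tt}/P_{tt}, \dots$, and the genetic and maternal correlations
$r_G = \mathrm{Cov}_A(x,y) / \sqrt{V_A(x) V_A(y)}$ (likewise $r_M$ from
$\mathbf{M}$). Selection responses use the multivariate breeder's
equation $\Delta \bar{z} = \mathbf{G} \beta$.

## Priors and a caveat about the degree of belief

Each component has an inverse-Wishart prior with scale $\nu V_0$ and
degree of belief $\nu$, where $V_0$ is diagonal with entries one quarter
of the observed per-trait phenotypic variance and modal covariances zero.
The package default is $\nu = 0.001$, the conventional "very wide and
flat" setting for this kind of analysis, and `prior_from_data()` keeps it
for compatibility with published practice.

That convention deserves a caution that is rarely stated: for a $p \times
p$ component the inverse-Wishart is a proper distribution only when
$\nu > p - 1$. With four traits, $\nu = 0.001$ is an *improper* prior with
a non-integrable spike at singular component matrices, and because the
marginal likelihood does not vanish at singular $\mathbf{M}$ or
$\mathbf{G}$, the posterior inherits the impropriety. A slowly mixing
sampler can sit near a reasonable mode for a long time and look
convergent; a well-mixing sampler eventually drifts into the spike
(component correlations pinned at $\pm 1$, single-trait variances
collapsing). For that reason every *validation* study in this package
(the parameter-recovery harness in the test suite) uses the weakest
proper choice $\nu = p + 1 = 5$, which implies a uniform marginal prior on
the component correlations while remaining heavy-tailed on the variances.
For data analysis you should prefer `prior_from_data(tt, nu = 5)` as
well; $\nu = 0.001$ is retained as the default only because it is what
the published analyses of this design used.

## The Gibbs sampler

`run_gibbs()` is a systematic-scan Gibbs sampler with data augmentation
for the structurally unobserved traits, written in C++ (RcppArmadillo).
All conditional draws are exact; no approximations are involved. The
plain conjugate scan (sample effects, then each component from its
inverse-Wishart full conditional) is well known to mix poorly for animal
models when heritability is small, because the component conditionals
given the latent effects are far tighter than the marginal posterior. The
sampler therefore augments the scan with several exact auxiliary moves:

* **Joint breeding-value draws.** All additive effects are drawn in one
  block per sweep. Simultaneous diagonalization of
  $(\mathbf{G}^{-1}, \mathbf{R}^{-1})$ decouples the four traits; within
  a trait direction the conditional precision is block-diagonal over the
  independent family clusters of the pedigree, and each cluster is
  sampled through a founder-block Schur complement (tank rows of
  $\mathbf{A}^{-1}$ are diagonal).
* **Partially collapsed component updates.** $\mathbf{G}$ and
  $\mathbf{R}$ are updated from conditionals that integrate out both the
  tank-level mendelian deviations and the unobserved trait coordinates,
  using the observed-coordinate marginal likelihood
  $y_{obs} \sim N(\text{parent-average fit}, (\mathbf{G}/2 +
  \mathbf{R})_{[obs,obs]})$, via coordinate slice sampling on the
  component's Cholesky factor. The deviations and imputations are redrawn
  immediately afterwards, which is what makes the collapsed step valid.
* **ASIS interweaving.** $\mathbf{G}$ (and $\mathbf{M}$) are re-updated
  in the non-centered parameterization in which founder breeding values
  (maternal effects) are whitened, removing the artificial tightness of
  the centered conditionals.
* **Hierarchical recentering.** Exact translation moves shift variation
  between nested blocks that the likelihood only identifies jointly:
  dam breeding values vs. maternal effects, maternal vs. block effects,
  block effects vs. trait means, additive effects vs. trait means.
* **Group-scaling ("sandwich") moves.** Whole-matrix and per-trait scale
  transformations of an effect block and its covariance, drawn from the
  exact conditional implied by the multiplicative group with Haar
  measure.

All of these are standard generalized-Gibbs constructions: each extra
move is an exact transition that leaves the posterior invariant, so the
sampler targets precisely the same distribution as the plain conjugate
scan while traversing it far faster. The test suite pins the sampler's
correctness with a conjugate closed-form check (a degenerate
residual-only model must reproduce the analytic inverse-Wishart
posterior) and with the replicated parameter-recovery harness; the
non-collapsed path remains available (`collapsed_G = FALSE`) and targets
the same posterior. For real analyses the chain defaults follow published
practice: 150,000 iterations, burn-in 1,000, thinning 80, giving 1,862
stored samples.

Reproducibility: a single integer seed drives R's own RNG, which the C++
core also uses, so chains are bit-for-bit reproducible.

## Trait estimation choices

* Daily mortality rate is the negative slope of an ordinary
  least-squares regression of $\log N_t$ on day. Days with zero
  survivors are excluded (the series is truncated at the last positive
  count) rather than offset-corrected, which keeps the estimator exact
  on noiseless exponential decay; day 0, the known initial stocking, is
  included.
* Growth is the total change in mean standard length over the rearing
  period (mm), not a daily rate.
* Treatment contrasts use paired t tests over block means, treating
  blocks as replicates.

## The synthetic-data generator

`simulate_dataset()` generates the full observation chain with known
ground truth: the factorial breeding design (with random subsetting of
families when a block's capacity of 12 family-replicates per treatment is
exceeded, and a configurable fraction of duplicated families), latent
4-trait tank values built from user-specified $\mathbf{G}, \mathbf{M},
\mathbf{B}, \mathbf{R}$ via the pedigree recursion (founder breeding
values $N(0, \mathbf{G})$, offspring mendelian deviations
$N(0, \mathbf{G}/2)$), daily survivor counts as binomial thinning with
survival $e^{-m}$ (so the log-survivor regression estimator is
asymptotically unbiased), and length samples with gaussian noise.

Default truth values are chosen to be realistic for this system: daily
mortality means around 0.05/day (ambient) and 0.065/day (acidified),
total phenotypic SDs near 0.045-0.055/day for mortality and 0.5 mm for
growth, heritabilities 0.2 (mortality) and 0.1 (growth), maternal
proportion 0.3, block proportion 0.4, cross-environment correlations
$r_G = 0.45 / 0.15$ and $r_M = 0.8$ — magnitudes matching the reported
biology of this design.

What the generator does *not* emulate: individual larvae (only group
records), egg/embryo-stage mortality, size-selective mortality,
transgenerational effects, or temporal drift in water chemistry within a
block. A latent gaussian mortality rate can be slightly negative; the
count simulator truncates it at zero. Passing tests therefore show the
estimation machinery is correct under the stated generative model, not
that the model captures every feature of real rearing data.

## Validation problem sizes

The recovery harness in the test suite runs twenty independent datasets
at four times the experimental design (64 blocks, two 3x3 sets each,
roughly 1,500 tanks) with 15,000-iteration chains, checking that the true
heritabilities, genetic correlations and maternal/block proportions fall
inside the 95% HPD intervals at close to nominal frequency. Calibration
of the Heidelberger-Welch stationarity test uses 1,000 replicate iid
chains of length 1,862. These sizes were chosen so that each property is
decided by sampling error of the *method*, not of the check itself, while
keeping the suite runnable on a laptop in well under half an hour.

## Numerical details

* Inverse-Wishart convention: density $\propto
  |\Sigma|^{-(\nu+p+1)/2} \exp(-\tfrac12 \mathrm{tr}(\nu V_0
  \Sigma^{-1}))$; the conjugate update adds the effect cross-product to
  the scale and the number of effect levels to $\nu$.
* A non-SPD conditional scale is jittered once by $10^{-10} I$; if still
  non-SPD the sampler aborts rather than silently continuing.
* $\mathbf{A}^{-1}$ is built by Henderson's rules for non-inbred
  pedigrees; if inbreeding is detected (an individual whose parents are
  related) the code falls back to dense inversion with a warning, and
  the collapsed updates (which assume mendelian variance
  $\mathbf{G}/2$) are disabled.
* HPD intervals are the shortest window of order statistics containing
  the target mass, leftmost on ties; quantile intervals are available as
  an option.
* The Heidelberger-Welch stationarity test normalizes Brownian-bridge
  partial sums by the spectral density at frequency zero (AR fit with
  AIC order selection on the second half of the chain) and, on failure,
  discards 10% increments up to 50%; the halfwidth test requires the
  95% mean halfwidth to be at most 10% of the mean's magnitude.

## Known limitations

* The model is Gaussian throughout; mortality rates near zero violate
  normality mildly, and no threshold model is offered.
* Dominance and epistatic variance are not separable from the maternal
  and residual terms in this design and are not modeled.
* Single-generation selection projections assume $\mathbf{G}$ constant;
  multi-generation trajectories are deliberately out of scope.
* The meta-analysis helpers implement the added-mortality construction
  and simple pooled / per-species OLS sensitivity slopes, not a formal
  random-effects meta-analysis.
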