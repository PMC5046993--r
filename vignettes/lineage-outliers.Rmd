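---
title: "Detecting exceptional trait evolution along a focal lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting exceptional trait evolution along a focal lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The question

Given continuous trait measurements (for example log10 physiological
reference values) across a clade of species, has one focal species — say,
humans among primates — undergone *exceptional* evolutionary change? The
package approaches this with two complementary Bayesian phylogenetic
comparative analyses:

1. **Phylogenetic prediction.** Model trait covariation in the non-focal
   species with a phylogenetic regression, predict the focal species'
   phenotype as if it were a typical member of the clade, and measure how
   far the observed value falls in the posterior predictive distribution.
   A species in the extreme tail is an *evolutionary outlier*.
2. **Adaptive-regime modelling.** Fit a multi-optimum Ornstein–Uhlenbeck
   (OU) model in which the trait optimum can shift at points on the tree,
   and ask how often the posterior places an optimum shift on the focal
   species' terminal branch, and whether those shifts agree in direction.

The two stages make different assumptions (trait covariation plus
phylogenetic signal vs. an explicit adaptive model) and are combined in the
final report: the strongest claims are the traits supported by both.

# Stage 1: RJ-MCMC over PGLS regressions

## Model

For a trait vector $y$ over $n$ species with predictor $x$ (log10 body
mass throughout the reference analyses),

$$y \sim \mathcal{N}\!\big(\alpha + \gamma\,\beta x,\;
\sigma^2\, C_\lambda\big), \qquad
C_\lambda = \lambda\,(C - \mathrm{diag}\,C) + \mathrm{diag}\,C,$$

where $C$ is the phylogenetic covariance matrix (entry $(i,j)$ = shared
root-to-MRCA path length), $\lambda \in [0,1]$ is Pagel's signal parameter
and $\gamma \in \{0,1\}$ is a predictor-inclusion indicator subject to
Bayesian model selection. $\lambda$ is implemented as off-diagonal
covariance scaling rather than literal internal-branch edits: this
reproduces the $\lambda = 0$ star-phylogeny (independent-species) limit
exactly and is well defined for non-ultrametric trees. Whether tip
branches should also be rescaled to preserve tree height is ambiguous in
the verbal description of the transform; the covariance convention adopted
here is the standard one and is what the tests pin down.

## Priors and moves

* intercept and coefficient: proper uniform on $\pm 100$ (log10 trait
  units). A proper prior is required because reversible-jump birth moves
  propose the coefficient from it; $\pm 100$ is vastly wider than any
  log10-scale biological signal, so it is flat in practice.
* $\gamma$: Bernoulli(0.5) per candidate predictor. The intercept is
  always in the model — model selection concerns predictors only.
* $\lambda$: uniform on $[0,1]$.
* $\sigma^2$: half-Cauchy with scale equal to the sample trait variance.
* phylogenetic uncertainty: the tree index is a parameter, resampled
  uniformly over the supplied tree set, so the posterior averages over
  trees.

Each MCMC step performs one of: predictor toggle (RJ, coefficient from its
prior, Jacobian 1), random walk on a coefficient or the intercept,
reflected random walk on $\lambda$, log-scale walk on $\sigma^2$, or a tree
resample; standard Metropolis–Hastings acceptance throughout. The
reference chain configuration is 200,100 steps, burn-in 100, thin 100 —
exactly 2000 retained models. Retained log-likelihoods are checked for
autocorrelation and a warning is attached to the chain when lag-1
correlation exceeds 0.5.

## Prediction and outlier probabilities

Each retained state contributes one draw from the focal species'
conditional normal,

$$\mu_t = \alpha + \gamma\beta x_t + c_{to} C_{oo}^{-1}(y - \mu_o),
\qquad
v_t = \sigma^2\big(c_{tt} - c_{to} C_{oo}^{-1} c_{ot}\big),$$

with all covariance blocks $\lambda$-scaled. No residual tip noise is
added beyond the conditional variance: the predictive spread already
contains the phylogenetic residual variance of the target plus parameter
uncertainty across the chain. The two-sided outlier probability compares
the observed value against the normal summary of the draws (the predictive
distributions are expected to be checked for normalcy, e.g. by Q-Q plots;
an empirical-tail mode with add-one smoothing is available). Per-trait
probabilities are converted to outlier calls by Benjamini–Hochberg step-up
selection at a false discovery rate of 10%.

When published probabilities are only available rounded (two decimals,
with very small values printed as "<0.01"), `fdr_select(printed_digits =
2)` maps each value to the lower bound of its rounding interval before the
step-up pass — the reported significance set is then reproduced exactly;
applying the step-up rule to the rounded values as-is misclassifies values
at the threshold boundary.

# Stage 2: multi-optimum OU regime shifts

## Model

Trait evolution follows an OU process with mean-reversion rate $\alpha$,
diffusion rate $\sigma^2$ and a piecewise-constant optimum: a *shift
configuration* places at most one optimum change on any branch (position
uniform along the branch). With the root state fixed at the root optimum
(the default; a stationary-root option exists), the expected tip value is
a convex combination of regime optima,

$$\mathbb{E}[y_i] = \sum_r \theta_r w_{ir} + \beta\,m_i,
\qquad
\mathrm{Cov}(y_i, y_j) = \frac{\sigma^2}{2\alpha}
e^{-\alpha(T_i + T_j - 2 t_{ij})}\big(1 - e^{-2\alpha t_{ij}}\big),$$

where a regime segment $[t_a, t_b]$ on the root-to-tip path contributes
weight $e^{-\alpha(T_i - t_b)} - e^{-\alpha(T_i - t_a)}$, the root regime
additionally carries $e^{-\alpha T_i}$, and $t_{ij}$ is the shared
root-path time. The covariance is evaluated with `expm1` so that the
$\alpha \to 0$ limit recovers the Brownian covariance $\sigma^2 C$ to
machine precision. Only optima shift; $\alpha$ and $\sigma^2$ are global
(shift-specific rates are out of scope).

## Priors

Half-Cauchy on $\alpha$ (scale $1/$tree height — a half-life of order the
tree depth is the prior's centre of mass) and on $\sigma^2$ (scale
trait variance / tree height, so the implied stationary spread tracks the
observed trait spread); uniform on the mass coefficient; Poisson on the
number of shifts $k$ (mean 1 by default — regime shifts should be rare *a
priori*; this scale is a package choice and is a mandatory-visible config
entry); optima (root included) normal with mean and SD matched to the
trait's own distribution; shift placement uniform over branches with at
most one shift per branch. Branches are identified by the sorted tip set
of the clade they subtend, which is stable across tree re-orderings.

## Sampler design

Reversible-jump moves add, remove or relocate shifts; scalar parameters
use random walks ($\log\alpha$, $\log\sigma^2$, $\beta$). Two design
choices matter for mixing and were validated explicitly:

* **Conditional optimum proposals.** The full conditional of any single
  optimum is Gaussian; births, deaths and cross-branch relocations propose
  the new optimum from that conditional (with the exact MH correction) and
  optimum updates are Gibbs draws. Proposing optima from the prior
  instead leaves shifts on recently diverged branches essentially
  unreachable, because the optimum required to displace a tip at moderate
  $\alpha$ lies far in the prior tail.
* **Joint $\alpha$–dimension jumps.** A data set with one strongly
  displaced tip admits two rival explanations: weak adaptation with no
  shift (the displacement absorbed into phylogenetic noise) and strong
  adaptation with a shift. These form separated posterior modes along
  $\alpha$. Dedicated moves that propose a birth or death *together with*
  a large log-jump in $\alpha$ connect the modes. Chains additionally
  start from dispersed $\alpha$ values so the convergence diagnostic can
  expose any remaining failure to mix.

With the likelihood forced constant, the sampled $k$ reproduces its
Poisson prior (chi-square test in the suite) — the reversible-jump
acceptance ratios satisfy detailed balance.

## Convergence and summaries

Two chains (reference configuration 2,002,000 steps, burn-in 2000, thin
1000; 2000 samples per chain) are compared by Gelman's
potential-scale-reduction factor on the log-likelihood series. A grid of
ten equal front-truncation fractions (0–45%) is scanned and the smallest
truncation bringing $R$ closest to 1 is applied before pooling; the
effective sample size of the pooled log-likelihoods is reported. The OU
stage uses a single tree (the first of the supplied set): the model's
regime painting is tree-specific, so tree-averaging is not defined here.

Shift summaries report, for a branch: the proportion of posterior models
with a shift there, its rank among all branches, and the mean, SD and sign
consistency of the shift magnitude $\theta_{\text{new}} -
\theta_{\text{parent regime}}$ (computed over models containing the
shift; the parent-relative convention is what the sign summary
presupposes). The focal branch is called *shifted* when at least 20% of
models place a shift there and at least 95% of those shifts agree in
direction.

# The synthetic study generator

`make_study()` emulates the shape of a zoo-derived physiological
reference-value table: ~50 species on an ultrametric tree of unit depth,
one log10 body-mass covariate evolving by Brownian motion (root 0.7 ≈ 5
kg, rate 0.3 per unit depth, giving a ~2.5-decade mass range), traits
generated under BM ($\sigma^2 = 1$, root 0 by default, both configurable)
or under the exact multi-optimum OU law, a linear mass effect, optional
per-trait missingness, and a designated focal tip. The default focal tip
is a *cherry* tip whose terminal branch is closest to 10% of tree depth —
a recently diverged lineage with a close extant sister, the configuration
whose prediction problem the reference analyses pose. Missingness is
uniform at random and never masks the focal species.

What the generator does **not** emulate: within-species measurement error
and sample-size heterogeneity, systematic differences between data sources
(captive vs. reference populations), unit or assay heterogeneity between
laboratories, and correlated missingness (traits missing together for
poorly sampled species). Passing recovery and calibration tests on these
synthetic tables therefore demonstrates correctness of the inference
machinery under the stated model, not robustness to those survey
artefacts.

`simulate_bm()` draws independent per-branch increments (variance
$\sigma^2 \times$ length $\times$ multiplier), so a lineage-specific rate
multiplier is *exactly* equivalent to pre-scaling that branch's length —
the equivalence is asserted bit-for-bit in the suite. `simulate_ou()`
draws from the exact multivariate normal implied by the OU mean and
covariance above, not from a discretized path. All generators are pure
functions of (spec, seed).

# The validation study

`rate_multiplier_study()` reproduces the false-positive / false-negative
design used to validate the prediction stage: BM data sets on a fixed
tree, a null arm with no excess change on the focal branch, and an
alternative arm whose focal terminal branch carries a rate multiplier
drawn uniformly per data set (one draw per data set is the reading that
yields a smooth detection-vs-rate curve; the multiplier scales the
branch's variance, which for BM is identical to scaling its length). A
data set counts as detected when the focal value's two-sided normal-tail
probability against its predictive draws is below 0.05 — i.e. outside the
central 95% predictive interval, matching the species-scan definition.
The normal-tail form is used rather than raw empirical quantiles because
interval-endpoint noise at a few hundred draws inflates the false-positive
rate.

Problem sizes: the packaged analyses and tests run this study with
20,100-step chains (thin 50, 400 retained models per data set) on 50-tip
trees — the point where the detection curve is stable against further
chain lengthening in our checks. The suite's calibration property draws
the generating parameters across the regression family ($\lambda \sim
U(0,1)$, log-uniform $\sigma^2$, uniform $\beta$ and intercept): over 500
such replicates the nominal 95% predictive interval covers the held-out
tip in ~94–95% of cases. Holding the generator at the boundary value
$\lambda = 1$ instead measures the prior's pull away from the boundary,
not calibration: coverage there is ~93%, and correspondingly the null arm
of the validation study runs at ~6–8% rather than the nominal 5%. This
boundary behaviour is inherent to the uniform $\lambda$ prior, and worth
remembering when interpreting small excesses in species-wide outlier
rates.

# The species-wide scan and meta-analysis

`scan_all_species()` repeats the hold-out prediction for *every* species
and trait (scaled-down chains by default — the scan is one MCMC run per
cell), flagging values outside the central 95% predictive interval. The
focal species' headline per-trait calls additionally pass FDR selection at
10%; both thresholds are distinct and both are reported.
`meta_predict_target()` then asks whether the focal species has
exceptionally *many* outlier traits: each species' outlier proportion is
empirical-logit transformed ($\log\frac{c + 0.5}{n - c + 0.5}$, finite for
zero-outlier species), the number of traits tested enters as the
predictor, the prediction stage is re-run holding the focal species out,
and the reported tail probability is one-sided (the hypothesis is "more
outlier traits than expected").

# Numerical choices and degenerate inputs

* Species are ordered alphabetically everywhere before any linear algebra;
  results are invariant (bit-for-bit) to row and column order of inputs.
* Tip labels are matched exactly after whitespace→underscore
  normalization.
* Cholesky factors are cached per $(\lambda, \text{tree})$ or $\alpha$
  value; $\sigma^2$ updates reuse the cached quadratic form, so most MCMC
  steps cost $O(n^2)$.
* The OU covariance gets a $10^{-12}$-scale diagonal jitter before
  factorization (one retry in `ou_loglik`, then an error); negative
  conditional variances from round-off are clamped to zero with a warning
  beyond $-10^{-8}$.
* Zero-length terminal branches are legal (a target at zero phylogenetic
  distance from an observed tip with equal covariates gets its value
  predicted with zero variance); polytomies are accepted as-is, since the
  covariance construction does not require binary trees.
* Constant predictive draws yield probability 1 (value equal to the
  constant) or 0, with a warning.

# Known limitations

* The OU stage accepts one tree; phylogenetic uncertainty is averaged only
  in the prediction stage.
* Single-tip optimum shifts are intrinsically hard: when mean reversion is
  weak, the optimum needed to displace one tip lies outside the
  data-matched optimum prior and the posterior legitimately prefers the
  no-shift explanation. Recovery studies in the suite therefore plant
  shifts under strong mean reversion ($\alpha = 30$ on a unit-depth tree,
  shift ≈ 4 cross-species SDs); shifts much weaker than that are not
  reliably detectable at these data sizes, which mirrors how such methods
  behave on real clades.
* The predictive intervals inherit mild anti-conservatism at the
  $\lambda = 1$ boundary (see above).
* Half-Cauchy scales and the Poisson shift-rate are package defaults, not
  universal constants; analyses of real data should state them and, where
  conclusions are sensitive, vary them.
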