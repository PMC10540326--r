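---
title: "Testing gene presence under imperfect genome recovery: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing gene presence under imperfect genome recovery: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latentpan)
```

## The problem

Pangenome studies ask whether a gene is *enriched* in genomes from one group
relative to another — tongue versus plaque isolates, one country's gut
samples versus another's. When the genomes are metagenome-assembled genomes
(MAGs), the observed presence/absence matrix confounds two things: whether
the gene is truly present in the source genome, and whether the sequencing
and assembly were good enough to recover it. A shallowly covered MAG misses
genes it really carries; a contaminated bin contains genes it does not.
Ordinary logistic regression of observed presence on covariates cannot tell
these apart, and when genome quality is correlated with the covariate of
interest (deeper sequencing in one group, say), it systematically converts
quality differences into spurious "enrichment".

`latentpan` models the two stages separately. For genome $i$ with covariates
$X_i \in \mathbb{R}^p$ and a quality variable $M_i$ (mean coverage, CheckM
completion, ...):

$$
\operatorname{logit} \Pr(\lambda_i = 1 \mid X_i) = X_i^\top \beta,
\qquad
\Pr(Y_i = 1 \mid \lambda_i, M_i) =
\begin{cases}
f(M_i) & \lambda_i = 1\\
\varepsilon & \lambda_i = 0,
\end{cases}
$$

where $\lambda_i$ is the latent true-presence indicator, $Y_i$ the observed
detection, $f$ a monotone non-decreasing detection curve, and $\varepsilon$
the probability of observing a truly absent gene (contamination,
index-switching crosstalk). Interest is in $\beta$: the log-odds of true
presence, purged of detectability.

## Assumptions worth stating

* **Monotone detectability.** Better quality never hurts detection. This is
  the defining constraint on $f$ and matches read-subsampling experiments in
  which detection of a target gene rises with coverage. It can fail for some
  deep-sequencing/short-read-assembly combinations; the package does not
  model non-monotone curves.
* **$\varepsilon$ is fixed, not estimated.** $\varepsilon$ and $f$ are not
  jointly identifiable from one gene's detections, so $\varepsilon$ is a
  hyperparameter. Choose it from contamination/redundancy metrics (e.g. the
  maximum CheckM contamination across the MAGs); use
  `lp_epsilon_sensitivity()` to check that a discovery does not hinge on
  assuming near-zero contamination.
* **Genes are modeled independently**; there is no joint multi-gene model.
* **No missing values** in $Y$, $X$, $M$: the model defines no missingness
  mechanism for them, so `data_io` treats missingness as a hard error rather
  than imputing.

## Estimation

The latent structure makes EM natural. With
$\tilde f = \operatorname{logit} f$, the expected complete-data penalized
log-likelihood at posterior weights $p_i = \Pr(\lambda_i = 1 \mid Y_i)$
separates into a detection term in $f$, a presence term in $\beta$, and a
Jeffreys (Firth) penalty $\tfrac12 \log \lvert \sum_i X_i X_i^\top w_i
(1 - w_i)\rvert$, $w_i = \operatorname{expit}(X_i^\top\beta)$. Each EM
iteration therefore:

1. **E-step** — computes $p_i$ by Bayes' rule (`posterior_presence()`),
   clamped to $[10^{-10}, 1 - 10^{-10}]$ before the M-steps because exact
   0/1 posteriors arise whenever $\varepsilon = 0$;
2. **M-step for $\beta$** — Firth-penalized logistic regression with the
   $p_i$ as fractional outcomes, solved by Newton's method with
   step-halving to an adjusted-score norm of $10^{-8}$
   (`update_beta_firth()`). The penalty guarantees finite estimates even
   when the posteriors are separated by a covariate — frequent for
   accessory genes at small $n$;
3. **M-step for $f$** — one of two monotone classes (below).

The monitored quantity is the *penalized observed-data* log-likelihood
(marginal likelihood plus the Firth term). Because each sub-step maximizes
its block of the minorizing objective, this monitor is non-decreasing; the
test suite asserts it on 100 seeded fixtures. Iteration stops after `t_max`
steps or once the relative increase falls below `delta` for 5 consecutive
steps, with a floor of `min_iter = 16` iterations so that loose `delta`
values (used in simulation work) cannot stop the fit before the curve has
moved off its initializer.

### The two curve classes

**I-spline class (default, `f_class = "ispline"`).** $\tilde f(m) =
\alpha_0 + \sum_{j=1}^{k} \alpha_j I_j(m)$ with $\alpha_j \ge 0$ for
$j \ge 1$, where $I_j$ are I-spline (integrated M-spline) basis functions —
each rises from 0 to 1, so non-negative combinations are monotone. The
basis is built from `splines::splineDesign` via the B-spline partial-sum
identity and is verified in the tests against direct quadrature of the
M-spline basis. The M-step is a box-constrained (L-BFGS-B) weighted
logistic fit; logits are clamped to `logit_cap` *inside* the objective so
the optimized criterion coincides exactly with the likelihood that the EM
monitors. If the optimizer fails the update falls back to the constant
fit, and the returned curve never has a lower objective than that constant
fit.

Defaults `spline_df = 4`, degree 3: with $k = 4$ basis functions of degree
3 there are no interior knots — a deliberately small basis, because the
target applications have tens to low hundreds of genomes and the curve is a
nuisance function; larger `spline_df` places interior knots at quantiles of
the observed $M$.

**Isotonic class (`f_class = "isotone"`).** A non-decreasing step function
on the observed $M$ values maximizing the same detection term plus a
$-\cosh((\tilde f_i / a)^2)$ penalty per observation ($a = 50$) that keeps
the logits bounded where the unpenalized maximizer would diverge. The
solver is pool-adjacent-violators with an exact one-dimensional concave
solve per block (bisection-safeguarded Newton, vectorized over blocks);
ties in $M$ share a fitted value. This class is retained chiefly for the
estimator comparison harness: in our simulations the I-spline class
estimates $\beta_1$ with equal or lower mean squared error (the acceptance
suite checks the $n{=}100$, $\beta_1{=}2$, $\sigma_x{=}0.5$ cell at 250
draws), which is why it is the default.

A third option, `fixed_detection_curve()`, bypasses estimation when the
detection curve is known — e.g. measured by read subsampling — and is also
what reduces the model to plain Firth logistic regression
($\varepsilon = 0$, $f \equiv 1$), an identity the tests exploit as an
oracle.

### Numerical choices

* `logit_cap = 10`: fitted detection probabilities live in
  $[4.5\times10^{-5},\,1 - 4.5\times10^{-5}]$. Applied to both classes; the
  cosh penalty already bounds the isotonic class, the cap gives the spline
  class the same protection (an all-detected gene pushes the spline
  intercept to the cap rather than to infinity).
* Evaluation outside the observed $M$ range is constant at the boundary
  value — the only extrapolation that preserves both monotonicity and
  boundedness.
* The contamination term of the EM objective is constant in $(\beta, f)$
  and is dropped from optimization; when $\varepsilon = 0$ it is degenerate
  and omitted from the diagnostic objective as well.
* Ties in $M$: one fitted value per distinct $M$; secondary order is
  irrelevant.
* All-zero or all-one genes with $\varepsilon = 0$ are not identified; the
  fit is returned flagged (`identifiable = FALSE`) with the Firth-stabilized
  boundary values rather than erroring, so whole-matrix runs skip nothing
  silently.

## Hypothesis testing

Null hypotheses $A\beta = c$ (rank $h$) are fit by reparameterization:
$\beta = \beta_0 + N\gamma$ with $A\beta_0 = c$ and $N$ spanning the null
space of $A$, so the null model is the same EM on the reduced design $XN$
with offset $X\beta_0$; the Firth penalty is computed on the reduced
design. The statistic is $Q_{\mathrm{LRT}} = 2[\mathcal{L}(\hat\theta) -
\mathcal{L}(\hat\theta_0)]$ on the *unpenalized* marginal likelihood — the
penalty is an estimation device, not part of the evidence — floored at 0.

Because the alternative and null carry different Firth penalties (full
versus reduced design), the unpenalized likelihoods can order "wrongly" by
a small margin at small $n$ even at exact convergence. When that happens
the alternative is refit once from the null's parameters, the better fit
kept, and any residual negative statistic floored and noted — it is a
structural feature of penalized estimation, not an optimizer failure.

* **happi-a** (`method = "asymptotic"`): $p$ from the upper tail of
  $\chi^2_h$. Well calibrated at $n \approx 100$ and up.
* **happi-np** (`method = "permutation"`): the tested covariate columns are
  permuted jointly across genomes, holding $Y$, $M$ and nuisance columns
  fixed; each of the $B$ permutations refits both models (warm-started at
  the observed fits) and the add-one estimator
  $p = (1 + \#\{Q_b \ge Q_0\})/(B+1)$ guarantees $p \ge 1/(B+1)$.
  Deterministic given a seed. Recommended for modest $n$, where the
  $\chi^2$ approximation is anti-conservative. The permutation unit is the
  covariate (not the response), the standard exchangeable-covariate scheme
  for regression LRTs; ties count as exceedances.

Across genes, `bh_adjust()` applies Benjamini–Hochberg step-up FDR control,
and `cmd_test()` runs the per-gene pipeline over a whole presence/absence
matrix with per-gene seeds derived from one master seed, so results are
independent of the worker count.

Defaults mirror the two analysis regimes: asymptotic testing with
`t_max = 1000`, `delta = 0.01` for large collections; permutation testing
with `B = 1000`, `delta = 0.1` for small ones.

## The simulation framework

`simulate_dataset()` draws from the model itself under the standard study
design: a deterministic coverage grid $M_i = 10 + 30\frac{i-1}{n-1}$, a
covariate $X_{i2} \sim \mathcal{N}(\frac{i-1}{n-1}, \sigma_x)$ whose
correlation with coverage is controlled by $\sigma_x$ (0.25 ≈ strong, 0.5 ≈
moderate), $\varepsilon = 0$, and a fixed surrogate detection curve

$$ f(m) = \operatorname{expit}(-2 + 0.3\,m), $$

monotone, ≈0.12 at zero coverage, ≈0.73 at the design's lowest coverage
(10×), ≈1 beyond 30×. The surrogate emulates the *shape* of empirical
coverage–detection curves from read-subsampling experiments; it is not fit
to any particular gene's subsampling data. One consequence is worth
flagging: over the simulated range $M \in [10, 40]$ the surrogate varies
only from 0.73 to ≈1, so the spurious signal available to a
quality-ignoring GLM is modest, and the GLM's type-1 inflation here
(≈6–8%) is far milder than what steeper empirical curves produce —
reported inflations above 30% require detection probabilities near 0.3 at
10× coverage. The calibration claims for the latent-model tests do not
depend on the curve's steepness; the GLM comparison should be read as
directional.

What the generator does *not* emulate: phylogenetic correlation between
genomes, gene-gene linkage, annotation error structure, or multi-dimensional
quality. Passing tests therefore demonstrate correctness of the estimator
and calibration under the model's own assumptions, not robustness to those
real-data features.

Harnesses: `run_type1_study()` and `run_power_study()` report rejection
rates with 95% Wald binomial CIs per $(n, \sigma_x, \beta_1)$ cell (Wald
because the rates sit well inside (0,1) at the replicate counts used);
`compare_f_estimators()` reports mean and median squared error of
$\hat\beta_1$ for the two curve classes over the factorial grid
$n \in \{30, 50, 100\}$, $\beta_1 \in \{0.5, 1, 2\}$,
$\sigma_x \in \{0.25, 0.5\}$. Full-scale runs use 500 replicates and
$B = 1000$; the packaged test suite runs reduced versions (100 replicates
at $B = 99$ for the permutation calibration check, exact binomial CI; 500
replicates for the asymptotic and GLM cells; 250 draws for the estimator
comparison) sized so the whole suite runs in minutes on one core.

## Worked example

```{r example}
d <- simulate_dataset(sim_config(n = 100, beta = c(0, 2), sigma_x = 0.5,
                                 seed = 42))
ctl <- lp_control(delta = 0.1)
fit <- lp_fit(d$Y, d$X, d$M, ctl)
fit

hyp <- lp_hypothesis(test_cols = 2, p = 2)
lp_single_test(d$Y, d$X, d$M, hyp, method = "asymptotic", control = ctl)
```

## Known limitations

* One quality variable for the nonparametric curves; $q \ge 2$ only through
  the parametric logit-linear class (`f_class = "linear"`).
* No confidence intervals for $\beta$ — the inferential output is the test.
* $\varepsilon$ is global across genomes; genome-specific contamination
  rates are not supported.
* The permutation test's runtime is $\approx B$ times an asymptotic test;
  warm starts reduce but do not remove this.
* Under strong covariate–quality correlation and small $n$, no method has
  meaningful power; the latent model's contribution there is keeping the
  type-1 error at its nominal level, not rescuing power.
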