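---
title: "Normative modeling of white matter asymmetry: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative modeling of white matter asymmetry: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmasym)
```

## The problem

Hemispheric asymmetry of white matter pathways — a left arcuate fasciculus
that is denser than the right, a right superior longitudinal fasciculus
that is bulkier than the left — is a basic organizational feature of the
brain, and it is not static: asymmetries emerge in infancy, remodel during
development, and often amplify in aging. A single mean-difference test
cannot describe this; what a developmental or clinical study needs is a
*normative chart*: for a given tract, feature and age, what is the typical
asymmetry and how widely do healthy individuals vary around it?

wmasym builds such charts. The unit of analysis is the laterality index of
a paired bilateral measurement,

$$\mathrm{LI} = \frac{R - L}{R + L},$$

computed per subject, tract and feature from left/right tract values (DTI
microstructure: FA, MD, AD, RD; macrostructure: volume, mean streamline
length, surface area). LI is 0 at perfect symmetry, positive for rightward
asymmetry, and bounded in $[-1, 1]$ for nonnegative inputs. Pairs with a
missing hemisphere (segmentation failures) are excluded with counts rather
than imputed, and pairs with $R + L = 0$ are excluded because the index is
undefined there — silently scoring them 0 would bias symmetry estimates.
For users who hold per-voxel maps, `streamline_weighted_mean()` implements
the standard streamline-count-weighted tract average; the pipeline's
canonical input, though, is the already-aggregated tract value.

## The model

For each tract-feature, LI is modeled as Gaussian with age-varying
location and scale:

$$\mathrm{LI}_i \sim \mathcal{N}(\mu_i, \sigma_i^2)$$
$$\mu_i = f_\mu(\mathrm{age}_i) + \beta_{\mu,\mathrm{sex}}\,\mathrm{male}_i + u_{\mu,c(i)}$$
$$\log \sigma_i = f_\sigma(\mathrm{age}_i) + \beta_{\sigma,\mathrm{sex}}\,\mathrm{male}_i + u_{\sigma,c(i)}$$

This is a location-scale (GAMLSS-type) formulation: the log link keeps
$\sigma > 0$ everywhere, and letting $\sigma$ depend on age captures the
age-dependent heteroscedasticity that lifespan data show (wider spread in
early childhood and old age). Sex is coded female = 0, male = 1 and enters
both predictors.

### Fractional polynomial smooths

$f_\mu$ and $f_\sigma$ are fractional polynomials (FP) of order 1 or 2
with powers from $\{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$; power 0 denotes
$\log t$ and a repeated pair $(p, p)$ contributes $(t^p,\; t^p \log t)$,
the standard FP convention for repeated powers (so $(0,0)$ gives
$(\log t, \log t^2)$). That yields 8 order-1 candidates and
$8 + \binom{8}{2} + 8 = 44$ candidates up to order 2.

FP bases need a strictly positive argument, and the cohorts include
age 0, so age is first transformed as

$$t = \frac{\mathrm{age} + 1}{10}.$$

The +1 shift makes $t$ positive from birth; the /10 scale keeps the
extreme bases numerically tame over 0–100 years ($t^3 \le 1030$,
$t^{-2} \le 100$). The transform is a declared design choice, stored in
every fit artifact so charts are reproducible from the artifact alone.
FP terms are used uncentered; the intercept absorbs centering.

### Cohort effects

Multi-site lifespan data carry between-study offsets. The model uses
sum-to-zero cohort intercepts on both predictors — deterministic,
reproducible, and zeroed out when predicting the population reference.
An optional ridge penalty $\lambda(\lVert u_\mu\rVert^2 +
\lVert u_\sigma\rVert^2)$ (`cohort_effect = "ridge"`) shrinks the offsets
toward zero, mimicking random-effect shrinkage while staying sum-to-zero;
population charts are identical under either choice by construction.

### Estimation and numerics

The fit maximizes the exact Gaussian likelihood with the analytic
gradient: BFGS from a deterministic start ($\mu$ coefficients from least
squares on the $\mu$ design, $\log\sigma$ intercept from the log residual
SD, everything else 0), followed by Newton polishing with a numerically
differentiated Hessian and step-halving. There are no random restarts, so
a fit is a pure function of data and spec, and refitting permuted rows
reproduces coefficients to ~1e-8.

Numerical guards and conventions:

* the $\log\sigma$ predictor is floored at $-12$ during iteration; fits
  ending within 1 unit of the floor are flagged (`near_sigma_floor`);
* convergence is declared when $\max_j |g_j| \le
  \mathrm{tol}\,(1 + |\ell|)$ with tol = 1e-8 — a relative criterion,
  because the likelihood scales with $n$ and an absolute gradient norm is
  not comparable across sample sizes. Newton polishing typically lands
  orders of magnitude below this;
* with an intercept-only $\sigma$ and no cohorts, the ML $\hat\mu$
  coincides with ordinary least squares; the test suite asserts agreement
  to 1e-6 against an independent least-squares oracle, and the $\mu$
  predictions are also cross-checked against `mgcv::gam` with the
  `gaulss` family on a simulated table.

### Model selection

Candidate smooths are compared by BIC, $-2\ell + k \log n$, where $k$
counts all free coefficients (each sum-to-zero cohort block contributes
cohort-count minus one). No effective-degrees-of-freedom adjustment is
applied to the penalized variant — the count is deterministic and
recorded in the artifact. The default search is *staged*: select $f_\mu$
over the 44 candidates with $f_\sigma$ fixed linear, then select
$f_\sigma$ given the winner (88 fits). An exhaustive $44 \times 44$ cross
(1936 fits) is available behind `strategy = "exhaustive"`; on the
simulation scenarios the staged search recovers the generating $\mu$
smooth reliably (19/20 seeds in the replicate harness), so staged is the
default at desk scale. BIC ties within 1e-6 break toward the smaller
total order, then lexicographically smaller powers — simpler shapes win
ties.

## Charts and derived summaries

Centile curves evaluate $\mu(a) + z_q\,\sigma(a)$ on a dense age grid
(default step 0.25 years, confined to the fitted age range — FP tails
are not trustworthy outside the observed support; no extrapolation).
Levels default to the 2.5th/25th/50th/75th/97.5th percentiles. Because
$z_q$ is monotone and $\sigma > 0$, curves cannot cross. The pooled-sex
curve averages the two sex-specific $\mu$ and $\sigma$ with equal weight;
this is an approximation to the mixture quantile, adequate for
median-level summaries (sex differences in these data are small) and
recorded in the chart artifact.

Four summaries mirror the questions a lifespan asymmetry chart is asked:

* **Milestones** (`milestone_summary()`): median LI and model-based
  percent right-lateralized, $100\,\Phi(\mu/\sigma)$, at representative
  ages 3, 12, 30 and 50 years. Prevalence is model-based rather than an
  empirical count so it is available at exact ages; the generator-based
  tests confirm it matches empirical fractions of simulated draws.
* **Reversals** (`detect_reversals()`): zero-crossings of the median
  trajectory, linearly interpolated between grid points of opposite
  sign; an exact grid-point zero attaches to the following sign change.
  All crossings are reported in age order; an optional `epsilon`
  (default 0) treats $|m| \le \epsilon$ as zero to suppress numerically
  trivial crossings.
* **Window slopes** (`window_slope()`, `lifespan_slopes()`): the mean
  finite-difference derivative of $|m(a)|$ within childhood (2–12 y),
  adolescence (12–20 y), young adulthood (20–40 y) and middle/late
  adulthood (40–100 y). On a uniform grid the mean telescopes to
  $(|m(b)| - |m(a)|)/(b-a)$; positive values mean asymmetry is
  strengthening, negative attenuating, exact zero is labeled neutral
  rather than forcing a sign claim.

## The synthetic-cohort generator

Real multi-site lifespan data of this kind are not redistributable, so
the package ships a generator that inverts the model: ages uniform over
the range (deliberately harder for smooth recovery than the age pyramids
of real consortia), sex Bernoulli with a 44.4% female mix typical of
large lifespan consortia, balanced cohort assignment with centered
cohort offsets drawn once on a sub-seed (so redrawing subjects never
shifts the cohort configuration), and
$\mathrm{LI} \sim \mathcal{N}(\mu, \sigma)$.
`simulate_bilateral_table()` additionally inverts the LI definition —
$R = B(1+\ell)$, $L = B(1-\ell)$ around a positive base curve $B$ — so
the full pairing-and-LI path reproduces the drawn values to 1e-12.

Five catalog scenarios (`scenario()`) exercise the phenomena the charts
must capture: `flat_symmetric` (null), `linear_drift`,
`log_growth_reversal` (median $0.04(\log t - \log 3.1)$, root placed
analytically at exactly age 30, with a local slope steep enough that the
crossing age is estimable to well under a year at $n = 10{,}000$),
`heteroscedastic_u_shape`, and `multi_cohort_shift`. The u-shape
scenario is the stress case for selection: its mean,
$-0.02 + 0.08\log t - 0.02 t$, was chosen so that the best rival FP
basis leaves a weighted approximation residual large enough for BIC to
discriminate at $n = 5000$ (an expected deviance gap of roughly 20) —
"strong curvature" made precise — while its U-shaped scale
($\sigma \approx 0.02$ mid-life, $\approx 0.03$–0.045 at the extremes)
emulates the wider centile bands of early childhood and aging. LI
magnitudes in all scenarios stay within the ranges reported for real
tracts (microstructural medians a few hundredths; macrostructural
medians up to ~0.1–0.2 with strong population consensus).

What the generator does *not* emulate: realistic per-cohort age pyramids
(an optional restriction of cohort age ranges is future work), scanner
and protocol harmonization artifacts, tractography failure modes, and
non-Gaussian LI tails. Passing the recovery and calibration tests
therefore demonstrates correctness of the estimation machinery under the
model's own assumptions, not robustness to violations of them.

## Problem sizes and reproducibility

The validation harness uses $n = 10{,}000$ subjects for median-recovery
and reversal checks (max median error < 0.005 LI units, crossing within
1 year of the planted root), $n = 20{,}000$ for centile calibration
(empirical tail fraction 0.025 ± 0.004), $n = 5000 \times 20$ seeds for
selection recovery, and $n = 50{,}000$ single-age draws for the
prevalence link — sizes at which Monte-Carlo error is comfortably inside
the asserted bounds. All randomness flows from explicit integer seeds;
fits are deterministic given data and spec; pipeline runs with the same
config and seed produce byte-identical summary tables.

## Known limitations

* The Gaussian family is fixed: skewed or heavy-tailed LI distributions
  are not modeled (no Box-Cox-type shape parameters).
* FP smooths are global polynomials in transformed age; they cannot
  express sharp local features (e.g. a perinatal spike) the way
  penalized splines could, and they are unstable outside the observed
  age support — hence the no-extrapolation rule.
* The pooled-sex curve is an equal-weight average, not the mixture
  quantile; for strongly sex-divergent tracts use per-sex charts.
* Cohort offsets are intercepts only; cohort-specific age slopes
  (scanner-by-age interactions) are out of scope.
* Individual-level z-scoring of new subjects against a chart is a
  straightforward extension but intentionally not included.
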