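---
title: "Methods: a bivariate Vasicek diffusion model of stand growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a bivariate Vasicek diffusion model of stand growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standsde)
```

## The model

Tree size in a stand is modelled as a bivariate diffusion
$X(t) = (D(t), H(t))^\top$ — diameter at breast height in cm and total
height in m — driven by a mean-reverting (Vasicek) stochastic differential
equation

$$dX^i(t) = A(X^i(t))\,dt + B^{1/2}\,dW^i(t), \qquad
A(x) = \begin{pmatrix}\beta_d(\alpha_d + \varphi_d^i - d)\\
\beta_h(\alpha_h + \varphi_h^i - h)\end{pmatrix},\qquad
B = \begin{pmatrix}\sigma_{11} & \sigma_{12}\\
\sigma_{12} & \sigma_{22}\end{pmatrix},$$

where $i$ indexes stands. Each stand shifts the asymptotes through
independent Gaussian random effects $\varphi_d^i \sim N(0, \sigma_d^2)$,
$\varphi_h^i \sim N(0, \sigma_h^2)$; the diffusion matrix $B$ (required
positive definite) carries the within-stand noise. Every tree starts at the
breast-height initial condition $t_0 = 5$ yr, $d_0 = 0$ cm, $h_0 = 1.3$ m:
the age at which a tree reaches 1.3 m, where dbh is defined and equals
zero.

**Assumptions.** Trees within a stand are conditionally independent
realisations of the stand's diffusion given $(\varphi_d^i, \varphi_h^i)$;
inventory data are single-visit (one measurement age per tree); parameters
are constant in age; the noise is Gaussian, so simulated or implied sizes
can be non-positive with small probability at young ages.

### Transition law

Linear drift makes the transition law Gaussian in closed form. Writing
$a = \alpha + \varphi$ per trait and $\tau = t - t_0$:

$$\mu(t) = a + (x_0 - a)e^{-\beta\tau},\qquad
\nu_d^2(t) = \frac{\sigma_{11}(1 - e^{-2\beta_d\tau})}{2\beta_d},\qquad
\nu_{d,h}^2(t) = \frac{\sigma_{12}(1 - e^{-(\beta_d+\beta_h)\tau})}
{\beta_d + \beta_h},$$

with $\nu_h^2$ analogous to $\nu_d^2$. The mean form
$a + (x_0 - a)e^{-\beta\tau}$ is the only Vasicek mean consistent with the
initial condition $\mu(t_0) = x_0$; the package uses it everywhere — in the
density, the mixed-model predictors, the calibration inversion and the
trees-per-ha model alike — so that all layers are mutually consistent.
The joint density is the standard bivariate normal
$N_2(\mu(t), \Sigma(t))$, evaluated in log space with the closed-form
$2\times 2$ inverse (determinant guarded at $10^{-300}$). Conditionals are
the usual Gaussian regressions, e.g.
$E[H|D=d] = \mu_h + (\nu_{d,h}^2/\nu_d^2)(d - \mu_d)$ with
size-independent variance $(1-\rho^2(t))\,\nu_h^2(t)$. The stationary law
has mean $(\alpha_d + \varphi_d, \alpha_h + \varphi_h)$, variances
$\sigma_{11}/2\beta_d$, $\sigma_{22}/2\beta_h$ and covariance
$\sigma_{12}/(\beta_d + \beta_h)$.

Parameter validation rejects non-positive-definite diffusion matrices with
a diagnostic reporting $\sigma_{12}^2 - \sigma_{11}\sigma_{22}$ rather than
silently projecting; a parameter set whose implied stationary covariance is
not positive definite is likewise refused. This matters in practice: fitted
parameter sets from sparse inventories can land outside the admissible
region, and guessing a repair would change the model.

## Estimation

### Likelihood structure

Each tree contributes the transition density from the initial state to its
size at its measurement age; stands are independent. For the fixed-effects
variants the log-likelihood is the plain sum of per-tree log densities with
$\varphi = 0$. For the mixed variants, the stand's tree-product is
integrated against the Gaussian effect law:

$$\ell = \sum_i \log \int\!\!\int \Big[\prod_j f(d_j, h_j, t_j \mid \theta,
\varphi)\Big]\, \phi(\varphi_d; \sigma_d)\, \phi(\varphi_h; \sigma_h)\,
d\varphi_d\, d\varphi_h .$$

Because the transition mean is *linear* in $\varphi$ (with per-tree loading
$k(t) = 1 - e^{-\beta\tau}$), the integrand is exactly Gaussian in
$\varphi$. The implementation exploits that twice: the per-stand posterior
mode and curvature are available in closed form, and adaptive Gauss–Hermite
quadrature centred and scaled there (default 15 nodes per dimension,
`quad_spec()`) is exact for any node count — a single node (the Laplace
option) already reproduces the integral. The node count is kept
user-settable because the machinery is generic; the test suite verifies
15-node, 25-node and Laplace evaluations agree to $10^{-8}$, and that a
one-tree stand matches the analytic Gaussian convolution (variances
inflated by $k(t)^2\sigma^2$).

### Optimisation, parameterisation, standard errors

Optimisation (`stats::nlminb`) runs on a transformed scale that makes the
constraints structural: $\log$ for the reversion rates, variance rates and
effect SDs, and $\sigma_{12}$ through
$\rho = \tanh(\eta)\in(-1,1)$ times $\sqrt{\sigma_{11}\sigma_{22}}$, which
enforces positive definiteness of $B$ by construction. Fixed-effects fits
multi-start from a grid of reversion rates $\{0.01, 0.03, 0.08\}$/yr with
the asymptote and variance rate closed by least squares and moments given
the rate; mixed fits warm-start from the fixed optimum, with effect-SD
starts from the spread of crude per-stand mean inversions and the
within-stand variance rates deflated by 0.6 (the fixed fit absorbs
between-stand spread into the diffusion). Standard errors come from the
observed information on the transformed scale (finite-difference Hessian),
delta-method mapped to the natural scale; they are omitted when the Hessian
is not positive definite.

The comparison index reported alongside each fit is $-2\,\ell$
(`aic_index()`), the convention used with these models; the conventional
penalised form $-2\ell + 2k$ is available via `penalized = TRUE` and stored
as `aic_penalized`, clearly labelled, since the two orderings can differ
when comparing variants of different dimension.

### Volume regression and trees per ha

The stem-volume equation $V(d,h) = \beta_1 d^{\beta_2} h^{\beta_3}$ is fit
by weighted least squares (`minpack.lm::nlsLM`), initialised from the
log-linear OLS fit. The default weights $w_i = d_i^{-2}$ are the classical
choice for heteroscedastic stem-volume data; they are user-overridable and
the estimates are invariant to rescaling all weights.

Stand density $N^i(t)$ (trees/ha) follows a univariate Vasicek diffusion
anchored by $P(N^i(200) = \delta) = 1$: running the law backwards from the
anchor gives $N(t) \sim N\!\big(a(1 - e^{\beta(t-200)}) +
\delta e^{\beta(t-200)},\ \sigma^2(1 - e^{2\beta(t-200)})/2\beta\big)$ with
$a = \alpha + \varphi_N$, so the variance vanishes exactly at age 200 and
is undefined beyond it (ages above 200 are rejected). The mean is coded as
the convex blend $a(1-e) + \delta e$, which is bit-exact at the anchor.
The two reference parameter scenarios shipped with the package — wildly
different in $(\alpha, \beta, \delta)$ — agree to within half a tree at age
100 (≈372 vs ≈373 trees/ha), a useful internal consistency check of the
anchored mean form. The fixed-effects fit profiles $\sigma$ out of the
Gaussian likelihood (exact, and numerically robust down to noise-free
data); the mixed fit adds $\varphi_N \sim N(0, \sigma_N^2)$ marginalised by
1-D adaptive Gauss–Hermite quadrature. This model is weakly identified on
short age ranges — $(\alpha, \beta, \delta)$ trade off along a ridge when
no observations approach the anchor age — which is why the shipped
scenarios can differ so much while implying nearly identical curves over
the observed range; fits should span ages as close to 200 as the data
allow.

## Calibration and prediction

A new stand's effects are predicted by inverting the mean curve per tree
and averaging:

$$\hat\varphi = \frac1m \sum_{j=1}^m
\frac{x_j - \hat\alpha - (x_0 - \hat\alpha)e^{-\hat\beta\tau_j}}
{1 - e^{-\hat\beta\tau_j}}$$

per trait, using each tree's own age. This is a pure inversion: exact on
noise-free data (tested to $10^{-10}$) and unshrunken — a deliberate
choice, implemented as the simple averaged inversion rather than a BLUP,
so a single-tree calibration at great age reduces to
$x - \hat\alpha$. The price is extra variance for small $m$; the
regression slope of $\hat\varphi$ on the true effect stays in
$[0.9, 1.05]$ at $m = 8$ trees in the shipped simulations.

Eight mean predictors are exposed (`predict_mean`): marginal fixed (`d1`,
`h1`), marginal calibrated (`d2`, `h2`), conditional-on-the-other-trait
fixed (`d3`, `h3`) and conditional calibrated (`d4`, `h4`). They nest
exactly: zero effects collapse 4→3 and 2→1, and conditioning at the stand's
own mean collapses 4→2. Prediction quality is summarised by the mean bias
B, percentage bias PB, absolute bias AB, percentage absolute bias PAB (both
percentage indexes scaled by 100), adjusted RMSE
$AE = \sqrt{B^2 + \frac{1}{n-1}\sum(y - \hat y - B)^2}$ and adjusted
$R^2 = 1 - \frac{n-1}{n-p}\frac{\sum(y-\hat y)^2}{\sum(y-\bar y)^2}$ with
$p = 7$ for fixed- and $p = 9$ for mixed-effects predictors by default.

## Integral stand attributes

Slenderness $E[H/D]$, mean stem volume $E[V(D,H)]$, its SD/CV, and stand
volume per ha $\mu_N(t)\,E[V]$ are expectations under the bivariate law.
They share one engine, `integrate_bivariate()`: product Gauss–Legendre
quadrature over mean $\pm 8$ SD intersected with the positive quadrant
(floor $\varepsilon = 10^{-6}$), doubling the node count until the relative
change is below $10^{-6}$. Power-law and ratio integrands are undefined for
non-positive sizes, hence the truncation; the retained probability mass is
computed as a diagnostic, and slenderness values at ages where more than
0.1% of the mass is cut (very young stands, where the $1/d$ singularity
meets non-negligible density) are flagged with a warning. Near an active
floor the $d$-axis (and $h$-axis) is split into a log-spaced panel on
$(\varepsilon, 1]$ plus a linear panel above — the substitution
$d = e^u$ removes the $1/d$ singularity, without which the plain rule
stalls near the $10^{-5}$ level. Slenderness is normalised by the retained
mass (a truncated-law expectation); the volume moments are not, the deficit
being far below the quadrature tolerance at the ages of interest.

Assortment fractions $100\,P(D > d_\min, H > h_\min)$ use the Gaussian
rectangle probability via the conditional-slice decomposition
$\int_{d_\min}^\infty \phi_d(x)\,\bar\Phi\big((h_\min - m_h(x))/w_h\big)dx$
with adaptive 1-D quadrature — accurate to $10^{-6}$ against direct 2-D
quadrature and independent of the product-rule engine. Every integral
attribute is also validated against a Monte-Carlo oracle built on the exact
sampler (up to $10^6$ draws in the acceptance suite).

## The synthetic inventory generator

`simulate_forest()` emulates single-visit national-forest-inventory plots
of Scots pine, the package's reference study conditions: stand ages drawn
uniformly on 17–221 yr (one shared age per plot, since a plot is visited
once; per-tree ages are available as an option), 3–10 measured trees per
plot, and the reference parameter set of `scots_pine_params()` including
$\sigma_d = 5.9592$ cm, $\sigma_h = 3.6830$ m. A master seed spawns one
substream per stand, so datasets are reproducible and insensitive to
generation order. Simulated sizes are kept exactly as drawn from the
Gaussian law — occasional non-positive values at young ages included — so
moment tests against the closed forms remain exact; `truncate_positive`
redraws them for applications needing physical sizes.

What the generator deliberately does *not* emulate: measurement error,
diameter-threshold plot inclusion rules (real inventories calliper only
trees above a minimum dbh), spatial structure, competition and mortality
(beyond the separate $N(t)$ model), and non-Gaussian size distributions.
Passing tests therefore demonstrate correctness of the model's own
machinery — likelihoods, quadrature, calibration, attribute integrals —
under the model's assumptions, not fidelity of those assumptions to any
real inventory.

## Problem sizes and numerical choices

The shipped test and acceptance runs use desk-scale designs chosen to give
tight Monte-Carlo and recovery tolerances at interactive runtimes:
fixed-effects recovery on 1,500 plots × 4 trees (all seven parameters
within 10–15%), mixed-effects recovery on 200 stands × 8 trees (fixed
effects within 10%, effect SDs within 25%), 2×10⁵ exact-sampler draws
(moments within 3 Monte-Carlo SEs), Euler–Maruyama with dt = 0.01 yr
(means within 1%), ten-replicate model comparisons (the mixed variant's
$-2\ell$ beats the fixed one in ≥ 9/10 clustered datasets), and 10⁶-draw
Monte-Carlo oracles for the attribute integrals (0.3 pp on assortments,
0.5–1% on volume moments). Step-size convergence of the Euler scheme is
checked as a 5-seed trend at two step sizes.

Other numerical choices: all densities in log space; log-sum-exp for the
quadrature mixtures; `nlminb` iteration caps of 1,000; the
tanh-correlation transform clamped to $|\rho| \le 0.99$ at start
construction; quadrature-noise negative variances clamped to zero only
below $10^{-10}$ (larger negatives raise an error); calibration refuses
ages at or below $t_0$ where the inversion denominator vanishes.

## Known limitations

- The Gaussian law admits negative sizes; all attribute integrals truncate
  to the positive quadrant, which is an approximation at very young ages
  (flagged for slenderness).
- Calibration is unshrunken: noisy for one or two trees per stand.
- The trees-per-ha model's parameters ride a stiff ridge unless the data
  approach the anchor age; interpret individual parameter values with
  care even when the fitted curve is stable.
- Only asymptote random effects are supported (not rates or diffusion),
  matching the estimation design; dominant height and stand basal area
  are out of scope, as is a trivariate (d, h, N) model.
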