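---
title: "Delta-GLMM standardization of shark longline CPUE: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delta-GLMM standardization of shark longline CPUE: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sharkCPUE)
```

## The two-part model and its assumptions

Set-by-set shark CPUE (retained sharks per 1,000 hooks) is zero-inflated:
a large fraction of longline sets record no blue shark or shortfin mako
at all, while positive catches are strongly right-skewed. `sharkCPUE`
follows the fisheries delta (hurdle) decomposition, which splits the
likelihood into two parts fit on disjoint information:

1. a **binomial submodel** with logit link for the probability that a set
   has a non-zero catch, and
2. a **gamma submodel** with log link for the magnitude of positive CPUE,
   with a constant shape parameter $k$ estimated jointly by maximum
   likelihood.

Both parts share the same covariate structure: categorical fixed effects
for year (the quantity of interest), month, fleet (local vs foreign) and
observer status (yes/no/unknown, three genuine levels rather than
dropping unknowns), plus a per-vessel random intercept that absorbs
persistent skipper/vessel catchability differences. The two random
intercepts are independent between parts: nothing in the data identifies
a cross-part correlation, and assuming independence keeps the product
variance formula exact to first order.

The gamma choice is diagnosable rather than assumed:
`dispersion_diagnostic()` regresses log variance on log mean of positive
CPUE across year × area cells. Under a constant-shape gamma,
$\mathrm{Var} = \mu^2/k$, so the Taylor power-law exponent is 2; the
test suite verifies the generator reproduces a slope of 2 (within
$\pm 0.2$ at 30 cells of 200 positives) and the diagnostic returns an
explicit `insufficient_cells` status — never a fabricated slope — when
fewer than 3 cells have 5 positives (both minima configurable).

A modelling decision the data leave open is whether the gamma response
is the positive CPUE itself or the positive count with a log-effort
offset. The package models CPUE directly, which matches the index's
units and makes the intercept-only fit collapse to the sample mean of
positive CPUE; counts-with-offset would weight sets by effort
differently but is otherwise equivalent in structure.

## Random-effect integration: Laplace, audited by quadrature

The marginal likelihood integrates the vessel intercept per vessel. With
a single scalar random effect the integrand is log-concave for both
families, so the package uses the Laplace approximation: for each vessel
a damped Newton iteration locates the mode of the joint log-density, and
the integral is replaced by the second-order expansion at the mode. The
outer optimization is quasi-Newton (`nlminb`) over
$(\beta, \log\sigma[, \log k])$ with the exact analytic gradient of the
Laplace objective (including the curvature term, via implicit
differentiation of the mode), fixed starting values (zeros,
$\log\sigma = \log 0.5$, $\log k = 0$) and a relative tolerance of
$10^{-8}$, so fits are deterministic given the data. The coefficient
covariance is the inverse observed information, computed by central
finite differences of the analytic gradient.

Accuracy is audited, not assumed: `marginal_loglik_oracle()` recomputes
the marginal log-likelihood by adaptive Gauss–Hermite quadrature (nodes
from `pracma`), using `stats::optimize` for its mode search and
`dbinom`/`dgamma` densities so it shares no code with the fitter. The
acceptance suite requires agreement within $10^{-3}$ per observation on
small fleets; observed discrepancies are one to two orders of magnitude
smaller. The suite also cross-checks whole fits against `lme4::glmer`
and `glmmTMB` on shared datasets.

Two boundary behaviours deserve note:

- **No random term.** The fit reduces exactly to `stats::glm`; for the
  gamma part the shape is then the root of the profile score
  $\log k - \psi(k) = \overline{y/\hat\mu - \log(y/\hat\mu)} - 1$
  (cross-checked against `MASS::gamma.shape` in tests).
- **Vessel SD on the boundary.** On data without real vessel
  heterogeneity the ML estimate of $\sigma$ sits at a small interior
  value on roughly half of datasets and collapses toward zero on the
  rest; below $\sigma = 10^{-3}$ (link scale — scientifically
  indistinguishable from zero, and the log-$\sigma$ profile is flat
  there) the fit is finalized through the GLM path with
  $\sigma_{\mathrm{vessel}} = 0$, which keeps the covariance
  well-defined. The variance component still counts as an estimated
  parameter in BIC, because it was estimated.

Non-convergence is always flagged (`converged = FALSE`), never silently
returned; coefficients beyond a configurable bound (default 15 on the
link scale) attach a separation warning.

## Model selection

`stepwise_select()` performs forward inclusion over the candidate terms
month, fleet and observer; year and the vessel intercept are always
retained so an annual index can be extracted. At each step the term
lowering BIC ($-2\ell + p\ln n$, $p$ counting fixed coefficients,
variance components and the gamma shape) the most is added; selection
stops when no addition lowers BIC. Fits that fail to converge are
excluded from the comparison but recorded in the returned table, and
ties are broken by candidate order, so selection is deterministic. The
error structures and links are fixed at binomial-logit and gamma-log —
the choices the diagnostic above supports — so the search is over fixed
terms only. One structural caveat built into the synthetic studies:
vessels are nested within fleets, so the sampling error of a fleet
contrast is dominated by the number of vessels per fleet (roughly
$\sigma\sqrt{2/G_\mathrm{fleet}}$), not by the number of sets; detecting
fleet effects requires them to be large relative to that, which is why
the selection-consistency simulations use a fleet effect of 1.5 on the
logit scale against a vessel SD of 0.5 across 15 vessels per fleet.

## The index and its errors

`predict_year_effects()` forms, per year, the linear predictor of each
submodel under a prediction policy, back-transforms with the first-order
delta method ($\hat p = \mathrm{logit}^{-1}(c)$ with
$se \cdot \hat p(1-\hat p)$; $\hat\mu = e^{c}$ with $se \cdot \hat\mu$),
and multiplies:
$$ I_t = \hat p_t \hat\mu_t, \qquad
   se(I_t) = \sqrt{\hat\mu_t^2 se_p^2 + \hat p_t^2 se_\mu^2}. $$

The default **reference policy** evaluates each year at the reference
cell (January, foreign fleet, observer absent, vessel intercept 0) — the
year trace on the link scale shifted to the observation scale. The
alternative **population policy** averages response-scale predictions
over the observed joint distribution of the other factors, with the
delta-method SE of the weighted average; the two coincide exactly when
year is the only fixed term. Neither is presented as the canonical
choice: the reference policy is cleaner for trend comparison, the
population policy for absolute magnitude.

The delta-method transforms deliberately omit the lognormal mean
correction; `bias_correct = TRUE` switches on $e^{c + se^2/2}$ for the
log link. The test suite checks every propagated SE against Monte-Carlo
standard deviations ($10^6$ draws) and requires agreement within 10% in
the moderate-uncertainty regime ($se/\mathrm{estimate} \le 0.3$); outside
that regime first-order propagation degrades and the reported SEs should
be read as approximate.

`flag_anomalies()` screens the finished series for year-on-year scale
jumps — changes exceeding a 3-fold ratio by default, in either direction,
with a small additive floor so near-zero indices do not explode the
ratio. The threshold is an artifact default for a screen that is
qualitative in practice; flagged years (such as a 4 to 191 jump, a
roughly 48-fold increment) are for inspection, not automatic removal.

## What the synthetic generator does and does not emulate

`generate_logbook()` draws data from the exact model above, so parameter
recovery is a well-posed question. Defaults encode the study fishery's
nominal structure: 29,018 sets over 2000–2015 split between 61 local and
49 foreign vessels (16,810/12,208 sets); hooks per line from truncated
normals with (1282, 250) local and (2493, 597) foreign on the plausible
effort range 310–3,800; zero-catch rates of 37%/29% (blue, by fleet) and
32%/40% (mako) at the reference cell via the binomial intercepts and
fleet effects; near-complete observer coverage on foreign vessels from
2003; positions drawn inside per-area boxes so the generated area label
is the stratification truth; and mean individual weights of about
10.5 kg (blue) and 21 kg (mako) back-calculated from the reported
landings totals and compositions. Year and month effect shapes, vessel
SDs (0.5 logit / 0.4 log), the gamma shape (2) and the non-shark weight
scale are not reported quantities; they were fixed once at
field-plausible values and are fully configurable.

Counts are back-derived as `round(CPUE × hooks / 1000)` and coerced to
at least 1 on an encounter (an encounter must be visible in a
retained-count logbook), so the observed CPUE carries a small rounding
discretisation the latent gamma does not; at the default catch rates
this is negligible relative to sampling error, and the recovery tests
confirm nominal coverage despite it.

What passing tests therefore show is that the pipeline recovers truth
when the data follow the assumed process with realistic sizes and
contamination. They cannot show robustness to what real logbooks add:
unreported discarding that varies over time (retained counts are not
catches), reporting behaviour that differs between observed and
unobserved sets in unmodelled ways, spatial effort contraction within
areas, species misidentification, or oceanographic drivers of
catchability. Those remain caveats on any real-data application, not
properties the synthetic studies can certify.

The contamination process (`inject_anomalies()`) corrupts disjoint
record subsets per defect class (positions outside the region,
out-of-range years or effort, counts above the 801 cap, sharks
outnumbering hooks, missing fields), returning the corrupted ids so the
cleaning oracle test can demand exact recovery.

## Cleaning and stratification conventions

Filters retain sets with years 2000–2015 and 310–3,800 hooks
(inclusive), at most 801 retained sharks of each species (inclusive; the
cap's per-species reading is a documented choice, with the combined-total
alternative behind `cap_scope = "combined"`), strictly fewer sharks than
hooks, positions inside the study region, and no missing required
field — the last rule standing in for upstream checks (depth, set
duration) on fields not modelled here. Rejections are tallied under the
first failing rule in a fixed order (missing → year → position → hooks →
cap → sharks-vs-hooks) so reports are deterministic; the suite verifies
idempotence, monotonicity in every bound, and exact partition of the
input.

Stratification splits the region at 20°E (ICCAT/IOTC reporting), at 33°S
on the Atlantic side (West vs Southwest) and at 26°E (South vs East),
with half-open eastern/southern edges so boundary points assign
deterministically (exactly 20°E falls to IOTC/South). The Namibian and
Mozambique border latitudes are configurable northern bounds (−28.6°,
−26.85°): only region membership, not the exact border, affects the
analysis. The reading of the Southwest as "west of 20°E and south of
33°S" is a stated interpretation of a boundary description that mixes a
latitude and a longitude.

## Problem sizes and numerical tolerances used in validation

The simulation studies in the test suite use sizes chosen to make their
statistical assertions sharp: 50 replicates of 5,000 sets across 30
vessels for Wald coverage (pooled over replicate × coefficient pairs per
submodel, since per-coefficient binomial noise at 50 replicates would
dominate a per-coefficient assertion) and for index recovery within 2
propagated SEs; 20 replicates for BIC selection consistency; 10,000
random positions for the stratification oracle; $10^6$ draws for
Monte-Carlo SE checks. Quadrature audits use 50–100 nodes, where halving
the node count moves the oracle by under $10^{-8}$. Closed-form limits
(intercept-only fits) are required to $10^{-8}$; the $\sigma = 0$
collapse to the GLM to $10^{-4}$.

## Known limitations

- The random effect is a vessel intercept only: no vessel-level slopes,
  no spatial or spatio-temporal random fields, no vessel-within-area
  structure (species × area models are fully independent fits).
- First-order delta-method errors understate uncertainty when
  submodel SEs are large relative to estimates, and the product-error
  formula drops the (positive) second-order term.
- The gamma shape is constant across observations; dispersion that
  varies with covariates would be absorbed into the mean model.
- Zero-inflated discrete alternatives to the hurdle-gamma are out of
  scope; the Taylor diagnostic motivates the gamma but does not compare
  it against them.
- BIC's parameter count includes variance components at face value;
  boundary-constrained components make BIC comparisons conservative
  toward simpler models.
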