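---
title: "Movement type and post-transition child mortality: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Movement type and post-transition child mortality: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(demotransit)
```

## The scientific question

Democratization tends, on average, to be followed by faster-than-expected
declines in under-5 child mortality, but the effect is heterogeneous: some
new democracies see mortality fall well below the pre-transition trend, others
see it rise above it. This package implements a quantitative workflow for one
candidate explanation: the *type of movement* that produced the transition.
Protest-led transitions — driven by broad, nonviolent mass campaigns — are
hypothesised to build the representative, accountable institutions that lower
child mortality; violence-led transitions (coups, insurrections, civil wars)
are hypothesised not to.

The unit of analysis is a democratic transition. Each country contributes one
case: movement-type flags (`protest_led`, `violence_led`, mutually exclusive,
with elite-negotiated and other nonviolent transitions forming a residual
third group), a set of political-economy covariates, and a **long-run
mortality deviation** — how far (log-scale) under-5 mortality sat above or
below the extrapolated pre-transition trend ten or more years after the
transition, with a 95% interval. The packaged classification table
(`transition_fixture()`) covers 51 transitions: 33 protest-led and 14
violence-led.

## Stage 1: country-specific interrupted time series

`fit_its()` estimates the deviation outcome from annual mortality series. For
country $i$ with transition year $T_i$, writing $t = \mathrm{year} - T_i$ and
$\mathrm{post} = \mathbf{1}(t > 0)$:

$$\log(\mathrm{U5MR}_{it}) = \alpha_i + \beta_i t +
  \gamma_i\,\mathrm{post} + \delta_i\, t\,\mathrm{post} + \varepsilon_{it}$$

$\gamma_i$ is the level break at the transition and $\delta_i$ the slope
break. The long-run deviation at horizon $h$ (default 10 years, the smallest
horizon the long-run estimand admits) is the linear combination
$\gamma_i + \delta_i h$, with a delta-method interval from the OLS covariance.
The log scale encodes proportional mortality decline and matches the magnitude
of deviations the estimates take (roughly $-0.05$ to $0.04$).

Two pooling modes are provided. `pooling = "none"` fits each country
independently. `pooling = "partial"` is a two-stage empirical-Bayes
random-coefficients fit: per-country OLS, then DerSimonian–Laird shrinkage of
the level and slope breaks toward their precision-weighted grand means
(`metafor::rma.uni`), each country pulled with weight $v_i/(v_i+\tau^2)$. The
original deviation estimates this mirrors came from a Bayesian random-slopes
model; we use the frequentist two-stage form deliberately — it is
deterministic, fast at desk scale, and admits an exact no-pooling limit
(`shrinkage = 0` reproduces `pooling = "none"`, which the tests assert). One
approximation is worth naming: after shrinking the two break coefficients
marginally, their cross-covariance is rescaled by the geometric mean of the
two shrink factors rather than re-derived from a joint posterior. At the
noise levels used here the effect on interval width is negligible (coverage
in the recovery study stays at ~95%), but it is an approximation, not an
identity.

## Stage 2: bivariate effect regressions

`fit_bivariate()` regresses the deviation point estimates on a movement flag
by OLS. With a single binary regressor the coefficient is exactly the
difference in group means, which gives the tests a machine-precision oracle.
Standard errors are classical by default (a `robust = TRUE` HC1 switch
exists); p-values are two-sided from the t distribution.

## Stage 3: propagating credible-interval uncertainty

The deviations are estimates, not data. `propagate_uncertainty()`
re-estimates the bivariate model (default 1000 times per predictor), each
time perturbing every country's outcome with
$N(0, ((\mathrm{upper} - \mathrm{lower})/(2 \times 1.96))^2)$ noise, i.e.
treating the 95% interval as a symmetric normal posterior (the interval
family — equal-tailed vs HPD — is not stated by the upstream estimates, so
equal-tailed normal is assumed). The share of replicate p-values below 0.05
summarises whether the headline association survives the scenarios the
intervals envision. Because the design matrix is fixed across replicates, all
replicate fits are computed in one least-squares solve; a per-replicate `lm()`
oracle in the tests confirms the identity.

## Stage 4: multiverse robustness

With only ~51 cases, adjusting for all eight candidate covariates at once
costs too much precision, and picking one subset invites specification
hunting. `run_multiverse()` therefore fits **every** covariate subset
($2^8 = 256$ models), with `coloniser` entering as two dummies against a
"not colonised" reference, and summarises:

* **sign stability** — percent of estimable models whose coefficient shares
  the preferred estimate's sign;
* **significance rates** at $p < 0.05$ and $p < 0.1$;
* **robustness ratio** — the preferred estimate divided by a spread measure
  of the estimates across models.

The preferred estimate is the bivariate (empty-subset) model, which is the
headline presentation. For the denominator the default is the Young–Holsteen
total standard error, $\sqrt{\overline{se^2} + \mathrm{Var}(\hat\beta_m)}$,
combining mean sampling variance with between-model variance — this is the
estimate the cited robustness methodology defines, and it degenerates to
$|\beta/se|$ for a single model. The literal "standard deviation of the
estimates across models" reading is available as
`denominator = "sd-of-estimates"`. Specifications rendered non-estimable by
perfect collinearity or too few complete cases are dropped from the summaries
and counted, not imputed.

## Stage 5: coarsened exact matching

`cem_match()` implements CEM: bin the matching covariates (`coarsen()`
defaults to Sturges binning, $\lceil\log_2 n\rceil + 1 = 7$ equal-width bins
at $n = 51$; quantile bins and user edges are supported), form strata from the
bin signatures, prune strata lacking either treatment level, and weight
controls by (stratum treated count)/(stratum control count) so control weights
sum to the treated count within each stratum. The weighted effect is
re-estimated by WLS with HC1 robust standard errors — the weights themselves
induce heteroskedasticity. Two structural identities anchor the tests: the L1
imbalance on the coarsened covariates is zero among retained cases, and a
single all-inclusive stratum reproduces the bivariate OLS estimate exactly.
Default matching covariates are GDP per capita, mortality at transition and
democratic history; the original matched analysis also used two variables
("weak democratic transitions", post-transition corruption) whose definitions
live in an unavailable appendix, so they are left as optional user-supplied
columns rather than guessed. The pipeline driver uses median splits rather
than Sturges bins, because 7³ cells over 51 cases prunes nearly everything —
a well-known small-sample CEM trade-off the user controls via
`matching_bins`.

## Stage 6: the necessity test under measurement error

Is a non-protest-led transition *necessary* for higher-than-expected
mortality? Any deviant case (a protest-led transition with
higher-than-expected mortality) logically refutes necessity — but only under
zero measurement error. The Braumoeller–Goertz $p_I$-test asks instead
whether the deviant cases are too many to blame on misclassification:

1. classify each case (`classify_outcome()`): `higher` iff the 95% interval
   lies strictly above 0, `lower` iff strictly below, `null` otherwise
   (null cases are *not* deviant — they sit in the "not
   higher/lower-than-expected" row of the 2×2 tables);
2. build the 2×2 condition-by-outcome table (`classification_table()`);
3. compute $\hat p$ = deviant/condition cases and its one-sided exact
   (Clopper–Pearson) 95% lower bound, $\mathrm{qbeta}(\alpha, x, n-x+1)$
   (`binomial_lower_bound()`); the exact construction, rather than a normal
   approximation, is required for validity at $n = 14$ and reproduces the
   published bounds;
4. reject necessity only if that lower bound exceeds the assumed
   misclassification rate (`necessity_test()`).

The error rate is an analyst input, not an estimate the data provide; 2% is
the documented default (the literature's benchmark for an "enviably low"
rate), and the decision should be read as a sensitivity statement in that
rate.

```{r necessity}
fx <- transition_fixture()
necessity_test(classification_table(fx, "protest_led", "higher"),
               assumed_error_rate = 0.02)
necessity_test(classification_table(fx, "violence_led", "lower"),
               assumed_error_rate = 0.03)
```

With 2 deviants of 33 protest-led cases, the lower bound 1.09% sits below any
plausible error rate (2%): the deviant cases could be measurement error, so
necessity is not rejected. Same conclusion for 2 of 14 violence-led cases
(bound 2.60% < 3%).

## The synthetic-data generator

Real inputs (the upstream Bayesian deviation estimates, World Bank / V-Dem
covariates) require external downloads, so every stage is exercised against
`simulate_transitions()`, whose defaults *are* the study conditions:

* 51 cases; movement type a three-way categorical with $P(\text{protest}) =
  0.65$, $P(\text{violent}) = 0.27$ (observed prevalences), the remainder
  other-nonviolent;
* true group-mean deviations $-0.017$ (protest), $+0.020$ (violent), $0$
  (other) — the headline coefficients read as group effects;
* between-country spread 0.019 and interval half-widths uniform on
  $[0.005, 0.02]$. These two are not printed anywhere directly; they are
  derived from printed quantities: the bivariate SEs (~0.0055–0.0058 at group
  sizes 33/18 and 14/37) imply a residual SD of ~0.020, of which the average
  sampling variance implied by half-widths of that range contributes
  $\overline{(hw/1.96)^2} \approx 4.6\times10^{-5}$, leaving
  $\sqrt{4.0\times10^{-4} - 4.6\times10^{-5}} \approx 0.019$ between
  countries. The one worked example of an interval (half-width 0.0145) falls
  inside the configured range. The width distribution itself is unstated
  upstream; uniform is an assumption;
* covariates drawn independently from scaled-Beta (continuous), Bernoulli
  (binary) and categorical marginals matching the observed ranges, means and
  frequencies. Only marginals are published, so no correlation structure is
  imposed by default; `confound_treat` / `confound_outcome` tie treatment and
  outcome to baseline mortality when a matching test needs a known
  confounder.

What passing tests on this generator do and do not show: they demonstrate
that the estimators recover known truths under the stated noise model —
unbiasedness, coverage, sign stability, significance propagation — not that
real transition data satisfy that model. In particular the generator draws
covariates independently of movement type (except via the explicit
confounding hooks), has no serial structure in the deviation estimates, and
does not mimic the census/vital-registration mixture behind real mortality
estimates.

`implied_contrast()` converts a configuration's group means into the expected
bivariate coefficient (focal group mean minus the prevalence-weighted mean of
the rest); recovery tests always compare against this generator-implied
truth, never against a hard-coded number.

## Numerical choices and problem sizes

* Noiseless inputs are exact identities, asserted at `1e-10`–`1e-12`; the
  Clopper–Pearson bound is checked against a bisection oracle on the exact
  binomial tail to `1e-6` for all $x \le n \le 60$.
* Recovery studies use 200 simulated datasets for coefficient means, 40–50
  multiverse sweeps for sign stability, 10×1000 replicates for uncertainty
  propagation, and 500 countries for ITS bias/coverage — sizes at which
  Monte-Carlo error is a few percent of the quantities checked while the
  whole suite stays interactive.
* Ties and degenerate inputs: intervals touching zero classify as `null`;
  zero-width intervals are allowed (degenerate but valid); zero deviant cases
  give a lower bound of exactly 0; quantile coarsening deduplicates repeated
  quantiles; non-estimable regressions carry a reason string instead of
  raising.

## Known limitations

* The ITS stage fixes the estimand (level + slope break at a known transition
  year, log scale); it does not reproduce the upstream Bayesian estimator,
  only its target, and `pooling = "partial"` shrinks the two breaks
  marginally rather than jointly.
* The necessity decision is only as meaningful as the assumed error rate, and
  with 14 condition cases the exact bound is wide.
* Listwise deletion is the only missing-data strategy (one covariate has a
  single missing value in the real data; the generator produces none).
* The 51-case classification fixture carries no covariates or interval
  estimates; regression-stage examples therefore run on synthetic data unless
  the user supplies the deposited dataset.
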