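---
title: "Assessing lake ecological security with screened DPSIR indices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing lake ecological security with screened DPSIR indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(lakesec)
```

## The assessment model

`lakesec` turns a long-running lake monitoring programme into a single
annual **Ecological Security Index (ESI)**. Candidate indicators are
organised by the DPSIR causal chain — **D**riving force (socio-economic
development), **P**ressure (emissions, land conversion), **S**tatus
(in-lake water quality), **I**mpact (fisheries, recreation) and **R**isk
(the chance of an ecological disaster, here a cyanobacterial bloom).

Three statistical ingredients sit on top of that bookkeeping.

### 1. A bloom-risk statistic from daily records

Eutrophic lakes bloom when temperature and nutrient preconditions are
met simultaneously. With $n_i$ daily records in year $i$, of which
$n_{Ti}$, $n_{Pi}$, $n_{Ni}$ lie strictly below the lowest temperature,
total phosphorus and total nitrogen levels at which blooms occur, the
annual risk indicator is

$$x_{i,r} \;=\; 1-\frac{n_i-n_{Ti}}{n_i}\cdot
  \frac{n_i-n_{Pi}}{n_i}\cdot\frac{n_i-n_{Ni}}{n_i} \in [0,1].$$

Note the orientation: the statistic **rises** when more days fail a
bloom precondition. As defined it is a the-higher-the-better (safety)
quantity — a low value flags a year in which the lake was bloom-capable
nearly year-round — so it enters normalization as a *benefit* indicator
by default. Because prose discussions of "risk" often assume the
opposite orientation, `risk_as_indicator()` exposes a `direction`
override rather than silently reinterpreting the formula. Records lying
exactly on a threshold count as bloom-capable (strictly-below
counting). Thresholds are user inputs: they must come from local bloom
observations, and the synthetic defaults
(`bloom_thresholds(10, 0.05, 1)` — 10&nbsp;°C, 0.05&nbsp;mg/L TP,
1&nbsp;mg/L TN) are placeholders of plausible magnitude, not calibrated
values.

### 2. Indicator screening against multicollinearity

Socio-economic series from one watershed (population, GDP, industrial
output, ...) are usually near-duplicates of a single growth trend.
Averaging them all into the D component would count the same signal
several times and drag the composite index down (or up) with redundant
weight. Screening enforces two of the classic indicator criteria,
independence and representativeness:

1. **Correlation test.** Within each category, every indicator pair is
   tested with a Pearson correlation and a two-sided t-test on
   $n-2$ degrees of freedom (`correlation_matrix()`). Zero-variance
   series are flagged and treated as non-significant.
2. **Clustering.** Pairs significant at `alpha` (default 0.05; 0.01 is
   the common stricter choice, both exposed in `screening_config()`)
   become edges of a graph whose connected components are the clusters
   of mutually redundant indicators (`cluster_correlated()`).
   Connected components are the weakest grouping assumption that still
   yields a partition; no stronger cluster model is imposed.
3. **PCA selection.** Within a multi-member cluster the standardized
   member series are decomposed by PCA on their correlation matrix
   (units are incommensurable, so covariance PCA would be arbitrary).
   If PC1 explains at least `pc_variance_threshold` (default 0.8) of
   the variance, the cluster is represented by the single member with
   the largest absolute PC1 loading; otherwise one member is taken per
   leading component until the cumulative explained variance reaches
   the threshold (`select_representative()`).

Correlations are computed on the raw annual series without detrending:
co-trending is exactly the redundancy being screened, so inflated
correlations among trending series are a feature, not a bias.

Degenerate cases are deterministic: loading ties (which always occur in
standardized two-member clusters, whose PC1 loadings are equal in
magnitude by construction) are broken lexicographically by indicator id
and reported via a message; clusters of constant series fall back to the
lexicographically first id.

### 3. Baseline normalization and geometric aggregation

All surviving indicators are expressed relative to a baseline
(background) year $b$. Benefit-direction indicators use
$x'_{i,j} = x_{i,j}/x_{b,j}$; cost-direction indicators use
$x'_{i,j} = x_{b,j}/x_{i,j}$. The direction flag belongs to the
*indicator*, not to individual values — a per-value rule would force
$x' \ge 1$ everywhere and could never produce a sub-baseline index.
After normalization every indicator equals exactly 1 in the baseline
year and "higher is better" holds uniformly.

Component indices and the ESI are weighted geometric means,

$$\mathrm{Index}_{k,i} = \prod_{j\in k}\big(x'_{i,j}\big)^{w_{k,j}},
 \qquad
 \mathrm{ESI}_i = \prod_{k}\big(\mathrm{Index}_{k,i}\big)^{w_k},$$

with uniform default weights ($1/m_k$ within a component, $1/5$
across the five components). The geometric mean is the natural
aggregator for ratio-scaled data: it makes the pipeline invariant to
rescaling any raw series (units cancel), keeps every index between the
smallest and largest normalized value, and forces the baseline-year
identity $\mathrm{ESI}_b = 1$ exactly. Both properties are enforced in
the test suite to 10–12 decimals against an independent
$\exp(\sum w\log x')$ computation. Zeros are structurally excluded —
panel values must be strictly positive, and a zero baseline risk value
raises an error rather than being patched with an epsilon, since any
epsilon choice would silently dominate the geometric mean.

## The synthetic watershed generator

No public monitoring panel accompanies the method, so `lakesec` ships a
generator (`generate_panel()`, `generate_daily_conditions()`) that
reproduces the two structural features the method is designed to
handle, together with the planted ground truth needed to test recovery:

* **A collinear driver block.** `driver_block_size` cost-direction
  series follow a single-factor model
  $z_j = c_j\,\ell + \sqrt{1-c_j^2}\,\varepsilon_j$ on a monotone
  standardized latent trend $\ell$, mapped to positive values by
  $x_j = 100\,j\,e^{s_j z_j}$ (log-linear growth, the standard shape
  for socio-economic series). The latent correlations $c_j$ are spread
  asymmetrically around $\sqrt{r}$ (representative at
  $\min(0.9995, \sqrt{r}+0.0095)$, the rest at $\sqrt{r}-0.0035$ to
  $\sqrt{r}-0.006$) so that pairwise correlations average the target
  `driver_block_correlation` while exactly one member carries a
  recoverable largest loading. This spread is a deliberate compromise,
  chosen once from a design-stage power analysis at the default 20-year
  panel: a wider spread would make the top loading easier to recover
  from 20 samples but push the weakest pairwise correlation below the
  emulated `> 0.95` regime; a narrower one would make sample PCA
  loadings effectively exchangeable. The per-member log-scales
  $s_j = 0.06 + 0.03\,(\textrm{rank}_j - 1)$ grow as loadings shrink:
  the most representative driver (think resident population) grows
  slowest, the noisier economic series grow faster — which is what
  makes unscreened driving-force indices decline more steeply than
  screened ones. Which indicator id receives the top loading is
  shuffled per seed and recorded in the planted truth.
* **A V-shaped ecological trajectory.** Pressure, status and impact
  series are tied to a piecewise-linear latent with vertex at
  `worst_year` (cost series peak there, benefit series trough there).
  A piecewise-linear V is the simplest latent whose extremum year is
  well-posed to recover. Each category mixes one strongly tied series
  (log amplitude 1.0, noise `noise_sd`, default 0.04) with — for
  status and impact — a weakly tied companion (amplitude 0.08, noise
  `2.5 * noise_sd`), so that within-category correlations stay mostly
  below significance and screening is exercised on the driver block
  rather than on everything. The distributional forms and noise levels
  are chosen for test power (sharp, recoverable structure), not
  calibrated to any real watershed; magnitudes are deliberately
  arbitrary.
* **Daily conditions.** Temperature follows a fixed seasonal sine
  cycle (16&nbsp;±&nbsp;8&nbsp;°C, noise sd 2&nbsp;°C), guaranteeing a
  below-threshold cold season every year so the annual risk value never
  hits zero; daily TP/TN levels are lognormal around a mean that rises
  toward `worst_year` and falls back (log amplitude 0.52, daily noise
  sd 0.3, baselines 0.04 and 0.8&nbsp;mg/L just below the default
  thresholds), so below-threshold day counts — and hence the risk
  indicator — dip markedly at the planted worst year without
  saturating at the vertex.

Everything is driven by one integer seed; generation restores the
caller's RNG state, and fixture files (`generate_fixture()`) are
byte-identical across reruns.

What passing the recovery tests does **not** show: real monitoring
panels have missing years, autocorrelated noise, indicators whose
direction is debatable, and redundancy that spans categories. The
generator emulates none of these; it validates the machinery, not the
field-readiness of any particular indicator set.

## A worked run

```{r run}
cfg <- synthetic_config(seed = 1)
gen <- generate_panel(cfg)
daily <- generate_daily_conditions(cfg)
assessment <- run_assessment(
  gen$panel, daily,
  assessment_config(baseline_year = 1988)
)
assessment
glance(assessment)
```

The screening audit trail shows the driver block collapsing to its
planted representative:

```{r screening}
assessment$screening
tidy(assessment$screening)
```

```{r plots}
autoplot(assessment)
plot_screening_effect(assessment)
```

The `comparison` table regresses each unscreened index series on its
screened counterpart (baseline year excluded, since both series are
pinned to 1 there). The slopes document the multicollinearity
mechanism: with redundant drivers included, the D index declines more
steeply. Impact and risk comparisons are computed for completeness and
flagged `supplementary`, since assessments of this design conventionally
report the D, P, S and ESI comparisons.

```{r comparison}
assessment$comparison
```

## Numerical choices and problem sizes

* Correlation p-values come from the exact t-transform
  $t = r\sqrt{(n-2)/(1-r^2)}$; the clustering edge rule is
  $p \le \alpha$.
* Geometric means are computed as $\prod x^w$ directly; agreement with
  the log-space route is a test invariant (1e-10), not a runtime
  branch.
* Index comparisons use simple OLS; $R^2$ is computed from residual
  and total sums of squares, so identical series give exactly 1 and a
  constant predictor gives `NA` (undefined), never 0.
* Validation suites use a 20-year panel (1988–2007, baseline 1988,
  worst year 1998), a driver block of 3 at target correlation 0.98,
  365 daily records per year, and 100-seed batches for the recovery
  rates; these sizes mirror the two-decade monitoring horizon the
  method targets — roughly 20 annual samples are the accepted minimum
  for the correlation screening to be meaningful.

## Known limitations

* Indicator-to-category assignment and direction flags remain expert
  judgment; the package checks consistency, not ecology.
* Screening is within-category only; a driver that duplicates a
  pressure series is not detected.
* The PC1-loading selection rule is degenerate for two-member clusters
  (equal |loadings|); the lexicographic tie-break makes the choice
  deterministic but arbitrary, and the audit trail is the place to
  catch it.
* Weights are configuration, defaulting to uniform; no elicitation
  (AHP, entropy) is provided.
* No spatial dimension: one panel describes one integrated water body.
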