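# lakesec

Composite ecological-security assessment for lakes under long-term
monitoring, built on the DPSIR indicator framework (Driving force,
Pressure, Status, Impact, Risk). The package is aimed at environmental
analysts who hold two decades of annual socio-economic and water-quality
series plus daily condition records, and want a defensible annual index
of how far the lake has drifted from a chosen background condition.

## What it computes

**Bloom risk.** From daily records, with `n` entries in a year of which
`n_T`, `n_P`, `n_N` lie strictly below the lowest temperature, total
phosphorus and total nitrogen levels at which cyanobacterial blooms
occur:

```
x_r = 1 - ((n - n_T)/n) * ((n - n_P)/n) * ((n - n_N)/n)
```

`x_r` lies in [0, 1] and rises when more days fail a bloom
precondition, so it enters the index as a benefit-direction (safety)
indicator by default.

**Screening.** Within each DPSIR category, indicator pairs are tested
with Pearson correlation (two-sided t-test, `n - 2` df); significant
pairs form a graph whose connected components are clusters of redundant
indicators; each multi-member cluster is reduced by PCA on the
correlation matrix — one representative (largest |PC1 loading|) when
PC1 explains ≥ 80 % of the variance, otherwise one indicator per
leading component. This removes the multicollinearity that would
otherwise double-count a shared growth trend.

**Index construction.** Each surviving indicator is normalized against
the baseline year `b` — benefit: `x' = x/x_b`, cost: `x' = x_b/x` — and
aggregated with weighted geometric means:

```
Index_k,i = prod_j (x'_ij)^w_kj        (within component k)
ESI_i     = prod_k (Index_k,i)^w_k     (across D, P, S, I, R; w_k = 1/5)
```

Every index equals 1 at the baseline year; values below 1 mean
deterioration. The pipeline also recomputes everything *without*
screening (the "ESINEW" variant) and regresses each unscreened series
on its screened counterpart to quantify the redundancy bias.

A synthetic watershed generator (`generate_panel()`,
`generate_daily_conditions()`) provides panels with planted ground
truth — a near-collinear driver block with a known most-representative
member, and a V-shaped ecological trajectory with a known worst year —
used throughout the test suite to verify that screening and the ESI
recover what was planted.

## Worked example

```r
library(lakesec)

cfg   <- synthetic_config(seed = 1)          # 1988-2007, worst year 1998
gen   <- generate_panel(cfg)
daily <- generate_daily_conditions(cfg)

assessment <- run_assessment(
  gen$panel, daily,
  assessment_config(baseline_year = 1988)
)
assessment
#> # Ecological security assessment
#>   years: 1988-2007, baseline 1988
#>   indicators: 8 -> 6 after screening (+ bloom risk)
#>   minimum ESI: 0.5521 in 1998
#>   screened vs unscreened ESI R^2: 0.998

assessment$screening
#> # Indicator screening: 8 -> 6 indicators
#>   D: {gdp, industry_output, population} -> population
#>   P: tp_load (independent)
#>   S: do_conc (independent)
#>   ...
```

The three collinear driving-force series (pairwise r > 0.95) collapse
to the planted representative, `population`. The screened ESI declines
from 1 in 1988 to its minimum 0.55 in the planted worst year 1998 and
recovers afterwards. In `assessment$comparison`, the unscreened D index
slope (−0.0132/yr) is steeper than the screened one (−0.0091/yr):
redundant drivers exaggerate the decline, which is exactly what
screening removes. `autoplot(assessment)` and
`plot_screening_effect(assessment)` draw the trajectories;
`tidy()`/`glance()` give tabular summaries; `run_assessment(...,
out_dir = "report")` writes `esi.csv`, `screening.json` and
`report.json`.

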