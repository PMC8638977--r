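---
title: "Normality testing for interval-valued data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normality testing for interval-valued data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutrojb)
```

## The model

An interval-valued (neutrosophic) observation is written

$$z = a + b\,I, \qquad I \in [I_L, I_U],$$

with determinate part $a$, indeterminacy coefficient $b$, and an unknown
indeterminacy level $I$ shared by the whole sample. At $I = 0$ the
observation is the exact value $a$; as $I$ grows, the observation drifts by
$b I$. Data recorded directly as intervals $[L, U]$ are mapped to this form
by $a = L$, $b = U - L$ with $I \in [0, 1]$, so the realized series sweeps
exactly the recorded interval.

Every statistic in this package is computed by **endpoint evaluation**: the
classical statistic of the realized series $z(i) = a + b\,i$ is evaluated at
$i = I_L$ and at $i = I_U$, and the ordered pair is reported. The pair is
kept in endpoint correspondence (the value at $I_U$ may be *smaller* than at
$I_L$ — higher moments are not monotone in $i$), alongside a sorted
$[\min, \max]$ view used for interval comparisons. Alternatives based on
interval arithmetic over all cross products of endpoint terms produce wider,
convention-dependent bounds and are deliberately not implemented: endpoint
evaluation is the unique convention under which every interval statistic is
an actual classical statistic of an attainable data set.

Moment conventions, fixed throughout:

* variance divisor $n$ (not $n-1$): $S = \sqrt{\sum (z - \bar z)^2 / n}$;
* skewness $k_3 = \sum d^3 / (n S^3)$, the third standardized moment;
* kurtosis is **excess** kurtosis $k_4 = \sum d^4 / (n S^4) - 3$, zero for
  normal moments and bounded below by $-2$ for any real series. The excess
  convention is forced by the test statistic below, which squares $k_4$
  directly.

The neutrosophic Jarque–Bera statistic is then, per endpoint,

$$JB_N = n\left(\frac{k_3^2}{6} + \frac{k_4^2}{24}\right),
  \qquad JB_N \in [JB_L, JB_U],$$

each endpoint equal to the classical JB statistic of the realized series
there — so with $b \equiv 0$, or $I_L = I_U$, the procedure *is* the
classical JB test, exactly.

## Decision rule and the measure of indeterminacy

Under normality $JB$ is asymptotically $\chi^2_2$, giving the default
critical value $-2\log\alpha$ (5.991 at $\alpha = 0.05$) and the closed-form
p-value $e^{-JB/2}$, attached endpoint-wise. Applied work sometimes compares
against the $\chi^2_3$ quantile 7.815 instead; a `critical_value` argument
supports any override, and the worked example in the README uses it. The
package does not take a position on which quantile such sources intended —
both are available, the 2-df value is the default because it matches the
statistic's stated null distribution.

The classical rule only covers intervals wholly below the threshold. We make
the straddling case explicit rather than forcing it to either side:

* **accept** — both (sorted) endpoints below the critical value;
* **reject** — both at or above it;
* **indeterminate** — the interval straddles it: the data's vagueness alone
  prevents a decision.

The scalar **measure of indeterminacy** is the relative width
$(JB_{\max} - JB_{\min})/JB_{\max}$ (0 for a degenerate interval), which
satisfies the identity $JB_{\min} + JB_{\max} m = JB_{\max}$ exploited by
the rendered neutrosophic form `JB_N = JB_L + JB_U I_N; I_N in [0, m]`.
This is the unique one-parameter relative-width measure consistent with the
published comparative tables for the gold-mines data (0.6353, 0.3187,
0.7061 for the three centres).

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `i = c(i_lower, i_upper)` | `c(0, 1)` | Indeterminacy interval; dimensionless, `0 <= i_lower <= i_upper`. `[0, 1]` sweeps from "no indeterminacy" to "full coefficient"; `c(0, 0)` is the classical analysis. |
| `alpha` | 0.05 | Significance level of the chi-square comparison. |
| `critical_value` | `-2 log(alpha)` | Override for the threshold; e.g. 7.815. |
| `b` | 0 | Indeterminacy coefficients; 0 reproduces classical data. |

The default `[0, 1]` interval deserves a note: published gold-mines analyses
state a nominal indeterminacy interval of $[0, 0.05]$ yet their upper-endpoint
sums of squares are reproducible only at $i = 1$, i.e. on the series $a + b$.
We therefore treat the interval as a user-configurable input with default
$[0, 1]$, which reproduces both published SS endpoints; the fixture analyses
in the tests use it. The published *upper* endpoints of the skewness,
kurtosis and JB values themselves are not reproducible under endpoint
evaluation at any single $i$ (several imply raw kurtosis below 1, impossible
for any real series) and are treated as a known divergence: the package
asserts only the lower endpoints, both SS endpoints and the indeterminacy
measures, and does not attempt to guess the convention behind the remaining
printed values.

## Degenerate inputs and numerical choices

* Moments need $n \ge 3$; below that the constructor of the test errors.
* A realized series constant at an endpoint has $S = 0$; skewness and
  kurtosis are then undefined and the package raises a typed
  `neutrojb_degenerate_error` naming the endpoint instead of returning 0/0.
  In the data-frame interface the affected group gets an `NA` row with the
  message in `note` while other groups proceed; in the simulator such
  replicates are counted, excluded from rates, and warned about.
* All computation is in double precision; printed reports round to 4
  decimals (mirroring how such tables are usually published), with a
  `--full-precision` CLI flag. Tests compare published 4-decimal values with
  an absolute ±0.001 band, since the sources truncate rather than round.
* Deviations at each endpoint sum to zero to ~1e-12 by construction; the
  test suite holds all moment operations to 1e-10 against independent
  naive-loop oracles.

## The simulation harness

The paper-scale worked example is desk-sized, so the package's operating
characteristics are established by simulation. A `sim_scenario()` fixes the
determinate-part distribution (normal, uniform, exponential, Student t,
chi-square), a model for the indeterminacy coefficients, the indeterminacy
interval, `n`, the replicate count and a root seed; `run_simulation()`
tallies accept/reject/indeterminate decisions with binomial Monte-Carlo
standard errors, and `estimate_size()` restricts to the normal null.

Coefficient models: `zero` (classical), `constant` ($b = c$),
`proportional` ($b = c|a|$), `halfnormal` ($b = |N(0, c)|$). Note that the
`constant` and `proportional` (for positive data) models shift or scale the
realized series affinely, and JB is affine-invariant — both endpoints then
coincide and no indeterminate decisions arise. The `halfnormal` model is the
one that genuinely perturbs the shape of the series and is used to study the
indeterminate-decision rate; under it, widening the indeterminacy interval
drives the indeterminate rate up, checked empirically in the tests.

Reproducibility: one root seed per scenario draws one sub-seed per replicate,
so any replicate can be regenerated from the root seed alone; reports echo
the full scenario.

The generator emulates independent draws with a homogeneous indeterminacy
mechanism. It does not emulate correlated observations, group structure,
measurement rounding, or indeterminacy coefficients dependent on unobserved
covariates — so passing size/power checks here says nothing about robustness
to dependence or heteroskedastic vagueness in real data.

Problem sizes used in the checked-in tests: size under the normal null at
$n = 2000$ with 2000 replicates (empirical size must land in
$[0.03, 0.07]$ at $\alpha = 0.05$ — JB converges to its asymptotic null
slowly, so desk-scale $n$ keeps the check honest without being excessive);
power against the exponential alternative at $n \in \{50, 200, 800\}$ with
300 replicates; 1000 random samples of $n \le 50$ for the oracle-equivalence
property.

## Known limitations

* A single shared indeterminacy level: per-observation intervals
  $[I_{L,k}, I_{U,k}]$ are not modelled (convert such data to the
  interval layout instead).
* Sample-size intervals $n \in [n_L, n_U]$ are not supported; the size is a
  single integer.
* The endpoint pair is not a bound on $JB_N(i)$ over the whole interval:
  higher moments are not monotone in $i$, so intermediate $i$ can exceed
  both endpoints. The tri-state decision refers to the endpoint interval.
* Asymptotic critical values only; small-sample Monte-Carlo critical-value
  tables can be produced with the simulation harness but are not a default.
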