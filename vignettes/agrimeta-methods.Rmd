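---
title: "Methods: hierarchical meta-analysis of organic farming effects on species richness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical meta-analysis of organic farming effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrimeta)
```

## The problem

Field studies comparing species richness on organic and conventional farms
report arm-level summaries (mean richness per sampling unit, SD, replicate
count) for many taxa, crops and countries, and a single publication often
contributes several observations (different organism groups or crops on the
same farms). `agrimeta` synthesizes such a literature: it computes
per-observation effect sizes, pools them in a model that respects the
within-publication dependence, quantifies heterogeneity, probes the
file-drawer problem, and attaches standardized land-use-intensity covariates
sampled from land-cover maps.

## Effect size

For one observation with organic arm $(\bar x_o, s_o, n_o)$ and conventional
arm $(\bar x_c, s_c, n_c)$, the effect size is the log response ratio

$$y = \ln \bar x_o - \ln \bar x_c, \qquad
  v = \frac{s_o^2}{n_o \bar x_o^2} + \frac{s_c^2}{n_c \bar x_c^2},$$

so $y > 0$ means the organic arm is richer and $100(e^y-1)$ is the percent
richness difference. The normal approximation to the log ratio degrades for
noisy small arms; the per-arm score $\sqrt{n}\,\mu/\sigma$ should generally
exceed 3. `adequacy_summary()` reports the fractions below/above 3 and 6 —
both per effect (minimum over the two arms) and per arm, because field usage
is ambiguous between the two conventions. The screen is diagnostic only:
flagged effects are reported, never dropped, and no small-sample bias
correction is applied to $y$ itself.

A score exactly at a threshold counts as "not below" it, so the below-3 and
not-below-3 fractions always partition the data.

## The hierarchical Bayes linear model

Effect sizes follow

$$y_i = x_i'\beta + \delta_i + \varepsilon_i, \qquad
  \varepsilon \sim N(0, \mathrm{diag}(v)), \qquad
  \delta \sim N(0, \tau^2 M(\phi)),$$

where $M(\phi)$ is block-diagonal by publication with 1 on the diagonal and
$\phi \in [0,1)$ off-diagonal inside a block. $\tau^2$ is the between-effect
variance; $\phi$ is the share of it carried by a publication-level deviation
common to all of a publication's observations. Large within-publication
clusters of extreme effects are thereby down-weighted instead of dominating
the pooled mean.

Choices the model fixes, with rationale:

* **Prior on $\beta$:** flat. The coefficient posterior conditional on
  $(\tau, \phi)$ is then the GLS solution $\hat\beta(\tau,\phi)$ with
  covariance $(X'V^{-1}X)^{-1}$, $V = \mathrm{diag}(v) + \tau^2 M(\phi)$.
* **Prior on $\tau$:** DuMouchel log-logistic
  $p(\tau) = s_0/(s_0+\tau)^2$ with $s_0$ the square root of the harmonic
  mean of the $v_i$ — the standard weakly-informative choice for this model
  family; it is proper, puts half its mass below a "typical" standard error,
  and has no user-tuned hyperparameter.
* **Quadrature:** $\tau$ is integrated on a deterministic 201-node
  trapezoidal grid on $[0,\ 10\sqrt{\tilde s^2}]$ (ten typical within-study
  standard errors; $\tilde s^2$ defined below). Posterior moments of $\beta$
  are the grid-weighted mixtures of $\hat\beta(\tau,\phi)$ and its
  covariance. Deterministic quadrature was preferred over MCMC or adaptive
  schemes so identical inputs give bitwise-identical output. Grid settings
  are configuration, recorded in the output.
* **Dependence $\phi$:** by default chosen on the grid
  $\{0, 0.05, \dots, 0.95\}$ by maximizing the marginal evidence
  (the $\tau$-integrated likelihood); a fixed-$\phi$ mode exists and is used
  by tests and by repeated internal refits. With one observation per
  publication all blocks are singletons and the fit is $\phi$-invariant
  (tested).
* **Cost:** each grid node uses the Woodbury identity on the block
  structure, so a node is $O(Np^2)$ and a full profiled fit at $N = 184$
  takes about a second. A dense brute-force evaluation (full $V$,
  `solve()`, `determinant()`) is kept in the test suite as an independent
  oracle; the two routes agree to $10^{-4}$ (they are the same mathematics,
  so observed agreement is near machine precision).

Degenerate inputs: $v_i \le 0$, non-finite $y$, $N < p$, and aliased design
columns are errors — aliasing is never silently repaired. Fixing
$\tau = 0$ reproduces weighted least squares exactly and is the
fixed-effect limit.

## Credible intervals and heterogeneity

Intervals are $\hat\beta_k \pm t_{N-p,\,0.975}\,\mathrm{SE}_k$ at the 95%
level — the "95% point" of the $t$ distribution is read as the two-sided
point (0.975 quantile), the interpretation that reproduces a printed
interval of the form $0.296 \pm 0.065$ at $N - p = 183$. The heterogeneity
summary is

$$I^2 = 100\,\frac{\tau^2}{\tau^2 + \tilde s^2}, \qquad
  \tilde s^2 = \frac{(N-1)\sum w_i}{(\sum w_i)^2 - \sum w_i^2},
  \quad w_i = 1/v_i,$$

the Higgins–Thompson "typical" within-study variance. Because the posterior
of $\tau$ is available on the grid, the fit reports both
$\mathrm{Var}(\tau)$ and $\mathrm{Var}(\tau^2)$ — published "variance of
$\tau$" figures are ambiguous between the two.

## Publication-bias diagnostics

The funnel is residual-based: residuals $y_i - x_i'\hat\beta$ against
precision $1/\sqrt{v_i}$.

**Trim-and-fill** uses the $L_0$ estimator on values centered at the pooled
estimate: with $T$ the sum of absolute-value ranks of the positive centered
values, $L_0 = (4T - n(n+1))/(2n-1)$ and $k_0 = \max(0,
\mathrm{round}(L_0))$; trim the $k_0$ most extreme, re-center on the trimmed
set, re-rank the full set, iterate to stability (cap 20), then mirror the
$k_0$ extremes about the final center and refit. $L_0$ (not $R_0$) is the
common default and the source analysis names neither. In pipeline mode the
center is the hierarchical intercept, so the centered values are exactly the
model residuals; a classical inverse-variance "raw" mode exists for
textbook cross-checks. On an exactly symmetric funnel the rank sum ties out
and $k_0 = 0$ deterministically; on *stochastically* symmetric data $k_0$
is a rounded random variable and can exceed 0 by chance — tests therefore
use mirrored pairs when asserting $k_0 = 0$.

**Cumulative meta-analysis** refits the full hierarchical intercept-only
model on every prefix of the data ordered by increasing sampling variance
(or publication year), ties broken by publication then observation id. The
trace minimum is the most conservative pooled estimate under the assumption
that late-added studies carry the bias. The final trace entry equals the
full-data fit to numerical precision (not bitwise: summation order differs
between sorted and input order).

**Slope tests** regress $y$ on sampling variance (small-study trend) and on
publication year (temporal stability) with the same hierarchical engine.

Inside trim iterations and cumulative prefixes, $\phi$ is held at the
full-data profiled estimate rather than re-profiled: profiling on a short
prefix is unstable and multiplies cost by the $\phi$-grid size. One-off
fits (grand mean, subgroups, slope tests) profile $\phi$.

## Landscape metrics

Maps are planar categorical rasters (habitat labels from {field, pasture,
forest, wetland, water, rural, urban, line_element}) with an arable
parcel-id layer; no geodesy — synthetic maps stand in for digitized
imagery, whose manual classification is out of scope. A study region is a
centre plus radius in metres. Each of $k = 5$ transects is placed by three
random numbers: distance $d \sim U[0, r]$, bearing $\sim U[0, 360)$ fixing
the start point, and an orientation from $\{0, 45, 90, 180\}$ degrees along
which the transect spans 500 m to each side. Transects may not cross
(shared endpoints count as crossing — the conservative reading); crossing
draws are rejected and redrawn up to a cap. Start points lie inside the
region; ends may overhang it, which the source procedure leaves
unspecified. The orientation set is kept verbatim even though 0 and 180
define the same line through a point.

Metrics per transect: the line is discretized at 1-m midpoints (1000
points, each standing for 1 m, so per-habitat segment lengths sum to
exactly 1000 m); `pct_arable` is the percent of points on field cells;
`n_habitats` the count of distinct labels touched; `avg_field_size` the
mean area of the distinct arable parcels intersected (transect-intersected,
not region-wide — the source is silent; region-wide is a trivial variant).
Exactness is unnecessary here, determinism is; the 1-m step is
configurable. Region metrics are arithmetic means over the five transects.
Records whose landscape triple is wholly missing receive country means of
complete records; partial triples are rejected at intake.

## The synthetic-data generator

The generator emulates the structure of the published literature — its
defaults are the stated world, chosen once and not revisited:

| parameter | default | basis |
|---|---|---|
| publications | 94 | published corpus size |
| observations/publication | categorical on 1..6, mean ≈ 1.96 | 184/94 |
| grand mean $\beta_0$ | 0.3 | published scale (0.296) |
| $\tau$ | 0.3 | published scale (0.304) |
| $\phi$ | 0.5 | dependence reported positive; magnitude unpublished |
| arm replicate counts | discrete uniform 2..30 | inclusion rule $n>1$; field-study scale |
| conventional mean richness | log-normal, median 15, sdlog 0.5 | typical per-unit richness counts |
| within-arm CV | 0.4 | gives adequacy scores mostly above 3, as published |
| covariate level frequencies | Fig.-1-style counts (e.g. producers 62, predators 49, pollinators 21; cereals 100, mixed 40) | published breakdown |

True effects are $\theta_{ij} = x_{ij}'\beta + b_j + w_{ij}$ with
$b_j \sim N(0, \phi\tau^2)$ shared within a publication and
$w_{ij} \sim N(0, (1-\phi)\tau^2)$. Arm summaries are *sample statistics*
of $n$ log-normal replicate draws at the target mean and CV, so sampling
variance arises organically and the analytic $v$ formula can be checked
against the empirical variance of generated effects (law of total
variance). Log-normal replicates (not Poisson counts) keep the SD
controlled by the CV independently of the mean, matching inputs that are
reported summaries rather than raw counts. Censoring
(`inject_small_study_bias()`) drops negative effects with above-median
sampling variance, the mechanism the funnel-plot diagnostics assume.

What the generator does **not** emulate: correlated covariates (taxon,
crop and scale are drawn independently), literature-search artefacts,
digitization error, non-normal true-effect distributions, and any real
spatial structure linking the landscape covariates to effect sizes unless a
slope is configured. A green parameter-recovery or coverage test therefore
establishes internal consistency of model + generator at the published
scale, not fidelity to the archived data; reproducing the archived
estimates requires the archive itself (see README).

## Numerical conventions collected

* Grid: 201 $\tau$ nodes, trapezoidal weights, upper bound
  $10\sqrt{\tilde s^2}$; $\phi$ grid step 0.05; first maximum wins ties.
* Rounding only at the presentation layer (`percent_change()` is exact).
* Adequacy thresholds: boundary counts as "not below".
* $k_0$: `round()` of $L_0$, floored at 0.
* Determinism: every stochastic entry point takes a seed; identical seed
  and configuration reproduce reports bitwise.
* Cumulative final step vs full fit: equal to $10^{-12}$, not bitwise
  (summation order).

## Known limitations

* The original analysis's exact prior and dependence estimator are
  unpublished; agreement with its printed estimates beyond ~2 significant
  figures is a tolerance target, not a guarantee.
* The evidence-profiled $\phi$ is a point estimate; $\phi$ uncertainty is
  not propagated into coefficient posteriors.
* Trim-and-fill assumes the skew it corrects is caused by suppression of
  small negative studies; on genuinely asymmetric ecological responses the
  "adjusted" estimate is a sensitivity bound, not a corrected truth.
  Under strong heterogeneity ($I^2$ far above 50%) the rank-based $k_0$ is
  also known to over-impute on unbiased data — seeded runs of the unbiased
  generator can show sizeable $k_0$ — which is why the package's symmetric
  null check uses exactly mirrored pairs.
* Landscape sampling is bufferless-line only; no polygon buffers, no
  geographic projections, no real-map ingestion.
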