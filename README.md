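# agrimeta

Hierarchical meta-analysis of organic vs. conventional farming effects on
species richness, for ecologists and meta-analysts synthesizing paired
farm-comparison studies. The package turns a table of per-observation
arm summaries (mean richness, SD, replicate count in each farming system,
plus taxonomic/functional/crop/scale covariates and three land-use-intensity
metrics) into a fully reproducible analysis: effect sizes, a dependence-aware
hierarchical pooled estimate, heterogeneity, publication-bias diagnostics,
and plot-ready tables.

## The model

The effect size for each observation is the log response ratio

```
y = ln(mean_org) - ln(mean_conv)
v = sd_org^2 / (n_org * mean_org^2) + sd_conv^2 / (n_conv * mean_conv^2)
```

(`y > 0` means the organic arm is richer; `100 (e^y - 1)` is the percent
difference). Effect sizes are pooled with a hierarchical Bayes linear
meta-regression

```
y_i = x_i' beta + delta_i + eps_i,   eps ~ N(0, diag(v)),
delta ~ N(0, tau^2 M(phi))
```

where `M(phi)` is block-diagonal by publication (unit diagonal, `phi`
off-diagonal within a publication), so multiple observations extracted from
one publication share a publication-level random deviation instead of being
treated as independent. The prior on `beta` is flat and on `tau` DuMouchel
log-logistic; `tau` is integrated on a deterministic 201-node grid and
`phi` chosen by marginal evidence on `{0, 0.05, ..., 0.95}`. Credible
intervals are `beta_hat +/- t_{N-p, 0.975} * SE`; heterogeneity is reported
as `tau^2` and Higgins-Thompson `I^2`. Bias diagnostics: residual funnel
data, L0 trim-and-fill, cumulative meta-analysis ordered by sampling
variance and by publication year, and slope tests of effect size on both.
A randomized five-transect sampler computes `% arable fields`, `number of
habitats` and `average field size` on categorical land-cover rasters, and a
ground-truth generator simulates whole study tables (94 publications, ~184
observations by default) for validation. See
`vignettes/agrimeta-methods.Rmd` for the full account.

## Worked example

```r
library(agrimeta)

sim <- simulate_meta_dataset(sim_config(seed = 2026))
f <- tempfile(fileext = ".csv")
write_study_table(sim$records, f)
report <- run_full_analysis(f, seed = 2026)
print(report)
```

Output from this exact run:

```
[read] 181 accepted, 0 rejected
[effect_sizes] 181 effect sizes; 3% of minima below 3
[grand_mean] estimate 0.345 (0.284-0.406), phi = 0.45
[subgroups] 4 covariates fitted
[landscape_slopes] pct_arable slope 0.193 (0.193 after removing 0)
[heterogeneity] tau = 0.302, I2 = 82.3%
[bias] k0 = 33; cumulative minimum 0.288; slopes v 0.065, year -0.0007
grand mean log RR 0.345 (95% CI 0.284-0.406); richness +41%
tau = 0.302, I2 = 82.3%; trim-and-fill k0 = 33 (adj 0.1871)
cumulative minimum (by variance): 0.288 at step 23 of 181
```

Reading it: the pooled log response ratio 0.345 (CI 0.284-0.406) says
organic farms in this synthetic literature hold about 41% more species;
the generator's truth was 0.3 with `tau = 0.3`, and the fit recovers
`tau = 0.302` with a positive publication-level dependence (`phi = 0.45`
against a true 0.5). `I^2 = 82%` says most variation among effect sizes is
real heterogeneity, not sampling noise. The bias block is a caution tale:
this dataset is unbiased by construction, yet rank-based trim-and-fill
imputes `k0 = 33` studies under such strong heterogeneity — the diagnostics
are sensitivity analyses, not truth-finders (see the vignette's
limitations). With `out_dir =` the same call writes `report.json`, funnel,
cumulative-trace, subgroup-coefficient and effect-size CSVs.

A command-line wrapper ships in `inst/cli/agrimeta.R`:

```sh
Rscript inst/cli/agrimeta.R simulate --out sim/ --seed 7
Rscript inst/cli/agrimeta.R analyze sim/study_table.csv --out out/ --seed 7
```

with YAML configuration as in `inst/extdata/default_config.yaml`.

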