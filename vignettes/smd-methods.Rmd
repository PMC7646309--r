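---
title: "Standardized mean differences for paired designs: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized mean differences for paired designs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdpair)
```

## The problem

Repeated-measures studies report a mean change $\bar\delta$ from pre- to
post-intervention, and often standardize it so that results measured on
different scales can be compared or meta-analyzed. But "the" standardized
mean difference (SMD) is not one statistic: dividing the same mean change by
different standard deviations yields estimators with different meanings and
different sampling behaviour. smdpair implements the two families and the
machinery needed to use them honestly: bias correction, sampling variances,
confidence intervals, probability conversions, and a simulator for studying
the estimators themselves.

## The estimators

**Signal-to-noise.** Cohen's $d_z = \bar\delta / \sigma_\delta$, where
$\sigma_\delta$ is the SD of the change scores $\delta_i = y_i - x_i$. It
measures how *consistent* the change is, not how large: it is tied to the
paired $t$-statistic by $d_z = t/\sqrt{n}$ (`dz_from_t()`), and for this
reason carries no information beyond $t$ and its degrees of freedom. Its
natural interpretive companion is the common language effect size
$\mathrm{CLES} = \Phi(d_z)$ — the probability that a randomly selected
individual's change score is positive — with inverse
$d_z = \Phi^{-1}(\mathrm{CLES})$.

**Magnitude-based.** Glass's $\Delta_{pre} = \bar\delta / \sigma_{pre}$,
Cohen's $d_{av} = \bar\delta / \tfrac12(\sigma_{pre}+\sigma_{post})$ and
Cohen's $d_{rm} = (\bar\delta/\sigma_\delta)\sqrt{2(1-r)}$ standardize by a
between-subject spread, so they measure the *size* of the expected change in
sample-SD units. Under equal pre/post variances,
$\sigma_\delta = \sqrt{2\sigma^2(1-r)}$ and all three coincide for any
$-1 \le r < 1$ — an identity the test suite asserts to $10^{-12}$. Their
interpretive device is the percentile shift: a median individual improving
by the expected change moves to percentile $100\,\Phi(\Delta)$
(`percentile_shift()`; $\Delta = 0.5$ gives the 69th percentile). For the
pretest–posttest–control design, $\Delta_{ppc} = \Delta_T - \Delta_C$.

The exact formulas adopted for $d_{av}$ and $d_{rm}$ follow the common
convention in the methodological literature; we chose them because both
reduce exactly to $\Delta_{pre}$ under equal variances, which is the defining
constraint for the family.

## Bias and its correction

Uncorrected SMDs are biased upward in small samples: the estimate has
expectation $d/c(m)$, where $c(m) = 1 - 3/(4m - 1)$ and $m$ is the design's
degrees of freedom — $m = n-1$ for a paired sample, $m = n_1+n_2-2$ for two
groups with a pooled SD. Multiplying by $c(m)$ (Hedges' correction,
`hedges_g()`) removes the bias: about 10% at $n=10$ pairs and 5% at $n=15$.
The printed approximation is the default because it is what is reported and
reproduced in practice; the exact gamma-ratio factor
$c(m) = \Gamma(m/2)/(\sqrt{m/2}\,\Gamma((m-1)/2))$ is available via
`exact = TRUE` and differs by under 0.2% for $m \ge 9$. Whichever variant is
selected is used consistently for both the point correction and the
$c(m)^2$ variance scaling.

## Sampling variances and intervals

For bivariate-normal data the two best-understood paired SMDs have
closed-form variances, both functions of the (uncorrected) estimate itself:

$$\mathrm{Var}[d_z] = \frac{n-1}{n(n-3)}\,(1 + d_z^2 n) -
  \frac{d_z^2}{c(n-1)^2}, \qquad
  \mathrm{Var}[\Delta_{pre}] = \frac{n-1}{n(n-3)}\,(2(1-r) +
  \Delta_{pre}^2 n) - \frac{\Delta_{pre}^2}{c(n-1)^2}.$$

They coincide when $r = 0.5$ and the estimates are equal. $\Delta_{pre}$'s
variance *decreases* as $r \to 1$ (homogeneous change is measured more
precisely) whereas $d_z$'s variance explodes — one of the central practical
differences between the families. Corrected-estimator variances are obtained
by multiplying by $c(n-1)^2$, which always shrinks them. Both formulas are
validated empirically in the test suite against $10^5$-replicate Monte Carlo
at $n = 20$, within three Monte-Carlo standard errors.

`wald_ci()` builds symmetric normal-quantile intervals from these variances.
A noncentral-$t$ inversion is deliberately not implemented: for small
samples the package's recommended interval is the subject-level bootstrap
(`bootstrap_ci()`), which resamples complete pairs — never pre and post
independently, which would destroy the within-pair correlation — and offers
percentile (default) and BCa constructions. Defaults: 2000 replicates and a
mandatory-for-reproducibility user-visible seed recorded in every report.
Replicates on which the estimator is undefined (zero spread after
resampling) are dropped and counted; more than 10% of them aborts with a
typed error, because at that point the resampling distribution no longer
describes the estimator. The BCa bias-correction constant is clamped to
$(\tfrac{1}{B+1}, \tfrac{B}{B+1})$ so a point estimate outside the
resampled range cannot produce an infinite adjustment.

## The synthetic-data generator and the simulator

`generate_paired()` draws $(x, y)$ from a bivariate normal with means
$\mu_{pre}$ and $\mu_{pre} + \bar\delta$, the stated SDs, and correlation
$r$, via the Cholesky construction $y = \mu + \sigma_{post}(r z_1 +
\sqrt{1-r^2}\,z_2)$. Lognormal mode applies the same machinery on the log
scale and exponentiates — a reasonable model for perception-type outcomes
(e.g. soreness ratings), which are multiplicative; in that mode the
generator parameters are log-scale parameters. The generator emulates the
idealized sampling model under which the bias and variance formulas are
exact. It does not emulate measurement floors/ceilings, heteroscedastic
change, non-normal tails, or dropout — so passing tests demonstrate
correctness of the estimator machinery under the model, not robustness of
the estimators to real-world violations of it.

`sim_sweep()` runs the estimator-property study: a grid over pre-post
correlation and pre-intervention SD, by default $r \in \{-0.5, -0.25, 0,
0.25, 0.5, 0.75, 0.9, 0.95\}$ and $\sigma_{pre} \in \{0.25, 0.5, 1, 2,
3\}$ with $n = 20$ pairs, $\bar\delta = 1$ and 1000 replicates per cell.
The grid spans both blow-up regimes — $d_z$ as $r \to 1$, every SMD as
$\sigma_{pre} \to 0$ — and the replicate count keeps per-cell Monte-Carlo
error near 2% while the full sweep runs in seconds. The qualitative surface
it reproduces: magnitude-based means vary only with $\sigma_{pre}$
(invariant to $r$), $d_z$ means increase with $r$; $\Delta_{pre}$'s
standard error is non-increasing in $r$ while $d_z$'s grows. Since
empirical and formula-based standard errors are both legitimate summaries,
`sim_sweep()` emits both side by side and `plot_sweep(..., metric = "se")`
overlays them.

Reproducibility uses a master-seed/substream scheme: the master seed
generates one sub-seed per grid cell up front, and each cell's replicates
are drawn under its own sub-seed. Cell results are therefore identical
regardless of execution order, and any single cell can be re-run in
isolation.

```{r}
res <- sim_sweep(sim_config(sd_pre_grid = c(0.5, 1, 2),
                            r_grid = c(0, 0.5, 0.9),
                            replicates = 300, seed = 7))
dplyr::filter(res, family %in% c("dz", "delta_pre"), !corrected, sd_pre == 1)
```

## Reporting

`smd_analyze()` assembles a report bundle: estimates with intervals, the
paired $t$ (df $= n-1$, two-sided $p$), the raw-unit mean change with its
CI, the CLES, and a deterministic narrative paragraph. Conventions, chosen
to match how results paragraphs are actually written:

* statistics to 2 decimals; $p$ as `p < .001` below 0.001, else 3 decimals;
  CLES as an integer percent; percentiles rounded half-away-from-zero with
  an ordinal suffix ("69th").
* the CLES is computed from the *uncorrected* $d_z$ by default — it
  describes the observed signal-to-noise, and this is the convention under
  which a printed $t = 3.54$ with 8 pairs yields 89% — with the corrected
  variant behind `corrected_cles = TRUE`. For a negative mean change the
  sentence describes a *reduction* and uses $\Phi(|d_z|)$.
* the default estimator set is $\Delta_{pre}$ plus the CLES (the
  magnitude-based lean); $d_z$ is available but is redundant with the
  $t$-statistic.
* no qualitative labels ("small/medium/large") are ever emitted; the
  percentile-shift sentence takes their place. Default benchmark scales
  ignore the outcome and population, and the package deliberately refuses
  to institutionalize them.
* SMDs are never computed from percent-change scores: such an SMD is a
  different quantity, the raw-unit SMD cannot be recovered from it, and
  both the API (`percent_change = TRUE`) and the CLI (`--percent-change`)
  refuse with an explanation.

When raw data are available, summary statistics are always recomputed from
the change scores; the equal-variance identity
$\sigma_\delta = \sqrt{2\sigma^2(1-r)}$ is used only to fill gaps in
printed summary statistics, because it is an assumption, not an identity,
in real data. Cross-checks among redundant printed inputs use a 5% relative
tolerance — wide enough to absorb published rounding (a mean change printed
as 0.23 against means printed as 4.13 and 3.89) — and inconsistencies warn
but never overwrite a supplied value.

## Numerical and degenerate-input policy

Zero-spread denominators ($\sigma_\delta = 0$ or $\sigma_{pre} = 0$) raise
typed errors rather than returning infinities: the estimators genuinely
blow up there, and a library should fail loudly rather than propagate
$\pm\infty$ into downstream arithmetic. $r = 1$ is permitted where the
estimator remains defined (e.g. $d_{av}$) but rejected where it forces
$\sigma_\delta = 0$ ($d_z$, $d_{rm}$ with equal SDs); generation requires
$|r| < 1$ strictly. Sample SDs use the $n-1$ denominator everywhere, which
is what makes the $d_z = t/\sqrt{n}$ round-trip exact to $10^{-10}$.
Variance formulas require $n \ge 4$ ($n-3$ denominator) and raise a
`formula_undefined` error below that.

## Validation problem sizes

The test suite validates the bias law at $n = 10$ with $2\times10^5$
simulated studies (ratio within 3 MC SEs of $1/c(9) = 1.09375$), the
variance formulas at $n = 20$ with $10^5$ studies per setting, the sweep
surface on the full default grid, and 95% percentile-bootstrap coverage for
$\Delta_{pre}$ at $n = 40$, true value 0.5, over 2000 simulated studies
with 500 replicates each (coverage within $0.95 \pm 0.02$). The coverage
study generator uses $r = 0.5$, the neutral point at which the change-score
SD equals the baseline SD. These sizes keep Monte-Carlo error well below
the assertion tolerances while the whole suite runs in well under a minute.

## Known limitations

* Closed-form variances (and hence Wald intervals) exist only for $d_z$ and
  $\Delta_{pre}$; $d_{av}$ and $d_{rm}$ get bootstrap intervals only.
* The bias and variance theory assumes bivariate normality; under the
  lognormal generator the closed forms are approximations.
* $\Delta_{ppc}$ is the simple treatment-minus-control contrast; pooled-SD
  and covariate-adjusted variants for parallel-group designs are out of
  scope, as are power analysis, shrinkage estimators, and meta-analytic
  pooling (the outputs are meta-analysis-ready; the pooling belongs
  elsewhere).
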