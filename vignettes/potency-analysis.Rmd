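---
title: "Power-law potency analysis of plate-based cytotoxicity screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Power-law potency analysis of plate-based cytotoxicity screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanopotency)
```

## The problem

In vitro screening of (nano)particle cytotoxicity typically exposes cells
to a dose series of each particle and reads out several complementary
endpoints on 96-well plates: cellular ATP (energy metabolism, luminescence),
resazurin reduction (CTB, viability, fluorescence) and LDH released into the
supernatant (membrane integrity, absorbance). Raw instrument signals are not
comparable across plates, endpoints or days, and particles themselves can
interfere optically with the readouts. The question the analyst needs
answered is simple: *which particles are most potent, and which of their
physicochemical properties explain that potency?*

`nanopotency` implements that workflow end to end: normalization to fold
effects, one-parameter power-law potency estimation, consensus ranking
across endpoints, descriptor association, treatment/dose inference,
oxidative-stress and secreted-protein panel analysis, and a synthetic-data
generator that emulates the whole design with known ground truth.

## Normalization model

Within each independent experiment, and separately per cell type and
endpoint (different assay chemistries have unrelated signal scales), every
well is divided by the grand mean of all zero-dose control wells:

$$\mathrm{FE}_{ij} = \frac{y_{ij}}{\overline{y}_{0}}$$

so the fold effect (FE) is dimensionless, equals 1 on average for controls,
and is invariant to rescaling a whole experiment. When matched "no-cells"
interference wells (particle suspension without cells) are present, their
mean is subtracted first, floored at zero with a warning. Fold effects that
end up nonpositive are clipped to `1e-6` with a warning, so the log-domain
estimator below stays defined; in practice clipping only triggers when
interference exceeds the biological signal.

LDH release is additionally expressed as a percentage of the total LDH
content of lysed untreated wells (`pct_ldh()`), the conventional
cytolysis scale.

## Potency model

Dose-response is summarized by the one-parameter power law

$$\mathrm{FE} = (\mathrm{Dose} + 1)^{\beta}$$

with dose in ug/cm^2. The `+1` makes the zero-dose point informative and
finite (FE = 1 exactly), and $\beta$ is interpretable as the rate of change
of log fold effect with log shifted dose. Endpoints that fall with
cytotoxicity (ATP, CTB) give $\beta < 0$; LDH release gives $\beta > 0$.
Two estimators are provided:

* **`nls`** (default): least squares in FE space,
  $\min_\beta \sum_i (\mathrm{FE}_i - (d_i + 1)^\beta)^2$, solved by
  bounded one-dimensional minimization over $[-5, 5]$ (tolerance 1e-10)
  followed by a root solve of the analytic gradient. The problem has one
  smooth parameter, so no multistart is needed; the bracket comfortably
  contains every exponent a cytotoxicity screen produces (the case study
  spans 0.001-1.6 in magnitude).
* **`loglinear`**: the closed-form through-origin slope of
  $\log \mathrm{FE}$ on $\log(d + 1)$. It is the exact solution under
  multiplicative log-normal noise and serves as an independent cross-check;
  on noise-free power-law data the two agree to better than 1e-9.

FE-space least squares is the default because generic curve fitters used
with this model historically operate on untransformed fold effects; both
residual scales are exposed so the choice is explicit.

Before fitting, duplicate wells are averaged within each experiment and
dose; the per-(experiment, dose) means of all experiments are then pooled
and weighted equally. The number of independent experiments (3 in the
emulated design) is the replication unit.

## Consensus potency and ranking

Per particle and cell type, the consensus average potency is

$$\beta_{avg} = \tfrac{1}{3}\left(|\beta_{ATP}| + |\beta_{LDH}| +
|\beta_{CTB}|\right)$$

and particles are ranked within a cell type by $\beta_{avg}$ (rank 1 = most
potent). Ranking always uses full-precision values: in the bundled ZnO case
study two A549 particles tie at three displayed decimals (0.096) but differ
at full precision (0.09633 vs 0.09600), and the published rank order is
reproduced only by the unrounded comparison. Exact ties are broken
lexicographically by particle label, with a notice, so output is
deterministic.

## Descriptor association

Physicochemical determinants of potency are screened two ways:

* `pearson_r()` / `pairwise_associations()`: product-moment correlation of
  each descriptor with the *signed* exponent, with per-pair listwise
  deletion of missing descriptors (e.g. DLS size is unmeasurable for a
  silicone-oil coating) and the effective n reported. The signed convention
  matters: published potency tables print $|\beta|$, but correlations of
  descriptors with toxicity are only coherent on the signed scale, so
  `signed_beta()` restores the endpoint direction
  (ATP, CTB decreasing; LDH increasing).
* `backward_stepwise()`: OLS with intercept on internally standardized
  predictors, iteratively removing the largest p-value above
  `alpha_remove` (default 0.10, the common stepwise screening default;
  configurable). With fewer than p + 2 rows the fit is refused - with only
  three uncoated nanoforms, for example, any multivariable model is
  degenerate and pairwise correlation is the honest summary. Collinear
  designs error with the aliased predictors named rather than silently
  dropping them.

The bundled descriptor table records two derived elemental quantities:
`total_metals_ppm` (sum over the full elemental panel, Zn included - Zn is
the dominant constituent and drives the total) and `transition_metals_ppm`
(sum of the contaminant transition-metal elements, Zn excluded, since the
bulk constituent would swamp the contaminant signal by six orders of
magnitude).

## Treatment/dose inference

`two_way_anova()` runs the classical fixed-effects decomposition with
treatment and dose as crossed factors on balanced designs only; unbalanced
tables are rejected explicitly rather than silently picking a
sums-of-squares type. With `transform = "auto"` a Shapiro-Wilk test of the
raw-scale residuals at $\alpha = 0.05$ decides whether the rank transform
is applied - the standard fallback when fold effects violate normality or
variance homogeneity. A response with no variance at all returns F = 0 for
every term (both numerator and denominator sums of squares are exactly
zero).

`holm_sidak()` implements the step-down Sidak adjustment: sort the m raw
p-values ascending, adjust the i-th as $1 - (1 - p_{(i)})^{m - i + 1}$,
enforce monotonicity with a running maximum, cap at 1. It is uniformly no
larger than Bonferroni-Holm. The default contrast family in
`adjusted_comparisons()` is every treatment against control
(all-pairs optional), the family a dose-response screen actually reports.

## Oxidative stress and secretome

`gsh_gssg_fc()` expresses the reduced/oxidized glutathione ratio of a
treated group as a fold change of the control ratio; values below 1 mean
oxidation of the glutathione pool. `stress_analysis()` wraps the ratio
computation, a one-way ANOVA across treatments and Holm-Sidak adjusted
contrasts against control.

Secreted-protein panels are analyzed as fold changes versus control.
`filter_responders()` keeps proteins at or beyond the cutoff (default 1.5)
in either direction - $\mathrm{FC} \ge c$ or $\mathrm{FC} \le 1/c$,
boundaries inclusive - in at least one treatment. `hierarchical_cluster()`
log2-transforms the matrix and clusters rows and columns agglomeratively;
the default Pearson correlation distance ($1 - r$) with average linkage is
the common choice for expression-style heatmaps, and both choices are
fixed and recorded so output is deterministic given input order (ties in
`stats::hclust` resolve by original index). Constant rows have no defined
correlation and error with the offending row named. Euclidean distance and
complete linkage are available.

## Synthetic data: what it emulates, and what it does not

`simulate_assay()` inverts the potency model generatively: each cells-well
signal is

$$y = L_e \cdot (d + 1)^{\beta_{true}} \cdot e^{\varepsilon},
\qquad \varepsilon \sim N(0, \sigma^2)$$

with a per-experiment control level $L_e$ (between-experiment CV 0.1
around 5e4 arbitrary units), multiplicative log-normal well noise
($\sigma = 0.1$ by default, a typical plate-assay CV - signals are
positive and their spread is roughly scale-proportional), a
dose-proportional interference baseline added to both the cells wells and
the emitted `no_cells` wells (2% of the control signal at the top dose),
and lysed-control wells at 5 times the control LDH signal. The default
design is the emulated study: 8 particles x 2 cell types x 3 endpoints,
dose grid {0, 5, 10, 20, 40, 80, 100} ug/cm^2 (the source design states
only a 0-100 span; a 7-point grid is this package's fixed choice), 3
experiments x duplicate wells, and true exponents taken from the bundled
case-study potency table so the simulated screen has a realistic potency
spread. All generators are pure functions of (config, seed) and restore
the caller's RNG state.

What the generator does *not* emulate: particle dissolution and Zn ion
release kinetics, saturating or non-monotone dose-response shapes,
plate-position and edge effects, heteroscedasticity beyond the log-normal
model, and correlated noise between endpoints measured on the same wells.
Passing recovery tests therefore demonstrate that the estimator chain is
correct and well calibrated *under the stated noise model*, not that the
power law is an adequate description of any particular real screen.

`simulate_descriptors()` couples each descriptor column to the true signed
exponent with a chosen population correlation
($y = r z_\beta + \sqrt{1 - r^2}\,\varepsilon$); `simulate_stress()`
applies per-treatment suppression factors to the control GSH/GSSG ratio;
`simulate_proteins()` builds block-structured panels where treatment
columns within a block share a latent log2 profile (within-block
correlation $\sigma_p^2 / (\sigma_p^2 + \sigma_n^2)$, about 0.95 by
default) and designated responder proteins carry specified fold changes.

## Numerical and design choices

* Dose 0 is required in every fit; the model makes it informative rather
  than discarding it.
* Reported exponents are kept at full precision everywhere; rounding to 3
  decimals happens only in display layers. This is what resolves the
  near-tie in the case-study ranking.
* The Monte-Carlo suite sizes are fixed in the tests: 1000 replicates for
  exponent recovery per true value, 1000 null simulations for the one-way
  type-I calibration (expected 0.05 +/- 0.02), 100 seeded panels for the
  block-clustering rate. The acceptance script uses 500 recovery
  replicates per exponent, which bounds its Monte-Carlo error on the mean
  at about 0.002.
* Degenerate inputs fail loudly with the offending group named: missing
  zero-dose controls, nonpositive control means, all-identical doses,
  unbalanced ANOVA tables, constant rows under correlation distance,
  underdetermined or collinear regressions.
* The pipeline entry point is the exported function surface
  (`run_pipeline()`, `validate_inputs()`) rather than a shell executable:
  the package is an analysis library, and R users drive it from scripts;
  `scripts/acceptance.R` in the repository shows exactly that usage.

## Known limitations

* The power law cannot represent non-monotone dose-response (e.g. hormesis)
  or plateaus; a systematic lack of fit shows up in `rss` but no
  alternative family is provided by design.
* Published-table workflows (re-entering rounded absolute exponents)
  reproduce consensus values, ranks and the signed-convention correlations,
  but not quantities that depend on unpublished raw well data (exact ANOVA
  p-values, per-dose error bars). One published correlation (BET surface
  area vs the A549 ATP exponent, r = -0.875) recomputes to -0.871 from
  3-decimal rounded exponents; the gap is rounding of unpublished raw
  values and the package does not assert it.
* `backward_stepwise` inherits the known inferential caveats of stepwise
  selection (post-selection p-values are optimistic); it is provided as the
  field's screening convention, not as a confirmatory procedure.
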