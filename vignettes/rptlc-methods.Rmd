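---
title: "Chromatographic lipophilicity descriptors: models, assumptions and design choices"
author: "rptlc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromatographic lipophilicity descriptors: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rptlc)
```

## The problem

Lipophilicity — classically quantified as logP, the base-10 logarithm of a
compound's n-octanol/water partition coefficient — governs membrane
permeation and is central to ADMET profiling in drug discovery. The
shake-flask measurement of logP is slow and irreproducible for many drug-like
compounds, so reversed-phase thin-layer chromatography (RP-TLC) is widely
used as a surrogate: a compound's retention on a C18 layer developed with an
aqueous-organic mobile phase reflects its partitioning between a nonpolar
stationary phase and a polar eluent.

`rptlc` implements the full analysis chain from raw retardation factors to
the three chromatographic descriptors in common use, their comparison with
computed and experimental logP scales, and similarity clustering of
descriptor profiles. The bundled data cover fifteen drugs in three classes
(four antiparasitic nitroimidazoles, four dihydropyridine antihypertensives,
seven NSAIDs) chromatographed with methanol-water and acetone-water eluents.

## Retention models

**The R_M transform.** A spot's retardation factor $R_F \in (0,1)$ is the
migration distance relative to the solvent front. The working quantity is

$$R_M = \log_{10}\!\left(\frac{1}{R_F} - 1\right),$$

the planar analogue of a log retention factor. It is undefined at
$R_F \in \{0, 1\}$; `rf_to_rm()` rejects such values, and
`aggregate_replicates()` drops endpoint measurements with a warning rather
than clamping them, because silent clamping would bias the extrapolations
that follow.

**Soczewiński–Wachtmeister extrapolation.** For well-behaved reversed-phase
systems $R_M$ is linear in the organic-modifier volume fraction $\varphi$:

$$R_M = R_{MW} - S\varphi.$$

`fit_sw()` estimates this line by ordinary least squares. The intercept
$R_{MW}$ — retention extrapolated to pure water — is the principal
lipophilicity descriptor; the slope magnitude $S$ measures solvent-strength
sensitivity and must be positive for reversed-phase data (a non-positive
fitted slope is returned but flagged with a warning). Their ratio

$$\varphi_0 = R_{MW}/S$$

is the isocratic hydrophobicity index: the modifier fraction at which the
analyte migrates exactly half of the development distance. At least three
distinct compositions are required for a fit; the bundled designs use nine
or ten.

**Ościk excess-retention model.** The second extrapolation treats the mixed
eluent on the *mole-fraction* scale $x$ and decomposes retention into an
ideal blend of the pure-solvent retentions plus an excess term whose
normalised form $G(x) = a x + b$ is linear in $x$:

$$R_M = x\,R_{M,org} + (1-x)\,R_{MWO} + x(1-x)(a x + b).$$

With the pure-organic retention $R_{M,org}$ held at its measured value
($\varphi = 1$), the model is linear in $(R_{MWO}, a, b)$ and `fit_oscik()`
estimates it by least squares on that rearranged form. This is the standard
additive formulation of the excess-retention approach; the published
accounts cite the methodology without a complete set of equations, and the
compact typeset form is ambiguous about where $R_{MWO}$ enters, so the
package fixes the rearranged model above as its definition. It requires at
least four interior compositions plus the pure-organic point.

**Mole-fraction conversion.** The literature states compositions as volume
fractions; the excess model needs mole fractions. `volume_to_mole_fraction()`
assumes ideal (additive-volume) mixing with constants fixed in one auditable
block (`solvent_constants()`): water M = 18.015 g/mol, ρ = 0.9978 g/mL;
methanol M = 32.04, ρ = 0.7914; acetone M = 58.08, ρ = 0.7845 — densities at
roughly 22 °C, the development temperature of the bundled designs. Excess
molar volumes of these mixtures are at most a few percent and are neglected;
this choice is documented rather than hidden because the conversion affects
the Ościk coefficients (though not $R_{MWO}$ at the endpoints).

**Degenerate Ościk fits.** Some eluent systems are chemically unsuitable for
the extrapolation — in the bundled tables the acetone-water system yields no
$R_{MWO}$ for any NSAID. `fit_oscik()` therefore carries a validity flag:
a fit is invalid when its coefficient of determination falls below 0.5, any
coefficient is non-finite, or $|R_{MWO}| > 15$ (an extrapolation far outside
the physically observed range, which ends near 7). Invalid fits propagate as
missing values in `fit_all()` output, never as numbers. The thresholds are
tunable via `oscik_validity()`.

## Replicate aggregation

Chromatograms are spotted in triplicate. The default aggregates replicates
on the measured scale — mean $R_F$ per composition, then transform — because
$R_F$ is the quantity with (approximately) symmetric measurement error;
`aggregate = "rm"` switches to averaging transformed values, matching the
alternative reading of the protocol. For triplicate noise at the levels seen
here the two differ by far less than the reported precision.

## Cross-scale regression

`ols_fit()` performs simple linear regression with classical inference
(coefficient standard errors, Pearson r, residual standard error s, the
slope F-test on (1, n−2) df), dropping incomplete pairs listwise. On the
bundled tables, regressing the computed scales and the experimental logP
mean on $\varphi_0$(acetone) reproduces the published coefficient sets
exactly at printed precision:

```{r regressions}
tab <- assemble_descriptor_table()
ols_fit(tab$phi0_a, tab$xlogp3,   xname = "phi0_a", yname = "XlogP3")
ols_fit(tab$phi0_a, tab$aclogp,   xname = "phi0_a", yname = "AClogP")
ols_fit(tab$phi0_a, tab$logp_exp_mean, xname = "phi0_a", yname = "logP_exp")
```

Two data choices matter for exact reproduction and are worth stating:

* The experimental-logP regression uses the *published 2-dp mean* column for
  multi-source compounds (and the single literature value otherwise). With
  full-precision means the slope shifts from 10.655 to 10.657 — the rounded
  summaries are evidently what entered the original regression, so the
  package ships them as part of the Table-4 fixture and uses them on this
  path. `mean_sd_logp()` always recomputes mean and n−1 sd from the raw
  values, and the reporting layer rounds half-away-from-zero at 2 dp, which
  reproduces every printed summary.
* The reported F statistic obeys the identity $F = (n-2)r^2/(1-r^2)$; for
  the experimental-logP fit this gives F ≈ 40 (the value printed alongside
  that equation in the source tables appears to carry a typographical
  error, and is not asserted).

The fitted experimental-logP line then predicts logP for the three compounds
with no literature value:

```{r predict}
fit <- ols_fit(tab$phi0_a, tab$logp_exp_mean)
phi0 <- setNames(tab$phi0_a, tab$compound)
round_half_away(predict_logp(fit, phi0[c("nilvadipine", "lacidipine", "carprofen")]), 2)
```

$\varphi_0$ itself is a relative ranking index: it orders compounds by
lipophilicity and predicts logP through a fitted line, but its values are
volume fractions and are not directly comparable to logP, which is why it is
excluded from the clustering below.

## Similarity clustering of descriptors

`distance_matrix()` treats each descriptor column as an object whose
coordinates are its per-compound values and computes Euclidean distances
(all descriptors share the log10 scale, so no standardisation is applied by
default; a z-score option is a one-liner with `scale()` before the call).
`agglomerate()` performs standard agglomerative clustering. The linkage of
the original analysis is unstated, so the package asserts only the
linkage-independent feature of each dendrogram — the first merge, i.e. the
nearest descriptor pair — and makes the linkage configurable with `single`
as the default joining rule. On the bundled tables the nearest
computed-scale pairs are (AClogP, AlogPs) for the antiparasitic set and
(XlogP2, XlogP3) for the antihypertensive set under every linkage.
Dendrograms export losslessly to JSON and to Newick text in which each node
sits at its merge height.

## The synthetic-data generator

Raw plate measurements for the bundled tables are not published, so the
descriptor values are fixtures, not recomputation targets. To make every
estimator testable, `simulate_sw_series()` and `simulate_oscik_series()`
generate measurements with the statistical structure the analysis assumes:

* the design grids are exactly the three experimental gradient programmes
  (methanol 20–100% in 10% steps and acetone 10–100% in 10% steps for the
  antiparasitic class; both modifiers 60–100% in 5% steps for the
  antihypertensive class; methanol 60–100% in 5% steps and acetone 20–100%
  in 10% steps for the NSAIDs);
* triplicate spotting (`replicates = 3`) matches the protocol;
* noise is additive Gaussian on the $R_M$ scale with default sd 0.05. The
  protocol reports no replicate variance, so this default is a judgement
  call: it corresponds to an $R_F$ uncertainty of roughly ±0.01–0.03 over
  the usual working range, typical of densitometric plate reading, and it
  is stored in `default_config()` rather than hard-coded;
* simulated $R_F$ values are truncated to [0.01, 0.99] (with a reported
  count), and a design is flagged when the noiseless truth already falls
  outside that window at most of the grid — such a compound/design pairing
  could not have been measured.

`make_cohort()` samples class cohorts whose true $R_{MW}$ values span the
observed per-class ranges (antiparasitic 0.65–1.46, NSAID 1.26–3.12,
antihypertensive 3.13–5.01) with slopes chosen so $\varphi_0$ stays in a
plausible window. What the generator deliberately does **not** model:
plate-to-plate drift, chamber-saturation effects, densitometer optics, or
heteroscedastic error near the solvent front. Passing recovery tests
therefore demonstrate correctness of the estimators under the assumed
linear-plus-Gaussian structure, not robustness to those instrumental
artefacts.

Monte-Carlo recovery at the default settings (noise sd 0.05, 3 replicates,
100 seeds, 9-point grid) gives a mean absolute $R_{MW}$ error of about
0.04–0.05 — comfortably inside the 0.15 tolerance the test suite enforces,
and small relative to the ~0.3-unit class gaps in the tables. The suite runs
these sizes because they are statistically sufficient: errors stabilise to
two significant figures by 100 seeds.

## Numerical choices and edge cases

* OLS is delegated to `stats::lm`; the test suite checks it against a
  closed-form normal-equation oracle to 1e−10, and noiseless series are
  recovered to 1e−9 through the full simulate-aggregate-fit chain.
* Clustering is delegated to `stats::hclust` (`ward` maps to `ward.D2`,
  the Ward criterion on non-squared Euclidean input); the suite checks all
  four linkages against a brute-force Lance–Williams implementation on
  instances of up to six objects.
* Ties in agglomeration are resolved deterministically by the underlying
  implementation; no asserted result depends on a tie.
* Reported descriptors are rounded only at the reporting layer
  (half-away-from-zero; 2 dp for retention-type values, 3 dp for
  $\varphi_0$); all internal arithmetic is double precision.
* `read_measurements()` validates the exact input schema row by row and
  flags percent-style compositions (e.g. 60 instead of 0.60) with a hint,
  since that is the most likely transcription mistake.

## Known limitations

* The mole-fraction conversion ignores excess molar volumes; for
  methanol-water this is a ≤3% effect on $x$ at mid-range compositions.
* The Ościk validity thresholds are heuristics tuned to drug-like retention
  ranges; extreme but genuine chemistry could be flagged as invalid and
  should be inspected via the returned `r2` rather than the flag alone.
* Dendrogram topology beyond the first merge depends on unstated linkage
  and standardisation settings and is deliberately not asserted anywhere.
* In the bundled descriptor tables the $\varphi_0$ rows follow the row
  labels of the source; its footnote letters for the two $\varphi_0$
  columns are internally inconsistent with those rows, and the fixture
  files note this (the acetone set is the lower one, 0.398–0.565, which is
  also the physically expected ordering given acetone's greater elution
  strength).
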