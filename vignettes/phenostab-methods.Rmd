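---
title: "Methods: quantifying developmental stability, canalization and plasticity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying developmental stability, canalization and plasticity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenostab)
```

## The three buffering processes

Plants (and organisms generally) regulate phenotypic variation through three
partly antagonistic processes:

* **Developmental stability** — the ability of one individual to buffer its
  development against perturbation. It is measured here from *fluctuating
  asymmetry* (FA) of bilateral leaves — random deviation from perfect
  left–right symmetry — and from the *intra-individual* coefficient of
  variation of leaf size (`CV_intra`).
* **Canalization** — buffering at the population level: phenotypic
  convergence among individuals grown under the same conditions, measured as
  the *inter-individual* CV of leaf size and mass traits (`CV_inter`; lower
  CV, stronger canalization).
* **Phenotypic plasticity** — environment-induced phenotype change,
  measured by plasticity indices (PI) contrasting covariate-adjusted
  treatment means.

phenostab computes all three families from tidy leaf-measurement and
individual-trait tables, plus the correlation machinery used to relate them
across species, and ships a synthetic-data generator that emulates a
two-round split-plot water-availability experiment so that every estimator
can be validated against known generative parameters.

## The experimental design being emulated

The generator reproduces a two-round greenhouse design. In round one,
plants of 8 species experience either temporally *heterogeneous* water
supply (alternating inundation and drought, `E_het`) or constant moderate
watering (`E_hom`). After 90 days a subgroup of 20 plants per species ×
early cell is harvested (these provide the round-1 FA and CV measures); the
rest are split across three *late* treatments — inundation, moderate,
drought — with 10 replicates per species × early × late cell, harvested
after 150 days (these provide round-2 CVs and plasticity). The default
layout therefore contains

\[
8 \ \text{species} \times 2 \ \text{early} \times (3 \ \text{late} \times 10
+ 20) = 800 \ \text{plants},
\]

one plant per pot. Before treatments begin, the longest leaf of each plant
is measured as its *initial size* (IS), the covariate used throughout.

`design_config()` holds this layout (all counts configurable), plus the
leaf-count range per plant and the number `M` of successive caliper
readings per leaf side. `M = 2` by default and must be at least 2: the FA10
index needs replicate measurements to estimate measurement error.

## The latent leaf model

For a leaf of latent size \(s\) (half-width at the widest point, mm), the
signed asymmetry \(d = R - L\) is drawn as

\[
d \sim \mathcal{N}(\mu_{da},\ \sigma_d^2), \qquad
\sigma_d = \sigma_{fa} + \beta_{size}\, s ,
\]

optionally shifted by \(\pm\delta\) with equal probability (a symmetric
two-point mixture producing *antisymmetry* — platykurtic, ultimately
bimodal signed differences). Side widths are \(R = s + d/2\) and
\(L = s - d/2\), chosen so that leaf size \(LS = (R + L)/2\) recovers \(s\)
exactly. Each of the `M` replicate readings per side adds independent
\(\mathcal{N}(0, \sigma_{me}^2)\) measurement error. Leaves with any
non-positive reading are redrawn wholesale rather than truncated, so the
distribution of \(d\) is unbiased at realistic parameter values.

Key defaults, with the reasoning:

| parameter | default | why |
|---|---|---|
| `sigma_fa` | 0.25 mm | baseline between-sides SD, a few percent of leaf size |
| `size_slope` | 0.02 per mm | asymmetry scales with leaf size, the commonly observed pattern |
| `sigma_me` | 0.1 mm | repeatability of a digital caliper reading on soft tissue |
| `da_offset`, `antisym_delta` | 0 | ideal fluctuating asymmetry unless the user injects pathology |
| leaves per plant | 4–12 | typical main-stem leaf counts for herbaceous rosettes; the real counts are not knowable from summary data, so the range is configuration |

## The trait model

Individual-level traits are lognormal around species baselines times a
per-cell treatment multiplier:

\[
\log T_i = \log(\text{baseline}_{sp} \cdot m_{cell}) +
\beta_{IS}\,(\log IS_i - \overline{\log IS}) + \varepsilon_i ,
\]

with \(\varepsilon_i\) chosen so the among-individual CV equals `cv_inter`
(0.3 by default — a typical greenhouse mass CV) and the mean stays at the
baseline. Shoot and root mass are generated separately (total mass is their
sum, so the additive identity holds exactly; the root:shoot ratio is their
quotient). Within-plant leaf sizes scatter around the individual's mean
with CV `cv_intra` (0.15), which makes `CV_intra` independent of plant size
by construction. Mortality is Bernoulli per plant at rate 0.1 per cell, so
an 800-plant run retains about 720 survivors, matching the survival level
typical of such greenhouse experiments. Treatment multipliers default to
mild early-stress and late-stress mass reductions (heterogeneous early
experience ×0.9; inundation ×0.75; drought ×0.6; first-round harvests are
younger plants, masses ×0.45); they are inputs, not estimates.

What the generator deliberately does **not** emulate: the tank-level
(whole-plot) error structure of the split-plot layout (treatments act
independently on each plant), temporal growth dynamics within a round,
correlated shoot/root deviations, and non-normal measurement error.
Passing tests therefore demonstrate the *estimators'* correctness under a
clean generative model, not robustness to every feature of real data.

## Fluctuating-asymmetry indices

With \(\bar R_j, \bar L_j\) the replicate-mean side widths of leaf \(j\)
and \(LS_j\) their average, for \(n\) leaves:

\[
FA_1 = \frac{1}{n}\sum_j |\bar R_j - \bar L_j|, \qquad
FA_2 = \frac{1}{n}\sum_j \frac{|\bar R_j - \bar L_j|}{LS_j}.
\]

`fa2()` uses the absolute value (the size-standardised magnitude index);
`signed = TRUE` gives the signed average, which is near zero under ideal
FA. FA1 and FA2 are computed from replicate means — averaging first removes
part of the measurement error, and only the sides ANOVA below needs the raw
replicates.

**FA10** is the variance-component index. A balanced two-way factorial
ANOVA of the raw readings — side (2 levels) crossed with measured leaf as
the unit, `M` replicates per cell — yields mean squares \(MS_{si}\)
(side × unit interaction) and \(MS_m\) (replicate measurement error), and
the interaction variance component

\[
s^2 = \frac{MS_{si} - MS_m}{M}.
\]

Because the side factor has two levels, the variance of the signed
difference is twice the interaction component:
\(\operatorname{Var}(R - L) = 2 s^2\). The default (`variant =
"between_sides"`) therefore reports

\[
FA_{10} = 0.798\,\sqrt{2 s^2},
\]

the measurement-error-free counterpart of FA1: for normally distributed
\(d\), \(E|d| = \sqrt{2/\pi}\,\mathrm{sd}(d) \approx 0.798\,\mathrm{sd}(d)\).
This scaling is what makes FA1 and FA10 directly comparable (they agree as
measurement error goes to zero), and it is the classical form of the
variance-components FA index. The alternative `variant = "component"`
reports \(0.798\sqrt{s^2}\), i.e. the interaction component itself on the
half-normal scale, for comparability with analyses that use that
convention; it is smaller by \(\sqrt 2\). A negative \(s^2\) estimate
(possible when measurement error rivals true asymmetry) is clamped to zero
and flagged rather than returned as missing, so cell means remain
computable; flag counts are carried through `fa_table()`.

FA10 is a group-level index, yet per-species means ± SE are the natural
display. The default grouping computes FA10 *per individual*, using that
plant's leaves as the ANOVA units, so dispersion across individuals is
definable; `fa_table()` also reports the pooled-cell FA10 computed from all
of a cell's leaves at once. Indices FA3–FA8 are not implemented: their
definitions vary across the literature and nothing downstream needs them.

## Asymmetry diagnostics

FA-based inference assumes the signed differences are centred, unimodal
and roughly normal. `asymmetry_diagnostics()` checks:

* **Directional asymmetry**: one-sample t test of \(d\) against zero, and,
  in the sides ANOVA, \(F_{da} = MS_s / MS_{si}\) — the side main effect
  tested against the side × unit interaction (the appropriate denominator
  when units are random).
* **Antisymmetry**: bias-corrected excess kurtosis \(G_2\) with a z test; a
  significantly *negative* \(G_2\) suggests a bimodal either-side-larger
  pattern. The standard error uses the exact normal-theory moment formula
  \(2\,SE_{G_1}\sqrt{(n^2-1)/((n-3)(n+5))}\) (the familiar
  \(\sqrt{24/n}\) is its large-\(n\) limit). The exact form was adopted
  because it keeps the two-sided test closest to its nominal level at the
  sample sizes used here; the calibration is verified by simulation in the
  test suite.
* **Size dependence**: OLS of \(|d|\) on leaf size with the slope t test.
  When asymmetry scales with size, FA2 is the more comparable index.
* **Measurement error**: \(F_{me} = MS_{si}/MS_m\) confirms the
  between-sides signal exceeds replicate noise.

With fewer than 4 leaves the moments are reported and the tests returned as
`NA`. The classification string flags antisymmetry first (it invalidates FA
interpretation outright), then directional asymmetry, at the 0.05 level.

## Coefficients of variation

`cv()` is the sample SD (n − 1 denominator) over the mean. CVs are computed
on **raw** trait values even though the ANCOVA analyses log-transform: the
CV of log-transformed data is not a coefficient of variation, and the CV's
definition is on the trait scale. (Callers who want the literal
log-then-CV reading can pass transformed columns explicitly.)

`cv_equality_test()` compares CVs between treatment groups per species.
The default method is the Feltz–Miller asymptotic chi-square test; with
\(m_i = n_i - 1\), \(c_i\) the group CVs and \(c_p\) their
\(m_i\)-weighted mean,

\[
D = \frac{\sum_i m_i (c_i - c_p)^2}{c_p^2\,(0.5 + c_p^2)}
\sim \chi^2_{k-1}.
\]

A likelihood-ratio alternative (`method = "lrt"`) maximises the normal
likelihood under the common-CV constraint numerically and refers
\(2(\ell_1 - \ell_0)\) to \(\chi^2_{k-1}\), returning the signed root for
two groups. The small-sample *modified* signed-likelihood-ratio variant is
not provided — its correction terms are not reproduced here — and the
plain tests are adequate at the cell sizes this design produces; the
default test's type-I error calibration at n = 50 per group is checked in
the test suite.

## Plasticity indices

Adjusted means come from a one-way ANCOVA per species × early cell:
`trait ~ late + initial_size`, fitted on the natural-log trait (the
variance-stabilising scale used for all trait analyses), each late
treatment evaluated at the grand mean of initial size. For the plasticity
index the adjusted log-means are **back-transformed** (geometric adjusted
means) so that the ratio index keeps its dimensionless meaning:

\[
PI_{rel} = \frac{Y_2 - Y_1}{Y_1}, \qquad PI_{abs} = |PI_{rel}|,
\]

with \(Y_1\) the adjusted mean under moderate water and \(Y_2\) under
inundation (`IM` contrast) or drought (`DM`). Under a purely
multiplicative treatment effect \(r\), \(PI_{rel} = r - 1\) in
expectation — the property the parameter-recovery tests exploit. An
alternative `"srdpi"` variant computes the simplified relative-distance
form \((Y_2 - Y_1)/(Y_2 + Y_1)\), bounded in (−1, 1) for positive traits;
both variants are labelled in the output, and the signed index is positive
exactly when \(Y_2 > Y_1\) under either. Computing PI on the log scale
itself was rejected as the default because the resulting index depends on
the measurement unit of the trait.

## Inference machinery

* **ANCOVA effect tables** (`ancova()`): fixed-effects linear models with
  sum-to-zero contrasts and partial (Type III style) term tests — each term
  against the model containing all others — matching common GLM practice
  for unbalanced designs; sequential (Type I) tests are available. Empty
  cells drop the affected interaction with a warning rather than failing.
* **LSD comparisons** (`lsd_compare()`): all-pairs t tests on the pooled
  residual mean square, no multiplicity adjustment (that is what "least
  significant difference" means), with a compact letter display built by
  insert-and-absorb. A pair at exactly `p == alpha` is not significant.
  Zero residual MS with unequal means marks all pairs different.
* **Correlations** (`pearson_corr()`, `partial_corr()`): partial
  correlations use the residual method — correlate the residuals of each
  variable after regressing out the covariates — with `df = n − 2 − k`.
  With no covariates the partial correlation is exactly the plain Pearson
  coefficient.
* **Cross-species tables** (`correlation_tables()`): correlations are
  computed *across species* (one point per species per cell, n = 8 under
  the default design), controlling initial size. With so few points these
  tests are low-powered; rows with fewer than 5 points carry a
  `low_power` flag. Significance tiers are marked at 0.10 / 0.05 / 0.01
  with one to three stars, in a separate column from the numeric values,
  and no multiple-testing correction is applied (an explicit design
  choice: the tables are descriptive screens, and their star rate under a
  null generator is itself verified by simulation). For the round-2 tables
  either mean initial size or the inter-individual CV of initial size can
  serve as the covariate — the appropriate choice is genuinely ambiguous,
  so both are exposed via `covariate =`.
* **Slope differences** (`slope_difference_test()`): the pooled
  interaction model `y ~ x * group`, reporting the interaction t test and
  the per-group slopes (which equal the separate per-group regressions
  exactly).

## Numerical choices

* The sides ANOVA uses the closed-form balanced decomposition on centred
  data; it matches `lm`/`anova` oracles to well below 1e−9 relative error
  and is orders of magnitude faster for the many small per-individual fits.
* All randomness in a synthetic run flows from the single design seed:
  `simulate_experiment()` seeds once, then generation and mortality consume
  the stream in a fixed order, so identical configurations are
  byte-identical.
* Degenerate inputs fail loudly and specifically: non-positive widths,
  missing sides (the offending leaf is named), unbalanced replicates,
  constant covariates (fall back to raw means with a warning), collinear
  covariates, constant correlation inputs.

## Problem sizes used for validation

The package validates itself at these scales (chosen to give tight Monte
Carlo error while keeping the suite quick): the half-normal constant at
10^6 leaves; FA10 measurement-error correction at 200 replicate experiments
of 500 leaves (σ_fa = 1, σ_me = 0.3, M = 2); diagnostic calibration at
2000 null replicates of n = 100 leaves and power at 1000 replicates with
antisymmetry half-separation 1; plasticity recovery over 200 full 800-plant
experiments with a ×1.5 inundation effect on mass; CV-equality calibration
at 2000 replicates of n = 50 per group. The oracle-equivalence checks
(ANOVA, ANCOVA, partial correlation, LSD) run at 1e−9 relative tolerance.

## Known limitations

* The analyses are fixed-effects throughout, mirroring standard GLM
  practice for this design; the split-plot tank structure is not modelled
  as a random effect, so treatment tests are anti-conservative to the
  extent that tanks share conditions. A mixed-model treatment is out of
  scope here.
* FA3–FA8 are not implemented.
* True leaf counts per plant and the caliper's measurement-error magnitude
  are unknowable from published summaries; both are exposed as
  configuration with documented defaults rather than hidden constants.
* Cross-species correlations rest on 8 points per cell; they are reported
  with that caveat (`low_power` flagging) rather than suppressed.
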