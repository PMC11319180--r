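---
title: "Methods: two-sample MR of lipid species on hemorrhagic stroke"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR of lipid species on hemorrhagic stroke}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lipidmr` implements a complete two-sample Mendelian randomization (MR)
scan of many quantitative exposures — plasma lipid species, each
measured in standard-deviation units — against binary cerebrovascular
outcomes (intracerebral hemorrhage, ICH; subarachnoid hemorrhage, SAH)
whose genetic effects are log odds ratios. This vignette is the
package's own account of the statistical machinery: the model and its
assumptions, the parameters that matter, the synthetic-data design that
makes the whole pipeline testable offline, and the numerical choices a
maintainer would want written down.

## The design and its assumptions

A genetic variant $j$ qualifies as an instrument for an exposure $X$
when (1) it is robustly associated with $X$, (2) it is independent of
confounders of the $X$–$Y$ relation, and (3) it affects the outcome $Y$
only through $X$. Under these assumptions each variant yields a Wald
ratio $\hat\beta_j = \hat\Gamma_j / \hat\gamma_j$ — outcome effect over
exposure effect — that estimates the causal log odds ratio $\theta$ per
SD of exposure. The two-sample form takes $\hat\gamma_j$ and
$\hat\Gamma_j$ from *different* GWAS, which makes their sampling errors
independent but obliges explicit allele harmonization
(`harmonize()`).

Assumption (1) is enforced by the instrument cascade
(`build_instrument_set()`): genome-wide significance
($p < 5\times10^{-8}$, strict), greedy LD clumping
($r^2 \le 0.001$ within 10,000 kb), and per-variant strength statistics

$$R^2_j = \frac{2\beta_j^2 f_j(1-f_j)}
               {2\beta_j^2 f_j(1-f_j) + 2\,se(\beta_j)^2 N f_j(1-f_j)},
\qquad
F = \frac{R^2}{1-R^2}\cdot\frac{N-k-1}{k},$$

with $f_j$ the minor-allele frequency, $N$ the exposure sample size and
$k$ the instrument count. Algebraically $R^2_j$ reduces to
$\beta_j^2 / (\beta_j^2 + N\,se^2)$ — the allele frequency cancels — but
the package computes the full form and requires a frequency, which also
gates palindromic-variant resolution. $F \le 10$ marks a weak
instrument; the default policy *flags* rather than removes
(`f_policy = "flag"`), because silently changing instrument counts is
worse than reporting weakness — `"exclude"` is available. $k$ is the
count in the final set, recomputed after all filters. Assumption (3)
is approximated by excluding instruments associated with the outcome at
$p < 5\times10^{-5}$ and by the Steiger directionality test. Exposures
retaining at least two instruments are eligible for MR.

## Estimators

All five estimators consume the same harmonized set. With ratio
standard errors $se_j = se(\hat\Gamma_j)/|\hat\gamma_j|$ (first order)
and weights $w_j = se_j^{-2}$:

* **IVW (fixed effect)** — $\hat\theta = \sum w_j\hat\beta_j / \sum
  w_j$, $se = (\sum w_j)^{-1/2}$; identical to weighted least squares
  of $\hat\Gamma$ on $\hat\gamma$ through the origin (the test suite
  checks this equivalence to $10^{-12}$).
* **IVW (multiplicative random effects)** — same point estimate;
  the standard error is scaled by $\max\{1, \sqrt{Q/(J-1)}\}$ so
  observed heterogeneity widens, and can never narrow, the interval.
  The *headline* estimate (`mr_ivw_headline()`) is the MRE variant when
  Cochran's Q has $p < 0.05$ and the FE variant otherwise; both are
  always reported.
* **MR-Egger** — weighted regression of $\hat\Gamma_j$ on
  $\hat\gamma_j$ with a free intercept, each instrument oriented so
  $\hat\gamma_j \ge 0$. The slope estimates $\theta$ under the InSIDE
  assumption; the intercept estimates average directional pleiotropy.
  Standard errors use the residual-sigma unit floor (multiplicative
  random effects) and $t_{J-2}$ p-values.
* **Weighted median** — the ratio at cumulative weight 0.5 under the
  midpoint convention with linear interpolation; with equal weights and
  odd $J$ this is exactly the sample median. Consistent when valid
  instruments carry over half the weight.
* **Weighted mode** — argmax of a normal-kernel weighted density of
  the ratios on a 512-point grid spanning their range; bandwidth is
  `phi` (default 1) times the modified Silverman rule
  $0.9\,\min(sd, mad)\,J^{-1/5}$. Consistent when the largest group of
  instruments sharing an effect is valid.

Weighted-median and weighted-mode standard errors come from a seeded
parametric bootstrap (default 1,000 resamples of the per-variant
effects from $\mathcal N(\hat\beta, se)$); the seed is mandatory, so
identical configurations reproduce byte-identical output. MR-Egger and
the weighted mode require $J \ge 3$; the others $J \ge 2$.

## Sensitivity battery

* **Cochran's Q** on the ratios, $\chi^2_{J-1}$.
* **Egger intercept test**, $t_{J-2}$.
* **MR-PRESSO**: observed residual sum of squares against leave-one-out
  IVW predictions, compared with `n_sim` (default 1,000) parametric
  simulations under the no-pleiotropy model; global p is the fraction
  of simulated RSS at or above the observed. Per-variant contributions
  give Bonferroni-adjusted outlier p-values; when outliers are found, a
  distortion test compares the estimate shift after their removal with
  shifts after removing random subsets of the same size. With $J < 4$
  the test is unidentifiable and every field is `NA` by design, not an
  error. A large planted outlier is reliably flagged, though it can
  drag the leave-one-out slopes enough to flag a companion variant —
  behaviour inherited from the RSS construction itself.
* **Steiger**: summed per-variant $R^2$ for exposure versus outcome
  (same formula on the log-odds scale for the binary outcome — an
  approximation worth remembering), direction `TRUE` when the exposure
  side explains more; p from Fisher's z comparison of the implied
  correlations.
* **Leave-one-out**: J re-runs of IVW omitting one variant each. The
  set is stable when every re-run keeps the sign and stays inside the
  full-set 95% CI. These re-runs use the fixed-effect variant: under
  MRE a single outlier inflates the interval by the same heterogeneity
  factor its omission moves the estimate, so the containment check
  could never fire — the FE interval makes the rule operational.

## Candidates, FDR and meta-analysis

Headline IVW p-values are BH-adjusted across exposures per outcome
(`bh_fdr()`, reported but not gating). An exposure is a *candidate*
when the headline IVW is nominally significant, all available
estimators agree in sign (the package's operationalisation of
"consistent direction"; magnitude agreement is not quantified), Q,
Egger-intercept and PRESSO global tests are all non-significant
(PRESSO vacuously passes when `NA`), Steiger supports the assumed
direction, and leave-one-out is stable. Candidates are re-analysed on
the replication cohort with instruments re-selected from scratch, and
the two headline IVW estimates are pooled by DerSimonian–Laird
random-effects meta-analysis:
$\tau^2 = \max\{0, (Q_m - (k-1)) / (\sum w - \sum w^2/\sum w)\}$,
re-weighting by $1/(se_i^2+\tau^2)$. Candidacy is decided on the
discovery cohort only; a candidate that fails replication still appears
in the meta table with its pooled (possibly non-significant) estimate.
All odds-ratio intervals use $\exp(\hat\theta \pm 1.959964\,se)$, and
`p_from_or_ci()` inverts that construction to audit reported
`p; OR (95% CI)` triplets — `p_from_or_ci_range()` propagates the
printed rounding, which is the honest resolution limit of such audits.

## The synthetic-data generator

`simulate_two_sample()` draws summary statistics directly at the
summary level — no individual genotypes — because two-sample MR
consumes nothing else and the closed-form standard error
$se = 1/\sqrt{2N f(1-f)}$ makes the oracles exact. Per variant:
$\hat\gamma_j \sim \mathcal N(\gamma_j, se_{x,j})$,
$\hat\Gamma_j \sim \mathcal N(\theta\gamma_j +
\mathrm{sign}(\gamma_j)\,\alpha_j, se_{y,j})$, independently (two-sample
independence), twice (two cohorts sharing the truth but not the noise).
Pleiotropic shifts $\alpha_j$ are expressed on the exposure-increasing
allele — the orientation MR-Egger uses — so "directional" pleiotropy
remains directional after orientation; without this convention random
instrument signs would cancel the planted intercept. Defaults mirror
the study scale the package targets: exposure GWAS of $N = 7{,}174$;
outcome effective sample sizes $4/(1/\text{cases} +
1/\text{controls})$ from 4,056/371,717 (discovery) and 1,935/471,578
(replication) case/control designs; minor-allele frequencies uniform on
$[0.05, 0.5]$; instrument magnitudes uniform on $[0.12, 0.30]$ with
random sign, sized so instruments can reach genome-wide significance at
$N = 7{,}174$. Binary-outcome effects are simulated on the log-odds
scale with the same normal approximation; case/control imbalance enters
only through the effective $N$. Instruments are placed on alternating
chromosomes far apart, matching the post-clumping independence the real
pipeline produces; LD structure and population stratification are *not*
simulated, so passing tests say nothing about clumping against real LD
panels or confounding by ancestry.

## Problem sizes and numerical choices

The calibration experiments (in `analysis/03_calibration.R`, the
acceptance script and the test suite) use: 1,000 replicates at
$\theta = 0.2$, $J = 30$, strong instruments
(`gamma_range = c(0.25, 0.4)`) for IVW bias and coverage — measured on
the simulate–harmonize–IVW path, without the outcome-association
filter, which at larger $\theta$ would remove genuinely causal
instruments and measure the filter rather than the estimator; 500
replicates at $J = 50$ with large cohorts for Egger intercept recovery;
200 null sets with `n_sim = 200` for PRESSO global-p uniformity
(Kolmogorov–Smirnov); an 8-lipid study with 3 planted causal exposures
for end-to-end recovery. The end-to-end fixtures use
`gamma_range = c(0.15, 0.5)` and $\theta = 0.1$: MR-Egger's slope sign
is identified by the *spread* of instrument effects, and a small
$\theta$ keeps true outcome signal from tripping the
$p < 5\times10^{-5}$ exclusion — both properties of the study design,
chosen up front.

Other numerics: clumping ties break on the lexicographically smaller
variant id (reproducibility); a failing LD *lookup* is treated as
$r^2 = 1$ (conservative removal) while a pair absent from a sparse LD
table counts as $r^2 = 0$; palindromic variants (A/T, C/G) default to
`drop_ambiguous` with a 0.08 frequency window around 0.5, requiring
both frequencies informative and direction-concordant; exact-fit
regressions (zero residual sigma) return p = 1 for a zero coefficient
rather than 0/0; empirical PRESSO p-values are unsmoothed fractions, so
0 is possible at finite `n_sim`; p-values are stored as given in input
files, never recomputed at the I/O layer.

## Known limitations

Instrument selection on the same data that estimates $\hat\gamma$
induces winner's-curse bias that the generator can reproduce (set
`gamma_range` near the significance boundary) but the estimators do not
correct. The first-order ratio standard error ignores exposure-side
noise, giving mild undercoverage (about 94% rather than 95% at the
default sample-size ratio) — visible in the calibration output and
inherent to the standard IVW form. The Steiger binary-outcome $R^2$ is
a log-odds-scale approximation. The distortion test's null set of
random subsets is small when few variants remain. None of the
synthetic checks exercise real LD, real allele-frequency spectra, or
real pleiotropic architectures.
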