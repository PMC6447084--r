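---
title: "Two-sample Mendelian randomization with mrpipe: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The question mrpipe answers

Mendelian randomization (MR) uses genetic variants as instrumental variables
for a modifiable exposure: because alleles are assigned at conception,
a variant that raises the exposure provides a natural experiment that is
immune to classical confounding and reverse causation, provided the variant
affects the outcome *only* through the exposure. In the two-sample design the
variant–exposure associations $(\hat\beta_{Xj}, \sigma_{Xj})$ and the
variant–outcome associations $(\hat\beta_{Yj}, \sigma_{Yj})$ come from
non-overlapping GWAS, so only published summary statistics are needed.

mrpipe implements the full analysis pipeline for this design as it is used in
cardiometabolic epidemiology — for example, asking whether lower birthweight
(a proxy for restricted intrauterine growth) causally raises the risk of
coronary artery disease or type 2 diabetes: harmonization of summary
statistics, construction of three nested instrument sets of increasing
stringency, a battery of four estimators with heterogeneity and pleiotropy
diagnostics, multivariable MR for mediation questions, analytic power, and a
synthetic-data generator with known ground truth so that every stage is
testable without access to consortium data.

## Estimators

Per variant, the Wald ratio is $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
with first-order standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$ (exposure-side
noise ignored; see *Finite instrument strength* below). All pooled estimators
use the inverse-variance weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$.

**IVW.** $\hat\theta = \sum w_j \hat\theta_j / \sum w_j$, equivalently the
zero-intercept weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$.
Under the default multiplicative random-effects (mre) variance model the
fixed-effect standard error $(\sum w_j)^{-1/2}$ is scaled by
$\max\{1, \sqrt{Q/(J-1)}\}$, so between-variant heterogeneity widens but never
narrows the interval. The fixed/mre choice is a parameter because the variance
model actually used in applied reports is rarely stated; mrpipe labels every
output with the model used.

**Penalized robust IVW.** Per-variant Cochran's $Q$ contributions $q_j$ are
converted to upper-tail $\chi^2_1$ probabilities $p_j$ and each weight is
multiplied by $\min(1, 20\,p_j)$ (so any variant whose outlier test exceeds
$P = 0.05$ keeps its full weight). The zero-intercept regression is then refit
by bounded-influence M-estimation with the Tukey bisquare
($c = 4.685$). Residuals are standardized by their *known* sampling scale —
$\sqrt{w^{\mathrm{pen}}_j}(\hat\beta_{Yj} - \theta\hat\beta_{Xj})$ is
unit-normal under homogeneity — rather than by a re-estimated robust scale.
This detail matters: with an internally re-estimated scale the bisquare
weights respond to *relative* spread and the estimator never reduces to plain
IVW even on homogeneous data, whereas with the known scale the penalties and
the $\psi$-weights are inactive exactly when no variant is outlying.

**Weighted median.** Ratios are sorted, weights normalized, and the estimate
interpolated at the 50th weight percentile
$s_j = 100(\sum_{i\le j}\bar w_i - \bar w_j/2)$; it is consistent while less
than half the total weight comes from invalid instruments. Its standard error
is the SD of the estimate across `n_boot` parametric bootstrap resamples
(both $\hat\beta_{Xj}$ and $\hat\beta_{Yj}$ redrawn from their reported normal
distributions), fixed seed, default `n_boot = 1000`. This bootstrap is the
field's standard construction, and it is conservative: the resampling noise is
added to ratios that are already noisy, which flattens the density near the
median and inflates the SD by roughly 10–15% relative to the true sampling SD
at the default study scale. The package keeps the standard construction and
documents the conservatism rather than re-deriving an analytic median SE.

**MR-Egger.** Weighted regression *with* intercept: the slope estimates the
causal effect free of directional pleiotropy under the InSIDE assumption
(instrument strength independent of direct effects), and the intercept
estimates the average direct effect — its two-sided test is the pleiotropy
diagnostic. Both standard errors are scaled by $\max\{1,\sqrt{Q/(J-2)}\}$;
the spec of the analysis only forces this for the slope, but deflating the
intercept test while inflating the slope would be incoherent, so the same
factor is applied to both. Egger requires all instruments oriented to
positive exposure effect (`orient_to_exposure()`), which leaves Wald ratios
unchanged.

**Multivariable MR.** For $K \ge 2$ exposures, the outcome effects are
regressed on the $J \times K$ matrix of exposure effects without intercept,
weights $1/\sigma_{Yj}^2$, giving each exposure's *direct* effect holding the
others fixed — the mediation analysis (e.g. birthweight and BMI jointly on
disease). Standard errors are mre-scaled on $J - K$ degrees of freedom;
rank-deficient designs are rejected naming the collinear columns.

All P values are two-sided normal rather than $t$: the estimators are applied
to consortium-scale GWAS where the within-variant sampling distributions are
effectively Gaussian, and normal theory is what the corresponding published
tools use. Binary outcomes are analysed on the log-odds scale throughout;
odds ratios appear only in reporting columns.

## The three instrument sets

* **IV1** — all independent lead variants of the exposure GWAS, minus loci
  excluded on biological grounds (e.g. an imprinted locus, where the
  fetal-genotype interpretation of the association fails). Maximizes power.
* **IV2** — the main model: IV1 minus every variant associated with a listed
  outcome disease or confounder trait either (a) at genome-wide significance
  (default $5\times10^{-8}$) or (b) more strongly than with the exposure
  itself ($P_{\text{trait}} < P_{\text{exposure}}$). A variant is excluded at
  its first triggering trait (association-table order) and every trigger is
  logged. A variant absent from the association table is retained and
  logged — absence of evidence is not treated as exclusion evidence.
* **IV3** — stepwise downward heterogeneity pruning: while Cochran's $Q$ on
  the IVW fit has $P < 0.05$, the variant with the largest $Q$ contribution
  is removed (exact ties broken lexicographically by variant ID, for
  reproducibility) and the estimate *refit*; the floor is two variants, below
  which IVW is undefined. Refitting at each step is implied by "stepwise
  model selection"; it also guarantees monotone non-increasing $Q$, which the
  test suite asserts. Whether pruning starts from IV1 or IV2 is a parameter
  (`iv3_parent`, default IV2) because published pipelines differ and rarely
  say.

## Harmonization

Allele alignment resolves order swaps and strand-complement reporting; an
outcome record whose effect allele matches the exposure's other allele has
its beta negated and frequency complemented. Palindromic variants (A/T, C/G)
cannot be strand-resolved from labels; the default policy infers orientation
from which side of 0.5 the two studies' effect-allele frequencies fall,
dropping the variant when either frequency is missing or within 0.08 of 0.5.
The 0.08 band is the conventional compromise between losing variants and
silently mis-orienting common palindromes — mis-orientation flips the sign of
a variant's contribution, the dominant silent error in two-sample MR.
Duplicate variant IDs are a hard error (silent duplicates double-weight the
IVW), and every intersection variant leaves harmonization with an explicit
action tag (`unchanged`, `flipped`, `dropped_palindromic`, `dropped_missing`,
`dropped_mismatch`), so record counts are conserved and auditable. Variant
matching is by exact ID only; proxy lookup and LD operations are out of scope
because the intended inputs are pre-clumped lead variants.

## Power and variance explained

For independent biallelic variants and a standardized exposure, the
instrument explains $R^2 = \sum_j 2p_j(1-p_j)\beta_j^2$. Analytic power uses
the standard asymptotic normal approximation with noncentrality
$|b|\sqrt{N R^2}$ (continuous) or $|\ln \mathrm{OR}|\sqrt{N R^2 f(1-f)}$
(binary, case fraction $f$):

```{r power}
power_continuous(n_outcome = 1e5, r2 = 0.022, effect = 0.15)
power_binary(n_outcome = 184305, r2 = 0.022, effect = 1.2,
             case_fraction = 0.33)
```

These formulas describe the *fixed-effect* IVW test, so the suite's
power-versus-simulation agreement check runs IVW with `model = "fixed"`; the
mre truncation $\max(1,\cdot)$ would add roughly two percentage points of
conservatism that has nothing to do with the formula under test.

## The synthetic-data generator

`simulate_two_sample()` emulates the two-sample design directly on the
summary-statistic scale. Defaults are the study conditions the package is
built around: $J = 46$ independent instruments explaining $R^2 = 2.2\%$ of a
standardized exposure, exposure GWAS of $N = 150{,}000$, outcome GWAS of
$N = 100{,}000$, equal per-variant variance contributions, effect-allele
frequencies uniform on $(0.1, 0.9)$. Observed effects are the true effects
plus normal noise with the asymptotic standard errors
$\sigma_{Xj} = (N_X\,2p_j(1-p_j))^{-1/2}$ and the analogous outcome-scale
form (binary: $\times (f(1-f))^{-1/2}$ on the log-odds scale), which is what
makes the analytic power formulas and the simulated rejection rates
commensurable. Pleiotropy modes add per-variant direct effects to the flagged
`prop_invalid` fraction: `balanced` (zero mean), `directional` (mean $c$), or
`inside_violating` (proportional to instrument strength, breaking InSIDE).
One root seed drives deterministic per-table substreams, and
`outcome_stream` lets several outcome studies share one exposure draw. A
fraction of outcome records (default 25%) is written with swapped allele
order so that harmonization is exercised on every run.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real data: linkage disequilibrium between instruments,
winner's curse in the discovery GWAS, sample overlap between exposure and
outcome studies, population stratification, and non-normal effect
heterogeneity. The per-variant equal-contribution default is deliberately
conservative for MR-Egger (see below); an exponential-decay profile
(`effect_profile = "decay"`) is available where a realistic spread of effect
sizes matters.

## Finite instrument strength: what "recovering the truth" can mean

Under the default conditions each variant's F-statistic is
$F \approx N_X R^2 / J \approx 72$. All ratio-based estimators then carry a
known attenuation of order $1/F \approx 1.4\%$ of the true effect, because
the observed $\hat\beta_{Xj}$ enter both the ratios and the weights. MR-Egger
is hit much harder: its slope is identified from the *spread* of instrument
strengths, and under the equal-contribution profile that spread is comparable
to the exposure-side noise (low $I^2_{GX}$), producing substantial regression
dilution of the slope that the intercept partially absorbs whenever the true
effect is nonzero. These are properties of the estimators, not bugs; the
acceptance suite measures them at 2000 replicates and the corresponding
mean-recovery assertions document precisely this gap. Tests of pleiotropy
properties (Egger intercept location, median robustness) are therefore run at
the causal null, where the dilution term vanishes and the property under test
is isolated.

Relatedly, the weighted median's bounded bias under invalid instruments is a
*separation* property: with 40% of weight on invalid instruments whose common
direct effect shifts ratios by many ratio-SEs, the median stays pinned to the
valid cluster while IVW shifts linearly. When the invalid shift is within a
couple of ratio-SEs the two distributions merge and *no* estimator can tell
them apart; the suite plants direct effects of 0.04 per allele (about ten
ratio-SEs at the default scale) so that "invalid" means something.

## Numerical and interface choices

* Exact-zero exposure effects are dropped at orientation (undefined ratio),
  with a warning; `se = 0` or out-of-range probabilities are row-level
  validation errors at ingestion, reported with line numbers.
* IV3 tie-breaking is lexicographic; the weighted-median bootstrap and every
  simulation stream take explicit integer seeds; reruns of a pipeline
  configuration are byte-identical, and the report logs a configuration hash
  (excluding the output directory), the seed and the package version.
* Monte-Carlo sizes in the test suite: 2000 replicates for calibration,
  recovery and power-agreement checks (rejection-rate standard error
  $\le 1.1$ points), 200–600 for pruning and pleiotropy-location checks,
  bootstrap sizes 100–300 inside simulation loops where only the point
  estimate or rejection decision is consumed.
* The pipeline reports raw P values plus an optional Bonferroni column with a
  configurable trait count, reflecting designs that test one exposure against
  a dozen outcomes.

## Known limitations

Exact-ID variant matching only; no correlated-instrument (generalized) IVW,
mode-based estimators or outlier tests beyond $Q$ (MR-PRESSO and friends are
out of scope); the Egger intercept test is mildly anticonservative when
pleiotropy adds *additive* heterogeneity that the multiplicative
random-effects model mis-specifies; and the analytic power formulas are
asymptotic approximations that inherit the $1/F$ attenuation of the
estimators they describe, so empirical power sits a point or two below the
formula in weak-instrument corners of the design space.
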