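---
title: "Methods: two-sample Mendelian randomization in ivmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in ivmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivmr)
```

## The model

Two-sample MR treats genetic variants as instrumental variables. For
instrument $j$, let $\gamma_j$ be its true effect on the exposure (in SD
units of the exposure per effect allele) and $\Gamma_j$ its true effect on
the outcome. If the variant affects the outcome only through the exposure,
$\Gamma_j = \theta\,\gamma_j$, where $\theta$ is the causal effect of one SD
of exposure. We observe $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$
from the exposure GWAS and $\hat\beta_{Yj} \sim N(\Gamma_j, \sigma_{Yj}^2)$
from an independent outcome GWAS. Three assumptions carry the
identification: the instrument is associated with the exposure (relevance),
independent of confounders, and has no direct path to the outcome
(exclusion). The estimators in this package differ in how much of the third
assumption they are willing to relax.

Horizontal pleiotropy enters as a direct effect $\alpha_j$, giving
$\Gamma_j = \theta\gamma_j + \alpha_j$. IVW assumes all $\alpha_j = 0$;
MR-Egger allows a nonzero mean $\alpha$ provided the direct effects are
independent of instrument strength (InSIDE); the weighted median tolerates
up to half the weight coming from invalid instruments; MR-PRESSO hunts for
individual violators.

## Harmonization

All estimators consume a `harmonized_set`, in which each variant's exposure
and outcome effects refer to the same allele, chosen as the
exposure-raising allele (so every $\hat\beta_{Xj} > 0$; this is a labelling
convention, not a restriction — flipping an allele negates the effect and
complements the frequency, and `swap_alleles()` is an exact involution).

Outcome records are matched to the oriented exposure record in this order:
identical allele pair; swapped pair (effect negated, frequency
complemented, `flipped = TRUE`); strand-complement of either (summary files
differ in strand convention, so complementing is attempted before declaring
failure). Pairs that match none of these — for example A/G against A/C —
are dropped with reason `"allele mismatch"` rather than guessed at.

Palindromic variants (A/T or C/G) are strand-ambiguous: their complement is
the same pair, so allele labels cannot distinguish the two orientations.
The package resolves them by allele frequency, choosing the orientation
that minimizes $|\mathrm{EAF}_X - \mathrm{EAF}_Y|$, and refuses to resolve
a palindrome whose exposure minor-allele frequency is within
`palindrome_eaf_window` of 0.5 (dropped as `"ambiguous palindrome"`).
The default window of 0.08 — resolvable only when the exposure EAF is
outside [0.42, 0.58] — is a conventional safe margin: frequency estimates
in large GWAS are precise to well under a percentage point, but
cross-cohort frequency differences of a few points are common, so a band
of eight points keeps the flip/no-flip decision far from the noise. It is
exposed as a parameter because cohorts with known ancestry mismatch warrant
a wider band.

Instruments are assumed to arrive pre-pruned for linkage disequilibrium, as
instrument lists published with GWAS typically are; no LD step is
implemented, and positions are carried along but never used in computation.

## Estimators and their conventions

**IVW.** The inverse-variance weighted estimate is the weighted
through-origin regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with
weights $1/\sigma_{Yj}^2$. The default model is multiplicative random
effects: the fixed-effect SE $1/\sqrt{\sum \hat\beta_{Xj}^2/\sigma_{Yj}^2}$
is multiplied by $\max(1, \sqrt{Q/(k-1)})$, where $Q$ is the weighted
residual sum of squares. Overdispersion therefore widens the interval;
underdispersion is floored at 1 so sampling luck never *narrows* it. With a
single instrument the estimate reduces exactly to the Wald ratio.

**MR-Egger** fits the same regression with a free intercept. The slope
estimates $\theta$ under InSIDE; the intercept estimates the mean direct
effect. Standard errors come from the WLS information matrix, inflated by
$\max(1, \sqrt{Q_E/(k-2)})$ with $Q_E$ the residual sum of squares of the
Egger fit. Because the regression uses signed exposure effects, Egger is
only meaningful after orientation — the fitting functions refuse
non-positive $\hat\beta_{Xj}$.

**Confidence intervals and p-values** for IVW, Egger and the weighted
median use standard-normal quantiles ($\pm 1.96\,\mathrm{SE}$), the
convention of the established summary-data MR toolchain; degrees-of-freedom
corrections at $k \approx 10$ would widen them noticeably and are not what
practitioners report. The one deliberate exception: the MR-PRESSO raw and
corrected estimates keep a normal-based interval but take their p-value
from a Student-t reference with $k-1$ degrees of freedom, matching the
through-origin weighted regression that produces them (this is why an
MR-PRESSO p-value on the same data is slightly larger than the IVW one).

**Weighted median.** Per-variant ratios $r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
are ordered and assigned weights $w_j = (\hat\beta_{Xj}/\sigma_{Yj})^2$;
with running sums $S_j$, each ratio sits at standardized position
$p_j = (S_j - w_j/2)/S_{\text{total}}$, and the estimate interpolates $r$
against $p$ linearly at $p = 0.5$ (clamped to the extreme ratio when 0.5
falls outside the grid, so the estimate always lies within
$[\min r_j, \max r_j]$). Several interpolation conventions circulate; this
midpoint convention is the one used by the standard implementations. The SE
is a parametric bootstrap (default 1000 replicates, explicit seed):
exposure and outcome effects are redrawn from their sampling distributions
and the estimate — ratios *and* weights — recomputed; the SE is the SD of
the replicates.

**MR-PRESSO.** The observed statistic is
$\mathrm{RSS} = \sum_j \sigma_{Yj}^{-2}\,(\hat\beta_{Yj} -
\hat\theta^{(-j)}\hat\beta_{Xj})^2$ with $\hat\theta^{(-j)}$ the
leave-one-out fixed-effect IVW slope, so each variant is judged against a
fit it did not influence. The null distribution is simulated (default 1000
replicates, seeded): $\beta_{Xj}^* \sim N(\hat\beta_{Xj}, \sigma_{Xj})$,
$\beta_{Yj}^* \sim N(\hat\theta^{(-j)}\hat\beta_{Xj}, \sigma_{Yj})$, with
the leave-one-out slopes recomputed per replicate. Empirical p-values use
the $(1 + \#\{\cdot\})/(n_{\text{sim}} + 1)$ convention, so they are never
exactly zero and never smaller than $1/(n_{\text{sim}}+1)$. Per-variant
outlier p-values compare each observed weighted residual with its own
simulated distribution, flagged below $0.05/k$ (Bonferroni). When variants
are flagged, the corrected estimate refits without them and a distortion
test compares the raw-to-corrected shift against shifts from removing 1000
random subsets of the same size. Simulation counts below 100 are rejected
as meaningless.

**Heterogeneity.** Cochran's $Q$ is computed on the ratio scale around the
*fixed-effect* IVW estimate — the standard definition, independent of the
dispersion model used for reporting the IVW interval — with
$I^2 = \max(0, (Q - \mathrm{df})/Q) \cdot 100$. The $I^2$ confidence
interval is the Higgins–Thompson test-based interval on
$H = \sqrt{Q/\mathrm{df}}$: a normal interval for $\log H$ (large-$Q$ and
small-$Q$ standard-error formulas), back-transformed and truncated to
[0, 100]. With $k = 2$ and small $Q$ no standard error is defined and the
bounds degrade to the uninformative [0, 100].

## Instrument strength and power

Per-variant variance explained uses the F-statistic identity
$R^2_j = F_j/(F_j + n_j - 2)$, $F_j = (\hat\beta_{Xj}/\sigma_{Xj})^2$,
summed over instruments. A large-sample approximation with denominator
$\hat\beta^2 + 2 n \sigma^2$ is also provided (`method = "approx"`); it is
noticeably smaller for strong instruments (roughly half, since
$F \approx \hat\beta^2/\sigma^2$ dwarfs $n$ only rarely) and is included
for comparison with formulas of that shape, not as the default.

Binary-outcome power follows the non-centrality-parameter approximation of
the mRnd calculator: with case fraction $K$, odds ratio OR per SD of
exposure, and total sample size $N$, the attenuated slope is
$b = K\,(\mathrm{OR}/(1 + K(\mathrm{OR}-1)) - 1)$, its variance
$v = (K(1-K) - b^2)/(N R^2)$, and power is the noncentral
$\chi^2_1(b^2/v)$ tail beyond the central $\chi^2_1$ quantile at
$1-\alpha$. At OR = 1 this returns exactly $\alpha$. `detectable_or()`
inverts the curve by bisection (tolerance $10^{-6}$ on power) inside
(0.5, 1) for protective or (1, 2) for risk effects.

`pd_power_presets()` ships two case/control configurations for the bundled
example: the full PD case-control meta-analysis (56,306 cases, 1,417,791
controls) and the 14-study subset whose association statistics the outcome
fixture actually reports (33,674 cases, 449,056 controls). Power is a
design property of the instrument panel against the full phenotype
collection, so the full-meta preset is the default configuration for power
statements; the subset preset quantifies the sensitivity of those
statements to the available summary statistics. Power for a quantitative
outcome such as age at onset is not implemented: it needs
observational-regression coefficients (crude and confounder-adjusted) that
no public study provides for this exposure/outcome pair.

## The simulator

`sim_config()` / `simulate_study()` generate instrument-level summary
statistics with known ground truth: $\gamma_j$ uniform on a strictly
positive range (mirroring the harmonized orientation), direct effects
$\alpha_j$ that are zero (`none`), centred (`balanced`) or shifted
(`directional`, mean `pleiotropy_mean`), optionally correlated 0.5 with
$\gamma_j$ to break InSIDE (`inside_violation`), and observed effects drawn
from the sampling distributions above. Defaults emulate the bundled
instrument panel: $k = 11$, exposure effects in [0.036, 0.36], exposure SE
0.01 (a 52,018-sample exposure GWAS), outcome SE 0.15 (a ~30,000-sample
quantitative-outcome GWAS); SE arguments accept vectors to match a real
panel variant-by-variant. Simulated studies use the same TSV dialect and
flow through `harmonize()` exactly like real data (allele pairs are drawn
non-palindromic so no simulated variant is lost to frequency ambiguity).

What the simulator does *not* emulate: linkage disequilibrium between
instruments, winner's-curse bias in instrument selection, sample overlap
between the two GWAS, allele-frequency-dependent power, and non-normal
effect-size sampling. Passing operating-characteristic tests therefore
demonstrates correctness of the estimators under the stated sampling model,
not robustness to those real-data pathologies.

`operating_characteristics()` summarizes bias, empirical SE, CI coverage
and rejection rate over seeded replicates. The test suite exercises it at
1000 replicates for IVW size and coverage, 500 for Egger-intercept
recovery of planted pleiotropy, and 200 studies (500 null simulations
each) for the MR-PRESSO global-test size — sizes chosen to put
Monte-Carlo noise well inside the asserted bands while keeping the default
suite quick on a laptop.

## Numerical choices and degenerate inputs

- Dispersion inflation factors are floored at 1 everywhere (IVW, Egger,
  MR-PRESSO raw/corrected), so no interval is ever *shrunk* by observed
  underdispersion.
- Empirical p-values use the add-one convention; analytic p-values are
  floored at the smallest positive double so that "p in (0, 1]" holds even
  for astronomically strong signals, and a zero outcome effect gives
  p = 1 exactly.
- A Wald ratio with a zero exposure effect is an error, not an Inf;
  degenerate weights (all-zero exposure signal) abort rather than return
  NaN.
- The weighted-median grid uses ordered ties (`ties = "ordered"`), so
  duplicated ratios are handled deterministically.
- `harmonize()` refuses to return an empty set: zero retained variants is
  an error naming the cause, since every downstream estimator would be
  undefined.
- Seeds: every stochastic routine takes an explicit seed; pipeline-level
  runs derive sub-seeds deterministically from the master seed (outcome
  index offsets for `run_analysis()`, `seed`/`seed + 1` for the
  weighted-median bootstrap and MR-PRESSO inside one fit), so whole reports
  are reproducible digest-for-digest.

## Known limitations

- No LD clumping, proxy lookup or liftover: instruments must arrive
  independent and on a shared genome build.
- First-order Wald-ratio SEs ignore exposure measurement error (the NOME
  approximation); with very weak instruments the intervals are
  anti-conservative, and no weak-instrument correction (e.g. simulation
  extrapolation) is provided.
- Mode-based estimators, multivariable MR and robust/penalized IVW
  variants are out of scope.
- The I² interval for k = 2 with small Q is reported as [0, 100] rather
  than by a specialised small-sample method.

```{r example}
paths <- vitc_pd_example()
h <- harmonize(read_associations(paths$exposure),
               read_associations(paths$pd_aao))
summary(mr_fit(h, seed = 42))
```
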