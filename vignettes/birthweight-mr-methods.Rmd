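---
title: "Methods: two-sample Mendelian randomization of birth weight"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization of birth weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`bwmr` estimates the causal effect of birth weight on ischemic heart
disease (IHD), myocardial infarction (MI) and blood lipids using genetic
variants as instrumental variables. Genotypes are allocated at conception,
so SNPs that robustly raise birth weight define a quasi-randomized contrast
that is immune to the confounding that plagues observational birth-weight
epidemiology — provided three assumptions hold for each instrument j: it
predicts the exposure (relevance), it shares no confounder with the
outcome, and it affects the outcome only through the exposure (exclusion
restriction).

The design is two-sample: SNP–exposure associations
$(\hat\beta_{Xj}, \sigma_{Xj})$ come from a birth-weight GWAS (z-score
units per allele), SNP–outcome associations
$(\hat\beta_{Yj}, \sigma_{Yj})$ from independent case-control or lipid
consortia (log-odds or SD units per allele). Under a linear homogeneous
structural model with causal effect $\theta$,

$$\hat\beta_{Yj} \approx \theta\,\gamma_j + \alpha_j + \text{noise},
  \qquad \hat\beta_{Xj} \approx \gamma_j + \text{noise},$$

where $\gamma_j$ is instrument j's true exposure effect and $\alpha_j$ its
direct (pleiotropic) path, zero for a valid instrument. The package's four
estimators make progressively weaker demands on the $\alpha_j$.

## Per-SNP Wald ratios and Fieller's theorem

Each SNP yields $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$. A ratio of
normals has no finite moments, so the per-SNP confidence set is taken from
Fieller's theorem: all $g$ with
$(\hat\beta_{Yj} - g\hat\beta_{Xj})^2 \le z^2(\sigma_{Yj}^2 +
g^2\sigma_{Xj}^2)$, the covariance term being zero because the two samples
do not overlap. The quadratic's leading coefficient
$\hat\beta_{Xj}^2 - z^2\sigma_{Xj}^2$ and discriminant decide the case:

* **bounded** interval when the instrument is individually significant at
  level $\alpha$ ($|\hat\beta_{Xj}| > z\sigma_{Xj}$) — the only case that
  yields a usable weight;
* **exclusive** (complement of an interval) or **unbounded** (the whole
  line) for weak instruments — surfaced as diagnostics, never silently
  converted to numbers.

Fieller's theorem yields an interval rather than a variance, but the
pooling step needs a variance. The package derives it as
$\big((\text{upper}-\text{lower})/2z\big)^2$ from a bounded interval — the
variance of the normal distribution whose $1-\alpha$ interval has that
width. The first-order delta variance $\sigma_{Yj}^2/\hat\beta_{Xj}^2$ is
available as `weight_scheme = "first_order_delta"`; for strong instruments
the two agree (the package tests require agreement of interval half-widths
to 5% when $|\hat\beta_{Xj}|/\sigma_{Xj} > 10$), and both weight schemes are
run when reproducing published tables since reports rarely state which was
used. Unbounded cases under Fieller weights raise an error naming the SNP
and pointing to the fallback, because quietly substituting a weight would
misstate the precision.

## Pooled estimators

**IVW (fixed effects).** $\hat\theta = \sum w_j\hat\theta_j / \sum w_j$
with $w_j = 1/\mathrm{var}_j$, $\mathrm{SE} = (\sum w_j)^{-1/2}$. Fixed
effects encode the homogeneity assumption of one causal effect. With
first-order weights this is algebraically the slope of a zero-intercept
regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ weighted by
$1/\sigma_{Yj}^2$ (a tested invariant).

**MR-Egger.** The same regression with a free intercept, after orienting
every instrument so $\hat\beta_{Xj} > 0$. The intercept estimates the
average directional pleiotropic effect; its two-sided test is the
directional-pleiotropy screen. Inference uses a Student t reference with
$J-2$ degrees of freedom (configurable to normal): the residual variance is
estimated from as few as 5 points in the 7-SNP analysis, and a normal
reference would overstate precision. Validity requires InSiDE (pleiotropy
independent of instrument strength) *and* negligible exposure-side
measurement error relative to the spread of the $\gamma_j$ (the
$I^2_{GX}$ condition); with a compressed strength spread the slope
attenuates and the intercept absorbs the difference, which is why the
Egger row of a small-J analysis should be read as a sensitivity check, not
a primary estimate.

**Weighted median.** Instruments are ordered by $\hat\theta_j$; with
normalized information weights $w'_j = (\hat\beta_{Xj}^2/\sigma_{Yj}^2) /
\sum_k(\cdot)$ the estimate interpolates the ratio at cumulative midpoint
$s_j = \sum_{k\le j} w'_k - w'_j/2 = 1/2$. It is consistent whenever valid
instruments carry more than half the information. When a single SNP's
share exceeds `dominance_threshold` (default 0.5) that guarantee is vacuous
and the result is reported *not available* — a first-class result state
rendered "N/A", not an error, so sensitivity grids always complete. This
occurs for the 2-SNP subset, where the strongest birth-weight locus
dominates its companion. The SE is a parametric bootstrap (resample
$\hat\beta_{Xj}, \hat\beta_{Yj}$ from normals at the observed values and
SEs, 10,000 replicates, fixed default seed 20161207 so results are
bit-reproducible); ties in the ratio ordering are broken by rsid to keep
the sort stable.

## Harmonization

Exposure and outcome tables are joined on rsid and aligned to the
exposure's effect allele: matching alleles pass through (`aligned`),
swapped effect/other alleles negate the outcome beta (`flipped`), strand
complements are complemented first, and anything else is
`allele_mismatch`. Palindromic variants (A/T, G/C) are special: both strand
readings show the same two letters, so orientation is inferred from allele
frequencies — concordant sides of 0.5 mean aligned, discordant mean
flipped — and the variant is excluded as `palindromic_ambiguous` when
either frequency is missing or lies within ±0.08 of 0.5 (configurable).
The window is a deliberate package rule: the 7 curated instruments were
extracted manually in the original analysis and the issue never arose
there, but arbitrary inputs need a stated policy, and ±0.08 keeps the
misorientation probability low at consortium sample sizes without
discarding clearly one-sided variants. Exposure SNPs absent from an
outcome are reported and the analysis proceeds on the intersection with
the effective J logged; nothing is dropped silently.

Instruments are assumed mutually independent (they come from distinct
loci); an optional user-supplied pairwise $r^2$ table triggers a warning
above $r^2 > 0.05$ but no adjustment — LD-aware MR is out of scope.

## Instrument subsets and annotations

The five named subsets drive the sensitivity analyses: all 7 genome-wide
significant SNPs; 5 after removing the height-associated loci (LCORL,
HMGA2); 4 after also removing the blood-pressure locus (ADRB1); 2 after
also removing the diabetes loci (CDKAL1, ADCY5); and 10 adding three SNPs
at the relaxed $p < 10^{-5}$ threshold. A packaged TSV of (rsid,
trait_tag) pairs records the curation; users may substitute their own.

## Unit conversion

Exposure effects are in birth-weight z-score units. For interpretability
estimates are rescaled to 100-gram units assuming SD(birth weight) = 484 g:
estimates, SEs and CI bounds multiply by 100/484, and odds ratios become
$\exp(\beta_{\text{per SD}} \times 100/484)$. The Egger intercept is in
outcome units per allele and is therefore untouched by exposure rescaling.
Double conversion is refused.

## The synthetic generator

`sim_scenario()`/`sim_generate()` draw summary statistics directly at the
summary level: $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$,
$\hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2)$ with
independent noise, encoding the separate-sample design. Pleiotropy regimes:
none, balanced ($\alpha_j \sim N(0,\tau^2)$), directional
($N(\mu_\alpha, \tau^2)$), and InSiDE-violating ($\alpha_j$ correlated
with $\gamma_j$). Defaults are chosen to look like the study's data:
per-allele exposure effects 0.03–0.09 z-score units with SEs around 0.006
(a ~70k-sample exposure GWAS) and outcome SEs around 0.012 (a ~180k
case-control meta-analysis), spanning instrument F-statistics from weak to
strong.

The packaged 7-SNP dataset (`paperlike_fixture()`, `paperlike_tables()`)
uses the real instrument rsids and curation so every named subset
resolves, per-allele strengths with the known ordering (the CCNL1 locus by
far the strongest — which is what makes the 2-SNP weighted median
unavailable), and true effects equal to the reported association
magnitudes: $\theta = -0.2$ per SD for IHD/MI
($\ln 0.96 \times 484/100 = -0.198$), $-0.068/-0.046/-0.004$ per SD for
HDL/LDL/triglycerides. All numbers are generated from fixed seeds and are
clearly synthetic: agreement of the pipeline's output with the published
tables to the printed digit requires the actual consortium per-SNP
extracts, which users must supply themselves.

What the generator does **not** model — and therefore what passing tests
do not certify about real data: LD between instruments, sample overlap
between exposure and outcome studies, winner's-curse in instrument
selection, allele-frequency-dependent SEs, population stratification, and
non-collapsibility of odds ratios (the generator treats the log-odds
outcome scale as exactly linear in the exposure).

## Simulation study design

The operating-characteristics runs use replicate counts sized so
Monte-Carlo SEs resolve the contrasts of interest: 2000 replicates for the
type-I error of IVW at $\theta = 0$ (MC SE of a 5% rate: 0.5 points), 1000
for unbiasedness at $\theta = 0.3$, 500 for the pleiotropy-robustness
contrast, 300 for the mean Egger intercept under InSiDE. For the
unbiasedness scenario the exposure-side SE is set to 0.0015 against a
strength spread of 0.03–0.09 so that $I^2_{GX} > 0.99$: "valid
instruments" is taken to mean *all* of each estimator's assumptions hold,
and MR-Egger's no-measurement-error condition is part of its validity —
with larger exposure noise the Egger row would measure regression dilution
rather than implementation error. Weighted-median SEs inside simulations
use a reduced 200-replicate bootstrap; the point estimate, which drives
bias measurements, does not depend on the bootstrap at all.

## Numerical choices and degenerate inputs

* When the Fieller leading coefficient is positive the discriminant is
  provably positive (it equals
  $4z^2[\sigma_{Yj}^2(\hat\beta_{Xj}^2 - z^2\sigma_{Xj}^2) +
  \sigma_{Xj}^2\hat\beta_{Yj}^2]$), so the bounded case never needs a
  guard against a negative square root.
* $\hat\beta_{Xj} = 0$ gives an undefined ratio: flagged, excluded from
  funnel data with a message, and fatal only under Fieller weights.
* Standard errors must be strictly positive at ingestion; violations name
  the rsid and line number.
* The weighted-median cumulative function is piecewise linear; the
  interpolation is clamped to the extreme ratios when 1/2 falls outside
  the midpoints (possible at J = 2 with lopsided weights).
* All bootstrap and simulation code restores or namespaces the RNG so a
  fixed seed gives bit-identical output and library calls do not disturb
  the caller's RNG stream; grid reruns are byte-identical on disk.

## Known limitations

Estimates inherit every limitation of the underlying summary statistics
(genomic control, ancestry mix, overlap the consortia do not disclose).
The fixed-effect IVW offers no heterogeneity-robust variance; the paper's
design is reproduced deliberately, so random-effects IVW, modal
estimators and outlier-removal procedures are out of scope. MR-Egger at
J = 7 is weakly identified and its intercept screen is under-powered —
the funnel-plot export exists precisely because visual inspection is the
honest complement at this scale.
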