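---
title: "Methods: two-sample Mendelian randomization from summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization from summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the design

Observational associations between age at menarche and time spent in
education are confounded by obesity, family structure and socio-economic
factors. Mendelian randomization (MR) sidesteps this by using genetic
variants as instrumental variables: genotypes are fixed at conception, so a
SNP that shifts age at menarche can affect education only through that shift
— provided it has no other pathway to the outcome (no pleiotropy).

`mrsummary` implements the two-sample summary-statistics form of this
design. The inputs are two GWAS association tables over a shared instrument
panel: per-allele effects on the exposure (age at menarche, years) from one
sample of women, and per-allele effects on the outcome (time in education,
SD units) from a non-overlapping sample. Nothing individual-level is needed.

## Model and estimators

For instrument $i$, write $\gamma_i$ for the SNP-exposure effect and
$\Gamma_i$ for the SNP-outcome effect, with estimates $\hat\gamma_i$ (SE
$\sigma_{x,i}$) and $\hat\Gamma_i$ (SE $\sigma_{y,i}$). Under an additive
model with no interactions, a valid instrument satisfies
$\Gamma_i = \beta\,\gamma_i$, and each SNP yields a Wald ratio estimate

$$\hat\beta_i = \hat\Gamma_i / \hat\gamma_i.$$

Its SE comes from the Delta method. Both expansion orders are available:
first order, $\sigma_{y,i}/|\hat\gamma_i|$, and second order (the default),
$\sqrt{\sigma_{y,i}^2/\hat\gamma_i^2 +
\hat\Gamma_i^2\sigma_{x,i}^2/\hat\gamma_i^4}$, which keeps the
exposure-uncertainty term. The exposure–outcome covariance is fixed at zero:
the two samples do not overlap. The first order exists because it makes the
IVW estimator algebraically identical to a zero-intercept weighted
least-squares regression of $\hat\Gamma$ on $\hat\gamma$ with weights
$\sigma_y^{-2}$, which the test suite exploits as an oracle.

**Fixed-effect IVW.** The per-SNP ratios are pooled with inverse-variance
weights $w_i = \text{se}(\hat\beta_i)^{-2}$:
$\hat\beta = \sum w_i\hat\beta_i / \sum w_i$, with
$\text{se}(\hat\beta) = (\sum w_i)^{-1/2}$, a 95% normal CI (multiplier
1.959964, not the rounded 1.96) and a two-sided normal p-value, the standard
large-sample convention for fixed-effect meta-analysis.

**Heterogeneity.** Cochran's
$Q = \sum w_i(\hat\beta_i - \hat\beta)^2$ on $n-1$ degrees of freedom
measures between-instrument dispersion;
$I^2_{MR} = \max\{0, 100\,(Q - df)/Q\}$ expresses it as the percentage of
variation beyond chance and serves as a pleiotropy proxy (flagged when
above 25%). The 95% CI uses the test-based method of Higgins & Thompson on
$\ln H$, $H = \sqrt{Q/df}$, back-transformed and truncated to $[0, 100]$.
With a single instrument the heterogeneity fields are absent, never zero:
a diagnostic that cannot be computed is not fabricated.

**Units.** A pooled effect in SD units of education is converted with
`units_to_days()`: SD × 3.6 years × 365.25 days/year, with the exact value
in years kept alongside the rounded day count.

## Sensitivity analyses

**MR-Egger.** Weighted regression of $\hat\Gamma_i$ on $\hat\gamma_i$ with
a free intercept (weights $\sigma_y^{-2}$). The slope is a causal estimate
robust to directional pleiotropy under the InSIDE assumption (pleiotropic
effects independent of instrument strength); the intercept estimates the
average direct effect per allele. Because the fit is not invariant to which
allele each SNP is coded on, instruments are re-oriented so every
$\hat\gamma_i \ge 0$ (flipping $\hat\Gamma_i$ jointly) before fitting — the
exposure-increasing-allele convention. Standard errors use a multiplicative
residual scale floored at 1 (overdispersion inflates them, underdispersion
earns no credit), with t-based inference on $n-2$ degrees of freedom, the
convention of the Egger-regression literature. The $I^2_{GX}$ statistic —
the meta-analytic $I^2$ of the $\hat\gamma_i$ themselves — quantifies
regression dilution from exposure measurement error; values near 100% mean
the Egger slope is essentially undiluted.

**Weighted median.** The per-SNP ratios are ordered and the 50th weighted
percentile taken, placing each order statistic at its centred cumulative
weight $(S_j - w_j/2)/S_n$ and interpolating linearly at 0.5; with equal
weights this reduces exactly to the ordinary interpolated median, and ties
are broken by a stable sort. The estimator is consistent while at least
half the total weight comes from valid instruments. Its SE is a parametric
bootstrap: each replicate redraws
$\hat\gamma_i^* \sim N(\hat\gamma_i, \sigma_{x,i})$ and
$\hat\Gamma_i^* \sim N(\hat\Gamma_i, \sigma_{y,i})$ independently and
recomputes everything, weights included. The default is 10,000 replicates
with a mandatory, recorded seed. The reported CI is the normal
approximation (the percentile interval is attached for comparison); which
of the two a published CI used is generally unstated, so exact digit-level
replication of a bootstrap CI is stochastic by nature.

**Exclusion rerun.** `exclude_snps()` removes a caller-supplied list —
e.g. instruments also associated with BMI at genome-wide significance — and
the estimators re-run unchanged on the reduced panel. The package accepts
any list rather than re-deriving trait overlaps itself.

**Unweighted allele score.** IVW pooling of the outcome effects alone
(weights $\sigma_y^{-2}$) on the exposure-increasing orientation. Because
the exposure effect sizes enter only through orientation, discovery-stage
inflation of $\hat\gamma$ ("winner's curse") cannot bias it — but the
pooled value is a per-allele association, a test statistic, never a causal
magnitude.

**Male negative control.** Men do not undergo menarche, so the same allele
score computed on male outcome statistics should find nothing. The
comparison passes when the women's score is significant at $\alpha = 0.05$
and the men's is not. Identical inputs for both populations therefore fail
by construction, which the tests use as the control of the control.

## Harmonization

Two GWAS sources rarely agree on effect alleles or strand. For each shared
SNP the outcome estimate is aligned to the exposure's effect allele:
swapped alleles flip the sign, strand complements are resolved via base
pairing, and irreconcilable pairs are excluded with a reason code.
Palindromic SNPs (A/T, C/G) are ambiguous from the alleles alone; the
default policy aligns them by effect-allele frequency with an ambiguity
window — either frequency in (0.42, 0.58), or missing, drops the SNP. This
is the conservative community convention; `drop` and `keep` policies are
available. Finally all instruments are jointly re-oriented to
$\hat\gamma_i \ge 0$, which leaves every ratio invariant (a property the
tests verify with a scrambling round-trip oracle: randomly swapping and
strand-complementing allele encodings must reproduce the identical per-SNP
ratios after harmonization). Every action — kept, flipped,
strand-complemented, excluded and why — lands in a per-SNP report, because
allele bookkeeping is the least auditable step of summary-statistics MR.
SNPs present in only one source are excluded and reported; proxy lookup is
out of scope.

## The synthetic generator

`simulate_gwas()` produces datasets with known truth so that every
estimator is testable without any external download. Per SNP: a minor
allele frequency from $U(\text{maf range})$; a true exposure effect
$\gamma_i = |N(0, \texttt{gamma\_sd})|$ oriented positive; a direct effect
$\alpha_i$ under one of four pleiotropy models (`none`; `balanced`,
zero-mean; `directional`, nonzero mean with InSIDE holding;
`inside_violating`, correlated 0.7 with $\gamma_i$); the true outcome
effect $\Gamma_i = \beta\gamma_i + \alpha_i$. Standard errors follow the
unit-variance-trait approximation $1/\sqrt{2N\,\text{maf}(1-\text{maf})}$
and observed estimates are independent normal draws around the truth — two
non-overlapping samples by construction, no overlap parameter. With
`selection_p` set, only SNPs whose *observed* exposure p-value clears the
threshold are retained, which reproduces winner's curse mechanically: the
selected $|\hat\gamma_i|$ overshoot their $\gamma_i$ on average, most
strongly for marginal instruments. All randomness flows from one explicit
seed, the global RNG state is restored on exit, and the same truth yields
byte-identical files.

**The paper-like preset** (`sim_truth_paper()`) fixes the study geometry:
122 candidate SNPs, exposure GWAS of 182,416 women, outcome GWAS of
118,443 women, causal effect 0.045 SD/year, genome-wide selection at
5×10⁻⁸. The effect-size spread (`gamma_sd = 0.045`) and balanced
pleiotropy (`sd = 0.0042`) are calibrated, not derived — no generative
parameters exist to copy, only the observable geometry they must
reproduce: after selection roughly 75–85 instruments survive, all with
F ≥ ~30, median F near 140, and the between-instrument $I^2_{MR}$ of the
Wald ratios lands in the mid-40s percent. Selection is kept on because the
study's instruments were themselves discovery-stage selections (all
F ≥ 25); the cost is that fewer than 122 instruments remain, which we
consider the better trade against a panel padded with weak instruments the
study did not have.

What the generator does **not** emulate: linkage disequilibrium between
instruments (all independent), population stratification, secular birth-year
trends, allele-frequency differences between the two samples, and
measurement properties of self-reported phenotypes. Passing tests therefore
validate the estimators under the stated sampling model, not robustness to
those real-data features.

## Numerical choices and degenerate inputs

- CI multiplier `qnorm(0.975)` at full precision; rounding happens only in
  print methods.
- Generated p-values are floored at the smallest positive double — very
  strong associations would otherwise underflow to 0, violating the (0, 1]
  domain of a p-value.
- `wald_ratio()` refuses $\hat\gamma_i = 0$ by name; in the bootstrap,
  resampled $\hat\gamma^*$ exactly 0 (a measure-zero event) is nudged by
  machine epsilon so the replicate stays defined.
- An exact linear fit gives MR-Egger a residual scale of 0; its zero
  standard errors are kept rather than divided into NaN.
- Weighted-percentile ties are broken by a stable radix sort, so instrument
  order cannot affect the median.
- `Q` needs two estimates, MR-Egger three; both refuse smaller inputs
  rather than degrade silently.

## Validation design and its limits

The test suite checks each estimator against an independent oracle:
IVW against zero-intercept WLS and against an external fixed-effect
meta-analysis routine; the second-order Delta SE against a 10⁶-draw
Monte-Carlo SD; Q against its χ² mean; coverage, Egger bias correction,
intercept test size and weighted-median breakdown against simulations with
known truth (1000–2000 replicates each, instrument panels of 20–100 SNPs —
sizes chosen so the full suite runs in a few minutes while keeping
Monte-Carlo error well under the asserted margins).

Two limitations are worth stating plainly. First, the second-order Delta SE
undershoots the true ratio SD by a relative factor of roughly $1.5/F$: about
1% at F = 150, 2.3% at F = 64, ~6% at F = 25. The Monte-Carlo comparisons
are therefore run in the strong-instrument regime (F ≥ 100) where the
expansion is within 2%; for the weakest acceptable instruments the reported
SEs are mildly anti-conservative. Second, the weighted median is only
*consistent* under a valid-weight majority: its finite-sample bias under
40% invalid weight is about one ratio-SE, so the breakdown simulations use
very large GWAS sizes to sit near the asymptote; at realistic sample sizes
the estimator tolerates the same invalid fraction with proportionally wider
error, not with the same 5% bias bound.

Random-effects and overdispersed IVW variants, mode-based estimators,
outlier-removal procedures and multivariable MR are deliberately out of
scope; the analysis surface is fixed-effect IVW plus the five sensitivity
analyses above.
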