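---
title: "Two-sample MR with two-step mediation: models, parameters and design"
author: "TwoStepMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR with two-step mediation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TwoStepMR)
```

## The statistical problem

Two-sample Mendelian randomization (MR) estimates the causal effect of a
modifiable exposure $X$ on an outcome $Y$ from two independent GWAS: one
reporting per-variant associations $(\hat\beta_{Xj}, \sigma_{Xj})$ with
the exposure, one reporting $(\hat\beta_{Yj}, \sigma_{Yj})$ with the
outcome. If a variant $j$ satisfies the instrumental-variable
assumptions — associated with $X$, independent of confounders, affecting
$Y$ only through $X$ — then $\beta_{Yj} = \theta\,\beta_{Xj}$ and the
per-variant Wald ratio $\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the
causal log-effect $\theta$. For a binary outcome the effects are
log-odds ratios and $e^\theta$ is the causal odds ratio.

`TwoStepMR` implements the full pipeline around this idea — instrument
selection, harmonization, five estimators, diagnostics, multi-exposure
screening with reverse-MR gating — and, on top of it, **two-step
mediation MR**: given an exposure, a candidate mediator $M$ and the
outcome, three MR analyses give
$\beta_1$ ($X \to M$), $\beta_2$ ($M \to Y$) and $\beta_{all}$
($X \to Y$, the total effect), and the product-of-coefficients rule
decomposes

$$\text{indirect} = \beta_1\beta_2, \qquad
  \text{direct} = \beta_{all} - \beta_1\beta_2, \qquad
  \text{proportion mediated} = \beta_1\beta_2/\beta_{all}.$$

The decomposition presumes no causal path from mediator back to
exposure; the pipeline tests this by reverse MR and flags (rather than
silently accepts) violations.

## Instrument selection

Selection mirrors standard practice for molecular-trait exposures:

| step | rule | default |
|---|---|---|
| association screen | $p <$ `p_threshold` | $10^{-5}$ |
| LD clumping | greedy, best p first; drop same-chromosome variants within `window_kb` with $r^2 >$ `r2_max` | 10000 kb, 0.001 |
| allele frequency | min(eaf, 1−eaf) > `maf_min`, strict | 0.01 |
| weak instruments | per-variant $F \ge$ `f_min` | 10 |

The $F$ statistic is $F = R^2(N-K-1)/\{K(1-R^2)\}$ with $R^2$ the
cumulative exposure variance explained, $K$ the instrument count and $N$
the exposure sample size. The per-variant $R^2$ feeding it is
$2p(1-p)\beta^2$ for a variance-standardized trait (frequency $p$,
per-allele effect $\beta$); when the frequency is missing the summary
approximation $\beta^2/(\beta^2 + N\sigma^2)$ is used and flagged. The
weak-instrument rule is applied per variant ($K=1$) before the set-level
$F$ is computed, because removal is defined variant-wise.

Clumping takes an explicit LD matrix as input rather than an external
reference panel: the algorithm is unchanged, but the package carries no
hidden dependency on a genotype resource, and the synthetic-data module
generates matched LD. Ties in the greedy ordering are broken
lexicographically by variant id so results cannot depend on input row
order.

## Harmonization

Exposure and outcome records are aligned to a shared effect allele:
direct matches are kept; swapped alleles negate the outcome effect and
complement its frequency; complementary-strand codings are flipped
first. Palindromic variants (A/T, C/G) cannot be oriented from alleles
alone. Under the default `infer_by_eaf` policy they are oriented by
comparing which side of 0.5 the two studies' frequencies fall on and
dropped when either study's minor-allele frequency exceeds
`ambiguity_maf = 0.42` (or when a frequency is missing); `drop_all`
removes them outright. These choices mirror the de-facto conventions of
the established two-sample-MR tooling. Indels and multi-allelic records
are rejected at load: the pipeline is SNP-based. Every drop is counted
with a reason, and retained + dropped always equals the id
intersection.

## The five estimators

All estimators act on the harmonized pairs; each returns beta, SE, a
two-sided p, and $e^\beta$ with a 95% interval
$e^{\beta \pm 1.96\,\mathrm{se}}$.

* **IVW** — weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin, weights $1/\sigma_Y^2$. The default error model is
  multiplicative random effects: the fixed-effect SE is inflated by
  $\sqrt{\max(Q/(k-1), 1)}$, never deflated, so homogeneous data reduce
  to the fixed-effect analysis. A single variant degenerates to the Wald
  ratio with first-order SE $\sigma_Y/|\hat\beta_X|$.
* **MR-Egger** — the same regression with a free intercept, after
  orienting each variant so $\hat\beta_X \ge 0$. The slope is the causal
  estimate; the intercept estimates directional pleiotropy, and its
  t-test (df $k-2$) is the pleiotropy diagnostic. p-values use the t
  distribution on $k-2$ df, matching the reference implementations;
  the residual-dispersion floor at 1 is shared with IVW.
* **Weighted median** — the interpolated weighted median of the Wald
  ratios with weights $(\hat\beta_X/\sigma_Y)^2$; consistent when at
  least half the weight comes from valid instruments.
* **Simple and weighted mode** — the argmax of a Gaussian-kernel density
  over the ratios, uniform or inverse-variance weights, bandwidth
  $\phi \cdot 0.9\min(\mathrm{sd}, \mathrm{IQR}/1.349)\,k^{-1/5}$ with
  $\phi = 1$ by default; the density is maximized over the ratios
  refined by a 1000-point grid across their range. If all ratios
  coincide the common ratio is returned with SE 0 and a flag.

Median and mode SEs come from a seeded parametric bootstrap
(`n_boot = 1000` by default): effects are redrawn from
$N(\hat\beta, \sigma^2)$ per variant and the estimator recomputed. The
seed is explicit everywhere; the bootstrap restores the caller's RNG
state.

Panels dispatch by instrument count: one variant gives the Wald ratio
only, two give IVW, three or more give all five methods plus Cochran's
Q (IVW and Egger references), the Egger intercept and leave-one-out.
Skipped methods are listed with reasons rather than omitted silently.

## Screening and reverse-MR gating

Multi-exposure screens apply three rules per exposure: IVW
$p <$ `ivw_p_max` (0.01 for the primary exposures, 0.001 for mediator
candidates), Egger-intercept $p >$ 0.05, and direction consistency of
all methods' odds ratios (all above or all below 1; a beta of exactly 0
counts as inconsistent, and a panel whose intercept is untestable fails
the pleiotropy rule rather than passing silently). No multiple-testing
correction enters selection — the raw-threshold design is replicated
deliberately — but a Benjamini–Hochberg FDR column is emitted in every
screen report for transparency. Selected exposures are gated by reverse
MR (outcome as exposure): the gate passes when the reversed IVW
$p \ge 0.05$, and a reversed trait with no derivable instruments is
flagged `untestable`, never silently passed.

## Mediation uncertainty

The delta-method SE of the indirect effect is
$\sqrt{\beta_1^2\sigma_2^2 + \beta_2^2\sigma_1^2}$, the classical
companion of the coefficient-product method; the indirect effect is
tested against zero with a normal test. The proportion's interval
propagates $\mathrm{se}_{\text{ind}}/|\beta_{all}|$ treating
$\beta_{all}$ as fixed — the simplest defensible propagation;
`full_delta = TRUE` adds the total effect's uncertainty
($\sqrt{\sigma_{\text{ind}}^2/\beta_{all}^2 +
\text{ind}^2\sigma_{all}^2/\beta_{all}^4}$). When indirect and total
effects disagree in sign the proportion can leave $[0,1]$; the result
carries an `inconsistent mediation` flag instead of being clipped.
`direct + indirect = beta_all` holds by construction and is enforced by
the class validity check.

## What the synthetic generator emulates — and what it does not

`simulateStudy()` draws a variant panel (frequencies uniform on
`maf_range`, default 0.10–0.40; alleles uniform over ordered base
pairs, palindromes included) and generates the three tables directly on
the summary-statistic scale:

* exposure: spike-and-slab architecture — `prop_causal` (default 8.5%)
  of variants carry an effect with magnitude uniform on `slab_range`
  (default 0.10–0.25, random sign) — observed with noise at
  $\mathrm{se} = 1/\sqrt{2p(1-p)\,n}$;
* mediator: $\theta_{XM}\beta_X$ plus mediator-specific effects on an
  independent 5.5% of variants (magnitudes 0.12–0.30), so mediator
  instruments exist that are not exposure instruments and reverse-MR
  checks are meaningful;
* binary outcome on the log-odds scale:
  $(\theta_{XM}\theta_{MY} + \theta_{XY}^{\text{direct}})\beta_X +
  \theta_{MY}\alpha_M$ plus optional per-variant pleiotropy
  (`pleiotropy_sd`, mean `directional_pleiotropy_mean`), with
  case-control SEs using $n_{\text{eff}} = 4/(1/\text{cases} +
  1/\text{controls})$;
* LD: block-diagonal from `ld_blocks` (default 5-variant blocks at
  $r^2 = 0.3$), blocks separated far beyond the clumping window.

The default sample sizes are the study conditions the package targets:
a specialized lipid GWAS (n = 7174), a metabolite GWAS (n = 8000) and a
rare disease outcome (98 cases, 218,694 controls,
$n_{\text{eff}} \approx 392$). The bounded uniform effect magnitudes
emulate the *selected-instrument* regime of molecular-trait GWAS, where
published instruments are large-effect QTLs; they keep exposure
instruments detectable in the exposure study but not in the
under-powered outcome study, which is exactly the regime in which
reverse MR of a rare outcome is untestable or null.

The generator does **not** simulate individual-level genotypes, sample
overlap between the two GWAS, winner's-curse bias of instrument
selection performed in the same cohort, population stratification,
assortative mating, or LD beyond the block structure. Passing tests
therefore certify the estimation machinery under clean two-sample
assumptions, not robustness to those real-data pathologies.

`exampleStudy()` is the bundled fixed-seed fixture: true effects chosen
so the three true odds ratios are 1.059, 4.295 and 1.962 (true
proportion mediated 12.40%), with the planted architecture sized so the
default pipeline retains close to 28 exposure and 18 mediator
instruments. `exampleRunConfig()` adds four null lipids and two null
metabolites so a full `runStudy()` exercises screening, gating and
mediation and yields exactly one decomposition.

## Numerical and design choices

* Exposure cohort size: the targeted lipid GWAS literature reports both
  a 771-person cohort and n = 7174 for the lipid species; the generator
  adopts 7174 because a 771-person exposure would make every detectable
  instrument also detectable in the outcome, collapsing the
  forward/reverse asymmetry the pipeline relies on.
* The recovery experiments in the test suite run at deliberately
  well-powered sizes so they measure the machinery rather than outcome
  noise: estimator calibration at 50 instruments with
  $\sigma_Y = 0.01$ (200 replicates per effect size, 5000 under the
  null); mediation recovery over the
  $(\theta_{XM}, \theta_{MY}, \theta_{XY}) \in \{0.1,0.3,0.5\}^3$ grid
  at 100 candidate variants and n = 10,000 for all three GWAS (balanced
  outcome), three replicates per cell.
* p-values are clamped into $(0, 1]$; simulated p-values are floored at
  the smallest positive double rather than emitted as zero.
* Cumulative $R^2$ is capped just below 1; degenerate designs
  ($N \le K+1$, all-zero exposure effects, all-equal $|\hat\beta_X|$
  for Egger) raise informative errors.
* All report TSVs are written with fixed formatting and no timestamps,
  so identical config and seed give byte-identical outputs.

## Known limitations

$\beta_2$ is estimated from mediator → outcome without adjusting for
the exposure (simple two-step, as in the coefficient-product tradition).
When the exposure has a strong direct outcome effect *and* exposure
instruments leak into the mediator's instrument set, $\beta_2$ absorbs
exposure-correlated pleiotropy; no Steiger filtering or multivariable
MR is applied (deliberately out of scope). The proportion mediated is
only interpretable when mediation is sign-consistent and the total
effect is bounded away from zero; the flags surface both conditions.
MR-PRESSO-style outlier removal and Rucker model selection are not
implemented; leave-one-out tables and Q statistics are provided so
users can inspect influence manually.
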