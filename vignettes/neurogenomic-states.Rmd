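---
title: "Methods: from amplification curves to neurogenomic states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from amplification curves to neurogenomic states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurostates)
```

This vignette explains the statistical machinery of `neurostates`, the
assumptions behind each stage, and the design choices made where the
underlying analysis tradition leaves the details open.

## The experimental design being modelled

A dyadic agonistic-contest study induces four social phenotypes in male
zebrafish: **winners** and **losers** of a 30-minute real-opponent fight
(each winner is bound to exactly one loser — the dyad is the pairing unit),
**mirror-fighters** that fight their own reflection and therefore express
aggression without a change in social status, and visually isolated
**controls**. Default group sizes are 10/12/12/11 (45 fish). Two hours
after the interaction, expression of six neuroplasticity genes (*bdnf*,
*npas4*, *nlgn1*, *nlgn2*, *wnt3*, *neurod*) plus the reference gene
*eef1a1l1* is assayed by qPCR in five microdissected nuclei of the social
decision-making network: Dm, Dl, Vv, Vs and POA. Plasma cortisol and
behavioral event logs complete the dataset.

## The generative model of the synthetic-data module

Latent log-expression for fish $i$, nucleus $k$, gene $g$ is

$$y_{ikg} = \mu_{kg} + \delta_{t(i)kg} + b_i + u_{d(i)} + e_{ikg},$$

with subject intercept $b_i \sim N(0, \sigma_s^2)$ shared across that
fish's nuclei, a dyad intercept $u_d \sim N(0, \sigma_d^2)$ shared by the
winner and loser of one contest (controls and mirror-fighters carry no
dyad effect, mirroring the mixed model fitted downstream, where their dyad
levels are singletons), and residual vectors
$e_{ik\cdot} \sim N(0, \sigma_r^2\, C_{t(i),k})$. The correlation matrix
$C_{t,k}$ is the per-(treatment, nucleus) **co-expression truth** —
imposed on residuals, because the downstream correlation analysis is
computed within treatment across individuals, after fixed and random
effects. Relative expression is $e^y$: qPCR expression ratios are
multiplicative, so a log-normal model is the natural choice. The
distributional family is an assumption of the generator, not something the
analysis tradition fixes.

Defaults and why:

* $\sigma_s = 0.3$, $\sigma_d = 0.2$, $\sigma_r = 0.5$ (natural-log scale)
  — moderate repeatability of individual expression (about 26% of the
  non-dyad variance is subject-level), typical of within-individual qPCR
  panels.
* $\mu_{kg}$ reproduces the qualitative ranking of the panel across nuclei
  (e.g. *bdnf* highest in Dl, *neurod* in Dm/Dl, *nlgn2* in Vs/Vv), on a
  baseline of 0.2 relative units.
* $\delta_{tkg}$ is non-zero only at the handful of cells where the
  contest phenotypes are known to depart from isolated controls (e.g.
  *bdnf* up in the Dl of mirror-fighters and losers), with shifts of
  0.3–0.7 log units — roughly 1 to 1.5 residual SDs.
* Default co-expression truths are composed from deterministic
  "archetype" matrices (`coexpr_archetype()`, two-factor loadings plus a
  diagonal, all off-diagonal values distinct so that the QAP permutation
  null is informative). Conditions that share a neurogenomic state share
  an archetype; the default map encodes mirror = loser in Dm/Dl/Vs,
  control = mirror in Vv, everyone but losers sharing POA, winners
  coupling Dm with Dl, and losers coupling Dm with POA.

Random numbers are drawn from substreams keyed on the master seed and the
unit (fish, dyad, reaction), so removing fish from a design never shifts
any other unit's draws and identical seeds give byte-identical studies.

Behavioral event streams follow the contest phenomenology: a first-bite
latency (log-normal, median ≈ 1 min in real fights, sooner against a
mirror), gamma-distributed resolution times centred on 7 minutes for real
fights (mirror fights never resolve), Poisson event trains at per-minute
rates, winners exclusively aggressive and losers exclusively submissive
after resolution, and silent controls. Cortisol is log-normal per
treatment, ordered mirror ≈ winner > loser ≈ control.

**What the generator does not emulate:** plate/batch effects, reference-gene
instability, censored or failed reactions beyond what curve noise induces,
heavy-tailed expression outliers (screening power is therefore evaluated
with explicitly injected contamination), assessment dynamics within
fights, and cortisol kinetics. Passing tests show the *pipeline* is
correct and calibrated under this generative model; they cannot certify
distributional assumptions about real tissue.

## qPCR quantification

The forward model for a synthetic amplification curve is exponential
growth saturating sharply into a plateau:
$F(c) = \text{baseline} + \text{plateau} \cdot x(1+x^h)^{-1/h}$ with
$x = F_0 (1+E)^c/\text{plateau}$ and sharpness $h = 8$ — the signal stays
within a fraction $x^h/h$ of pure exponential growth until close to the
plateau, which is what makes efficiency recoverable from the curve at all.

Quantification reconstructs a PCR-Miner-style analysis:

1. **Fit**: four-parameter logistic
   $b + L/(1+\exp(-k(c-m)))$ by Levenberg–Marquardt, start values anchored
   on curve quantiles. Curves with dynamic range below `min_range`
   (default 10 fluorescence units against a default plateau of 100) are
   flagged `no_amplification`.
2. **CT**: the fractional cycle of maximum second derivative of the fitted
   logistic, $CT = m - \log(2+\sqrt3)/k$ — threshold-free, so no arbitrary
   fluorescence line needs to be chosen.
3. **Efficiency**: $E = e^{\text{slope}} - 1$ from the regression of
   $\log(F - \text{background})$ on cycle over the exponential window,
   defined as the cycles where the background-subtracted signal lies
   between 5% and 50% of the fitted amplitude. The background is the mean
   of the earliest cycles rather than the symmetric-logistic baseline
   parameter: real chemistry saturates asymmetrically, and the early-cycle
   average is accurate to the read noise while the fitted baseline
   inherits shape mismatch. Windows shorter than 3 cycles are flagged;
   estimates above 1.1 are clipped with a flag (a reaction cannot more
   than double per cycle; the margin absorbs noise).
4. **Quantity**: $R_0 = (1+E)^{-CT}$, evaluated as
   $\exp(-CT\,\log(1+E))$ so that late thresholds (CT > 35) do not
   underflow. Targets are divided by the same fish-and-nucleus reference
   reaction; cells whose reference is missing or flagged are dropped
   entirely and logged.

Validation (regenerated by `qpcr_recovery_study()` and the test suite):
noiseless curves across $E \in \{0.8, 0.9, 1.0\}$ and a 4-log dilution
range recover $E$ to within 3×10⁻⁴, quantity ratios to within 1.4%, and
10-fold CT spacing at $E = 1$ of 3.323 cycles against the closed form
$\log_2 10 = 3.3219$. The absolute scale of $R_0$ is arbitrary (the
second-derivative CT sits a fixed $\log(2+\sqrt3)/k$ cycles before the
midpoint), which is why only ratios are meaningful — hence reference-gene
normalization.

## Outlier screening

Rosner's generalized ESD procedure runs independently within every
condition cell — treatment × nucleus × gene for expression, treatment for
cortisol ("condition" is not pinned down further by the tradition; the
finest grouping is the conservative reading, since coarser cells would mix
genuinely different means). Deviations are two-sided (expression outliers
occur in both directions), α = 0.05, and at most ⌊0.2 n⌋ values may leave
one cell (`floor`, the conservative rounding). Cells with n < 5 are
skipped and logged. Screening runs after normalization, before the mixed
model and all correlation stages. Every removal is logged with its
$R_i$, $\lambda_i$ and iteration.

## Mixed-model planned contrasts

Per gene, `log(expression) ~ treatment * nucleus + (1|subject) + (1|dyad)`
is fitted by REML. The subject intercept crosses nuclei within a fish; the
dyad intercept is shared by the two members of a real contest and is a
singleton level for everyone else, so it is identified by the
winner–loser pairs alone. The log scale matches the multiplicative error
of qPCR ratios (a raw-scale option exists behind `log_scale = FALSE`);
one immediate consequence, tested as an invariance, is that rescaling all
expression by a positive constant leaves every z statistic unchanged.

Planned pairwise treatment comparisons within each nucleus are reported as
$z = \hat\beta/\text{SE}$ with two-sided normal p-values, **unadjusted**
for multiplicity — planned comparisons in this tradition are reported
test-by-test, and single p-values near 0.046 are read at face value.
Omnibus F tests for treatment, nucleus and interaction use Satterthwaite
denominator degrees of freedom; exact df depend on the random-effect
structure and are reported rather than forced to match any particular
convention. Singular fits (a variance component estimated at zero, common
with 11 dyads) are refitted without the near-zero component, down to
ordinary least squares, and the decision is logged in the output notes.

Effect sizes follow the d_s/d_z convention: winner-vs-loser contrasts are
dyad-paired, so they carry $d_z = \bar{d}/s_d$ on within-dyad differences;
every other pair carries $d_s$ with the pooled SD. (Published analyses of
this design mix the two inconsistently for winner–loser; here the rule is
fixed: paired data get the paired effect size.) Magnitudes are labelled at
the conventional 0.2/0.5/0.8 thresholds.

Calibration at the default study conditions, regenerated by
`lmm_calibration_study()` (500 replicate studies, one null gene and one
gene carrying a 1-residual-SD winner shift in Dm per replicate): the
pooled per-contrast type-I rate of the z tests is ≈ 0.05 (the asymptotic
normal reference costs well under one percentage point against a
t-reference at these sizes), the injected shift's sign is recovered in
≈ 98% of replicates, and its power is ≈ 0.5 — comparable to the two-group
t benchmark at n ≈ 11 per group.

## Co-expression matrices and the QAP test

Per (treatment, nucleus), pairwise-complete Pearson correlations between
all 15 gene pairs (pairwise rather than listwise deletion, so an outlier
removed from one gene does not erase a fish's other pairs; configurable),
two-sided p-values BH-adjusted within the matrix, genes observed in fewer
than 3 fish marked missing.

Two matrices are compared with the quadratic assignment procedure: the
observed statistic is the Pearson correlation over the
$\binom{g}{2}$ upper off-diagonal cells (for symmetric matrices the full
off-diagonal set is the same information duplicated), and the null
distribution relabels one matrix's genes by a common row+column
permutation. The p-value is one-tailed for positive association — calling
two matrices "similar" is a positive-association claim; a two-tailed
option exists. Monte-Carlo mode uses the add-one estimator
$p = (1 + \#\{r_\pi \ge r_{obs}\})/(1 + n_{perm})$, which includes the
identity and never returns 0; exhaustive mode enumerates all $g!$
relabelings (exact rational p) and is selected automatically whenever
$g! \le n_{perm}$ — at the default 6 genes and 5000 permutations the test
is always exact. Tie comparisons use a 10⁻¹² tolerance so the identity
permutation always counts.

Letter classes (the familiar compact-letter display over conditions) are
the **connected components** of the graph with an edge wherever QAP
p < α. The grouping rule is not dictated by the tradition; components are
the weakest closure consistent with the pairwise calls, and any
intransitive triad (A similar to B, B to C, but not A to C) is surfaced
with a loud warning and an `intransitive` table rather than hidden.
Two epistemic caveats are worth stating plainly: a *non-significant* QAP
p-value is absence of evidence of association, which the inherited
decision rule reads as "different states"; and no multiplicity correction
is applied across the QAP family, matching that rule. Both are decision
conventions, not statistical guarantees.

Validation: Monte-Carlo p-values track the exhaustive oracle within
3-sigma binomial bands (50 random 5×5 pairs at 5000 permutations); the
type-I error for independent 12-fish, 6-gene matrices is ≈ 0.045 over
1000 repetitions; and in a study where two treatments share an archetype
truth and a third carries an unrelated one (12 fish per group), the
partition recovers {shared},{distinct} in ≈ 76–80% of 200 replicates,
stable across seeds.

## Pipeline, reproducibility and problem sizes

`run_pipeline()` drives simulate-or-load → quantify → screen → univariate
statistics → neurogenomic states, writing one fresh run directory per
invocation (never overwritten) with every stage's tables, optional
heatmaps (diverging blue–white–red anchored at ±1 with significance
marks), and a JSON manifest carrying the configuration echo and MD5
checksums of every output. All stochastic stages derive their streams from
the single master seed, so identical configurations produce byte-identical
statistical tables; the full default study (45 fish, 1575 reactions,
63 000 curve rows) runs in well under a minute on one core.

The replicate counts used throughout the validation studies — 50 matrix
pairs for the oracle comparison, 1000 null repetitions for QAP type-I,
1000 vectors for the gESD cross-check, 500 mixed-model replicates, 200
state-recovery replicates per seed — were chosen to give Monte-Carlo
standard errors comfortably inside the decision bands they feed
(binomial SE ≤ 1.6 percentage points in every case).

## Known limitations

* The qPCR stage reconstructs a PCR-Miner-style analysis from its
  published description; it is validated by parameter recovery on the
  forward model, not by bit-agreement with any specific software.
* The normal z reference for planned contrasts is slightly liberal at
  these group sizes (measured ≈ 0.05–0.06); Satterthwaite t references
  would tighten this at the cost of df conventions the source tradition
  does not specify.
* gESD assumes approximate normality within cells; on the log scale this
  is reasonable for qPCR ratios but heavy-tailed contamination beyond the
  20% cap will survive screening.
* Connected-component letters can chain conditions that are not pairwise
  similar; the intransitivity log should be checked before reading the
  letters as equivalence classes.
* The co-expression truth of the generator operates on residual
  correlations; subject- and dyad-level variance adds a common positive
  component to every observed gene-pair correlation, just as biological
  individual variation does in real data.
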