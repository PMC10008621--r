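---
title: "Methods and design choices in btcbm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design choices in btcbm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(btcbm)
```

`btcbm` packages the statistical machinery of an exploratory multi-omics
biomarker analysis for a single-arm immuno-chemotherapy trial in biliary
tract cancer. This vignette records the models it implements, the knobs
that matter, and the design decisions taken where the underlying methods
description left the choice open.

## The MSI caller

The classifier works on mononucleotide microsatellite loci summarized as
read counts: at each locus a sample has a depth $d$ and a count $x$ of
"unstable" reads, i.e. supporting reads whose observed repeat length
differs from the reference repeat length. Counting unstable reads from
alignments is upstream of this package — the caller's input contract is
the count table, not BAMs.

Loci are eligible when the reference repeat length is at least 11 units
and the depth at least 51 reads. Both thresholds are strict readings of
"exceeds 10" and "greater than 50" and both are exposed as arguments
(`min_repeat_length`, `min_depth`) of `filter_loci()`.

From a panel of stable baseline samples, `build_baseline()` estimates each
locus's prior unstable-read probability by pooling reads across samples
with a symmetric Jeffreys-style pseudocount ($c = 0.5$ by default):

$$\hat p_0 = \frac{\sum x + c}{\sum d + 2c}.$$

The estimator was an open choice — the method description says only that a
prior probability is "calculated" from hundreds of confirmed samples. We
chose pooled counts (equivalent to depth-weighting the samples) with
smoothing so that $0 < \hat p_0 < 1$ always holds; an alternative Bayesian
reading (using the posterior rather than the smoothed frequency in the
test) would behave almost identically at these pooled depths and is noted
as a limitation rather than implemented as an option.

Per locus the caller computes the inclusive upper binomial tail
$P(X \ge x)$ for $X \sim \mathrm{Bin}(d, \hat p_0)$ and calls the locus
MSI-high when the tail is $\le \alpha = 0.001$. Both the tail and the
$\alpha$ comparison are inclusive. The cutoff is applied per locus without
multiplicity adjustment — with $\alpha = 10^{-3}$ and tens of loci the
expected number of false locus calls per sample is well below the
sample-level decision margin. The sample's MSI score is
$100 \cdot (\text{MSI-high loci}) / (\text{evaluable loci})$, and the
sample is labelled unstable at score $\ge 20$. A sample with zero
evaluable loci raises an explicit "unevaluable" error rather than
defaulting to stable.

## Genomic biomarkers

TMB counts somatic coding SNVs, insertions and deletions per megabase of
panel coding footprint. Copy-number records never count. Synonymous
variants are excluded by default — the panel's own convention was
unstated, so the choice is exposed as `include_synonymous`. The footprint
(`coding_footprint_mb`, default 1.0 Mb for synthetic runs) is a required
configuration value because the real panel's footprint is not public.
TMB-high is the cohort median split with ties going high.

Gene status is `mutant` under the any-alteration rule (any non-synonymous
coding small variant, or any copy-number event) or the loss-of-function
rule (nonsense, frameshift, splice-site, or copy-number deletion). The
loss-of-function rule is deliberately a subset of the any-alteration rule,
so `lof_only = TRUE` mutant implies `lof_only = FALSE` mutant. Germline
variants count toward gene/pathway status only for the germline-eligible
genes (BRCA1/2, PALB2 by default) and never toward TMB. Pathway status is
the disjunction over an editable gene set; the shipped HRR and
chromatin-remodeling lists contain the genes named in the trial's report
plus standard pathway members, and are configuration (GMT files), not
code — users reanalyzing real data should substitute their panel's lists.

## Transcript scoring

Housekeeping normalization rescales each sample by
$(\overline{g}) / g_j$ where $g_j$ is the sample's geometric mean over
housekeeping genes and $\overline{g}$ the arithmetic mean of those
geometric means. After normalization every sample has the same
housekeeping geometric mean, and renormalizing is a no-op (factors of 1).
The manufacturer's spike-in control step is intentionally omitted — only
the housekeeping step the analysis describes is modelled.

Metagene scores are the log2 geometric mean of member-gene expression,
computed as the mean of $\log_2(\text{count} + 1)$. The exact transform
used by the vendor software is unstated; $\log_2(x+1)$ produces score
magnitudes in the published range (total T-cell scores around 7). Member
genes absent from the matrix are dropped with a warning, never imputed; a
fully absent set is an error. The HRD transcriptomic score is simply the
metagene score of the fixed 7-gene set, with "BRCA1/2" read as two genes.
Median-split labels send ties high, so a 28-sample cohort with distinct
scores splits 14/14.

## Association and survival statistics

The two-sided Fisher exact p sums hypergeometric probabilities of all
tables with the observed margins whose probability is at most the observed
table's, with $1{+}10^{-7}$ relative slack — the dominant convention.
Degenerate zero-margin tables return $p = 1$, flagged. The implementation
enumerates `stats::dhyper` directly (the conditional-MLE odds ratio, when
requested, comes from `stats::fisher.test`); the test suite checks it
exactly against an independent log-binomial-coefficient enumeration over
an exhaustive margin sweep. One published value is a knife-edge case: the
chromatin-remodeling table's exact two-sided p is 0.04650, which standard
half-up rounding prints as 0.047 rather than the published 0.046; the
suite therefore asserts agreement within half a unit of the printed last
digit throughout.

Clopper–Pearson intervals use the inverse-beta closed form. ORR and DCR
use the intention-to-treat denominator (all treated patients, with NE in
the denominator). Wilcoxon rank-sum comparisons use mid-ranks and switch
from the exact distribution to the continuity-corrected normal
approximation when the smaller group exceeds 10 or ties are present.

Survival estimation stands on the `survival` package: product-limit
curves with Greenwood variance and log(−log) bands, log-rank via
`survdiff`, and univariate Cox fits with Efron tie handling (Breslow by
option; the two coincide without ties). Median survival is the first time
the curve reaches 0.5 or below, reported as the explicit string
`"not reached"` — never infinity — when the curve stays above one half;
median confidence intervals invert the log(−log) band
(Brookmeyer–Crowley style), since the original report names no method.
Monotone-likelihood Cox fits (a stratum without events) are reported
non-estimable rather than fitted. Whether the trial's printed hazard
ratios came from Cox fits or O/E ratios is unknowable from the text; we
chose Cox, and accordingly treat printed HRs as context, not as
reproduction targets.

## Trial design

The design module reproduces the single-arm exponential calculation: with
medians $m_0 = 9.5$ and $m_1 = 16$ months, one-sided $\alpha = 0.05$ and
power $0.8$,

$$d = \left\lceil \frac{(z_{1-\alpha} + z_{\text{pow}})^2}{\ln^2(m_0/m_1)} \right\rceil = 23,$$

and with uniform accrual over $A = 24$ months and administrative censoring
at $T = 48$ months the event probability under the *alternative* hazard
$\lambda = \ln 2 / m_1$ is

$$P = 1 - \frac{e^{-\lambda(T-A)} - e^{-\lambda T}}{\lambda A} = 0.780,
\qquad n = \lceil d / P \rceil = 30.$$

Two conventions were open and were fixed by internal consistency: the
one-arm event formula (no factor-4 two-arm multiplier) and evaluation of
$P$ under the alternative median — the only pair that turns 23 events into
30 patients. Ceiling is applied at both stages. `exponential_rate_test()`
provides the matching one-sided analysis test (asymptotic normality of
$\log \hat\lambda$ with variance $1/d$), used to verify the design's power
by simulation.

## The synthetic cohort generator

The generator's defaults are the trial's stated conditions: 30 patients,
24-month uniform accrual, 48-month administrative censoring, exponential
OS with median 16 months in the biomarker-positive group versus the
9.5-month historical control in the negative group, and response
probabilities 7/9 versus 4/21 given the driver biomarker (prevalence 0.30,
matching the HRR-altered fraction). PFS is an independent exponential with
its own group medians (9.8 / 4.5 months, the published stratified
medians) — no joint OS/PFS model is described anywhere, so independence
was chosen for simplicity and is a known departure from reality, where the
two are strongly correlated. There is no dropout: censoring is purely
administrative, matching the design assumption.

Mutations are independent per gene with a per-gene marginal probability
(defaults shaped like the published alteration spectrum, TP53 40%,
KRAS 33%, ...); for enriched genes the configured value is the
non-responder probability and responders' odds are multiplied by the
configured odds ratio (default 5 for HRR and chromatin-remodeling genes).
MSI data use locus-specific baseline rates drawn from a Beta distribution
with mean `baseline_unstable_rate` (1%) and concentration 200, a baseline
panel of 200 stable samples ("hundreds" in the source), depths of at least
51 reads with Poisson variation around 150, and — for samples designated
MSI-high — elevation of a random 40% of loci to a 30% unstable-read rate.
The trial cohort itself is generated entirely stable, as observed.

Expression counts are rounded log-normal: gene baseline log2 means uniform
on [4, 10], a per-sample library offset (removed by normalization), log2
noise with standard deviation 0.5, and a responder shift of
`signature_effect_log2` (default 0.8, the size of the published total
T-cell score difference) on the T-cell/interferon-axis sets, mirrored
negatively on mast cells. Counts are independent across genes: the
generator does not emulate inter-gene correlation, so covariance-sensitive
analyses of signatures should not be validated against it. Negative
binomial counts were considered and rejected — the scoring pipeline only
uses positivity and multiplicative structure, which the log-normal supplies.

A single master seed is expanded into independent per-generator
substreams, so adding or re-running one generator never perturbs the
others, and regeneration under the same configuration is bit-identical.

## Numerical choices and scales of the checks

Tolerances used by the test suite reflect the arithmetic, not the science:
binomial tails are required to match brute-force summation to $10^{-9}$
relative (down to double underflow), Fisher p-values to match full
enumeration to $10^{-10}$ relative across every table with total $n \le 40$
plus a seeded sample of larger tables with all margins $\le 40$, and
normalization identities to hold to $10^{-9}$. Stochastic checks use
scales chosen to keep Monte-Carlo error far below the assertion margin
while running in seconds: $10^4$-patient cohorts for event-fraction and
Kaplan–Meier median recovery (three large-sample standard errors), $10^5$
locus tests for the caller's type-I error, 500 replicates for MSI label
reliability, 200 replicates of 500-per-arm Cox fits for Wald coverage, and
2000 replicates of the designed 30-patient trial for power, which is
required to reach 0.75 against the nominal 0.8.

## Known limitations

* The shipped immune-cell and signature gene memberships are
  representative placeholders; the exact panel memberships live in the
  trial's supplementary material and must be substituted (via GMT files)
  for a faithful reanalysis.
* The patient-level endpoints of the original trial (median OS 15.9
  months, PFS 5.1 months, and all real-data transcriptome findings) are
  not reproducible here: the raw data are access-restricted. The package's
  evidence is therefore operating-characteristic evidence on synthetic
  data, not reproduction of those numbers.
* The CEA dichotomy assigns the boundary value (10 ng/ml) to the abnormal
  group; the source text places 10 in both groups in the same sentence,
  so the boundary side is exposed as configuration.
* The MSI caller consumes unstable-read counts; it does not model
  repeat-length distributions, realignment, or PCR concordance.
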