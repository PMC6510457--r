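---
title: "Methods: signature enrichment and the I_MDS disease-activity score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature enrichment and the I_MDS disease-activity score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imdscore)
```

## Overview

`imdscore` turns a genes × samples log2 expression matrix and a library of
immune-process gene signatures into (i) a signatures × samples enrichment
score (ES) matrix, (ii) per-comparison lists of differentially enriched
signatures, and (iii) a per-sample molecular disease-activity score (I_MDS)
with a responder / non-responder classification. This vignette records the
model, the parameters that matter, what the synthetic generator does and
does not emulate, and the numerical and design choices a maintainer should
know about.

## The enrichment model and its assumptions

The ES engine is a single-sample, rank-based method in the GSVA family.

**Kernel CDF.** For gene $i$ with cohort values $x_{i1},\dots,x_{in}$ and
sample standard deviation $s_i$,
$$z_{ij} = \frac{1}{n}\sum_{k=1}^{n}\Phi\!\left(\frac{x_{ij}-x_{ik}}{h_i}\right),
\qquad h_i = s_i/4 .$$
The Gaussian kernel suits continuous log-intensity data (a count-oriented
kernel is out of scope). $z$ is invariant to per-gene positive affine
transforms, which removes per-gene dynamic-range differences. Assumption:
scores are *cohort-relative* — each sample is placed within the cohort's
per-gene distributions, so samples that must be comparable should be scored
in one `gsva_scores()` call. Scoring a validation cohort in its own call is
the independent-validation mode; both are legitimate, they just answer
different questions.

**Folded ranks.** Within each sample, genes are ranked by decreasing $z$
and folded about the list middle, $r_{ij} = |p/2 - \mathrm{rank}_{ij}|$,
so both tails of the expression distribution carry weight.

**Random walk.** Walking the ranked list, in-set genes add
$r^{\tau}/\sum_{\text{set}} r^{\tau}$ and out-of-set genes subtract
$1/(p-k)$; the ES is the maximum positive plus the maximum negative
deviation ("max-diff"), bounded in $[-1,1]$ and near 0 for a set scattered
uniformly.

### Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| bandwidth $h_i$ | $s_i/4$ | log2 units | the method family's standard choice; smaller sharpens the empirical CDF, larger smooths it |
| $\tau$ | 1 | ≥ 0 | weight on rank extremity; 1 = linear weighting, 0 = unweighted KS |
| ES mode | max-diff | — | symmetric two-sided statistic; sign carries direction |
| size bounds | 5–500 genes | after universe intersection | <5 unstable, >500 uninformative |
| `min_delta` | 0.2 | ES units | practical-significance floor on ΔES |
| `alpha` | 0.05 | probability | significance cutoff, inclusive |
| score cutoff | 32 | I_MDS units | published operating point of the original training cohort; cohort- and signature-set-specific, so `choose_threshold()` is the recommended path on new data |

## Differential enrichment

`compare_groups()` uses a pooled-variance two-sample t per signature — the
exact reduction of a general linear model with one two-level factor — and a
paired t for post-treatment vs baseline when subject identifiers link the
samples (unpaired otherwise). BH adjustment is applied across the
signatures of one comparison. Two published statements conflict slightly
(an FDR procedure is reported, but the selection sentence thresholds "a
t-test"); `selection_criteria()` defaults to the BH-adjusted p and exposes
`use_adjusted = FALSE`, and the choice travels with all outputs. Both
boundaries are inclusive: ΔES = 0.20 with significance = 0.05 is selected;
ΔES = 0.19 never is.

Library redundancy is audited with `overlap_summary()`. The published
description of pairwise overlap names no denominator; the default here is
$|A\cap B|/\min(|A|,|B|)$ because containment is exactly the redundancy
that would double-count biology in an *additive* score; the Jaccard index
is available for sensitivity analysis.

## The I_MDS score

$$\mathrm{I\_MDS}_j=\sum_{s\in S}ES_{sj}-\frac{1}{n_{\mathrm{NHV}}}
\sum_{h\in \mathrm{NHV}}\sum_{s\in S}ES_{sh}$$

with $S$ the disease-shared upregulated selection. Centering makes the NHV
mean exactly 0, so the score reads as distance from molecular health; it is
additive over disjoint signature sets, and a signature with constant ES
across samples cannot change score differences or classifications. The
published formula reuses one symbol for both the signature count and the
healthy-sample count; the subtraction term is interpreted here as the NHV
mean of the signature sum, consistent with the stated "subtracted the mean
of the healthy controls". When a validation cohort has its own healthy
samples the score is re-centered on them; otherwise the training offset can
be carried explicitly (`compute_imds(..., offset = )`), and the choice is
logged in the run manifest.

Classification: score < cutoff → responder-like; ≥ cutoff →
nonresponder-like (the stated boundary rule; configurable). Sensitivity is
the responder detection rate and specificity the non-responder detection
rate; the full confusion table is returned because the published "100%
specificity" is also readable as a PPV-style statement, and the table lets
either convention be checked. How the published cutoff of 32 was chosen was
never described; `choose_threshold()` therefore scans all midpoints between
observed scores and, by default, maximizes sensitivity subject to perfect
specificity (ties → lowest cutoff), which reproduces the operating
philosophy of never denying anti-TNF to a molecular responder-like sample.

## The synthetic cohort generator

`simulate_cohort()` emits the world the analysis assumes: per-gene baseline
means drawn once from Normal(7, 1.5) log2 units (a typical microarray
intensity range — no value was stated anywhere, so this was chosen once and
not revisited), independent Gaussian noise (sd 0.5), and additive log2
shifts of the truly dysregulated signatures' genes: responders +0.8 at
baseline and +0 post-treatment (reversion), non-responders +1.6 at both
timepoints (no change), identically in both disease arms (disease-shared
biology). Signature gene blocks are disjoint, so null signatures are
exactly null. Generation is bit-reproducible from the design seed
(Mersenne-Twister, inversion normals — the versioned RNG contract).

What it does **not** emulate: batch and probe-level artifacts, gene–gene
correlation beyond co-shifting, missingness, heavy-tailed noise, or
subject-level random effects. A green recovery test therefore establishes
that the pipeline's inference machinery is correct under its own
assumptions — not that the published cohort-specific numbers (59/67/58
selected signatures, 100%/78.8% and 87.5%/85.7% operating points) are
reproduced; those require the original accessions and are deliberately out
of the test suite.

## Numerical choices

- Ranking ties break stably by gene index (radix order), so ES is
  deterministic; other tie conventions can differ at machine precision.
- Zero-variance genes get $z = 0.5$ everywhere (uninformative) with a
  warning rather than an error — constant probes are common after
  filtering mistakes and should not kill a run.
- A signature whose genes all fold to rank weight 0 (measure-zero edge
  case) falls back to unweighted in-set steps instead of 0/0.
- Zero-variance ES rows yield `NA` correlations with a warning.
- Identical constant rows in the t-test are reported as t = 0 rather than
  NaN.
- Linkage for heatmap-style clustering is unstated in the source
  description; the default is complete (the common heatmap default), with
  average and Ward.D2 available. Clustering operates on samples over
  signature-ES rows; signature-side ordering carries no inferential weight.

## Known limitations

- **Clustering acceptance gap (intentional red test).** Under the stated
  generator (responder baseline shift 0.8 vs non-responder 1.6, noise 0.5),
  cohort-relative scoring places baseline responders' ES roughly midway
  between healthy and non-responders (group means ≈ −0.60 / −0.11 / +0.55),
  so the larger Euclidean gap separates R_BL from NR and every linkage's
  2-cut assigns R_BL to the healthy-side cluster. The published heatmaps
  show R_BL clustering with non-responders because real baseline
  dysregulation nearly saturates the ES in both groups. Reproducing that
  would require raising the responder effect size after observing the test
  outcome, which this package's validation policy forbids; the acceptance
  test is kept faithful and left red, and the I_MDS ordering criterion
  (NR_BL > R_BL > 0 ≈ R_PT), which the same world does satisfy, is the
  tested stand-in for the figure's narrative.
- ES depends on cohort composition; adding samples changes everyone's
  scores slightly. This is inherent to the method, not a bug.
- The replicate-heavy acceptance simulations (500 null, 100 power) keep
  the stated effect sizes and noise but drop the groups their comparison
  never touches, to fit a single-CPU budget.
- Gene-symbol harmonization is a user-supplied alias table applied at GMT
  load; there is no network symbol-checking, by design.
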