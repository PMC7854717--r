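---
title: "The genomic fabric model: expression level, variability and coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The genomic fabric model: expression level, variability and coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GenomicFabric)
```

# The model

A replicated, multi-condition expression experiment — the motivating
design is four heart chambers (LA, RA, LV, RV) profiled in four
biological replicas (animals) on two-color microarrays, where a gene
may be probed by 1 to 13 redundant spots — yields three independent
characteristics for every gene in every condition:

* **AVE**, the average expression level. Spot values are first averaged
  across the biological replicas (giving the spot means
  $\mu_{ik}$), then across the gene's $R_i$ redundant spots.
  The unit is the *median gene*: after normalization the median over
  all genes and samples of the per-gene sample means is 1, so
  AVE = 20 reads "twenty times the median gene".

* **REV**, the relative expression variability: the spot-pooled
  coefficient of variation across replicas,
  $\sqrt{\tfrac{1}{R_i}\sum_k (s_{ik}/\mu_{ik})^2}$, multiplied by a
  mid-interval chi-square correction and expressed in percent. The
  correction, $\tfrac12\bigl(\sqrt{r/\chi^2(r;0.975)} +
  \sqrt{r/\chi^2(r;0.025)}\bigr)$ with $r = 4R_i - 1$ degrees of
  freedom, de-biases the small-sample CV estimate; it is strictly
  decreasing in $R_i$ and tends to 1. With four replicas it evaluates
  to 2.1475 at $R = 1$ and 1.0391 at $R = 13$. (Published
  descriptions of this correction sometimes quote a range of 1.566 to
  1.05 for the four-replica case; the formula itself does not
  reproduce those numbers, and this package follows the formula —
  `chi2Correction()` is tested against direct numerical chi-square
  quantiles.)

* **COR**, the Pearson correlation of log2 expressions across
  replicas with every other gene in the same condition, or with the
  same gene in an adjacent condition (synchrony).

Derived from REV are the control scores: $REC_i = \langle REV\rangle /
REV_i - 1$ against the condition's median REV (0 at the median, large
and positive for tightly controlled genes), and its pathway analogue
PREC using the median REV over a gene set's quantified members, which
is 0 for the whole transcriptome by construction.

## Differential expression with a per-gene cut-off

Two conditions are compared by the signed ratio $x$ of the summed spot
means ($|x| \ge 1$, negative for down-regulation in the referred
condition), gated by an adaptive cut-off

$$CUT_i = 1 + \sqrt{2\,(rev_{i,A}^2 + rev_{i,B}^2)}$$

and by a two-tail heteroscedastic (Welch) t-test of the per-replica
gene means, $p < 0.05$. The REVs enter CUT as *fractions*
(percent / 100): a gene at 21% REV in both conditions gets
CUT = 1.42. Entering them in percent would produce cut-offs of tens of
folds and no calls at all, so the fractional convention is the only
reading consistent with the method's reported behaviour; it is applied
uniformly and documented here prominently. Replicas are treated as
unpaired in the test (the formula is a two-sample test even though
animals are shared across conditions; pairing is exploited only by the
synchrony analysis). No multiple-testing correction is applied by
default, matching the original procedure; `chamberComparison(adjust =
"BH")` enables Benjamini–Hochberg for modern use.

Pathway alteration is summarized two ways: the percentage of regulated
members, and the Weighted Pathway Regulation

$$WPR_\Gamma = \overline{\; AVE_i^{(A)} \,(|x_i| - CUT_i)\,(1 - p_i)
\;\bigl[\,|x_i| > CUT_i\,\bigr]\;}$$

which weights each gene's excess fold over its own cut-off by its
reference-condition expression and the confidence of the call. A gene
exactly at its cut-off contributes zero. The weight uses the
spot-aggregated AVE of the reference condition (the aggregation level
of the weight is not fixed by the original formula; this choice is
applied consistently).

## Coordination, synchrony and the df rule

Correlations use all $4R$ log2 spot values when both genes share the
same redundancy $R$, pairing spots in index order within replicas, so
the significance t-test has $df = 4R - 2$ (one spot: 2; two spots: 6;
three spots: 10). With unequal redundancies each gene's spots are
averaged within every replica before log2, leaving four points and
$df = 2$. Significance is the two-tail t-test of
$t = \rho\sqrt{df/(1-\rho^2)}$.

Pairs are classified *synergistic* ($\rho > 0$, $p < 0.05$),
*antagonistic* ($\rho < 0$, $p < 0.05$), *independent*
($|\rho| \le 0.05$, configurable via `independenceBand`), and
otherwise *undecided*. The independence criterion is a design choice:
"independently expressed" is used in the field without a formal
definition, and at $df = 2$ mere non-significance is the norm, so
counting every non-significant pair as independent would inflate that
class enormously. Only near-zero correlations qualify; everything else
non-significant stays undecided. A zero-variance expression vector
makes $\rho$ undefined; such pairs are reported undecided with a
warning.

Synchrony correlates the same gene across two conditions with
replicas paired by animal (and spots by index, $df = 4R - 2$); a gene
is synchronous where that pair is synergistic. For the canonical
four-chamber design the four adjacent pairings are LA–RA, LV–RV,
LA–LV and RA–RV, giving $4n$ evaluations next to the $n(n-1)/2$
within-condition pairs.

## Gene commanding height

$$GCH_i = (REC_i + 1)\,\exp\!\bigl(4\,\overline{\rho^2_{ij}}\bigr),
\qquad j \ne i$$

combines tight control with strong (sign-blind) coordination; it is
bounded by $(REC+1)e^4$ and equals 1 for an uncoordinated gene at
baseline control. The partner universe defaults to all other
quantified genes (a `partners` argument restricts it for exploratory
pathway panels; pathway-level summaries average GCH arithmetically).
The top-ranked gene of a condition is its gene master regulator;
ties are broken by higher REC, then by gene symbol, so ranks are
always a deterministic permutation.

# Input processing

Spot-level tables (one row per spot × condition × replica, column
names remapped through a schema) are quality-filtered *globally*: a
spot flagged corrupted, or with foreground fluorescence less than
twice its background in **any** sample, is removed from all samples
(strict inequality — exactly 2× is retained). Normalization then
proceeds in three steps: background subtraction floored at a small
positive epsilon (10⁻⁶ × the sample median, so downstream logs and
CVs are defined), per-sample median scaling to 1 (making the result
invariant to per-sample multiplicative rescaling, e.g. scanner gain),
and one global rescale so the median of per-gene sample means is 1 —
the AVE unit. Established usage of this unit does not pin down every
normalization detail; this implementation is the simplest scheme that
honours the unit and the invariances above, and dye-specific
corrections (dye swap, loess) are deliberately out of scope. Gene symbols are case-preserved but matched case-insensitively
against gene sets, since mouse symbol capitalization varies across
KEGG/GO exports.

# The synthetic-data generator

`simConfig()`/`simulateFabric()` emulate the study design so that
every downstream statistic can be checked against planted truth:

* 4 conditions × 4 replicas; spot redundancies drawn from configurable
  weights (default 70% $R=1$, 20% $R=2$, 10% $R=3$ — desk-scale
  stand-ins for the array's 1–13 range).
* Baseline gene means are log-normal with `baselineSdlog = 1.2`
  (natural log), median-normalized — spanning roughly 0.1×–10× the
  median gene, a realistic dynamic range for expressed transcripts.
* Per-gene biological CV uniform on 0.05–0.40. After the $R=1$
  correction factor 2.1475 this implies REVs of roughly 11–86% with a
  median near the 21–57% range reported for real chamber
  transcriptomes.
* Technical spot noise CV 0.05 (multiplicative, per spot), reflecting
  an optimized microarray protocol.
* Planted structure: fold changes per (gene, comparison); correlation
  modules as a single shared latent factor per module per condition,
  so any two members' log-scale correlation is exactly
  $loading^2$ (times the sign pattern) — chosen over arbitrary
  covariance matrices because it is analytically checkable; and
  cross-condition synchrony via a per-animal factor shared by the two
  conditions.
* Intensities: foreground = background + value × sample scale, with
  small backgrounds (U(0.5, 1.5)) against sample scales near 1000, so
  clean spots pass the 2× filter by construction; a configurable
  fraction of spots is planted to fail it in exactly one sample and
  another fraction is flagged corrupted, which makes removal counts
  exactly predictable.

Identical seeds give byte-identical output; the configuration
round-trips losslessly through YAML.

The generator does **not** emulate dye bias, spatial array artifacts,
probe-sequence effects, cross-hybridization, or intensity-dependent
variance trends. Passing recovery tests on this generator therefore
demonstrates the estimators' correctness and calibration under the
declared noise model, not robustness to those real-data artifacts.

## A note on median renormalization at small scale

Per-sample median scaling estimates each sample's scale from the
finite spot population. With only a few hundred genes the sample
median itself fluctuates across replicas, which adds a small
replica-level offset to every log expression value. Offsets are shared
within a sample, so within-condition correlations are barely affected,
but between conditions the offsets are independent and slightly
attenuate cross-condition correlations of low-CV genes. At realistic
spot counts (tens of thousands) the effect is negligible. Recovery
studies of the planted correlation structure therefore evaluate the
classifiers on the generator's emitted expression values
(`fabricFromTruth()`, which applies only a single global rescale),
while the intensity → filter → normalize path is exercised by its own
planted-scale-recovery and differential-expression tests.

# Numerical choices and degenerate inputs

* Medians use the midpoint-of-middle-two convention for even counts
  (R's default).
* Zero-variance genes: REV = 0 propagates; scalar `computeREC()`
  returns +Inf with a warning, while ranking contexts
  (`fabricSummary()`) substitute a capped sentinel (10× the largest
  finite REC in the condition) so orderings stay finite. Real
  replicated noise never produces these, but degenerate simulations
  do.
* Constant replica vectors make the Welch test degenerate; the limit
  is used (p = 1 for equal means, 0 otherwise).
* $|\rho| = 1$ maps to p = 0; undefined correlations are excluded
  from GCH partner means with a logged count.
* All-pairs computation is tiling-independent: bulk edge enumeration
  and per-pair recomputation agree exactly, which the tests assert.

# Problem sizes

The shipped tests run the full stack at desk scale: 20-gene fixtures
for the equation-level oracles, 510 genes × 20 seeds for coordination
recovery, 1,000 genes for differential-expression recovery, 10,000
draws for Welch-calibration, and a 200-gene seeded end-to-end
determinism check. The pair-enumeration arithmetic (142,222,545
within-condition pairs and 67,464 adjacent-condition evaluations for a
16,866-gene transcriptome) is verified in closed form rather than by
materializing the full edge set.

# Limitations

* No variance moderation or shrinkage: the CV-based estimator is
  reproduced as defined, so single-gene REVs at $n = 4$ are noisy by
  design.
* $df = 2$ correlation tests are extremely stringent (critical
  $|\rho| = 0.95$); only near-perfect coordination reaches
  significance for single-spot genes, which is faithful to the method
  but limits sensitivity.
* No FDR control by default; with tens of millions of pairs the
  nominal 5% error rate implies many false edges — the optional BH
  flag applies only to differential expression.
* The two-color dye structure is flattened to one value per (spot,
  condition, replica); dye-swap modelling is out of scope.
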