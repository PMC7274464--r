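---
title: "Rank-based deregulation calling in single samples: model, simulator and tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based deregulation calling in single samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssdereg)
```

## The problem

Population-level differential expression asks whether a gene's mean
expression differs between two cohorts. Many questions in precision
oncology are different: *in this one tumor, which genes are abnormal?*
With no replicates of the individual and strong technical variability
between samples, absolute expression values are a fragile basis for such
calls. What is remarkably stable across samples, however, is the relative
ordering of genes within a sample: if gene *a* is expressed below gene *b*
in essentially every healthy tissue sample, that ordering is a property of
the tissue, and its reversal in a tumor is evidence that one of the two
genes is deregulated there.

`ssdereg` implements a detector built entirely on this idea, together with
the machinery needed to tune and validate it offline: a realistic tumor
simulator with known ground truth, an ROC / informedness evaluation
harness, cohort-level summaries, and a synthetic control-cohort generator.

## The detector

### Ordering reference

From a control cohort, `build_reference()` computes for every gene $g$:

* $L(g)$ — genes expressed strictly below $g$ in at least a fraction
  `threshold_LH` of control samples (default 0.99),
* $H(g)$ — genes expressed strictly above $g$ under the same rule,

each truncated to the $l$ candidates whose control median is closest to
$g$'s median (default $l = 30$). The truncation keeps the comparison local:
genes far away in expression rarely flip and would only dilute the signal.
Ties within a sample count as neither "lower" nor "higher", so genes with
identical control profiles never anchor each other. Equal median distances
during truncation are broken by input gene order, which keeps the
construction fully deterministic. With an even number of controls the
median is the mean of the two central values.

The comparison is performed on *fractions*: a candidate qualifies when
(qualifying samples)/(total samples) $\ge$ `threshold_LH`. With 14
controls and the 0.99 default this demands 14/14 agreement; no rounding
rule is involved.

### Decision rule

For a case sample with expression $E(\cdot)$, the members of $L(g)$ and
$H(g)$ (restricted to the currently *active* genes, see below) are
partitioned by comparison against $E(g)$ into

$$L_u = \{g' \in L(g): E(g') > E(g)\}, \quad
  L_d = \{g' \in L(g): E(g') < E(g)\},$$

and symmetrically $H_d$, $H_u$. Exact ties belong to neither side and are
excluded from the effective list sizes $|L| = |L_u| + |L_d|$,
$|H| = |H_d| + |H_u|$. The gene is flagged when

$$\frac{|L_u|}{|L|} \ge h \quad \text{or} \quad \frac{|H_d|}{|H|} \ge h,$$

with the threshold $h \in (0, 1]$ (default 0.3) — i.e. when a sufficient
fraction of its lower neighbours has risen above it, or of its upper
neighbours has fallen below it. Direction follows the complementary
counts: down-regulated when $|L_d| + |H_d| < |L|$, up-regulated when
$|L_u| + |H_u| < |H|$. With tie-excluded denominators these two conditions
reduce to $|H_d| < |L_u|$ (down) and $|L_u| < |H_d|$ (up), so they can
never hold simultaneously; if the counts tie exactly the evidence is
contradictory and the gene abstains. The boundary is inclusive: $|L_u| = 3$
of $|L| = 10$ fires at $h = 0.3$.

### Iterated exclusion and oscillations

A flipped ordering between $g$ and $g'$ may be caused by either gene. After
the first sweep, all flagged genes are removed from every list and the
sweep repeats, so that deregulated genes stop vouching against their
neighbours. Iteration ends when the flagged set (identities and
directions) repeats. Two terminal behaviours exist besides plain
convergence:

* **period-2 oscillation** — the set alternates between two configurations
  (typically a pair of genes that implicate each other exactly when the
  other is present). The union of both sets is returned, each gene keeping
  the direction of its latest nonzero call.
* **iteration cap** — `max_iter` (default 20) sweeps without stabilising;
  the union of the last two sets is returned with a warning. On realistic
  cohorts convergence takes a handful of iterations; the cap exists for
  small adversarial inputs whose limit cycles can exceed period 2.

### Percentile fallback

A gene whose effective lists are both empty (no ordering information, e.g.
genes at the extremes of the expression range once their few neighbours are
excluded) is resolved by an outlier test on absolute values:
`percentile_call()` computes the $x$-th and $(100-x)$-th
linear-interpolation percentiles $p_l, p_u$ of the gene's control values
and calls down when $E(g) < p_l / f$, up when $E(g) > p_u \cdot f$. The
defaults $x = 2$, $f = 1.2$ are the tuned operating point for count data.
When exactly one list is empty the rule above is evaluated on the non-empty
side alone — one-sided ordering evidence is still evidence. Genes called by
the fallback join the exclusion set like any other deregulated gene.
Setting `fallback = "none"` abstains instead, which makes the detector
exactly invariant to any per-sample positive rescaling of the case.

## The simulator

`fit_packet_model()` ranks every control (gene, sample) value and cuts the
ranking into consecutive packets of 100 values of similar magnitude. Per
packet it collects the within-control differences $\Delta_n$ (each cell
against the same gene in all other controls) and, when a tumor cohort is
available, the tumor-minus-control differences $\Delta_c$. Differences
outside the 5–95% band of $\Delta_n$ form the abnormal pool $\Delta_c'$,
and $r = |\Delta_c'| / |\Delta_c|$ estimates the local deregulation
probability. `simulate_tumors()` then copies a random control and perturbs
each gene with probability $r(k)$ (or a fixed proportion) by adding one
random element of its packet's pool. Unperturbed genes keep the source
control's values bit-identically, so ground truth is exact; perturbed
values clipped at zero are flagged but keep their label. The simulation is
deliberately *not* rank-based, so it cannot trivially favour the detector.

### Surrogate pools

Fully synthetic benchmarking has no tumor cohort to harvest $\Delta_c'$
from. `surrogate_packet_model()` keeps the packet structure and normal
bands, and fills each pool with
$\delta = s\,(m_k\,(2^u - 1) + b_k)$ upward or
$\delta = -\,(m_k\,(1 - 2^{-u}) + b_k)$ downward, where $s$ is a random
sign, $u \sim \mathrm{Unif}(1, 3)$, $m_k$ is the packet's median
expression and $b_k = \max(|p_5|, |p_{95}|)$. Every draw is strictly
outside the normal band and has the magnitude of a 2- to 8-fold expression
change — the effect-size range standard differential-expression benchmarks
use. This is fixture machinery, not an estimate of tumor biology: real
abnormal differences are heavier-tailed and asymmetric. Surrogate models
carry `r = NA` and can only be used in fixed-proportion mode.

## Evaluation harness

`roc_sweep()` re-runs the full iterative detector at every threshold of an
`h` grid (21 points from 0 to 1 by default) and scores the pooled
(gene, sample) cells of all simulated tumors against ground truth. Two
conventions matter:

* **Leave-one-out contract.** The reference used to score a tumor is built
  with that tumor's source control excluded; supplying a contaminated
  reference is a hard error, not a silent degradation. References are
  cached per left-out control.
* **Pooled cells.** Rates are computed over the union of all cells rather
  than averaged per run, so tumors with many calls weigh accordingly.

A true positive is any nonzero call on a truly perturbed gene; direction
correctness is reported separately (`direction_accuracy`) rather than
folded into TPR. `max_informedness()` summarises a sweep by the maximal
Youden $J = \mathrm{TPR} - \mathrm{FPR}$; `operating_point()` picks the
highest-TPR grid point under an FPR ceiling. Although `detection_params()`
insists on $h > 0$ for ordinary use, the sweep accepts $h = 0$: the rule
then fires for every gene with a non-empty list, but genes with no flipped
neighbour still abstain through the direction tie, so the endpoint is well
defined.

The closed form
$\mathrm{FDR} = (T-P)(1-SP)\,/\,[(T-P)(1-SP) + P\cdot SE]$
(`fdr_from_se_sp()`) converts published sensitivity/specificity pairs into
false discovery rates for comparison at, e.g., $T = 15000$, $P = 3000$.

## Cohort summaries

`sample_burden()` reports per-sample up/down percentages.
`super_pattern_classify()` tests each gene's 0/1 deregulation indicator
vector against the grand mean $\mu$ of the corresponding indicator matrix
(up, down, or total) with a one-sample t-test, and labels genes
*super-up* / *super-down* (deregulated count above the cohort's median
total, expressed in controls, significant) or *super-conserved* (total
count below the median, expressed, significant). Three conventions:

* Multiple testing uses Benjamini–Hochberg on the two-sided t p-values.
  An empirical-null recalibration of the p-values would shift the
  significance cutoff but not the gene ranking; BH is standard and fully
  reproducible.
* A constant indicator vector has no t-statistic. Such genes carry an
  infinite sentinel, are excluded from BH, and count as significant exactly
  when the constant differs from $\mu$ (a saturated gene in a cohort with
  $\mu < 1$ is as extreme as evidence gets); they are flagged
  `zero_variance`.
* A gene qualifying for both super-up and super-down takes the side with
  the larger count; an exact tie stays unlabeled. For unlabeled genes the
  reported test columns come from the total-deregulation test.

## Synthetic cohorts and what the tests do (and do not) show

`generate_controls()` draws per-gene base levels log-normally
(`meanlog = 4`, `sdlog = 1.5`, so medians span more than three orders of
magnitude) and multiplies per-sample log-normal noise
(`noise_sdlog = 0.2`). Two genes must differ by roughly one natural-log
unit for their ordering to hold across all 97 samples of the default
cohort, which reproduces the regime the detector assumes: locally dense
expression levels with stable ordering at moderate distance. The defaults
— 5,000 genes and 97 controls — mirror the leave-one-out benchmark scale;
detection performance plateaus above a few thousand genes, so desk-scale
results transfer qualitatively to transcriptome-wide inputs.

The generator emulates rank stability, not real transcriptomes: there is
no gene–gene correlation, no count noise (a negative binomial's
variance-mean coupling), no batch structure, and the noise level is
homogeneous across genes. Passing benchmarks therefore demonstrate the
correctness and internal consistency of the method — recovery of planted
perturbations under the stated noise model — not clinical performance on
any particular platform.

## Numerical choices

* Quantiles are linear-interpolation (R type 7) everywhere one is needed.
* All comparisons in list construction and the decision rule are strict;
  ties are excluded rather than split.
* The benchmark problem size is 5,000 genes x 97 controls with 10 tumors
  at 30% deregulation, swept over 21 thresholds; the reference for a
  list-size sweep is built once at $l = 100$ and truncated, which is exact
  because lists are stored in median-distance order.
* Simulator replicate checks use 3-sigma binomial bands, allowing the
  ~0.3% of draws a correct simulator is expected to place outside.
* Per-tumor random substreams are derived deterministically from the
  dataset seed, so enlarging a simulation never changes existing tumors.

## Limitations

* A trustworthy control cohort is a prerequisite; the reference encodes
  whatever systematic biases the controls share.
* Genes lowly expressed everywhere carry no usable ordering and should be
  filtered out first (`filter_low_expression()`).
* The detector is a decision rule, not a test: it returns calls, not
  p-values, and its error rates are controlled empirically via simulation
  rather than analytically.
* Scale invariance holds for the ordering rule, not the percentile
  fallback; under severe normalization artefacts run with
  `fallback = "none"`.
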