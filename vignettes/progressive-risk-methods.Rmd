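---
title: "Progressive risk formulations: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Progressive risk formulations: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progrisk)
```

## The modelling problem

For a progressive joint disease, the probability that a subject reaches a
terminal intervention (the motivating case is total knee replacement)
within a fixed horizon of a scan date cannot decrease between two scans of
the same knee: disease severity does not reverse. A per-scan classifier
knows nothing of this and will happily emit a lower risk for the later
scan. `progrisk` treats the constraint as a modelling primitive rather
than a regularization target.

## Risk compositions

With scorers $f$, $g$ and $\sigma(z) = 1/(1+e^{-z})$, the first-scan risk
is always $\hat y_1 = \sigma(f(x_1))$, and the second-scan risk is:

| formulation | $\hat y_2$ | guarantee |
|---|---|---|
| baseline   | $\sigma(f(x_2))$ | none |
| riskform1  | $1 - (1-\sigma(f(x_1)))(1-\sigma(f(x_2)))$ | $\hat y_2 \ge \hat y_1$ |
| riskform2  | $1 - (1-\sigma(f(x_1)))\,\sigma(g(x_2))$ | $\hat y_2 \ge \hat y_1$ |

The guarantee is purely algebraic: the first scan's no-event probability
is multiplied by a factor strictly inside $(0,1)$, so the composed no-event
probability can only shrink. `riskform1` reuses $f$ for both scans, which
forces $f(x_2)$ to be positively related to risk; `riskform2` gives the
second scan its own scorer whose output is *inversely* related to risk
(a large $g(x_2)$ means "confidently event-free"). Consequences worth
knowing:

* `riskform1`'s $\hat y_2$ is symmetric in the two scores;
* $\hat y_2$ is increasing in $s_2$ under `riskform1`, decreasing under
  `riskform2`;
* as $f(x_1) \to -\infty$, `riskform1` collapses to $\sigma(f(x_2))$; as
  $g(x_2) \to +\infty$, `riskform2` attains the equality boundary
  $\hat y_2 = \hat y_1$.

Training minimizes the summed natural-log binary cross-entropy over the
available scans of each unit; single-scan units contribute only the
first-scan term, and under `riskform2` the scorer $g$ receives gradients
only from units with two scans.

## Comparator penalties

Two soft-constraint comparators are implemented as additions to the
*baseline* pair loss (they are alternatives to the compositions, never
combined with them):

* **Margin loss on scores** (`riskreg_penalty`):
  $\gamma \max(0, m - (s_2 - s_1))$ applied to raw scores. The penalty
  operates on logits deliberately — the default margin $m = 2$ is only
  meaningful on an unbounded scale, since probability differences never
  exceed 1. Defaults $m = 2.0$, $\gamma = 1.0$.
* **Contrastive (Siamese) loss on embeddings** (`conreg_penalty`): with
  $d = \lVert h_1 - h_2 \rVert_2$ and the two scans' labels defining the
  dissimilar condition,
  $\gamma[(1-s)d^2 + s\max(0, m-d)^2]$, the classic Hadsell-style form on
  the scorer's final hidden layer. The precise functional forms of both
  comparators were design decisions of this package (the approaches they
  represent are usually described at the level of "margin loss" and
  "Siamese contrastive loss"); both are documented as such and share one
  `regularizer_config`. $\gamma$ is an outer multiplicative weight in both,
  the simplest reading consistent with a tuned margin/weight pair.

## The synthetic cohort

The simulator generates the statistical structure the method assumes,
nothing more:

* **Severity** is linear: $s(t) = s_0 + r t$ with $r \ge 0$, a mixture of
  stable subjects ($r = 0$, 55% by default) and progressors with
  Gamma-distributed slopes (shape 4, rate 8: mean 0.5 severity units/year).
  This is the simplest dynamic consistent with a monotone-risk disease; the
  generating functions are small and replaceable.
* **Events** fire when severity crosses a threshold ($\theta = 4$), giving
  the closed-form event time $(\theta - s_0)/r$. Events are ascertained
  through the study end even after imaging dropout, as with surgery
  registries; imaging stops at the event.
* **Scans** occur at annual visits over 9 years of follow-up with 5%
  per-visit dropout, so "last available scan" selection is non-trivial.
* **Grades** 0–4 bin severity at fixed cuts (0.8, 1.6, 2.4, 3.2),
  left-closed, mirroring an ordinal radiographic severity scale.
* **Payloads** are either noisy feature vectors
  $x = w \cdot \text{severity} + \varepsilon$,
  $\varepsilon \sim N(0, 0.5^2 I)$, or synthetic two-band images whose
  vertical gap (a joint-space-width analog) closes linearly with severity.
* **Demographics** (integer age 55–70, binary sex, 3-level ethnicity,
  log-normal BMI) are drawn so exact matching is feasible but rejects a
  realistic fraction of subjects.

What the simulator does **not** emulate: real radiographic appearance and
its confounders, measurement error in event dates, informative dropout,
bilateral joints, site effects, or any distribution shift between cohorts.
Passing tests on this cohort therefore demonstrate the algebraic and
statistical machinery — the ordering guarantee, label handling, matching,
splitting, metric computation — not clinical-grade discrimination on real
images.

## Cohort construction conventions

Several conventions are unstated in the usual description of this design;
the package fixes them as follows:

* **Horizon boundary inclusive**: an event at exactly $h$ years counts
  positive; follow-up of exactly $h$ years yields a defined negative.
* **Labels undefined** (scan censored before $t + h$) exclude the scan
  from training and evaluation at that horizon.
* **Case second scans**: latest scan acquired 1–4 years (inclusive) before
  the event. A consequence: subjects who reach the event within a year of
  baseline have no eligible second scan, so the stable-positive pair group
  is empty at the 1-year horizon by design.
* **Control second scans**: latest scan with at least $h$ years of
  follow-up beyond it.
* **Matching** requires identical integer age (widenable via
  `age_tolerance`), identical sex and ethnicity, and BMI within 10% *of
  the case's* BMI (the tolerance anchor follows the constraint's usual
  phrasing). It is solved as maximum-cardinality bipartite matching
  (via `igraph`), so results are order-independent and no matchable case
  is stranded by a greedy pass; controls are used at most once.
* **Nested splits**: subjects are stratified by case status into 7 outer
  folds; the inner 6-fold cross-validation reuses the six non-test folds,
  each serving once as validation — exactly 42 train/validation/test
  assignments with 5/7–1/7–1/7 fractions.

## Training and ensembling

The reference scorer is a single-hidden-layer perceptron (tanh, width 8)
on payload features, fitted by minibatch Adam (default learning rate 0.05,
weight decay $10^{-4}$, 60 epochs, batch 64) with analytically derived
gradients through the composed losses; image payloads pass through a fixed
band-gap feature extractor first. Deep imaging backbones are out of scope
at desk scale, but the scorer contract — any map from payload matrix to a
real score vector — allows substituting one. Mixed batches of singles and
pairs are allowed, with absent second-scan terms masked out.

Model selection retains the parameters with the best validation AUROC,
checked each epoch (negative mean loss when the validation set is
single-class); AUROC is the natural choice given that the evaluation is
rank-based. Ensembles average member *probabilities*, which preserves the
pairwise risk ordering of the members; averaging logits would too, but
probability averaging keeps ensemble members interpretable as risks.
Class imbalance is handled by the matched design alone — no reweighting.

## Evaluation

All metrics are scan-level: each scan's risk is scored against its own
horizon label, pooling first and second scans. Choices fixed here:

* AUROC is computed from midranks (exact Mann–Whitney, ties one half);
  AUPRC by the step-wise average-precision rule over distinct thresholds.
* Confidence intervals are percentile bootstrap over scans, 1000 resamples
  by default; degenerate one-class resamples are skipped and counted.
  Scan-level resampling ignores within-subject correlation between a
  pair's two scans — deliberately, to match the scan-level evaluation
  itself.
* The DeLong test uses the structural-components variance estimate on
  paired scores, pooled across folds; zero variance with equal AUROCs
  returns $p = 1$ by convention.
* Undefined metrics (single-class cells, e.g. a grade with only negatives)
  are reported as missing, never as 0 or 0.5.

## Numerical choices

The logistic function clips scores to $\pm 500$ and uses the sign-split
branch form; outputs (and composed risks, whose float product can
saturate) are pinned inside $(0,1)$ at distance $10^{-16}$. Cross-entropy
clamps probabilities at $10^{-7}$ from both ends. Severity-to-grade cuts
are left-closed (a severity exactly at a cut takes the higher grade). All
randomness flows from one root seed through named derived substreams, so
cohorts, fits and reports are byte-reproducible.

## Problem sizes

The shipped checks run at sizes chosen to exercise the claims while
remaining desk-scale: $10^5$ score pairs for the ordering guarantee; 1000
random instances of size $\le 12$ against exhaustive metric oracles; 1000
simulated null replicates ($n = 300$ scans) for the DeLong size; 500
replicates ($n = 200$ scans, binormal scores with known true AUROC) for
bootstrap coverage; and a 5-seed end-to-end benchmark on simulated raw
cohorts of 760 subjects, which the matching step reduces to roughly 400
matched subjects — there one outer fold's six inner models are trained per
formulation and ensembled on the held-out fold.

## Known limitations

* Two scans at most per unit: compositions conditioning on longer scan
  histories are not implemented.
* The reference scorers are deliberately small; results on synthetic
  payloads say nothing about feature learning from real images.
* The DeLong and bootstrap procedures ignore within-subject correlation
  across the two scans of a pair (consistent with scan-level evaluation,
  but a caveat for inference).
* One knee per subject; no competing risks; censoring in the simulator is
  administrative or dropout-driven, never informative.
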