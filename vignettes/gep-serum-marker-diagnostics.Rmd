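---
title: "Evolving serum-marker classifiers for small cell lung cancer with gepdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evolving serum-marker classifiers for small cell lung cancer with gepdx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gepdx)
library(dplyr)
```

## The problem

Small cell lung cancer (SCLC) is aggressive, usually asymptomatic until
late stages, and far more treatable when caught early. Routine serum
biochemistry offers an inexpensive screen: SCLC patients tend to show
elevated lactate dehydrogenase (LDH), C-reactive protein (CRP),
carcino-embryonic antigen (CEA) and neuron-specific enolase (NSE), and —
through paraneoplastic SIADH — depressed sodium and chloride. No single
marker is sensitive or specific enough on its own, which motivates a
learned combination of all six.

`gepdx` implements that combination with **gene expression programming
(GEP)**: an evolutionary algorithm that searches the space of closed-form
arithmetic expressions over the marker panel, producing a transparent
symbolic classifier rather than a black-box score. The package contains
the full pipeline — a calibrated synthetic cohort generator, the GEP
engine, two fixed previously-evolved classifiers, the train/test
evaluation panel with ROC analysis, and the univariate cohort statistics —
so every stage runs and is testable without patient data.

## The GEP model

A candidate classifier is a **chromosome** of five **genes**. Each gene is
a fixed-length string in *karva notation*: a head of length $h = 8$ that
may hold functions or terminals, and a tail of length

$$t = h\,(n - 1) + 1$$

that holds terminals only, where $n = 2$ is the maximum arity of the
function set — hence the gene size $8 + 9 = 17$. The tail rule guarantees
that *any* head decodes into a complete expression tree: decoding is
breadth-first (the first symbol is the root; each function node consumes
the next arity-many unread symbols, level by level), and trailing symbols
beyond this open reading frame are silently ignored, so every genetic
operator is closed over valid programs.

The function set is
$\{+,\, -,\, \times,\, /,\, \mathrm{Exp},\, \mathrm{Sqrt},\,
\mathrm{Log},\, \mathrm{Logi},\, \mathrm{Inv}\}$
with `Log` the base-10 logarithm, `Logi` the logistic sigmoid
$1/(1 + e^{-x})$ and `Inv` the reciprocal. Terminals are the marker
columns plus a constant reference `?` that indexes, through a Dc domain of
length $t$, a per-gene pool of ten floating-point random constants drawn
uniformly from $[-10, 10]$ — the canonical random-numerical-constants
scheme. The five gene outputs are combined by the **linking function**
(addition), and a record is classified as the positive class (patient)
when the combined output $y$ is greater than **or equal to** the rounding
threshold.

Fitness is plain classification accuracy,

$$\mathrm{fitness} = \frac{TP + TN}{TP + FN + TN + FP},$$

with sensitivity $TP/(TP+FN)$ and specificity $TN/(TN+FP)$ reported
alongside. Arithmetic is made total by sentinels rather than exceptions:
division by zero, `Log`/`Sqrt` outside their domain, `Inv` of zero and
overflow all yield a non-finite value; `Exp` and `Logi` clamp their
argument to $\pm 700$ first. A chromosome that produces a non-finite
output on *any* training record receives fitness 0 — the simplest
selection-viable penalty, and one that keeps the search inside the domain
of every record it has seen.

### The generational loop

Each generation evaluates the population (100 chromosomes), clones the
single best unchanged into the next generation (elitism — which makes the
best-fitness history non-decreasing, a property the tests assert), fills
the rest by roulette-wheel selection proportional to fitness (uniform if
all fitness is zero), and applies the seven genetic operators at their
configured rates: point mutation (0.044 per symbol; head positions may
become any symbol, tail positions only terminals or `?`), head-segment
inversion (0.1), IS transposition (0.1; a short segment copied into a
non-root head position, head truncated back to $h$), RIS transposition
(0.1; a segment starting at a function symbol becomes the new root), gene
transposition (0.1; a non-first gene moves to the front), and one-point
(0.3), two-point (0.3) and whole-gene (0.1) recombination between random
pairs. Recombination swaps position-aligned blocks between structurally
identical chromosomes, so head/tail legality is preserved by construction;
an odd unpaired survivor passes through unchanged.

### The complexity schedule

The configuration block "generations without change 200 / number of tries
3 / max. complexity 5" is not given an operational definition by the tool
family that popularized it, so the package adopts one and documents it:
the run starts with 2 of the 5 genes *active* (the linking sum reads only
active genes), and after 200 generations without improvement of the best
fitness it restarts — a fresh random population seeded with the best-ever
chromosome — with one more active gene, up to 3 restarts and at most 5
active genes. Two further controls that the original tool leaves unstated
are exposed as parameters with defaults: a total generation cap
(`max_generations = 2000`, so runs always terminate) and the rounding
threshold (0.5, the standard default when a 0/1 target is modelled by a
numeric expression). Ties for "best" resolve to the lowest population
index, making runs bit-reproducible for a fixed seed.

## The two published classifiers

Two previously evolved classifiers over this panel are shipped as fixed
formulas so cohorts can be scored without re-running evolution:
`model1_score()` over all six markers
($x_0$ = LDH, $x_1$ = CRP, $x_2$ = Na$^+$, $x_3$ = Cl$^-$, $x_4$ = CEA,
$x_5$ = NSE) and `model2_score()` over the four tumor-marker inputs
($x_0$ = LDH, $x_1$ = CRP, $x_2$ = CEA, $x_3$ = NSE). The six-marker
formula's flat typesetting is ambiguous about what each $e$ exponent
covers; the package's canonical parse applies each $e$ to the single
following sigmoid term, and the parse lives in exactly one place
(`model1_score()`, mirrored by a hand-built expression tree used in the
cross-module tests) so an alternative reading can be swapped in. Domain
violations ($x_0 \le 0$ or $x_3 \le 0$, outside the `log10` domains)
return `NaN`; exponent arguments are clamped to $\pm 700$ because raw-unit
CRP$\times$NSE products otherwise overflow — a policy that only affects
extreme inputs.

Because the original rounding threshold and any input normalization are
not recoverable, thresholded accuracies of these formulas on new data are
indicative only; per-marker ROC analysis and the threshold-free score AUC
are the stable quantities. Optional per-marker min–max scaling (fitted on
a reference cohort, persistable as JSON) is provided but off by default.
Note that scaling maps the reference minimum of LDH to 0, which is outside
the formulas' `log10` domain — such records score `NaN` and are dropped
from ROC sweeps with a warning.

## The synthetic cohort generator

The generator emulates the study conditions: 145 SCLC patients, 130 NSCLC
patients and 155 non-cancer controls, with per-group marker distributions
calibrated to the published group-wise medians and observed ranges
(e.g. SCLC NSE median 24.27 ng/ml, range 1.07–370; control LDH median
146 u/l, range 55–397).

* **Family.** Only a median and a range are published per group, so the
  family is a modelling choice: truncated log-normal for LDH, CRP, CEA and
  NSE (their ranges are strongly right-skewed) and truncated normal for
  the physiologically regulated electrolytes Na$^+$ and Cl$^-$.
* **Spread.** The scale parameter is set so the *untruncated* 0.5th–99.5th
  percentile span matches the printed range (for a log-normal with a
  non-positive printed lower bound, the upper half-span is used).
* **Location.** The location parameter is then solved numerically so the
  *truncated* distribution's median equals the printed median exactly —
  asymmetric truncation would otherwise bias the realized median off
  target. The root is bracketed on a grid around the target before
  refinement, because the objective saturates in the far tails.
* **Dependence.** The one strong published inter-marker association, the
  Na–Cl rank correlation of 0.705, is induced by a Gaussian copula with
  $\rho = 2\sin(\pi \rho_s / 6)$; all other pairs (all below 0.31) are
  left independent. Truncation by inverse-CDF restriction preserves ranks,
  so the realized Spearman correlation matches the target (the tests
  check $\pm 0.05$ at $2 \times 10^4$ per group).
* **Demographics.** Sex, age (truncated normal, integer years), smoking
  and disease stage are drawn from the published marginals, independently
  of the markers — no marker–demographic coupling is published. The
  stage split within NSCLC (I vs II) is unreported and set to 50/50.
* **Determinism.** One RNG substream per group, derived from a single
  integer seed; a fixed seed reproduces the cohort byte-identically.

What passing tests on this generator do **not** show: real serum panels
have measurement error, batch effects, marker–demographic correlations and
inter-marker dependences beyond the Na–Cl pair, and the true group
distributions need not be (log-)normal. Calibration tests demonstrate that
the generator reproduces the published summaries, not that the classifiers
would reproduce their published accuracies on real measurements — those
require the original data.

## Evaluation and statistics

`split_cohort()` partitions at 4/5 by default, stratified by class, with
per-class rounding of the training fraction. The historical allocation of
115/125 training subjects out of 145/155 cannot arise from per-class
rounding of 4/5 (which gives 116/124); the `train_counts` argument
reproduces any exact allocation. `panel_metrics()` reports the
confusion-matrix rates plus CC, MSE, RMSE, MAE, RAE and RSE computed on
raw scores (clipped to $[0,1]$, consistent with reading the model output
as a class probability) against the 0/1 labels — not on thresholded
classes; both conventions exist and this one is stated rather than
asserted as original. `roc_curve()` sweeps thresholds over the unique
scores and integrates trapezoidally; orientation is preserved, so markers
depressed in cases (Na$^+$, Cl$^-$) legitimately show AUC < 0.5, and the
AUC equals the midrank Mann–Whitney $U/(n_1 n_2)$ to $10^{-10}$ (a
cross-module test). `run_experiment()` composes filter → label → split →
score/train → metrics, supports stage-stratified and NSCLC-vs-control
designs, seeded control subsampling (which of the 155 controls entered the
130-control comparison is unstated, so the package treats it as a seeded
random choice), and triplicate runs with the best-by-training-accuracy
replicate flagged.

The univariate layer uses midranks, a tie-corrected variance and no
continuity correction for the Mann–Whitney deviate
$Z = (U - n_1 n_2 / 2)/\sigma$ — the convention of the major statistical
packages — and the uncorrected Pearson chi-square, which reproduces the
published demographic p-values. $Z$ is signed (negative when the first
sample ranks lower); published tables that print all comparisons negative
follow a min-$U$ convention that affects only the sign, never the
p-value. The normal approximation is accurate for the cohort sizes this
package targets; below about 3 observations per group the discrete $U$
distribution is too coarse for *any* normal approximation, and exact
enumeration should be used instead (the test suite quantifies this
boundary).

## Worked example

```{r example, eval = FALSE}
cohort <- generate_cohort(cohort_spec(), seed = 1)
summarize_cohort(cohort)

# univariate screen, control vs SCLC
cohort_marker_tests(cohort, c("CONTROL", "SCLC"))

# score with the published four-marker classifier and evaluate
run_experiment(cohort, model = "published2", seed = 1)

# evolve a fresh classifier on a training split
lab <- dplyr::filter(cohort, group != "NSCLC") |>
  dplyr::mutate(class = as.integer(group == "SCLC"))
sp <- split_cohort(lab, seed = 1)
fit <- gep_evolve(sp$train, params = gep_params(max_generations = 500,
                                                seed = 1))
glance(fit)
autoplot(fit)
```

Problem sizes used by the shipped checks — 200-subject recovery tasks,
$2\times10^4$-per-group calibration cohorts, five-seed replication — were
chosen as the smallest sizes at which the stochastic properties under test
are stable.

## Known limitations

* The restart/complexity schedule is one documented reading of an
  under-specified configuration block; other readings (e.g. growing head
  length instead of active genes) are plausible.
* The six-marker formula's exponent grouping is a parse decision; scores
  under a different parse would differ.
* Fitness-0 penalties for non-finite outputs discard partial information;
  a softer penalty could preserve selection pressure on almost-valid
  programs.
* The generator models group distributions marginally (plus one copula
  pair) and cannot stand in for real measurements when validating
  diagnostic accuracy.
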