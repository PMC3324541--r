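---
title: "Extracting combinatorial expression rules from binary ion-channel panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting combinatorial expression rules from binary ion-channel panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ionrules)
```

## The problem

Single-cell multiplex RT-PCR screens of neocortical neurons produce, per
neuron, a binary presence/absence call for each gene of an ion-channel panel
together with three categorical labels: cortical layer (L2/3–L6),
morphological type (LBC, MC, NBC, PC) and electrical firing type (cAD, cFS,
dFS, cST) — the *LME* triple. The scientific question is whether the
expression of one channel gene is predictable from the expression of the
others within a neuronal type, i.e. whether *combinatorial expression rules*
such as `Kv1.4 = HCN3` or `Kv1.2 = Kv3.1 AND Kv3.2` govern which channels a
neuron deploys. Exhaustive screening of gene combinations is hopeless — a
26-gene panel admits $2^{26}-1 = 67{,}108{,}863$ non-empty subsets — so the
package uses a greedy wrapper around a supervised classifier to find the
informative combinations, then reads the *form* of each relationship off a
Boolean minimization of the within-type truth table.

`ionrules` implements that pipeline end to end: data ingestion and
model/generalization splitting, per-gene classifiers with hyper-parameter
tuning, incremental input-gene selection (the "iSVM"), two resampling null
models, exact Boolean rule extraction, and a directed gene-predictivity
network. Because the original 203-neuron dataset was never deposited, the
package ships a synthetic-data generator that emulates the study design, and
every statistical claim the package makes is demonstrated on that generator.

## The model

For a target gene $i$, neurons are encoded as a 12-dimensional one-hot block
for (L, M, E) plus the raw 0/1 values of any selected input genes. The base
classifier is a soft-margin SVM (RBF or linear kernel; `e1071`/libsvm).
Hyper-parameters are tuned by grid search over
$C, \gamma \in \{2^{-15}, \dots, 2^{15}\}$ with 31 integer exponents per
axis — 961 grid points — scored by $k$-fold cross-validated accuracy
(default $k = 10$). The printed range "[2e-15, 2e15]" is read as powers of
two: the best-parameter bounds reported alongside it ($3.05\times10^{-5}$,
$0.03125$, $32$) are exactly $2^{-15}$, $2^{-5}$ and $2^5$, which fixes the
interpretation. A logistic-regression baseline uses the same features and CV
protocol; because expression frequencies are low (panel mean near 23%), its
decision cutoff defaults to the panel-mean expression frequency rather
than 0.5.

Incremental selection then iterates: every not-yet-selected candidate gene
is appended to the current inputs, re-tuned by its own grid search (default;
a cheaper tune-once mode reuses the base parameters), and the best candidate
is retained only if it *strictly* increases CV accuracy. The loop stops when
no candidate improves. Two design choices matter here:

* **Paired folds.** One fold assignment per target, derived from the seed,
  is shared by the base model and every candidate evaluation. Comparisons
  are therefore paired: a candidate must beat the base on the same split of
  the data, not on a luckier reshuffle.
* **Strict improvement, no epsilon.** Accuracy ties (within $10^{-12}$,
  used only to detect floating-point ties) do not retain a candidate.
  Tie-breaks are deterministic throughout: grid ties prefer smaller $C$,
  then smaller $\gamma$, then the RBF kernel; candidate ties prefer the
  lowest panel index.

## Null models

Two constructions calibrate the selection against chance:

* **rdiSVM** (random data): every expression bit is redrawn independently
  from a Bernoulli distribution at the gene's observed marginal frequency,
  with neurons, labels and group counts preserved, and the full incremental
  fit is repeated. Frequencies are matched overall rather than per type
  (a per-type option exists), since the construction is meant to destroy
  all between-gene structure while preserving marginals.
* **riiSVM** (random inputs): the fitted model's input genes and
  hyper-parameters are replaced by uniform random draws — input count
  uniform on 1..5 per run (5 being the deepest selection observed in
  practice), inputs and the $(C, \gamma)$ grid point drawn jointly — and
  the model is re-scored.

The accuracy streams of the fitted models (re-scored under re-randomized CV
folds, their only stochastic source), riiSVM and rdiSVM are compared by
one-way ANOVA and pairwise Student's t-tests. Classifier discrimination is
summarized by the rank-based AUC (ties count one half); a classifier that
always predicts "not expressed" scores 0.5.

## Rule extraction

Rules are only sought where the added inputs demonstrably helped: in the
LME types whose held-out per-type accuracy under the full model strictly
exceeds the base model's. Within such a type, input genes constant across
the type are dropped (they carry no within-type information; they are
reported as context), the truth table of observed input patterns is built,
and the majority target label per pattern defines an on/off-set. Tied
patterns and unobserved patterns are don't-cares. Exact Quine–McCluskey
minimization (with don't-cares) returns a minimal DNF; ties between covers
prefer fewer clauses, then fewer literals, then lexicographic order, so
minimization is deterministic, canonicalization is idempotent, and logically
equivalent formulas always print identically — which is what makes
cross-type consistency grouping a string comparison. A rule's *occurrence*
is the fraction of the type's neurons whose observed target bit equals the
formula's prediction; rules at or above `min_occurrence` (default 0.8,
matching the observed quality of reliable rules) are retained, and weaker
rules are reported rather than discarded, since documented exceptions (68%,
57%) are part of the method's output. Exact Quine–McCluskey is sufficient
here because selections rarely exceed five inputs; no heuristic (ESPRESSO-
style) minimizer is needed.

Constant formulas (`TRUE`/`FALSE`) can arise when the target's majority
label ignores the inputs; they are flagged with `constant = TRUE` since
"the inputs do not matter" is a different claim from a combinatorial rule.

## The synthetic generator

`generate_synthetic()` emulates what the study's data look like:

* **Design**: neurons in LME groups with fixed counts. The default is the
  printed design — ten model groups of 7, 7, 4, 9, 12, 4, 6, 5, 5, 6
  neurons (65 total) plus fourteen held-out groups totalling 18 — so
  `split_model_generalization()` reproduces the 65/10 and 18/14 partition
  with nothing discarded.
* **Marginals**: per-gene Bernoulli frequencies, by default drawn once from
  U(0.05, 0.5), matching the reported scale (no gene above ~50%, panel mean
  near 23%).
* **Rules**: in planted mode, selected targets are computed from a Boolean
  formula within their applicable types and remain Bernoulli elsewhere.
* **Noise**: false negatives only — expressed bits flip to 0 with
  probability `fn_rate` across the whole matrix — because the assay's
  false-positive rate is essentially nil while its dropout rate is high
  (estimated up to 66%). A symmetric-noise flag exists for robustness
  studies only.

What the generator does *not* emulate: correlated expression beyond the
planted rules, per-type marginal differences, and label noise in L/M/E.
Passing tests on this generator therefore demonstrate that the machinery
recovers structure it was built to represent, not that real neurons obey
such rules.

## Problem sizes and numerical choices

The test suite and the acceptance script run the pipeline at reduced but
structurally faithful sizes, chosen so the full suite completes in minutes
on one CPU: toy panels of 4–5 genes with a 3×3-exponent grid for the
oracle-equivalence and rule-recovery simulations, and the full 26-gene
panel at the 65-neuron design (10-fold CV, coarse grid, tune-once mode) for
the null-calibration study. The grid resolution affects absolute
accuracies only marginally on binary features; all comparisons in those
studies are internal (greedy vs exhaustive, planted vs null), so the
conclusions do not hinge on grid density.

Degenerate cases are handled explicitly: single-class training folds
predict that class; non-convergent logistic fits fall back to
majority-class prediction and are flagged; AUC is undefined (NA) for
single-class labels; all-tied truth tables yield "no rule".

## Known limitations

* Greedy forward selection can in principle stop short of the best gene
  subset (it is compared against exhaustive search only on small panels);
  the strict-improvement stopping rule makes it conservative.
* On fully random data the selection rate is *low but not zero*: the
  maximum of ~25 paired CV comparisons occasionally clears the strict
  improvement bar by chance at $n = 65$, and any spurious selection inside
  a small type produces a high in-sample-occurrence rule, because
  occurrence is evaluated on the same neurons that built the truth table.
  A held-out occurrence estimate would remove this bias but is not part of
  the method being implemented.
* Per-type accuracies rest on very few neurons (4–12), so candidate-type
  detection is noisy at realistic group sizes.

## A worked example

```{r example, eval = FALSE}
library(ionrules)

panel <- gene_panel(c("A", "B", "C", "D"))
data <- generate_synthetic(synth_config(
  panel = panel,
  group_counts = tibble::tibble(layer = c("L2/3", "L4"),
                                morphology = c("MC", "PC"),
                                etype = c("cAD", "cFS"), n = c(25, 25)),
  frequencies = c(A = 0.3, B = 0.7, C = 0.7, D = 0.4),
  planted_rules = list(list(target = "A", formula = "B AND C")),
  mode = "planted", seed = 7
))

fit <- fit_all_targets(data, panel, k = 5, seed = 1,
                       grid = make_hyper_grid(-3, 3, 3))
tidy(fit)
rules <- extract_rules(data, fit, panel)
rules
autoplot(build_network(fit))
```

The fitted model for `A` selects `B` and `C`, its accuracy rises from the
LME-only baseline to 1.0, and `extract_rules()` returns `B AND C` with
occurrence 1.0 in both types — the planted rule, recovered.
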