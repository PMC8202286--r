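---
title: "Interventional probing of adverse-event report classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interventional probing of adverse-event report classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvprobe)
```

## The problem

Spontaneous adverse-event reporting systems (FAERS and its relatives)
collect case reports: a patient, a suspect drug, a dose, an indication, a
set of adverse events, and a clinical outcome. Signal detection asks which
clinical terms are associated with — and ideally contribute causally to —
a serious endpoint such as death or acute liver failure. Classical
disproportionality statistics (PRR, ROR, EBGM) answer this term by term
from 2×2 count tables. `pvprobe` implements a complementary,
classifier-based route:

1. each case report is rendered as a short template sentence;
2. a probabilistic classifier is fitted to predict the binary endpoint
   from the sentence;
3. the fitted model is *probed interventionally*: for every clinical term
   the predicted endpoint probabilities are split into a "do" stratum
   (reports containing the term) and a "not do" stratum (feature observed,
   term absent), and the one-tailed two-sample z-test asks whether the
   model assigns systematically higher endpoint probability under the
   intervention.

Terms surviving a multiplicity correction form the enriched causal set
`L`; re-running the probe inside the stratum of an enriched parent term
yields second-level terms and, recursively, a causal tree.

## The model and its assumptions

Write $p'_i = F(s_i)$ for the model's predicted probability that report
$i$ is endpoint-positive. For a term $t$ of feature $f$:

$$L_1 = \{p'_i : t \in f_i\}, \qquad
  L_2 = \{p'_i : f_i \neq \emptyset,\ t \notin f_i\},$$

$$z = \frac{\bar L_1 - \bar L_2}
           {\sqrt{s_1^2/n_1 + s_2^2/n_2}},$$

with unbiased variances (the unpooled Welch form; a pooled variant is
available via `pooled = TRUE` for sensitivity analysis). The p-value is
the upper normal tail, Bonferroni-corrected by default over every term
tested in the run (Benjamini–Hochberg selectable). The probe treats the
classifier as the system under intervention: it measures whether the
*model's* conditional distribution responds to the term. Whether that
transfers to the data-generating process depends on the classifier being
well calibrated — see the limitations below.

## Interfaces at a glance

```{r, eval = FALSE}
sim      <- default_sim_config(5000, seed = 1)   # planted ground truth
reports  <- generate_cases(sim)
sent     <- generate_sentences(reports, sim$schema)
split    <- stratified_split(sent, seed = 1)
model    <- fit_endpoint_classifier(split$train, split$dev,
                                    classifier_config("token-logistic"))
probs    <- predict(model, sent)
terms    <- infer_causes(reports, probs, sim$schema)
tree     <- build_causal_tree(reports, probs, sim$schema)
signals  <- score_signals(reports, sim$schema)   # PRR / ROR / EBGM
```

`run_pipeline()` chains all stages and writes artifacts plus a manifest;
`inst/scripts/pvprobe` exposes the same stages as shell subcommands.

## Design decisions

**Preprocessing boundaries.** Missing-value tokens (`"UNK"`, `"UNKNOWN"`,
`"()"`, empty) normalise to the empty set. Doses are dichotomised at
100 mg with the boundary in the *low* class (the class wording "larger
than 100 mg" is read as a strict inequality). Ages bin as `[0,18)`,
`[18,40)`, `[40,65)`, `[65,∞)`; 65 itself goes to the oldest bin, the only
assignment consistent with four exhaustive groups.

**Label-leak prevention.** The endpoint term must not appear in the
rendered sentence, otherwise the classifier learns a copy rule and the
probe degenerates. When the endpoint is an adverse-event term, only that
term is excised; when the endpoint is an outcome, the whole outcomes
clause is dropped (outcomes co-occur too strongly with each other to be
safe); for any other endpoint feature its slot is blanked.

**Splitting.** Stratified 0.64/0.16/0.20 by default: per-class seeded
shuffle, floor allocation, largest remainders to train first. Class totals
are conserved exactly.

**Classifier.** Two interchangeable kinds behind one contract.
`token-logistic` is logistic regression on bag-of-token counts, fitted
full-batch with Adam — fast, convex, bitwise reproducible; it is the
workhorse for simulation studies. `transformer` is a compact bidirectional
self-attention encoder (2 layers, 2 heads, hidden 32 by default, ReLU
feed-forward blocks, post-layer-norm) with a CLS-token softmax head,
trained from scratch on the corpus vocabulary with hand-written
backpropagation verified against finite differences in the test suite.
Checkpoints are scored on the development split every `checkpoint_every`
steps and the checkpoint with maximum dev accuracy wins, earliest step on
ties; the decision threshold is 0.5. Non-separable corpora need a few
hundred steps before the dev accuracy plateaus — an under-trained model
makes the probe meaningless, so convergence should always be checked in
the returned trace.

**Probe defaults.** `min_group_size = 30` (normal-approximation
heuristic); strata below it are skipped and logged. All labeled reports
enter the probe by default because the procedure is defined over the
whole dataset; restricting to held-out reports changes nothing structural
(the probed object is the model, not the sample). Degenerate strata (zero
variance on both sides) return $z = 0, p = 0.5$ on equal means and a
signed infinite z sentinel otherwise, rather than propagating NaN.

**Tree.** The root is the single globally highest-z enriched term (a
per-feature-roots mode exists). At level $N$ the candidate children of all
level-$N-1$ parents are pooled, ranked by z and truncated to at most $N$
— the cap keeps the display to the most significant factors and produces
the widening 1, 2, 3, ... shape. A feature already fixed on the path is
not re-tested, since conditioning a term on itself is degenerate.

**Disproportionality.** PRR with uncorrected Pearson χ² (Yates behind a
flag), signal at $a \ge 3$, PRR ≥ 2, χ² ≥ 4. ROR with log-normal 95% CI
and Haldane–Anscombe +0.5 on zero cells, signal at lower limit > 1. EBGM
via the DuMouchel gamma-Poisson shrinker: $a \sim \text{Pois}(\lambda E)$
with $E$ from the 2×2 margins under independence, a two-component gamma
mixture prior on $\lambda$, hyperparameters fitted by multi-start
L-BFGS-B on the negative-binomial marginal; EBGM $= \exp E[\log\lambda
\mid a]$, EB05 the 5th posterior percentile by root finding on the
mixture CDF, signal at EB05 ≥ 2.

**Robustness.** Enriched-term lists from repeated seeds are compared by
the average percentage of common terms and by POT curves on z-ranked
prefixes; the POT denominator is the prefix size $k$. z ties break
alphabetically so rankings are well defined.

## What the generator emulates — and what it does not

`default_sim_config()` draws gender, age group, primary suspect drug,
dose class, indication, multi-valued adverse events and outcomes for each
report, with 10% missingness per non-endpoint feature. The endpoint
("death" in outcomes) follows a logistic model: intercept −1.5 (baseline
positive rate ≈ 0.33, comparable to the 0.57–0.71 positive/negative mixes
of real endpoint corpora), one strong planted cause (drug APAP, log-odds
+2.0 at prevalence 0.3) and one second-level effect (+1.0 for female, but
only among APAP reports — the ground-truth tree edge). Every feature
keeps zero-effect terms as negative controls.

The generator does *not* emulate duplicate reports, free-text narratives,
reporting dynamics over time, correlated feature structure (drug–
indication coupling), or terminology noise. Tests passing on this fixture
therefore demonstrate the machinery — recovery of planted effects,
determinism, calibration behaviour — not performance on real
pharmacovigilance data.

## Numerical choices

Cross-entropy clamps the true-class probability at $10^{-12}$. Layer norm
uses $\epsilon = 10^{-5}$. Adam uses $(0.9, 0.999, 10^{-8})$ with linear
warmup. EBGM optimisation runs from 5 starts (3 fixed, the rest seeded
jitter) in log/logit parameterisation, bounded at $e^{\pm 12}$. EB05 is
found by `uniroot` at tolerance $10^{-10}$. Probabilities are clipped to
$[0,1]$ at the predict boundary. All randomness flows through an
RNG-state-preserving seed wrapper, so library calls never disturb the
caller's stream.

## Problem sizes used by the test and acceptance suites

The simulation studies run at the sizes of the study design they mirror:
null calibration at $n = 3000$ with 30 terms over 200 Monte-Carlo runs;
planted-cause recovery at $n = 5000$ over 20 seeds; tree recovery at
$n = 8000$ over 20 seeds; the acceptance script uses 50 null runs, 10
recovery seeds and 5 tree seeds with the same generators. The
token-logistic classifier drives these studies; the transformer is
exercised on smaller corpora where its from-scratch training converges in
a few hundred steps.

## Known limitations

*The probe inherits the classifier's estimation noise.* The z-test treats
the fitted probabilities as data. But a fitted coefficient for a null
term is itself noisy, and that noise moves the do/not-do stratum means by
an amount that the within-stratum spread of probabilities does not
reflect — the ratio is invariant to uniform shrinkage of the
coefficients, so early stopping does not remove it. On pure-null
simulations the family-wise false-positive rate of the probe is therefore
far above the nominal Bonferroni level (the package's own Monte-Carlo
reports it honestly), and weak enrichments near the significance boundary
on real data should be read as hypotheses, not discoveries. Strong
signals — z an order of magnitude above the boundary — are unaffected in
practice, planted causes are recovered with the top z in their feature
essentially always, and every conventional-method signal is contained in
the probe's enriched set on the planted fixture. A principled fix
(propagating classifier uncertainty into the test, e.g. by refitting
across bootstrap resamples) is out of scope here.

*Other caveats.* The probe conditions on one term (or path) at a time and
does not adjust for confounding beyond what the classifier's conditional
distribution encodes; sibling terms in the tree are not oriented against
each other; EBGM expected counts use the independence margins rather than
stratified expectations.
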