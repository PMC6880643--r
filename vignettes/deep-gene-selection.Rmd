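---
title: "Deep gene selection: an evolutionary wrapper for expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep gene selection: an evolutionary wrapper for expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dgsel)
```

## The problem

Microarray and other bulk expression studies routinely measure tens of
thousands of probes on a few dozen to a few hundred samples. For a
classification endpoint — tumour recurrence versus non-recurrence, say —
almost all of those attributes are irrelevant, and the sample size is far
too small to fit a classifier in the full space. *Wrapper* feature
selection scores candidate attribute subsets by the cross-validated
accuracy of an actual classifier, which captures interactions that
univariate filters miss, but the search space of subsets is astronomically
large.

`dgsel` implements a gene-expression-programming (GEP) wrapper that makes
this search tractable by *shrinking the search space itself* as the
search proceeds: every generation, the attributes carried by the fittest
half of the population become the entire candidate pool (the *terminal
set*) for the next generation. After a few dozen generations the pool has
contracted from thousands of attributes to a handful, and the reported
subset typically holds 2–6 genes.

## Encoding: karva chromosomes

A candidate subset is encoded as a GEP chromosome of `N` genes. Each gene
is a fixed-length string with a *head* of length `h` (operator tokens or
attribute IDs) and a *tail* of attribute IDs only, with

\[ t = h\,(n-1) + 1, \]

where `n` is the largest arity in the operator set (`{+, -, *, /, Q}`,
`Q` unary, so `n = 2`). Decoding fills an expression tree breadth-first;
the consumed prefix is the *expressed region* and its distinct attribute
leaves are the subset the chromosome selects. The tail length rule
guarantees every tree closes, so any string with terminals in the tail is
a valid genotype. The operators are never evaluated numerically: the
classifier sees the raw expression values of the expressed attributes, so
the operators act purely as arity-bearing connectors and no protected
arithmetic is needed.

## Generation sizing

The population should give every attribute in the current terminal set a
realistic chance of appearing. With `CH` chromosomes of length
`L = N(h + t)`, the head size is chosen each generation so that the
generation's symbol capacity is about twice the terminal-set size `T`:

\[ h = \max\!\big(h_{\min},\ \mathrm{round}\,[(T/CH - 1)/n]\big), \qquad
   h_{\min} = 3. \]

Two numerical notes. First, the rounding is *to the nearest integer*
(half away from zero): the worked size table this formula reproduces
(`T = 2200 → h = 7`, `1852 → 6`, `1583 → 5`, `1296 → 4` at `CH = 150`)
is only consistent with round-to-nearest, although the accompanying prose
says "floor"; the table wins because it is the formula's own worked
output. Second, the published derivation fixes `n = 2` in the
denominator; `dgsel` generalizes it to the configured arity, which
reduces to the same formula for the default operator set.

## Attribute weights

Before the loop starts, every attribute is ranked once by *gain ratio*:
the information gain of its best single binary split (thresholds at
midpoints of consecutive distinct sorted values, classic C4.5 style)
divided by the split's intrinsic information, in bits. Ranks are
normalized into weights summing to 1 and the table is never recomputed.
Constant attributes rank 0; if every rank is 0 the weights fall back to
uniform with a warning. Because the split depends only on the ordering of
values, the rank is invariant to monotone rescaling of an attribute.

The weights are the method's steering signal, and `dgsel` uses them in
three places:

* **Generation.** Freshly generated chromosomes draw their terminals with
  probability proportional to weight (`terminal_sampling = "weighted"`,
  the default). This is what makes the search *systematic* rather than
  blind: with 500 candidate attributes and the study-scale population of
  100 chromosomes, a generation expresses only ~350 attribute draws, so
  uniform sampling would fail to express a given attribute anywhere in
  generation one with probability ~0.5 — and an attribute never expressed
  in the fittest half is dropped from the terminal set irreversibly. At
  realistic microarray scale (tens of thousands of probes) uniform
  generation would express a given signature gene with probability of a
  few percent per run, and stable recovery of the same genes across runs
  — the behaviour this class of methods reports — would be impossible.
  Weight-proportional sampling concentrates the lottery on the attributes
  the filter already considers promising, while the wrapper's accuracy
  ranking, not the filter, decides what survives. Uniform sampling
  remains available for comparison.
* **Mutation.** A triggered chromosome has its lowest-weight *expressed*
  terminal replaced: in the head, with probability 1/2 by a random
  operator and otherwise by a strictly-higher-weight terminal (drawn
  weight-proportionally); in the tail, only by a strictly-higher-weight
  terminal, and if none exists the chromosome is returned unchanged.
  Restricting to expressed positions keeps every mutation phenotypically
  active — replacing a symbol beyond the expressed prefix would change
  nothing the classifier sees.
* **Recombination.** The strongest gene (largest weight sum over its
  expressed terminals) of the lower-fitness parent is swapped into the
  weakest gene slot of the higher-fitness parent; the child is kept only
  if its fitness strictly exceeds both parents', trying up to `N` donor
  genes before giving up.

## Fitness

A chromosome selecting subset size `s` with cross-validated accuracy `AC`
scores

\[ f = (1 - r)\,AC + r\,\frac{t - s}{t}, \qquad r \in [0, 0.5), \]

`r = 0.2` by default. Inside a generation, `t` is the current terminal-set
size, so the reward for parsimony grows as the search space contracts —
this is what drives final subsets down to a few genes. Accuracy is
estimated by a linear support-vector machine (`C = 1`, unscaled features)
under stratified 5-fold cross-validation. Folds are *redrawn every
generation* and subset scores cached once per generation: a subset keeps
its standing only if its accuracy holds up across independent fold draws,
which suppresses fold overfitting — with a single fixed fold assignment,
the wrapper reliably crowns subsets that are lucky on those folds.

Two bookkeeping rules keep cross-generation comparisons coherent:

* the ranked top half of each generation is carried into the next
  (elitist carry-over) and re-scored under the new folds and terminal-set
  size, while the bottom half is regenerated from the newly extracted
  terminal set — without carry-over, an attribute survives only if it is
  re-expressed by chance every single generation, and the selected subset
  is unstable across runs;
* the reported best-ever subset is judged on a *fixed* penalty
  denominator (the original attribute count, so values are comparable
  across generations) and on the *running mean* of its per-generation
  accuracy re-measurements, so neither the shrinking denominator nor one
  lucky fold draw decides the final answer.

## Termination

The loop stops when the terminal set and the top individual's selected
subset are both unchanged for `patience = 3` consecutive generations
("stagnation" — the selected genes and their classification result have
stopped changing), or at `max_generations = 200`. On data with real
signal the study-scale configuration typically stagnates after 20–50
generations; on label-permuted data no subset is robustly best under
fold redraws, so runs mostly exhaust their generation cap.

## What the synthetic generator emulates

`simulate_expression()` produces the study-scale conditions used by the
test-suite: 60 samples, 500 continuous attributes, 5 informative
attributes whose class-1 mean is shifted by `2` noise standard
deviations, all other attributes pure `N(0, 1)` noise, labels drawn
independently per sample with probability 0.5. It deliberately omits
several features of real expression data: correlated probe blocks,
heavy-tailed and heteroscedastic intensities, batch effects, and
class-imbalanced cohorts. Passing the recovery tests therefore shows the
search machinery works when the signal model is clean and additive; it
does not certify performance on real microarrays, where correlated
redundant probes make "the" informative set ill-defined.

The generator accepts an explicit `informative` vector, so an independent
*replicate* with the same planted truth can be drawn; the test-suite uses
replicates to measure the generalization accuracy of a selected subset.
That measurement choice matters: re-running cross-validation on the same
60 samples the wrapper optimized over cannot fall much below ~0.7 even on
pure noise (the selection maximized over thousands of candidate subsets),
so "no illusory signal" is only a meaningful check on data the selection
never saw.

## Problem sizes used by the test-suite

Recovery and null-safety checks run the full search on 60 × 500 synthetic
data with `CH = 100`, `N = 2`, `r = 0.2` over ten seeds each; recovery
runs terminate by stagnation on their own (22–46 generations), and the
null-safety runs cap `max_generations` at 60, past the range where the
informative-data runs converge (the null mean-accuracy outcome is
insensitive to the cap — permuted-label runs rarely stagnate by design).

## Numerical choices and degenerate inputs

* Rounding in the head-size law: half away from zero (see above).
* Gain-ratio ties: the smallest-threshold split wins; weight ties order
  by attribute ID, so every ordering in the package is deterministic.
* Ranking ties: equal fitness prefers the smaller subset, then stable
  input order.
* All randomness flows from the run seed; a run is bit-reproducible given
  (data, configuration, seed). The SVM fast path for the binary/linear
  case marshals directly to the same compiled libsvm routine the generic
  interface uses and is prediction-identical to it.
* Degenerate inputs fail before the loop: all-constant matrices,
  single-class labels, classes with fewer than two samples. A class
  smaller than the fold count reduces the fold count with a message.
  Mixed missingness is handled at load time: at most 5% missing per
  attribute is mean-imputed, more is an error.

## Known limitations

* The inner accuracy estimate at 60 samples is noisy (±0.03–0.04), and
  small-sample cross-validation does not always reward adding a third or
  fourth truly informative attribute; selected subsets therefore tend to
  be small, and their replicate accuracy — not their inner estimate — is
  the honest performance figure.
* The terminal set only ever contracts; an attribute dropped early can
  only matter again through the weight-guided mutation draw while it is
  still in the set, never after. This is the method's central speed
  device and its central risk.
* Multi-class labels are accepted by the weighting and accuracy modules,
  but the confusion-count report collapses to correct/incorrect beyond
  two classes.
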