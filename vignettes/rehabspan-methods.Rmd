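---
title: "Span-based NER for rehabilitation-medicine text: models and methods"
author: "rehabspan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Span-based NER for rehabilitation-medicine text: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rehabspan)
```

## The problem

Rehabilitation-medicine text in Chinese mixes long domain terms, rare
vocabulary and nested mentions: an assessment-scale name may contain a
body-part mention, a therapy description may embed an equipment term.  A
corpus for this domain annotates six entity categories — dysfunction and
performance, rehabilitation assessment, rehabilitation methods,
rehabilitation equipment, body, and drugs — as typed character spans on raw
sentences.  Per-character BIO tagging, the standard sequence-labeling
formulation, assigns exactly one tag per character and therefore cannot
represent a span inside another span.  `rehabspan` implements the
span-based formulation that can.

## The span head

Let $E \in \mathbb{R}^{n\times d}$ be the representation matrix an encoder
produces for a sentence of $n$ characters.  For each entity category the
head holds $T_{start}, T_{end} \in \mathbb{R}^{d\times2}$, an indicator
embedding $U \in \mathbb{R}^{2\times d}$ and a matching vector
$m \in \mathbb{R}^{2d}$:

$$P_{start} = \mathrm{softmax}_{row}(E\,T_{start}), \qquad
  P_{end} = \mathrm{softmax}_{row}\big((E + H\,U)\,T_{end}\big),$$

where $H$ is the $n\times2$ one-hot start-indicator matrix.  Candidate
boundaries are the rows whose entity-class probability strictly exceeds the
non-entity probability; a candidate pair $(i, j)$, $i \le j$, is accepted
as a span iff $\sigma(m \cdot [E_i; E_j]) > 0.5$.  All accepted pairs are
kept, so nested and overlapping spans decode naturally.

Three design points here were genuinely open and are resolved as follows.

* **Indicator embedding.**  Adding the raw $n\times2$ one-hot matrix to the
  $n\times d$ representation is dimensionally inconsistent; the learned
  $2\to d$ embedding $U$ is the minimal construction that injects start
  information into the end sequence while keeping shapes coherent.
* **Per-category heads.**  The binary $\mathbb{R}^{n\times2}$ boundary
  formulation is inherently per-category, and pair matching is only
  meaningful within a category, so the package instantiates one parameter
  set per schema label rather than one multi-class head.
* **Teacher forcing.**  During training $H$ comes from the gold start
  labels; at inference from the row argmax of $P_{start}$.  This stabilizes
  the end head early in training and matches the machine-reading-
  comprehension lineage of the approach.

## Loss

$$L = \alpha\,L_{start} + \beta\,L_{end} + \gamma\,L_{span},$$

where $L_{start}$ and $L_{end}$ are mean cross-entropies of the boundary
predictions over positions (averaged over categories) and $L_{span}$ is the
mean binary cross-entropy over a sampled set of candidate pairs.  The
weights default to $\alpha=\beta=\gamma=1$ (no other values are prescribed
by the method).  The loss is zero exactly at perfect prediction, and the
total is linear in the weights — both properties are asserted by tests.

The method leaves the negative-pair sample undefined.  The package labels
every gold $(start, end)$ pair 1 and every $i \le j$ combination of gold
starts with gold ends that is not itself a gold pair 0, capped at 50 pairs
per sentence and category with seed-deterministic subsampling.  This
trains the matcher on exactly the confusions it must resolve at decode
time (crossed pairs of co-occurring same-category entities) without
enumerating all $O(n^2)$ pairs.

## Encoder contract

The head consumes any encoder that maps a character window to an
$n \times d$ matrix and exposes trainable parameters.  Production
deployments would plug in a Chinese BERT-family model; the packaged
`TinyEncoder` is a character embedding table plus a position-wise mixing
layer over a three-character window with a tanh nonlinearity.  It is not a
substitute transformer and does not model long-range context; it exists so
the span head — the contribution under test — can be trained and exercised
end-to-end on a CPU in seconds.  Gradients for both encoder and head are
computed analytically (verified against central finite differences in the
test suite) and optimized with Adam.

## Training schedule and defaults

The committed defaults file (`inst/extdata/default-train.yaml`) records the
standard fine-tuning recipe: Adam, initial learning rate $2\times10^{-5}$,
warmup proportion 0.15, batch size 8, 20 epochs, a 9:1 train/test split and
5-fold cross-validation for small corpora.  The learning-rate multiplier
rises linearly from 0 to 1 over the first 15 % of steps and then decays
linearly to 0 (the post-warmup schedule is unspecified in the method
description; linear decay is the common default and is configurable).
That learning rate is calibrated to fine-tuning a pretrained transformer;
the `TinyEncoder` trains from random initialization, so desk-scale runs in
the examples, tests and acceptance script use learning rate 0.05 and up to
30 epochs — a deliberate re-calibration for from-scratch training, not a
change to the committed defaults.

Degenerate inputs are handled explicitly: sentences longer than
`maxSeqLen` are truncated with boundary-crossing entities dropped under a
warning; an entity-free corpus trains with $L_{span}=0$; an empty
candidate-pair sample warns rather than fails.

## Decoding choices

* Argmax ties (exactly 0.5/0.5) resolve to non-entity: conservative and
  deterministic.
* `maxSpanLen` defaults to 30 characters, generous for long
  rehabilitation-scale terms while bounding the pair enumeration.
* The matching threshold defaults to 0.5, the sigmoid midpoint.
* No bias terms in $T_{start}$, $T_{end}$ or $m$, matching the formulation
  literally.
* A brute-force oracle (exhaustive enumeration of all category/start/end
  triples under the same argmax and threshold rules) is kept in the test
  suite and acceptance script as an independent check of the decoder.

## Corpus model and I/O

Spans are 0-based half-open character offsets on the raw sentence string —
unambiguous slicing, no tokenizer in the contract.  The JSON dialect is the
package's own (`{"schema": [...], "sentences": [{"id", "text", "entities":
[{"label", "start", "end", "surface"}]}]}`); round-trips are exact and
byte-stable.  BIO conversion is lossy by construction for nested
annotation: the outermost spans (earlier start, then longer) are encoded
and every dropped span warns.  On BIO import, orphan `I-` tags are repaired
to `B-` with a warning — tolerant ingestion of third-party files.  The
annotation-rule validator (span overlap, all-Latin surfaces) warns rather
than errors, because nested annotation is a feature of span corpora even
where flat annotation guidelines exist; structural invariants (offsets in
range, surface/slice agreement, labels in schema) are hard errors enforced
by the `SpanCorpus` validity method.

## Metrics

Scoring is entity-level exact match (label, start, end).  Overall rows are
micro-averaged — counts pooled over categories before P/R/F1 — and
per-type rows are computed independently; whether published aggregate
tables are micro or macro is typically unstated, so the package labels its
outputs explicitly.  Zero-denominator conventions: a precision or recall
with an empty denominator is 0 when the opposite error count is nonzero;
F1 is 0 when $P+R=0$; all-empty gold and prediction score 100 by
convention.  Inter-annotator agreement is the same F1 treating one
annotator as reference; it is provably symmetric under swapping (TP is
symmetric, FP and FN exchange) and is micro-averaged.  Display rounding is
half-away-from-zero: two decimals for percent metrics, whole percents for
the low-frequency proportions (the conventions of published tables; base
R's banker's rounding would not reproduce them).

A low-frequency entity is a surface form occurring exactly once within its
entity type; the proportion is singletons over total mentions of the type.
This reading reproduces all six published numerator/denominator/percent
triples of the frequency table it models, which is the evidence for the
interpretation.

## The synthetic generator

The generator emulates the structural properties that matter to the span
head, not Chinese as a language: per-category surfaces drawn from disjoint
CJK-codepoint alphabets separated by filler runs, entity lengths 2–12
characters, 1–4 mentions per sentence with distinct categories, a
configurable fraction of sentences carrying one nested pair (outer span
strictly containing an inner span of a different type), and a low-frequency
proportion steered by drawing surfaces from a truncated power law whose
exponent is solved numerically so the expected singleton fraction
$\sum_k p_k(1-p_k)^{N-1}$ matches the target (default 0.25, the mid-range
of observed corpora; default corpus size 2,500 sentences, the scale of a
manually annotated corpus in this domain).  Distinct categories per
sentence keep within-category pair matching learnable by a local-window
encoder — the separable regime the overfit tests presume.

What the generator does **not** emulate: real lexical ambiguity (the same
surface in several categories), context-dependent entity types, segmentation
noise, and annotator disagreement about boundaries.  Passing tests on
synthetic corpora therefore demonstrate the correctness and capacity of the
machinery — decoding, losses, training dynamics, metrics — not expected F1
on real clinical text.

The simulated second annotator perturbs each span independently with
probability $r$ (boundary shift, label swap or deletion, equal thirds),
giving the closed-form expectation $R = 1-r$, $P = (1-r)/(1-r+2r/3)$
against which the agreement pipeline is checked.

## Self-training

A trained model annotates unlabeled sentences, and the pseudo-labeled
sentences are appended to the manual corpus with per-span provenance tags
(`manual` vs `model`) so reports can separate them.  Pseudo-labels carry no
confidence filter by default (none is prescribed); an optional minimum
matching probability is exposed.  Manual and model-annotated sentences are
weighted equally during subsequent training.

## Problem sizes

The test suite and acceptance script run at desk scale by design: decoder–
oracle equivalence on 1,000 random instances of up to 12 characters;
overfit recovery on a 200-sentence separable corpus with a $d=32$ encoder
(30 epochs); agreement symmetry on 200 corpus pairs; low-frequency
calibration on roughly 1,000 mentions.  These sizes exercise every code
path while keeping a full run under a minute.

## Known limitations

* The `TinyEncoder` sees a three-character window; entities whose
  boundaries require long-range context need a real pretrained encoder
  behind the same contract.
* Pair matching scores each pair independently; no global decoding
  constraint (e.g. non-crossing structure) is imposed.
* Checkpoints serialize only `TinyEncoder`-backed models; external encoders
  must be stored by reference.
* The BiLSTM-CRF baseline is out of scope; structural comparisons use the
  softmax BIO head.
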