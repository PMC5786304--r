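---
title: "treeddi: model, preprocessing and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{treeddi: model, preprocessing and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treeddi)
```

## The task and the pipeline

A drug–drug interaction (DDI) extraction system receives sentences in
which drug mentions are annotated, and classifies every candidate drug
pair: does the sentence assert an interaction, and of which kind
(`advice`, `effect`, `mechanism`, `int`)? `treeddi` implements this as
a five-part pipeline — corpus ingestion, preprocessing, parse-tree
annotation, a tree-LSTM classifier, and evaluation — plus a synthetic
corpus generator so everything is runnable and testable offline.

## Preprocessing

**Anonymization.** Target drugs are replaced by placeholders
(`Ddrug0`, `Ddrug1`, ... assigned by order of first span start). This
shrinks the vocabulary and resolves discontinuous mentions: a mention
like "nonheme ... iron" collapses to a single placeholder at its first
span, and the *union* of all annotated spans is deleted. Taking the
union is what makes shared words work — in the classic example,
"Calcium ... absorption of both nonheme and heme iron.", the word
"iron" belongs to two mentions at once; deleting the union and
inserting placeholders at first-span anchors yields exactly
"... of both Ddrug1 and Ddrug2." Overlap between *first* spans (the
anchors themselves) is ill-posed and raises a validation error.

**Tokenization and number masking.** Tokens are maximal alphanumeric
runs, signed integer/decimal literals, or single punctuation
characters, with character offsets retained. After tokenization, any
token that is a whole number (`^[+-]?\d+([.,]\d+)?$`) becomes `#`;
tokens merely containing digits (`CYP3A4`) are untouched. "Independent
number" is not defined more precisely anywhere we could anchor to, so
the whole-token regex is the frozen interpretation.

**Candidate generation and filtering.** Every annotated pair (or every
unordered placeholder pair, for unannotated corpora) becomes one
instance. Two rules remove likely-negative instances:

1. *same-drug*: the two surface forms are equal after trimming and
   lower-casing. True synonym resolution would need an external
   normalizer; the package exposes a `synonym_map` hook and defaults to
   surface equality, the reproducible core of the rule.
2. *coordination*: both targets sit in one run of ≥ 3 drug
   placeholders separated only by `,`, `and`, `or`, `/`. The rule is
   lexical rather than parse-based: the cited criterion (drugs in one
   coordinated noun phrase) comes with no algorithm, and the token-run
   formulation reproduces the published examples — in particular a
   two-drug coordination ("both Ddrug1 and Ddrug2") is *kept*.

Gold positives are never filtered from a training split by default
(`filter_train_positives` exposes the other reading, which the sources
leave unstated). Gold positives filtered from a *test* split go into a
ledger and are charged as false negatives at evaluation time, so
filtering cannot inflate recall.

**Deduplication** keys on the post-preprocessing token string plus the
target indices: sentences are deduplicated in effect, but the
classified unit is the instance, and two instances from one sentence
with different targets are both kept.

## Parse trees

Bracketed (Penn-Treebank-style) trees are read as-is; `binarize()`
right-branch-collapses n-ary nodes into `parent|merge` auxiliaries and
collapses unary chains into their child. Any consistent binarization
convention yields a valid binary tree, and internal-node labels never
affect features — only structure does — so the dialect is fixed here
rather than delegated to an external tool. Leaves must match the
preprocessed tokens exactly; a mismatch (e.g. a parser that
retokenized) is an error, not a heuristic repair, because silently
shifting leaves corrupts every position feature downstream. The
synthetic generator emits trees directly over the preprocessed tokens,
so alignment is guaranteed by construction there.

Annotation walks the tree once: a leaf gets its containment flag
(is it a target?) and signed distances `d_i = target_i − index`; an
internal node takes, per component, the child value of smaller absolute
value, and the OR of containment flags. When the two absolute values
tie, the left child's value is kept. Because sibling subtrees span
contiguous leaves, an equal-magnitude tie always has equal sign too, so
the tie-break never changes a value — it exists to make the procedure
total and order-stable.

## Input features

Each node input is `x_j = [containment (10) | code(d1) (10) |
code(d2) (10) | word vector (200)]`, length 230.

The distance code is thermometer-style: component 1 flags `d ≥ 1`, and
components 2–10 are |d| thresholds 21, 16, 11, 6, 5, 4, 3, 2, 1.
Distance 0 encodes as all-zeros; each |d| ≤ 5 has its own vector;
beyond 5 distances share vectors in buckets of five. The published
table omits the negative long-range columns for space; the symmetric
completion used here (thresholds on |d|) matches every printed column
and the "units of 5" bucketing, and is the only completion that does.

Word vectors are **static**: they are never updated during training
(the ablation evidence favors frozen embeddings at this data scale,
and it keeps the gradient surface small). Known words come from a
plain-text embedding file (`word v1 ... v200` per line); unknown words
and internal nodes draw a uniform(−0.05, 0.05) vector once per key
from a hash-seeded generator, so lookups are reproducible and
independent of lookup order. Internal-node vectors are shared per
constituent label by default — nodes with the same label play the same
structural role, and sharing keeps the number of random draws bounded —
with a per-node policy available (`internal_policy = "node"`).

## The tree-LSTM

The model is a binary child-pair tree-LSTM: gates `i, o, u` are
computed from `[x_j, h̃_j]` with `h̃_j` the sum of the two child hidden
states, and each child has its own forget gate `f_jk` computed from
`[x_j, h_k]` with weights shared across children (the child-sum
formulation). Leaves use `h̃ = 0` and no forget terms. Only the root
hidden state is classified, by an affine layer; internal-node outputs
are never scored.

**Loss.** Softmax cross-entropy, read as one-hot selection of the
gold-class log-probability, averaged over the batch. Detection
positives carry weight 3. The weighting is applied to the detection
classifier only: the source ties it explicitly to the detection loss,
and type classifiers see a much milder imbalance; a flag extends it if
wanted.

**Recurrent dropout.** A Bernoulli(keep_p) mask multiplies the
candidate update `u` during training; evaluation is the identity. The
literal published rule (`mask*x` in training, `x` otherwise) leaves a
train/test scale mismatch, so the default is inverted dropout
(`mask/keep_p`), with `dropout_variant = "paper"` reproducing the
literal rule for fidelity experiments. One mask is drawn per tree per
step and shared across nodes (recurrent-dropout style); per-node masks
are available via `mask_scope = "node"`.

**Optimization.** Mini-batch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8 —
the library defaults of the era, unstated in the source) over shuffled
instances; weights initialize uniform(−0.05, 0.05), biases at zero,
all seeded. Trees are processed by per-tree recursion; batching only
groups gradient updates. Correctness over throughput: dynamic batching
à la TensorFlow-Fold is an optimization, not part of the contract.
Training is bitwise deterministic given the seed.

**Defaults.** The published hyperparameter search fixes hidden size
128, batch 100, containment block 10, detection learning rate 8e-4,
keep probability 0.75, 100 epochs; these are `train_config()`'s
defaults. `separable_train_config()` (hidden 32, batch 25, lr 0.005,
keep 0.9, 15 epochs) is the package's frozen setting for toy-scale
learnability checks, where corpus-scale values leave too few Adam
steps to converge.

**Ensemble.** Ten members, identical architecture, seeds
`seed + 0:9`; prediction sums the members' root logits and takes the
argmax. Ties break toward the lower class index everywhere.

**Gradients** are hand-derived backpropagation through the tree
recursion (R has no autodiff in this stack). They are validated two
ways: a scalar-loop forward oracle (shared-code-free) on random trees,
and central finite differences at two step sizes — a genuine backprop
defect disagrees by O(1) at every step size, while difference-quotient
roundoff shrinks at the better-conditioned step.

## Classification modes and evaluation

*One-stage* runs a single 5-class pass. *Two-stage* runs the binary
detector first; predicted negatives are final, predicted positives are
re-scored by a 4-class typer trained on gold positives. Detection
false negatives therefore never reach the typer — the cascade bound
(type recall ≤ detection recall) holds by construction and is tested.

Micro-averaged P/R/F1 pools TP/FP/FN over the scored classes:
detection scores the single positive class (the binary-task
convention); type classification pools the four DDI types; `negative`
is never a scored class. Every ledger entry adds one false negative to
its gold class. `0/0` is defined as 0. Strict label match only — no
partial credit across DDI types.

## The synthetic generator

`generate_corpus()` emits sentences from class-specific template
grammars (e.g. advice: "X should not be combined with Y"), with
exhaustive pair annotation, optional distractor drugs (a third drug
forming negative pairs inside a positive sentence — this is what makes
position/containment features necessary rather than decorative),
three-drug coordination runs and same-name case-variant pairs to
exercise both filtering rules, and a small adverb/template pool for
lexical variety. Trees come from the derivation itself, binary and
leaf-aligned, not from a statistical parser. Default mixture: 50%
negative, 12.5% each DDI type (roughly the class balance after
negative filtering in real corpora); distractor rate 0.2, coordination
0.15, same-name 0.05 — chosen once as plausible and frozen.

`make_separable()` forces distractor/coordination/same-name rates to 0
and guarantees each positive class a unique deterministic trigger
token absent from all negatives, making the detection label linearly
learnable from token presence.

What the generator does **not** emulate: real MEDLINE lexical
statistics, parser noise, discontinuous mentions, sentence length
variation beyond the templates, or ambiguous/negated interaction
language. A green learnability test therefore establishes that the
implementation can fit and generalize a planted signal end-to-end —
optimizer, gradients, features and plumbing all working — not that it
reproduces published corpus-level F1 scores, which require the
original corpora, parser and pre-trained embeddings.

One interaction worth knowing: anonymization makes template sentences
with different drug names byte-identical, so the default deduplication
collapses synthetic corpora substantially. Learnability checks run
with `drop_duplicates = FALSE` (sample size is the point of those
checks); deduplication remains the default for real corpora, where it
mirrors the published data preparation.

## Numerical and degenerate-input choices

* Character offsets: the XML dialect is 0-based end-inclusive
  (`charOffset="12-18;25-29"`), converted once at the boundary to
  half-open intervals; stated here to prevent off-by-one drift.
* Unknown DDI type strings are validation errors, not coerced.
* Cross-sentence pairs are rejected; entities of non-drug classes are
  carried but never paired or anonymized.
* Empty text tokenizes to an empty vector; fewer than two drugs yields
  zero candidates; an empty training set is an error.
* `predict_class` returns 1-based indices (R convention), ties toward
  the lower index.
* Checkpoints store tensors as 17-significant-digit decimal strings in
  JSON: exact double round-trip, still human-readable and diffable.
* Non-finite node inputs raise immediately rather than propagating
  NaNs into the recursion.

## Known limitations

* Pure-R training: fine at desk scale (a few hundred instances, hidden
  32, seconds per epoch), not meant for corpus-scale grid searches.
* Rule-1 filtering without a synonym table reduces to surface
  equality; supplying a curated `synonym_map` is the user's job.
* The l2-regularization comparison arm and attention mechanisms are
  out of scope; recurrent dropout is the only regularizer.
* The CLI consumes corpus XML + tree files; there is no streaming
  interface.
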