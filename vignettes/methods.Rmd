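---
title: "Relation extraction with attention and dependency-path features: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relation extraction with attention and dependency-path features: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biorel)
```

## The problem

Biomedical shared tasks such as Bacteria-Biotope relation extraction provide
texts in which entities (microorganisms, habitats, geographical locations,
phenotypes; or, for plant seed development, genes, proteins, tissues, ...)
are already annotated, and ask systems to decide which annotated entity
pairs stand in which relation (`Lives_In`, `Exhibits`, ..., or none).
`biorel` implements one family of solutions end to end: sentence-level
candidate classification with distributed features, a multi-head
self-attention sentence encoder, and a convolutional encoder of the
shortest dependency path (SDP) between the two candidate entities.

Only intrasentence pairs are modeled. Gold relations crossing a sentence
boundary still count as false negatives at evaluation time, which is why
intrasentence scores are higher than overall ones. This mirrors how such
systems are actually scored; cross-sentence inference is out of scope.

## Instance construction

Corpora arrive as standoff annotation (`.txt`, `.a1`, `.a2`) plus a
dependency-parse sidecar produced by an external NLP pipeline (this package
deliberately does not parse text; it consumes parses in a documented
CoNLL-style format with 0-based half-open character offsets). Within each
sentence, every unordered entity pair whose type pair is licensed by the
task's constraint rules becomes a candidate; annotated pairs keep their
category, all others are labeled `none`. Pairs whose types can never carry
a relation (e.g. Geographical with Phenotype) are dropped, as are pairs
whose head tokens are disconnected in the dependency graph. Because
enumerated negatives dominate training sets, a configurable fraction of
negatives is deleted uniformly at random (`floor((1 - keep) * N)`, the
convention that makes a 90% deletion of 17,489 negatives remove exactly
15,740); validation and test splits are never subsampled.

Entity-to-token alignment uses character overlap: any token whose span
intersects the entity span belongs to it, which is robust to
tokenizer/entity boundary mismatches (`N.` + `gonorrhoeae` vs the entity
`N. gonorrhoeae`). The entity's *last* token serves as its dependency-path
endpoint — a head-final heuristic for English noun phrases; the choice is
isolated in `entity_head_token()` and configurable.

## Feature combination

Each token of a candidate sentence is represented as the concatenation of

* a word embedding (dimension 200 by default; pretrained word2vec-format
  tables can be loaded, unknown words are randomly initialized, and an
  entity token missing from the dictionary falls back to a per-type
  placeholder embedding such as "Microorganism"),
* a POS embedding (200),
* an entity-type embedding (200; non-entity tokens get a dedicated
  "non-entity" row, the two candidate entities their types),
* two relative-distance embeddings (100 each, one table shared by both
  chains): the signed token distance to each candidate entity scaled by the
  corpus maximum `s`, i.e. `l/s` in `[-1, 1]`, bucketized at resolution
  `1/s` for table lookup,

for 800 dimensions per token at the defaults. A sinusoidal positional
encoding of the word dimension (`sin`/`cos` at geometrically spaced
frequencies) is added to the word channel only, injecting order information
that a pure attention encoder otherwise lacks. Padding rows (index 1 of
every table) are zero and frozen during training.

The SDP channel represents each path token as word embedding plus
dependency-type embedding (200 + 200); the dependency-type sequence is one
shorter than the token sequence and is padded to the path length.

## Encoders

**Sentence encoder.** Eight scaled dot-product attention heads with
unshared projections: per head, queries/keys/values are linear maps of the
800-dimensional feature combination into `d/8`-dimensional subspaces,
attention weights are `softmax(QK'/sqrt(d_k))` rows with `d_k` the per-head
dimension, and head outputs are concatenated back to width `d`. A
position-wise feed-forward layer (hidden width `d`, ReLU) follows, with one
residual connection around the whole attention + feed-forward block; no
layer normalization is used. Column-wise max-pooling over tokens yields the
sentence vector. Design points that the source description leaves open and
that we fixed: the scaling dimension is the per-head width (the standard
transformer construction; configurable), the feed-forward hidden width
equals `d`, the activation is ReLU, and no dropout is applied inside the
block (dropout is applied only to the combined feature before the softmax
classifier). Ablation encoders sit behind the same interface: a
multi-filter CNN, a BiLSTM, and both with additive-attention pooling in
place of max-pooling.

**SDP encoder.** Path lengths concentrate on 2–5 tokens, so the path is a
super-short sequence and a multi-filter CNN (window sizes 2, 3, 4; 128
filters each; single layer; ReLU; max-over-time) is the default, giving a
384-dimensional path feature. Paths are zero-padded so every window fits;
with zero biases, padding cannot win the max. A bidirectional LSTM variant
(final states of both directions) and a disabled variant (classifier uses
the sentence feature alone) reproduce the ablation grid.

**Classifier.** The sentence and path features are concatenated, dropout
(rate 0.5) is applied, and a linear softmax layer yields a distribution
over the categories including `none`.

## Training protocol

Multiclass cross-entropy, Adam at learning rate 0.001 (published default
moments), batches of 8 instances (gradients are accumulated per instance
and averaged — equivalent to padded batching but with no padding or masking
machinery), validation micro-F1 computed after every epoch, early stopping
after 3 epochs without improvement (the convergence reported for this
architecture is around 4 epochs; the patience is a config key), best-epoch
weights restored. Because small corpora make the outcome sensitive to the
random initialization, the protocol trains the same architecture under
several seeds (10 in the original setting) and selects the model with the
best validation F1, reporting min/max/mean/SD across seeds. Training is
seed-deterministic end to end: initialization, batch order and dropout all
derive from the given seed, and all gradients are verified against central
finite differences in the test suite.

## Evaluation

Micro-averaged precision/recall/F1 over pooled true/false positives and
false negatives, with per-category rows, an intrasentence sub-report
(computed against intrasentence gold; predictions are unchanged, so
intersentence gold depresses only recall), and optional pooling of
categories into clusters via an editable mapping file. A prediction is
correct iff its (document, unordered entity pair, category) triple matches
gold — strict matching. Report tables round half-up to two decimals.
Recomputing F1 from a table's rounded P/R can differ from the printed F1 by
one unit in the last decimal; the package reports the recomputed harmonic
mean.

## The synthetic corpus

Real shared-task corpora cannot ship with the package, so every stage is
exercised on a generator that emulates their statistical shape: Zipf
pseudo-word lexicons, random-attachment dependency trees, 2–3 entities per
sentence with type-specific surface lexicons (entity names are
type-indicative in real text: taxon names do not look like habitat nouns),
dominant negatives, short dependency paths, a small rate of cross-sentence
gold relations, and an optional forest mode that disconnects parses to
exercise the no-path filter.

The planted signal makes learnability testable: an eligible legal pair
(path length 3–5 with an interior token private to its own path) becomes
positive with probability 0.6, and a trigger lemma is written onto that
private token — except with noise probability 0.05, when the positive
carries no trigger. Distractor triggers appear off every candidate path at
rate 0.2. Restricting triggers to private tokens keeps the generating rule
exactly "related iff a trigger lies on the pair's dependency path": without
it, a trigger planted for one pair can sit on an overlapping negative
pair's path and no classifier, however good, can reach high F1. The
category is determined by the entity-type pair, as in the Bacteria-Biotope
rules.

Defaults are 200 documents of 3–5 sentences (8–30 tokens each), sized so
that a training split of a few hundred instances gives enough optimizer
steps for convergence within ~10 epochs at desk scale. Synthetic
experiments use scaled-down embeddings (word 32, POS 8, type 8, distance 8,
dependency type 16; 16 filters) — the architecture is unchanged, only
widths shrink; package defaults keep the full published dimensions. What
passing these tests shows is that the implementation can recover a clean
relational signal carried by the dependency path and that removing the SDP
channel loses it; it does not show anything about performance on real
biomedical text, which depends on parse quality, pretrained embeddings and
annotation conventions that the generator does not emulate.

## Numerical and degenerate-case choices

* Shortest paths: Dijkstra on the undirected dependency graph with unit
  weights; ties between equal-length paths break toward the
  lexicographically smallest token-index sequence, so output is
  deterministic on non-tree parses. Two entities sharing a head token is a
  degenerate-path error; pairs in disconnected components are filtered with
  a logged count.
* Path orientation: tasks with a type priority (Microorganism first)
  reverse the path when needed, regardless of sentence order; otherwise
  sentence order is kept.
* Discontinuous entities collapse to their envelope span with a warning;
  entities overlapping no or several parsed sentences are flagged and
  excluded from candidates.
* A gold annotation whose category violates the type constraints is kept
  with a warning — the corpus is trusted over the rules.
* Offsets are validated against the raw text; 1-based parse offsets are
  detected (by the one-off match) and rejected with a pointed message.
* `softmax` is computed with max-subtraction; probabilities are floored at
  1e-12 inside the loss.

## Limitations

The package consumes parses, it does not produce them; results on real
corpora inherit the parser's errors. Training is plain R matrix code: fine
for the corpus sizes here (minutes on one CPU at the scaled dimensions) but
not for large corpora at the full 800-dimensional configuration. Only
binary (pairwise) relations are supported — no events, no cross-sentence
inference, and no coreference-aware candidate generation. The shipped
seed-development constraint table and cluster mapping are deliberately
editable stand-ins to be completed from task documentation.
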