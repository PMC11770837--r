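---
title: "Relation classification to complement a rule-based biomedical triple extractor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relation classification to complement a rule-based biomedical triple extractor}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(relclass)
```

## The problem

Rule-based biomedical relation extractors produce subject–predicate–object
triples (predications) from sentences whose entities have already been
mapped to ontology concepts. Such systems tend to have reasonable precision
but low recall: indicator rules and ontological constraints only fire on
the patterns their authors anticipated. `relclass` implements the
complementary strategy: treat the problem as supervised *relation
classification* over entity pairs that the extractor's own entity
recognition already provides, and use the classifier both to re-score
sentences and to propose predications the rule-based system missed, at a
scale suitable for growing a predication database.

The classifier decides, for a sentence and an ordered (subject, object)
entity pair, which of 22 relation types holds — `administered_to` through
`uses` — or whether none does (the null label `no_rel`, giving 23 labels in
total). Two relation types (`associated_with`, `interacts_with`) are
bidirectional; `location_of` and `part_of` are inverses of one another.
Those equivalences are used in three places: training-data expansion,
matching predictions against gold triples, and deduplicating proposed
predications.

## Corpus construction

Training data is assembled from three kinds of sources:

* a fully annotated gold-standard collection, split **at the sentence
  level** with 20% of sentences for training and 80% reserved for testing
  (the fully annotated source is the only one on which recall can be
  measured, so most of it is kept for evaluation);
* two accuracy-annotated collections (extractor outputs judged
  correct/incorrect), split 90/10 into training and validation at the
  instance level; they cannot contribute to recall evaluation because they
  only contain extractor proposals;
* negatives of two kinds: extractor false positives (`neg_fp`; hard
  negatives, because they already satisfy the extractor's constraints), and
  constraint-conformant entity pairs that carry no annotation
  (`neg_conformant`). Both are labeled `no_rel`. Pairs carrying any gold
  relation are never emitted as negatives, and duplicate pairs are emitted
  once with `neg_fp` precedence.

Counting conventions the sources do not pin down are fixed as: training
sentences = `floor(0.20 n)`; validation instances = `floor(0.10 n)`; the
reversed `interacts_with` subsample is 10% rounded half-up, drawn seeded
and uniformly without replacement. Reversal of `location_of`/`part_of`
instances relabels to the inverse predicate so that the stored triple
remains constraint-conformant. Split assignment sorts inputs by a canonical
key before the seeded shuffle, so it is invariant to input order.

## Entity representations and markers

Besides raw mentions, the classifier can be trained on sentences in which
both argument mentions are replaced by their primary (first-listed)
semantic type or semantic group — e.g. *quercetin → Pharmacologic
Substance → Chemicals and Drugs*. Type- and group-level inputs push the
model toward constraint-like generalizations instead of memorizing entity
strings. The type-to-group map and the ontological constraint table are
data inputs (plain TSV), not code; the package ships small synthetic
fixtures (`inst/extdata/`) sufficient for the bundled generator.

The argument positions are communicated to the encoder with four reserved
marker tokens `<s>`, `</s>`, `<o>`, `</o>`, registered as atomic vocabulary
items. Markers are inserted without padding characters, so removing the
four marker substrings reconstructs the sentence text exactly; nested
argument spans produce correspondingly nested markers. ASCII glyphs were
chosen over typographic angle brackets so that every terminal and file
format renders them identically.

## Model

The model follows the entity-marker classification architecture:

1. an **encoder backend** turns the marked token sequence into per-token
   vectors from its last layer plus a sentence-summary vector (maximum
   tokenized length 384; longer samples are excluded, counted and
   reported);
2. the subject and object representations are **mean-pooled** over their
   marker-enclosed token spans, markers included;
3. the sentence-summary, subject and object vectors each pass through an
   independent transform (linear → dropout 0.1 → tanh → layer
   normalization), are concatenated, and mapped to 23 scores, normalized
   by softmax.

The backend is a contract, not a fixed architecture: any encoder exposing a
tokenizer with atomic markers and last-layer states satisfies it — in
production that would be a pretrained biomedical transformer. The built-in
backend (`tiny_backbone()`) is a small seeded network: token and position
embeddings followed by two context-mixing layers computing
`tanh(H W1 + mean(H) W2 + b)`, with the summary vector being the mean of
the final token vectors. All gradients (including layer normalization and
the contrastive objective below) are written out analytically and verified
against finite differences in development; the package has no automatic
differentiation dependency and runs entirely offline.

### Contrastive pre-training

Before fine-tuning, the encoder can be pre-trained on positive pairs
generated by EDA-style augmentation (synonym replacement, random
swap/deletion/insertion over a pluggable synonym lexicon). Augmentation
never touches the marker tokens or anything inside the argument regions —
stricter than generic EDA — because perturbing the arguments would corrupt
the relation the pair is supposed to preserve. For a batch of N sources,
the 2N variants are scored with a temperature-scaled cosine loss: for
anchor \(z'\) with partner \(z''\),

$$\ell(z', z'') = -\log\frac{\exp(\mathrm{sim}(z',z'')/\tau)}
{\sum_{k \neq \mathrm{anchor}} \exp(\mathrm{sim}(z', z_k)/\tau)},\qquad \tau = 0.1,$$

averaged over all 2N anchors. The exclusion in the denominator is by
anchor *index*, not by value, so duplicate vectors behave correctly; with
a single pair the loss is exactly zero. A projection head (linear →
dropout 0.1 → tanh) is used only during pre-training and discarded
afterwards, which is the convention of the contrastive sentence-embedding
approach this follows. Pre-training draws on an RNG stream independent of
fine-tuning, so the supervised stage consumes identical batches whether or
not pre-training ran.

### Class weighting

Minority relation types are protected with per-batch class weights
\(w_c = B/(C\,n_c)\) (batch size B, C classes present, class count
\(n_c\)); absent classes get weight 0, a balanced batch gets all weights
1, and the weighted cross-entropy reduces exactly to the unweighted loss
in that case. A description of this weighting as "the ratio of samples in
that class to the total" would up-weight *frequent* classes — the opposite
of its stated purpose — so the balanced inverse-frequency form, which
matches the intent, is what is implemented. This choice is deliberate and
worth flagging prominently.

### Hyperparameters

Defaults: 10 epochs for both stages, batch size 16 (16 sources = 32
sequences in contrastive batches), maximum length 384, Adam with learning
rate 5e-5 and epsilon 1e-8, temperature 0.1, dropout 0.1. The 5e-5 rate is
the established setting for fine-tuning a large pretrained encoder; the
small built-in backbone trains from random initialization, for which the
standard Adam-scale rate 1e-3 (`default_backbone_lr()`) is appropriate.
No scheduler or weight decay is used. Mean (not sum) reduction is used for
the per-anchor contrastive loss. Dropout is active only in training mode;
evaluation is deterministic.

## Threshold calibration

After training, a per-class decision threshold is fitted on validation
predictions: for each non-null class, candidates are the observed
probabilities of that class plus 0.5, the one-vs-rest F1 is maximized
(predict the class iff its probability **is at least** the threshold —
inclusive, so the 0.5 floor is attainable), ties break toward the smallest
candidate, and the result is floored at 0.5. At inference, classes whose
probability reaches their threshold are *eligible*; if none is, the null
label is assigned, otherwise the eligible class with maximal probability
wins (eligibility-then-argmax, rather than argmax-then-check, when several
classes pass). `no_rel` never competes via a threshold; it is the
fallback. Classes without positive validation instances default to 0.5
with a logged warning.

## Evaluation

`prf()` computes per-class and aggregate precision/recall/F1 with the null
label excluded from the aggregates: a null-gold instance predicted as
class c counts as a false positive of c, and a c-gold instance predicted
null as a false negative of c, but `no_rel` contributes no class of its
own. Micro-F1 is exactly the harmonic mean of micro-precision and
micro-recall; macro metrics are unweighted means over the non-null classes
with gold or predicted support (on fully covered data, all 22).
`auc_ovr()` macro-averages rank-based one-vs-rest AUC over all 23 classes
(null included) that have both positives and negatives. `mcnemar()` uses
the exact two-sided binomial p-value when the discordant count is below 25
and the continuity-corrected chi-square \((|b-c|-1)^2/(b+c)\) otherwise —
the standard switch point. `overlap()` partitions gold relations into
found-by-both / A-only / B-only / neither, matching under the
bidirectional and inverse-pair equivalences.

## Expansion pipeline

To propose new predications from extractor-style tables (sentences,
entities with semantic types, an existing predication store), the pipeline:

1. enumerates every ordered entity pair and every (subject type, object
   type) combination licensed by the constraint table — an entity with 2
   types against an entity with 3 types yields up to 6 candidates;
2. scores each candidate under the substituted-semantic-type
   representation, applies the calibrated thresholds, and keeps the
   highest-probability eligible predication per pair (ties toward earlier
   label order, then earlier candidate);
3. verifies `isa` predications against a concept hierarchy: the subject
   must be a descendant of the object over the transitive closure of a
   supplied parent–child edge table (directionality is configurable in
   principle; descendant(subject, object) is the default and the
   documented reading);
4. diffs against the store by predication key with bidirectional/inverse
   folding, partitioning into new / shared / store-only;
5. draws a stratified review sample (by default 23 per relation type, the
   506-triple protocol) and scales the new-predication count by the review
   accuracy to estimate store growth, rounding half-up.

The constraint filter runs before scoring; whether predicted labels should
additionally be restricted to the licensed predicates of the scored type
pair is genuinely ambiguous in the underlying procedure, so it is a
`strict` switch. Strict mode is what makes end-to-end recovery exact on
synthetic data: the reverse ordering of, say, an `inhibits` pair is often
licensed only for `interacts_with`, and a non-strict run would emit the
trigger's label for that reversed pair as a spurious new predication.
Duplicate predications from repeated sentences are deduplicated by key,
keeping the highest probability.

## The synthetic data generator

`make_corpus()` emulates the statistical structure the system assumes,
not real abstracts: template sentences *"In a \<adj\> \<noun\> , SUBJECT
trigger OBJECT \<adverb\> \<adverb\> ."* where the trigger phrase
determines the label (trigger words such as *induces* and *promotes* are
taken from the indicator vocabulary of rule-based extraction), entities
drawn from a small typed inventory, a constraint table covering every
planted triple, hard negatives built from constraint-conformant pairs with
neutral phrases, geometric class skew, and optional label noise applied
last. With zero noise a trigger-lookup oracle is a perfect classifier —
the separability guarantee behind the learnability tests. The synonym
lexicon for augmentation is generated from context-word families so EDA
has material to perturb.

What passing tests on this corpus do **not** show: robustness to real
sentence length and vocabulary distributions, multi-type entities in
training data, annotation disagreement, or cross-sentence relations. The
generator's purpose is to make every mechanical and statistical contract
of the pipeline testable offline, and to provide a scaled-down stand-in
for the full training result.

## Problem sizes and numerical choices

The learnability study trains the 2-layer, 64-dimensional built-in
backbone for 10 epochs on a 2,000-sentence noise-free corpus with 8
relation types plus the null label (roughly 1,400 training instances),
then evaluates with calibrated thresholds on the held-out test split;
micro-F1 reaches 1.0 and the same run with 10% label noise stays far above
the label-frequency baseline (the most frequent training relation label
predicted for every instance). The expansion study uses 400 sentences with
30% of gold predications withheld from the store. These sizes were chosen
so the whole suite runs in about a minute on one CPU while still
exercising every stage at a statistically meaningful scale.

Numerical details: softmax is computed with max-subtraction; cosine
similarities are clamped to [−1, 1]; layer normalization uses epsilon
1e-5; probabilities are floored at 1e-12 inside the log-loss; Adam uses
bias correction with β = (0.9, 0.999). Sampling counts round half-up
(`floor(x + 0.5)`) everywhere a "nearest integer" is required, because
R's banker's rounding would make seeded counts parity-dependent. All
randomness flows through locally scoped, seed-derived RNG streams, so
every stage is reproducible and independent of evaluation order.

## Known limitations

* The built-in backbone is intentionally small; headline benchmark numbers
  from the literature require a pretrained biomedical transformer and the
  original annotated corpora, neither of which this package downloads.
* Augmentation of the validation split is not performed (training split
  only); whether that is the right choice for a given corpus is untested.
* The command-line `expand` subcommand uses the trigger-lexicon oracle as
  its scorer; running expansion with a trained model is done through the R
  API (`model_scorer()`), since model checkpoints are in-memory R objects.
* Negated predicates, the comparative subtypes, and the other excluded
  rare relation types are out of scope, as is named-entity recognition:
  the package consumes pre-recognized, concept-mapped entities.
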