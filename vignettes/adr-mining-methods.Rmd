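---
title: "Mining adverse drug reactions from forum text: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining adverse drug reactions from forum text: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adrminer)
```

## The problem

Online healthcare forums carry first-hand patient reports of drug
side-effects, often years before those effects are frequent enough in
spontaneous-report databases to trigger regulatory attention. Mining them
means solving three problems at once: the text is noisy (HTML, casing,
punctuation, numerals, no medical vocabulary), a drug and a side-effect
co-occurring in a message is *not* evidence of a causal report, and the
interesting signals are precisely the drug/side-effect combinations that
have never been reported before — so any method keyed on previously seen
pairs cannot find them.

`adrminer` addresses all three: a staged, individually toggleable
normalisation pipeline; a causal-keyword dictionary and a hidden Markov
model that requires a causal sequence, not mere co-occurrence; and
class-level observation symbols that make the model indifferent to
*which* drug and side-effect appear, so it generalises to unseen pairs.

## The message model

A forum message is modelled as an ergodic four-state HMM over
`{Drug, SideEffect, Keyword, Other}`. The hidden chain starts in any
state according to Π (start and end are not modelled as states: the start
is encoded by Π and the sequence simply truncates at the end), moves
between states under the 4×4 transition matrix A, and each state emits
one observation symbol per token under the emission matrix B. Ergodicity
— no structural zeros — lets the three entities occur in any order with
repetition, which matches real messages where the side-effect is
sometimes mentioned before the drug.

Observations are the preprocessed token stream after lexicon-identifier
substitution. Under the default *class-level* granularity every
drug-dictionary match emits the same `<drug>` symbol (likewise `<se>`,
`<kw>`), and unmatched words emit word symbols, with words seen fewer
than `min_count = 2` times in training mapped to `<unk>`. This is the
crucial representational choice: the emission distributions learn "a
drug mention here", not "lipitor here", so a relation between a drug and
a side-effect never paired in training is still decodable. An
*entry-level* granularity (one symbol per dictionary entry) is available
for contrast experiments; it removes exactly this generalization.

## Preprocessing pipeline

Stages, in order, each toggleable for the component-removal ablations:

1. **HTML filter** — visible-text extraction via libxml2 (script/style
   content dropped, entities decoded, element boundaries become single
   spaces). Malformed markup is handled best-effort and never raises; if
   libxml2 cannot parse at all, a conservative regex fallback strips tags.
2. **Plain-text filter** (one unit: lowercasing, punctuation, numerals)
   — NFC normalisation, casefolding, ASCII punctuation replaced by
   spaces (so `"pain.I"` splits rather than merging), digit-only tokens
   dropped, digits stripped from mixed tokens (`"20mg"` → `"mg"`). The
   operation is idempotent.
3. **Tokenization** on whitespace runs.
4. **Lexicon phrase matching** — greedy leftmost-longest dictionary
   matching, window up to 5 tokens, with precedence
   drug > side-effect > keyword for equal-length competitors at the same
   position. Matching runs *before* stop-word filtering deliberately:
   many causal keywords ("i am having", "due to", "now i have") are
   built from stop words and could never match afterwards. Matched spans
   are protected from the stop-word filter.
5. **Stop-word filter** — a pinned ~130-word English function-word list
   shipped as a fixture (the exact list is a reproducibility decision;
   no standard list is canonical for this task).
6. **Symbol substitution** as described above; each matched multi-token
   phrase collapses to a single observation.

Part-of-speech tagging, stemming, spelling correction and word-sense
disambiguation are deliberately out of scope: the design aim is a
pipeline that does not depend on language semantics.

## Training

Positive training messages are state-annotated by the dictionary matches
themselves (a drug match is a Drug token, etc.; everything else is
Other). This mirrors how such corpora are annotated in practice — a
dictionary pass proposes entities, reviewers confirm — and avoids
carrying token-level gold spans through noise injection and token
filtering; the synthetic generator's gold spans are instead used in the
test suite to verify that the pipeline and matcher recover them.

Supervised initialization counts starts, transitions and emissions over
the annotated positive sequences and normalises with an additive
smoothing constant; Baum–Welch (multi-sequence EM, scaled
forward–backward) then refines the model on the positive sequences only.
The Other state absorbs non-entity words inside positives; negatives are
not needed for training because the decision rule is structural (all
three entity states present in the Viterbi path).

Two numerical parameters deserve explanation because their natural-looking
values are wrong:

* **Smoothing (`pseudocount`, default 0.01).** The entity states emit
  roughly once per positive message, while the symbol count M grows with
  the training vocabulary (M ≈ 1000–2000 at realistic scale). A Laplace
  pseudocount of 1 adds M counts of smoothing mass per state — an order
  of magnitude more than the real entity counts — flattening
  B[Drug, `<drug>`] from ≈1 to ≈0.2–0.45 and leaving Baum–Welch free to
  drift the states. 0.01 keeps every probability strictly positive (EM
  can still move mass anywhere) without drowning the signal.
* **Stopping (`tol`, default 1e-3 per-observation log-likelihood
  improvement; `max_iter` 100).** After supervised initialization the
  likelihood plateaus within about three iterations. Running EM further
  *keeps improving the unsupervised likelihood* — for tens of iterations
  — by reassigning the rare entity states to help model background
  words, because two states modelling the abundant Other material buy
  more likelihood than one state reserved for ~1 token per message. That
  is optimal for density estimation and fatal for a classifier whose
  decision rule reads the state identities. Stopping at the first
  plateau preserves the supervised semantics; we measured held-out
  recall collapsing from 26/26 to 3/26 when EM was instead run to full
  convergence at 1e-4. `baum_welch()` itself is a faithful generic EM
  (monotone likelihood trace, fixed points stay fixed) and keeps 1e-4 as
  its own default; the 1e-3 default applies to classifier training.

## Classification and mining

`hmm_classify()` Viterbi-decodes a message (log-space; ties break toward
the lowest state index) and labels it positive iff the path visits Drug,
Keyword and SideEffect on tokens that also carry the corresponding
dictionary match. Requiring the matched variant resolves an ambiguity in
the decision rule — a token decoded as Drug without a drug match carries
no usable surface form — and guarantees every mined relation has
dictionary-resolvable fields. One relation per positive message: the
first decoded drug anchors it (training positives contain a single drug
mention), the first decoded keyword and the first instance of each
distinct side-effect term fill it.

The co-occurrence baseline counts, over gold-positive training messages,
each (drug, side-effect) dictionary pair at most once per message, and
flags a test message positive iff any of its pairs has count > 0.
Counting positives only reflects the "learns associations" reading of
the baseline; an all-messages scope is a configuration switch, and on
generated corpora the qualitative contrast with the HMM is the same
under either.

Corpus mining aggregates relations per drug: messages yielding a
relation, total and distinct side-effect mentions, terms occurring
strictly more than 5 times, and each term's percentage among the drug's
side-effect *mentions* (mention-denominators, not unique terms — the
percentage columns of drug-level mined-ADR tables are consistent with
this reading; percentages are displayed at 2 decimals). A known-ADR
table (drug package insert data) splits each drug's terms into known and
novel; a drug absent from the table is all-novel.

## Evaluation protocol

Precision = TP/(TP+FP), recall = TP/(TP+FN), F = 2PR/(P+R) from the
*unrounded* P and R, accuracy = (TP+TN)/total. Degenerate denominators
give value 0 with a `defined = FALSE` flag (keeping fold means
computable); reported values round half away from zero to 3 decimals —
both conventions verified against all 20 published confusion-count rows
of the reference cross-validation table. Folds are a seeded uniform
shuffle cut into k contiguous near-equal parts, non-stratified (the
reference table's per-fold positive counts vary 52–63, inconsistent with
stratification), with symbol tables, HMM parameters and co-occurrence
maps built from fold-train data only. Fold metrics aggregate by
arithmetic mean (macro average). The ablation harness runs repeated
cross-validation per variant with seed = base_seed + run, using the same
seed for dictionary subsampling (`subset_lexicon()` keeps
floor(fraction·size) entries).

## The synthetic corpus generator

The generator stands in for the undistributed crawled corpora and
defines the conditions under which the package validates itself:

* 25% positives (`positive_fraction = 0.25`, the reference corpus ratio),
  exactly `round(n · fraction)` of them, assignment then seeded shuffle;
* each positive embeds exactly one drug, ≥1 keyword from the real
  45-entry fixture, and 1–3 side-effects, ordered by a transition model
  favouring Drug → Keyword → SideEffect while allowing all orders;
* negatives mix none / drug-only / side-effect-only / drug+side-effect
  compositions (0.4/0.2/0.2/0.2); the last are *hard negatives* — both
  entities, no causal keyword — that separate the HMM from the baseline;
* mean message length 40 tokens (Poisson), padding drawn from a 2000-word
  seeded pseudo-vocabulary (kept disjoint from all lexicon and stop
  words) with a 0.2 chance of a stop word per padding token;
* drug and side-effect mentions are sampled with Zipf(1) popularity:
  forum traffic concentrates heavily on popular drugs (drug-level mined
  message counts in real corpora are strongly skewed), and without this
  skew virtually every (drug, side-effect) pair would be unique, the
  baseline would have recall ≈ 0 everywhere and no side-effect would
  ever reach the "frequent" aggregation threshold;
* surface noise, applied token-wise after gold spans are recorded: case
  flips, trailing punctuation, digit-only insertions (outside entity
  spans, so spans stay contiguous), HTML wrapping. Defaults
  (html 0.05, uppercase 0.1, punct 0.2, digit 0.1) are a low-noise
  regime; the ablation experiments use a high-noise setting
  (uppercase 0.6, punct 0.8, digit 0.3).

Every noise phenomenon at the default settings is exactly invertible by
the corresponding pipeline stage. The generated corpus is therefore a
*clean-signal* regime: with all filters on, cross-validated F-scores
approach 1.0, and what the passing tests demonstrate is that the
machinery — pipeline, matcher, training, decoding, evaluation — is
internally correct and that the qualitative orderings hold (HMM ≫
baseline; baseline recall = 0 on unseen pairs while the HMM's stays
near 1; removing the plain-text filter is catastrophic on noisy text;
halving the drug dictionary halves recall; the HTML filter is inert on
HTML-free text). It does **not** demonstrate real-forum performance:
real text has misspellings, synonyms, negation, symptom/side-effect
confusions and annotation noise, none of which the generator emulates,
and absolute synthetic scores are accordingly optimistic.

## Problem sizes used in validation

The acceptance script cross-validates both classifiers on a 2000-message
corpus (10 folds), measures unseen-pair generalization on a
drug-disjoint split of the same corpus, and runs the ablation grid on a
600-message high-noise corpus with 2 runs × 3 folds per variant; oracle
checks compare Viterbi/forward against exhaustive path enumeration on
200 random 4-state models with sequences up to length 6, where all 4^T
paths can be enumerated exactly. These sizes were chosen so the full
validation completes in minutes on a laptop while keeping every check at
the scale the protocol describes.

## Known limitations

* Exact dictionary matching only: no spelling variants, synonyms or
  ontology mapping — coverage is bounded by the lexicons, which the
  dictionary-halving ablation quantifies.
* No symptom-vs-side-effect disambiguation: a drug's indication mentioned
  alongside it can be mined as its side-effect (the dominant
  false-positive mode on real text).
* One relation per message, single-drug anchor; multi-drug messages
  attribute all side-effects to the first decoded drug.
* Viterbi-only decision rule; no posterior-probability scores, so no
  precision/recall trade-off tuning.
* The co-occurrence baseline is order-insensitive and cannot, even in
  principle, find novel pairs — it is a reference point, not a method.
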