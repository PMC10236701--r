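---
title: "Auditing entity-normalization evaluations: models, indicators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing entity-normalization evaluations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(normaudit)
```

## The problem

Entity normalization (EN) links text mentions to concepts of a reference
set `C` — typically an ontology such as OntoBiotope (bacterial habitats)
or MEDIC (diseases). Reported EN accuracies are hard to compare across
papers because three things vary silently: the accuracy formula used for
multi-normalized mentions, the candidate set (full ontology or a subset
leaked from the annotations), and the composition of the gold standard
itself (how much of the test set a model can simply memorize from
training). `normaudit` turns each of these into a number.

## The metric family

All metrics are means over the `N` evaluated mentions of a per-mention
contribution in `[0, 1]`; a mention with gold annotation but no
prediction contributes 0 rather than being dropped, because dropping it
would shrink the denominator and inflate every score.

Writing `n_i` for the number of gold concepts of mention `m_i`, `p_i`
for the number of distinct predicted concepts, and `strict(m, c) = 1`
iff `c` is one of the gold concepts:

| function | contribution | behavior on over-prediction |
|---|---|---|
| `accuracy()` | `strict(m_i, c_i)` | refuses `p_i > 1` |
| `topk_accuracy()` | any of the first `k` candidates correct | ignores it |
| `accuracy_multinorm()` | `sum_j strict(m_i, c_i^j) / n_i` | none: whole-ontology prediction scores 1 |
| `accuracy_general()` | `sum_j strict(m_i, c_i^j) / max(n_i, p_i)` | whole-ontology prediction scores `1/|C|` |
| `accuracy_lenient()` | 1 iff any prediction correct (multi-labeled, non-composite); else as `accuracy_general` | as the column above, per case |

Assumptions worth stating:

* Predicted concepts are distinct (enforced by `en_predictions()`), so the
  sum of `strict` never exceeds `min(n_i, p_i)` and the `min(1, ·)` guard
  in the unpenalized variant is unreachable in valid input; it is kept as
  a numerical guard only.
* NIL mentions (empty gold set) are not scorable by the multi-normalization
  formulas — their `n_i = 0` denominator is undefined — and raise an error
  instead of being silently skipped. Evaluate them separately or filter
  them first; the NIL *rate* tells you how much that filtering removes.
* Composite mentions (gold sets produced by splitting identifiers such as
  `D001943+D010051`) are flagged at read time by the PubTator reader.
  `accuracy_lenient()` consumes these flags instead of inferring them,
  because the lenient rule behaves differently on composite and
  multi-labeled mentions and a silent guess would corrupt exactly the
  comparison the function exists to make.

## The bias indicators

All rates are percentages with explicit denominators in the report.
Conventions that were genuinely open, and how they were fixed:

* **"Same surface form"** defaults to exact string equality
  (`policy = "exact"`), the least interpretive choice; `casefold` and
  `casefold+ws` are selectable and the policy is recorded in every
  report.
* **Ambiguity** is counted over mention *instances* and compares **full
  gold concept sets**, so a multi-normalized mention is not ambiguous
  against another instance with the identical set.
* **Redundancy** counts test *instances* whose `(surface key, gold set)`
  example occurs anywhere in the training material — not unique pairs —
  because a memorizable example inflates the score once per test
  occurrence.
* **FSL counts**: a multi-normalized mention increments every concept of
  its gold set (one full count each, not fractional), which keeps the sum
  of instance counts interpretable: it equals the number of annotated
  mentions exactly when there is no multi-normalization.
* **NIL** is encoded as the empty gold set everywhere; corpora using a
  sentinel concept-less label are mapped to it at read time.

## The two-sieve baseline

The baseline cascades two classical strategies from most to least
precise; mentions unmatched by stage 1 fall through to stage 2, and
mentions unpredictable by both get no prediction (scored 0 by the
generalized accuracy — the conservative reading; a most-frequent-concept
fallback can be built from the lexicon's frequency column if wanted).

**Stage 1 — lexicon exact match.** All ontology labels plus all training
mention surfaces, normalized by lowercase + punctuation removal + Porter
stem + single-space join. A training surface annotated by several
concepts enters the lexicon only for its most frequent concept, ties
broken by smallest concept id; collisions with an ontology label keep the
ontology entry. Matched mentions always yield exactly one concept.
The stemmer identity matters for reproducibility, so it is pinned: the
original Porter (1980) rule set, implemented in the package (no stemming
package exists in the target environment) and frozen against an external
reference implementation in the test suite.

**Stage 2 — embedding projection.** A mention is embedded as the mean of
its in-vocabulary token embeddings (lowercased, punctuation-split,
unstemmed — embedding vocabularies are built from raw text). A linear map
`W` is fitted by ridge least squares to send mention embeddings onto the
embedding of their gold concept's *preferred* (first) label — preferred
rather than nearest label because it is deterministic. The ridge penalty
defaults to `lambda = 1e-8`: a pure numerical stabilizer, small enough
that a planted linear map is recovered to `1e-6` (tested). Prediction is
the concept owning the cosine-nearest label embedding, ties broken by
lexicographic `(concept id, label)` order so two runs can never disagree.
An optional weak-supervision flag adds every `(label, concept)` pair of
the ontology as training pairs; it is **off** by default, since the
baseline is meant to measure what the training set alone supports.

## Ontology subsetting and preprocessing ablations

`subset_ontology()` reproduces the common (and biasing) practice of
evaluating against only the concepts used in released annotation: it
keeps exactly the used concepts and drops parent links to removed
concepts *without re-wiring* — a deliberately "broken" hierarchy, because
re-wiring would silently change graph-based methods while the ablation's
point is only to shrink the candidate set.

`apply_preproc()` applies generic transforms in one fixed, documented
order — hooks, lowercasing, punctuation removal, stopword removal,
stemming or lemmatization (mutually exclusive), whitespace collapse —
so that two ablations differing in one flag differ in nothing else. The
stopword list is a versioned packaged file. Domain-specific transforms
(acronym expansion, typo lists, composite splitting) are *not*
implemented: they are exactly the under-documented, domain-specialized
preprocessing this toolkit exists to isolate, so they enter only as
name-registered external hooks. The built-in lemmatizer is a naive
plural/inflection suffix stripper, documented as an approximation;
serious lemmatization should be plugged in as a hook.

## The synthetic test bed

The generator emulates the structural properties of EN gold standards
that the indicators measure: a single-root ontology tree with 1–3-token
labels; train/dev/test splits with controllable redundancy, ZSL,
ambiguity, multi-normalization and NIL rates; surface variation by
deterministic suffix edits; and embeddings clustered around per-concept
anchor directions with noise `sigma`.

Default parameters are the stated world, chosen once:

* the five rates default to the profile measured on a real bacterial-
  habitat benchmark — redundancy 24.6%, ZSL 48.2%, ambiguity 19.3%,
  multi-norm 8.1%, NIL 0% — i.e. a *realistic* corpus, not an easy one;
* split sizes (200/60/100) and ontology size (40 concepts) are scaled
  down from real corpora (thousands of mentions, thousands of concepts)
  so the whole suite runs in seconds on one CPU; rates, which are the
  quantities under test, are preserved by construction;
* embedding dimension 16 and noise 0.1 give a stage-2 baseline that is
  good but not perfect, as with real embeddings.

Rates are satisfied by quota assignment, not rejection sampling:
redundancy and ZSL are exact whenever the request is divisible by the
relevant denominator (test size, test concept count), ambiguity /
multi-norm / NIL are within one mention of the pooled total. The token
vocabulary consists of CVCVC strings that are fixed points of the Porter
stemmer, so stemmed lexicon keys cannot collide across concepts, and the
surface-variant rounds have a *known* dictionary-solvable partition:
`-s` and `-ing` variants stem back to the label, `-es` variants do not
and must be solved by the embedding stage (or by having been seen in
training).

What the generator does **not** emulate — and therefore what a green test
does not establish: real lexical variation (abbreviations, typos, word
order, paraphrase), document context, realistic label/synonym
distributions, annotation noise, and embedding anisotropy. A perfect
sieve score on synthetic data says the machinery is correct, not that the
baseline is strong; conversely, the baseline's absolute accuracy on real
corpora depends on stemmer/tokenizer/projection details that are pinned
and logged but are this package's own choices.

## Numerical choices and degenerate inputs

* All tie-breaks are total orders (lexicographic concept id, then label);
  prediction and report generation are deterministic, tested at byte
  level.
* The projection warns when there are fewer training pairs than
  dimensions and errors when there are none; unembeddable mentions and
  labels are skipped, and an all-OOV mention is an explicit "no
  prediction", never an error.
* Empty splits, empty pools, empty gold in a scoring call, unknown hook
  names, unresolvable ids (strict mode), truncated embedding files and
  infeasible generator rate combinations all raise errors naming the
  violated constraint rather than degrading silently.
* Scores are kept in `[0, 1]` internally and multiplied by 100 only for
  presentation.

## Known limitations

* Graph-similarity scores (lowest-common-ancestor distances, learning
  accuracy) are out of scope; only set-based metrics are provided.
* Readers cover the openly distributable formats (standoff, PubTator,
  OBO, MEDIC, word2vec); licensed vocabularies (SNOMED, MedDRA, UMLS) are
  not supported.
* The baseline's second stage assumes a single embedding space for
  mentions and labels; contextual encoders would need a different
  `embed_mention`.
* `read_standoff_corpus` treats a kept mention without normalization
  lines as NIL; corpora that instead leave mentions unannotated should be
  filtered by entity type first.
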