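# normaudit

Auditing and scoring toolkit for **biomedical entity normalization** (also
called concept normalization or entity linking against an ontology): the
task of mapping text mentions such as *"breast or ovarian cancer"* or
*"gopher tortoise burrows"* to standard concepts of a reference like MEDIC
or OntoBiotope.

It is written for people who **evaluate** normalizers rather than build
them: shared-task organizers, dataset designers, and authors who want to
report how much of a score is method and how much is dataset artifact.
Published comparisons in this area are distorted by several recurring
biases — train/test example redundancy, silently subset ontologies,
undocumented preprocessing, and accuracy formulas that disagree on
multi-normalized mentions. This package makes each of those measurable.

## What it computes

**Metric family.** With `N` mentions, gold concept sets of size `n_i`,
and `p_i` distinct predicted concepts `c_i^j`:

- classical accuracy — mean of `strict(m_i, c_i)` over mentions
  (`accuracy()`), and its top-k generalization (`topk_accuracy()`);
- multi-normalization accuracy — per-mention credit
  `sum_j strict(m_i, c_i^j) / n_i` (`accuracy_multinorm()`), which does
  **not** penalize over-prediction: predicting the whole ontology scores 1;
- generalized accuracy — credit `sum_j strict(m_i, c_i^j) / max(n_i, p_i)`
  (`accuracy_general()`), whose max-denominator makes the same pathology
  score `1/|C|`;
- the lenient any-correct variant used by some published evaluation
  scripts, with composite mentions still requiring all concepts
  (`accuracy_lenient()`).

**Bias indicators** (`indicator_report()` and the individual functions):
few-shot statistics (mean/median/max mentions per used concept, with a
distinct-surface variant), multi-normalization rate, NIL rate, ambiguity
rate (same surface, different gold sets), train/test redundancy
(instance-level `(surface, gold set)` example overlap) and zero-shot rate
(test concepts never seen in training), each with its denominator.

**Two-sieve baseline** (`build_augmented_lexicon()`, `fit_projection()`,
`sieve_predict()`): stage 1 matches Porter-stemmed lowercased mentions
against stemmed ontology labels augmented with training mentions
(most-frequent-concept rule for ambiguous surfaces); stage 2 projects
averaged word2vec token embeddings through a ridge linear map into label
space and predicts the cosine-nearest label's concept. It runs in seconds
on a CPU and is meant as a difficulty probe, not a contender.

**Infrastructure**: readers/writers for BioNLP-ST standoff (.a1/.a2),
PubTator, OBO 1.2, CTD MEDIC TSV, word2vec text/binary and prediction TSV;
ontology subsetting ablation (`subset_ontology()`, hierarchy deliberately
left broken); a seeded synthetic generator (`generator_spec()`,
`simulate_dataset()`) whose redundancy/ZSL/ambiguity/multi-norm/NIL rates
are met by construction.

## Worked example

```r
library(normaudit)

spec   <- generator_spec(seed = 42)         # defaults mimic a realistic habitat corpus
ont    <- generate_ontology(spec)           # 40 concepts, single-root tree
splits <- generate_splits(spec, ont)        # train/dev/test with controlled biases
emb    <- generate_embeddings(spec, ont, attr(splits, "token_owner"))

indicator_report(splits$train, splits$test, dev = splits$dev)
#> <indicator_report> (surface policy: exact )
#>   FSL avg/med/max:          10.3 / 10.0 / 15 (distinct 10.3 / 10.0 / 15) over 21 concepts
#>   multinorm 8.1%  nil 0.0%  ambiguity 18.9%  redundancy 25.0%  zsl 47.5%

lex   <- build_augmented_lexicon(ont, splits$train)
model <- fit_projection(splits$train, ont, emb)
preds <- sieve_predict(splits$test, lex, model, ont, emb)

accuracy_general(splits$test, preds)
#> <en_score> generalized accuracy = 0.9600  (96.0 points, N = 100)
accuracy_lenient(splits$test, preds)
#> <en_score> lenient accuracy = 1.0000  (100.0 points, N = 100)
```

Reading: a quarter of the test examples were already seen verbatim in
training (redundancy 25%), while nearly half the test concepts were never
trained on (ZSL 47.5%) — the two numbers that most inflate and deflate
published scores. The 4-point gap between the generalized and the lenient
metric comes entirely from the 8% multi-normalized mentions, for which the
single-prediction baseline earns half credit under the penalized formula
and full credit under the lenient one: exactly the scoring-convention gap
the metric family is designed to expose.

One call bundles all of it (JSON + Markdown output, byte-reproducible):

```r
audit_report(splits$train, splits$test, ont, dev = splits$dev,
             embeddings = emb, out = "report.json", markdown = TRUE)
```

## Command line

```sh
Rscript -e 'normaudit::en_cli()' simulate --out sim/ --seed 17
Rscript -e 'normaudit::en_cli()' audit --train sim/train --dev sim/dev \
    --test sim/test --ontology sim/ontology.obo \
    --embeddings sim/embeddings.w2v.txt --out report.json
Rscript -e 'normaudit::en_cli()' predict --train sim/train --test sim/test \
    --ontology sim/ontology.obo --embeddings sim/embeddings.w2v.txt --out pred.tsv
Rscript -e 'normaudit::en_cli()' score --gold sim/test --pred pred.tsv \
    --ontology sim/ontology.obo --metric eq4
```

`audit` and `predict` accept real corpora too: standoff directories or
PubTator files, OBO or MEDIC references, word2vec embeddings.

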