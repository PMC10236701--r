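mini_ontology <- function() {
  en_ontology(list(
    en_concept("C:1", c("gopher tortoise", "tortoise")),
    en_concept("C:2", "soil"),
    en_concept("C:3", c("deep soil", "subsoil"), parents = "C:2")
  ), name = "mini")
}

test_that("augmented lexicon: ontology labels, frequency rule, tie-breaks", {
  ont <- mini_ontology()
  # no training data: normalized ontology labels only
  lex0 <- build_augmented_lexicon(ont)
  expect_setequal(lex0$entries$provenance, "ontology-label")
  expect_true("gopher tortois" %in% lex0$entries$key)

  # most frequent concept wins the surface
  train <- make_split(c("cat", "cat", "cat", "cat"),
                      list("C:1", "C:1", "C:1", "C:2"))
  lex <- build_augmented_lexicon(ont, train)
  expect_identical(lex$entries$concept_id[lex$entries$key == "cat"], "C:1")

  # tie broken by lexicographically smallest concept id
  tie <- make_split(c("cat", "cat", "cat", "cat"),
                    list("C:2", "C:2", "C:1", "C:1"))
  lex2 <- build_augmented_lexicon(ont, tie)
  expect_identical(lex2$entries$concept_id[lex2$entries$key == "cat"], "C:1")

  # collision with an ontology label keeps the ontology entry
  clash <- make_split("Soil", list("C:1"))
  lex3 <- build_augmented_lexicon(ont, clash)
  row <- lex3$entries[lex3$entries$key == "soil", ]
  expect_identical(row$concept_id, "C:2")
  expect_identical(row$provenance, "ontology-label")

  expect_error(build_augmented_lexicon(structure(list(concepts = list()),
                                                 class = "en_ontology")),
               "empty ontology")
})

test_that("exact_match_predict stems both sides and misses cleanly", {
  ont <- mini_ontology()
  lex <- build_augmented_lexicon(ont)
  expect_identical(exact_match_predict("Tortoises", lex), "C:1")
  expect_identical(exact_match_predict("SOIL", lex), "C:2")
  expect_identical(exact_match_predict("unseen thing", lex), NA_character_)
  expect_identical(exact_match_predict("gopher tortoise", lex), "C:1")
})

test_that("embed_mention averages in-vocabulary tokens", {
  mat <- rbind(u = c(1, 0), v = c(0, 1))
  tab <- en_embeddings(mat)
  expect_equal(embed_mention("u v", tab), c(0.5, 0.5))
  expect_equal(embed_mention("u zzz", tab), c(1, 0)) # OOV token dropped
  expect_null(embed_mention("zzz yyy", tab))
})

test_that("fit_projection recovers a planted linear map", {
  set.seed(21)
  d <- 6
  W0 <- matrix(rnorm(d * d), d, d)
  n <- 40
  X <- matrix(rnorm(n * d), n, d)
  toks_m <- sprintf("m%02d", 1:n)
  toks_l <- sprintf("l%02d", 1:n)
  Y <- X %*% W0
  tab <- en_embeddings(rbind(`rownames<-`(X, toks_m), `rownames<-`(Y, toks_l)))
  ont <- en_ontology(lapply(1:n, function(i) en_concept(sprintf("K:%02d", i), toks_l[i])))
  train <- make_split(toks_m, as.list(sprintf("K:%02d", 1:n)))
  model <- fit_projection(train, ont, tab)
  expect_lt(max(abs(model$W - W0)), 1e-6)
  # identity-generating data: labels are the mentions
  ont_id <- en_ontology(lapply(1:n, function(i) en_concept(sprintf("K:%02d", i), toks_m[i])))
  model_id <- fit_projection(train, ont_id, tab)
  expect_lt(max(abs(model_id$W - diag(d))), 1e-6)
  # ridge limit: W -> 0 as lambda -> Inf
  model_inf <- fit_projection(train, ont, tab, lambda = 1e12)
  expect_lt(max(abs(model_inf$W)), 1e-6)
  expect_error(fit_projection(make_split("zzz", list("K:01")), ont, tab),
               "no usable")
})

test_that("nearest_label_predict agrees with brute-force cosine argmax", {
  set.seed(22)
  d <- 5
  labs <- sprintf("lab%d", 1:5)
  L <- matrix(rnorm(5 * d), 5, d, dimnames = list(labs, NULL))
  ment <- matrix(rnorm(3 * d), 3, d, dimnames = list(c("ma", "mb", "mc"), NULL))
  tab <- en_embeddings(rbind(L, ment))
  ont <- en_ontology(lapply(1:5, function(i) en_concept(sprintf("K:%d", i), labs[i])))
  ident <- structure(list(W = diag(d), dim = d, lambda = 0, n_pairs = 0,
                          weak_supervision = FALSE), class = "en_projection")
  for (m in rownames(ment)) {
    got <- nearest_label_predict(m, ident, ont, tab)
    cosims <- apply(L, 1, function(l) {
      sum(l * ment[m, ]) / sqrt(sum(l^2) * sum(ment[m, ]^2))
    })
    expect_identical(got$concept_id, sprintf("K:%d", unname(which.max(cosims))))
    expect_equal(got$score, max(cosims))
  }
  # subset restriction and the single-concept case
  got_sub <- nearest_label_predict("ma", ident, ont, tab, concept_subset = "K:3")
  expect_identical(got_sub$concept_id, "K:3")
  expect_error(nearest_label_predict("ma", ident, ont, tab,
                                     concept_subset = character()), "empty")
  # unembeddable mention: explicit none
  expect_identical(nearest_label_predict("zzz", ident, ont, tab)$concept_id,
                   NA_character_)
})

test_that("sieve order: dictionary first, embedding fallback, none last", {
  ont <- mini_ontology()
  lex <- build_augmented_lexicon(ont)
  d <- 4
  set.seed(23)
  tab <- en_embeddings(matrix(rnorm(3 * d), 3, d,
                              dimnames = list(c("soil", "deep", "subsoil"), NULL)))
  expect_warning(
    model <- fit_projection(make_split("subsoil", list("C:3")), ont, tab),
    "fewer training pairs")
  split <- make_split(c("Tortoises", "deep", "qqqq"),
                      list("C:1", "C:3", "C:2"))
  preds <- sieve_predict(split, lex, model, ont, tab)
  stage <- attr(preds, "stage")
  expect_identical(unname(stage), c("dict", "embed", "none"))
  # dict-matched mention never consults the embedding stage, so a dict hit
  # is possible even with no model at all
  preds_dict <- sieve_predict(split, lex)
  expect_identical(unname(attr(preds_dict, "stage")), c("dict", "none", "none"))
  # unpredictable-by-both mention has no prediction row
  expect_false(split$mentions$mention_id[3] %in% preds$df$mention_id)
})

test_that("sieve prediction is deterministic", {
  spec <- generator_spec(n_train = 60, n_dev = 0, n_test = 30, seed = 9)
  ont <- generate_ontology(spec)
  sp <- generate_splits(spec, ont)
  tab <- generate_embeddings(spec, ont, attr(sp, "token_owner"))
  lex <- build_augmented_lexicon(ont, sp$train)
  model <- fit_projection(sp$train, ont, tab)
  p1 <- sieve_predict(sp$test, lex, model, ont, tab)
  p2 <- sieve_predict(sp$test, lex, model, ont, tab)
  expect_identical(p1$df, p2$df)
})

test_that("perfect-coverage synthetic data gives sieve accuracy 1", {
  # every test surface occurs in training with a unique concept
  spec <- generator_spec(n_concepts = 12, vocab_size = 200, n_train = 40,
                         n_dev = 0, n_test = 20, redundancy = 100, zsl = 0,
                         ambiguity = 0, multinorm = 0, nil = 0, sigma = 0,
                         seed = 17)
  ont <- generate_ontology(spec)
  sp <- generate_splits(spec, ont)
  lex <- build_augmented_lexicon(ont, sp$train)
  preds <- sieve_predict(sp$test, lex) # dictionary stage alone
  expect_equal(accuracy_general(sp$test, preds)$value, 1)
})

test_that("restricting candidates to test concepts never hurts (synthetic)", {
  for (seed in c(4, 5)) {
    spec <- generator_spec(n_train = 80, n_dev = 0, n_test = 40,
                           sigma = 0.8, seed = seed)
    ont <- generate_ontology(spec)
    sp <- generate_splits(spec, ont)
    tab <- generate_embeddings(spec, ont, attr(sp, "token_owner"))
    model <- fit_projection(sp$train, ont, tab)
    lex_full <- build_augmented_lexicon(ont, sp$train)
    full <- accuracy_general(sp$test,
                             sieve_predict(sp$test, lex_full, model, ont, tab))$value
    test_ids <- concept_ids(subset_ontology(ont, sp$test))
    lex_sub <- build_augmented_lexicon(subset_ontology(ont, sp$test), sp$train)
    sub <- accuracy_general(sp$test,
                            sieve_predict(sp$test, lex_sub, model, ont, tab,
                                          concept_subset = test_ids))$value
    expect_gte(sub, full)
  }
})
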