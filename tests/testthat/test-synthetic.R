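test_that("generator_spec validates its stated world", {
  expect_error(generator_spec(redundancy = 120), "rates")
  expect_error(generator_spec(n_test = 0), "sizes")
  expect_error(generator_spec(labels_per_concept = c(3, 1)), "increasing")
  expect_error(generator_spec(dim = 1), "dimension")
})

test_that("generate_ontology: tree shape, unique labels, determinism", {
  spec <- generator_spec(n_concepts = 50, vocab_size = 500, seed = 2)
  ont <- generate_ontology(spec)
  expect_length(ont$concepts, 50L)
  # tree: exactly n - 1 parent links, single root
  n_links <- sum(lengths(lapply(ont$concepts, `[[`, "parents")))
  expect_identical(n_links, 49L)
  expect_identical(sum(lengths(lapply(ont$concepts, `[[`, "parents")) == 0L), 1L)
  all_labels <- unlist(lapply(ont$concepts, `[[`, "labels"))
  expect_false(anyDuplicated(all_labels) > 0)
  # single concept: root only
  ont1 <- generate_ontology(generator_spec(n_concepts = 1, vocab_size = 50, seed = 2))
  expect_identical(ont1$concepts[[1]]$parents, character(0))
  # determinism
  ont2 <- generate_ontology(spec)
  expect_identical(ont2$concepts, ont$concepts)
  expect_error(generate_ontology(generator_spec(n_concepts = 50, vocab_size = 60)),
               "vocabulary too small")
})

test_that("round-trip: measured indicators reproduce the requested rates", {
  # divisible request: redundancy and zsl must come out exactly
  spec <- generator_spec(n_train = 100, n_dev = 20, n_test = 40,
                         redundancy = 50, zsl = 50, ambiguity = 20,
                         multinorm = 10, nil = 10, seed = 13)
  ont <- generate_ontology(spec)
  sp <- generate_splits(spec, ont)
  expect_equal(redundancy_rate(sp$train, sp$test), 50)
  expect_equal(zsl_rate(sp$train, sp$test), 50)
  pool <- list(sp$train, sp$dev, sp$test)
  tol <- 100 / n_mentions(sp$test)
  expect_lt(abs(ambiguity_rate(pool) - 20), tol)
  expect_lt(abs(multinorm_rate(pool) - 10), tol)
  expect_lt(abs(nil_rate(pool) - 10), tol)
  # r=0, z=100: no test example in train, no test concept in train
  spec2 <- generator_spec(n_concepts = 30, n_train = 60, n_dev = 0,
                          n_test = 20, redundancy = 0, zsl = 100,
                          ambiguity = 0, multinorm = 0, nil = 0, seed = 13)
  ont2 <- generate_ontology(spec2)
  sp2 <- generate_splits(spec2, ont2)
  expect_equal(redundancy_rate(sp2$train, sp2$test), 0)
  expect_equal(zsl_rate(sp2$train, sp2$test), 100)
})

test_that("changing only the seed preserves the measured rates", {
  for (seed in c(101, 202)) {
    spec <- generator_spec(n_train = 80, n_dev = 20, n_test = 40,
                           redundancy = 25, zsl = 50, ambiguity = 10,
                           multinorm = 5, nil = 0, seed = seed)
    ont <- generate_ontology(spec)
    sp <- generate_splits(spec, ont)
    expect_equal(redundancy_rate(sp$train, sp$test), 25)
    expect_equal(zsl_rate(sp$train, sp$test), 50)
  }
})

test_that("infeasible rate combinations fail with a named constraint", {
  expect_error(generate_splits(
    generator_spec(n_concepts = 8, n_test = 10, zsl = 100, redundancy = 50,
                   n_train = 20, n_dev = 0),
    generate_ontology(generator_spec(n_concepts = 8))),
    "redundancy > 0 requires")
  expect_error(generate_splits(
    generator_spec(n_train = 10, n_dev = 0, n_test = 10, ambiguity = 100,
                   multinorm = 50, nil = 50),
    generate_ontology(generator_spec())),
    "infeasible")
})

test_that("generate_embeddings: sigma = 0 collapses mentions onto anchors", {
  spec <- generator_spec(n_train = 40, n_dev = 0, n_test = 20, sigma = 0,
                         redundancy = 0, zsl = 0, ambiguity = 0,
                         multinorm = 0, nil = 0, seed = 6)
  ont <- generate_ontology(spec)
  sp <- generate_splits(spec, ont)
  tab <- generate_embeddings(spec, ont, attr(sp, "token_owner"))
  # a mention embedding equals the embedding of its concept's labels
  surf <- sp$test$mentions$surface[1]
  cid <- sp$test$gold[[sp$test$mentions$mention_id[1]]]
  lab <- ont$concepts[[cid]]$labels[1]
  expect_equal(embed_mention(surf, tab), embed_mention(lab, tab))
  # determinism
  tab2 <- generate_embeddings(spec, ont, attr(sp, "token_owner"))
  expect_identical(tab$vectors, tab2$vectors)
})

test_that("distributional accuracy degrades monotonically with noise (trend)", {
  accs <- vapply(c(0, 1.5, 6), function(sg) {
    spec <- generator_spec(n_concepts = 20, vocab_size = 300, n_train = 60,
                           n_dev = 0, n_test = 30, redundancy = 0, zsl = 0,
                           ambiguity = 0, multinorm = 0, nil = 0,
                           sigma = sg, seed = 10)
    ont <- generate_ontology(spec)
    sp <- generate_splits(spec, ont)
    tab <- generate_embeddings(spec, ont, attr(sp, "token_owner"))
    model <- fit_projection(sp$train, ont, tab)
    # embedding stage only: bypass the dictionary sieve entirely
    preds <- lapply(seq_len(n_mentions(sp$test)), function(i) {
      nearest_label_predict(sp$test$mentions$surface[i], model, ont, tab)$concept_id
    })
    mean(mapply(function(mid, p) p %in% sp$test$gold[[mid]],
                sp$test$mentions$mention_id, preds))
  }, numeric(1))
  expect_equal(accs[1], 1) # noiseless: perfect
  expect_lte(accs[3], accs[1])
  expect_lt(accs[3], 1) # heavy noise visibly degrades
})
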