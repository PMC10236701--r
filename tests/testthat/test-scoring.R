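test_that("strict_match is membership in the gold set", {
  expect_identical(strict_match("A", "A"), 1L)
  expect_identical(strict_match("A", "B"), 0L)
  expect_identical(strict_match(c("A", "B"), "B"), 1L) # any correct concept
})

test_that("classical accuracy averages strict over mentions", {
  gold <- list(m1 = "A", m2 = "B", m3 = "C")
  preds <- make_preds(list(m1 = "A", m2 = "B", m3 = "X"))
  expect_equal(accuracy(gold, preds)$value, 2 / 3)
  expect_equal(accuracy(gold, make_preds(list(m1 = "A", m2 = "B", m3 = "C")))$value, 1)
  expect_equal(accuracy(gold, make_preds(list(m1 = "X", m2 = "X", m3 = "X")))$value, 0)
  # missing prediction scores 0 instead of being excluded
  expect_equal(accuracy(gold, make_preds(list(m1 = "A")))$value, 1 / 3)
  # refuses multi-gold / multi-prediction input
  expect_error(accuracy(list(m1 = c("A", "B")), preds), "multinorm")
  expect_error(accuracy(gold, make_preds(list(m1 = c("A", "B")))), "topk")
})

test_that("topk_accuracy credits any correct candidate within rank k", {
  gold <- list(m1 = "A")
  ranked <- make_preds(list(m1 = c("X", "Y", "A", "Z")))
  expect_equal(topk_accuracy(gold, ranked, 5)$value, 1)
  expect_equal(topk_accuracy(gold, ranked, 2)$value, 0)
  expect_error(topk_accuracy(gold, ranked, 0), "k must be")
  # top-1 equals classical accuracy on single-gold single-prediction data
  set.seed(11)
  for (rep in 1:10) {
    pb <- random_problem(12, max_gold = 1, single_pred = TRUE)
    preds <- make_preds(pb$preds)
    expect_equal(topk_accuracy(pb$gold, preds, 1)$value,
                 accuracy(pb$gold, preds)$value)
  }
})

test_that("multinorm and generalized accuracy follow their formulas", {
  expect_equal(accuracy_multinorm(list(m = c("A", "B")),
                                  make_preds(list(m = "A")))$value, 0.5)
  # no over-prediction penalty in the un-penalized variant ...
  expect_equal(accuracy_multinorm(list(m = "A"),
                                  make_preds(list(m = c("A", "X", "Y"))))$value, 1)
  expect_equal(accuracy_multinorm(list(m = c("A", "B")),
                                  make_preds(list(m = c("A", "B"))))$value, 1)
  # ... and a max(n, p) denominator in the penalized one
  expect_equal(accuracy_general(list(m = "A"),
                                make_preds(list(m = c("A", "X", "Y"))))$value, 1 / 3)
  expect_equal(accuracy_general(list(m = c("A", "B")),
                                make_preds(list(m = "A")))$value, 0.5)
  # NIL mentions are not scorable
  expect_error(accuracy_general(list(m = character()), make_preds(list(m = "A"))),
               "NIL")
})

test_that("lenient accuracy gives multi-labeled mentions full credit, composite not", {
  gold <- list(m = c("A", "B"))
  one <- make_preds(list(m = "A"))
  expect_equal(accuracy_lenient(gold, one)$value, 1)
  expect_equal(accuracy_lenient(gold, one, composite_flags = c(m = TRUE))$value, 0.5)
  expect_error(accuracy_lenient(gold, one, composite_flags = c(zz = TRUE)),
               "unknown")
  # single-gold data: identical to the generalized accuracy
  set.seed(12)
  for (rep in 1:10) {
    pb <- random_problem(12, max_gold = 1)
    preds <- make_preds(pb$preds)
    expect_equal(accuracy_lenient(pb$gold, preds)$value,
                 accuracy_general(pb$gold, preds)$value)
  }
})

test_that("metric family matches literal formula translations on random problems", {
  set.seed(13)
  for (rep in 1:25) {
    pb <- random_problem(15)
    preds <- make_preds(pb$preds)
    expect_equal(accuracy_multinorm(pb$gold, preds)$value,
                 oracle_eq3(pb$gold, pb$preds))
    expect_equal(accuracy_general(pb$gold, preds)$value,
                 oracle_eq4(pb$gold, pb$preds))
    comp <- stats::setNames(sample(c(TRUE, FALSE), length(pb$gold), TRUE),
                            names(pb$gold))
    expect_equal(accuracy_lenient(pb$gold, preds, comp)$value,
                 oracle_lenient(pb$gold, pb$preds, as.list(comp)))
  }
})

test_that("metrics are invariant to mention order; top-k to sub-k permutations", {
  set.seed(14)
  pb <- random_problem(20)
  preds <- make_preds(pb$preds)
  perm <- sample(names(pb$gold))
  expect_equal(accuracy_general(pb$gold[perm], preds)$value,
               accuracy_general(pb$gold, preds)$value)
  # permuting candidates below rank k leaves top-k unchanged
  gold <- list(m = "A")
  p1 <- make_preds(list(m = c("X", "A", "Y", "Z")))
  p2 <- make_preds(list(m = c("X", "A", "Z", "Y")))
  expect_equal(topk_accuracy(gold, p1, 2)$value, topk_accuracy(gold, p2, 2)$value)
})

test_that("adding a wrong prediction never helps the penalized metric", {
  set.seed(15)
  for (rep in 1:15) {
    pb <- random_problem(10, n_concepts = 6)
    before <- make_preds(pb$preds)
    worse <- pb$preds
    mid <- sample(names(worse), 1)
    wrong <- setdiff(pb$universe, c(worse[[mid]], pb$gold[[mid]]))
    if (length(wrong) == 0) next
    worse[[mid]] <- c(worse[[mid]], wrong[1])
    after <- make_preds(worse)
    expect_lte(accuracy_general(pb$gold, after)$value,
               accuracy_general(pb$gold, before)$value)
    expect_equal(accuracy_multinorm(pb$gold, after)$value,
                 accuracy_multinorm(pb$gold, before)$value)
  }
})
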