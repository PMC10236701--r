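test_that("subset_ontology keeps used concepts and leaves hierarchy broken", {
  ont <- en_ontology(list(
    en_concept("K:1", "a"),
    en_concept("K:2", "b", parents = "K:1"),
    en_concept("K:3", "c", parents = "K:2"),
    en_concept("K:4", "d", parents = "K:3"),
    en_concept("K:5", "e")
  ))
  sp <- make_split(c("x", "y"), list("K:2", "K:4"))
  sub <- subset_ontology(ont, sp)
  expect_setequal(concept_ids(sub), c("K:2", "K:4"))
  # K:4's parent K:3 was removed: link dropped, no re-wiring to K:2
  expect_identical(sub$concepts[["K:4"]]$parents, character(0))
  # identity when all concepts are used
  all_sp <- make_split(letters[1:5], as.list(sprintf("K:%d", 1:5)))
  expect_setequal(concept_ids(subset_ontology(ont, all_sp)), concept_ids(ont))
  expect_error(subset_ontology(ont, make_split("x", list("Z:9"))), "no used")
  # idempotent and monotone
  twice <- subset_ontology(sub, sp)
  expect_identical(concept_ids(twice), concept_ids(sub))
  bigger <- subset_ontology(ont, list(sp, make_split("z", list("K:5"))))
  expect_true(all(concept_ids(sub) %in% concept_ids(bigger)))
})

test_that("apply_preproc: identity, fixed order, stopwords, hooks", {
  ident <- preproc_config()
  strs <- c("Gopher Tortoises,", "  odd   spacing ", "UPPER")
  expect_identical(apply_preproc(strs, ident), strs)

  full <- preproc_config(lowercase = TRUE, punctuation_removal = TRUE,
                         stemming = TRUE)
  expect_identical(apply_preproc("Gopher Tortoises,", full), "gopher tortois")

  stop_cfg <- preproc_config(stopword_removal = TRUE)
  expect_identical(apply_preproc("populations of gopher tortoises", stop_cfg),
                   "populations gopher tortoises")

  expect_error(preproc_config(stemming = TRUE, lemmatization = TRUE),
               "mutually exclusive")
  expect_error(apply_preproc("x", preproc_config(hooks = "no-such-hook")),
               "unknown preprocessing hook")

  register_preproc_hook("test-upper", toupper)
  hooked <- preproc_config(hooks = "test-upper")
  expect_identical(apply_preproc("abc", hooked), "ABC")
  # hooks run before the generic flags
  hooked_lc <- preproc_config(lowercase = TRUE, hooks = "test-upper")
  expect_identical(apply_preproc("AbC", hooked_lc), "abc")
})

test_that("audit_report echoes generator rates and is byte-deterministic", {
  spec <- generator_spec(n_train = 80, n_dev = 20, n_test = 40,
                         redundancy = 25, zsl = 50, ambiguity = 20,
                         multinorm = 10, nil = 0, seed = 7)
  sim <- simulate_dataset(spec, tempfile())
  rep <- audit_report(sim$splits$train, sim$splits$test, sim$ontology,
                      dev = sim$splits$dev, embeddings = sim$embeddings)
  ach <- attr(sim$splits, "achieved")
  expect_equal(rep$indicators$rates$redundancy, ach$redundancy)
  expect_equal(rep$indicators$rates$zsl, ach$zsl)
  expect_equal(rep$indicators$rates$multinorm, ach$multinorm)

  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  on.exit(unlink(c(f1, f2)))
  audit_report(sim$splits$train, sim$splits$test, sim$ontology,
               dev = sim$splits$dev, embeddings = sim$embeddings,
               out = f1, markdown = TRUE)
  audit_report(sim$splits$train, sim$splits$test, sim$ontology,
               dev = sim$splits$dev, embeddings = sim$embeddings, out = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_true(file.exists(sub("\\.json$", ".md", f1)))
})

test_that("zero ambiguity/multinorm data: lenient equals generalized accuracy", {
  spec <- generator_spec(n_train = 60, n_dev = 0, n_test = 30,
                         redundancy = 40, zsl = 20, ambiguity = 0,
                         multinorm = 0, nil = 0, sigma = 0, seed = 8)
  ont <- generate_ontology(spec)
  sp <- generate_splits(spec, ont)
  tab <- generate_embeddings(spec, ont, attr(sp, "token_owner"))
  rep <- audit_report(sp$train, sp$test, ont, embeddings = tab)
  expect_equal(rep$metric_variants$delta, 0)
})

test_that("cli verbs run end to end on a simulated dataset", {
  d <- file.path(tempfile(), "sim")
  en_cli(c("simulate", "--out", d, "--seed", "5"))
  expect_true(file.exists(file.path(d, "ontology.obo")))
  out_json <- tempfile(fileext = ".json")
  en_cli(c("audit", "--train", file.path(d, "train"),
           "--dev", file.path(d, "dev"), "--test", file.path(d, "test"),
           "--ontology", file.path(d, "ontology.obo"),
           "--embeddings", file.path(d, "embeddings.w2v.txt"),
           "--out", out_json))
  rep <- jsonlite::read_json(out_json)
  expect_true(rep$indicators$rates$redundancy >= 0)
  pred_tsv <- tempfile(fileext = ".tsv")
  en_cli(c("predict", "--train", file.path(d, "train"),
           "--test", file.path(d, "test"),
           "--ontology", file.path(d, "ontology.obo"),
           "--embeddings", file.path(d, "embeddings.w2v.txt"),
           "--out", pred_tsv))
  expect_gt(nrow(read_predictions_tsv(pred_tsv)$df), 0)
  out <- capture.output(
    en_cli(c("score", "--gold", file.path(d, "test"), "--pred", pred_tsv,
             "--ontology", file.path(d, "ontology.obo"), "--metric", "eq4")))
  expect_match(out, "generalized accuracy")
  sub_obo <- tempfile(fileext = ".obo")
  en_cli(c("subset", "--splits", file.path(d, "train"),
           "--ontology", file.path(d, "ontology.obo"), "--out", sub_obo))
  expect_lte(length(read_obo_ontology(sub_obo)$concepts),
             length(read_obo_ontology(file.path(d, "ontology.obo"))$concepts))
})
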