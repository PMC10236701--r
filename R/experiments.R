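# Ablation harness: ontology subsetting (the "evaluate on the concepts the
# test set happens to use" shortcut, reproduced deliberately so its effect
# can be measured), and the combined bias-audit report.

#' Subset an ontology to the concepts used by given splits
#'
#' Keeps exactly the concepts appearing in the splits' gold sets.  Parent
#' links to removed concepts are dropped without re-wiring: the broken
#' subsumption hierarchy is left broken, because re-wiring would silently
#' change graph-based methods while the point of the ablation is only to
#' shrink the candidate set.
#'
#' @param ontology An \code{en_ontology}.
#' @param splits A list of \code{en_split}s (or a single split).
#' @return An \code{en_ontology}; error when no concept remains.
#' @export
subset_ontology <- function(ontology, splits) {
  if (inherits(splits, "en_split")) splits <- list(splits)
  used <- character()
  for (s in splits) used <- union(used, used_concepts(s))
  keep <- intersect(names(ontology$concepts), used)
  if (length(keep) == 0L) stop("no used concept found in the ontology")
  kept <- lapply(ontology$concepts[keep], function(con) {
    con$parents <- intersect(con$parents, keep) # broken hierarchy stays broken
    con
  })
  aliases <- ontology$aliases[ontology$aliases %in% keep]
  en_ontology(kept, name = paste0(ontology$name, " (subset)"),
              version = ontology$version, aliases = aliases)
}

#' Combined bias-audit report
#'
#' One call that operationalizes "report the dataset biases next to the
#' scores": the six indicators, the baseline generalized accuracy under
#' full / train-only / train+eval ontology subsets (when embeddings are
#' available the full sieve runs, otherwise the dictionary stage alone),
#' and the delta between the penalized and the lenient metric.  The result
#' is a pure function of its inputs and configuration: rerunning with the
#' same inputs yields byte-identical JSON.
#'
#' @param train,test \code{en_split}s.
#' @param ontology An \code{en_ontology}.
#' @param dev Optional dev \code{en_split}.
#' @param embeddings Optional \code{en_embeddings} enabling the second sieve.
#' @param policy Surface comparison policy for the indicators.
#' @param lambda Ridge penalty for the projection.
#' @param out Optional path: writes the JSON report there (and a Markdown
#'   rendering next to it when \code{markdown = TRUE}).
#' @param markdown Also write a Markdown rendering.
#' @return The report (nested list), invisibly when \code{out} is given.
#' @export
audit_report <- function(train, test, ontology, dev = NULL, embeddings = NULL,
                         policy = "exact", lambda = 1e-8, out = NULL,
                         markdown = FALSE) {
  ind <- indicator_report(train, test, dev = dev, policy = policy)

  eval_gold_ok <- all(lengths(test$gold) >= 1L)
  subsets <- list(full = NULL)
  subsets[["train"]] <- concept_ids(subset_ontology(ontology, list(train)))
  subsets[["train+eval"]] <- concept_ids(subset_ontology(
    ontology, c(list(train), if (!is.null(dev)) list(dev), list(test))))

  lexicon <- build_augmented_lexicon(ontology, train)
  model <- if (!is.null(embeddings)) {
    fit_projection(train, ontology, embeddings, lambda = lambda)
  } else NULL

  baseline <- list()
  preds_full <- NULL
  for (sub_name in names(subsets)) {
    sub_ids <- subsets[[sub_name]]
    lex <- if (is.null(sub_ids)) lexicon else {
      build_augmented_lexicon(subset_ontology_ids(ontology, sub_ids), train)
    }
    preds <- sieve_predict(test, lex, model = model, ontology = ontology,
                           table = embeddings, concept_subset = sub_ids)
    if (sub_name == "full") preds_full <- preds
    baseline[[sub_name]] <- if (eval_gold_ok) {
      accuracy_general(test, preds)$value
    } else NA_real_
  }

  metric_delta <- if (eval_gold_ok) {
    eq4 <- accuracy_general(test, preds_full)$value
    len <- accuracy_lenient(test, preds_full)$value
    list(general = eq4, lenient = len, delta = len - eq4)
  } else list(general = NA_real_, lenient = NA_real_, delta = NA_real_)

  rep <- list(
    config = list(policy = policy, lambda = lambda,
                  stemmer = "porter-1980", tokenizer = "alnum-split",
                  embeddings = !is.null(embeddings),
                  significance_note = paste(
                    "heuristic: differences under 3 points should not be",
                    "called significant")),
    indicators = unclass(ind),
    baseline_accuracy_general = baseline,
    metric_variants = metric_delta,
    ontology = list(n_concepts = length(ontology$concepts),
                    n_train_subset = length(subsets[["train"]]),
                    n_train_eval_subset = length(subsets[["train+eval"]]))
  )
  if (!is.null(out)) {
    json <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    con <- file(out, open = "wb")
    writeLines(json, con, sep = "\n", useBytes = TRUE)
    close(con)
    if (markdown) {
      md_path <- sub("\\.json$", ".md", out)
      if (identical(md_path, out)) md_path <- paste0(out, ".md")
      writeLines(.report_markdown(rep), md_path, useBytes = TRUE)
    }
    return(invisible(rep))
  }
  rep
}

# helper: materialize a subset ontology from a vector of ids
subset_ontology_ids <- function(ontology, ids) {
  keep <- intersect(names(ontology$concepts), ids)
  if (length(keep) == 0L) stop("no concept to keep")
  kept <- lapply(ontology$concepts[keep], function(con) {
    con$parents <- intersect(con$parents, keep)
    con
  })
  en_ontology(kept, name = paste0(ontology$name, " (subset)"),
              version = ontology$version)
}

.report_markdown <- function(rep) {
  r <- rep$indicators$rates
  f <- rep$indicators$fsl
  c(
    "# Normalization dataset audit",
    "",
    sprintf("Surface policy: `%s`", rep$config$policy),
    "",
    "## Indicators",
    "",
    "| indicator | value | denominator |",
    "|---|---|---|",
    sprintf("| FSL average / median / max | %.2f / %.2f / %d | %d used concepts |",
            f$average, f$median, as.integer(f$max), f$n_used_concepts),
    sprintf("| FSL (distinct) | %.2f / %.2f / %d | %d used concepts |",
            f$average_distinct, f$median_distinct, as.integer(f$max_distinct),
            f$n_used_concepts),
    sprintf("| multi-normalization | %.1f%% | %d mentions |",
            r$multinorm, rep$indicators$denominators$intra_mentions),
    sprintf("| NIL | %.1f%% | %d mentions |",
            r$nil, rep$indicators$denominators$intra_mentions),
    sprintf("| ambiguity | %.1f%% | %d mentions |",
            r$ambiguity, rep$indicators$denominators$intra_mentions),
    sprintf("| redundancy | %.1f%% | %d test mentions |",
            r$redundancy, rep$indicators$denominators$test_mentions),
    sprintf("| ZSL | %.1f%% | %d test concepts |",
            r$zsl, rep$indicators$denominators$test_concepts),
    "",
    "## Baseline (generalized accuracy, points)",
    "",
    "| ontology | accuracy |",
    "|---|---|",
    sprintf("| full (%d concepts) | %.1f |",
            rep$ontology$n_concepts, 100 * rep$baseline_accuracy_general$full),
    sprintf("| train subset (%d) | %.1f |",
            rep$ontology$n_train_subset, 100 * rep$baseline_accuracy_general[["train"]]),
    sprintf("| train+eval subset (%d) | %.1f |",
            rep$ontology$n_train_eval_subset,
            100 * rep$baseline_accuracy_general[["train+eval"]]),
    "",
    sprintf("Lenient minus generalized accuracy: %.2f points",
            100 * rep$metric_variants$delta),
    "",
    sprintf("_%s_", rep$config$significance_note)
  )
}
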