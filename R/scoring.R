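# The accuracy family.  All metrics are means over the N evaluated
# mentions of a per-mention contribution in [0,1].  Mentions present in
# gold but absent from the predictions contribute 0 (p_i = 0), they are
# never silently excluded: excluding them would inflate scores because the
# denominator of every metric is over all N mentions.

# normalize the gold argument: either an en_split or a named list of
# character vectors (mention_id -> gold concept set)
as_gold <- function(gold) {
  if (inherits(gold, "en_split")) return(gold$gold)
  if (is.list(gold)) {
    if (length(gold) && is.null(names(gold))) stop("gold list must be named by mention id")
    return(gold)
  }
  stop("gold must be an en_split or a named list of concept-id vectors")
}

new_score_result <- function(per_mention, metric) {
  structure(
    list(value = if (length(per_mention)) mean(per_mention) else NA_real_,
         per_mention = per_mention,
         n = length(per_mention),
         metric = metric),
    class = "en_score"
  )
}

#' @export
print.en_score <- function(x, ...) {
  cat(sprintf("<en_score> %s = %.4f  (%.1f points, N = %d)\n",
              x$metric, x$value, 100 * x$value, x$n))
  invisible(x)
}

#' Strict per-concept correctness
#'
#' 1 if \code{concept_id} is a correct concept of the mention (i.e. belongs
#' to its gold set), 0 otherwise.
#'
#' @param gold_set Character vector of gold concept ids for one mention.
#' @param concept_id Single concept id.
#' @return 0 or 1.
#' @export
strict_match <- function(gold_set, concept_id) {
  as.integer(concept_id %in% gold_set)
}

# per-mention prediction lists, aligned to the gold mentions
.pred_lists <- function(gold, preds) {
  stopifnot(inherits(preds, "en_predictions"))
  df <- preds$df
  by_m <- split(df$concept_id, df$mention_id)
  lapply(names(gold), function(mid) {
    p <- by_m[[mid]]
    if (is.null(p)) character(0) else p
  })
}

#' Classical accuracy (single gold concept, single prediction)
#'
#' The consensus task-level metric: the mean over mentions of
#' \code{strict_match} between the single predicted concept and the single
#' gold concept.  Refuses multi-gold or multi-prediction input; use
#' \code{\link{accuracy_multinorm}} or \code{\link{accuracy_general}} for
#' those.  A mention with no prediction contributes 0.
#'
#' @param gold An \code{en_split} or named list mention_id -> gold set.
#' @param preds An \code{en_predictions}.
#' @return An \code{en_score}.
#' @export
accuracy <- function(gold, preds) {
  gold <- as_gold(gold)
  if (length(gold) == 0L) stop("no annotated mentions to evaluate")
  if (any(lengths(gold) != 1L)) {
    stop("accuracy() requires exactly one gold concept per mention; ",
         "use accuracy_multinorm() / accuracy_general() for multi-normalization")
  }
  plists <- .pred_lists(gold, preds)
  if (any(lengths(plists) > 1L)) {
    stop("accuracy() requires at most one prediction per mention; ",
         "use topk_accuracy() or accuracy_general()")
  }
  contrib <- mapply(function(g, p) {
    if (length(p) == 0L) 0 else strict_match(g, p[1L])
  }, gold, plists)
  new_score_result(stats::setNames(as.numeric(contrib), names(gold)), "accuracy")
}

#' Top-k accuracy
#'
#' Per-mention contribution 1 iff any of the first k ranked candidates is a
#' correct concept of the mention.
#'
#' @param gold An \code{en_split} or named gold list.
#' @param preds Ranked \code{en_predictions}.
#' @param k Number of candidates considered, >= 1.
#' @return An \code{en_score}.
#' @export
topk_accuracy <- function(gold, preds, k) {
  if (!is.numeric(k) || length(k) != 1L || k < 1) stop("k must be >= 1")
  gold <- as_gold(gold)
  if (length(gold) == 0L) stop("no annotated mentions to evaluate")
  plists <- .pred_lists(gold, preds)
  contrib <- mapply(function(g, p) {
    topk <- utils::head(p, k)
    as.numeric(any(topk %in% g))
  }, gold, plists)
  new_score_result(stats::setNames(as.numeric(contrib), names(gold)),
                   sprintf("top-%d accuracy", as.integer(k)))
}

# shared engine for the multi-normalization metrics
.multinorm_engine <- function(gold, preds, denom_fun, metric) {
  gold <- as_gold(gold)
  if (length(gold) == 0L) stop("no annotated mentions to evaluate")
  if (any(lengths(gold) == 0L)) {
    stop("NIL mentions (empty gold set) are not scorable by this metric; ",
         "filter them out or evaluate them separately")
  }
  plists <- .pred_lists(gold, preds)
  contrib <- mapply(function(g, p) {
    hits <- sum(p %in% g)
    den <- denom_fun(length(g), length(p))
    if (den == 0) 0 else min(1, hits / den)
  }, gold, plists)
  new_score_result(stats::setNames(as.numeric(contrib), names(gold)), metric)
}

#' Accuracy generalized to multi-normalization (no over-prediction penalty)
#'
#' Per-mention contribution: (number of correctly predicted distinct
#' concepts) / n_i, where n_i is the number of gold concepts.  Predicting
#' extra wrong concepts costs nothing, which is the known pathology this
#' family fixes: predicting the whole ontology scores a perfect 1 here.
#'
#' @inheritParams accuracy
#' @return An \code{en_score}.
#' @export
accuracy_multinorm <- function(gold, preds) {
  .multinorm_engine(gold, preds, function(n, p) n, "multinorm accuracy")
}

#' Generalized accuracy with over-prediction penalty
#'
#' Per-mention contribution: (number of correctly predicted distinct
#' concepts) / max(n_i, p_i), where p_i is the number of predicted distinct
#' concepts.  The max operator penalizes predicting more concepts than
#' expected; with a single prediction per mention it reduces to
#' \code{\link{accuracy_multinorm}}.  A mention with no prediction (p_i = 0)
#' contributes 0.
#'
#' @inheritParams accuracy
#' @return An \code{en_score}.
#' @export
accuracy_general <- function(gold, preds) {
  .multinorm_engine(gold, preds, function(n, p) max(n, p), "generalized accuracy")
}

#' Lenient (any-correct) accuracy for multi-labeled mentions
#'
#' The scoring convention popularized by the BioSyn evaluation script: a
#' multi-labeled (non-composite) mention gets the full point as soon as any
#' predicted concept is correct.  Composite mentions (whose gold set comes
#' from splitting a composite identifier, e.g. "breast or ovarian cancer")
#' still require all concepts and are scored as
#' \code{\link{accuracy_general}}, as are single-gold mentions.
#'
#' @inheritParams accuracy
#' @param composite_flags Named logical vector mention_id -> is-composite.
#'   When \code{gold} is an \code{en_split} the flags default to its
#'   \code{composite} mention column.  Flags for unknown mentions are an
#'   error.
#' @return An \code{en_score}.
#' @export
accuracy_lenient <- function(gold, preds, composite_flags = NULL) {
  if (inherits(gold, "en_split") && is.null(composite_flags)) {
    composite_flags <- stats::setNames(gold$mentions$composite,
                                       gold$mentions$mention_id)
  }
  gold <- as_gold(gold)
  if (length(gold) == 0L) stop("no annotated mentions to evaluate")
  if (is.null(composite_flags)) {
    composite_flags <- stats::setNames(rep(FALSE, length(gold)), names(gold))
  }
  unknown <- setdiff(names(composite_flags), names(gold))
  if (length(unknown)) {
    stop("composite flag(s) for unknown mention(s): ",
         paste(unknown, collapse = ", "))
  }
  if (any(lengths(gold) == 0L)) {
    stop("NIL mentions (empty gold set) are not scorable by this metric")
  }
  plists <- .pred_lists(gold, preds)
  contrib <- mapply(function(mid, g, p) {
    multi <- length(g) >= 2L
    comp <- isTRUE(composite_flags[[mid]])
    if (multi && !comp) {
      as.numeric(any(p %in% g))
    } else {
      hits <- sum(p %in% g)
      den <- max(length(g), length(p))
      if (den == 0) 0 else min(1, hits / den)
    }
  }, names(gold), gold, plists)
  new_score_result(stats::setNames(as.numeric(contrib), names(gold)),
                   "lenient accuracy")
}
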