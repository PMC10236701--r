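# Dataset-bias indicators for (train, test) pairs of entity-normalization
# gold standards.  Intra-fold: few-shot (FSL) statistics, multi-norm, NIL
# and ambiguity rates.  Inter-fold: redundancy (examples seen in training
# and met again at test time) and zero-shot (ZSL, test concepts never seen
# in training).  All rates are percentages in [0, 100] and come with their
# denominators so a report is auditable.

# pool several splits into one (mentions get a split-name prefix to stay
# unique; surfaces and gold sets are what matters for the indicators)
pool_splits <- function(splits, name = "pool") {
  stopifnot(length(splits) >= 1L)
  ms <- list(); gold <- list()
  for (i in seq_along(splits)) {
    s <- splits[[i]]
    stopifnot(inherits(s, "en_split"))
    m <- s$mentions
    prefix <- paste0(i, ":", s$name, "::")
    new_ids <- paste0(prefix, m$mention_id)
    g <- s$gold
    names(g) <- paste0(prefix, names(g))
    m$mention_id <- new_ids
    ms[[length(ms) + 1L]] <- m
    gold <- c(gold, g)
  }
  en_split(name, do.call(rbind, ms), gold)
}

# annotated (mention instance) view of one or more splits: surface key and
# canonical gold-set key per annotated mention
.instances <- function(splits, policy) {
  pooled <- if (inherits(splits, "en_split")) splits else pool_splits(splits)
  gold <- pooled$gold
  if (length(gold) == 0L) stop("no annotated mentions in the given split(s)")
  surf <- stats::setNames(pooled$mentions$surface, pooled$mentions$mention_id)
  data.frame(
    mention_id = names(gold),
    skey = surface_key(unname(surf[names(gold)]), policy),
    gkey = vapply(gold, gold_key, character(1), USE.NAMES = FALSE),
    n_gold = lengths(gold),
    row.names = NULL
  )
}

#' Few-shot learning statistics of a training split
#'
#' Distribution statistics of the number of mentions annotated per used
#' concept: how many examples a learner gets to see for each concept.
#' Only concepts annotating at least one mention are considered.  With
#' \code{distinct = TRUE}, mentions sharing a surface form (per
#' \code{\link{surface_key}}) contribute a single example.
#'
#' @param split An \code{en_split} (typically the training material).
#' @param distinct Count distinct surface forms instead of instances.
#' @param policy Surface comparison policy.
#' @return List with \code{average}, \code{median}, \code{max} and
#'   \code{n_concepts} (the denominator).
#' @export
fsl_stats <- function(split, distinct = FALSE, policy = "exact") {
  counts <- concept_usage_counts(split, policy)
  if (nrow(counts) == 0L) stop("split has no annotated mentions")
  v <- if (distinct) counts$distinct_surfaces else counts$instances
  list(average = mean(v), median = stats::median(v), max = max(v),
       n_concepts = nrow(counts))
}

#' Multi-normalization rate
#'
#' Percentage of annotated mentions whose gold set contains two or more
#' distinct concepts (includes composite mentions).
#'
#' @param splits An \code{en_split} or list of splits pooled together.
#' @param policy Surface comparison policy (unused here; kept for a uniform
#'   signature).
#' @return Percentage in [0, 100].
#' @export
multinorm_rate <- function(splits, policy = "exact") {
  inst <- .instances(splits, policy)
  100 * sum(inst$n_gold >= 2L) / nrow(inst)
}

#' NIL rate
#'
#' Percentage of annotated mentions whose gold set is empty: mentions that
#' should be normalized by no concept of the reference (corpora often mark
#' these with a "CONCEPT_LESS" label, mapped to the empty set at read
#' time).
#'
#' @inheritParams multinorm_rate
#' @return Percentage in [0, 100].
#' @export
nil_rate <- function(splits, policy = "exact") {
  inst <- .instances(splits, policy)
  100 * sum(inst$n_gold == 0L) / nrow(inst)
}

#' Ambiguity rate
#'
#' Percentage of mention instances whose surface form also occurs, anywhere
#' in the pooled splits, with a different gold concept set.  Full gold sets
#' are compared (not single concepts) so a multi-normalized mention is not
#' spuriously ambiguous against itself.
#'
#' @inheritParams multinorm_rate
#' @return Percentage in [0, 100].
#' @export
ambiguity_rate <- function(splits, policy = "exact") {
  inst <- .instances(splits, policy)
  amb_by_surface <- tapply(inst$gkey, inst$skey, function(g) length(unique(g)) > 1L)
  ambiguous <- amb_by_surface[inst$skey]
  100 * sum(ambiguous) / nrow(inst)
}

#' Redundancy rate between training and test material
#'
#' An example is the pair (surface form, gold concept set).  Redundancy is
#' the percentage of test mention instances whose example was already met
#' in the training material — instance-level counting, not unique pairs:
#' a frequent memorizable example inflates test scores once per occurrence.
#'
#' @param train,test \code{en_split}s (train may be a pooled split, e.g.
#'   train + dev).
#' @param policy Surface comparison policy.
#' @return Percentage in [0, 100].
#' @export
redundancy_rate <- function(train, test, policy = "exact") {
  tr <- .instances(train, policy)
  te <- .instances(test, policy)
  train_examples <- unique(paste(tr$skey, tr$gkey, sep = "\r"))
  test_examples <- paste(te$skey, te$gkey, sep = "\r")
  100 * sum(test_examples %in% train_examples) / nrow(te)
}

#' Zero-shot (ZSL) rate between training and test material
#'
#' Percentage of concepts used in the test set that are never used in the
#' training material.  A high value means the dataset actually probes the
#' ability to predict unseen concepts.
#'
#' @inheritParams redundancy_rate
#' @return Percentage in [0, 100].
#' @export
zsl_rate <- function(train, test) {
  ctr <- used_concepts(if (inherits(train, "en_split")) train else pool_splits(train))
  cte <- used_concepts(if (inherits(test, "en_split")) test else pool_splits(test))
  if (length(cte) == 0L) stop("test split uses no concepts")
  100 * length(setdiff(cte, ctr)) / length(cte)
}

#' Full indicator report for a (train, [dev,] test) dataset
#'
#' Computes the six bias indicators with their denominators.  FSL
#' statistics are computed on \code{fsl_on} (default: the training split);
#' multi-norm, NIL and ambiguity on \code{pool} (default: all provided
#' splits pooled); redundancy and ZSL compare \code{train} (pooled with
#' \code{dev} when \code{pool_dev_into_train} is TRUE) against \code{test}.
#'
#' @param train,test Required \code{en_split}s.
#' @param dev Optional \code{en_split}.
#' @param policy Surface comparison policy, recorded in the report.
#' @param fsl_on Split used for FSL statistics; defaults to \code{train}.
#' @param pool Splits pooled for the intra-fold rates; defaults to all.
#' @param pool_dev_into_train Whether dev counts as training material for
#'   redundancy/ZSL (the convention when the final model trains on
#'   train + dev).
#' @return An object of class \code{indicator_report} (a nested list).
#' @export
indicator_report <- function(train, test, dev = NULL, policy = "exact",
                             fsl_on = NULL, pool = NULL,
                             pool_dev_into_train = FALSE) {
  stopifnot(inherits(train, "en_split"), inherits(test, "en_split"))
  if (is.null(fsl_on)) fsl_on <- train
  if (is.null(pool)) {
    pool <- c(list(train), if (!is.null(dev)) list(dev), list(test))
  }
  train_side <- if (pool_dev_into_train && !is.null(dev)) {
    pool_splits(list(train, dev), "train+dev")
  } else train
  pooled <- if (inherits(pool, "en_split")) pool else pool_splits(pool)
  fsl <- fsl_stats(fsl_on, distinct = FALSE, policy = policy)
  fsl_d <- fsl_stats(fsl_on, distinct = TRUE, policy = policy)
  rep <- list(
    policy = policy,
    fsl = list(average = fsl$average, median = fsl$median, max = fsl$max,
               average_distinct = fsl_d$average, median_distinct = fsl_d$median,
               max_distinct = fsl_d$max, n_used_concepts = fsl$n_concepts),
    rates = list(
      multinorm = multinorm_rate(pooled, policy),
      nil = nil_rate(pooled, policy),
      ambiguity = ambiguity_rate(pooled, policy),
      redundancy = redundancy_rate(train_side, test, policy),
      zsl = zsl_rate(train_side, test)
    ),
    denominators = list(
      intra_mentions = length(pooled$gold),
      test_mentions = length(test$gold),
      test_concepts = length(used_concepts(test)),
      train_mentions = length(train_side$gold)
    )
  )
  class(rep) <- "indicator_report"
  rep
}

#' @export
print.indicator_report <- function(x, ...) {
  cat("<indicator_report> (surface policy:", x$policy, ")\n")
  cat(sprintf("  FSL avg/med/max:          %.1f / %.1f / %d (distinct %.1f / %.1f / %d) over %d concepts\n",
              x$fsl$average, x$fsl$median, as.integer(x$fsl$max),
              x$fsl$average_distinct, x$fsl$median_distinct,
              as.integer(x$fsl$max_distinct), x$fsl$n_used_concepts))
  r <- x$rates
  cat(sprintf("  multinorm %.1f%%  nil %.1f%%  ambiguity %.1f%%  redundancy %.1f%%  zsl %.1f%%\n",
              r$multinorm, r$nil, r$ambiguity, r$redundancy, r$zsl))
  invisible(x)
}
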