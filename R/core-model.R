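#' Construct a concept
#'
#' A concept is one entry of the reference set used for normalization: an
#' opaque identifier (e.g. \code{"OBT:001351"}, \code{"MESH:D001943"}), an
#' ordered non-empty vector of labels (the first one is the preferred term),
#' and the identifiers of its parent concepts in the subsumption hierarchy
#' (empty for roots or non-hierarchical references).
#'
#' @param id Non-empty identifier string.
#' @param labels Character vector of surface strings; duplicates (after exact
#'   comparison) are collapsed keeping first occurrence.
#' @param parents Character vector of parent concept ids.
#' @return An object of class \code{en_concept}.
#' @export
en_concept <- function(id, labels, parents = character()) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop("concept id must be a single non-empty string")
  }
  labels <- as.character(labels)
  labels <- labels[nzchar(labels)]
  if (length(labels) == 0L) {
    stop("concept '", id, "' must have at least one non-empty label")
  }
  labels <- labels[!duplicated(labels)]
  structure(
    list(id = id, labels = labels, parents = unique(as.character(parents))),
    class = "en_concept"
  )
}

#' Construct an ontology (the reference set)
#'
#' The reference set C of the normalization task: a collection of concepts
#' keyed by id, with an acyclic parent relation.  Alternative identifiers
#' (e.g. MEDIC \code{AltDiseaseIDs}) may be registered as aliases resolving
#' to a primary concept.
#'
#' @param concepts List of \code{en_concept} objects.
#' @param name,version Free-text metadata.
#' @param aliases Named character vector mapping alias id -> primary id.
#' @return An object of class \code{en_ontology}.
#' @export
en_ontology <- function(concepts, name = "", version = "", aliases = character()) {
  if (length(concepts) == 0L) stop("an ontology must contain at least one concept")
  ids <- vapply(concepts, function(x) x$id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate concept id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  names(concepts) <- ids
  # every parent must resolve
  for (con in concepts) {
    missing <- setdiff(con$parents, ids)
    if (length(missing)) {
      stop("concept '", con$id, "' has unresolvable parent(s): ",
           paste(missing, collapse = ", "))
    }
  }
  obj <- structure(
    list(concepts = concepts, name = name, version = version,
         aliases = aliases),
    class = "en_ontology"
  )
  .check_acyclic(obj)
  obj
}

# depth-first cycle check over the parent relation
.check_acyclic <- function(ontology) {
  ids <- names(ontology$concepts)
  state <- new.env(parent = emptyenv()) # 1 = in progress, 2 = done
  visit <- function(id) {
    s <- state[[id]]
    if (!is.null(s)) {
      if (s == 1L) stop("cyclic parent relation involving concept '", id, "'")
      return(invisible())
    }
    state[[id]] <- 1L
    for (p in ontology$concepts[[id]]$parents) visit(p)
    state[[id]] <- 2L
    invisible()
  }
  for (id in ids) visit(id)
  invisible(ontology)
}

#' @export
print.en_ontology <- function(x, ...) {
  cat("<en_ontology>", if (nzchar(x$name)) x$name else "(unnamed)",
      "-", length(x$concepts), "concepts,",
      length(x$aliases), "aliases\n")
  invisible(x)
}

#' Resolve a concept id against an ontology
#'
#' Follows aliases; returns \code{NA_character_} when the id is unknown.
#'
#' @param ontology An \code{en_ontology}.
#' @param id Concept id or alias.
#' @return The primary concept id, or \code{NA_character_}.
#' @export
resolve_concept_id <- function(ontology, id) {
  if (id %in% names(ontology$concepts)) return(id)
  hit <- ontology$aliases[id]
  if (!is.na(hit) && hit %in% names(ontology$concepts)) return(unname(hit))
  NA_character_
}

#' Concept ids of an ontology
#' @param ontology An \code{en_ontology}.
#' @return Character vector of primary concept ids.
#' @export
concept_ids <- function(ontology) names(ontology$concepts)

#' Construct a dataset split
#'
#' A split (train, dev, test or an arbitrary fold) holds mentions and their
#' gold annotations.  Mentions are rows of a data frame; gold annotations
#' map mention ids to sets of concept ids.  An empty gold set encodes a NIL
#' mention (no concept in the reference applies); corpora that use a
#' sentinel "CONCEPT_LESS" concept are mapped to the empty set at read time.
#'
#' @param name Split label ("train", "dev", "test", fold id ...).
#' @param mentions Data frame with columns \code{mention_id}, \code{doc_id},
#'   \code{surface}, \code{entity_type} and logical \code{composite}
#'   (composite mentions such as "breast or ovarian cancer" whose gold set
#'   was produced by splitting a composite identifier).
#' @param gold Named list: mention_id -> character vector of concept ids
#'   (possibly empty = NIL).  Every key must be a mention id of the split.
#' @param spans Named list: mention_id -> integer matrix with columns
#'   \code{start}, \code{end} (0-based, end-exclusive), rows sorted by start
#'   and non-overlapping.  Optional (span-free datasets).
#' @return An object of class \code{en_split}.
#' @export
en_split <- function(name, mentions, gold = list(), spans = list()) {
  stopifnot(is.data.frame(mentions))
  required <- c("mention_id", "doc_id", "surface", "entity_type")
  missing_cols <- setdiff(required, names(mentions))
  if (length(missing_cols)) {
    stop("mentions is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (!"composite" %in% names(mentions)) mentions$composite <- FALSE
  if (anyDuplicated(mentions$mention_id)) {
    stop("duplicate mention id(s) in split '", name, "'")
  }
  if (any(!nzchar(mentions$surface))) {
    stop("empty mention surface(s) in split '", name, "'")
  }
  bad <- setdiff(names(gold), mentions$mention_id)
  if (length(bad)) {
    stop("gold annotation(s) for unknown mention id(s): ",
         paste(bad, collapse = ", "))
  }
  if (anyDuplicated(names(gold))) stop("a mention has more than one gold entry")
  for (mid in names(spans)) {
    sp <- spans[[mid]]
    if (!is.matrix(sp) || ncol(sp) != 2L) stop("spans for '", mid, "' must be a 2-column matrix")
    if (nrow(sp) > 1L) {
      if (is.unsorted(sp[, 1L])) stop("spans for '", mid, "' not sorted by start")
      if (any(sp[-1L, 1L] < sp[-nrow(sp), 2L])) stop("overlapping spans for '", mid, "'")
    }
  }
  rownames(mentions) <- NULL
  structure(list(name = name, mentions = mentions, gold = gold, spans = spans),
            class = "en_split")
}

#' @export
print.en_split <- function(x, ...) {
  n_ann <- length(x$gold)
  cat("<en_split>", x$name, "-", nrow(x$mentions), "mentions,",
      n_ann, "annotated\n")
  invisible(x)
}

#' Number of mentions in a split
#' @param split An \code{en_split}.
#' @return Integer count.
#' @export
n_mentions <- function(split) nrow(split$mentions)

#' Construct a prediction set
#'
#' Per-mention ranked (or unranked) predicted concepts.  Unranked
#' predictions carry equal scores.  For one mention the predicted concept
#' ids must be distinct and the scores non-increasing in list order.
#'
#' @param df Data frame with columns \code{mention_id}, \code{concept_id}
#'   and optionally \code{score} (finite; defaults to 1).  Row order within
#'   a mention is the rank order.
#' @return An object of class \code{en_predictions}.
#' @export
en_predictions <- function(df = data.frame(mention_id = character(),
                                           concept_id = character(),
                                           score = numeric())) {
  stopifnot(is.data.frame(df))
  if (!"score" %in% names(df)) df$score <- rep(1, nrow(df))
  need <- c("mention_id", "concept_id", "score")
  if (!all(need %in% names(df))) {
    stop("predictions need columns mention_id, concept_id[, score]")
  }
  df <- df[, need, drop = FALSE]
  if (nrow(df)) {
    if (any(!is.finite(df$score))) stop("prediction scores must be finite")
    by_m <- split(seq_len(nrow(df)), df$mention_id)
    for (idx in by_m) {
      if (anyDuplicated(df$concept_id[idx])) {
        stop("duplicate predicted concept for mention '",
             df$mention_id[idx[1L]], "'")
      }
      sc <- df$score[idx]
      if (length(sc) > 1L && any(diff(sc) > 1e-12)) {
        stop("scores must be non-increasing in rank order for mention '",
             df$mention_id[idx[1L]], "'")
      }
    }
  }
  rownames(df) <- NULL
  structure(list(df = df), class = "en_predictions")
}

#' @export
print.en_predictions <- function(x, ...) {
  cat("<en_predictions>", nrow(x$df), "predictions for",
      length(unique(x$df$mention_id)), "mentions\n")
  invisible(x)
}

#' Predicted concepts for one mention, in rank order
#' @param preds An \code{en_predictions}.
#' @param mention_id Mention identifier.
#' @return Character vector (possibly empty).
#' @export
predictions_for <- function(preds, mention_id) {
  preds$df$concept_id[preds$df$mention_id == mention_id]
}

#' Canonical key for "same surface form" comparisons
#'
#' Single point of truth for deciding whether two mention surfaces count as
#' the same example surface in the indicators.  \code{"exact"} returns the
#' input unchanged; \code{"casefold"} lower-cases; \code{"casefold+ws"}
#' additionally trims and collapses internal whitespace runs to one space.
#'
#' @param surface Character vector.
#' @param policy One of \code{"exact"}, \code{"casefold"},
#'   \code{"casefold+ws"}.
#' @return Character vector of keys; idempotent under every policy.
#' @export
surface_key <- function(surface, policy = c("exact", "casefold", "casefold+ws")) {
  policy <- match.arg(policy)
  switch(policy,
    "exact" = surface,
    "casefold" = tolower(surface),
    "casefold+ws" = gsub("[[:space:]]+", " ", trimws(tolower(surface)))
  )
}

# canonical single-string key for a gold concept set (sorted, "|"-joined);
# the empty set (NIL) maps to "".
gold_key <- function(concept_set) paste(sort(concept_set), collapse = "|")

#' Per-concept usage counts in a split
#'
#' For every concept that annotates at least one mention, the number of
#' annotating mention instances and the number of distinct surface forms
#' (per \code{surface_key}).  A multi-normalized mention increments every
#' concept of its gold set, so the instance counts sum to at least the
#' number of annotated mentions, with equality iff there is no
#' multi-normalization.
#'
#' @param split An \code{en_split}.
#' @param policy Surface comparison policy, see \code{\link{surface_key}}.
#' @return Data frame with columns \code{concept_id}, \code{instances},
#'   \code{distinct_surfaces}, sorted by \code{concept_id}.
#' @export
concept_usage_counts <- function(split, policy = "exact") {
  gold <- split$gold
  if (length(gold) == 0L) {
    return(data.frame(concept_id = character(), instances = integer(),
                      distinct_surfaces = integer()))
  }
  surf <- stats::setNames(split$mentions$surface, split$mentions$mention_id)
  pairs_concept <- character()
  pairs_key <- character()
  for (mid in names(gold)) {
    cs <- gold[[mid]]
    if (length(cs) == 0L) next # NIL mentions annotate no concept
    k <- surface_key(surf[[mid]], policy)
    pairs_concept <- c(pairs_concept, cs)
    pairs_key <- c(pairs_key, rep(k, length(cs)))
  }
  if (length(pairs_concept) == 0L) {
    return(data.frame(concept_id = character(), instances = integer(),
                      distinct_surfaces = integer()))
  }
  inst <- table(pairs_concept)
  dst <- tapply(pairs_key, pairs_concept, function(k) length(unique(k)))
  ids <- sort(names(inst))
  data.frame(concept_id = ids,
             instances = as.integer(inst[ids]),
             distinct_surfaces = as.integer(dst[ids]),
             row.names = NULL)
}

# gold sets of a split as a named list restricted to annotated mentions
split_gold <- function(split) split$gold

# union of concepts used by the gold sets of one or more splits
used_concepts <- function(...) {
  splits <- list(...)
  out <- character()
  for (s in splits) out <- union(out, unlist(s$gold, use.names = FALSE))
  out
}
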