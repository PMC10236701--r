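# Two-sieve baseline normalizer, most precise stage first:
#   1. dictionary + symbolic rules: exact match between stemmed lowercased
#      mentions and a lexicon of stemmed ontology labels augmented with
#      training mentions;
#   2. distributional + machine learning: a ridge linear projection from
#      averaged token embeddings of mentions to the embedding of their
#      concept's preferred label, with cosine nearest-label prediction.
# Mentions unmatched by stage 1 fall through to stage 2; mentions
# unpredictable by both get no prediction (scored 0 by the generalized
# accuracy).

#' Build the augmented matching lexicon
#'
#' Normalized label string -> concept map.  All ontology labels are
#' entered first; training mention surfaces are then added as extra labels
#' of their concept.  A training surface annotated by several concepts
#' goes to the concept annotating it most frequently (ties: smallest
#' concept id); a collision with an existing ontology entry keeps the
#' ontology entry.  Normalization uses \code{preproc} (default: lowercase,
#' punctuation removal, Porter stem, single-space join), which must match
#' the one used at prediction time.
#'
#' @param ontology An \code{en_ontology}.
#' @param train Optional training \code{en_split}.
#' @param preproc A \code{\link{preproc_config}}.
#' @return An object of class \code{en_lexicon}: data frame with columns
#'   \code{key}, \code{concept_id}, \code{provenance}, \code{freq}.
#' @export
build_augmented_lexicon <- function(ontology, train = NULL,
                                    preproc = baseline_preproc()) {
  if (length(ontology$concepts) == 0L) stop("empty ontology")
  lab_concept <- character(); lab_text <- character()
  for (con in ontology$concepts) {
    lab_concept <- c(lab_concept, rep(con$id, length(con$labels)))
    lab_text <- c(lab_text, con$labels)
  }
  keys <- apply_preproc(lab_text, preproc)
  keep <- nzchar(keys)
  df <- data.frame(key = keys[keep], concept_id = lab_concept[keep],
                   provenance = "ontology-label", freq = NA_integer_)
  # ontology-internal collisions: same normalized key for several concepts
  # -> keep the lexicographically smallest concept id (deterministic)
  df <- df[order(df$key, df$concept_id), , drop = FALSE]
  df <- df[!duplicated(df$key), , drop = FALSE]

  if (!is.null(train) && length(train$gold)) {
    surf <- stats::setNames(train$mentions$surface, train$mentions$mention_id)
    tk <- character(); tc <- character()
    for (mid in names(train$gold)) {
      cs <- intersect(train$gold[[mid]], names(ontology$concepts))
      if (length(cs) == 0L) next
      k <- apply_preproc(surf[[mid]], preproc)
      if (!nzchar(k)) next
      tk <- c(tk, rep(k, length(cs)))
      tc <- c(tc, cs)
    }
    if (length(tk)) {
      counts <- stats::aggregate(list(freq = rep(1L, length(tk))),
                                 by = list(key = tk, concept_id = tc), FUN = sum)
      # most frequent concept per surface key, ties by smallest concept id
      counts <- counts[order(counts$key, -counts$freq, counts$concept_id), ,
                       drop = FALSE]
      counts <- counts[!duplicated(counts$key), , drop = FALSE]
      counts <- counts[!(counts$key %in% df$key), , drop = FALSE] # ontology wins
      if (nrow(counts)) {
        counts$provenance <- "training-mention"
        df <- rbind(df, counts[, c("key", "concept_id", "provenance", "freq")])
      }
    }
  }
  df <- df[order(df$key), , drop = FALSE]
  rownames(df) <- NULL
  structure(list(entries = df, preproc = preproc), class = "en_lexicon")
}

#' @export
print.en_lexicon <- function(x, ...) {
  tab <- table(x$entries$provenance)
  cat("<en_lexicon>", nrow(x$entries), "entries (",
      paste(names(tab), as.integer(tab), collapse = ", "), ")\n")
  invisible(x)
}

#' Dictionary-stage prediction: exact match against the lexicon
#'
#' Lowercases/stems the surface with the lexicon's own preprocessing chain
#' and looks the result up.  At most one concept is returned (the lexicon
#' maps each key to a single concept).
#'
#' @param surface Mention surface string(s).
#' @param lexicon An \code{en_lexicon}.
#' @return Character vector of concept ids, \code{NA_character_} where no
#'   entry matches.
#' @export
exact_match_predict <- function(surface, lexicon) {
  stopifnot(inherits(lexicon, "en_lexicon"))
  keys <- apply_preproc(surface, lexicon$preproc)
  idx <- match(keys, lexicon$entries$key)
  out <- lexicon$entries$concept_id[idx]
  out[!nzchar(keys)] <- NA_character_
  out
}

# tokens used for embedding lookup: lowercased alnum tokens, no stemming
# (embedding vocabularies are built from raw text)
.embed_tokens <- function(x) lapply(en_tokenize(tolower(x)), unique)

#' Embed a mention surface
#'
#' Mean of the embeddings of the in-vocabulary tokens of the surface
#' (lowercased, punctuation-split; no stemming, embedding vocabularies are
#' unstemmed).  \code{NULL} when every token is out of vocabulary.
#'
#' @param surface Single surface string.
#' @param table An \code{en_embeddings}.
#' @return Numeric vector of length \code{table$dim}, or \code{NULL}.
#' @export
embed_mention <- function(surface, table) {
  toks <- .embed_tokens(surface)[[1]]
  hit <- table$vectors[match(toks, rownames(table$vectors)), , drop = FALSE]
  hit <- hit[stats::complete.cases(hit), , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  colMeans(hit)
}

#' Fit the mention-to-label embedding projection
#'
#' Ridge-regularized linear least squares: W minimizes
#' sum ||W' v(m) - v(label(c(m)))||^2 + lambda ||W||^2 over training pairs,
#' where v(m) is the averaged token embedding of the mention and the target
#' is the embedding of the preferred (first) label of its gold concept.
#' Multi-normalized mentions contribute one pair per gold concept; pairs
#' with an unembeddable side are skipped.  With \code{weak_supervision},
#' every (label, concept) couple of the ontology is added as a training
#' pair.
#'
#' @param train Training \code{en_split}.
#' @param ontology An \code{en_ontology}.
#' @param table An \code{en_embeddings}.
#' @param lambda Ridge penalty (default 1e-8: numerical stabilizer only).
#' @param weak_supervision Add ontology label/concept pairs (default off).
#' @return An object of class \code{en_projection} holding the d x d map.
#' @export
fit_projection <- function(train, ontology, table, lambda = 1e-8,
                           weak_supervision = FALSE) {
  d <- table$dim
  xs <- list(); ys <- list()
  pref_label_vec <- function(cid) {
    con <- ontology$concepts[[cid]]
    if (is.null(con)) return(NULL)
    embed_mention(con$labels[1L], table)
  }
  surf <- stats::setNames(train$mentions$surface, train$mentions$mention_id)
  for (mid in names(train$gold)) {
    mv <- embed_mention(surf[[mid]], table)
    if (is.null(mv)) next
    for (cid in train$gold[[mid]]) {
      lv <- pref_label_vec(cid)
      if (is.null(lv)) next
      xs[[length(xs) + 1L]] <- mv
      ys[[length(ys) + 1L]] <- lv
    }
  }
  if (weak_supervision) {
    for (con in ontology$concepts) {
      tgt <- pref_label_vec(con$id)
      if (is.null(tgt)) next
      for (lab in con$labels) {
        lv <- embed_mention(lab, table)
        if (is.null(lv)) next
        xs[[length(xs) + 1L]] <- lv
        ys[[length(ys) + 1L]] <- tgt
      }
    }
  }
  n <- length(xs)
  if (n == 0L) stop("no usable (mention, label) embedding pairs to fit on")
  if (n < d) {
    warning("fewer training pairs (", n, ") than embedding dimensions (", d,
            "); projection will be heavily regularized", call. = FALSE)
  }
  X <- do.call(rbind, xs)
  Y <- do.call(rbind, ys)
  W <- solve(crossprod(X) + diag(lambda, d), crossprod(X, Y))
  if (any(!is.finite(W))) stop("projection fit produced non-finite coefficients")
  structure(list(W = W, dim = d, lambda = lambda, n_pairs = n,
                 weak_supervision = weak_supervision),
            class = "en_projection")
}

#' @export
print.en_projection <- function(x, ...) {
  cat("<en_projection>", x$dim, "x", x$dim, "map fitted on", x$n_pairs,
      "pairs (lambda =", format(x$lambda), ")\n")
  invisible(x)
}

#' Project a mention embedding into label space
#' @param model An \code{en_projection}.
#' @param v Mention embedding vector.
#' @return Projected vector.
#' @export
project_mention <- function(model, v) as.numeric(v %*% model$W)

# label embedding index over a concept subset: matrix of label embeddings
# (unit-normalized) with aligned concept ids, ordered by (concept_id,
# label) so that which.max implements the lexicographic tie-break
label_index <- function(ontology, table, concept_subset = NULL) {
  ids <- if (is.null(concept_subset)) names(ontology$concepts) else concept_subset
  ids <- intersect(ids, names(ontology$concepts))
  if (length(ids) == 0L) stop("empty concept subset")
  rows <- list(); row_concept <- character(); row_label <- character()
  for (cid in sort(ids)) {
    con <- ontology$concepts[[cid]]
    for (lab in sort(con$labels)) {
      v <- embed_mention(lab, table)
      if (is.null(v)) next
      rows[[length(rows) + 1L]] <- v
      row_concept <- c(row_concept, cid)
      row_label <- c(row_label, lab)
    }
  }
  if (length(rows) == 0L) stop("no embeddable label in the concept subset")
  L <- do.call(rbind, rows)
  nrm <- sqrt(rowSums(L^2))
  nrm[nrm == 0] <- 1
  list(mat = L / nrm, concept = row_concept, label = row_label)
}

#' Distributional-stage prediction: cosine-nearest label
#'
#' Projects the mention embedding with the fitted map and returns the
#' concept owning the label whose embedding is cosine-nearest.  Ties are
#' broken by lexicographic (concept id, label) order.  The search can be
#' restricted to a concept subset (ontology subsetting ablations).
#'
#' @param surface Mention surface string.
#' @param model An \code{en_projection}.
#' @param ontology An \code{en_ontology}.
#' @param table An \code{en_embeddings}.
#' @param concept_subset Optional character vector of concept ids.
#' @param index Optional precomputed index from \code{label_index} (for
#'   repeated calls).
#' @return List with \code{concept_id} (or \code{NA} if unembeddable) and
#'   \code{score} (cosine similarity).
#' @export
nearest_label_predict <- function(surface, model, ontology, table,
                                  concept_subset = NULL, index = NULL) {
  if (is.null(index)) index <- label_index(ontology, table, concept_subset)
  v <- embed_mention(surface, table)
  if (is.null(v)) return(list(concept_id = NA_character_, score = NA_real_))
  p <- project_mention(model, v)
  np <- sqrt(sum(p^2))
  if (np == 0) return(list(concept_id = NA_character_, score = NA_real_))
  sims <- as.numeric(index$mat %*% (p / np))
  best <- which.max(sims) # first max = lexicographic (concept, label) tie-break
  list(concept_id = index$concept[best], score = sims[best])
}

#' Two-sieve baseline prediction over a split
#'
#' Stage 1 (dictionary exact match after stemming) is tried first; only
#' mentions it leaves unmatched are passed to stage 2 (embedding
#' projection + nearest label).  Mentions unpredictable by both stages get
#' no prediction.  One concept per predicted mention (p_i = 1).
#'
#' @param split An \code{en_split} to predict on.
#' @param lexicon An \code{en_lexicon} (stage 1).
#' @param model Optional \code{en_projection} (stage 2; NULL disables it).
#' @param ontology,table Required when \code{model} is given.
#' @param concept_subset Optional restriction of the candidate concepts for
#'   stage 2.
#' @return An \code{en_predictions}; attribute \code{"stage"} records per
#'   mention which sieve produced the prediction (\code{"dict"},
#'   \code{"embed"} or \code{"none"}).
#' @export
sieve_predict <- function(split, lexicon, model = NULL, ontology = NULL,
                          table = NULL, concept_subset = NULL) {
  m <- split$mentions
  dict <- exact_match_predict(m$surface, lexicon)
  stage <- ifelse(is.na(dict), "none", "dict")
  concept <- dict
  score <- ifelse(is.na(dict), NA_real_, 1)
  todo <- which(is.na(dict))
  if (!is.null(model) && length(todo)) {
    stopifnot(!is.null(ontology), !is.null(table))
    idx <- label_index(ontology, table, concept_subset)
    for (i in todo) {
      hit <- nearest_label_predict(m$surface[i], model, ontology, table,
                                   index = idx)
      if (!is.na(hit$concept_id)) {
        concept[i] <- hit$concept_id
        score[i] <- hit$score
        stage[i] <- "embed"
      }
    }
  }
  keep <- !is.na(concept)
  preds <- en_predictions(data.frame(mention_id = m$mention_id[keep],
                                     concept_id = concept[keep],
                                     score = score[keep]))
  attr(preds, "stage") <- stats::setNames(stage, m$mention_id)
  preds
}
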