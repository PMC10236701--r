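# Shared fixtures and independent brute-force oracles.  The oracles
# deliberately use naive all-pairs loops and literal formula translations:
# they must stay independent of the package code paths they check.

# quick split builder: surfaces is a character vector, gold a list of
# concept-id vectors aligned with it (NULL entries = unannotated)
make_split <- function(surfaces, gold, name = "s", composite = NULL) {
  k <- length(surfaces)
  mid <- sprintf("d%03d#T%d", 1L + (seq_len(k) - 1L) %/% 10L,
                 1L + (seq_len(k) - 1L) %% 10L)
  if (is.null(composite)) composite <- rep(FALSE, k)
  m <- data.frame(mention_id = mid, doc_id = sub("#.*", "", mid),
                  surface = surfaces, entity_type = "X",
                  composite = composite)
  g <- stats::setNames(gold, mid)
  g <- g[!vapply(g, is.null, logical(1))]
  en_split(name, m, g)
}

# simple predictions builder: named list mention_id -> concept vector
make_preds <- function(lst) {
  rows <- do.call(rbind, lapply(names(lst), function(mid) {
    p <- lst[[mid]]
    if (length(p) == 0L) return(NULL)
    data.frame(mention_id = mid, concept_id = p,
               score = seq(1, by = -0.001, length.out = length(p)))
  }))
  if (is.null(rows)) return(en_predictions())
  en_predictions(rows)
}

oracle_key <- function(x, policy) {
  if (policy == "exact") x
  else if (policy == "casefold") tolower(x)
  else gsub("[[:space:]]+", " ", trimws(tolower(x)))
}

oracle_instances <- function(splits, policy = "exact") {
  if (inherits(splits, "en_split")) splits <- list(splits)
  out <- list()
  for (s in splits) {
    surf <- stats::setNames(s$mentions$surface, s$mentions$mention_id)
    for (mid in names(s$gold)) {
      out[[length(out) + 1L]] <- list(surface = oracle_key(surf[[mid]], policy),
                                      gold = sort(s$gold[[mid]]))
    }
  }
  out
}

oracle_multinorm <- function(splits) {
  inst <- oracle_instances(splits)
  100 * sum(vapply(inst, function(x) length(x$gold) >= 2, logical(1))) / length(inst)
}

oracle_nil <- function(splits) {
  inst <- oracle_instances(splits)
  100 * sum(vapply(inst, function(x) length(x$gold) == 0, logical(1))) / length(inst)
}

oracle_ambiguity <- function(splits, policy = "exact") {
  inst <- oracle_instances(splits, policy)
  n_amb <- 0L
  for (i in seq_along(inst)) {
    for (j in seq_along(inst)) {
      if (i == j) next
      if (inst[[i]]$surface == inst[[j]]$surface &&
          !identical(inst[[i]]$gold, inst[[j]]$gold)) {
        n_amb <- n_amb + 1L
        break
      }
    }
  }
  100 * n_amb / length(inst)
}

oracle_redundancy <- function(train, test, policy = "exact") {
  tr <- oracle_instances(train, policy)
  te <- oracle_instances(test, policy)
  hit <- 0L
  for (x in te) {
    for (y in tr) {
      if (x$surface == y$surface && identical(x$gold, y$gold)) {
        hit <- hit + 1L
        break
      }
    }
  }
  100 * hit / length(te)
}

oracle_zsl <- function(train, test) {
  ctr <- unique(unlist(lapply(oracle_instances(train), `[[`, "gold")))
  cte <- unique(unlist(lapply(oracle_instances(test), `[[`, "gold")))
  100 * length(setdiff(cte, ctr)) / length(cte)
}

oracle_usage <- function(split, policy = "exact") {
  surf <- stats::setNames(split$mentions$surface, split$mentions$mention_id)
  inst <- list(); keys <- list()
  for (mid in names(split$gold)) {
    for (cid in split$gold[[mid]]) {
      inst[[cid]] <- c(inst[[cid]], 1L)
      keys[[cid]] <- c(keys[[cid]], oracle_key(surf[[mid]], policy))
    }
  }
  data.frame(concept_id = sort(names(inst)),
             instances = vapply(sort(names(inst)), function(c) sum(inst[[c]]), integer(1)),
             distinct_surfaces = vapply(sort(names(inst)),
                                        function(c) length(unique(keys[[c]])), integer(1)),
             row.names = NULL)
}

# literal translations of the four accuracy formulas
oracle_eq3 <- function(gold, preds) {
  vals <- vapply(names(gold), function(mid) {
    p <- preds[[mid]]
    if (is.null(p)) p <- character()
    sum(p %in% gold[[mid]]) / length(gold[[mid]])
  }, numeric(1))
  mean(pmin(1, vals))
}

oracle_eq4 <- function(gold, preds) {
  vals <- vapply(names(gold), function(mid) {
    p <- preds[[mid]]
    if (is.null(p)) p <- character()
    den <- max(length(gold[[mid]]), length(p))
    if (den == 0) 0 else sum(p %in% gold[[mid]]) / den
  }, numeric(1))
  mean(vals)
}

oracle_lenient <- function(gold, preds, composite = NULL) {
  vals <- vapply(names(gold), function(mid) {
    p <- preds[[mid]]
    if (is.null(p)) p <- character()
    g <- gold[[mid]]
    if (length(g) >= 2 && !isTRUE(composite[[mid]])) {
      as.numeric(any(p %in% g))
    } else {
      den <- max(length(g), length(p))
      if (den == 0) 0 else sum(p %in% g) / den
    }
  }, numeric(1))
  mean(vals)
}

# random evaluation problem: gold sets + ranked predictions over a small
# concept universe; exercised by the property/acceptance suites
random_problem <- function(n_mentions = 10, n_concepts = 8, max_gold = 3,
                           max_pred = 4, single_pred = FALSE) {
  universe <- sprintf("C%02d", seq_len(n_concepts))
  mids <- sprintf("m%03d", seq_len(n_mentions))
  gold <- lapply(mids, function(m) {
    sample(universe, sample.int(max_gold, 1))
  })
  names(gold) <- mids
  preds <- lapply(mids, function(m) {
    k <- if (single_pred) 1L else sample.int(max_pred + 1L, 1) - 1L
    if (k == 0L) character() else sample(universe, k)
  })
  names(preds) <- mids
  list(gold = gold, preds = preds, universe = universe)
}
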