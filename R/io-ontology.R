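# Ontology readers: OBO 1.2 term stanzas (OntoBiotope-style) and the CTD
# MEDIC tab-separated dump (MeSH + OMIM disease vocabulary).

#' Read an OBO 1.2 ontology
#'
#' One concept per \code{[Term]} stanza: \code{name} becomes the preferred
#' (first) label, synonyms of the requested scopes are appended,
#' \code{is_a} targets become parents.  Obsolete terms are excluded.  The
#' result can be restricted to the sub-hierarchy under a root id (the term
#' itself plus all its descendants), which is how the habitat part of a
#' mixed ontology is extracted.
#'
#' @param path OBO file.
#' @param root Optional concept id; keep only this term and its descendants.
#' @param synonym_scopes Synonym scopes to keep as labels (default only
#'   \code{"EXACT"}; broad synonyms inflate the lexicon).
#' @return An \code{en_ontology}.
#' @export
read_obo_ontology <- function(path, root = NULL, synonym_scopes = "EXACT") {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  concepts <- list()
  cur <- NULL
  in_term <- FALSE
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id) || isTRUE(cur$obsolete)) return(NULL)
    if (is.null(cur$name)) cur$name <- cur$id
    en_concept(cur$id, c(cur$name, cur$synonyms), cur$parents)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "[Term]") {
      con <- flush(cur)
      if (!is.null(con)) concepts[[length(concepts) + 1L]] <- con
      cur <- list(synonyms = character(), parents = character(), obsolete = FALSE)
      in_term <- TRUE
      next
    }
    if (grepl("^\\[", ln)) { # other stanza type ([Typedef] ...)
      con <- flush(cur)
      if (!is.null(con)) concepts[[length(concepts) + 1L]] <- con
      cur <- NULL
      in_term <- FALSE
      next
    }
    if (!in_term || !nzchar(ln) || grepl("^!", ln)) next
    if (!grepl("^[a-z_]+:", ln)) {
      stop("malformed OBO line ", i, " in '", path, "': ", ln)
    }
    key <- sub(":.*$", "", ln)
    val <- trimws(sub("^[a-z_]+:", "", ln))
    val <- sub("\\s*!.*$", "", val) # trailing comment
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "is_obsolete" && val == "true") cur$obsolete <- TRUE
    else if (key == "is_a") cur$parents <- c(cur$parents, sub("\\s.*$", "", val))
    else if (key == "synonym") {
      m <- regmatches(val, regexec('^"(.*)"\\s*([A-Z_]*)', val))[[1]]
      if (length(m) >= 2L) {
        scope <- if (length(m) >= 3L && nzchar(m[3L])) m[3L] else "RELATED"
        if (scope %in% synonym_scopes) cur$synonyms <- c(cur$synonyms, m[2L])
      }
    }
  }
  con <- flush(cur)
  if (!is.null(con)) concepts[[length(concepts) + 1L]] <- con
  if (length(concepts) == 0L) stop("no terms found in '", path, "'")
  # drop parent links to obsolete/absent terms only if they are obsolete;
  # genuinely unresolvable targets are an error raised by en_ontology
  ids <- vapply(concepts, function(x) x$id, character(1))
  concepts <- lapply(concepts, function(x) {
    x$parents <- intersect(x$parents, ids)
    x
  })
  ont <- en_ontology(concepts, name = basename(path))
  if (!is.null(root)) ont <- restrict_to_root(ont, root)
  ont
}

#' Restrict an ontology to the descendants of a root concept
#'
#' Keeps the root and every concept reachable from it by following child
#' links; parent links leaving the kept set are dropped.
#'
#' @param ontology An \code{en_ontology}.
#' @param root Concept id present in the ontology.
#' @return An \code{en_ontology}.
#' @export
restrict_to_root <- function(ontology, root) {
  if (!root %in% names(ontology$concepts)) {
    stop("root concept '", root, "' not in ontology")
  }
  children <- list()
  for (con in ontology$concepts) {
    for (p in con$parents) children[[p]] <- c(children[[p]], con$id)
  }
  keep <- character()
  queue <- root
  while (length(queue)) {
    id <- queue[[1L]]; queue <- queue[-1L]
    if (id %in% keep) next
    keep <- c(keep, id)
    queue <- c(queue, children[[id]])
  }
  kept <- lapply(ontology$concepts[keep], function(con) {
    con$parents <- intersect(con$parents, keep)
    con
  })
  aliases <- ontology$aliases[ontology$aliases %in% keep]
  en_ontology(kept, name = ontology$name, version = ontology$version,
              aliases = aliases)
}

#' Write an ontology as OBO
#'
#' Minimal OBO 1.2 serialization (id, name, EXACT synonyms, is_a) used to
#' materialize synthetic ontologies; round-trips through
#' \code{\link{read_obo_ontology}}.
#'
#' @param ontology An \code{en_ontology}.
#' @param path Output file.
#' @export
write_obo_ontology <- function(ontology, path) {
  out <- c("format-version: 1.2",
           paste0("ontology: ", ontology$name), "")
  for (id in sort(names(ontology$concepts))) {
    con <- ontology$concepts[[id]]
    out <- c(out, "[Term]", paste0("id: ", con$id),
             paste0("name: ", con$labels[1L]))
    for (s in con$labels[-1L]) out <- c(out, sprintf("synonym: \"%s\" EXACT []", s))
    for (p in sort(con$parents)) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}

#' Read the CTD MEDIC disease vocabulary (TSV)
#'
#' Expects the CTD dump layout: comment header lines starting with
#' \code{#}, then tab-separated rows with columns DiseaseName, DiseaseID,
#' AltDiseaseIDs, Definition, ParentIDs, TreeNumbers, ParentTreeNumbers,
#' Synonyms (multi-values separated by \code{|}).  Alternative ids are
#' registered as aliases resolving to the primary concept; synonyms are
#' appended as labels.
#'
#' @param path MEDIC TSV file.
#' @return An \code{en_ontology} with \code{MESH:}/\code{OMIM:} ids.
#' @export
read_medic_tsv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("no data rows in '", path, "'")
  concepts <- list()
  aliases <- character()
  seen <- character()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) stop("malformed MEDIC row ", i, " in '", path, "'")
    pad <- function(k) if (length(f) >= k) f[k] else ""
    name <- f[1L]; id <- f[2L]
    if (id %in% seen) stop("duplicate primary id '", id, "' at MEDIC row ", i)
    seen <- c(seen, id)
    split_bar <- function(x) {
      if (!nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1]]
    }
    alt <- split_bar(pad(3L))
    parents <- split_bar(pad(5L))
    synonyms <- split_bar(pad(8L))
    concepts[[length(concepts) + 1L]] <- en_concept(id, c(name, synonyms), parents)
    if (length(alt)) aliases[alt] <- id
  }
  ids <- vapply(concepts, function(x) x$id, character(1))
  # parent ids referencing rows outside the dump (partial fixtures) are kept
  # only when resolvable; MEDIC proper is closed under ParentIDs
  concepts <- lapply(concepts, function(x) {
    x$parents <- intersect(x$parents, ids)
    x
  })
  aliases <- aliases[!(names(aliases) %in% ids)]
  en_ontology(concepts, name = "MEDIC", aliases = aliases)
}
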