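# Corpus readers/writers: BioNLP-ST standoff (.a1 entities + .a2
# normalizations next to .txt documents) and the PubTator abstract format.
# Mention ids are "<doc_id>#<entity_id>" so they stay unique corpus-wide
# while the original entity id remains recoverable for .a2 output.

.resolve_or_handle <- function(ontology, id, strict, where) {
  if (is.null(ontology)) return(id)
  rid <- resolve_concept_id(ontology, id)
  if (is.na(rid)) {
    msg <- paste0("concept id '", id, "' (", where, ") not in ontology")
    if (strict) stop(msg)
    warning(msg, "; annotation skipped", call. = FALSE)
    return(NA_character_)
  }
  rid
}

#' Read a BioNLP-ST standoff corpus
#'
#' Reads every \code{.a1} file in a directory together with its \code{.a2}
#' normalization file (when present).  Each entity line yields a mention
#' (discontinuous fragments: \code{;}-separated span list, fragment texts
#' joined by one space); each normalization line referencing the entity
#' adds its referent concept to the mention's gold set, so several lines
#' encode multi-normalization.  A kept mention with no referent line has an
#' empty gold set (NIL).
#'
#' @param dir Directory containing paired \code{.a1}/\code{.a2} files.
#' @param ontology Optional \code{en_ontology} used to resolve referent ids.
#' @param types Entity types to keep (default \code{"Habitat"}); \code{NULL}
#'   keeps all.
#' @param strict If TRUE (default) an unresolvable referent id is an error;
#'   otherwise a warning, and the referent is skipped.
#' @param name Split name.
#' @return An \code{en_split}.
#' @export
read_standoff_corpus <- function(dir, ontology = NULL, types = "Habitat",
                                 strict = TRUE, name = basename(dir)) {
  a1_files <- sort(list.files(dir, pattern = "\\.a1$", full.names = TRUE))
  if (length(a1_files) == 0L) stop("no .a1 files in '", dir, "'")
  rows <- list(); gold <- list(); spans <- list()
  for (a1 in a1_files) {
    doc_id <- sub("\\.a1$", "", basename(a1))
    kept_tids <- character()
    for (entry in .parse_a1(a1)) {
      if (!is.null(types) && !(entry$type %in% types)) next
      mid <- paste0(doc_id, "#", entry$tid)
      rows[[length(rows) + 1L]] <- data.frame(
        mention_id = mid, doc_id = doc_id, surface = entry$surface,
        entity_type = entry$type, composite = FALSE)
      spans[[mid]] <- entry$spans
      gold[[mid]] <- character()
      kept_tids <- c(kept_tids, entry$tid)
    }
    a2 <- file.path(dir, paste0(doc_id, ".a2"))
    if (file.exists(a2)) {
      for (norm in .parse_a2(a2)) {
        if (!(norm$tid %in% kept_tids)) next
        rid <- .resolve_or_handle(ontology, norm$referent, strict,
                                  paste0(basename(a2), " line ", norm$line))
        if (is.na(rid)) next
        mid <- paste0(doc_id, "#", norm$tid)
        gold[[mid]] <- union(gold[[mid]], rid)
      }
    }
  }
  if (length(rows) == 0L) stop("no mentions of type(s) ",
                               paste(types, collapse = "/"), " in '", dir, "'")
  en_split(name, do.call(rbind, rows), gold, spans)
}

.parse_a1 <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (!grepl("^T", ln)) next # title/paragraph meta lines etc. use T too;
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stop("malformed .a1 line ", i, " in '", basename(path), "': ", ln)
    }
    tid <- f[1L]
    ann <- f[2L]
    type <- sub("\\s.*$", "", ann)
    span_str <- trimws(sub("^\\S+\\s*", "", ann))
    frags <- strsplit(span_str, ";", fixed = TRUE)[[1]]
    mat <- t(vapply(frags, function(fr) {
      se <- strsplit(trimws(fr), "\\s+")[[1]]
      if (length(se) != 2L || anyNA(suppressWarnings(as.integer(se)))) {
        stop("malformed span in .a1 line ", i, " of '", basename(path), "': ", ln)
      }
      as.integer(se)
    }, integer(2)))
    colnames(mat) <- c("start", "end")
    out[[length(out) + 1L]] <- list(tid = tid, type = type, spans = mat,
                                    surface = f[3L])
  }
  out
}

.parse_a2 <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || !grepl("^N", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2L) {
      stop("malformed .a2 line ", i, " in '", basename(path), "': ", ln)
    }
    parts <- strsplit(trimws(f[2L]), "\\s+")[[1]]
    tid <- NULL; ref <- NULL
    for (p in parts) {
      if (grepl("^Annotation:", p)) tid <- sub("^Annotation:", "", p)
      if (grepl("^Referent:", p)) ref <- sub("^Referent:", "", p)
    }
    if (is.null(tid) || is.null(ref)) {
      stop("malformed .a2 line ", i, " in '", basename(path), "': ", ln)
    }
    out[[length(out) + 1L]] <- list(tid = tid, referent = ref, line = i)
  }
  out
}

#' Read a PubTator-format corpus
#'
#' PubTator layout: \code{PMID|t|title} and \code{PMID|a|abstract} lines,
#' then one tab-separated line per mention (pmid, start, end, text, type,
#' concept field), documents separated by blank lines.  The concept field
#' is split on both \code{+} (composite mentions) and \code{|}
#' (alternatives) into a gold concept set: composite mentions are treated
#' as any other multi-normalization case, but flagged \code{composite} so
#' the lenient metric can score them differently.  Bare MeSH ids receive
#' the \code{MESH:} prefix before ontology lookup.
#'
#' @param path PubTator file.
#' @param ontology Optional \code{en_ontology} for id resolution.
#' @param strict Unresolvable concept id: error (TRUE) or warn + skip.
#' @param name Split name.
#' @return An \code{en_split}.
#' @export
read_pubtator_corpus <- function(path, ontology = NULL, strict = TRUE,
                                 name = sub("\\.[^.]*$", "", basename(path))) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  rows <- list(); gold <- list(); spans <- list()
  counter <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^[^\t]+\\|[ta]\\|", ln)) next # title/abstract lines
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      stop("malformed PubTator line ", i, " in '", basename(path), "': ", ln)
    }
    pmid <- f[1L]
    start <- suppressWarnings(as.integer(f[2L]))
    end <- suppressWarnings(as.integer(f[3L]))
    if (is.na(start) || is.na(end)) {
      stop("malformed offsets at PubTator line ", i, " in '", basename(path), "'")
    }
    k <- (counter[[pmid]] <- if (is.null(counter[[pmid]])) 1L else counter[[pmid]] + 1L)
    mid <- sprintf("%s#%d", pmid, k)
    concept_field <- f[6L]
    composite <- grepl("+", concept_field, fixed = TRUE)
    ids <- strsplit(concept_field, "[+|]")[[1]]
    ids <- trimws(ids)
    ids <- ids[nzchar(ids)]
    ids <- ids[!(ids %in% c("-1", "CONCEPT_LESS"))] # NIL markers
    ids <- vapply(ids, normalize_mesh_id, character(1), USE.NAMES = FALSE)
    resolved <- character()
    for (id in ids) {
      rid <- .resolve_or_handle(ontology, id, strict,
                                paste0(basename(path), " line ", i))
      if (!is.na(rid)) resolved <- union(resolved, rid)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      mention_id = mid, doc_id = pmid, surface = f[4L],
      entity_type = f[5L], composite = composite && length(resolved) >= 2L)
    spans[[mid]] <- matrix(c(start, end), nrow = 1L,
                           dimnames = list(NULL, c("start", "end")))
    gold[[mid]] <- resolved
  }
  if (length(rows) == 0L) stop("no mention lines in '", path, "'")
  en_split(name, do.call(rbind, rows), gold, spans)
}

#' Normalize a bare MeSH/OMIM identifier to prefixed form
#'
#' \code{"D001943"} becomes \code{"MESH:D001943"}; already-prefixed ids
#' (\code{MESH:}, \code{OMIM:}, ...) are returned unchanged.
#'
#' @param id Identifier string.
#' @return Prefixed identifier.
#' @export
normalize_mesh_id <- function(id) {
  if (grepl(":", id, fixed = TRUE)) id else paste0("MESH:", id)
}

#' Write predictions to disk
#'
#' \code{tsv}: columns doc_id, mention_id, surface, rank, concept_id,
#' score, ordered by document then mention id then rank — deterministic, so
#' two identical runs are byte-identical.  \code{a2}: one normalization
#' line per predicted concept referencing the original entity id (the part
#' of the mention id after \code{#}), one file per document written into
#' \code{path} (a directory).
#'
#' @param preds An \code{en_predictions}.
#' @param split The \code{en_split} the predictions refer to (provides
#'   doc and surface information); unknown mention ids are an error.
#' @param path Output file (tsv) or directory (a2).
#' @param format \code{"tsv"} or \code{"a2"}.
#' @param resource Resource name written in a2 lines.
#' @return The path, invisibly.
#' @export
write_predictions <- function(preds, split, path, format = c("tsv", "a2"),
                              resource = "OntoBiotope") {
  format <- match.arg(format)
  stopifnot(inherits(preds, "en_predictions"), inherits(split, "en_split"))
  df <- preds$df
  unknown <- setdiff(unique(df$mention_id), split$mentions$mention_id)
  if (length(unknown)) {
    stop("prediction(s) for unknown mention id(s): ",
         paste(unknown, collapse = ", "))
  }
  meta <- split$mentions
  idx <- match(df$mention_id, meta$mention_id)
  df$doc_id <- meta$doc_id[idx]
  df$surface <- meta$surface[idx]
  # rank = position within mention in original order
  df$rank <- stats::ave(seq_len(nrow(df)), df$mention_id,
                        FUN = seq_along)
  ord <- order(df$doc_id, df$mention_id, df$rank)
  df <- df[ord, , drop = FALSE]
  if (format == "tsv") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(c("doc_id\tmention_id\tsurface\trank\tconcept_id\tscore",
                 sprintf("%s\t%s\t%s\t%d\t%s\t%.10g",
                         df$doc_id, df$mention_id, df$surface,
                         df$rank, df$concept_id, df$score)),
               con, sep = "\n", useBytes = TRUE)
    return(invisible(path))
  }
  # a2: one file per document
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  for (doc in unique(split$mentions$doc_id)) {
    sub <- df[df$doc_id == doc, , drop = FALSE]
    tids <- sub("^.*#", "", sub$mention_id)
    lines <- sprintf("N%d\t%s Annotation:%s Referent:%s",
                     seq_len(nrow(sub)), resource, tids, sub$concept_id)
    con <- file(file.path(path, paste0(doc, ".a2")), open = "wb")
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
  }
  invisible(path)
}

#' Read predictions written by \code{write_predictions(..., format = "tsv")}
#'
#' @param path TSV file.
#' @return An \code{en_predictions}.
#' @export
read_predictions_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(score = "numeric"))
  need <- c("mention_id", "concept_id", "score")
  if (!all(need %in% names(df))) stop("not a prediction tsv: '", path, "'")
  df <- df[order(df$doc_id, df$mention_id, df$rank), , drop = FALSE]
  en_predictions(df[, need])
}

#' Write a split as a BioNLP-ST standoff corpus
#'
#' Materializes synthetic corpora: one \code{.txt} document (mention
#' surfaces joined by single spaces), one \code{.a1} with the entity lines
#' and one \code{.a2} with the gold normalization lines per document.
#' Round-trips through \code{\link{read_standoff_corpus}}.
#'
#' @param split An \code{en_split}.
#' @param dir Output directory (created if needed).
#' @param resource Resource name for a2 lines.
#' @return \code{dir}, invisibly.
#' @export
write_standoff_corpus <- function(split, dir, resource = "OntoBiotope") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  m <- split$mentions
  for (doc in unique(m$doc_id)) {
    sub <- m[m$doc_id == doc, , drop = FALSE]
    text <- ""
    a1 <- character(); a2 <- character()
    n_norm <- 0L
    for (r in seq_len(nrow(sub))) {
      start <- nchar(text, type = "bytes")
      if (r > 1L) { text <- paste0(text, " "); start <- start + 1L }
      surf <- sub$surface[r]
      text <- paste0(text, surf)
      end <- start + nchar(surf, type = "bytes")
      tid <- sub("^.*#", "", sub$mention_id[r])
      a1 <- c(a1, sprintf("%s\t%s %d %d\t%s", tid, sub$entity_type[r],
                          start, end, surf))
      for (cid in sort(split$gold[[sub$mention_id[r]]])) {
        n_norm <- n_norm + 1L
        a2 <- c(a2, sprintf("N%d\t%s Annotation:%s Referent:%s",
                            n_norm, resource, tid, cid))
      }
    }
    writeLines(text, file.path(dir, paste0(doc, ".txt")), useBytes = TRUE)
    writeLines(a1, file.path(dir, paste0(doc, ".a1")), useBytes = TRUE)
    writeLines(a2, file.path(dir, paste0(doc, ".a2")), useBytes = TRUE)
  }
  invisible(dir)
}
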