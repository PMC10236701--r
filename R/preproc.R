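# Generic, order-fixed preprocessing used by the baseline lexicon and by
# the ablation harness.  Domain-specific transforms (acronym resolution,
# typo lists, composite-mention splitting) are deliberately NOT
# implemented here: they are pluggable named hooks, so their contribution
# can be isolated in ablations instead of being silently baked in.

.hook_registry <- new.env(parent = emptyenv())

#' Register a named preprocessing hook
#'
#' Hooks are external text transforms (character vector -> character
#' vector) applied before the generic flags, in the order listed in the
#' configuration.
#'
#' @param name Hook name.
#' @param fun Function taking and returning a character vector.
#' @export
register_preproc_hook <- function(name, fun) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fun))
  assign(name, fun, envir = .hook_registry)
  invisible(name)
}

#' Preprocessing configuration
#'
#' Flags for the generic normalization chain.  Transforms are applied in a
#' fixed, documented order: hooks, lowercasing, punctuation removal,
#' stopword removal, stemming or lemmatization, whitespace collapse.
#' Stemming and lemmatization are mutually exclusive.
#'
#' @param lowercase,punctuation_removal,stemming,lemmatization,stopword_removal
#'   Logical flags.
#' @param hooks Character vector of registered hook names, applied first in
#'   the given order.
#' @param stopwords Character vector; defaults to the packaged English list.
#' @return An object of class \code{preproc_config}.
#' @export
preproc_config <- function(lowercase = FALSE, punctuation_removal = FALSE,
                           stemming = FALSE, lemmatization = FALSE,
                           stopword_removal = FALSE, hooks = character(),
                           stopwords = NULL) {
  if (stemming && lemmatization) {
    stop("stemming and lemmatization are mutually exclusive")
  }
  if (is.null(stopwords)) stopwords <- en_stopwords()
  structure(
    list(lowercase = lowercase, punctuation_removal = punctuation_removal,
         stemming = stemming, lemmatization = lemmatization,
         stopword_removal = stopword_removal, hooks = hooks,
         stopwords = stopwords),
    class = "preproc_config"
  )
}

#' Packaged English stopword list
#' @return Character vector of lower-case stopwords.
#' @export
en_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "normaudit")
  if (!nzchar(path)) stop("packaged stopword list not found")
  readLines(path, encoding = "UTF-8", warn = FALSE)
}

# naive rule-based English lemmatizer: plural and inflection suffixes only.
# Deliberately lightweight -- documented as an approximation; serious
# lemmatization should be plugged in as a hook.
.naive_lemma <- function(tokens) {
  vapply(tokens, function(t) {
    if (!grepl("^[a-z]+$", t)) return(t)
    if (grepl("ies$", t) && nchar(t) > 4L) return(sub("ies$", "y", t))
    if (grepl("(ss|us|is)$", t)) return(t)
    if (grepl("(ches|shes|xes|zes|ses)$", t)) return(sub("es$", "", t))
    if (grepl("s$", t) && nchar(t) > 3L) return(sub("s$", "", t))
    t
  }, character(1), USE.NAMES = FALSE)
}

#' Apply a preprocessing configuration to strings
#'
#' Deterministic, order-fixed transform chain: hooks, lowercase,
#' punctuation removal (punctuation replaced by a space), stopword removal,
#' stemming or lemmatization, then whitespace collapse when any token-level
#' transform ran.  With all flags off and no hooks this is the identity.
#'
#' @param x Character vector.
#' @param config A \code{\link{preproc_config}}.
#' @return Character vector of transformed strings.
#' @export
apply_preproc <- function(x, config = preproc_config()) {
  stopifnot(inherits(config, "preproc_config"))
  for (h in config$hooks) {
    if (!exists(h, envir = .hook_registry, inherits = FALSE)) {
      stop("unknown preprocessing hook: '", h, "'")
    }
    x <- get(h, envir = .hook_registry)(x)
  }
  tokenized <- FALSE
  if (config$lowercase) x <- tolower(x)
  if (config$punctuation_removal) {
    x <- gsub("[[:punct:]]+", " ", x)
    tokenized <- TRUE
  }
  if (config$stopword_removal || config$stemming || config$lemmatization) {
    toks <- en_tokenize(x)
    toks <- lapply(toks, function(t) {
      if (config$stopword_removal) t <- t[!(tolower(t) %in% config$stopwords)]
      if (config$stemming) t <- porter_stem(t)
      if (config$lemmatization) t <- .naive_lemma(tolower(t))
      t
    })
    x <- vapply(toks, paste, character(1), collapse = " ")
    tokenized <- TRUE
  }
  if (tokenized) x <- gsub("[[:space:]]+", " ", trimws(x))
  x
}

# The baseline's label/mention normalization: lowercase + Porter stem each
# token, joined by single spaces.  Single point of truth so the lexicon and
# the matcher can never disagree.
baseline_preproc <- function() {
  preproc_config(lowercase = TRUE, punctuation_removal = TRUE, stemming = TRUE)
}
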