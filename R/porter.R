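# Porter suffix-stripping stemmer (original 1980 rule set, no later
# departures).  The exact stemmer identity matters: the dictionary stage of
# the baseline matches stemmed mentions against stemmed labels, so a
# different stemmer changes its predictions.  Checked against an external
# reference implementation in the test suite.

.porter_one <- function(word) {
  b <- strsplit(word, "", fixed = TRUE)[[1]]
  k <- length(b)
  if (k <= 2L) return(word)
  j <- 0L

  cons <- function(i) {
    ch <- b[i]
    if (ch %in% c("a", "e", "i", "o", "u")) return(FALSE)
    if (ch == "y") {
      if (i == 1L) TRUE else !cons(i - 1L)
    } else TRUE
  }
  # number of VC sequences in b[1..j]
  m <- function() {
    n <- 0L; i <- 1L
    repeat { if (i > j) return(n); if (!cons(i)) break; i <- i + 1L }
    i <- i + 1L
    repeat {
      repeat { if (i > j) return(n); if (cons(i)) break; i <- i + 1L }
      i <- i + 1L; n <- n + 1L
      repeat { if (i > j) return(n); if (!cons(i)) break; i <- i + 1L }
      i <- i + 1L
    }
  }
  vowelinstem <- function() {
    for (i in seq_len(j)) if (!cons(i)) return(TRUE)
    FALSE
  }
  doublec <- function(jj) {
    if (jj < 2L) return(FALSE)
    if (b[jj] != b[jj - 1L]) return(FALSE)
    cons(jj)
  }
  cvc <- function(ii) {
    if (ii < 3L || !cons(ii) || cons(ii - 1L) || !cons(ii - 2L)) return(FALSE)
    !(b[ii] %in% c("w", "x", "y"))
  }
  ends <- function(s) {
    sc <- strsplit(s, "", fixed = TRUE)[[1]]
    sl <- length(sc)
    if (sl > k) return(FALSE)
    if (!all(b[(k - sl + 1L):k] == sc)) return(FALSE)
    j <<- k - sl
    TRUE
  }
  setto <- function(s) {
    sc <- if (nzchar(s)) strsplit(s, "", fixed = TRUE)[[1]] else character(0)
    b <<- c(b[seq_len(j)], sc)
    k <<- j + length(sc)
  }
  r <- function(s) if (m() > 0L) setto(s)

  # step 1a/1b: plurals, -ed, -ing
  if (b[k] == "s") {
    if (ends("sses")) k <- k - 2L
    else if (ends("ies")) setto("i")
    else if (b[k - 1L] != "s") k <- k - 1L
  }
  if (ends("eed")) {
    if (m() > 0L) k <- k - 1L
  } else if ((ends("ed") || ends("ing")) && vowelinstem()) {
    k <- j
    if (ends("at")) setto("ate")
    else if (ends("bl")) setto("ble")
    else if (ends("iz")) setto("ize")
    else if (doublec(k)) {
      k <- k - 1L
      if (b[k] %in% c("l", "s", "z")) k <- k + 1L
    } else if (m() == 1L && cvc(k)) setto("e")
  }
  # step 1c: y -> i when the stem has a vowel
  if (k > 0L && b[k] == "y" && { j <- k - 1L; vowelinstem() }) b[k] <- "i"

  # step 2: double suffixes
  if (k > 1L) switch(b[k - 1L],
    "a" = { if (ends("ational")) r("ate")
            else if (ends("tional")) r("tion") },
    "c" = { if (ends("enci")) r("ence")
            else if (ends("anci")) r("ance") },
    "e" = { if (ends("izer")) r("ize") },
    "l" = { if (ends("abli")) r("able")
            else if (ends("alli")) r("al")
            else if (ends("entli")) r("ent")
            else if (ends("eli")) r("e")
            else if (ends("ousli")) r("ous") },
    "o" = { if (ends("ization")) r("ize")
            else if (ends("ation")) r("ate")
            else if (ends("ator")) r("ate") },
    "s" = { if (ends("alism")) r("al")
            else if (ends("iveness")) r("ive")
            else if (ends("fulness")) r("ful")
            else if (ends("ousness")) r("ous") },
    "t" = { if (ends("aliti")) r("al")
            else if (ends("iviti")) r("ive")
            else if (ends("biliti")) r("ble") }
  )
  # step 3
  if (k > 0L) switch(b[k],
    "e" = { if (ends("icate")) r("ic")
            else if (ends("ative")) r("")
            else if (ends("alize")) r("al") },
    "i" = { if (ends("iciti")) r("ic") },
    "l" = { if (ends("ical")) r("ic")
            else if (ends("ful")) r("") },
    "s" = { if (ends("ness")) r("") }
  )
  # step 4: -ant, -ence etc. when m > 1
  if (k > 1L) {
    hit <- switch(b[k - 1L],
      "a" = ends("al"),
      "c" = ends("ance") || ends("ence"),
      "e" = ends("er"),
      "i" = ends("ic"),
      "l" = ends("able") || ends("ible"),
      "n" = ends("ant") || ends("ement") || ends("ment") || ends("ent"),
      "o" = (ends("ion") && j >= 1L && b[j] %in% c("s", "t")) || ends("ou"),
      "s" = ends("ism"),
      "t" = ends("ate") || ends("iti"),
      "u" = ends("ous"),
      "v" = ends("ive"),
      "z" = ends("ize"),
      FALSE
    )
    if (isTRUE(hit) && m() > 1L) k <- j
  }
  # step 5a: drop final e
  j <- k
  if (b[k] == "e") {
    a <- m()
    if (a > 1L || (a == 1L && !cvc(k - 1L))) k <- k - 1L
  }
  # step 5b: -ll -> -l when m > 1
  j <- k
  if (b[k] == "l" && doublec(k) && m() > 1L) k <- k - 1L

  paste(b[seq_len(k)], collapse = "")
}

#' Porter stemmer
#'
#' Vectorized original Porter suffix stripper.  Input is lower-cased before
#' stemming; non-alphabetic tokens are returned unchanged apart from the
#' lower-casing.
#'
#' @param words Character vector of single tokens.
#' @return Character vector of stems.
#' @export
porter_stem <- function(words) {
  words <- tolower(words)
  vapply(words, function(w) {
    if (grepl("^[a-z]+$", w)) .porter_one(w) else w
  }, character(1), USE.NAMES = FALSE)
}

#' Tokenize a surface string
#'
#' Splits on whitespace and punctuation; punctuation characters are
#' dropped, digits and letters are kept.  This is the tokenizer used by the
#' baseline for both lexicon keys and embedding lookup.
#'
#' @param x Character vector.
#' @return List of character vectors (one per input string).
#' @export
en_tokenize <- function(x) {
  out <- strsplit(x, "[^[:alnum:]]+")
  lapply(out, function(t) t[nzchar(t)])
}
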