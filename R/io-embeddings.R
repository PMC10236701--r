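# word2vec-format embedding tables.  Internally a numeric matrix with one
# row per token; lookup is exact-token (no fuzzy fallback -- out-of-vocab
# tokens are the caller's problem and are reported as such).

#' Construct an embedding table
#'
#' @param mat Numeric matrix, one row per token; rownames are the tokens.
#' @return An object of class \code{en_embeddings}.
#' @export
en_embeddings <- function(mat) {
  stopifnot(is.matrix(mat), is.numeric(mat))
  if (ncol(mat) < 1L) stop("embedding dimension must be >= 1")
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat))) {
    stop("embedding matrix needs unique token rownames")
  }
  if (any(!is.finite(mat))) stop("embedding components must be finite")
  structure(list(vectors = mat, dim = ncol(mat)), class = "en_embeddings")
}

#' @export
print.en_embeddings <- function(x, ...) {
  cat("<en_embeddings>", nrow(x$vectors), "tokens, dimension", x$dim, "\n")
  invisible(x)
}

#' Look up a token vector
#'
#' @param table An \code{en_embeddings}.
#' @param token Single token.
#' @return Numeric vector, or \code{NULL} when the token is out of
#'   vocabulary (an explicit "not found", not an error).
#' @export
embedding_lookup <- function(table, token) {
  i <- match(token, rownames(table$vectors))
  if (is.na(i)) NULL else table$vectors[i, ]
}

#' Read a word2vec embedding file
#'
#' Both the text format (header line "vocab dim", then one token + values
#' line per entry) and the binary format (same header, then token bytes up
#' to a space followed by little-endian float32 values).  The table
#' contains exactly the declared vocabulary; a truncated file or a
#' dimension mismatch is an error.
#'
#' @param path Input file.
#' @param format \code{"word2vec-text"} or \code{"word2vec-binary"}.
#' @return An \code{en_embeddings}.
#' @export
read_embeddings <- function(path, format = c("word2vec-text", "word2vec-binary")) {
  format <- match.arg(format)
  if (format == "word2vec-text") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1]]))
    if (length(hdr) != 2L || anyNA(hdr)) stop("bad word2vec header in '", path, "'")
    v <- hdr[1L]; d <- hdr[2L]
    if (length(lines) - 1L < v) stop("truncated embedding file '", path, "'")
    toks <- character(v)
    mat <- matrix(NA_real_, nrow = v, ncol = d)
    for (i in seq_len(v)) {
      f <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
      if (length(f) != d + 1L) {
        stop("dimension mismatch at entry ", i, " of '", path, "'")
      }
      toks[i] <- f[1L]
      mat[i, ] <- as.numeric(f[-1L])
    }
    rownames(mat) <- toks
    return(en_embeddings(mat))
  }
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr_chars <- character()
  repeat {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("truncated embedding file '", path, "'")
    if (ch == "\n") break
    hdr_chars <- c(hdr_chars, ch)
  }
  hdr <- suppressWarnings(as.integer(strsplit(trimws(paste(hdr_chars, collapse = "")),
                                              "\\s+")[[1]]))
  if (length(hdr) != 2L || anyNA(hdr)) stop("bad word2vec header in '", path, "'")
  v <- hdr[1L]; d <- hdr[2L]
  toks <- character(v)
  mat <- matrix(NA_real_, nrow = v, ncol = d)
  for (i in seq_len(v)) {
    tok_chars <- character()
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      if (length(ch) == 0L) stop("truncated embedding file '", path, "'")
      if (ch == " ") break
      if (ch != "\n") tok_chars <- c(tok_chars, ch)
    }
    vec <- readBin(con, what = "numeric", n = d, size = 4L, endian = "little")
    if (length(vec) != d) stop("truncated embedding file '", path, "'")
    toks[i] <- paste(tok_chars, collapse = "")
    mat[i, ] <- vec
  }
  rownames(mat) <- toks
  en_embeddings(mat)
}

#' Write an embedding table in word2vec format
#'
#' Text output uses 17 significant digits so write-then-read round-trips
#' to identical doubles; binary output stores float32 (round-trips exactly
#' only for values representable in single precision).
#'
#' @param table An \code{en_embeddings}.
#' @param path Output file.
#' @param format \code{"word2vec-text"} or \code{"word2vec-binary"}.
#' @return \code{path}, invisibly.
#' @export
write_embeddings <- function(table, path,
                             format = c("word2vec-text", "word2vec-binary")) {
  format <- match.arg(format)
  mat <- table$vectors
  if (format == "word2vec-text") {
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(sprintf("%d %d", nrow(mat), ncol(mat)), con, useBytes = TRUE)
    body <- vapply(seq_len(nrow(mat)), function(i) {
      paste(rownames(mat)[i],
            paste(sprintf("%.17g", mat[i, ]), collapse = " "))
    }, character(1))
    writeLines(body, con, useBytes = TRUE)
    return(invisible(path))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeChar(sprintf("%d %d\n", nrow(mat), ncol(mat)), con, eos = NULL)
  for (i in seq_len(nrow(mat))) {
    writeChar(paste0(rownames(mat)[i], " "), con, eos = NULL)
    writeBin(as.numeric(mat[i, ]), con, size = 4L, endian = "little")
  }
  invisible(path)
}
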