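#' Normalize free text for dictionary matching
#'
#' Lower-cases, turns punctuation into spaces, and collapses whitespace.
#' Idempotent: `normalize_text(normalize_text(x)) == normalize_text(x)`.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

#' Build a term lexicon
#'
#' Maps surface terms to concept codes (many terms may share a code). Terms
#' are normalized with [normalize_text()]; a term mapping to two different
#' codes is an error — ambiguity must be resolved when the lexicon is built.
#'
#' @param terms Character vector of surface terms.
#' @param codes Character vector of concept codes, same length.
#' @return An object of class `lexicon`: a named character vector
#'   (normalized term -> code) with a `max_tokens` attribute.
#' @export
lexicon <- function(terms, codes) {
  stopifnot(length(terms) == length(codes))
  terms <- normalize_text(as.character(terms))
  codes <- as.character(codes)
  if (any(!nzchar(terms))) stop("lexicon term empty after normalization")
  dup <- duplicated(terms)
  if (any(dup)) {
    conflict <- tapply(codes, terms, function(v) length(unique(v)) > 1)
    if (any(conflict)) {
      stop("ambiguous lexicon: term(s) mapped to multiple codes: ",
           paste(names(conflict)[conflict], collapse = ", "))
    }
    terms <- terms[!dup]
    codes <- codes[!dup]
  }
  structure(stats::setNames(codes, terms),
            max_tokens = max(lengths(strsplit(terms, " ", fixed = TRUE))),
            class = "lexicon")
}

#' Read a lexicon from a two-column TSV (term, code)
#' @param path Path to the TSV file; `#`-prefixed lines are skipped.
#' @return A `lexicon`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  rows <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(rows, length, integer(1)) < 2
  if (any(bad)) stop("malformed lexicon row at line ", which(bad)[1])
  lexicon(vapply(rows, `[[`, "", 1), vapply(rows, `[[`, "", 2))
}

#' Write a lexicon as TSV
#' @param lex A `lexicon`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_lexicon <- function(lex, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c("#term\tcode", paste(names(lex), unname(lex), sep = "\t")),
             con, useBytes = TRUE)
  invisible(path)
}

# token table of the ORIGINAL text: word, 0-based start, 0-based half-open end
tokenize_offsets <- function(text) {
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1) {
    return(data.frame(token = character(), start = integer(), end = integer()))
  }
  len <- attr(m, "match.length")
  data.frame(token = tolower(regmatches(text, list(m))[[1]]),
             start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len,
             stringsAsFactors = FALSE)
}

#' Tag concept mentions in free text
#'
#' Deterministic, dictionary-based concept recognition: greedy left-to-right
#' longest match over normalized tokens, with matches anchored at token
#' boundaries (no hits inside words). Each character belongs to at most one
#' span. Offsets are 0-based, half-open.
#'
#' @param text A single string.
#' @param lex A `lexicon`.
#' @return data.frame with columns `start`, `end`, `code`, `surface`, in
#'   text order. Empty when nothing matches.
#' @export
tag_text <- function(text, lex) {
  stopifnot(inherits(lex, "lexicon"), length(lex) > 0, length(text) == 1)
  toks <- tokenize_offsets(text)
  n <- nrow(toks)
  out <- list()
  maxlen <- attr(lex, "max_tokens")
  i <- 1L
  while (i <= n) {
    hit <- 0L
    for (j in seq(min(n, i + maxlen - 1L), i)) {  # longest first
      key <- paste(toks$token[i:j], collapse = " ")
      if (!is.na(lex[key])) { hit <- j; break }
    }
    if (hit > 0L) {
      key <- paste(toks$token[i:hit], collapse = " ")
      out[[length(out) + 1L]] <- data.frame(
        start = toks$start[i], end = toks$end[hit],
        code = unname(lex[key]),
        surface = substr(text, toks$start[i] + 1L, toks$end[hit]),
        stringsAsFactors = FALSE)
      i <- hit + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(data.frame(start = integer(), end = integer(),
                      code = character(), surface = character()))
  }
  do.call(rbind, out)
}

#' Extract concept codes from text
#'
#' Distinct codes from [tag_text()], in order of first occurrence.
#'
#' @inheritParams tag_text
#' @return Character vector of concept codes (possibly empty).
#' @export
extract_codes <- function(text, lex) {
  unique(tag_text(text, lex)$code)
}
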