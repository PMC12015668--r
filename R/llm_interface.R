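#' Parse an asserted answer letter out of free text
#'
#' Scans the response for assertion cues in a fixed precedence order: an
#' explicit "answer ..." / "answer: ..." cue first, then the first
#' parenthesized letter "(A)" or "A)", then "option A", then a bare
#' standalone letter. Only letters in `letters_` count; anything else (or
#' no cue at all) is silence, returned as `NA`.
#'
#' @param response Free-text response string.
#' @param letters_ Character vector of valid choice letters.
#' @return A single letter, or `NA_character_` when no valid letter is
#'   asserted.
#' @export
parse_answer <- function(response, letters_) {
  stopifnot(length(letters_) > 0)
  if (is.null(response) || is.na(response) || !nzchar(response)) {
    return(NA_character_)
  }
  first_valid <- function(pattern) {
    m <- gregexpr(pattern, response, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1) return(NA_character_)
    for (s in regmatches(response, list(m))[[1]]) {
      letter <- toupper(gsub(pattern, "\\1", s, perl = TRUE, ignore.case = TRUE))
      if (letter %in% toupper(letters_)) {
        return(letters_[match(letter, toupper(letters_))])
      }
    }
    NA_character_
  }
  cues <- c(
    "\\banswer\\b(?:\\s+is)?\\s*[:]?\\s*[\"'(]?([A-Za-z])[\"').,]?(?![A-Za-z])",
    "\\(([A-Za-z])\\)",
    "(?<![A-Za-z(])([A-Za-z])\\)",
    "\\boption\\s+([A-Za-z])(?![A-Za-z])",
    "(?<![A-Za-z])([A-Z])(?![A-Za-z])")
  for (p in cues) {
    hit <- first_valid(p)
    if (!is.na(hit)) return(hit)
  }
  NA_character_
}

#' Construct an answer record
#' @param question_id Question identifier.
#' @param condition Condition label ("native" or "rag").
#' @param raw Raw backend response text.
#' @param letter Parsed choice letter or `NA`.
#' @param note Optional error/processing note.
#' @return A list of class `answer_record`; `correct` stays `NA` until scored.
#' @export
answer_record <- function(question_id, condition, raw, letter,
                          note = NA_character_) {
  structure(list(question_id = question_id, condition = condition,
                 raw = raw, letter = letter, correct = NA, silent = is.na(letter),
                 note = note),
            class = "answer_record")
}

#' Present one prompt to a backend
#'
#' A backend is any function of a prompt string returning a response string
#' (the whole contract). Unparseable output is recorded as silence, never an
#' error; a backend that throws (or times out) yields a record with a null
#' letter and an error note.
#'
#' @param backend A function `prompt -> response text`.
#' @param bundle A `prompt_bundle` from [build_prompt()].
#' @return An `answer_record`.
#' @export
ask <- function(backend, bundle) {
  letters_ <- names(bundle$question$choices)
  raw <- tryCatch(backend(bundle$prompt), error = function(e) e)
  if (inherits(raw, "error")) {
    return(answer_record(bundle$question$id, bundle$condition,
                         NA_character_, NA_character_,
                         note = paste("backend error:", conditionMessage(raw))))
  }
  answer_record(bundle$question$id, bundle$condition, raw,
                parse_answer(raw, letters_))
}

#' Present a batch of prompts to a backend
#' @param backend A backend function.
#' @param bundles List of `prompt_bundle`s.
#' @return List of `answer_record`s, order preserved (one per bundle).
#' @export
ask_all <- function(backend, bundles) {
  lapply(bundles, function(b) ask(backend, b))
}

#' Rule-based mock answer backend
#'
#' A deterministic-at-seed test double for a language model. Each question is
#' registered with its stem, its key sentence (the verbalized planted triple
#' that entails the answer), and its key letter. Given a prompt, the mock
#' locates the question by stem containment; if the prompt also contains the
#' key sentence the mock answers the key letter, always. Otherwise it guesses
#' a uniformly random letter with probability `propensity` (it does not know
#' the answer, so a guess is right only by chance) and stays silent with
#' probability `1 - propensity`. Unregistered questions get silence.
#'
#' @param knowledge data.frame (or list of lists) with columns `question_id`,
#'   `stem`, `key_sentence`, `key_letter`, `letters` (comma-separated or
#'   list of vectors).
#' @param propensity Probability of guessing when the key sentence is absent
#'   (the confabulation propensity c).
#' @param seed RNG seed for the mock's private stream.
#' @return A backend function (class `mock_backend`).
#' @export
rule_based_mock <- function(knowledge, propensity = 1, seed = 1) {
  stopifnot(propensity >= 0, propensity <= 1)
  if (is.data.frame(knowledge)) {
    knowledge <- lapply(seq_len(nrow(knowledge)), function(i) {
      k <- as.list(knowledge[i, , drop = FALSE])
      if (is.character(k$letters)) {
        k$letters <- strsplit(k$letters, ",", fixed = TRUE)[[1]]
      } else {
        k$letters <- unlist(k$letters)
      }
      k
    })
  }
  # per-question derived seed keeps the mock a pure function of the prompt
  hash_id <- function(id) {
    h <- 0
    for (v in utf8ToInt(id)) h <- (h * 131 + v) %% 2147480009
    as.integer((h + seed * 7919) %% 2147480009)
  }
  backend <- function(prompt) {
    hit <- NULL
    for (k in knowledge) {
      if (grepl(k$stem, prompt, fixed = TRUE)) { hit <- k; break }
    }
    if (is.null(hit)) return("I cannot determine the answer.")
    if (grepl(hit$key_sentence, prompt, fixed = TRUE)) {
      return(sprintf("Answer: (%s). The provided clinical knowledge states: %s",
                     hit$key_letter, hit$key_sentence))
    }
    guess <- local_seed(hash_id(hit$question_id), function() {
      if (stats::runif(1) < propensity) sample(hit$letters, 1L) else NA_character_
    })
    if (is.na(guess)) return("I cannot determine the answer.")
    sprintf("Answer: (%s).", guess)
  }
  class(backend) <- c("mock_backend", "function")
  backend
}

#' HTTP endpoint backend adapter
#'
#' Thin adapter around an external text-generation endpoint speaking a
#' minimal JSON contract (`{"prompt": ...}` in, `{"text": ...}` out). It is
#' provided for completeness behind the same backend contract as the mock
#' and is not exercised by the test suite (tests run model-free).
#'
#' @param url Endpoint URL.
#' @param timeout Seconds before giving up.
#' @return A backend function.
#' @export
http_backend <- function(url, timeout = 120) {
  force(url)
  function(prompt) {
    con <- base::url(url, open = "rb")
    on.exit(close(con))
    setTimeLimit(elapsed = timeout, transient = TRUE)
    on.exit(setTimeLimit(elapsed = Inf), add = TRUE)
    resp <- jsonlite::fromJSON(paste(readLines(con, warn = FALSE),
                                     collapse = "\n"))
    resp$text
  }
}

# run fn under a temporary RNG seed, restoring the caller's RNG state
local_seed <- function(seed, fn) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(seed)
  on.exit(if (has_old) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  fn()
}
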