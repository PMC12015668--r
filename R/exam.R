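#' Read a multiple-choice exam from JSON
#'
#' Schema: `{"questions": [{"id", "stem", "choices": {letter: text}, "meta":
#' {...}}], "key": {id: letter}}`. `meta` is free-form (the synthetic
#' generator stores the planted triple and key sentence there); questions
#' may carry `exclusion_reasons` for the curation rule engine.
#'
#' @param path Path to the exam JSON file.
#' @return List with `questions` (list of question lists) and `key` (named
#'   character vector).
#' @export
read_exam <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  questions <- lapply(x$questions, function(q) {
    q$choices <- unlist(q$choices)
    q
  })
  list(questions = questions, key = unlist(x$key))
}

#' Write an exam (questions + key) as JSON
#' @param questions List of question lists (`id`, `stem`, `choices`, ...).
#' @param key Named character vector, id -> key letter.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
write_exam <- function(questions, key, path) {
  payload <- list(
    questions = lapply(questions, function(q) {
      q$choices <- as.list(q$choices)
      q
    }),
    key = as.list(key))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

# reasons that make a question visual (image-dependent); anything else in an
# exclusion list is a nonvisual formatting exclusion
visual_exclusion_reasons <- c(
  "photograph", "graph", "photomicrograph",
  "multipart answer with directional arrows", "radiograph", "diagram",
  "ct scan", "mri", "doppler image", "bar graph", "ultrasonography",
  "cardiac rhythm strip", "fetal heart tracing", "hysterosalpingography",
  "stool smear", "family pedigree", "ecg component")

#' Classify an exclusion reason
#' @param reason Character vector of exclusion reason strings.
#' @return "visual" or "nonvisual" per element.
#' @export
exclusion_category <- function(reason) {
  ifelse(normalize_text(reason) %in% visual_exclusion_reasons,
         "visual", "nonvisual")
}

#' Curate an exam manifest
#'
#' Exam-ingest rule engine: questions carrying any exclusion reason (a visual
#' component such as a photograph or radiograph, or a nonvisual formatting
#' problem such as a multipart answer or complex table not conducive to a
#' text file) are dropped; the rest are kept for the study.
#'
#' @param questions List of question lists; each may have an
#'   `exclusion_reasons` character vector (absent or empty = keep).
#' @return List with `kept` (questions), `excluded` (questions), and
#'   `summary`: data.frame of reason, category, n over excluded questions.
#' @export
curate_exam <- function(questions) {
  reasons <- lapply(questions, function(q) {
    r <- q$exclusion_reasons
    if (is.null(r)) character() else unlist(r)
  })
  drop <- lengths(reasons) > 0
  tab <- if (any(drop)) {
    first <- vapply(reasons[drop], `[[`, "", 1)  # primary reason per question
    agg <- as.data.frame(table(first), stringsAsFactors = FALSE)
    names(agg) <- c("reason", "n")
    agg$category <- exclusion_category(agg$reason)
    agg[order(agg$category, -agg$n, agg$reason), c("reason", "category", "n")]
  } else {
    data.frame(reason = character(), category = character(), n = integer())
  }
  rownames(tab) <- NULL
  list(kept = questions[!drop], excluded = questions[drop], summary = tab)
}
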