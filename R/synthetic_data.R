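default_semantic_tags <- c("disorder", "finding", "procedure", "substance",
                           "organism", "body structure")

# pronounceable pseudoword labels: unique, non-English, safe for token-boundary
# dictionary tagging inside English question stems
make_labels <- function(n) {
  syl <- c("ka", "lo", "mi", "ra", "ne", "tu", "ve", "so", "pa", "di",
           "xu", "bel", "mor", "tan", "qui", "fen", "gal", "hep", "rin", "zol")
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    w1 <- vapply(seq_len(need), function(i)
      paste(sample(syl, sample(2:3, 1), replace = TRUE), collapse = ""),
      character(1))
    w2 <- vapply(seq_len(need), function(i)
      if (stats::runif(1) < 0.4)
        paste(sample(syl, 2, replace = TRUE), collapse = "") else "",
      character(1))
    lab <- trimws(paste(w1, w2))
    out <- unique(c(out, lab))
  }
  out[seq_len(n)]
}

#' Generate a random typed knowledge graph
#'
#' Samples `n_triples` distinct (subject, relation, object) triples over
#' `n_concepts` synthetic concepts. Relation counts follow `relation_mix`
#' exactly up to integer rounding (largest-remainder allocation), so the
#' realized frequencies are within 2% of the requested mix for any
#' non-trivial n; the default mix is proportional to the registry's corpus
#' frequency hints, under which "isa" is the most frequent relation.
#' Concepts get unique pseudoword labels and semantic tags.
#'
#' @param n_concepts Number of concepts (>= 2).
#' @param n_triples Number of distinct triples (0 allowed: concepts only).
#' @param relation_mix Named numeric vector of relation weights (normalized
#'   internally); default: registry `count_hint`s.
#' @param seed RNG seed.
#' @param registry Relation registry.
#' @param tags Semantic tag set to draw from.
#' @return A `knowledge_graph`.
#' @export
generate_kg <- function(n_concepts, n_triples, relation_mix = NULL, seed = 1,
                        registry = default_registry(),
                        tags = default_semantic_tags) {
  stopifnot(n_concepts >= 2, n_triples >= 0)
  if (is.null(relation_mix)) {
    relation_mix <- stats::setNames(registry$count_hint, registry$name)
    relation_mix[is.na(relation_mix)] <- 0
  }
  relation_mix <- relation_mix[relation_mix > 0]
  if (!length(relation_mix)) stop("empty relation mix")
  if (!all(names(relation_mix) %in% registry$name)) {
    stop("relation mix names must be registered relations")
  }
  if (n_triples > n_concepts * (n_concepts - 1) * length(relation_mix)) {
    stop("infeasible: more triples requested than distinct (s, r, o) exist")
  }
  set.seed(seed)
  concepts <- data.frame(
    code = sprintf("C%06d", seq_len(n_concepts)),
    label = make_labels(n_concepts),
    semantic_tag = sample(tags, n_concepts, replace = TRUE),
    stringsAsFactors = FALSE)
  if (n_triples == 0) {
    return(knowledge_graph(concepts = concepts, registry = registry))
  }

  # largest-remainder allocation keeps realized mix within rounding of target
  w <- relation_mix / sum(relation_mix)
  alloc <- floor(w * n_triples)
  rem <- n_triples - sum(alloc)
  if (rem > 0) {
    extra <- order(-(w * n_triples - alloc))[seq_len(rem)]
    alloc[extra] <- alloc[extra] + 1
  }
  alloc <- alloc[alloc > 0]

  parts <- lapply(names(alloc), function(r) {
    m <- alloc[[r]]
    s <- sample.int(n_concepts, m, replace = TRUE)
    o <- sample.int(n_concepts, m, replace = TRUE)
    for (iter in 1:100) {
      bad <- which(s == o | duplicated(paste(s, o)))
      if (!length(bad)) break
      s[bad] <- sample.int(n_concepts, length(bad), replace = TRUE)
      o[bad] <- sample.int(n_concepts, length(bad), replace = TRUE)
    }
    if (any(s == o | duplicated(paste(s, o)))) {
      stop("could not sample distinct triples for relation ", r)
    }
    data.frame(subject = concepts$code[s], relation = r,
               object = concepts$code[o], stringsAsFactors = FALSE)
  })
  triples <- do.call(rbind, parts)
  knowledge_graph(triples = triples, concepts = concepts, registry = registry)
}

#' Lexicon covering every concept label of a graph
#' @param g A `knowledge_graph`.
#' @return A `lexicon` mapping each label to its code.
#' @export
generate_lexicon <- function(g) {
  lexicon(g$concepts$label, g$concepts$code)
}

#' Generate an exam with planted answerable facts
#'
#' Each question is built from a distinct allow-listed (rag_use) triple: the
#' stem mentions the subject's label, the correct choice is the object's
#' label, and distractors are labels of concepts not adjacent to the subject
#' in the graph (so no graph fact entails them). The key letter position is
#' random. The verbalized planted triple is stored in `meta$key_sentence`.
#'
#' @param g A `knowledge_graph`.
#' @param n_questions Number of questions; needs at least this many distinct
#'   subjects with allow-listed triples.
#' @param n_choices Choices per question (letters A, B, ...).
#' @param seed RNG seed.
#' @return List with `questions` and `key` (named letter vector).
#' @export
generate_exam <- function(g, n_questions, n_choices = 5, seed = 1) {
  stopifnot(n_choices >= 2, n_questions >= 1)
  set.seed(seed)
  rag <- filter_by_relation(g$triples, g$registry)
  subjects <- unique(rag$subject)
  if (length(subjects) < n_questions) {
    stop(sprintf("graph has only %d subjects with allow-listed triples; %d needed",
                 length(subjects), n_questions))
  }
  picked_subj <- sample(subjects, n_questions)
  labels <- stats::setNames(g$concepts$label, g$concepts$code)
  letters_ <- LETTERS[seq_len(n_choices)]
  questions <- vector("list", n_questions)
  key <- character(n_questions)
  for (i in seq_len(n_questions)) {
    s <- picked_subj[i]
    cand <- rag[rag$subject == s, , drop = FALSE]
    tri <- cand[sample.int(nrow(cand), 1L), , drop = FALSE]
    adjacent <- unique(c(kg_neighbors(g, s)$subject, kg_neighbors(g, s)$object))
    pool <- setdiff(g$concepts$code, c(adjacent, s, tri$object))
    if (length(pool) < n_choices - 1) stop("not enough unrelated concepts for distractors")
    distract <- sample(pool, n_choices - 1)
    key_pos <- sample.int(n_choices, 1L)
    texts <- character(n_choices)
    texts[key_pos] <- labels[[tri$object]]
    texts[-key_pos] <- labels[distract]
    stem <- sprintf(paste0("A patient presents to the clinic. The record notes %s. ",
                           "Which of the following is most directly associated ",
                           "with this finding?"), labels[[s]])
    id <- sprintf("Q%04d", i)
    questions[[i]] <- list(
      id = id, stem = stem,
      choices = stats::setNames(as.list(texts), letters_),
      meta = list(subject = s, relation = tri$relation, object = tri$object,
                  key_sentence = verbalize_triple(tri, g$concepts)))
    key[i] <- letters_[key_pos]
  }
  names(key) <- vapply(questions, `[[`, "", "id")
  list(questions = questions, key = key)
}

#' Generate a complete synthetic world
#'
#' A reproducible end-to-end fixture: knowledge graph, lexicon over all
#' concept labels, exam with planted answerable facts, answer key, and the
#' mock backend's knowledge table. By construction, tagging a stem and
#' retrieving one adjacency hop through the allow-list recovers each
#' question's key sentence (at any k >= 0 and uncapped context).
#'
#' @param config Optional list overriding `n_concepts` (250), `n_triples`
#'   (900), `n_questions` (100), `n_choices` (5), `relation_mix` (registry
#'   frequencies).
#' @param seed RNG seed driving every generator.
#' @return An object of class `synthetic_world`: `graph`, `lexicon`,
#'   `questions`, `key`, `knowledge`, `config`, `seed`.
#' @export
make_world <- function(config = list(), seed = 1) {
  defaults <- list(n_concepts = 250, n_triples = 900, n_questions = 100,
                   n_choices = 5, relation_mix = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  g <- generate_kg(cfg$n_concepts, cfg$n_triples, cfg$relation_mix, seed = seed)
  lex <- generate_lexicon(g)
  exam <- generate_exam(g, cfg$n_questions, cfg$n_choices, seed = seed + 1)
  knowledge <- data.frame(
    question_id = vapply(exam$questions, `[[`, "", "id"),
    stem = vapply(exam$questions, `[[`, "", "stem"),
    key_sentence = vapply(exam$questions, function(q) q$meta$key_sentence, ""),
    key_letter = unname(exam$key),
    letters = vapply(exam$questions,
                     function(q) paste(names(q$choices), collapse = ","), ""),
    stringsAsFactors = FALSE)
  structure(list(graph = g, lexicon = lex, questions = exam$questions,
                 key = exam$key, knowledge = knowledge, config = cfg,
                 seed = seed),
            class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> seed=%d: %d concepts, %d triples, %d questions\n",
              x$seed, nrow(x$graph$concepts), nrow(x$graph$triples),
              length(x$questions)))
  invisible(x)
}

#' Generate an exam manifest with planted exclusions
#'
#' Builds question stubs for the curation rule engine: `n_questions` entries
#' of which randomly chosen ones carry the given exclusion reasons (named
#' vector reason -> count), e.g. photographs or complex tables. Used to
#' emulate the raw download of an exam before text-only curation.
#'
#' @param n_questions Total questions in the manifest.
#' @param exclusion_counts Named integer vector, exclusion reason -> number
#'   of questions carrying it.
#' @param seed RNG seed.
#' @return List of question stubs (`id`, `stem`, `exclusion_reasons`).
#' @export
generate_exam_manifest <- function(n_questions, exclusion_counts = integer(),
                                   seed = 1) {
  if (sum(exclusion_counts) > n_questions) stop("more exclusions than questions")
  set.seed(seed)
  reasons <- rep(names(exclusion_counts), exclusion_counts)
  slots <- sample.int(n_questions, length(reasons))
  qs <- lapply(seq_len(n_questions), function(i) {
    list(id = sprintf("M%04d", i),
         stem = sprintf("Manifest question %d.", i))
  })
  for (j in seq_along(reasons)) {
    qs[[slots[j]]]$exclusion_reasons <- reasons[j]
  }
  qs
}
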