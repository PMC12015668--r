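#' Retrieval configuration
#'
#' @param k Neighbors retrieved per seed code per embedding space during
#'   expansion (0 disables expansion).
#' @param cap Maximum number of context sentences (triples touching a seed
#'   code are kept in preference to neighbor-only triples).
#' @param template_id Prompt template identifier (currently "v1").
#' @return A list of class `rag_config`.
#' @export
rag_config <- function(k = 5, cap = 40, template_id = "v1") {
  stopifnot(k >= 0, cap >= 0)
  structure(list(k = k, cap = cap, template_id = template_id),
            class = "rag_config")
}

#' Expand question codes by embedding similarity
#'
#' Returns the seed codes followed by the union of each space's top-k cosine
#' neighbors of each seed, ordered by descending best similarity (ties by
#' code). Seeds absent from every space are kept as seeds but not expanded.
#'
#' @param codes Character vector of seed concept codes (order preserved).
#' @param spaces A single `embedding_space` or a list of them.
#' @param k Neighbors per seed per space (>= 0).
#' @return Character vector: seeds first, then expansion codes.
#' @export
expand_codes <- function(codes, spaces, k = 5) {
  stopifnot(k >= 0)
  codes <- unique(as.character(codes))
  if (inherits(spaces, "embedding_space")) spaces <- list(spaces)
  if (k == 0 || !length(codes) || !length(spaces)) return(codes)
  best <- numeric(0)
  for (sp in spaces) {
    for (seed in codes) {
      if (!seed %in% rownames(sp$vectors)) next
      nb <- nearest_neighbors(sp, seed, k)
      for (i in seq_len(nrow(nb))) {
        cd <- nb$code[i]
        if (is.na(best[cd]) || nb$similarity[i] > best[cd]) {
          best[cd] <- nb$similarity[i]
        }
      }
    }
  }
  best <- best[setdiff(names(best), codes)]
  if (length(best)) {
    best <- best[order(-unname(best), names(best))]
  }
  c(codes, names(best))
}

#' Retrieve triples incident to a set of codes
#'
#' Union of [kg_neighbors()] over the codes, deduplicated, in deterministic
#' order (codes in the given order, each code's incident triples in neighbor
#' order).
#'
#' @param g A `knowledge_graph`.
#' @param codes Character vector of concept codes.
#' @return data.frame of triples.
#' @export
retrieve_triples <- function(g, codes) {
  parts <- lapply(unique(codes), function(cd) kg_neighbors(g, cd))
  t <- do.call(rbind, c(parts, list(g$triples[0, , drop = FALSE])))
  t <- t[!duplicated(t[, c("subject", "relation", "object")]), , drop = FALSE]
  rownames(t) <- NULL
  t
}

#' Keep only relations on the retrieval allow-list
#'
#' A pure filter: keeps exactly the triples whose relation is flagged
#' `rag_use` in the registry (the curated 13-relation allow-list by default),
#' preserving order. Triples with unregistered relations are dropped with a
#' warning.
#'
#' @param triples data.frame of triples.
#' @param registry Relation registry (see [default_registry()]).
#' @return Subset of `triples`.
#' @export
filter_by_relation <- function(triples, registry = default_registry()) {
  if (!nrow(triples)) return(triples)
  idx <- match(triples$relation, registry$name)
  if (anyNA(idx)) {
    warning("dropping triple(s) with unregistered relation: ",
            paste(unique(triples$relation[is.na(idx)]), collapse = ", "))
  }
  keep <- !is.na(idx) & registry$rag_use[idx]
  out <- triples[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Verbalize a triple as a human-readable sentence
#'
#' Template: `"<subject label>" (<subject tag>) <relation> "<object label>"
#' (<object tag>)`; the parenthesized tag is omitted when a concept has no
#' semantic tag. Codes without a concept entry fall back to the code as
#' label with no tag.
#'
#' @param triple A one-row data.frame (or list) with `subject`, `relation`,
#'   `object`.
#' @param concepts Concept table (`code`, `label`, `semantic_tag`), e.g.
#'   `g$concepts`.
#' @return A single sentence string.
#' @export
verbalize_triple <- function(triple, concepts) {
  part <- function(code) {
    i <- match(code, concepts$code)
    label <- if (is.na(i)) code else concepts$label[i]
    tag <- if (is.na(i)) "" else concepts$semantic_tag[i]
    if (nzchar(tag)) sprintf('"%s" (%s)', label, tag) else sprintf('"%s"', label)
  }
  sprintf("%s %s %s", part(triple$subject), triple$relation,
          part(triple$object))
}

#' Build the clinical context for a question
#'
#' The retrieval pipeline: expand the question's codes by embedding
#' similarity, fetch all incident triples from the graph, keep only
#' allow-listed relations, verbalize, deduplicate, and truncate to the cap
#' (sentences whose source triple touches a seed code are kept first).
#' Deterministic for fixed inputs. Empty question codes yield an empty
#' context (the native-prompt fallback).
#'
#' @param g A `knowledge_graph`.
#' @param spaces `embedding_space` or list of them (may be empty list).
#' @param question_codes Character vector of codes tagged in the question.
#' @param config A [rag_config()].
#' @return An object of class `rag_context`: list with `sentences`,
#'   `source_triples`, `stats`.
#' @export
build_context <- function(g, spaces, question_codes,
                          config = rag_config()) {
  seeds <- unique(as.character(question_codes))
  expanded <- if (length(seeds)) expand_codes(seeds, spaces, config$k) else character()
  retrieved <- retrieve_triples(g, expanded)
  kept <- filter_by_relation(retrieved, g$registry)
  if (nrow(kept)) {
    seed_incident <- kept$subject %in% seeds | kept$object %in% seeds
    kept <- kept[order(!seed_incident), , drop = FALSE]  # stable: seeds first
    sentences <- vapply(seq_len(nrow(kept)),
                        function(i) verbalize_triple(kept[i, ], g$concepts),
                        character(1))
    dup <- duplicated(sentences)
    kept <- kept[!dup, , drop = FALSE]
    sentences <- sentences[!dup]
    if (length(sentences) > config$cap) {
      kept <- kept[seq_len(config$cap), , drop = FALSE]
      sentences <- sentences[seq_len(config$cap)]
    }
  } else {
    sentences <- character()
  }
  rownames(kept) <- NULL
  structure(list(sentences = sentences, source_triples = kept,
                 stats = list(n_seed_codes = length(seeds),
                              n_expanded_codes = length(expanded),
                              n_retrieved = nrow(retrieved),
                              n_after_filter = sum(
                                filter_keep_count(retrieved, g$registry)),
                              n_sentences = length(sentences))),
            class = "rag_context")
}

filter_keep_count <- function(triples, registry) {
  if (!nrow(triples)) return(logical(0))
  idx <- match(triples$relation, registry$name)
  !is.na(idx) & registry$rag_use[idx]
}

#' @export
print.rag_context <- function(x, ...) {
  cat(sprintf("<rag_context> %d sentences (retrieved %d, allow-listed %d)\n",
              length(x$sentences), x$stats$n_retrieved, x$stats$n_after_filter))
  for (s in utils::head(x$sentences, 5)) cat("  -", s, "\n")
  if (length(x$sentences) > 5) cat("  ...\n")
  invisible(x)
}

#' Write a context to disk (plain text and JSON)
#' @param context A `rag_context`.
#' @param prefix Path prefix; writes `<prefix>.txt` (one sentence per line)
#'   and `<prefix>.json` (sentences, source triples, stats).
#' @return Invisibly `prefix`.
#' @export
write_context <- function(context, prefix) {
  con <- file(paste0(prefix, ".txt"), open = "wb")
  writeLines(context$sentences, con, useBytes = TRUE)
  close(con)
  jsonlite::write_json(list(sentences = context$sentences,
                            source_triples = context$source_triples,
                            stats = context$stats),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(prefix)
}

empty_context <- function() {
  structure(list(sentences = character(),
                 source_triples = data.frame(subject = character(),
                                             relation = character(),
                                             object = character(),
                                             provenance = character()),
                 stats = list(n_seed_codes = 0L, n_expanded_codes = 0L,
                              n_retrieved = 0L, n_after_filter = 0L,
                              n_sentences = 0L)),
            class = "rag_context")
}

#' Render a prompt for a question, with or without context
#'
#' The RAG form prepends a context block (one verbalized sentence per line)
#' to the native form; the two renderings are otherwise identical. The
#' rendered prompt contains the question stem verbatim and every context
#' sentence exactly once.
#'
#' @param question List with `id`, `stem`, and `choices` (named list/vector,
#'   letter -> choice text; at least 2 choices).
#' @param context A `rag_context`, or `NULL` for the native form.
#' @param template_id Template identifier (currently "v1").
#' @return An object of class `prompt_bundle`: `question`, `context`,
#'   `prompt`, `template_id`, `condition` ("native" or "rag").
#' @export
build_prompt <- function(question, context = NULL, template_id = "v1") {
  if (is.null(question$choices) || length(question$choices) < 2) {
    stop("question must have at least 2 lettered choices")
  }
  if (template_id != "v1") stop("unknown template id: ", template_id)
  if (is.null(context)) context <- empty_context()
  letters_ <- names(question$choices)
  choice_lines <- sprintf("(%s) %s", letters_, unlist(question$choices))
  blocks <- character()
  if (length(context$sentences)) {
    blocks <- c("Relevant clinical knowledge:",
                context$sentences, "")
  }
  prompt <- paste(c(blocks, question$stem, "",
                    choice_lines, "",
                    sprintf("Answer with the letter of the single best choice (%s-%s).",
                            letters_[1], letters_[length(letters_)])),
                  collapse = "\n")
  structure(list(question = question, context = context, prompt = prompt,
                 template_id = template_id,
                 condition = if (length(context$sentences)) "rag" else "native"),
            class = "prompt_bundle")
}
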