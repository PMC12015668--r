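#' Normalize a relation name
#'
#' Relation names are stored lower-cased with single internal spaces, so that
#' the same relation spelled with different case or spacing collapses to one
#' registry entry ("Has Adverse  Reaction" -> "has adverse reaction").
#'
#' @param x Character vector of relation names.
#' @return Normalized character vector.
#' @export
normalize_relation <- function(x) {
  x <- tolower(trimws(x))
  gsub("[[:space:]]+", " ", x)
}

#' Build a relation registry
#'
#' @param name Character vector of relation names (normalized on entry).
#' @param rag_use Logical vector: is the relation eligible for context
#'   retrieval (the curated allow-list)?
#' @param count_hint Optional integer vector of corpus frequencies (used only
#'   by the synthetic generator to set a realistic relation mix).
#' @return A data.frame with columns `name`, `rag_use`, `count_hint`.
#' @export
relation_registry <- function(name, rag_use, count_hint = NA_real_) {
  name <- normalize_relation(name)
  if (anyDuplicated(name)) {
    stop("duplicate relation names in registry: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  data.frame(name = name, rag_use = as.logical(rag_use),
             count_hint = as.numeric(count_hint),
             stringsAsFactors = FALSE)
}

#' The default 40-relation registry
#'
#' The registry shipped with the package: 40 clinical relation types, 13 of
#' which are flagged `rag_use` (causes, clinical course of, definitional
#' manifestation of, diagnoses, finding method of, has adverse reaction,
#' has contraindication, has indication, occurs in, pathological process of,
#' predisposes, prevents, treats). `count_hint` carries corpus frequencies
#' used as the default relation mix by [generate_kg()].
#'
#' @return A relation registry data.frame (see [relation_registry()]).
#' @export
default_registry <- function() {
  path <- system.file("extdata", "relation_registry.json", package = "clinrag")
  if (!nzchar(path)) stop("relation registry fixture not found")
  reg <- jsonlite::fromJSON(path)
  relation_registry(reg$name, reg$rag_use, reg$count_hint)
}

#' Construct a knowledge graph from concept and triple tables
#'
#' A knowledge graph is a set of semantic triples (subject-relation-object
#' over coded concepts) together with a concept table, a relation registry,
#' and an adjacency index mapping each concept code to the triples it is
#' incident to. Duplicate (subject, relation, object) rows are collapsed.
#'
#' @param triples data.frame with columns `subject`, `relation`, `object` and
#'   optionally `provenance`.
#' @param concepts data.frame with columns `code`, `label`, `semantic_tag`;
#'   codes appearing only in `triples` are added with the code as label.
#' @param registry Relation registry; relations used by `triples` but absent
#'   from it are appended with `rag_use = FALSE` (with a warning).
#' @return An object of class `knowledge_graph`.
#' @export
knowledge_graph <- function(triples = NULL, concepts = NULL,
                            registry = default_registry()) {
  if (is.null(triples)) {
    triples <- data.frame(subject = character(), relation = character(),
                          object = character(), provenance = character(),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("subject", "relation", "object") %in% names(triples)))
  if (!"provenance" %in% names(triples)) triples$provenance <- ""
  triples <- triples[, c("subject", "relation", "object", "provenance")]
  triples$subject <- as.character(triples$subject)
  triples$object <- as.character(triples$object)
  triples$relation <- normalize_relation(as.character(triples$relation))
  if (any(!nzchar(triples$subject)) || any(!nzchar(triples$object))) {
    stop("triples with empty subject or object code")
  }

  dup <- duplicated(triples[, c("subject", "relation", "object")])
  if (any(dup)) triples <- triples[!dup, , drop = FALSE]
  rownames(triples) <- NULL

  unknown <- setdiff(unique(triples$relation), registry$name)
  if (length(unknown)) {
    warning("unknown relation(s) added to registry with rag_use = FALSE: ",
            paste(unknown, collapse = ", "))
    registry <- rbind(registry,
                      relation_registry(unknown, FALSE, NA_real_))
  }

  codes <- unique(c(triples$subject, triples$object))
  if (is.null(concepts)) {
    concepts <- data.frame(code = character(), label = character(),
                           semantic_tag = character(), stringsAsFactors = FALSE)
  }
  stopifnot(all(c("code", "label") %in% names(concepts)))
  if (!"semantic_tag" %in% names(concepts)) concepts$semantic_tag <- ""
  concepts <- concepts[, c("code", "label", "semantic_tag")]
  concepts$code <- as.character(concepts$code)
  concepts$label <- as.character(concepts$label)
  concepts$semantic_tag <- as.character(concepts$semantic_tag)
  if (anyDuplicated(concepts$code)) {
    stop("duplicate concept codes: ",
         paste(unique(concepts$code[duplicated(concepts$code)]), collapse = ", "))
  }
  missing <- setdiff(codes, concepts$code)
  if (length(missing)) {
    concepts <- rbind(concepts,
                      data.frame(code = missing, label = missing,
                                 semantic_tag = "", stringsAsFactors = FALSE))
  }
  bad <- !nzchar(concepts$code) | !nzchar(concepts$label)
  if (any(bad)) stop("concepts with empty code or label")
  rownames(concepts) <- NULL

  g <- structure(list(concepts = concepts, registry = registry,
                      triples = triples, adjacency = NULL),
                 class = "knowledge_graph")
  g$adjacency <- build_adjacency(g)
  g
}

# code -> integer indices into g$triples (subject or object incidence)
build_adjacency <- function(g) {
  n <- nrow(g$triples)
  if (n == 0) return(list())
  idx <- c(seq_len(n), seq_len(n))
  code <- c(g$triples$subject, g$triples$object)
  keep <- !duplicated(data.frame(idx, code))  # self-loops indexed once
  split(idx[keep], code[keep])
}

#' Check internal consistency of a knowledge graph
#'
#' Rebuilds the adjacency index from the triple table and compares; checks
#' that every triple's codes resolve to concepts and that relations are
#' registered.
#'
#' @param g A `knowledge_graph`.
#' @return Invisibly `TRUE`; stops on inconsistency.
#' @export
validate_kg <- function(g) {
  stopifnot(inherits(g, "knowledge_graph"))
  fresh <- build_adjacency(g)
  same <- identical(lapply(fresh[order(names(fresh))], sort),
                    lapply(g$adjacency[order(names(g$adjacency))], sort))
  if (!same) stop("adjacency index inconsistent with triple set")
  if (!all(c(g$triples$subject, g$triples$object) %in% g$concepts$code)) {
    stop("triple references unresolved concept code")
  }
  if (!all(g$triples$relation %in% g$registry$name)) {
    stop("triple uses unregistered relation")
  }
  if (anyDuplicated(g$triples[, c("subject", "relation", "object")])) {
    stop("duplicate triples present")
  }
  invisible(TRUE)
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf("<knowledge_graph> %d concepts, %d triples, %d relation types (%d RAG-eligible)\n",
              nrow(x$concepts), nrow(x$triples), nrow(x$registry),
              sum(x$registry$rag_use)))
  invisible(x)
}

#' Load a knowledge graph from a triple TSV file
#'
#' Format: UTF-8, tab-separated, no quoting, optional `#`-prefixed header
#' lines. Columns: subject, relation, object, and optionally subject_label,
#' subject_tag, object_label, object_tag, provenance. Duplicate
#' (subject, relation, object) rows collapse silently.
#'
#' @param path Path to the TSV file.
#' @param registry Relation registry to start from; unknown relations are
#'   appended with `rag_use = FALSE`.
#' @return A `knowledge_graph`. An empty file yields an empty graph.
#' @export
load_triples <- function(path, registry = default_registry()) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(lines)
  rows <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  arity <- vapply(rows, length, integer(1))
  if (any(arity < 3)) {
    stop(sprintf("malformed triple row (expected >= 3 tab-separated fields) at line %d of %s",
                 lineno[which(arity < 3)[1]], path))
  }
  pad <- function(r) c(r, rep("", 8 - length(r)))[1:8]
  m <- do.call(rbind, lapply(rows, pad))
  if (is.null(m)) {
    return(knowledge_graph(registry = registry))
  }
  triples <- data.frame(subject = m[, 1], relation = m[, 2], object = m[, 3],
                        provenance = m[, 8], stringsAsFactors = FALSE)
  conc <- rbind(
    data.frame(code = m[, 1], label = ifelse(nzchar(m[, 4]), m[, 4], m[, 1]),
               semantic_tag = m[, 5], stringsAsFactors = FALSE),
    data.frame(code = m[, 3], label = ifelse(nzchar(m[, 6]), m[, 6], m[, 3]),
               semantic_tag = m[, 7], stringsAsFactors = FALSE))
  # first annotation wins; rows without labels never override rows with them
  conc <- conc[order(conc$label == conc$code), , drop = FALSE]
  conc <- conc[!duplicated(conc$code), , drop = FALSE]
  knowledge_graph(triples = triples, concepts = conc, registry = registry)
}

#' Save a knowledge graph as a triple TSV file
#'
#' Writes the 8-column dialect read by [load_triples()]; `load(save(g))`
#' reproduces the graph up to row order.
#'
#' @param g A `knowledge_graph`.
#' @param path Output path.
#' @return Invisibly `path`.
#' @export
save_triples <- function(g, path) {
  stopifnot(inherits(g, "knowledge_graph"))
  lab <- stats::setNames(g$concepts$label, g$concepts$code)
  tag <- stats::setNames(g$concepts$semantic_tag, g$concepts$code)
  t <- g$triples
  header <- "#subject\trelation\tobject\tsubject_label\tsubject_tag\tobject_label\tobject_tag\tprovenance"
  body <- if (nrow(t)) {
    paste(t$subject, t$relation, t$object,
          lab[t$subject], tag[t$subject], lab[t$object], tag[t$object],
          t$provenance, sep = "\t")
  } else character()
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, body), con, useBytes = TRUE)
  invisible(path)
}

#' Incident triples of a concept
#'
#' Returns every triple in which `code` appears as subject or object,
#' optionally restricted to a set of relation names, in a deterministic
#' order (by relation, then counterpart code, then role).
#'
#' @param g A `knowledge_graph`.
#' @param code Concept code; an unknown code yields zero rows.
#' @param allowed Optional character vector of relation names to keep.
#' @return data.frame of triples (subset of `g$triples` rows).
#' @export
kg_neighbors <- function(g, code, allowed = NULL) {
  stopifnot(inherits(g, "knowledge_graph"), length(code) == 1)
  idx <- g$adjacency[[code]]
  t <- g$triples[idx, , drop = FALSE]
  if (!is.null(allowed)) {
    t <- t[t$relation %in% normalize_relation(allowed), , drop = FALSE]
  }
  if (nrow(t)) {
    counterpart <- ifelse(t$subject == code, t$object, t$subject)
    t <- t[order(t$relation, counterpart, t$subject), , drop = FALSE]
  }
  rownames(t) <- NULL
  t
}

#' Deconstruct triples into (code, relation) pairs
#'
#' Emits (subject, relation) and (object, relation) for every triple; these
#' pairs, together with sentence co-occurrence pairs, form the bipartite-ish
#' pair graph over which walk-based graph embeddings are trained.
#'
#' @param g A `knowledge_graph`.
#' @return data.frame with columns `code`, `relation`; `2 * nrow(g$triples)` rows.
#' @export
deconstruct_pairs <- function(g) {
  stopifnot(inherits(g, "knowledge_graph"))
  t <- g$triples
  data.frame(code = c(rbind(t$subject, t$object)),
             relation = c(rbind(t$relation, t$relation)),
             stringsAsFactors = FALSE)
}
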