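#' Training configuration for embedding models
#'
#' One bag of hyperparameters shared by the walk-based and knowledge-graph
#' embedding trainers. All values must be positive; the seed is recorded in
#' every trained space so runs are reproducible bit for bit (training is
#' single-threaded plain SGD by design).
#'
#' @param dim Embedding dimensionality d; 512 by default (128 and 256 are the
#'   other supported sweep points). RotatE stores d/2 complex entity
#'   coordinates in d reals, so `dim` must be even for RotatE.
#' @param epochs Training epochs.
#' @param learning_rate SGD step size.
#' @param negative Negative samples per positive example.
#' @param margin Margin gamma of the ranking loss (TransE/RotatE).
#' @param walk_length Maximum random-walk length (nodes per walk).
#' @param walks_per_node Walks started from each node.
#' @param window Skip-gram context window (tokens each side).
#' @param p node2vec return parameter (weight 1/p for stepping back).
#' @param q node2vec in-out parameter (weight 1/q for outward steps);
#'   `p = q = 1` reduces exactly to uniform DeepWalk.
#' @param seed Integer RNG seed.
#' @return A list of class `training_config`.
#' @export
training_config <- function(dim = 512, epochs = 5, learning_rate = 0.025,
                            negative = 5, margin = 1, walk_length = 10,
                            walks_per_node = 10, window = 5, p = 1, q = 1,
                            seed = 1) {
  cfg <- list(dim = dim, epochs = epochs, learning_rate = learning_rate,
              negative = negative, margin = margin, walk_length = walk_length,
              walks_per_node = walks_per_node, window = window, p = p, q = q,
              seed = as.integer(seed))
  num <- unlist(cfg[setdiff(names(cfg), "seed")])
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all training_config values must be positive and finite")
  }
  structure(cfg, class = "training_config")
}

#' Undirected pair graph for walk-based embeddings
#'
#' Walk-based graph embeddings ignore relation typing: the walk graph joins
#' each triple's subject and object to the relation name node (deconstructed
#' (code, relation) pairs) and, optionally, pairs of codes co-occurring in
#' the same source sentence.
#'
#' @param g A `knowledge_graph`.
#' @param cooccur Optional data.frame with columns `a`, `b` of co-occurring
#'   concept codes.
#' @return Adjacency list: named list, node -> sorted character vector of
#'   neighbors.
#' @export
build_pair_graph <- function(g, cooccur = NULL) {
  pairs <- deconstruct_pairs(g)
  a <- pairs$code
  b <- pairs$relation
  if (!is.null(cooccur) && nrow(cooccur)) {
    a <- c(a, as.character(cooccur$a))
    b <- c(b, as.character(cooccur$b))
  }
  nodes <- sort(unique(c(a, b)))
  adj <- split(c(b, a), c(a, b))
  adj <- lapply(adj, function(v) sort(unique(v)))
  adj[nodes]
}

#' Generate biased random walks
#'
#' Second-order (node2vec-style) walks over the pair graph: from state
#' (previous, current) a neighbor x of current is sampled with weight 1/p if
#' x is the previous node, 1 if x is also adjacent to the previous node, and
#' 1/q otherwise. With `p = q = 1` every step is uniform over neighbors
#' (DeepWalk). Isolated nodes yield length-1 walks. Seeded and reproducible.
#'
#' @param g A `knowledge_graph` (or an adjacency list as returned by
#'   [build_pair_graph()]).
#' @param config A [training_config()].
#' @param cooccur Optional co-occurrence pairs, see [build_pair_graph()].
#' @return List of character vectors (node sequences),
#'   `walks_per_node * n_nodes` of them.
#' @export
generate_walks <- function(g, config = training_config(), cooccur = NULL) {
  adj <- if (inherits(g, "knowledge_graph")) build_pair_graph(g, cooccur) else g
  if (!length(adj)) stop("empty graph: nothing to walk")
  set.seed(config$seed)
  nodes <- names(adj)
  walks <- vector("list", config$walks_per_node * length(nodes))
  w <- 0L
  inv_p <- 1 / config$p
  inv_q <- 1 / config$q
  for (rep in seq_len(config$walks_per_node)) {
    for (start in nodes) {
      walk <- character(config$walk_length)
      walk[1] <- start
      len <- 1L
      prev <- NA_character_
      cur <- start
      while (len < config$walk_length) {
        nbrs <- adj[[cur]]
        if (!length(nbrs)) break
        if (is.na(prev) || (inv_p == 1 && inv_q == 1)) {
          nxt <- nbrs[sample.int(length(nbrs), 1L)]
        } else {
          wts <- ifelse(nbrs == prev, inv_p,
                        ifelse(nbrs %in% adj[[prev]], 1, inv_q))
          nxt <- nbrs[sample.int(length(nbrs), 1L, prob = wts)]
        }
        len <- len + 1L
        walk[len] <- nxt
        prev <- cur
        cur <- nxt
      }
      w <- w + 1L
      walks[[w]] <- walk[seq_len(len)]
    }
  }
  walks
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Train skip-gram embeddings over walks
#'
#' Skip-gram with negative sampling (noise distribution: unigram frequency to
#' the 3/4 power), plain seeded SGD. Epoch losses are recorded in the
#' returned space (`space$losses`); on any nontrivial corpus the final epoch
#' loss is below the first.
#'
#' @param walks List of node sequences from [generate_walks()].
#' @param config A [training_config()].
#' @return An `embedding_space` with `method = "walk"`.
#' @export
skipgram_train <- function(walks, config = training_config()) {
  stopifnot(length(walks) > 0)
  vocab <- sort(unique(unlist(walks)))
  if (length(vocab) < 2) stop("vocabulary has fewer than 2 nodes; cannot negative-sample")
  n <- length(vocab)
  d <- config$dim
  counts <- table(factor(unlist(walks), levels = vocab))
  noise <- as.numeric(counts)^0.75
  noise <- noise / sum(noise)

  set.seed(config$seed)
  W <- matrix(stats::runif(n * d, -0.5, 0.5) / d, n, d,
              dimnames = list(vocab, NULL))
  C <- matrix(0, n, d, dimnames = list(vocab, NULL))

  iwalks <- lapply(walks, function(w) match(w, vocab))
  # precompute (center, context) index pairs once; order is corpus order
  centers <- integer(0); contexts <- integer(0)
  for (iw in iwalks) {
    L <- length(iw)
    if (L < 2) next
    for (i in seq_len(L)) {
      lo <- max(1L, i - config$window)
      hi <- min(L, i + config$window)
      ctx <- iw[setdiff(lo:hi, i)]
      centers <- c(centers, rep.int(iw[i], length(ctx)))
      contexts <- c(contexts, ctx)
    }
  }
  if (!length(centers)) stop("no training pairs (all walks length 1)")

  lr <- config$learning_rate
  losses <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(length(centers))
    loss <- 0
    negs <- matrix(sample.int(n, length(centers) * config$negative,
                              replace = TRUE, prob = noise),
                   ncol = config$negative)
    for (t in seq_along(ord)) {
      i <- ord[t]
      wv <- W[centers[i], ]
      targets <- c(contexts[i], negs[t, ])
      label <- c(1, numeric(config$negative))
      Cm <- C[targets, , drop = FALSE]
      u <- as.numeric(Cm %*% wv)
      s <- sigmoid(u)
      loss <- loss - sum(log(ifelse(label == 1, pmax(s, 1e-12),
                                    pmax(1 - s, 1e-12))))
      e <- (label - s) * lr
      W[centers[i], ] <- wv + as.numeric(crossprod(Cm, e))
      C[targets, ] <- Cm + outer(e, wv)
    }
    losses[ep] <- loss / length(ord)
  }
  embedding_space(method = "walk", vectors = W, seed = config$seed,
                  config = config, losses = losses)
}

#' Construct an embedding space
#'
#' @param method One of "walk", "transe", "rotate".
#' @param vectors Numeric matrix, one row per concept code (rownames), `dim`
#'   columns. RotatE entity vectors hold d/2 complex coordinates as d reals:
#'   real parts in columns 1..d/2, imaginary parts in d/2+1..d.
#' @param relation_vectors For "transe": real matrix (rownames = relation
#'   names). For "rotate": complex matrix of unit-modulus phases, d/2 columns.
#' @param seed Seed the space was trained with.
#' @param config Training configuration (stored for provenance).
#' @param losses Optional numeric vector of epoch losses.
#' @return An object of class `embedding_space`.
#' @export
embedding_space <- function(method, vectors, relation_vectors = NULL,
                            seed = NA_integer_, config = list(), losses = NULL) {
  method <- match.arg(method, c("walk", "transe", "rotate"))
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (!all(is.finite(vectors))) stop("non-finite entity vectors")
  if (method == "rotate") {
    if (ncol(vectors) %% 2 != 0) stop("RotatE needs an even dimension")
    if (!is.null(relation_vectors)) {
      if (!is.complex(relation_vectors)) stop("RotatE relation vectors must be complex")
      if (any(abs(Mod(relation_vectors) - 1) > 1e-6)) {
        stop("RotatE relation phases must have unit modulus (tolerance 1e-6)")
      }
    }
  }
  structure(list(method = method, dim = ncol(vectors), vectors = vectors,
                 relation_vectors = relation_vectors, seed = seed,
                 config = config, losses = losses),
            class = "embedding_space")
}

#' @export
print.embedding_space <- function(x, ...) {
  cat(sprintf("<embedding_space> method=%s d=%d, %d codes, %d relations, seed=%s\n",
              x$method, x$dim, nrow(x$vectors),
              if (is.null(x$relation_vectors)) 0L else nrow(x$relation_vectors),
              x$seed))
  invisible(x)
}

lookup_vec <- function(space, code, what = "code") {
  m <- if (what == "relation") space$relation_vectors else space$vectors
  if (is.null(m) || !code %in% rownames(m)) {
    stop(sprintf("unknown %s in embedding space: '%s'", what, code))
  }
  m[code, ]
}

entity_complex <- function(space, code) {
  v <- lookup_vec(space, code)
  h <- space$dim / 2
  complex(real = v[1:h], imaginary = v[(h + 1):space$dim])
}

#' TransE plausibility score
#'
#' Scores a candidate triple as minus the Euclidean residual of the
#' translation model: `-||v_s + v_r - v_o||`. Higher is more plausible; an
#' exactly satisfied triple scores 0. Invariant under adding any constant
#' vector to all entity embeddings.
#'
#' @param space An `embedding_space` with real relation vectors.
#' @param s,o Concept codes.
#' @param r Relation name.
#' @return A single numeric score (<= 0).
#' @export
transe_score <- function(space, s, r, o) {
  vs <- lookup_vec(space, s)
  vo <- lookup_vec(space, o)
  vr <- lookup_vec(space, r, "relation")
  -sqrt(sum((vs + vr - vo)^2))
}

#' RotatE plausibility score
#'
#' Entities are complex vectors; a relation is an elementwise rotation by
#' unit-modulus phases. Score is `-||v_s o v_r - v_o||` with the complex
#' elementwise product; rotation preserves entity norms.
#'
#' @inheritParams transe_score
#' @return A single numeric score (<= 0).
#' @export
rotate_score <- function(space, s, r, o) {
  if (space$method != "rotate") stop("rotate_score needs a RotatE space")
  hr <- lookup_vec(space, r, "relation")
  if (any(abs(Mod(hr) - 1) > 1e-6)) {
    stop("relation phases not unit modulus (tolerance 1e-6): ", r)
  }
  hs <- entity_complex(space, s)
  ho <- entity_complex(space, o)
  -sqrt(sum(Mod(hs * hr - ho)^2))
}

#' Score a triple under any knowledge-graph embedding space
#' @inheritParams transe_score
#' @return Numeric score; higher = more plausible.
#' @export
kge_score <- function(space, s, r, o) {
  switch(space$method,
         transe = transe_score(space, s, r, o),
         rotate = rotate_score(space, s, r, o),
         stop("space method '", space$method, "' does not score triples"))
}

#' Train TransE or RotatE knowledge-graph embeddings
#'
#' Margin-based ranking loss with uniform negative sampling: each observed
#' triple is contrasted with one corruption per step, replacing the head or
#' the tail (probability 1/2 each) by a uniformly drawn entity. Plain seeded
#' SGD; TransE entity vectors are re-normalized to unit length after each
#' update, RotatE relation phases are kept on the unit circle by storing
#' angles. Epoch losses are recorded in `space$losses`.
#'
#' @param g A `knowledge_graph` with at least 2 entities.
#' @param method "transe" or "rotate".
#' @param config A [training_config()].
#' @return A trained `embedding_space`.
#' @export
train_kge <- function(g, method = c("transe", "rotate"),
                      config = training_config()) {
  method <- match.arg(method)
  stopifnot(inherits(g, "knowledge_graph"))
  entities <- sort(unique(c(g$triples$subject, g$triples$object)))
  if (length(entities) < 2) stop("need at least 2 entities to train")
  relations <- sort(unique(g$triples$relation))
  n <- length(entities)
  d <- config$dim
  if (method == "rotate" && d %% 2 != 0) stop("RotatE needs an even dimension")
  set.seed(config$seed)

  si <- match(g$triples$subject, entities)
  oi <- match(g$triples$object, entities)
  ri <- match(g$triples$relation, relations)
  nt <- length(si)

  b <- 6 / sqrt(d)
  E <- matrix(stats::runif(n * d, -b, b), n, d, dimnames = list(entities, NULL))
  lr <- config$learning_rate
  gamma <- config$margin
  losses <- numeric(config$epochs)

  if (method == "transe") {
    R <- matrix(stats::runif(length(relations) * d, -b, b), length(relations), d,
                dimnames = list(relations, NULL))
    R <- R / sqrt(rowSums(R^2))
    E <- E / sqrt(rowSums(E^2))
    dist <- function(h, r, t) sqrt(sum((E[h, ] + R[r, ] - E[t, ])^2) + 1e-12)
    for (ep in seq_len(config$epochs)) {
      loss <- 0
      for (i in sample.int(nt)) {
        h <- si[i]; r <- ri[i]; t <- oi[i]
        corrupt_head <- stats::runif(1) < 0.5
        cand <- sample.int(n, 1L)
        hn <- if (corrupt_head) cand else h
        tn <- if (corrupt_head) t else cand
        dp <- dist(h, r, t)
        dn <- dist(hn, r, tn)
        l <- gamma + dp - dn
        if (l > 0) {
          loss <- loss + l
          gp <- (E[h, ] + R[r, ] - E[t, ]) / dp
          gn <- (E[hn, ] + R[r, ] - E[tn, ]) / dn
          E[h, ] <- E[h, ] - lr * gp
          E[t, ] <- E[t, ] + lr * gp
          R[r, ] <- R[r, ] - lr * (gp - gn)
          E[hn, ] <- E[hn, ] + lr * gn
          E[tn, ] <- E[tn, ] - lr * gn
          touched <- unique(c(h, t, hn, tn))
          E[touched, ] <- E[touched, , drop = FALSE] /
            sqrt(rowSums(E[touched, , drop = FALSE]^2))
        }
      }
      losses[ep] <- loss / nt
    }
    return(embedding_space("transe", E, R, seed = config$seed,
                           config = config, losses = losses))
  }

  # RotatE: entities as d/2 complex coords (re | im halves), relations as angles
  h2 <- d / 2
  theta <- matrix(stats::runif(length(relations) * h2, 0, 2 * pi),
                  length(relations), h2, dimnames = list(relations, NULL))
  getc <- function(i) complex(real = E[i, 1:h2], imaginary = E[i, (h2 + 1):d])
  setc <- function(i, z) E[i, ] <<- c(Re(z), Im(z))
  for (ep in seq_len(config$epochs)) {
    loss <- 0
    for (i in sample.int(nt)) {
      h <- si[i]; r <- ri[i]; t <- oi[i]
      corrupt_head <- stats::runif(1) < 0.5
      cand <- sample.int(n, 1L)
      hn <- if (corrupt_head) cand else h
      tn <- if (corrupt_head) t else cand
      rot <- exp(1i * theta[r, ])
      zh <- getc(h); zt <- getc(t); zhn <- getc(hn); ztn <- getc(tn)
      epos <- zh * rot - zt
      eneg <- zhn * rot - ztn
      fp <- sqrt(sum(Mod(epos)^2) + 1e-12)
      fn <- sqrt(sum(Mod(eneg)^2) + 1e-12)
      l <- gamma + fp - fn
      if (l > 0) {
        loss <- loss + l
        # complex gradients of the L2 residual
        gh <- Conj(rot) * epos / fp
        gt <- -epos / fp
        gth <- Im(Conj(epos) * zh * rot) / fp   # d f / d theta (positive term)
        ghn <- Conj(rot) * eneg / fn
        gtn <- -eneg / fn
        gthn <- Im(Conj(eneg) * zhn * rot) / fn
        setc(h, getc(h) - lr * gh)
        setc(t, getc(t) - lr * gt)
        setc(hn, getc(hn) + lr * ghn)
        setc(tn, getc(tn) + lr * gtn)
        theta[r, ] <- (theta[r, ] - lr * (gth - gthn)) %% (2 * pi)
      }
    }
    losses[ep] <- loss / nt
  }
  embedding_space("rotate", E, exp(1i * theta), seed = config$seed,
                  config = config, losses = losses)
}

#' Cosine similarity of two vectors
#'
#' `<x, y> / (||x|| ||y||)`, in [-1, 1]. Undefined (an error) for a zero
#' vector.
#'
#' @param x,y Numeric vectors of equal length.
#' @return A single numeric value.
#' @export
cosine_similarity <- function(x, y) {
  stopifnot(length(x) == length(y))
  nx <- sqrt(sum(x^2))
  ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("cosine similarity undefined for a zero vector")
  sum(x * y) / (nx * ny)
}

#' k nearest neighbors by cosine similarity
#'
#' Exhaustive scan over the space (the reference semantics; no approximate
#' index). The query code itself is excluded; ties are broken
#' lexicographically by code; fewer than k codes available returns them all.
#'
#' @param space An `embedding_space`.
#' @param code Query concept code (must be in the space).
#' @param k Number of neighbors (>= 1).
#' @return data.frame with columns `code`, `similarity`, descending.
#' @export
nearest_neighbors <- function(space, code, k) {
  stopifnot(k >= 1)
  v <- lookup_vec(space, code)
  m <- space$vectors[setdiff(rownames(space$vectors), code), , drop = FALSE]
  if (!nrow(m)) return(data.frame(code = character(), similarity = numeric()))
  nv <- sqrt(sum(v^2))
  nm <- sqrt(rowSums(m^2))
  if (nv == 0 || any(nm == 0)) stop("cosine similarity undefined for a zero vector")
  sims <- unname(as.numeric(m %*% v) / (nm * nv))
  ord <- order(-sims, rownames(m))
  take <- ord[seq_len(min(k, length(ord)))]
  data.frame(code = rownames(m)[take], similarity = sims[take],
             stringsAsFactors = FALSE)
}

#' Filtered hits@k for tail prediction
#'
#' For each test triple, ranks the true object among all entities substituted
#' as object; `filtered` removes other known-true completions from the
#' candidate list before ranking (ties rank pessimistically).
#'
#' @param space A TransE or RotatE `embedding_space`.
#' @param triples data.frame of test triples (subject, relation, object).
#' @param k Rank cutoff.
#' @param known data.frame of all known-true triples used for filtering
#'   (defaults to `triples`).
#' @return Proportion of test triples with true-object rank <= k.
#' @export
hits_at_k <- function(space, triples, k = 3, known = triples) {
  entities <- rownames(space$vectors)
  hits <- logical(nrow(triples))
  for (i in seq_len(nrow(triples))) {
    s <- triples$subject[i]; r <- triples$relation[i]; o <- triples$object[i]
    other_true <- known$object[known$subject == s & known$relation == r &
                                 known$object != o]
    cand <- setdiff(entities, other_true)
    sc <- vapply(cand, function(e) kge_score(space, s, r, e), numeric(1))
    true_sc <- sc[cand == o]
    rank <- sum(sc >= true_sc)  # pessimistic under ties
    hits[i] <- rank <= k
  }
  mean(hits)
}

#' Write an embedding space to disk
#'
#' Entity vectors go to `<prefix>.tsv` (code + d floats, full precision);
#' method, dimension, seed, config, and relation vectors go to a JSON sidecar
#' `<prefix>.json`. Complex RotatE phases are stored as re/im arrays.
#'
#' @param space An `embedding_space`.
#' @param prefix Path prefix (without extension).
#' @return Invisibly `prefix`.
#' @export
write_embedding_space <- function(space, prefix) {
  v <- space$vectors
  lines <- paste(rownames(v),
                 apply(v, 1, function(r) paste(sprintf("%.17g", r), collapse = "\t")),
                 sep = "\t")
  con <- file(paste0(prefix, ".tsv"), open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)
  rel <- space$relation_vectors
  side <- list(method = space$method, dim = space$dim, seed = space$seed,
               config = space$config[setdiff(names(space$config), "")],
               losses = space$losses)
  if (!is.null(rel)) {
    if (is.complex(rel)) {
      side$relations <- list(names = rownames(rel), re = Re(rel), im = Im(rel))
    } else {
      side$relations <- list(names = rownames(rel), re = rel)
    }
  }
  jsonlite::write_json(side, paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read an embedding space written by [write_embedding_space()]
#' @param prefix Path prefix (without extension).
#' @return An `embedding_space`.
#' @export
read_embedding_space <- function(prefix) {
  side <- jsonlite::fromJSON(paste0(prefix, ".json"))
  rows <- strsplit(readLines(paste0(prefix, ".tsv"), warn = FALSE), "\t",
                   fixed = TRUE)
  codes <- vapply(rows, `[[`, "", 1)
  V <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(V) <- codes
  rel <- NULL
  if (!is.null(side$relations)) {
    re <- matrix(unlist(side$relations$re), nrow = length(side$relations$names))
    if (!is.null(side$relations$im)) {
      im <- matrix(unlist(side$relations$im), nrow = length(side$relations$names))
      rel <- matrix(complex(real = re, imaginary = im), nrow = nrow(re))
    } else {
      rel <- re
    }
    rownames(rel) <- side$relations$names
  }
  embedding_space(side$method, V, rel, seed = side$seed,
                  config = as.list(side$config), losses = side$losses)
}
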