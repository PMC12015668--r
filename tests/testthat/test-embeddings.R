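test_that("walks respect graph structure and degenerate cases", {
  g <- knowledge_graph(data.frame(subject = "A", relation = "treats",
                                  object = "B"),
                       concepts = data.frame(code = c("A", "B", "LONER"),
                                             label = c("a", "b", "loner")))
  adj <- build_pair_graph(g)
  adj$LONER <- character(0)  # isolated node
  cfg <- training_config(dim = 4, walk_length = 6, walks_per_node = 3, seed = 2)
  walks <- generate_walks(adj, cfg)
  expect_length(walks, 3 * length(adj))
  loner_walks <- walks[vapply(walks, `[[`, "", 1) == "LONER"]
  expect_true(all(lengths(loner_walks) == 1))
  # pair graph of one triple is the path A - treats - B: forced alternation
  ab <- walks[vapply(walks, `[[`, "", 1) == "A"]
  for (w in ab) {
    expect_true(all(w[c(TRUE, FALSE)] %in% c("A", "B")))
    expect_true(all(w[c(FALSE, TRUE)] == "treats"))
  }
})

test_that("walks are reproducible at a fixed seed", {
  g <- clique_pair_graph()
  cfg <- training_config(dim = 4, walk_length = 8, walks_per_node = 4, seed = 31)
  expect_identical(generate_walks(g, cfg), generate_walks(g, cfg))
})

test_that("p = q = 1 walks take uniform next steps (chi-square vs DeepWalk)", {
  # fixed 5-node graph with mixed degrees
  g <- knowledge_graph(data.frame(
    subject = c("A", "A", "B", "C"),
    relation = c("treats", "causes", "prevents", "prevents"),
    object = c("B", "C", "C", "D")))
  cfg <- training_config(dim = 4, walk_length = 25, walks_per_node = 60,
                         p = 1, q = 1, seed = 17)
  walks <- generate_walks(g, cfg)
  steps <- do.call(rbind, lapply(walks, function(w) {
    if (length(w) < 2) return(NULL)
    data.frame(from = w[-length(w)], to = w[-1])
  }))
  expect_gt(nrow(steps), 1e4)
  adj <- build_pair_graph(g)
  for (node in names(adj)) {
    nbrs <- adj[[node]]
    if (length(nbrs) < 2) next
    obs <- table(factor(steps$to[steps$from == node], levels = nbrs))
    p <- stats::chisq.test(obs, p = rep(1 / length(nbrs), length(nbrs)))$p.value
    expect_gt(p, 1e-4)
  }
})

test_that("skip-gram separates communities, decreases loss, and is deterministic", {
  g <- clique_pair_graph()
  for (d in c(16, 128)) {
    cfg <- training_config(dim = d, epochs = 4, walk_length = 8,
                           walks_per_node = 8, window = 3, seed = 7)
    sp <- skipgram_train(generate_walks(g, cfg), cfg)
    expect_lt(sp$losses[length(sp$losses)], sp$losses[1])
    A <- sp$vectors[paste0("A", 1:5), ]
    B <- sp$vectors[paste0("B", 1:5), ]
    within <- mean(vapply(1:4, function(i) cosine_similarity(A[i, ], A[i + 1, ]),
                          numeric(1)))
    cross <- mean(vapply(1:5, function(i) cosine_similarity(A[i, ], B[i, ]),
                         numeric(1)))
    expect_gt(within, cross)
  }
  cfg <- training_config(dim = 8, epochs = 2, walk_length = 6,
                         walks_per_node = 4, window = 2, seed = 5)
  w <- generate_walks(g, cfg)
  expect_identical(skipgram_train(w, cfg)$vectors, skipgram_train(w, cfg)$vectors)
  expect_error(skipgram_train(list(c("solo")), cfg), "fewer than 2")
})

test_that("TransE score matches its definition and is translation invariant", {
  set.seed(4)
  d <- 6
  V <- matrix(rnorm(4 * d), 4, d, dimnames = list(c("s", "o", "x", "y"), NULL))
  R <- matrix(rnorm(2 * d), 2, d, dimnames = list(c("r1", "r2"), NULL))
  sp <- embedding_space("transe", V, R)

  # constructed identity: v_o = v_s + v_r scores exactly 0
  V2 <- V; V2["o", ] <- V["s", ] + R["r1", ]
  sp2 <- embedding_space("transe", V2, R)
  expect_equal(transe_score(sp2, "s", "r1", "o"), 0)

  # equals independent norm computation
  expect_equal(transe_score(sp, "s", "r2", "x"),
               -sqrt(sum((V["s", ] + R["r2", ] - V["x", ])^2)))

  # adding a constant vector to every entity leaves all scores unchanged
  shift <- matrix(rnorm(d), 4, d, byrow = TRUE)
  sp3 <- embedding_space("transe", V + shift, R)
  for (s in c("s", "x")) for (o in c("o", "y")) {
    expect_equal(transe_score(sp3, s, "r1", o), transe_score(sp, s, "r1", o))
  }
  expect_error(transe_score(sp, "nope", "r1", "o"), "nope")
  expect_error(transe_score(sp, "s", "nope", "o"), "nope")
})

test_that("RotatE rotation preserves norms and matches complex arithmetic", {
  set.seed(9)
  d <- 8
  V <- matrix(rnorm(3 * d), 3, d, dimnames = list(c("s", "o", "z"), NULL))
  theta <- matrix(runif(2 * d / 2, 0, 2 * pi), 2, d / 2,
                  dimnames = list(c("r1", "r2"), NULL))
  sp <- embedding_space("rotate", V, exp(1i * theta))

  # identity rotation maps s to itself: score 0
  id <- matrix(complex(real = 1, imaginary = 0), 1, d / 2,
               dimnames = list("id", NULL))
  spi <- embedding_space("rotate", V, id)
  expect_equal(rotate_score(spi, "s", "id", "s"), 0)

  # modulus preservation: ||v_s o v_r|| = ||v_s||
  zs <- complex(real = V["s", 1:(d / 2)], imaginary = V["s", (d / 2 + 1):d])
  rr <- exp(1i * theta["r1", ])
  expect_equal(sqrt(sum(Mod(zs * rr)^2)), sqrt(sum(Mod(zs)^2)))

  # score equals a brute-force complex oracle
  zo <- complex(real = V["o", 1:(d / 2)], imaginary = V["o", (d / 2 + 1):d])
  expect_equal(rotate_score(sp, "s", "r1", "o"),
               -sqrt(sum(Mod(zs * rr - zo)^2)))

  # non-unit modulus is rejected
  bad <- matrix(complex(real = 1.01, imaginary = 0), 1, d / 2,
                dimnames = list("bad", NULL))
  expect_error(embedding_space("rotate", V, bad), "unit modulus")
})

test_that("cosine similarity hits its anchor values and rejects zero vectors", {
  x <- c(1, 2, 3)
  expect_equal(cosine_similarity(x, x), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(x, -x), -1)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
})

test_that("nearest_neighbors equals an exhaustive brute-force scan", {
  sp <- random_space(n = 200, d = 128, seed = 13)
  codes <- rownames(sp$vectors)
  brute <- function(code, k) {
    sims <- vapply(setdiff(codes, code), function(o)
      cosine_similarity(sp$vectors[code, ], sp$vectors[o, ]), numeric(1))
    ord <- order(-sims, names(sims))[seq_len(k)]
    data.frame(code = names(sims)[ord], similarity = unname(sims[ord]),
               stringsAsFactors = FALSE)
  }
  for (code in codes[c(1, 57, 200)]) {
    expect_equal(nearest_neighbors(sp, code, 10), brute(code, 10))
  }
  # capped at available codes; duplicate vector ranks first with similarity 1
  sp3 <- embedding_space("walk", sp$vectors[1:3, ])
  expect_equal(nrow(nearest_neighbors(sp3, codes[1], 5)), 2)
  V <- sp$vectors[1:4, ]
  V[4, ] <- V[1, ]
  rownames(V)[4] <- "DUP"
  spd <- embedding_space("walk", V)
  nn <- nearest_neighbors(spd, codes[1], 3)
  expect_equal(nn$code[1], "DUP")
  expect_equal(nn$similarity[1], 1)
  expect_error(nearest_neighbors(sp, "missing", 3), "missing")
})

test_that("trained KGE models recover planted links above chance", {
  g <- generate_kg(30, 120, seed = 2)
  probe <- g$triples[seq(1, 120, by = 4), ]
  cfg_t <- training_config(dim = 32, epochs = 60, learning_rate = 0.05,
                           margin = 2, seed = 5)
  sp_t <- train_kge(g, "transe", cfg_t)
  expect_lt(sp_t$losses[length(sp_t$losses)], sp_t$losses[1])
  expect_gt(hits_at_k(sp_t, probe, 3, known = g$triples), 3 / 30 + 0.1)

  cfg_r <- training_config(dim = 32, epochs = 40, learning_rate = 0.05,
                           margin = 3, seed = 5)
  sp_r <- train_kge(g, "rotate", cfg_r)
  expect_gt(hits_at_k(sp_r, probe, 3, known = g$triples), 3 / 30 + 0.1)

  # determinism at fixed seed
  expect_identical(train_kge(g, "transe", cfg_t)$vectors, sp_t$vectors)
})

test_that("a single-triple graph trains and ranks the true tail first", {
  g <- knowledge_graph(data.frame(subject = "A", relation = "treats",
                                  object = "B"))
  cfg <- training_config(dim = 8, epochs = 30, learning_rate = 0.1, seed = 3)
  sp <- train_kge(g, "transe", cfg)
  expect_equal(hits_at_k(sp, g$triples, 1), 1)
})

test_that("embedding spaces round-trip through TSV + JSON sidecar", {
  g <- generate_kg(15, 40, seed = 6)
  cfg <- training_config(dim = 8, epochs = 3, seed = 21)
  for (method in c("transe", "rotate")) {
    sp <- train_kge(g, method, cfg)
    prefix <- file.path(withr::local_tempdir(), method)
    write_embedding_space(sp, prefix)
    sp2 <- read_embedding_space(prefix)
    expect_equal(sp2$vectors, sp$vectors)
    expect_equal(sp2$relation_vectors, sp$relation_vectors)
    expect_equal(sp2$method, sp$method)
    expect_equal(sp2$seed, sp$seed)
  }
})
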