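test_that("score_responses marks correctness and silence from the key", {
  key <- c(Q1 = "A", Q2 = "A", Q3 = "B")
  recs <- list(answer_record("Q1", "native", "(E)", "E"),
               answer_record("Q2", "native", "(A)", "A"),
               answer_record("Q3", "native", "none", NA_character_))
  scored <- score_responses(recs, key)
  expect_false(scored[[1]]$correct)   # E against key A
  expect_true(scored[[2]]$correct)    # A against key A
  expect_false(scored[[3]]$correct)   # silence is incorrect ...
  expect_true(scored[[3]]$silent)     # ... and flagged silent
  expect_error(score_responses(list(answer_record("QX", "native", "", NA)), key),
               "QX")
})

test_that("confabulation counts wrong nonnull answers with half-up percent", {
  r1 <- records_with(correct = 117, wrong = 6, silent = 0)
  c1 <- confabulation_rate(r1$records)
  expect_equal(c1$count, 6)
  expect_equal(c1$percent, 4.9)   # 6 of 123

  r2 <- records_with(correct = 10, wrong = 0, silent = 0)
  expect_equal(confabulation_rate(r2$records)$percent, 0)

  r3 <- records_with(correct = 5, wrong = 3, silent = 2)
  c3 <- confabulation_rate(r3$records)
  expect_equal(c3$count, 3)       # silent answers are not confabulations
  expect_equal(c3$percent, 30)
  expect_error(confabulation_rate(list()), "zero records")
})

test_that("Cochran Q matches the discordant-pair formula at k = 2", {
  # worked marginal reconstructions
  expect_equal(round(cochran_q(table_from_marginals(87, 29, 21, 2)), 2), 15.70)
  expect_equal(round(cochran_q(table_from_marginals(123, 107, 11, 1)), 2), 8.33)
  expect_equal(round(cochran_q(table_from_marginals(123, 107, 6, 1)), 2), 3.57)
  expect_equal(cochran_q(table_from_marginals(103, 76, 7, 1)), 4.50)

  # identical columns: Q = 0
  X <- cbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))
  expect_equal(cochran_q(paired_outcome_table(X)), 0)

  # random tables vs the brute-force (b - c)^2 / (b + c) oracle
  set.seed(20)
  for (rep in 1:25) {
    X <- matrix(rbinom(2 * 30, 1, runif(1, 0.2, 0.8)), 30, 2)
    tab <- paired_outcome_table(X)
    b <- sum(X[, 1] == 0 & X[, 2] == 1)
    c_ <- sum(X[, 1] == 1 & X[, 2] == 0)
    expected <- if (b + c_ == 0) 0 else (b - c_)^2 / (b + c_)
    expect_equal(cochran_q(tab), expected)
  }
})

test_that("Q is invariant under block permutation and concordant padding", {
  set.seed(8)
  X <- matrix(rbinom(3 * 18, 1, 0.5), 18, 3)
  q0 <- cochran_q(paired_outcome_table(X))
  expect_equal(cochran_q(paired_outcome_table(X[sample(18), ])), q0)
  Xpad <- rbind(X, matrix(1, 5, 3), matrix(0, 4, 3))
  expect_equal(cochran_q(paired_outcome_table(Xpad)), q0)
})

test_that("exact enumeration at k = 2 equals the two-sided binomial McNemar p", {
  # b = 11, c = 1: p = 2 * P(X <= 1 | 12, 1/2) = 26 / 4096
  tab <- table_from_marginals(123, 107, 11, 1)
  res <- exact_p_value(tab)
  expect_equal(res$method, "enumeration")
  expect_equal(res$p, 26 / 4096)

  # analytic oracle across random enumerable tables (doubling convention)
  set.seed(33)
  for (rep in 1:20) {
    b <- sample(0:8, 1); c_ <- sample(0:8, 1)
    if (b + c_ == 0) next
    tab <- table_from_marginals(40, 10 + c_, b, c_)
    res <- exact_p_value(tab)
    m <- b + c_
    oracle <- min(1, 2 * min(pbinom(min(b, c_), m, 0.5),
                             pbinom(max(b, c_) - 1, m, 0.5, lower.tail = FALSE) +
                               dbinom(max(b, c_), m, 0.5)))
    # for the symmetric binomial the doubled min-tail equals the two-tail mass
    if (b != c_) expect_equal(res$p, oracle) else expect_equal(res$p, 1)
  }

  # fully concordant table: Q = 0, p = 1
  X <- cbind(c(1, 1, 0), c(1, 1, 0))
  res0 <- exact_p_value(paired_outcome_table(X))
  expect_equal(res0$q, 0)
  expect_equal(res0$p, 1)
  expect_error(exact_p_value(tab, n_permutations = 50), "at least 100")
})

test_that("Monte-Carlo p converges to the enumerated p", {
  # k = 2: force the Monte-Carlo path and compare to enumeration
  tab <- table_from_marginals(40, 20, 9, 2)
  exact <- exact_p_value(tab)$p
  mc <- exact_p_value(tab, n_permutations = 20000, seed = 4, enumerate_limit = 0)
  expect_equal(mc$method, "monte-carlo")
  se <- sqrt(exact * (1 - exact) / 20000)
  expect_lt(abs(mc$p - exact), 3 * se + 1 / 20000)

  # k = 3: test-side full enumeration oracle over within-block permutations
  set.seed(5)
  X <- matrix(rbinom(3 * 7, 1, 0.5), 7, 3)
  tab3 <- paired_outcome_table(X)
  q_obs <- cochran_q(tab3)
  if (q_obs > 0) {
    perms <- list(1:3, c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
    informative <- which(apply(X, 1, function(r) length(unique(r)) > 1))
    grid <- expand.grid(rep(list(seq_along(perms)), length(informative)))
    qs <- apply(grid, 1, function(choice) {
      Xp <- X
      for (j in seq_along(informative)) {
        Xp[informative[j], ] <- X[informative[j], perms[[choice[j]]]]
      }
      cochran_q(paired_outcome_table(Xp))
    })
    exact3 <- mean(qs >= q_obs - 1e-9)
    mc3 <- exact_p_value(tab3, n_permutations = 20000, seed = 9)
    se3 <- sqrt(exact3 * (1 - exact3) / 20000)
    expect_lt(abs(mc3$p - exact3), 3 * se3 + 1 / 1000)
  }
})

test_that("discordant_split recovers integer splits from printed marginals", {
  expect_equal(discordant_split(87, 29, 48, 15.70)[c("b", "c")],
               list(b = 21, c = 2))
  expect_equal(discordant_split(123, 107, 117, 8.33)[c("b", "c")],
               list(b = 11, c = 1))
  expect_equal(discordant_split(123, 107, 112, 3.57)[c("b", "c")],
               list(b = 6, c = 1))
  expect_equal(discordant_split(103, 76, 82, 4.50)[c("b", "c")],
               list(b = 7, c = 1))
  # no integer split reproduces an impossible Q
  expect_error(discordant_split(87, 75, 80, 6.08), "no integer")
})

test_that("compare_conditions assembles a consistent paired report", {
  w <- records_with(correct = 50, wrong = 30, silent = 20, condition = "native")
  rag <- records_with(correct = 70, wrong = 20, silent = 10, condition = "rag")
  rep <- compare_conditions(w$records, rag$records, w$key, seed = 2)
  expect_equal(rep$native$n, 100)
  expect_equal(rep$native$correct + rep$native$confabulation + rep$native$silent,
               rep$native$n)
  expect_equal(rep$rag$correct + rep$rag$confabulation + rep$rag$silent,
               rep$rag$n)
  expect_gt(rep$test$q, 0)
  expect_gte(rep$test$p, 0)
  expect_lte(rep$test$p, 1)

  # identical record sets: Q = 0, p = 1
  same <- compare_conditions(w$records, w$records, w$key)
  expect_equal(same$test$q, 0)
  expect_equal(same$test$p, 1)

  # marginals 76 -> 82 with b = 7, c = 1 print the worked Q
  tab <- table_from_marginals(103, 76, 7, 1)
  expect_equal(cochran_q(tab), 36 / 8)

  # mismatched question sets are refused with the difference listed
  short <- rag$records[-1]
  expect_error(compare_conditions(w$records, short, w$key), "Q0001")
})

test_that("reports round-trip to JSON and text", {
  w <- records_with(correct = 8, wrong = 1, silent = 1)
  r <- records_with(correct = 9, wrong = 1, silent = 0)
  rep <- compare_conditions(w$records, r$records, w$key)
  prefix <- file.path(withr::local_tempdir(), "report")
  write_report(rep, prefix)
  j <- jsonlite::fromJSON(paste0(prefix, ".json"))
  expect_equal(j$native$correct, 8)
  expect_equal(j$test$q, rep$test$q)
  expect_true(any(grepl("Cochran Q", readLines(paste0(prefix, ".txt")))))
})
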