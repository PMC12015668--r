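#' Round half away from zero
#'
#' Percent values in reports are rounded half-up to match the convention of
#' printed exam tables (base `round()` rounds half to even).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Paired binary outcome table
#'
#' Blocks are questions; conditions are treatments (e.g. native vs RAG);
#' entries are 1 for a correct answer. The table must be complete: every
#' block has an outcome under every condition.
#'
#' @param outcomes Numeric/logical matrix, blocks x conditions, entries 0/1.
#' @param blocks Optional block (question) ids; defaults to rownames or 1..n.
#' @param conditions Optional condition labels; defaults to colnames.
#' @return An object of class `paired_outcome_table`.
#' @export
paired_outcome_table <- function(outcomes, blocks = NULL, conditions = NULL) {
  outcomes <- as.matrix(outcomes) * 1
  if (ncol(outcomes) < 2) stop("need k >= 2 conditions")
  if (anyNA(outcomes) || !all(outcomes %in% c(0, 1))) {
    stop("outcomes must be a complete 0/1 matrix")
  }
  if (is.null(blocks)) blocks <- rownames(outcomes)
  if (is.null(blocks)) blocks <- as.character(seq_len(nrow(outcomes)))
  if (is.null(conditions)) conditions <- colnames(outcomes)
  if (is.null(conditions)) conditions <- paste0("cond", seq_len(ncol(outcomes)))
  dimnames(outcomes) <- list(blocks, conditions)
  structure(list(outcomes = outcomes, blocks = blocks,
                 conditions = conditions),
            class = "paired_outcome_table")
}

#' Cochran Q statistic
#'
#' The standard Q for k matched binary treatments over b blocks:
#' `Q = k (k - 1) * sum_j (C_j - N/k)^2 / (k N - sum_i R_i^2)` with column
#' totals C_j, row totals R_i, grand total N. Blocks with all-equal outcomes
#' contribute nothing. For k = 2 this is exactly the McNemar statistic
#' `(b - c)^2 / (b + c)` over the discordant counts b, c. A fully concordant
#' table has Q = 0 by convention.
#'
#' @param table A [paired_outcome_table()].
#' @return A single numeric Q >= 0.
#' @export
cochran_q <- function(table) {
  stopifnot(inherits(table, "paired_outcome_table"))
  X <- table$outcomes
  k <- ncol(X)
  Cj <- colSums(X)
  Ri <- rowSums(X)
  N <- sum(X)
  denom <- k * N - sum(Ri^2)
  if (denom == 0) return(0)
  k * (k - 1) * sum((Cj - N / k)^2) / denom
}

#' Exact p-value for the Cochran Q test
#'
#' Conditional permutation test: within each block the outcomes are permuted
#' across conditions (the block totals are fixed), and p is the proportion of
#' permuted tables with Q >= the observed Q, observed included. Blocks with
#' all-equal outcomes are invariant and skipped. For k = 2 with at most
#' `enumerate_limit` discordant blocks the null is enumerated in closed form
#' (each discordant block flips independently with probability 1/2), which
#' equals the exact two-sided binomial McNemar p (doubling convention
#' `min(1, 2 * min-tail)` — identical here because the Binomial(m, 1/2) null
#' is symmetric). Otherwise a seeded Monte-Carlo permutation sample is used.
#'
#' @param table A [paired_outcome_table()].
#' @param n_permutations Monte-Carlo sample size (>= 100).
#' @param seed RNG seed for the Monte-Carlo path.
#' @param enumerate_limit Enumerate exactly when k = 2 and the number of
#'   discordant blocks is at most this.
#' @return List with `p`, `q`, `method` ("enumeration" or "monte-carlo"),
#'   `n_permutations` (NA for enumeration), `seed`.
#' @export
exact_p_value <- function(table, n_permutations = 10000, seed = 1,
                          enumerate_limit = 20) {
  stopifnot(inherits(table, "paired_outcome_table"))
  if (n_permutations < 100) stop("n_permutations must be at least 100")
  X <- table$outcomes
  k <- ncol(X)
  q_obs <- cochran_q(table)
  if (q_obs == 0) {
    return(list(p = 1, q = 0, method = "enumeration",
                n_permutations = NA_integer_, seed = seed))
  }
  informative <- which(apply(X, 1, function(r) length(unique(r)) > 1))

  if (k == 2) {
    b <- sum(X[, 1] == 1 & X[, 2] == 0)
    c_ <- sum(X[, 1] == 0 & X[, 2] == 1)
    m <- b + c_
    if (m <= enumerate_limit) {
      # Q under flips depends only on x = #blocks assigned (1,0):
      # Q(x) = (2x - m)^2 / m; null x ~ Binomial(m, 1/2)
      x <- 0:m
      p <- sum(stats::dbinom(x, m, 0.5)[(2 * x - m)^2 >= (b - c_)^2 - 1e-9])
      return(list(p = min(1, p), q = q_obs, method = "enumeration",
                  n_permutations = NA_integer_, seed = seed))
    }
  }

  local_seed(seed, function() {
    count <- 0L
    Xp <- X
    for (i in seq_len(n_permutations)) {
      for (j in informative) Xp[j, ] <- X[j, sample.int(k)]
      qp <- cochran_q(paired_outcome_table(Xp, table$blocks, table$conditions))
      if (qp >= q_obs - 1e-9) count <- count + 1L
    }
    list(p = (count + 1) / (n_permutations + 1), q = q_obs,
         method = "monte-carlo", n_permutations = n_permutations, seed = seed)
  })
}

#' Score answer records against a gold-standard key
#'
#' Sets `correct` on each record by comparing the parsed letter to the key;
#' a null (silent) letter is incorrect and flagged silent.
#'
#' @param records List of `answer_record`s.
#' @param key Named character vector, question id -> key letter.
#' @return The records with `correct` and `silent` filled in.
#' @export
score_responses <- function(records, key) {
  ids <- vapply(records, `[[`, "", "question_id")
  unknown <- setdiff(ids, names(key))
  if (length(unknown)) {
    stop("question id(s) not in answer key: ", paste(unknown, collapse = ", "))
  }
  lapply(records, function(r) {
    r$silent <- is.na(r$letter)
    r$correct <- !r$silent && identical(r$letter, unname(key[r$question_id]))
    r
  })
}

#' Confabulation count and rate
#'
#' A confabulation is a wrong nonnull answer — the model answered rather
#' than remaining silent, and the answer was wrong. The rate is the count
#' over all records, as a percent rounded half-up to one decimal.
#'
#' @param records Scored `answer_record`s (see [score_responses()]).
#' @return List with `count`, `percent`, `n`.
#' @export
confabulation_rate <- function(records) {
  n <- length(records)
  if (n == 0) stop("confabulation rate undefined for zero records")
  if (any(vapply(records, function(r) is.na(r$correct) || !is.logical(r$correct),
                 logical(1)))) {
    stop("records must be scored first (see score_responses)")
  }
  count <- sum(vapply(records, function(r) !r$correct && !r$silent, logical(1)))
  list(count = count, percent = round_half_up(100 * count / n, 1), n = n)
}

#' Solve integer discordant counts from marginals and a target Q
#'
#' For a two-condition table with n blocks and a1 -> a2 correct marginals,
#' finds nonnegative integers (b, c) with `b - c = a2 - a1` whose McNemar
#' statistic `(b - c)^2 / (b + c)` matches `q_target` at the printed
#' precision (2 decimals). Used to reconstruct full block tables from
#' published marginal counts.
#'
#' @param n Number of blocks.
#' @param correct1,correct2 Correct counts under conditions 1 and 2.
#' @param q_target Published Q value.
#' @param digits Precision at which Q must match (default 2).
#' @return List with `b` (condition-2-only successes), `c`
#'   (condition-1-only), and the implied exact `q`. Errors when no integer
#'   solution reproduces `q_target`.
#' @export
discordant_split <- function(n, correct1, correct2, q_target, digits = 2) {
  diff <- correct2 - correct1
  m_cand <- seq(abs(diff), n, by = 2)
  m_cand <- m_cand[m_cand > 0]
  ok <- NULL
  for (m in m_cand) {
    b <- (m + diff) / 2
    c_ <- (m - diff) / 2
    if (b > correct2 || c_ > correct1 || b > n - correct1) next
    q <- diff^2 / m
    if (round_half_up(q, digits) == q_target) { ok <- list(b = b, c = c_, q = q); break }
  }
  if (is.null(ok)) {
    stop(sprintf("no integer discordant split reproduces Q = %.2f for %d -> %d of %d",
                 q_target, correct1, correct2, n))
  }
  ok
}

#' Build a two-condition block table from marginals and a discordant split
#'
#' @param n Number of blocks.
#' @param correct1 Correct count under condition 1.
#' @param b Blocks correct only under condition 2.
#' @param c_ Blocks correct only under condition 1.
#' @param conditions Condition labels.
#' @return A [paired_outcome_table()] with the requested marginals.
#' @export
table_from_marginals <- function(n, correct1, b, c_,
                                 conditions = c("native", "rag")) {
  both <- correct1 - c_
  correct2 <- both + b
  neither <- n - both - b - c_
  if (min(both, neither, b, c_) < 0) stop("infeasible marginals")
  X <- rbind(cbind(rep(1, both), rep(1, both)),
             cbind(rep(0, b), rep(1, b)),
             cbind(rep(1, c_), rep(0, c_)),
             cbind(rep(0, neither), rep(0, neither)))
  colnames(X) <- conditions
  paired_outcome_table(X)
}

#' Compare two conditions over the same questions
#'
#' Scores both record sets, builds the paired outcome table, and computes
#' per-condition correct and confabulation statistics plus the exact Cochran
#' Q test.
#'
#' @param native_records,rag_records Lists of `answer_record`s over the same
#'   question ids.
#' @param key Named character vector, question id -> key letter.
#' @param n_permutations,seed Passed to [exact_p_value()].
#' @return An object of class `eval_report`.
#' @export
compare_conditions <- function(native_records, rag_records, key,
                               n_permutations = 10000, seed = 1) {
  ids_n <- vapply(native_records, `[[`, "", "question_id")
  ids_r <- vapply(rag_records, `[[`, "", "question_id")
  if (!setequal(ids_n, ids_r) || anyDuplicated(ids_n) || anyDuplicated(ids_r)) {
    stop("mismatched question sets; only in native: ",
         paste(setdiff(ids_n, ids_r), collapse = ", "),
         "; only in rag: ", paste(setdiff(ids_r, ids_n), collapse = ", "))
  }
  native_records <- score_responses(native_records, key)
  rag_records <- rag_records[match(ids_n, ids_r)]
  rag_records <- score_responses(rag_records, key)

  per_condition <- function(records) {
    n <- length(records)
    correct <- sum(vapply(records, `[[`, logical(1), "correct"))
    conf <- confabulation_rate(records)
    silent <- sum(vapply(records, `[[`, logical(1), "silent"))
    list(n = n, correct = correct,
         percent_correct = round_half_up(100 * correct / n, 1),
         confabulation = conf$count, percent_confabulation = conf$percent,
         silent = silent)
  }
  outcomes <- cbind(native = vapply(native_records, `[[`, logical(1), "correct"),
                    rag = vapply(rag_records, `[[`, logical(1), "correct"))
  rownames(outcomes) <- ids_n
  tab <- paired_outcome_table(outcomes)
  test <- exact_p_value(tab, n_permutations = n_permutations, seed = seed)
  structure(list(native = per_condition(native_records),
                 rag = per_condition(rag_records),
                 table = tab,
                 test = list(q = cochran_q(tab), p = test$p,
                             method = test$method,
                             n_permutations = test$n_permutations,
                             seed = test$seed)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  fmt <- function(s) sprintf("%3d (%.1f)", s$correct, s$percent_correct)
  fmtc <- function(s) sprintf("%3d (%.1f)", s$confabulation, s$percent_confabulation)
  cat(sprintf("Paired evaluation over %d questions\n", x$native$n))
  cat(sprintf("%-16s %-12s %-12s\n", "", "native", "rag"))
  cat(sprintf("%-16s %-12s %-12s\n", "Correct, n (%)", fmt(x$native), fmt(x$rag)))
  cat(sprintf("%-16s %-12s %-12s\n", "Confab., n (%)", fmtc(x$native), fmtc(x$rag)))
  cat(sprintf("Cochran Q = %.2f, exact P = %s (%s)\n", x$test$q,
              format.pval(x$test$p, digits = 2), x$test$method))
  invisible(x)
}

#' Write an evaluation report as JSON and a plain-text table
#' @param report An `eval_report`.
#' @param prefix Path prefix; writes `<prefix>.json` and `<prefix>.txt`.
#' @return Invisibly `prefix`.
#' @export
write_report <- function(report, prefix) {
  jsonlite::write_json(list(native = report$native, rag = report$rag,
                            test = report$test),
                       paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  txt <- utils::capture.output(print(report))
  con <- file(paste0(prefix, ".txt"), open = "wb")
  writeLines(txt, con, useBytes = TRUE)
  close(con)
  invisible(prefix)
}
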