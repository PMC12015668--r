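# Two-triple graph mirroring the canonical penicillin example: one shared node.
fig_graph <- function() {
  suppressWarnings(knowledge_graph(
    triples = data.frame(
      subject = c("C_PCN", "C_PNA"),
      relation = c("treats", "causal agent"),
      object = c("C_PNA", "C_SP"),
      stringsAsFactors = FALSE),
    concepts = data.frame(
      code = c("C_PCN", "C_PNA", "C_SP"),
      label = c("penicillin", "pneumococcal pneumonia", "S. pneumoniae"),
      semantic_tag = c("substance", "disorder", "organism"),
      stringsAsFactors = FALSE)))
}

# star: center X with three spokes over allow-listed relations
star_graph <- function() {
  knowledge_graph(data.frame(
    subject = c("X", "X", "Y3"),
    relation = c("treats", "causes", "prevents"),
    object = c("Y1", "Y2", "X"),
    stringsAsFactors = FALSE))
}

# two disjoint 5-cliques; walks can never cross between them
clique_pair_graph <- function() {
  mk <- function(prefix, rel) {
    do.call(rbind, lapply(utils::combn(paste0(prefix, 1:5), 2, simplify = FALSE),
                          function(p) data.frame(subject = p[1], relation = rel,
                                                 object = p[2])))
  }
  knowledge_graph(rbind(mk("A", "treats"), mk("B", "causes")))
}

# a deterministically seeded random embedding space
random_space <- function(n = 20, d = 8, seed = 42, method = "walk") {
  set.seed(seed)
  v <- matrix(stats::rnorm(n * d), n, d,
              dimnames = list(sprintf("N%03d", seq_len(n)), NULL))
  embedding_space(method, v, seed = seed)
}

# n scored records with a given composition (correct / wrong nonnull / silent)
records_with <- function(correct, wrong, silent, condition = "native") {
  n <- correct + wrong + silent
  key <- stats::setNames(rep("A", n), sprintf("Q%04d", seq_len(n)))
  letters_ <- c(rep("A", correct), rep("B", wrong), rep(NA_character_, silent))
  recs <- lapply(seq_len(n), function(i) {
    answer_record(names(key)[i], condition,
                  if (is.na(letters_[i])) "no answer" else paste0("(", letters_[i], ")"),
                  letters_[i])
  })
  list(records = score_responses(recs, key), key = key)
}

# exclusion profile of the first exam step's raw download (119 -> 87)
step1_exclusions <- function() {
  c("photograph" = 8, "graph" = 5, "photomicrograph" = 4,
    "multipart answer with directional arrows" = 3, "radiograph" = 2,
    "diagram" = 2, "CT scan" = 1, "MRI" = 1, "Doppler image" = 1,
    "bar graph" = 1, "ultrasonography" = 1,
    "multipart answer not conducive to a text file format" = 3)
}
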