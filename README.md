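# clinrag

Retrieval-augmented generation (RAG) over a clinical semantic-triple
knowledge graph, with a paired evaluation protocol for multiple-choice
medical exams.

## The problem

Large language models answer medical licensing-style questions better when
the prompt carries question-specific, formally represented clinical
knowledge. `clinrag` implements that augmentation pipeline end to end for R:

1. **Knowledge graph** — clinical facts as semantic triples
   *subject–relation–object* over coded concepts (e.g. *penicillin treats
   pneumococcal pneumonia*), stored with a 40-relation registry of which a
   curated allow-list of 13 relation types (causes, diagnoses, treats, has
   adverse reaction, ...) is eligible for context generation.
2. **Concept tagging** — a deterministic lexicon-based tagger maps question
   text to concept codes (greedy longest match over normalized tokens).
3. **Embeddings** — graph embeddings via biased random walks (node2vec-style,
   with return/in-out parameters p, q; p = q = 1 is DeepWalk) and skip-gram
   with negative sampling, plus knowledge-graph embeddings via TransE
   (score `-||v_s + v_r - v_o||`) and RotatE (complex rotation,
   `-||v_s o v_r - v_o||`), with cosine-similarity search
   `S(x, y) = <x, y> / (||x|| ||y||)`.
4. **Retrieval** — question codes are expanded through embedding neighbors,
   incident triples fetched from the graph, filtered by the relation
   allow-list, and verbalized as human-readable sentences
   (`"urinalysis" (procedure) diagnoses "crystalluria" (finding)`) that are
   prepended to the prompt.
5. **Answering** — a pluggable backend contract (any function
   prompt → text); a rule-based mock backend answers from the supplied
   context so the whole pipeline is testable without any language model.
6. **Evaluation** — answers are scored against a key; *confabulation* is a
   wrong nonnull answer (answering instead of staying silent); native vs
   RAG conditions are compared with the exact Cochran Q test with questions
   as blocks (at two conditions, Q reduces to the McNemar statistic
   `(b - c)^2 / (b + c)` over discordant pairs, with an exact conditional
   permutation/enumeration p-value).

Synthetic generators (`generate_kg()`, `generate_exam()`, `make_world()`)
build knowledge graphs, lexicons, and exams with planted answerable facts,
so every stage is exercised end to end offline.

## Worked example

```r
library(clinrag)

w <- make_world(list(n_concepts = 80, n_triples = 300, n_questions = 20),
                seed = 42)
q <- w$questions[[1]]
codes <- extract_codes(q$stem, w$lexicon)
build_context(w$graph, list(), codes, rag_config())
#> <rag_context> 4 sentences (retrieved 7, allow-listed 4)
#>   - "sofen" (body structure) has adverse reaction "hepquimi" (organism)
#>   - "kadixu" (finding) has adverse reaction "sofen" (body structure)
#>   - "tufen mihep" (organism) has adverse reaction "sofen" (body structure)
#>   - "sofen" (body structure) has adverse reaction "fenra" (procedure)

mock <- rule_based_mock(w$knowledge, propensity = 1, seed = 42)
rag <- score_responses(lapply(w$questions, function(q) {
  ctx <- build_context(w$graph, list(), extract_codes(q$stem, w$lexicon),
                       rag_config())
  ask(mock, build_prompt(q, ctx))
}), w$key)
native <- score_responses(lapply(w$questions, function(q) {
  ask(mock, build_prompt(q, NULL))
}), w$key)
compare_conditions(native, rag, w$key, seed = 42)
#> Paired evaluation over 20 questions
#>                  native       rag
#> Correct, n (%)     5 (25.0)    20 (100.0)
#> Confab., n (%)    15 (75.0)     0 (0.0)
#> Cochran Q = 15.00, exact P = 6.1e-05 (enumeration)
```

The mock answers every question whose planted key sentence reaches the
prompt through tagging → retrieval → allow-list filtering → verbalization
(100% under RAG); without context it guesses at chance over five choices
(25% here) and every wrong guess is a confabulation. The exact Cochran Q
test over the 20 question blocks rejects the hypothesis that the two
conditions perform equally.

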