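---
title: "Methods: knowledge-graph RAG for clinical question answering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-graph RAG for clinical question answering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clinrag)
```

## The pipeline and its assumptions

`clinrag` augments a multiple-choice answer backend with clinical knowledge
drawn from a semantic-triple knowledge graph. The pipeline assumes that

* clinical knowledge worth injecting can be expressed as atomic
  subject–relation–object triples over coded concepts;
* one adjacency hop from the concepts mentioned in a question (optionally
  widened by embedding-similarity neighbors) reaches the facts needed to
  answer it — retrieval is deliberately single-hop;
* not all relation types carry answer-relevant knowledge: a fixed
  allow-list of 13 of the 40 registered relation types (causes, clinical
  course of, definitional manifestation of, diagnoses, finding method of,
  has adverse reaction, has contraindication, has indication, occurs in,
  pathological process of, predisposes, prevents, treats) is eligible for
  context generation, which both bounds prompt size and concentrates it on
  clinically assertive content. The registry ships with per-relation corpus
  frequency hints; these printed counts are stored verbatim even though
  their published totals do not reconcile exactly with the column sums, and
  the package makes no attempt to repair them.

The concept tagger is an explicitly reduced stand-in for a full clinical
NLP system: a deterministic dictionary tagger (greedy left-to-right longest
match over case/punctuation-normalized tokens, matches anchored at token
boundaries so "men" never fires inside "abdomen"). The pipeline contract
only needs a set of concept codes per question; syntactic parsing, inexact
matching and disambiguation are out of scope, and an ambiguous lexicon
(one term, two codes) fails fast at build time because no principled
disambiguation rule is available. Span offsets are 0-based half-open
throughout.

## Embedding models

Two families are trained over the same graph:

* **Walk-based graph embeddings.** Triples are deconstructed into
  (code, relation) pairs — optionally joined by sentence co-occurrence
  pairs — forming an undirected pair graph that includes relation names as
  nodes. Second-order biased random walks follow the node2vec scheme
  (return parameter `p`, in-out parameter `q`; `p = q = 1` reduces exactly
  to DeepWalk's uniform walks, a property the tests check with a chi-square
  test on next-step frequencies). Skip-gram with negative sampling (noise
  distribution: unigram^0.75) embeds the walk corpus. Whether pair types
  should be embedded jointly or separately is not settled; the package
  embeds them jointly in one pair graph, which is the simpler choice and
  keeps one vector space per method.
* **Knowledge-graph embeddings.** TransE scores a triple as
  `-||v_s + v_r - v_o||` (invariant under any global translation of the
  entity space); RotatE represents entities as complex vectors and
  relations as unit-modulus phase rotations, scoring
  `-||v_s o v_r - v_o||`, which preserves entity norms. Both train with a
  margin-based ranking loss and uniform negative sampling (corrupt head or
  tail with probability 1/2). Uniform corruption is the simplest published
  variant; self-adversarial sampling is deliberately not used. RotatE
  phases are parameterized as angles, so unit modulus holds by
  construction (validated at 1e-6 when spaces are built from raw complex
  matrices).

All training is plain single-threaded SGD with a fixed learning rate and a
recorded seed, so every space is reproducible bit for bit. TransE entity
vectors are re-normalized to unit length after each update (the classic
recipe); a small epsilon (1e-12) guards distance gradients at zero.
Cosine similarity is the standard `<x, y> / (||x|| ||y||)` and is an error
for zero vectors rather than a silent 0. Nearest-neighbor search is an
exhaustive scan with lexicographic tie-breaking — correctness over speed at
package scale, and the semantics the tests can verify exactly against a
brute-force oracle.

The default dimensionality is `d = 512`, the sweep's upper point, which was
the strongest setting in the motivating evaluations; 128 and 256 are
supported, and the test suite exercises the clique-separation property at
two dimensions. Tests and examples use much smaller `d` where the property
under test does not depend on it.

## Retrieval and prompt assembly

`build_context()` runs: expand question codes by top-`k` cosine neighbors
per embedding space (union over spaces, seeds kept first) → fetch all
incident triples → keep allow-listed relations → verbalize → deduplicate →
truncate. Where several embedding methods are available their neighbor
sets are combined by union; no combination rule is prescribed by the
method's sources, so the union — the most permissive deterministic choice —
is used and documented here. Defaults `k = 5` neighbors per seed per space
and a `cap = 40` sentences keep prompts within typical backend input
limits; both are configurable and no claim is made that these values are
optimal. Truncation keeps triples incident to a seed (question) code ahead
of neighbor-only triples, on the reasoning that question-specific knowledge
is the point of the exercise. The verbalization template is
`"<subject label>" (<tag>) <relation> "<object label>" (<tag>)`, with the
parenthesized tag omitted for untagged concepts. Prompt layout (context
block, stem, lettered choices, one instruction line) is versioned by a
template id so that future layouts do not silently change archived runs.

## The mock backend and answer parsing

The rule-based mock makes the pipeline testable with no model: registered
with each question's stem, key sentence (the verbalized planted triple)
and key letter, it answers the key letter whenever the prompt contains the
key sentence. When the key sentence is absent it guesses a uniformly
random letter with probability `propensity` (c) and stays silent
otherwise. The guess is uniform over *all* letters, not just wrong ones:
an uninformed test-taker is right by chance 1/k of the time, which makes
the native condition land at chance level and makes wrong nonnull guesses
— confabulations — arise naturally at rate c·(k−1)/k. Guesses are seeded
per question id, so the mock is a pure function of the prompt.

`parse_answer()` extracts the asserted letter with a fixed precedence: an
explicit "answer ..." cue, then the first parenthesized letter, then
"option X", then a bare standalone capital. These rules are artifact-level
conventions (human adjudication of ambiguous responses cannot be encoded);
anything that asserts no valid letter is silence (`NA`), never an error.

## Evaluation statistics

Correctness is scored against the key; silence is incorrect (it is not a
correct answer) and additionally flagged, since confabulation — the error
metric — counts only *wrong nonnull* answers. Percentages are rounded half
away from zero to one decimal, matching the typography of printed exam
tables.

The paired test is the Cochran Q over question blocks (questions vary in
difficulty, so blocking on them is essential); at two conditions Q equals
the McNemar statistic `(b - c)^2 / (b + c)` over discordant pairs, and a
fully concordant table is defined as Q = 0 with p = 1. The "exact" p-value
is a conditional within-block permutation test: at k = 2 with at most 20
discordant blocks the Binomial(m, 1/2) null is enumerated in closed form,
which coincides with the exact two-sided binomial McNemar p under the
doubling convention `min(1, 2·min-tail)` (the two agree because the null
is symmetric — stated explicitly since two-sided conventions differ);
otherwise a seeded Monte-Carlo permutation sample is drawn with the
add-one estimator `(1 + #{Q* >= Q}) / (1 + B)`. Published Q values can be
reproduced from marginal correct counts alone by solving
`(b - c)^2 / (b + c) = Q` for integer discordant counts
(`discordant_split()`); not every printed Q admits such a solution, and
the package refuses rather than approximates when none exists.

## The synthetic world

`make_world()` emulates the study's data conditions without licensed
content: a knowledge graph whose relation mix follows the registry's
printed corpus frequencies (so "isa" dominates and roughly 39% of triples
are allow-listed), unique pseudoword concept labels (non-English by
construction, so dictionary tagging inside English stems cannot collide),
a lexicon covering every label, and an exam in which each question plants
exactly one allow-listed triple: the stem mentions the subject, the
correct choice is the object's label, and distractors are labels of
concepts not adjacent to the subject (so nothing in the graph entails
them). Defaults are study-sized: 100 questions with 5 choices over 250
concepts and 900 triples — large enough for a 100-block paired test and a
stable chance-level native arm, small enough that the whole closed loop
(tag → expand → retrieve → filter → verbalize → answer → exact test) runs
in seconds on one CPU, which is also the problem size the acceptance
script uses. Link-prediction recovery tests use a 30-entity, 120-triple
graph; walk-embedding community tests use two disjoint 5-cliques.

What the generator does **not** emulate: clinical language (stems are
template sentences, not vignettes), multi-hop reasoning, ambiguous or
overlapping terminology, noisy or contradictory triples, and image-based
questions (excluded by the curation rule engine instead). Passing the
closed loop therefore demonstrates the pipeline's plumbing — retrieval
completeness, filter correctness, statistical machinery — not clinical
performance on real exams or real models.

## Known limitations

* Single-hop retrieval only; facts two hops from any mentioned concept are
  unreachable by design.
* The tagger has no inexact matching; misspelled terms are missed.
* The HTTP backend adapter ships untested (the tested core is model-free);
  timeouts surface as records with null answers, counted as silence.
* Exact enumeration of the permutation null is limited to k = 2; k > 2
  always uses Monte Carlo.
* Conversion of percent-correct scores to scaled 3-digit exam scores is an
  external lookup and is intentionally not implemented.
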