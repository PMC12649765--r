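---
title: "ragcare: methods, parameters and design rationale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ragcare: methods, parameters and design rationale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ragcare)
```

`ragcare` is a desk-scale, fully deterministic implementation of a
retrieval-augmented generation (RAG) pipeline for postoperative
patient-education question answering, together with the evaluation
mathematics used to assess such systems. This vignette explains the model
and its assumptions, the parameters that matter, the numerical choices,
and what the synthetic test corpus does and does not show about real
clinical deployments.

## The pipeline model

The serving path is a conventional RAG loop with two hard gates:

1. **Safety routing** (before any retrieval): escalate, decline, or
   answer.
2. **Retrieval**: approximate nearest-neighbour search over chunk
   embeddings (top 10 by cosine), hybrid re-ranking with BM25, top 3 kept
   as evidence.
3. **Generation**: a pluggable generator drafts an answer from the
   evidence. The default is extractive — it can only emit evidence
   sentences — so hallucination enters only through tampering or a
   swapped-in generative backend, which is exactly what the gates are for.
4. **Gating**: sentence-level grounding verification and a numeral /
   citation heuristic. A rejected draft is replaced by a fixed safe
   handoff message; the pipeline returns a response object for every
   input.

The central modelling assumption is *lexical groundability*: a question
answerable from the knowledge base shares enough vocabulary with the
relevant passage for token-level retrieval and token-level verification to
work. That assumption is appropriate for curated patient handouts, which
are written in controlled vocabulary, and it is what allows every stage to
be deterministic with no model downloads. It fails for strongly
paraphrased or misspelled queries — see Limitations.

## Text primitives

Tokens are lowercased maximal runs of alphanumerics with internal hyphens
and decimal points preserved (`"pain-free"`, `"3.5"`). Sentences split on
terminal punctuation followed by whitespace and a capital or digit, with a
small protected abbreviation list; decimals never split. Both are pure
functions.

The similarity primitive throughout is **fuzzy Jaccard**: unique token
sets are matched greedily in descending normalized edit-distance
similarity (`1 - levenshtein / max(length)`), tokens match at similarity
`>= 0.85`, and the score is matches over the fuzzy union. The 0.85 default
tolerates plural and inflectional variants ("dressings" ~ "dressing",
similarity 0.889) without matching unrelated words; it is exposed in the
config. Greedy pairing is deterministic and near-optimal at sentence
lengths; the test suite checks it against an exact-assignment oracle on
enumerable cases. Two empty sets score 1 and carry a `degenerate` flag.

## Ingestion

Documents are segmented by greedy sentence packing into chunks of at most
500 characters (`chunk_limit`, minimum 100): sentences are appended while
the chunk span stays within budget; a sentence longer than the budget
becomes its own chunk, flagged `overflow`, rather than being split —
sentence integrity is what makes sentence-level grounding well defined. A
blank-line paragraph break forces an early boundary once a chunk is at
least 60% full (`paragraph_fill`), a cheap proxy for layout awareness that
can be disabled. Chunks never overlap; concatenated in order they
reproduce the document body modulo inter-chunk whitespace, and chunk count
is non-increasing in the chunk limit (both property-tested).

## Embeddings and the index

The default embedding backend maps each vocabulary token, via a seeded
polynomial string hash, to a fixed pseudo-random unit vector; a text is
the L2-normalized sum of its token vectors weighted by sublinear term
frequency (`1 + log tf`). Dimension defaults to 768. This backend is a
*contract implementation*, not a semantic model: identical texts embed
identically, token overlap drives cosine similarity, and no network or
model file is touched. Any hosted embedding service can be plugged in
behind the same function contract.

The index is a hierarchical navigable small-world (HNSW) graph implemented
in Rcpp with the standard construction: geometric level assignment with
`mL = 1/ln(M)`, greedy descent through upper layers, beam search with
`efConstruction = 200` during insertion, bidirectional links pruned to `M`
per layer (`2M` at layer 0). Defaults `M = 32`, `ef_search = 100`
(`ef_search` must be at least `k`; 100 comfortably exceeds the serving
`k = 10`). Insertion order is fixed by sorting chunk ids, and the level
RNG is seeded from the config, so index construction is reproducible. On
corpora up to a few hundred chunks with `ef_search` at corpus size the
search is exact; recall@10 against brute-force k-NN exceeds 0.95 on 1,000
random unit vectors (tested).

## Hybrid retrieval

BM25 is the Okapi form with `k1 = 1.5`, `b = 0.75` (the canonical
defaults) and `IDF(t) = ln((N - df + 0.5)/(df + 0.5) + 1)`, statistics
precomputed over the whole chunk corpus. Re-ranking happens only over the
10 ANN candidates. Because cosine and BM25 live on different scales, both
are min-max normalized *within the candidate set* before the convex
fusion `alpha * dense + (1 - alpha) * bm25` with `alpha = 0.5`; this makes
the ranking invariant to affine rescaling of raw BM25 scores. Constant
score vectors normalize to 0.5 (no ordering information). Ties break
lexicographically by chunk id. `alpha = 1` and `alpha = 0` reduce exactly
to pure dense and pure BM25 rankings. The full 10-candidate trace is kept
on every evidence set for auditing.

## Generation and gating

The prompt renders a fixed role instruction, the question, and the three
evidence passages tagged with their chunk ids; if the render exceeds the
context budget (6,000 characters) evidence is truncated from rank 3
upward and flagged. The extractive generator scores each evidence sentence
by fuzzy Jaccard against the question, keeps those above a low floor
(0.05), takes the best five, and emits them in evidence-rank-then-position
order.

**Grounding verification** scores each draft sentence as its maximum fuzzy
Jaccard against the *sentences* of the evidence (the sentence, not the
whole chunk, is the grounding unit — a sentence compared to a whole
300-character chunk under symmetric Jaccard could never reach a meaningful
threshold, and a verbatim-copied evidence sentence should score exactly
1). The draft is accepted only if *all* sentences reach the threshold
(default 0.35); the all-sentences rule is deliberately conservative —
one ungrounded sentence rejects the whole draft. Raising the threshold can
only move drafts from accepted to rejected (monotonicity, property-tested).

**Heuristic validation** extracts numerals (commas stripped, trailing
fractional zeros removed) and requires each draft numeral to occur in the
evidence. Comparison is literal by design: "2 weeks" does not match
"14 days", because a unit conversion layer would silently endorse
fabricated conversions; mismatches are flagged for review instead.
Bracketed citation numbers and "et al." without an evidence counterpart
are flagged likewise.

Gate failures produce the configured fallback handoff text rather than a
retry loop; regeneration policies belong to the generator adapter, not the
safety layer.

## Safety routing

Escalation detection is a reviewable phrase lexicon (categories:
breathing difficulty, uncontrolled bleeding, chest pain, high fever, loss
of consciousness, spreading infection, calf swelling) matched over tokens
with the same 0.85 fuzzy tolerance. A safety gate must be deterministic
and auditable, which rules out learned classifiers here.

Out-of-scope detection combines two independent signals and declines only
on their conjunction: (1) **scope affinity** below a floor, and (2) no
medical-lexicon token present. The conjunction biases toward answering —
wrongly declining a medical question is safer than fabricating, but worse
than answering with grounded content. Scope affinity is the number of
*informative* query tokens that co-occur (fuzzily) in a single
knowledge-base chunk, where informative means: not a stopword, and not
matching only vocabulary present in more than 40% of chunks
(document-frequency filtering removes timing words like "week" that are
ubiquitous in recovery handouts and carry no topical signal). Counting
co-occurrence within one chunk, rather than across the whole base,
separates topically anchored questions from queries sharing only scattered
everyday words. An early design used the best dense cosine of a
stopword-filtered query embedding; measurement on the synthetic corpus
showed the hashed embedding's function-word mass made the two classes
inseparable, and the count-based signal replaced it. The floor ships at 2,
the value produced by the prescribed calibration (5th percentile of
in-scope affinities on the synthetic corpus, `calibrate_scope_floor()`).

Routing precedence is total and fixed: escalate over decline over answer.

## The synthetic corpus

The generator emulates the *structure* of a clinical evaluation corpus:

* a 20-topic knowledge base of authored patient-handout documents
  (1,100+ characters each, so every document yields at least two serving
  chunks), whose facts carry explicit numerals to exercise the numeric
  gate;
* 250 base queries — 10 in-scope per topic (200), 40 non-medical
  (finance, travel booking, entertainment, tech support), 10 escalation
  scenarios built from the red-flag lexicon — each with two rule-based
  paraphrase variants (register-shift framing plus word-level synonym
  substitution; clause reordering is realized only as frame-level
  preposing, since label-blind reordering could break red-flag phrases),
  for exactly 600/120/30 = 750 queries. Category totals are a hard
  construction constraint, never sampled.

Two corpus-design policies are part of the generator's contract. Every
in-scope gold passage is a sentence present verbatim in the knowledge base
(groundability by construction), and every authored question shares at
least two informative tokens with its gold fact — a question must be
lexically anchored to the base to be answerable by a lexical retrieval
stack at all. Out-of-scope queries contain no medical-lexicon token and no
topic vocabulary; escalation queries contain at least one red-flag phrase.
All three properties are asserted by tests.

The knowledge-base facts themselves are fixed authored constants — the
seed drives paraphrase-frame selection and rating simulation, not the
clinical content — so `generate_kb()` is byte-identical across seeds by
construction.

The rating simulator draws a per-item consensus truth (correct with
probability 0.98), makes reviewer triples unanimous except for a 2%
two-vs-one split rate, and draws completeness/consistency/SSI scores from
truncated discrete distributions with means 4.83, 4.49 and 2.68. These
values parameterize the *simulator*; reliability coefficients computed
downstream characterize the simulator's agreement structure, not any
published human review. The SSI rubric is scored as gated cumulative
dimensions (sensible +1; if sensible, specific +1; if specific,
interesting +1).

What passing tests on this corpus shows: the routing, gating, retrieval
and metric layers behave exactly as specified on structurally faithful
inputs. What it does not show: performance on real patient language —
misspellings, dialect, ambiguity, and semantic paraphrase beyond shared
vocabulary are all absent by design.

## Evaluation mathematics

Confusion-matrix metrics are micro-averaged over the 250 base queries
(actual positive = in-scope; predicted positive = delivered; a true
positive additionally requires reviewer-consensus correctness). Precision
with `tp + fp = 0` is reported as an explicit undefined flag, never as 0
or 1. For accuracy and recall both Wald and Wilson 95% intervals are
reported, because the two constructions differ materially near p = 1 and
neither is canonical; the method is recorded per report.

Topic accuracy is the unweighted mean over 22 domains (20 topics plus the
out-of-scope and escalation classes) with sample SD (n - 1) and range.

The reliability suite implements Fleiss' kappa (category-count form),
pairwise Cohen's kappa, Krippendorff's alpha via the coincidence matrix
(nominal 0/1 distance; ordinal cumulative-margin squared distance;
missing ratings allowed), and two-way random-effects ICC from the ANOVA
mean squares:

```
ICC(2,1) = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE)/n)
ICC(2,k) = (MSR - MSE) / (MSR + (MSC - MSE)/n)
```

Degenerate inputs (zero expected disagreement) yield explicit undefined
flags. One cross-estimator note: two-rater Fleiss' kappa is Scott's pi,
which equals Cohen's kappa only under matched rater marginals; the test
suite checks the equality on matched-marginal data and the
Fleiss-Krippendorff convergence on large balanced data (tolerance 0.02).

Groundedness uses a two-stage hybrid evaluation retriever deliberately
distinct from the serving path: the knowledge base is re-chunked at 300
*words*, stage 1 takes the dense top-2k with maximal-marginal-relevance
diversification (`MMR(d) = lambda sim(q,d) - (1-lambda) max_{d' in S}
sim(d,d')`, `lambda = 0.7`, k = 4), stage 2 unions the BM25 top-2k, and
the union is fused and cut to k. The three metrics share the sentence as
the unit of support at threshold `tau_support = 0.35` (same family as the
serving grounding threshold, independently configurable): context
precision is the fraction of retrieved chunks with at least one sentence
supporting a gold sentence; context recall the fraction of gold sentences
supported; faithfulness the fraction of answer sentences supported, with
hallucination rate its complement. Batch metrics are means of item
metrics (conservation, tested).

Fluency: BLEU with orders 1-4, uniform weights, brevity penalty, and
add-one smoothing on orders >= 2 so short texts do not zero out (identity
still scores exactly 1, disjoint pairs exactly 0); ROUGE-1/2 as clipped
n-gram F1; ROUGE-L as LCS-based F1. The BERTScore slot is filled by a
greedy token-embedding matching on the hashed backend and is reported as
`bertscore_hash_f1` — explicitly not comparable to published BERTScore
values; it is an adapter slot for a real contextual model.

Readability: syllables by vowel-group counting with a silent-e rule and a
small exception table; `FKGL = 0.39 w/s + 11.8 syl/w - 15.59`;
`FRE = 206.835 - 1.015 w/s - 84.6 syl/w`; reading-level bins at FKGL 12
and 16 (at or below high school; college; college graduate), a
conventional 3-bin split of US grade levels. Lexical diversity is unique
over total tokens; the punctuation ratio is punctuation characters over
all characters.

## Problem sizes and determinism

The shipped study conditions are the full synthetic corpus: 20 documents
(~60 serving chunks), 750 queries end-to-end, 250 rated items, plus a
1,000-vector recall study for the index and a 500-item simulation for ICC
parameter recovery. A complete pipeline run takes about a minute on one
core; two runs from the same configuration produce byte-identical
answers, routes and reports, which the acceptance suite asserts file by
file. All randomness (paraphrase framing, rating simulation, HNSW levels,
token-vector hashing) derives from the single config seed, and the global
RNG state is restored around every internal draw.

## Known limitations

* Lexical-only semantics: synonym-heavy or misspelled queries defeat both
  retrieval and scope detection; six paraphrased in-scope queries in the
  default corpus already retrieve imperfectly and fall back to the safe
  handoff — visible in the run reports as in-scope `fallback_handoff`
  responses, and an honest reflection of the stack's failure mode.
* The rule-based sentence splitter covers common abbreviations only.
* The numeral gate compares literal values; it cannot detect a fabricated
  numeral that happens to equal some other evidence numeral.
* The escalation lexicon is English-only and phrase-based; paraphrases
  outside its fuzzy reach are not flagged.
* Reliability coefficients on simulated ratings characterize the
  simulator, not human reviewers.
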