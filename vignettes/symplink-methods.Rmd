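---
title: "Methods: hybrid symptom entity linking and NER data engineering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid symptom entity linking and NER data engineering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(symplink)
```

## The problem

Clinical entity linking assigns each annotated symptom mention in a case
report the identifier of a concept in a reference terminology (SNOMED CT
codes here). The search space is large — hundreds of thousands of aliases —
and most concepts sit in the long tail with one or two surface forms, while
mentions vary freely in casing, inflection and word order. Some mentions
name no concept at all; for these the correct answer is the sentinel
`NO_CODE`. The same machinery must work across languages when annotations
are transferred to translated reports.

`symplink` implements a hybrid pipeline that trades these difficulties off
stage by stage, plus the data-engineering scaffolding for the upstream
named-entity recognizer. This vignette records the model, its assumptions,
and the design decisions taken where the procedure left genuine choices
open.

## The linking pipeline

### Stage 1 — normalization and dictionary lookup

`normalize_text()` lowercases, trims, and collapses whitespace runs; it does
**not** strip accents or punctuation, because the dictionary stage is
defined as an exact lowercase match, not a fuzzy one. The knowledge base
(KB) indexes aliases by normalized surface at build time while storing
original casing; normalizing at index time rather than query time makes the
lookup a single hash probe and keeps storage faithful.

A surface can legitimately carry several codes (a term can denote both a
clinical finding and a morphologic abnormality). Rather than returning an
arbitrary code, `dictionary_lookup()` resolves ambiguity by a fixed
priority: aliases observed in the training annotations, then gazetteer main
terms, then the lexicographically smallest code, and flags the decision
`ambiguous`. The priority is a package convention: corpus-observed codes are
the best available evidence, and the final lexicographic tie-break exists
only to make behaviour reproducible.

### Stage 2 — embedding retrieval

Mentions missing from the dictionary are scored against every KB alias by
cosine similarity of text embeddings. The encoder is pluggable behind a
small contract (`dim`, deterministic `embed()` returning unit rows); a
production deployment would plug in a cross-lingual biomedical encoder,
while the shipped `hash_embedder()` — character n-gram hashing into `dim`
buckets, counts L2-normalized — keeps every test offline and deterministic.
Defaults `n = 3`, `dim = 256` were chosen once so that the synthetic
concepts' stems separate cleanly; both are arguments. Two caveats follow
from hashing: bucket collisions can give unrelated texts a small positive
cosine, so orthogonality is only guaranteed for collision-free n-gram sets;
and the embedder knows nothing about meaning — a green retrieval test
establishes the *mechanics* of ranking, not clinical embedding quality.

Candidates are aliases, not deduplicated codes: several surfaces of one
concept may occupy the top-*k*, which is what a reranker should see.
Rankings sort by score descending with ties broken by code then surface;
scores are rounded at 1e-12 before ordering so that floating-point summation
order cannot flip near-ties between equivalent implementations.

### The sliding-window composite score

Plain cosine struggles with long mentions whose informative part is at the
start. The composite score combines three cosines — full text, leading
window, trailing window — under convex weights that default to
(0.75, 0.17, 0.08). Choices the definition leaves open, fixed here:

* **Windows apply to both mention and alias.** The window is a convention
  about where information lives in a surface form; applying it to one side
  only would compare a truncated mention against a full alias.
* **"75 % of tokens" rounds up**, with a minimum of one token; a one- or
  two-token text is its own head and tail. A small epsilon guards the
  `ceiling()` against floating-point spill.
* **Tokens are whitespace tokens of the normalized text** — the simplest
  rule that is stable across languages in scope.

`grid_search_weights()` re-derives weights by exhaustively scanning the
discretized simplex `{i/N, j/N, (N-i-j)/N}` with `N = round(1/step)`; using
integer grid indices avoids accumulating `0.01` in floating point. The scan
enumerates `w_full` descending, then `w_head` descending, and keeps only
strictly better accuracies, which realizes the tie rule "prefer the largest
`w_full`, then the largest `w_head`" — in particular a fixture already
perfect under plain cosine returns exactly (1, 0, 0). Since (1, 0, 0) is a
grid point, the result can never score below plain cosine on its own
training input.

### Stage 3 — reranking and the NO_CODE fallback

The retrieved candidates, the mention, the source report and one worked
example are rendered into a one-shot prompt (templates ship as editable
files with `{mention}`, `{candidates}`, `{context}`, `{example}`
placeholders). The completion client is pluggable; tests use `mock_client()`
(scripted, or a longest-common-prefix rule). The client's free-text answer
is parsed by normalized exact match against candidate surfaces first, then
candidate codes, first match in rank order winning; an optional lenient
substring pass is off by default because it can only widen matches. An
answer naming no candidate maps to `NO_CODE` — the design treats "the
reranker declined everything" as evidence that the mention has no code,
which is exactly the failure mode plain nearest-neighbour retrieval cannot
express.

Rule-mode mocks receive the mention and candidate table as structured
metadata alongside the prompt. A prompt-string-only contract would force the
mock to parse its own prompt; real adapters simply ignore the metadata.

Translation, when enabled, rewrites **only the retrieval query**: the
dictionary is consulted before translation (mirroring the pipeline order),
and the prompt shows the original mention and source-language report.

### Rare-concept KB augmentation

Concepts with fewer than five aliases gain exactly five new ones, each a
single character edit (uniform insert-or-delete at a uniform position) of a
uniformly chosen existing alias of the same concept. Decisions taken where
the procedure is underdetermined: insertion characters are drawn from the
multiset of characters observed across KB surfaces (keeps the perturbations
language-plausible); exactly one edit per generated alias (keeps them near
the original); duplicate collisions re-draw up to 20 times and then append
random characters until unique; a single-character alias never takes the
deletion branch, so empty surfaces cannot arise. All randomness is governed
by one seed and the output is byte-identical across runs.

## NER data engineering

* **Sentence splitting** is a rule — terminator, whitespace, then an
  uppercase letter or digit, with an abbreviation list — standing behind a
  contract, and any boundary candidate inside an annotated span is
  suppressed: span integrity outranks splitting fidelity. Offsets are
  recorded so each sentence equals its document slice.
* **IOB2 encoding** snaps misaligned mention edges outward to token
  boundaries and counts the snaps rather than dropping mentions; nested or
  overlapping spans are rejected with an error, since IOB2 cannot represent
  them.
* **Binned splits** bin sentences by their longest mention's character
  length. Edges follow the mention-length distribution of the target
  corpus: short < 38, medium 38–90 inclusive on both ends, long > 90;
  mention-free sentences count as length 0 and land in the short bin. Per
  bin, a seeded shuffle takes `floor(0.8 n)` sentences for training.
* **Synonym augmentation** replaces mentions with a different same-code
  synonym under a per-mention Bernoulli draw (per-mention rather than
  per-sentence, so long sentences are not favoured); the default rate of
  0.15 reproduces the ~15 % corpus growth this procedure is meant to
  deliver. Offsets downstream of each replacement shift by the length
  delta, and originals are always retained.
* **Evaluation** micro-averages tp/fp/fn over documents. Strict matching
  requires identical (document, boundaries, label); overlap matching
  requires any character overlap with a same-label gold span. Matching is
  one-to-one and greedy over predictions sorted by position — a documented
  local convention, since challenge scorers differ on one-to-one versus
  many-to-one overlap credit. Every strict match is an overlap match, so
  overlap scores dominate strict scores by construction.

## The synthetic world

The generators state the world the tests run in: concepts with unique
pronounceable stems (so same-concept aliases share n-grams and concepts are
separable under the reference embedder), alias counts drawn from a
distribution with most mass on one or two aliases and a tail to six,
two languages with suffix-variant aliases, and a linking corpus stratified
into exact aliases, single-edit perturbations, and out-of-KB mentions with
gold `NO_CODE`. Stratum sizes are `round(n·rate)` with the remainder exact.

What the synthetic world does **not** model: clinical Spanish morphology,
translation noise, abbreviation-heavy prose, composite mentions mapping to
several codes, and real embedding-space geometry. A green end-to-end test
therefore establishes that the pipeline's plumbing, contracts and
determinism are correct — not that any particular accuracy transfers to a
real corpus, which additionally requires licensed terminology resources, a
trained encoder and a real reranker.

## Numerical and degenerate-input conventions

* Cosine of a zero vector is an error, not 0: a zero vector has no
  direction, and silently scoring it would mask an upstream bug. The empty
  string embeds to a fixed basis vector instead.
* Weight simplex membership is checked at 1e-9; backend unit norms at 1e-6.
* An empty KB is a valid object for building and persistence but a
  validation error for retrieval.
* Corpus linking in lenient mode records and skips a failing mention;
  strict mode aborts with its index.
* Seeds are threaded explicitly (`withr::with_seed`) so no function
  disturbs the caller's RNG state.

## Known limitations

The dictionary resolves ambiguous surfaces by a fixed priority rather than
context; roughly contemporaneous error analyses put such code conflicts at
a few percent of dictionary hits. The reference embedder is a testing
device, not a semantic model. The reranker's parsing is exact-match by
design and will send paraphrased answers to `NO_CODE` unless the lenient
pass is enabled. Nested mentions are rejected rather than encoded. The
token-classification model that produces NER predictions is out of scope;
the tagger contract (`dictionary_tagger()` being the shipped example) is
the integration point for any trained model.
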