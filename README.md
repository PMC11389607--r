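# symplink

`symplink` is an R toolkit for **normalizing symptom mentions in clinical
case reports to SNOMED CT concept codes**, in Spanish and across languages,
together with the data-engineering utilities needed around a span-based
named-entity recognizer. It is aimed at clinical-NLP practitioners who have
mention annotations (document, character offsets, surface form) and a
concept-alias resource (a gazetteer and/or UMLS synonym export) and need a
reproducible, testable linking pipeline.

## The method

Linking is a hybrid, four-stage pipeline. For a mention *m*:

1. **Normalize** — lowercase, trim, collapse whitespace.
2. **Dictionary** — exact match of the normalized mention against a
   knowledge base (KB) of concept aliases; a hit assigns the alias's code
   directly. Surfaces carried by several codes are resolved deterministically
   (training-set aliases > gazetteer main terms > smallest code).
3. **Candidate generation** — on a miss, embed the mention and every KB
   alias with a pluggable text encoder and keep the top *k* = 5 aliases by
   cosine similarity. For long mentions an optional *sliding-window*
   composite score is available:

   `score(m, a) = w_full·cos(E(m), E(a)) + w_head·cos(E(h(m)), E(h(a))) + w_tail·cos(E(t(m)), E(t(a)))`

   where `h(·)`/`t(·)` keep the first/last 75 % of tokens and the weights
   default to (0.75, 0.17, 0.08); `grid_search_weights()` re-derives them on
   labelled data by exhaustive simplex scan.
4. **Reranking** — a pluggable completion client (an LLM in production, a
   deterministic mock in tests) sees the mention, the five candidates and
   the source case report in a one-shot prompt and names the best candidate.
   An answer naming no candidate yields the sentinel `NO_CODE` — the
   pipeline's way of saying "no concept in the terminology applies".

The KB builder merges gazetteer, UMLS and training-set aliases, deduplicates
on (normalized surface, code), and can **augment rare concepts**: every code
with fewer than five aliases receives five synthetic aliases, each one
character-edit away from an existing alias, so long-tail concepts have more
surface to match against.

For NER data engineering the package provides sentence splitting that never
cuts through an annotated span, an IOB2 encoder/decoder, mention-length
binned 80/20 train/validation splits (bins < 38, 38–90, > 90 characters),
synonym-replacement augmentation with exact offset recomputation, and
micro-averaged strict/overlapping span evaluation.

Everything is testable offline: `fixture_spec()` / `make_kb()` /
`make_linking_corpus()` / `make_ner_corpus()` generate synthetic worlds with
the assumed structure (skewed alias counts, exact/perturbed/out-of-KB
mention strata), `hash_embedder()` is a deterministic character-n-gram
embedding backend, and `mock_client()` stands in for the LLM.

## Worked example

```r
library(symplink)
library(tibble)

gazetteer <- tribble(
  ~surface,          ~code,       ~language, ~source,     ~is_main,
  "fiebre",          "386661006", "es",      "gazetteer", TRUE,
  "fiebre alta",     "386661006", "es",      "gazetteer", FALSE,
  "tos",             "49727002",  "es",      "gazetteer", TRUE,
  "dolor abdominal", "21522001",  "es",      "gazetteer", TRUE
)
kb <- build_kb(gazetteer)
kb <- augment_rare_concepts(kb, rarity_threshold = 5, n_new = 5, seed = 1)
kb
#> <knowledge base> 19 aliases, 3 concepts, language: es

mentions <- tibble(
  mention_id = c("m1", "m2", "m3"),
  text       = c("Fiebre", "dolor abdominall", "cefalea intensa"),
  gold_code  = c("386661006", "21522001", "NO_CODE")
)
res <- link_corpus(mentions, kb, hash_embedder(),
  client = mock_client(rule = "longest_prefix"),
  config = link_config(use_reranker = TRUE))
res[, c("mention_id", "text", "code", "stage")]
#> # A tibble: 3 × 4
#>   mention_id text             code      stage
#>   <chr>      <chr>            <chr>     <chr>
#> 1 m1         Fiebre           386661006 dictionary
#> 2 m2         dolor abdominall 21522001  reranked
#> 3 m3         cefalea intensa  49727002  reranked
glance(res)
#> # A tibble: 1 × 7
#>       n skipped n_dictionary n_embedding_top1 n_reranked n_no_code accuracy
#>   <int>   <int>        <int>            <int>      <int>     <int>    <dbl>
#> 1     3       0            1                0          2         0    0.667
```

`m1` is an exact alias (case aside) and never reaches the embedding stage;
each augmented KB now contains perturbed variants, so the typo in `m2` still
retrieves the right concept, endorsed by the mock reranker. `m3` names a
concept absent from the KB: the longest-prefix mock, which always endorses
*some* candidate, links it wrongly — exactly the failure mode the `NO_CODE`
fallback addresses when a real reranker declines all five candidates
(`parse_rerank_response()` then returns `NO_CODE`). The accuracy of 0.667
reflects that deliberate miss.

Result objects have `tidy()`/`glance()` methods and `autoplot()` views
(alias distribution of a KB, per-stage linking outcomes, evaluation bars,
grid-search heatmap). A thin command-line interface over the same functions
ships at `system.file("cli", "symplink.R", package = "symplink")` with
subcommands `build-kb`, `augment-kb`, `link`, `gridsearch-weights`,
`evaluate-linking`, `evaluate-ner`, `generate-fixtures`.

## Acceptance script

`scripts/acceptance.R` regenerates the synthetic world from a seed and runs
the package end to end: KB generation and rare-concept augmentation, corpus
linking with and without the mock reranker, sliding-window weight grid
search, and the binned-split + dictionary-tagger NER evaluation (strict and
overlapping). Run it from the repository root against the installed package:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
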