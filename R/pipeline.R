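#' Configuration of the linking pipeline
#'
#' Bundles the knobs of the four-stage pipeline: dictionary lookup,
#' (optional) mention translation into the KB language, embedding-based
#' candidate generation, and (optional) LLM reranking with [NO_CODE]
#' fallback. Defaults mirror the reference system: five candidates, plain
#' cosine scoring, dictionary enabled, translation and reranking opt-in.
#'
#' @param k Candidates retrieved per mention (>= 1; default 5).
#' @param scorer `"plain"` cosine or `"sliding_window"` composite.
#' @param weights [sliding_window_weights()]; used by the composite scorer.
#' @param frac Window fraction for the composite scorer.
#' @param use_dictionary Consult the exact-match dictionary first.
#' @param use_translation Translate the mention into the KB language before
#'   retrieval (requires a completion client; affects the retrieval query
#'   only).
#' @param use_reranker Hand the candidates to the completion client.
#' @param lenient_parse Passed to [parse_rerank_response()].
#' @param kb_language Language of the knowledge base.
#' @param mention_language Language of the incoming mentions.
#' @param on_error `"abort"` stops corpus linking on a failing mention;
#'   `"skip"` records and drops it.
#' @return A list of class `sympl_link_config`.
#' @export
link_config <- function(k = 5L, scorer = c("plain", "sliding_window"),
                        weights = sliding_window_weights(), frac = 0.75,
                        use_dictionary = TRUE, use_translation = FALSE,
                        use_reranker = FALSE, lenient_parse = FALSE,
                        kb_language = "es", mention_language = "es",
                        on_error = c("abort", "skip")) {
  scorer <- match.arg(scorer)
  on_error <- match.arg(on_error)
  stopifnot(k >= 1L)
  if (scorer == "sliding_window") stopifnot(inherits(weights, "sympl_weights"))
  structure(
    list(
      k = as.integer(k), scorer = scorer, weights = weights, frac = frac,
      use_dictionary = isTRUE(use_dictionary),
      use_translation = isTRUE(use_translation),
      use_reranker = isTRUE(use_reranker),
      lenient_parse = isTRUE(lenient_parse),
      kb_language = kb_language, mention_language = mention_language,
      on_error = on_error
    ),
    class = "sympl_link_config"
  )
}

empty_candidates <- function() {
  tibble(
    rank = integer(), surface = character(), code = character(),
    score = numeric()
  )
}

#' Link a single mention to a concept code
#'
#' Runs the pipeline for one mention. A dictionary hit short-circuits: the
#' embedding backend is never invoked (observable through
#' [embedder_calls()]) and the result carries stage `"dictionary"`. On a
#' miss, the mention — optionally translated into the KB language, for the
#' retrieval query only — is scored against every KB alias and the top-k
#' candidates are kept. With the reranker enabled the completion client picks
#' among them ([parse_rerank_response()] decides, stage `"reranked"`, or
#' `"no_code"` when the fallback fires); otherwise the top candidate's code
#' is returned (stage `"embedding_top1"`).
#'
#' @param mention_text The mention surface (non-empty).
#' @param kb A knowledge base.
#' @param backend An embedding backend.
#' @param client A completion client (required for translation/reranking).
#' @param config A [link_config()].
#' @param context_doc Source case-report text, shown to the reranker.
#' @param example One-shot example for the reranking prompt (see
#'   [build_rerank_prompt()]).
#' @param alias_embeddings Optional precomputed [kb_alias_embeddings()].
#' @return A one-row tibble: `text`, `code`, `stage`, `candidates`
#'   (list-column holding the candidate tibble).
#' @export
link_mention <- function(mention_text, kb, backend = hash_embedder(),
                         client = NULL, config = link_config(),
                         context_doc = "", example = NULL,
                         alias_embeddings = NULL) {
  stopifnot(inherits(config, "sympl_link_config"))
  if (!is.character(mention_text) || length(mention_text) != 1L ||
    is.na(mention_text) || normalize_text(mention_text) == "") {
    abort("mention text must be a non-empty string",
      class = "sympl_validation_error"
    )
  }
  if (config$use_dictionary) {
    d <- dictionary_lookup(mention_text, kb)
    if (d$matched) {
      return(tibble(
        text = mention_text, code = d$code, stage = "dictionary",
        candidates = list(empty_candidates())
      ))
    }
  }
  query <- mention_text
  if (config$use_translation &&
    !identical(config$mention_language, config$kb_language)) {
    if (is.null(client)) {
      abort("translation requires a completion client",
        class = "sympl_validation_error"
      )
    }
    prompt <- build_translation_prompt(mention_text, config$mention_language)
    query <- str_trim(client$complete(prompt, meta = list(mention = mention_text)))
    if (normalize_text(query) == "") query <- mention_text
  }
  cands <- top_k_candidates(
    query, kb, backend,
    k = config$k, scorer = config$scorer,
    weights = config$weights, frac = config$frac,
    alias_embeddings = alias_embeddings
  )
  if (config$use_reranker) {
    if (is.null(client)) {
      abort("reranking requires a completion client",
        class = "sympl_validation_error"
      )
    }
    prompt <- build_rerank_prompt(
      mention_text, cands, context_doc, example,
      language = config$mention_language
    )
    resp <- client$complete(prompt, meta = list(mention = query, candidates = cands))
    outcome <- parse_rerank_response(resp, cands, lenient = config$lenient_parse)
    stage <- if (outcome$fallback_triggered) "no_code" else "reranked"
    return(tibble(
      text = mention_text, code = outcome$chosen_code, stage = stage,
      candidates = list(cands)
    ))
  }
  tibble(
    text = mention_text, code = cands$code[[1L]], stage = "embedding_top1",
    candidates = list(cands)
  )
}

#' Link a corpus of mentions
#'
#' Order-preserving application of [link_mention()] over a mention table.
#' Alias embeddings are computed once, lazily, on the first dictionary miss,
#' so a corpus resolved entirely by the dictionary never touches the
#' embedding backend. With `on_error = "skip"` in the config, a failing
#' mention (e.g. empty text) is recorded and dropped instead of aborting the
#' run; the number of skips is attached as attribute `"skipped"` and reported
#' by [generics::glance()].
#'
#' @param mentions A tibble with columns `text`, optionally `mention_id`,
#'   `doc_id`, `gold_code`.
#' @param kb A knowledge base.
#' @param backend An embedding backend.
#' @param client Optional completion client.
#' @param config A [link_config()].
#' @param documents Optional tibble (`doc_id`, `text`) supplying reranker
#'   context.
#' @param example One-shot example for the reranking prompt.
#' @return A tibble of class `sympl_linking`: the input columns plus `code`,
#'   `stage`, `candidates`.
#' @export
link_corpus <- function(mentions, kb, backend = hash_embedder(),
                        client = NULL, config = link_config(),
                        documents = NULL, example = NULL) {
  stopifnot(is.data.frame(mentions), "text" %in% names(mentions))
  # a gold `code` column on the input would collide with the predicted one
  if ("code" %in% names(mentions) && !"gold_code" %in% names(mentions)) {
    mentions <- dplyr::rename(mentions, gold_code = "code")
  }
  clash <- intersect(names(mentions), c("code", "stage", "candidates"))
  if (length(clash) > 0L) {
    abort(
      paste0("mention columns clash with result columns: ", paste(clash, collapse = ", ")),
      class = "sympl_validation_error"
    )
  }
  doc_text <- function(doc_id) {
    if (is.null(documents) || is.null(doc_id) || is.na(doc_id)) {
      return("")
    }
    hit <- documents$text[documents$doc_id == doc_id]
    if (length(hit) == 0L) "" else hit[[1L]]
  }
  ae_cache <- new.env(parent = emptyenv())
  get_ae <- function() {
    if (is.null(ae_cache$ae)) {
      ae_cache$ae <- kb_alias_embeddings(kb, backend, config$scorer, config$frac)
    }
    ae_cache$ae
  }
  needs_embeddings <- function(text) {
    !config$use_dictionary || !dictionary_lookup(text, kb)$matched
  }
  results <- vector("list", nrow(mentions))
  skipped <- 0L
  for (i in seq_len(nrow(mentions))) {
    row <- mentions[i, , drop = FALSE]
    res <- tryCatch(
      {
        ae <- if (needs_embeddings(row$text)) get_ae() else NULL
        link_mention(
          row$text, kb, backend, client, config,
          context_doc = doc_text(if ("doc_id" %in% names(row)) row$doc_id else NULL),
          example = example, alias_embeddings = ae
        )
      },
      sympl_validation_error = function(e) {
        if (config$on_error == "abort") {
          abort(
            paste0("mention ", i, " failed: ", conditionMessage(e)),
            class = "sympl_validation_error"
          )
        }
        warn(paste0("skipping mention ", i, ": ", conditionMessage(e)))
        NULL
      }
    )
    if (is.null(res)) {
      skipped <- skipped + 1L
      next
    }
    extra <- row[setdiff(names(row), "text")]
    results[[i]] <- bind_cols(as_tibble(extra), res)
  }
  out <- bind_rows(results)
  attr(out, "skipped") <- skipped
  class(out) <- c("sympl_linking", class(out))
  out
}

#' Top-1 linking accuracy against gold codes
#'
#' The fraction of mentions whose predicted code equals the gold code. A
#' [NO_CODE] prediction is correct only when the gold code is [NO_CODE].
#'
#' @param results A result table from [link_corpus()] (or any tibble with
#'   `code`, and `gold_code` when `gold` is `NULL`).
#' @param gold Optional named character vector keyed by `mention_id`; by
#'   default the `gold_code` column of `results` is used.
#' @return A number in \[0, 1\].
#' @export
linking_accuracy <- function(results, gold = NULL) {
  stopifnot(is.data.frame(results), "code" %in% names(results))
  if (is.null(gold)) {
    if (!"gold_code" %in% names(results)) {
      abort("no gold codes: supply `gold` or a `gold_code` column",
        class = "sympl_validation_error"
      )
    }
    gold_codes <- results$gold_code
  } else {
    if (!"mention_id" %in% names(results)) {
      abort("`gold` lookup requires a `mention_id` column",
        class = "sympl_validation_error"
      )
    }
    missing <- setdiff(results$mention_id, names(gold))
    if (length(missing) > 0L) {
      abort(
        paste0("missing gold code for mention(s): ", paste(head(missing, 3L), collapse = ", ")),
        class = "sympl_validation_error"
      )
    }
    gold_codes <- unname(gold[results$mention_id])
  }
  if (any(is.na(gold_codes))) {
    abort("gold codes contain NA", class = "sympl_validation_error")
  }
  if (nrow(results) == 0L) {
    return(NaN)
  }
  mean(results$code == gold_codes)
}

#' @exportS3Method generics::glance
glance.sympl_linking <- function(x, ...) {
  stages <- c("dictionary", "embedding_top1", "reranked", "no_code")
  counts <- as.list(setNames(
    vapply(stages, function(s) sum(x$stage == s), integer(1L)),
    paste0("n_", stages)
  ))
  acc <- if ("gold_code" %in% names(x)) linking_accuracy(x) else NA_real_
  as_tibble(c(
    list(n = nrow(x), skipped = attr(x, "skipped") %||% 0L),
    counts, list(accuracy = acc)
  ))
}
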