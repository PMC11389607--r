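#' Default prompt templates
#'
#' Templates are plain text with the named placeholders `{mention}`,
#' `{candidates}`, `{context}`, `{example}` (reranking) and `{mention}`,
#' `{source_language}` (translation). They ship as editable files under
#' `inst/templates/` so deployments can substitute their own wording; these
#' functions read the installed copies.
#'
#' @return A length-one character template.
#' @export
rerank_prompt_template <- function() {
  read_template("rerank_prompt.txt")
}

#' @rdname rerank_prompt_template
#' @export
translation_prompt_template <- function() {
  read_template("translation_prompt.txt")
}

read_template <- function(name) {
  path <- system.file("templates", name, package = "symplink")
  if (path == "") {
    abort(paste0("template not found: ", name), class = "sympl_io_error")
  }
  paste(readLines(path, encoding = "UTF-8", warn = FALSE), collapse = "\n")
}

fill_template <- function(template, values) {
  for (key in names(values)) {
    template <- str_replace_all(
      template, stringr::fixed(paste0("{", key, "}")), values[[key]]
    )
  }
  template
}

render_candidate_block <- function(candidates) {
  paste(
    sprintf("%d. %s (%s)", candidates$rank, candidates$surface, candidates$code),
    collapse = "\n"
  )
}

#' Build the one-shot candidate-reranking prompt
#'
#' Renders the prompt handed to the completion client: the query mention, its
#' retrieved candidates numbered in rank order (surface and code verbatim),
#' the clinical case report the mention came from, and one worked example
#' from the language's training split with its answer. Rendering is
#' deterministic: fixed inputs yield a byte-identical prompt.
#'
#' @param mention Character scalar; the mention to disambiguate.
#' @param candidates Candidate tibble from [top_k_candidates()] (non-empty).
#' @param context_doc Text of the source case report (may be empty).
#' @param one_shot_example A list with elements `mention`, `candidates`
#'   (tibble), `answer` (the correct surface), or `NULL` for no example.
#' @param language Language tag, interpolated into the instructions.
#' @param template Prompt template; defaults to the installed one.
#' @return The rendered prompt (character scalar).
#' @export
build_rerank_prompt <- function(mention, candidates, context_doc = "",
                                one_shot_example = NULL, language = "es",
                                template = rerank_prompt_template()) {
  stopifnot(is.character(mention), length(mention) == 1L)
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    abort("reranking needs at least one candidate",
      class = "sympl_validation_error"
    )
  }
  example <- if (is.null(one_shot_example)) {
    ""
  } else {
    paste0(
      "Example:\nMention: ", one_shot_example$mention, "\nCandidates:\n",
      render_candidate_block(one_shot_example$candidates),
      "\nAnswer: ", one_shot_example$answer, "\n"
    )
  }
  fill_template(template, c(
    mention = mention,
    candidates = render_candidate_block(candidates),
    context = context_doc,
    example = example,
    language = language
  ))
}

#' Build the mention-translation prompt
#'
#' Used when the retrieval knowledge base is Spanish but the mention is not:
#' the mention is translated into Spanish before the embedding search (the
#' dictionary stage and the reranking prompt keep the original surface).
#'
#' @param mention Character scalar, contained verbatim in the prompt.
#' @param source_language 2-letter tag of the mention's language (not
#'   `"es"`).
#' @param template Prompt template.
#' @return The rendered prompt.
#' @export
build_translation_prompt <- function(mention, source_language,
                                     template = translation_prompt_template()) {
  stopifnot(is.character(mention), length(mention) == 1L)
  if (identical(source_language, "es")) {
    abort("mention is already Spanish; nothing to translate",
      class = "sympl_validation_error"
    )
  }
  fill_template(template, c(mention = mention, source_language = source_language))
}

#' Parse a reranking response with NO_CODE fallback
#'
#' The completion client answers in free text; the response is normalized and
#' matched first against the candidate surfaces, then against the candidate
#' codes, in candidate rank order — the first match wins. A response naming
#' no candidate (a hallucinated entity, an empty string) yields the
#' [NO_CODE] sentinel with `fallback_triggered = TRUE`: if the reranker
#' cannot endorse any retrieved candidate, the mention is treated as having
#' no code rather than trusting the retriever's top hit.
#'
#' @param response Raw client response text.
#' @param candidates Candidate tibble (rank order respected).
#' @param lenient Also accept a normalized candidate surface appearing as a
#'   substring of the response (default off; exact match only).
#' @return A one-row tibble: `chosen_code`, `chosen_surface` (NA on
#'   fallback), `raw_response`, `fallback_triggered`.
#' @export
parse_rerank_response <- function(response, candidates, lenient = FALSE) {
  stopifnot(is.data.frame(candidates))
  resp <- normalize_text(response %||% "")
  surfaces <- normalize_text(candidates$surface)
  hit <- which(surfaces == resp)
  if (length(hit) == 0L) {
    hit <- which(str_trim(candidates$code) == str_trim(response %||% ""))
  }
  if (length(hit) == 0L && lenient && resp != "") {
    hit <- which(str_detect(resp, stringr::fixed(surfaces)) |
      str_detect(surfaces, stringr::fixed(resp)))
  }
  if (length(hit) == 0L) {
    return(tibble(
      chosen_code = NO_CODE, chosen_surface = NA_character_,
      raw_response = response, fallback_triggered = TRUE
    ))
  }
  i <- min(hit)
  tibble(
    chosen_code = candidates$code[[i]],
    chosen_surface = candidates$surface[[i]],
    raw_response = response, fallback_triggered = FALSE
  )
}

#' Scripted / rule-based mock completion client
#'
#' Tests and offline runs need a deterministic stand-in for the generative
#' reranker. Two modes:
#' * scripted — `script` maps prompt text to response text; in strict mode an
#'   unscripted prompt is an error, otherwise `default` is returned;
#' * rule — `rule = "longest_prefix"` answers with the surface of the
#'   candidate sharing the longest common prefix with the mention (using the
#'   structured metadata the pipeline passes alongside the prompt).
#'
#' A real client adapter implements the same contract — a `complete(prompt,
#' meta)` function plus an `id` — and simply ignores `meta`.
#'
#' @param script Named character vector, prompt -> response.
#' @param rule `NULL` or `"longest_prefix"`.
#' @param strict Error on unscripted prompts (scripted mode only).
#' @param default Fallback response in non-strict scripted mode.
#' @return An object of class `sympl_client` with fields `id` and
#'   `complete`.
#' @export
mock_client <- function(script = NULL, rule = NULL, strict = TRUE,
                        default = "") {
  if (!is.null(rule)) {
    rule <- match.arg(rule, "longest_prefix")
    complete <- function(prompt, meta = NULL) {
      if (is.null(meta) || is.null(meta$candidates) || is.null(meta$mention)) {
        abort("rule-mode mock needs mention/candidate metadata",
          class = "sympl_validation_error"
        )
      }
      surfaces <- meta$candidates$surface
      pref <- map_int(surfaces, ~ common_prefix_length(
        normalize_text(meta$mention), normalize_text(.x)
      ))
      surfaces[[which.max(pref)]]
    }
    id <- "mock-longest-prefix"
  } else {
    script <- script %||% character(0L)
    complete <- function(prompt, meta = NULL) {
      if (prompt %in% names(script)) {
        return(unname(script[[prompt]]))
      }
      if (strict) {
        abort("mock client received an unscripted prompt",
          class = "sympl_validation_error"
        )
      }
      default
    }
    id <- "mock-scripted"
  }
  structure(list(id = id, complete = complete), class = "sympl_client")
}

common_prefix_length <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) {
    return(0L)
  }
  ca <- substring(a, 1:n, 1:n)
  cb <- substring(b, 1:n, 1:n)
  diff <- which(ca != cb)
  if (length(diff) == 0L) n else diff[[1L]] - 1L
}
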