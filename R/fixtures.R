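#' Specification of a synthetic linking world
#'
#' The fixture generators emulate the statistical structure the pipeline
#' assumes: a knowledge base whose concepts mostly have one or two aliases
#' with a long tail of richer concepts, mentions that are exact aliases
#' (dictionary path), single-edit perturbations of aliases (embedding path),
#' and mentions of withheld concepts with gold [NO_CODE] (fallback path), in
#' two or more languages. Same-concept aliases share a unique pronounceable
#' stem, which makes concepts separable under the character n-gram reference
#' embedder.
#'
#' @param n_concepts Number of concepts in the KB.
#' @param alias_count_distribution Named probabilities: alias count ->
#'   probability (names are integers). The default puts most mass on one or
#'   two aliases with a tail up to six.
#' @param languages Language tags; aliases cycle through them.
#' @param typo_rate Fraction of corpus mentions that are 1-edit
#'   perturbations.
#' @param out_of_kb_fraction Fraction of corpus mentions drawn from withheld
#'   concepts (gold [NO_CODE]).
#' @param seed Integer seed threaded through every generator.
#' @return A list of class `sympl_fixture_spec`.
#' @export
fixture_spec <- function(n_concepts = 50L,
                         alias_count_distribution = c(
                           "1" = 0.45, "2" = 0.30, "3" = 0.12,
                           "4" = 0.08, "6" = 0.05
                         ),
                         languages = c("es", "en"),
                         typo_rate = 0.3, out_of_kb_fraction = 0.1,
                         seed = 42L) {
  p <- alias_count_distribution
  stopifnot(
    n_concepts >= 1L, abs(sum(p) - 1) < 1e-9, all(p >= 0),
    typo_rate >= 0, typo_rate <= 1,
    out_of_kb_fraction >= 0, out_of_kb_fraction <= 1,
    typo_rate + out_of_kb_fraction <= 1
  )
  structure(
    list(
      n_concepts = as.integer(n_concepts),
      alias_count_distribution = p,
      languages = languages,
      typo_rate = typo_rate,
      out_of_kb_fraction = out_of_kb_fraction,
      seed = as.integer(seed)
    ),
    class = "sympl_fixture_spec"
  )
}

syllable_stem <- function(n_syllables) {
  consonants <- c(
    "b", "c", "d", "f", "g", "l", "m", "n", "p", "r", "s", "t", "v", "z"
  )
  vowels <- c("a", "e", "i", "o", "u")
  paste0(
    paste0(sample(consonants, n_syllables, replace = TRUE),
      sample(vowels, n_syllables, replace = TRUE),
      collapse = ""
    )
  )
}

unique_stems <- function(n, taken = character(0L)) {
  stems <- character(0L)
  while (length(stems) < n) {
    s <- syllable_stem(sample(3:4, 1L))
    if (!s %in% c(stems, taken)) stems <- c(stems, s)
  }
  stems
}

alias_suffixes <- function(language) {
  switch(language,
    es = c("", "itis", "osis", " aguda", " leve", "emia", "ismo", " severa"),
    en = c("", "itis", "osis", " acute", " mild", "emia", "ism", " severe"),
    c("", "itis", "osis", " a", " b", "emia", "ism", " c")
  )
}

#' Generate a synthetic knowledge base
#'
#' Each concept receives a unique pronounceable stem and a SNOMED-like
#' numeric code; its aliases are the stem plus language-specific suffix
#' variants, with the alias count drawn from the spec's distribution. The
#' result is deterministic under the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @return A list: `kb` (a `sympl_kb`), `synonym_map` (code -> surfaces),
#'   and `stems` (code -> stem, used internally to build disjoint
#'   out-of-KB concepts).
#' @export
make_kb <- function(spec) {
  stopifnot(inherits(spec, "sympl_fixture_spec"))
  withr::with_seed(spec$seed, {
    stems <- unique_stems(spec$n_concepts)
    codes <- as.character(9999999L + sample.int(90000000L, spec$n_concepts))
    count_levels <- as.integer(names(spec$alias_count_distribution))
    counts <- count_levels[sample.int(
      length(count_levels), spec$n_concepts,
      replace = TRUE, prob = spec$alias_count_distribution
    )]
    rows <- list()
    for (i in seq_len(spec$n_concepts)) {
      lang <- spec$languages[[(i - 1L) %% length(spec$languages) + 1L]]
      suff <- alias_suffixes(lang)
      k <- min(counts[[i]], length(suff))
      rows[[i]] <- tibble(
        surface = paste0(stems[[i]], suff[seq_len(k)]),
        code = codes[[i]], language = lang, source = "gazetteer",
        is_main = seq_len(k) == 1L
      )
    }
    aliases <- bind_rows(rows)
    kb <- build_kb(
      aliases,
      language = if (length(spec$languages) == 1L) spec$languages else "mixed"
    )
    list(
      kb = kb, synonym_map = kb_synonym_map(kb),
      stems = setNames(stems, codes)
    )
  })
}

#' Generate a linking corpus with forced pipeline paths
#'
#' Builds `n` mentions in three strata: exact KB aliases (resolved by the
#' dictionary), 1-edit perturbations of aliases (forced through the embedding
#' stage), and mentions of concepts withheld from the KB with gold
#' [NO_CODE] (exercising the reranker fallback). Stratum sizes are
#' `round(n * typo_rate)` and `round(n * out_of_kb_fraction)`, the remainder
#' exact. Every mention is embedded in a small generated case report so
#' reranking prompts have context.
#'
#' @param fixture Output of [make_kb()].
#' @param spec The same [fixture_spec()].
#' @param n Number of mentions.
#' @return A list: `mentions` (tibble `mention_id`, `doc_id`, `text`,
#'   `gold_code`, `stratum`, `start`, `end`) and `documents` (tibble
#'   `doc_id`, `text`).
#' @export
make_linking_corpus <- function(fixture, spec, n = 200L) {
  stopifnot(inherits(spec, "sympl_fixture_spec"))
  kb <- fixture$kb
  n_typo <- round(n * spec$typo_rate)
  n_oof <- round(n * spec$out_of_kb_fraction)
  n_exact <- n - n_typo - n_oof
  alphabet <- unlist(strsplit(kb$aliases$surface, "", fixed = TRUE),
    use.names = FALSE
  )
  withr::with_seed(spec$seed + 1L, {
    draw_alias <- function() {
      kb$aliases[sample.int(nrow(kb$aliases), 1L), , drop = FALSE]
    }
    mk <- function(idx, stratum) {
      if (stratum == "out_of_kb") {
        stem <- unique_stems(1L, taken = unname(fixture$stems))
        text <- paste0(stem, sample(c("", "itis", "osis"), 1L))
        gold <- NO_CODE
      } else {
        a <- draw_alias()
        gold <- a$code
        text <- a$surface
        if (stratum == "perturbed") {
          repeat {
            text <- perturb_once(a$surface, alphabet)
            if (!(normalize_text(text) %in% kb$aliases$norm) &&
              normalize_text(text) != "") {
              break
            }
          }
        }
      }
      filler <- replicate(sample(3:6, 1L), syllable_stem(2L))
      prefix <- paste0(
        "Paciente ", paste(filler, collapse = " "), " presenta "
      )
      doc <- paste0(prefix, text, " desde hace dias.")
      tibble(
        mention_id = paste0("m", idx),
        doc_id = paste0("doc", idx),
        text = text, gold_code = gold, stratum = stratum,
        start = str_length(prefix),
        end = str_length(prefix) + str_length(text),
        doc_text = doc
      )
    }
    strata <- c(
      rep("exact", n_exact), rep("perturbed", n_typo),
      rep("out_of_kb", n_oof)
    )
    rows <- bind_rows(map(seq_len(n), ~ mk(.x, strata[[.x]])))
    list(
      mentions = select(rows, -"doc_text"),
      documents = tibble(doc_id = rows$doc_id, text = rows$doc_text)
    )
  })
}

#' Generate a sentence corpus for the NER machinery
#'
#' Sentences contain zero to three non-overlapping mentions drawn from KB
#' aliases, placed at token boundaries between filler words, with gold spans
#' recorded. Mention lengths are spread across the short/medium/long bins
#' (< 38, 38-90, > 90 characters) by stretching some mentions with extra
#' descriptor tokens of the same concept's stem family.
#'
#' @param fixture Output of [make_kb()].
#' @param n_sentences Number of sentences.
#' @param seed Integer seed.
#' @param label Entity label carried by every mention.
#' @return A sentence tibble: `doc_id`, `sentence_id`, `text`, `mentions`
#'   (list-column of tibbles `start`, `end`, `label`, `code`, `text`).
#' @export
make_ner_corpus <- function(fixture, n_sentences = 100L, seed = 7L,
                            label = "SINTOMA") {
  kb <- fixture$kb
  withr::with_seed(seed, {
    stretch_to <- function(surface, lo, hi) {
      out <- surface
      while (str_length(out) < lo) {
        out <- paste(out, syllable_stem(sample(2:3, 1L)))
      }
      if (str_length(out) > hi) {
        out <- surface # fall back; caller re-draws
      }
      out
    }
    rows <- vector("list", n_sentences)
    for (i in seq_len(n_sentences)) {
      target_bin <- c("short", "medium", "long")[[(i - 1L) %% 3L + 1L]]
      n_m <- if (i %% 7L == 0L) 0L else sample(1:3, 1L)
      words <- replicate(sample(4:8, 1L), syllable_stem(2L))
      text <- ""
      pos <- 0L
      ms <- list()
      add_word <- function(w) {
        sep <- if (pos == 0L) "" else " "
        text <<- paste0(text, sep, w)
        start <- pos + str_length(sep)
        pos <<- start + str_length(w)
        start
      }
      w_i <- 1L
      for (j in seq_len(n_m + length(words))) {
        place_mention <- n_m > 0L && length(ms) < n_m &&
          (j %% 2L == 0L || w_i > length(words))
        if (place_mention) {
          a <- kb$aliases[sample.int(nrow(kb$aliases), 1L), , drop = FALSE]
          surface <- a$surface
          if (length(ms) == 0L) { # first mention drives the sentence's bin
            if (target_bin == "medium") {
              surface <- stretch_to(surface, 38L, 90L)
            } else if (target_bin == "long") {
              surface <- stretch_to(surface, 91L, 200L)
            }
          }
          start <- add_word(surface)
          ms[[length(ms) + 1L]] <- tibble(
            start = start, end = start + str_length(surface),
            label = label, code = a$code, text = surface
          )
        } else if (w_i <= length(words)) {
          add_word(words[[w_i]])
          w_i <- w_i + 1L
        }
      }
      text <- paste0(text, ".")
      rows[[i]] <- tibble(
        doc_id = paste0("doc", (i - 1L) %/% 10L + 1L),
        sentence_id = paste0("s", i),
        text = text,
        mentions = list(if (length(ms) == 0L) {
          tibble(
            start = integer(), end = integer(), label = character(),
            code = character(), text = character()
          )
        } else {
          bind_rows(ms)
        })
      )
    }
    bind_rows(rows)
  })
}
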