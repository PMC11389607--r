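#' Normalize a mention or alias surface for dictionary matching
#'
#' Applies the canonical preprocessing used throughout the linking pipeline:
#' Unicode lowercasing, trimming of leading/trailing whitespace, and collapsing
#' of internal whitespace runs to single spaces. Accents and punctuation are
#' deliberately left untouched: the dictionary stage is an exact-match lookup,
#' not a fuzzy matcher.
#'
#' The function is idempotent: `normalize_text(normalize_text(x))` equals
#' `normalize_text(x)`.
#'
#' @param x Character vector of surfaces.
#' @return Character vector of the same length, normalized.
#' @examples
#' normalize_text("Fiebre  Alta ")
#' normalize_text("MACROCITOSE")
#' @export
normalize_text <- function(x) {
  stopifnot(is.character(x))
  str_squish(str_to_lower(x))
}

#' Look a mention up in the knowledge base by exact normalized match
#'
#' First stage of the linking pipeline: the normalized mention is matched
#' against the normalized alias surfaces of the knowledge base. When several
#' concept codes share the surface, the decision is marked ambiguous and the
#' tie is resolved deterministically: aliases observed in the training
#' annotations win over gazetteer/UMLS aliases, main terms win over synonyms,
#' and remaining ties go to the lexicographically smallest code. The same
#' surface carrying different codes across resources is a real phenomenon in
#' terminology-derived dictionaries (a term can be both a clinical finding and
#' a morphologic abnormality), so `considered` reports how many codes competed.
#'
#' @param mention_text Length-one character; raw mention surface.
#' @param kb A knowledge base built by [build_kb()].
#' @return A one-row tibble: `matched`, `code` (NA when unmatched),
#'   `ambiguous`, `considered`.
#' @examples
#' kb <- build_kb(list(tibble::tibble(
#'   surface = c("fiebre", "tos"), code = c("C1", "C2"),
#'   language = "es", source = "gazetteer", is_main = TRUE
#' )))
#' dictionary_lookup("Fiebre", kb)
#' @export
dictionary_lookup <- function(mention_text, kb) {
  stopifnot(is.character(mention_text), length(mention_text) == 1L)
  assert_kb(kb)
  key <- normalize_text(mention_text)
  hits <- kb$aliases[kb$aliases$norm == key, , drop = FALSE]
  if (nrow(hits) == 0L) {
    return(tibble(
      matched = FALSE, code = NA_character_,
      ambiguous = FALSE, considered = 0L
    ))
  }
  codes <- unique(hits$code)
  if (length(codes) == 1L) {
    return(tibble(
      matched = TRUE, code = codes,
      ambiguous = FALSE, considered = 1L
    ))
  }
  ranked <- hits |>
    mutate(
      from_train = source_has(.data$source, "train"),
      main = as.logical(.data$is_main)
    ) |>
    arrange(desc(.data$from_train), desc(.data$main), .data$code)
  tibble(
    matched = TRUE, code = ranked$code[[1L]],
    ambiguous = TRUE, considered = length(codes)
  )
}
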