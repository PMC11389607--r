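#' Augment rare concepts with perturbed aliases
#'
#' Concepts in the long tail of the alias distribution — the majority of
#' concepts in terminology-derived KBs have only one or two surface forms —
#' give the embedding retriever little to match against. This augmenter gives
#' every concept with fewer than `rarity_threshold` aliases exactly `n_new`
#' additional aliases, each derived from a uniformly chosen existing alias of
#' the same concept by a single character edit: either inserting one character
#' (drawn from the multiset of characters observed across all KB surfaces) at
#' a uniform position, or deleting one character at a uniform position. The
#' insert/delete choice is uniform per generated alias; duplicates trigger a
#' re-draw (up to 20 attempts, then characters are appended until unique), and
#' a deletion drawn for a single-character alias is replaced by an insertion
#' so an empty surface is never emitted.
#'
#' Augmented aliases carry provenance `"augmented"`; all original aliases are
#' preserved and concepts at or above the threshold are untouched. The result
#' is byte-identical across runs for a fixed seed.
#'
#' @param kb A knowledge base from [build_kb()].
#' @param rarity_threshold Concepts with fewer aliases than this are augmented
#'   (default 5).
#' @param n_new Number of new aliases per rare concept (default 5).
#' @param seed Integer seed controlling all randomness.
#' @return A new `sympl_kb` containing the original plus augmented aliases.
#' @export
augment_rare_concepts <- function(kb, rarity_threshold = 5L, n_new = 5L,
                                  seed = 1L) {
  assert_kb(kb)
  stopifnot(n_new >= 1L, rarity_threshold >= 1L)
  if (nrow(kb$aliases) == 0L) {
    return(kb)
  }
  counts <- kb_alias_counts(kb)
  rare <- sort(counts$code[counts$n_aliases < rarity_threshold])
  if (length(rare) == 0L) {
    return(kb)
  }
  alphabet <- unlist(strsplit(kb$aliases$surface, "", fixed = TRUE),
    use.names = FALSE
  )
  seen <- paste(kb$aliases$norm, kb$aliases$code, sep = "\r")
  new_rows <- withr::with_seed(seed, {
    out <- vector("list", length(rare))
    for (ci in seq_along(rare)) {
      code <- rare[[ci]]
      pool <- kb$aliases[kb$aliases$code == code, , drop = FALSE]
      made <- character(0L)
      made_lang <- character(0L)
      for (j in seq_len(n_new)) {
        attempt <- 0L
        repeat {
          attempt <- attempt + 1L
          base_i <- sample.int(nrow(pool), 1L)
          base <- pool$surface[[base_i]]
          cand <- perturb_once(base, alphabet)
          if (attempt > 20L) {
            # give up on re-drawing; append characters until unique
            while (paste(normalize_text(cand), code, sep = "\r") %in% seen) {
              cand <- paste0(cand, sample(alphabet, 1L))
            }
          }
          key <- paste(normalize_text(cand), code, sep = "\r")
          if (normalize_text(cand) != "" && !(key %in% seen)) {
            seen <- c(seen, key)
            made <- c(made, cand)
            made_lang <- c(made_lang, pool$language[[base_i]])
            break
          }
        }
      }
      out[[ci]] <- tibble(
        surface = made, code = code, language = made_lang,
        source = "augmented", is_main = FALSE
      )
    }
    bind_rows(out)
  })
  combined <- bind_rows(
    select(
      kb$aliases, "surface", "code", "language", "source", "is_main"
    ),
    new_rows
  )
  build_kb(combined, language = kb$language)
}

# one random single-character edit: insert (uniform char, uniform slot) or
# delete (uniform position); single-char surfaces always insert
perturb_once <- function(surface, alphabet) {
  chars <- strsplit(surface, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  do_insert <- n <= 1L || runif(1L) < 0.5
  if (do_insert) {
    ch <- sample(alphabet, 1L)
    pos <- sample.int(n + 1L, 1L) # 1 = before first char
    paste(append(chars, ch, after = pos - 1L), collapse = "")
  } else {
    pos <- sample.int(n, 1L)
    paste(chars[-pos], collapse = "")
  }
}
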