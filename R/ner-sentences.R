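#' Split a document into sentences
#'
#' Rule-based splitter standing in for heavier clinical sentence splitters:
#' a boundary is placed after a terminator (`.`, `?`, `!`, `;`) followed by
#' whitespace and an uppercase letter or digit, unless the terminator closes
#' a known abbreviation. Offsets are 0-based code points into the original
#' document and each sentence text equals the document slice at its offset,
#' so the document is reconstructible slice for slice. A boundary candidate
#' falling inside a supplied mention span is suppressed: spans must never be
#' split across sentences.
#'
#' @param document Document text.
#' @param mentions Optional tibble (`start`, `end`) of spans (0-based,
#'   end-exclusive) that must stay within one sentence.
#' @param abbreviations Terminator-bearing tokens that never end a sentence.
#' @return A tibble `sentence_id`, `start`, `end`, `text`.
#' @export
split_sentences <- function(document, mentions = NULL,
                            abbreviations = c(
                              "Dr.", "Dra.", "Sr.", "Sra.", "etc.", "p.ej.",
                              "vs.", "Fig.", "No."
                            )) {
  stopifnot(is.character(document), length(document) == 1L)
  n <- str_length(document)
  if (n == 0L) {
    return(tibble(
      sentence_id = integer(), start = integer(), end = integer(),
      text = character()
    ))
  }
  chars <- strsplit(document, "", fixed = TRUE)[[1L]]
  is_boundary <- rep(FALSE, n)
  for (i in seq_len(n - 1L)) {
    if (!chars[[i]] %in% c(".", "?", "!", ";")) next
    # next non-space char must open a new sentence
    j <- i + 1L
    while (j <= n && grepl("^\\s$", chars[[j]])) j <- j + 1L
    if (j > n || j == i + 1L) next # no whitespace after terminator
    if (!grepl("^[[:upper:][:digit:]]$", chars[[j]])) next
    # abbreviation check: token ending at i
    k <- i
    while (k > 1L && !grepl("^\\s$", chars[[k - 1L]])) k <- k - 1L
    token <- paste(chars[k:i], collapse = "")
    if (token %in% abbreviations) next
    is_boundary[[i]] <- TRUE
  }
  if (!is.null(mentions) && nrow(mentions) > 0L) {
    for (m in seq_len(nrow(mentions))) {
      # suppress boundaries strictly inside the span (0-based [start, end))
      lo <- mentions$start[[m]] + 1L
      hi <- mentions$end[[m]] - 1L
      if (hi >= lo) is_boundary[lo:hi] <- FALSE
    }
  }
  bounds <- which(is_boundary)
  starts0 <- c(1L, bounds + 1L)
  ends0 <- c(bounds, n)
  out <- list()
  for (s in seq_along(starts0)) {
    a <- starts0[[s]]
    b <- ends0[[s]]
    # trim whitespace, keeping offsets aligned with the original document
    while (a <= b && grepl("^\\s$", chars[[a]])) a <- a + 1L
    while (b >= a && grepl("^\\s$", chars[[b]])) b <- b - 1L
    if (a > b) next
    out[[length(out) + 1L]] <- tibble(
      start = a - 1L, end = b,
      text = paste(chars[a:b], collapse = "")
    )
  }
  bind_rows(out) |> mutate(sentence_id = row_number(), .before = 1L)
}

#' Tokenize sentence text into words and punctuation
#'
#' Tokens are maximal runs of letters/digits, or single punctuation marks;
#' offsets are 0-based, end-exclusive, relative to the sentence.
#'
#' @param text Sentence text.
#' @return A tibble `token`, `start`, `end`.
#' @export
tokenize_sentence <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  loc <- str_locate_all(text, "[\\p{L}\\p{N}]+|[^\\p{L}\\p{N}\\s]")[[1L]]
  if (nrow(loc) == 0L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  tibble(
    token = str_sub(text, loc[, 1L], loc[, 2L]),
    start = as.integer(loc[, 1L] - 1L),
    end = as.integer(loc[, 2L])
  )
}

#' Encode mention spans as IOB2 tags / decode tags back to spans
#'
#' `encode_iob2()` turns a sentence and its (0-based, end-exclusive) mention
#' spans into per-token IOB2 tags: `B-<label>` opens a span, `I-<label>`
#' continues it, `O` is outside. Mention boundaries that do not align with
#' token boundaries are snapped outward to the enclosing tokens and counted
#' in the `"snapped"` attribute. Nested or overlapping spans are rejected.
#' `decode_iob2()` inverts the encoding; for aligned spans
#' `decode(encode(x))` reproduces the spans exactly.
#'
#' @param text Sentence text.
#' @param mentions Tibble (`start`, `end`, `label`).
#' @param tokens Token table from [tokenize_sentence()]; computed if `NULL`.
#' @return `encode_iob2()`: a tibble `token`, `start`, `end`, `tag` (with
#'   attribute `snapped`); `decode_iob2()`: a tibble `start`, `end`, `label`.
#' @export
encode_iob2 <- function(text, mentions, tokens = NULL) {
  if (is.null(tokens)) tokens <- tokenize_sentence(text)
  tags <- rep("O", nrow(tokens))
  snapped <- 0L
  if (nrow(mentions) > 0L) {
    m <- mentions |> arrange(.data$start, .data$end)
    if (nrow(m) > 1L && any(m$start[-1L] < m$end[-nrow(m)])) {
      abort("nested or overlapping mention spans cannot be IOB2-encoded",
        class = "sympl_validation_error"
      )
    }
    for (i in seq_len(nrow(m))) {
      inside <- which(tokens$end > m$start[[i]] & tokens$start < m$end[[i]])
      if (length(inside) == 0L) next
      if (tokens$start[[min(inside)]] != m$start[[i]] ||
        tokens$end[[max(inside)]] != m$end[[i]]) {
        snapped <- snapped + 1L
      }
      tags[inside] <- paste0("I-", m$label[[i]])
      tags[[min(inside)]] <- paste0("B-", m$label[[i]])
    }
  }
  out <- mutate(tokens, tag = tags)
  attr(out, "snapped") <- snapped
  out
}

#' @rdname encode_iob2
#' @param tagged A tibble `start`, `end`, `tag` (token-aligned).
#' @export
decode_iob2 <- function(tagged) {
  validate_iob2(tagged$tag)
  spans <- list()
  open <- NULL
  for (i in seq_len(nrow(tagged))) {
    tag <- tagged$tag[[i]]
    if (startsWith(tag, "B-")) {
      if (!is.null(open)) spans[[length(spans) + 1L]] <- open
      open <- list(
        start = tagged$start[[i]], end = tagged$end[[i]],
        label = sub("^B-", "", tag)
      )
    } else if (startsWith(tag, "I-")) {
      open$end <- tagged$end[[i]]
    } else if (!is.null(open)) {
      spans[[length(spans) + 1L]] <- open
      open <- NULL
    }
  }
  if (!is.null(open)) spans[[length(spans) + 1L]] <- open
  if (length(spans) == 0L) {
    return(tibble(start = integer(), end = integer(), label = character()))
  }
  tibble(
    start = map_int(spans, ~ as.integer(.x$start)),
    end = map_int(spans, ~ as.integer(.x$end)),
    label = map_chr(spans, "label")
  )
}

#' Validate an IOB2 tag sequence
#'
#' An `I-<label>` tag may only continue a `B-<label>` or `I-<label>` of the
#' same label; any other transition is invalid. This is the contract boundary
#' for pluggable taggers: any tagger producing a valid sequence plugs into
#' the evaluation machinery.
#'
#' @param tags Character vector of IOB2 tags.
#' @return `TRUE` invisibly; aborts on an invalid transition.
#' @export
validate_iob2 <- function(tags) {
  prev <- "O"
  for (i in seq_along(tags)) {
    tag <- tags[[i]]
    ok <- tag == "O" || startsWith(tag, "B-") ||
      (startsWith(tag, "I-") &&
        (prev == paste0("B-", sub("^I-", "", tag)) ||
          prev == paste0("I-", sub("^I-", "", tag))))
    if (!ok) {
      abort(
        paste0("invalid IOB2 transition at position ", i, ": ", prev, " -> ", tag),
        class = "sympl_validation_error"
      )
    }
    prev <- tag
  }
  invisible(TRUE)
}

#' Dictionary-based mock tagger
#'
#' A stand-in for a trained token classifier, satisfying the same contract:
#' given a sentence it returns a valid IOB2 tag per token. Maximal token runs
#' whose joined, normalized text matches a KB alias are tagged; overlapping
#' matches are resolved leftmost-longest.
#'
#' @param kb A knowledge base.
#' @param label Entity label to emit (default `"SINTOMA"`).
#' @param max_tokens Longest alias run considered.
#' @return A function: sentence text -> tibble `token`, `start`, `end`,
#'   `tag`.
#' @export
dictionary_tagger <- function(kb, label = "SINTOMA", max_tokens = 6L) {
  assert_kb(kb)
  keys <- unique(kb$aliases$norm)
  function(text) {
    tokens <- tokenize_sentence(text)
    tags <- rep("O", nrow(tokens))
    i <- 1L
    while (i <= nrow(tokens)) {
      hit_len <- 0L
      for (len in rev(seq_len(min(max_tokens, nrow(tokens) - i + 1L)))) {
        run <- str_sub(text, tokens$start[[i]] + 1L, tokens$end[[i + len - 1L]])
        if (normalize_text(run) %in% keys) {
          hit_len <- len
          break
        }
      }
      if (hit_len > 0L) {
        idx <- i:(i + hit_len - 1L)
        tags[idx] <- paste0("I-", label)
        tags[[i]] <- paste0("B-", label)
        i <- i + hit_len
      } else {
        i <- i + 1L
      }
    }
    mutate(tokens, tag = tags)
  }
}
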