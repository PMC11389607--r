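#' Weights of the sliding-window composite similarity
#'
#' Plain cosine retrieval struggles with long mentions: the informative part
#' of a symptom mention tends to sit at its start. The composite score is a
#' convex combination of three cosines — full text, leading token window,
#' trailing token window. The defaults are the coefficients found by grid
#' search over a training set in the system this package implements
#' (0.75 / 0.17 / 0.08), reflecting that most of the signal lives in the full
#' mention and its head.
#'
#' @param w_full,w_head,w_tail Non-negative weights summing to 1 (within
#'   1e-9).
#' @return A classed named numeric vector of length 3.
#' @export
sliding_window_weights <- function(w_full = 0.75, w_head = 0.17,
                                   w_tail = 0.08) {
  w <- c(w_full = w_full, w_head = w_head, w_tail = w_tail)
  if (any(w < 0)) {
    abort("sliding-window weights must be non-negative",
      class = "sympl_validation_error"
    )
  }
  if (abs(sum(w) - 1) > 1e-9) {
    abort("sliding-window weights must sum to 1",
      class = "sympl_validation_error"
    )
  }
  structure(w, class = "sympl_weights")
}

window_size <- function(n, frac) {
  # ceil(frac * n) with a guard against floating-point spill, at least 1 token
  max(1L, as.integer(ceiling(frac * n - 1e-9)))
}

#' Leading / trailing token windows of a mention
#'
#' Tokens come from whitespace-splitting the normalized text. The head window
#' keeps the first `ceil(frac * n)` tokens, the tail window the last
#' `ceil(frac * n)`; a single-token mention is its own head and tail.
#'
#' @param tokens Character vector of tokens (non-empty).
#' @param frac Window fraction in (0, 1], default 0.75.
#' @return The selected tokens.
#' @export
head_window <- function(tokens, frac = 0.75) {
  stopifnot(frac > 0, frac <= 1)
  if (length(tokens) == 0L) {
    abort("cannot window an empty token sequence",
      class = "sympl_validation_error"
    )
  }
  tokens[seq_len(window_size(length(tokens), frac))]
}

#' @rdname head_window
#' @export
tail_window <- function(tokens, frac = 0.75) {
  stopifnot(frac > 0, frac <= 1)
  if (length(tokens) == 0L) {
    abort("cannot window an empty token sequence",
      class = "sympl_validation_error"
    )
  }
  k <- window_size(length(tokens), frac)
  tokens[seq.int(length(tokens) - k + 1L, length(tokens))]
}

tokenize_ws <- function(text) {
  t <- normalize_text(text)
  if (t == "") character(0L) else strsplit(t, " ", fixed = TRUE)[[1L]]
}

window_text <- function(text, which = c("full", "head", "tail"), frac = 0.75) {
  which <- match.arg(which)
  if (which == "full") {
    return(normalize_text(text))
  }
  toks <- tokenize_ws(text)
  if (length(toks) == 0L) {
    return("")
  }
  sel <- if (which == "head") head_window(toks, frac) else tail_window(toks, frac)
  paste(sel, collapse = " ")
}

#' Composite sliding-window similarity of a mention and an alias
#'
#' Computes `w_full * cos(E(m), E(a)) + w_head * cos(E(head(m)), E(head(a))) +
#' w_tail * cos(E(tail(m)), E(tail(a)))`, with windows applied symmetrically
#' to mention and alias and embeddings taken of the re-joined window tokens.
#' With weights (1, 0, 0) this reduces exactly to the plain cosine of the
#' full texts.
#'
#' @param mention,alias Character scalars.
#' @param weights A [sliding_window_weights()] object.
#' @param backend An embedding backend.
#' @param frac Window fraction (default 0.75).
#' @return A number in \[-1, 1\].
#' @export
composite_score <- function(mention, alias,
                            weights = sliding_window_weights(),
                            backend = hash_embedder(), frac = 0.75) {
  stopifnot(inherits(weights, "sympl_weights"))
  parts <- c("full", "head", "tail")
  texts <- c(
    vapply(parts, function(p) window_text(mention, p, frac), character(1L)),
    vapply(parts, function(p) window_text(alias, p, frac), character(1L))
  )
  m <- backend$embed(texts)
  cs <- vapply(1:3, function(i) cosine_similarity(m[i, ], m[i + 3L, ]), numeric(1L))
  sum(unclass(weights) * cs)
}

#' Precompute alias embeddings for a knowledge base
#'
#' Retrieval scores a query against every KB alias; embedding the alias side
#' once and reusing the matrices across queries is what makes corpus-level
#' linking tractable. For the sliding-window scorer three matrices are built
#' (full surface, head window, tail window); the plain scorer needs only the
#' first.
#'
#' @param kb A knowledge base.
#' @param backend An embedding backend.
#' @param scorer `"plain"` or `"sliding_window"`.
#' @param frac Window fraction.
#' @return A list of matrices (`full`, and for the sliding scorer `head`,
#'   `tail`), rows aligned with `kb$aliases`.
#' @export
kb_alias_embeddings <- function(kb, backend,
                                scorer = c("plain", "sliding_window"),
                                frac = 0.75) {
  assert_kb(kb)
  scorer <- match.arg(scorer)
  parts <- if (scorer == "plain") "full" else c("full", "head", "tail")
  out <- lapply(parts, function(p) {
    backend$embed(vapply(
      kb$aliases$surface, function(s) window_text(s, p, frac), character(1L),
      USE.NAMES = FALSE
    ))
  })
  names(out) <- parts
  out
}

#' Top-k candidate aliases for a mention
#'
#' Scores every KB alias against the mention — plain cosine by default, or
#' the sliding-window composite — and returns the `k` best as a candidate
#' table. Candidates are aliases, not deduplicated codes: several surfaces of
#' one concept may appear. Ties are broken by code then surface, ascending,
#' so rankings are deterministic.
#'
#' @param mention Character scalar.
#' @param kb A non-empty knowledge base.
#' @param backend An embedding backend.
#' @param k Number of candidates (default 5, the count handed to the
#'   reranker).
#' @param scorer `"plain"` or `"sliding_window"`.
#' @param weights [sliding_window_weights()] for the composite scorer.
#' @param frac Window fraction.
#' @param alias_embeddings Optional precomputed [kb_alias_embeddings()].
#' @return A tibble `rank`, `surface`, `code`, `score`, at most `k` rows.
#' @export
top_k_candidates <- function(mention, kb, backend = hash_embedder(), k = 5L,
                             scorer = c("plain", "sliding_window"),
                             weights = sliding_window_weights(), frac = 0.75,
                             alias_embeddings = NULL) {
  assert_kb(kb)
  scorer <- match.arg(scorer)
  stopifnot(k >= 1L)
  if (nrow(kb$aliases) == 0L) {
    abort("cannot generate candidates from an empty knowledge base",
      class = "sympl_validation_error"
    )
  }
  if (is.null(alias_embeddings)) {
    alias_embeddings <- kb_alias_embeddings(kb, backend, scorer, frac)
  }
  parts <- names(alias_embeddings)
  q <- backend$embed(vapply(
    parts, function(p) window_text(mention, p, frac), character(1L),
    USE.NAMES = FALSE
  ))
  if (scorer == "plain") {
    scores <- as.numeric(alias_embeddings$full %*% q[1L, ])
  } else {
    w <- unclass(weights)
    scores <- w[["w_full"]] * as.numeric(alias_embeddings$full %*% q[1L, ]) +
      w[["w_head"]] * as.numeric(alias_embeddings$head %*% q[2L, ]) +
      w[["w_tail"]] * as.numeric(alias_embeddings$tail %*% q[3L, ])
  }
  # round before ordering so near-ties resolve by the deterministic
  # code/surface rule regardless of float summation order
  ord <- order(-round(scores, 12L), kb$aliases$code, kb$aliases$surface)
  top <- ord[seq_len(min(k, length(ord)))]
  tibble(
    rank = seq_along(top),
    surface = kb$aliases$surface[top],
    code = kb$aliases$code[top],
    score = scores[top]
  )
}
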