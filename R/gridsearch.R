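#' Grid-search the sliding-window weights on labelled mentions
#'
#' Exhaustively scans the discretized simplex `{(w_full, w_head, w_tail) :
#' w_i in {0, step, ..., 1}, sum = 1}` and returns the weights maximizing
#' top-1 linking accuracy of the composite scorer on the labelled mentions.
#' The three cosine matrices (mention x alias, per window) are precomputed
#' once, so each grid point costs only a weighted matrix sum. Ties are
#' resolved in favour of the largest `w_full`, then the largest `w_head` —
#' in particular, when plain cosine already links everything correctly the
#' search returns (1, 0, 0).
#'
#' @param labeled A tibble with columns `mention` and `code` (gold).
#' @param kb A knowledge base.
#' @param backend An embedding backend.
#' @param step Grid resolution; `1/step` should be (close to) an integer.
#' @param frac Window fraction.
#' @return An object of class `sympl_grid_search`: list with `weights`
#'   ([sliding_window_weights()]), `accuracy`, and the full `grid` tibble.
#'   [generics::tidy()] returns the grid, [generics::glance()] the optimum.
#' @export
grid_search_weights <- function(labeled, kb, backend = hash_embedder(),
                                step = 0.01, frac = 0.75) {
  stopifnot(is.data.frame(labeled), nrow(labeled) > 0L)
  stopifnot(all(c("mention", "code") %in% names(labeled)))
  assert_kb(kb)
  if (nrow(kb$aliases) == 0L) {
    abort("cannot grid-search against an empty knowledge base",
      class = "sympl_validation_error"
    )
  }
  ae <- kb_alias_embeddings(kb, backend, "sliding_window", frac)
  parts <- c("full", "head", "tail")
  qmat <- lapply(parts, function(p) {
    backend$embed(vapply(
      labeled$mention, function(m) window_text(m, p, frac), character(1L),
      USE.NAMES = FALSE
    ))
  })
  names(qmat) <- parts
  # cosine matrices, mentions x aliases; all embeddings are unit rows
  C <- lapply(parts, function(p) qmat[[p]] %*% t(ae[[p]]))
  names(C) <- parts
  # pre-order alias columns so that ties.method = "first" realizes the
  # score-desc, code-asc, surface-asc candidate ordering
  col_ord <- order(kb$aliases$code, kb$aliases$surface)
  C <- lapply(C, function(m) m[, col_ord, drop = FALSE])
  codes <- kb$aliases$code[col_ord]
  gold <- labeled$code

  N <- as.integer(round(1 / step))
  if (N < 1L) abort("step must be at most 1", class = "sympl_validation_error")
  rows <- list()
  best <- list(acc = -Inf, w = NULL)
  for (i in N:0) { # w_full descending: first max wins ties
    for (j in (N - i):0) { # then w_head descending
      w1 <- i / N
      w2 <- j / N
      w3 <- (N - i - j) / N
      S <- w1 * C$full + w2 * C$head + w3 * C$tail
      pred <- codes[max.col(S, ties.method = "first")]
      acc <- mean(pred == gold)
      rows[[length(rows) + 1L]] <- tibble(
        w_full = w1, w_head = w2, w_tail = w3, accuracy = acc
      )
      if (acc > best$acc) best <- list(acc = acc, w = c(w1, w2, w3))
    }
  }
  structure(
    list(
      weights = sliding_window_weights(best$w[1L], best$w[2L], best$w[3L]),
      accuracy = best$acc,
      grid = bind_rows(rows),
      n = nrow(labeled)
    ),
    class = "sympl_grid_search"
  )
}

#' @export
print.sympl_grid_search <- function(x, ...) {
  w <- unclass(x$weights)
  cat(
    "<sliding-window grid search> ", nrow(x$grid), " grid points, ",
    x$n, " mentions\n  best weights: (",
    paste(format(w, digits = 3), collapse = ", "),
    ")  accuracy: ", format(x$accuracy, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sympl_grid_search <- function(x, ...) {
  x$grid
}

#' @exportS3Method generics::glance
glance.sympl_grid_search <- function(x, ...) {
  w <- unclass(x$weights)
  tibble(
    w_full = w[["w_full"]], w_head = w[["w_head"]], w_tail = w[["w_tail"]],
    accuracy = x$accuracy, n_grid_points = nrow(x$grid), n = x$n
  )
}
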