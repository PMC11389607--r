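#' Mention-length binned train/validation split
#'
#' Sentences are binned by the character length of their longest mention —
#' short (< `short_max`), medium (`short_max` to `medium_max`, inclusive),
#' long (> `medium_max`); mention-free sentences count as length 0 and fall
#' into the short bin. Within each bin a seeded shuffle assigns
#' `floor(train_fraction * n)` sentences to the training split and the rest
#' to validation, so both splits see the full mention-length distribution.
#' The default bin edges (38 / 90 characters) follow the mention-length
#' distribution of the clinical corpus this procedure was designed for.
#'
#' @param sentences A sentence tibble with a `mentions` list-column (each
#'   element a tibble with `start`, `end`).
#' @param short_max Exclusive upper edge of the short bin (default 38).
#' @param medium_max Inclusive upper edge of the medium bin (default 90).
#' @param train_fraction Fraction per bin assigned to training (default 0.8).
#' @param seed Integer seed for the per-bin shuffles.
#' @return A list with tibbles `train` and `validation`, each the input rows
#'   plus a `bin` column; together they partition the input.
#' @export
bin_split <- function(sentences, short_max = 38L, medium_max = 90L,
                      train_fraction = 0.8, seed = 1L) {
  stopifnot(
    is.data.frame(sentences), "mentions" %in% names(sentences),
    short_max > 0L, short_max <= medium_max,
    train_fraction > 0, train_fraction < 1
  )
  longest <- map_int(sentences$mentions, function(m) {
    if (is.null(m) || nrow(m) == 0L) {
      return(0L)
    }
    as.integer(max(m$end - m$start))
  })
  bin <- dplyr::case_when(
    longest < short_max ~ "short",
    longest <= medium_max ~ "medium",
    TRUE ~ "long"
  )
  sentences <- mutate(sentences, bin = bin)
  withr::with_seed(seed, {
    in_train <- rep(FALSE, nrow(sentences))
    for (b in unique(bin)) {
      idx <- which(bin == b)
      take <- floor(train_fraction * length(idx))
      in_train[sample(idx)[seq_len(take)]] <- TRUE
    }
    list(
      train = sentences[in_train, , drop = FALSE],
      validation = sentences[!in_train, , drop = FALSE]
    )
  })
}

#' Augment sentences by synonym replacement
#'
#' Creates additional training sentences by replacing annotated mentions with
#' a different synonym of the same concept code, drawn uniformly from the
#' synonym map. Selection is a per-mention Bernoulli draw at `rate`; a
#' sentence contributes a new example when at least one of its mentions is
#' replaced. All offsets in the new sentence are recomputed for the length
#' difference, labels and codes are unchanged, and the originals are
#' retained — augmentation adds examples. Mentions whose code has no
#' alternative synonym are left unchanged and counted in the
#' `"unreplaceable"` attribute.
#'
#' @param sentences Sentence tibble with a `mentions` list-column (elements
#'   carrying `start`, `end`, `label`, `code`, `text`).
#' @param synonym_map Named list code -> character vector of surfaces (see
#'   [kb_synonym_map()]).
#' @param rate Per-mention replacement probability in (0, 1].
#' @param seed Integer seed.
#' @return The input sentences followed by the generated ones
#'   (`sentence_id` suffixed with `"_aug"`), with attribute `unreplaceable`.
#' @export
augment_by_synonyms <- function(sentences, synonym_map, rate = 0.15,
                                seed = 1L) {
  stopifnot(
    is.data.frame(sentences), "mentions" %in% names(sentences),
    rate > 0, rate <= 1
  )
  unreplaceable <- 0L
  new_rows <- withr::with_seed(seed, {
    out <- list()
    for (i in seq_len(nrow(sentences))) {
      s <- sentences[i, , drop = FALSE]
      m <- s$mentions[[1L]]
      if (is.null(m) || nrow(m) == 0L) next
      m <- arrange(m, .data$start)
      pick <- runif(nrow(m)) < rate
      if (!any(pick)) next
      text <- s$text
      new_text <- ""
      cursor <- 0L # 0-based position consumed so far
      delta <- 0L
      starts <- integer(nrow(m))
      ends <- integer(nrow(m))
      texts <- character(nrow(m))
      changed <- FALSE
      for (j in seq_len(nrow(m))) {
        old_surface <- str_sub(text, m$start[[j]] + 1L, m$end[[j]])
        surface <- old_surface
        if (pick[[j]]) {
          alts <- setdiff(synonym_map[[m$code[[j]]]] %||% character(0L), old_surface)
          if (length(alts) == 0L) {
            unreplaceable <- unreplaceable + 1L
          } else {
            surface <- if (length(alts) == 1L) alts else sample(alts, 1L)
            changed <- TRUE
          }
        }
        gap <- str_sub(text, cursor + 1L, m$start[[j]])
        new_text <- paste0(new_text, gap, surface)
        starts[[j]] <- m$start[[j]] + delta
        ends[[j]] <- starts[[j]] + str_length(surface)
        texts[[j]] <- surface
        delta <- delta + str_length(surface) - str_length(old_surface)
        cursor <- m$end[[j]]
      }
      if (!changed) next
      new_text <- paste0(new_text, str_sub(text, cursor + 1L, str_length(text)))
      s$text <- new_text
      s$sentence_id <- paste0(s$sentence_id, "_aug")
      s$mentions <- list(mutate(m,
        start = starts, end = ends, text = texts
      ))
      out[[length(out) + 1L]] <- s
    }
    bind_rows(out)
  })
  out <- bind_rows(sentences, new_rows)
  attr(out, "unreplaceable") <- unreplaceable
  out
}
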