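#' Micro-averaged span evaluation, strict or overlapping
#'
#' Compares predicted entity spans against gold spans pooled over all
#' documents (micro-averaging: tp/fp/fn are summed before computing
#' precision, recall and F1). Two matching modes:
#' * `strict` — a prediction is a true positive iff an as-yet-unmatched gold
#'   span has identical document, boundaries and label;
#' * `overlap` — iff it shares at least one character with an unmatched gold
#'   span of the same label in the same document.
#'
#' Matching is one-to-one and greedy over predictions sorted by document,
#' start, then end. Since every strict match is also an overlap match,
#' overlap counts dominate strict counts on identical inputs; the gap between
#' the two scores measures how much of the error is boundary disagreement
#' rather than missed entities.
#'
#' @param gold,predicted Tibbles with columns `doc_id`, `start`, `end`,
#'   `label` (offsets 0-based, end-exclusive).
#' @param mode `"strict"` or `"overlap"`.
#' @return An object of class `sympl_eval`: tp, fp, fn, precision, recall,
#'   f1, mode. [generics::tidy()] returns it as a one-row tibble.
#' @examples
#' gold <- tibble::tibble(
#'   doc_id = "d1", start = c(0L, 10L, 20L), end = c(5L, 15L, 25L),
#'   label = "SINTOMA"
#' )
#' pred <- gold[c(1, 3), ]
#' pred$start[2] <- 26L
#' pred$end[2] <- 30L
#' tidy(ner_metrics(gold, pred, "strict"))
#' @export
ner_metrics <- function(gold, predicted, mode = c("strict", "overlap")) {
  mode <- match.arg(mode)
  for (df in list(gold, predicted)) {
    stopifnot(all(c("doc_id", "start", "end", "label") %in% names(df)))
    if (nrow(df) > 0L && any(df$start < 0L | df$start >= df$end)) {
      abort("invalid span: need 0 <= start < end",
        class = "sympl_validation_error"
      )
    }
  }
  pred <- arrange(predicted, .data$doc_id, .data$start, .data$end)
  gold_open <- mutate(gold, .matched = FALSE)
  tp <- 0L
  for (i in seq_len(nrow(pred))) {
    p <- pred[i, ]
    cand <- which(
      !gold_open$.matched &
        gold_open$doc_id == p$doc_id &
        gold_open$label == p$label &
        (if (mode == "strict") {
          gold_open$start == p$start & gold_open$end == p$end
        } else {
          gold_open$start < p$end & p$start < gold_open$end
        })
    )
    if (length(cand) > 0L) {
      j <- cand[order(gold_open$start[cand], gold_open$end[cand])][[1L]]
      gold_open$.matched[[j]] <- TRUE
      tp <- tp + 1L
    }
  }
  fp <- nrow(pred) - tp
  fn <- nrow(gold) - tp
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  structure(
    list(
      tp = tp, fp = fp, fn = fn,
      precision = precision, recall = recall, f1 = f1, mode = mode
    ),
    class = "sympl_eval"
  )
}

#' @export
print.sympl_eval <- function(x, ...) {
  cat(
    "<span evaluation, ", x$mode, "> tp=", x$tp, " fp=", x$fp, " fn=", x$fn,
    "  P=", format(x$precision, digits = 4),
    " R=", format(x$recall, digits = 4),
    " F1=", format(x$f1, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.sympl_eval <- function(x, ...) {
  tibble(
    mode = x$mode, tp = x$tp, fp = x$fp, fn = x$fn,
    precision = x$precision, recall = x$recall, f1 = x$f1
  )
}
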