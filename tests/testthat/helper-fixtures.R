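# small in-code fixtures shared across test files

alias_row <- function(surface, code, language = "es", source = "gazetteer",
                      is_main = FALSE) {
  tibble::tibble(
    surface = surface, code = code, language = language,
    source = source, is_main = is_main
  )
}

tiny_kb <- function() {
  build_kb(dplyr::bind_rows(
    alias_row("fiebre", "C1", is_main = TRUE),
    alias_row("fiebre alta", "C1"),
    alias_row("tos", "C2", is_main = TRUE),
    alias_row("dolor abdominal", "C3", is_main = TRUE)
  ))
}

write_fixture_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent ranking oracle: embed everything directly, score with base R,
# sort with base order()
brute_force_ranking <- function(mention, kb, backend) {
  q <- backend$embed(normalize_text(mention))[1L, ]
  scores <- vapply(kb$aliases$surface, function(s) {
    v <- backend$embed(normalize_text(s))[1L, ]
    sum(q * v) / (sqrt(sum(q^2)) * sqrt(sum(v^2)))
  }, numeric(1L), USE.NAMES = FALSE)
  ord <- order(-round(scores, 12L), kb$aliases$code, kb$aliases$surface)
  tibble::tibble(
    surface = kb$aliases$surface[ord],
    code = kb$aliases$code[ord],
    score = scores[ord]
  )
}

# brute-force Levenshtein via base R (independent of the augmenter)
edit_distance <- function(a, b) {
  as.integer(utils::adist(a, b))
}

random_spans <- function(n, doc_ids = c("d1", "d2"), label = "SINTOMA") {
  starts <- sample.int(80L, n, replace = TRUE)
  tibble::tibble(
    doc_id = sample(doc_ids, n, replace = TRUE),
    start = starts,
    end = starts + sample.int(10L, n, replace = TRUE),
    label = label
  )
}
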