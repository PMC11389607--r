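test_that("sentence splitting records slice-exact offsets", {
  s <- split_sentences("A. B.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$start, c(0L, 3L))
  expect_equal(s$text, c("A.", "B."))

  one <- split_sentences("Paciente con fiebre alta")
  expect_equal(nrow(one), 1L)
  expect_equal(one$text, "Paciente con fiebre alta")
  expect_equal(one$start, 0L)

  doc <- "El paciente refiere dolor. Presenta fiebre alta. Sin tos."
  ss <- split_sentences(doc)
  for (i in seq_len(nrow(ss))) {
    expect_equal(
      substr(doc, ss$start[[i]] + 1L, ss$end[[i]]), ss$text[[i]]
    )
  }
})

test_that("abbreviations do not end sentences", {
  s <- split_sentences("El Dr. Gomez llego. Saludo.")
  expect_equal(nrow(s), 2L)
  expect_equal(s$text[[1]], "El Dr. Gomez llego.")
})

test_that("a boundary candidate inside a mention is suppressed", {
  doc <- "Presenta sindrome X. Y grave. Sin mas."
  # mention spans "X. Y grave" (positions 18-28), across the candidate boundary
  mentions <- tibble::tibble(start = 18L, end = 28L)
  with_m <- split_sentences(doc, mentions)
  expect_equal(nrow(with_m), 2L)
  expect_equal(with_m$text[[1]], "Presenta sindrome X. Y grave.")
  # without the mention the boundary splits the same text into three
  expect_equal(nrow(split_sentences(doc)), 3L)
})

test_that("IOB2 encoding follows the B/I/O contract", {
  enc <- encode_iob2(
    "fiebre alta hoy",
    tibble::tibble(start = 0L, end = 11L, label = "SINTOMA")
  )
  expect_equal(enc$tag, c("B-SINTOMA", "I-SINTOMA", "O"))
  expect_equal(attr(enc, "snapped"), 0L)

  none <- encode_iob2("sin hallazgos relevantes", tibble::tibble(
    start = integer(), end = integer(), label = character()
  ))
  expect_true(all(none$tag == "O"))

  # misaligned edges snap outward and are counted
  snap <- encode_iob2(
    "fiebre alta hoy",
    tibble::tibble(start = 2L, end = 9L, label = "SINTOMA")
  )
  expect_equal(snap$tag, c("B-SINTOMA", "I-SINTOMA", "O"))
  expect_equal(attr(snap, "snapped"), 1L)

  expect_error(
    encode_iob2("a b c", tibble::tibble(
      start = c(0L, 2L), end = c(3L, 5L), label = "S"
    )),
    class = "sympl_validation_error"
  )
})

test_that("decode inverts encode on aligned spans", {
  text <- "fiebre alta hoy y tos seca"
  spans <- tibble::tibble(
    start = c(0L, 18L), end = c(11L, 26L), label = c("SINTOMA", "SINTOMA")
  )
  enc <- encode_iob2(text, spans)
  dec <- decode_iob2(enc)
  expect_equal(dec, spans)
})

test_that("invalid IOB2 transitions are rejected at the contract boundary", {
  expect_true(validate_iob2(c("O", "B-S", "I-S", "O", "B-T")))
  expect_error(validate_iob2(c("O", "I-S")), class = "sympl_validation_error")
  expect_error(
    validate_iob2(c("B-S", "I-T")),
    class = "sympl_validation_error"
  )
})

test_that("bin_split bins by longest mention and splits 80/20 per bin", {
  mk_sentence <- function(id, len) {
    tibble::tibble(
      doc_id = "d", sentence_id = id,
      text = strrep("x", max(len, 1L) + 5L),
      mentions = list(if (len == 0L) {
        tibble::tibble(start = integer(), end = integer(), label = character())
      } else {
        tibble::tibble(start = 0L, end = len, label = "S")
      })
    )
  }
  sentences <- dplyr::bind_rows(
    mk_sentence("a", 37L), # short (< 38)
    mk_sentence("b", 38L), # medium (inclusive lower edge)
    mk_sentence("c", 90L), # medium (inclusive upper edge)
    mk_sentence("d", 91L), # long
    mk_sentence("e", 0L) # mention-free -> short
  )
  split <- bin_split(sentences, seed = 5L)
  all_rows <- dplyr::bind_rows(split$train, split$validation)
  expect_equal(
    setNames(all_rows$bin[match(sentences$sentence_id, all_rows$sentence_id)], NULL),
    c("short", "medium", "medium", "long", "short")
  )
  # partition: union is the input, disjoint
  expect_setequal(all_rows$sentence_id, sentences$sentence_id)
  expect_length(
    intersect(split$train$sentence_id, split$validation$sentence_id), 0L
  )

  # floor rule: a 5-sentence bin gives 4 train, 1 validation
  five <- dplyr::bind_rows(lapply(1:5, function(i) mk_sentence(paste0("s", i), 10L)))
  sp5 <- bin_split(five, seed = 1L)
  expect_equal(nrow(sp5$train), 4L)
  expect_equal(nrow(sp5$validation), 1L)

  # deterministic under a fixed seed
  sp5b <- bin_split(five, seed = 1L)
  expect_identical(sp5$train$sentence_id, sp5b$train$sentence_id)
})

test_that("synonym replacement shifts downstream offsets by the length delta", {
  sentences <- tibble::tibble(
    doc_id = "d", sentence_id = "s1",
    text = "tiene fiebre y tos fuerte",
    mentions = list(tibble::tibble(
      start = c(6L, 15L), end = c(12L, 18L), label = "S",
      code = c("C1", "C2"), text = c("fiebre", "tos")
    ))
  )
  synonym_map <- list(C1 = c("fiebre", "fiebre alta"), C2 = c("tos"))
  aug <- augment_by_synonyms(sentences, synonym_map, rate = 1, seed = 4L)
  expect_equal(nrow(aug), 2L) # original + one new example
  new <- aug[2, ]
  m <- new$mentions[[1]]
  expect_equal(new$text, "tiene fiebre alta y tos fuerte")
  expect_equal(m$start, c(6L, 20L)) # +5 shift after the longer synonym
  expect_equal(m$end, c(17L, 23L))
  # every mention re-slices to its recorded text
  for (j in seq_len(nrow(m))) {
    expect_equal(
      substr(new$text, m$start[[j]] + 1L, m$end[[j]]), m$text[[j]]
    )
  }
  # C2 had no alternative synonym: counted, left unchanged
  expect_equal(attr(aug, "unreplaceable"), 1L)
})

test_that("a vanishing replacement rate returns the input unchanged", {
  fx <- make_kb(fixture_spec(n_concepts = 10L, seed = 6L))
  sentences <- make_ner_corpus(fx, n_sentences = 20L, seed = 6L)
  aug <- augment_by_synonyms(sentences, fx$synonym_map, rate = 1e-12, seed = 1L)
  expect_equal(nrow(aug), nrow(sentences))
})

test_that("augmented corpora re-slice correctly on a seeded fixture", {
  fx <- make_kb(fixture_spec(n_concepts = 15L, seed = 9L))
  sentences <- make_ner_corpus(fx, n_sentences = 50L, seed = 9L)
  aug <- augment_by_synonyms(sentences, fx$synonym_map, rate = 0.5, seed = 2L)
  expect_gt(nrow(aug), nrow(sentences))
  new_rows <- aug[-seq_len(nrow(sentences)), ]
  originals <- setNames(sentences$mentions, sentences$sentence_id)
  for (i in seq_len(nrow(new_rows))) {
    m <- new_rows$mentions[[i]]
    orig <- originals[[sub("_aug$", "", new_rows$sentence_id[[i]])]]
    for (j in seq_len(nrow(m))) {
      expect_equal(
        substr(new_rows$text[[i]], m$start[[j]] + 1L, m$end[[j]]),
        m$text[[j]]
      )
      # a mention is either untouched or swapped for a same-code synonym
      expect_true(
        m$text[[j]] == orig$text[[j]] ||
          m$text[[j]] %in% fx$synonym_map[[m$code[[j]]]]
      )
    }
  }
})

test_that("the dictionary tagger tags maximal alias runs, leftmost-longest", {
  kb <- build_kb(dplyr::bind_rows(
    alias_row("fiebre", "C1"),
    alias_row("fiebre alta", "C1"),
    alias_row("alta presion", "C7")
  ))
  tagger <- dictionary_tagger(kb)
  tagged <- tagger("paciente con fiebre alta presion")
  # leftmost-longest: "fiebre alta" beats "fiebre" and pre-empts "alta presion"
  expect_equal(
    tagged$tag,
    c("O", "O", "B-SINTOMA", "I-SINTOMA", "O")
  )
  dec <- decode_iob2(tagged)
  expect_equal(dec$start, 13L)
  expect_equal(dec$end, 24L)

  clean <- tagger("sin hallazgos")
  expect_true(all(clean$tag == "O"))
  expect_true(validate_iob2(tagged$tag))
})
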