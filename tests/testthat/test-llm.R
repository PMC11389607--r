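five_candidates <- function() {
  tibble::tibble(
    rank = 1:5,
    surface = c("fiebre", "fiebre alta", "febricula", "tos", "disnea"),
    code = c("C1", "C1", "C5", "C2", "C4"),
    score = c(0.9, 0.8, 0.7, 0.3, 0.2)
  )
}

test_that("the reranking prompt contains mention, candidates, context and example verbatim", {
  cands <- five_candidates()
  example <- list(
    mention = "cefalea", candidates = cands[1:2, ], answer = "fiebre"
  )
  prompt <- build_rerank_prompt(
    "calentura", cands, "Paciente con calentura nocturna.", example, "es"
  )
  for (s in cands$surface) expect_true(grepl(s, prompt, fixed = TRUE))
  for (code in cands$code) expect_true(grepl(code, prompt, fixed = TRUE))
  expect_true(grepl("calentura", prompt, fixed = TRUE))
  expect_true(grepl("Paciente con calentura nocturna.", prompt, fixed = TRUE))
  expect_true(grepl("cefalea", prompt, fixed = TRUE))

  # empty context still renders a valid prompt
  p2 <- build_rerank_prompt("calentura", cands, "", NULL, "es")
  expect_true(grepl("calentura", p2, fixed = TRUE))

  expect_error(
    build_rerank_prompt("x", cands[0, ], "", NULL, "es"),
    class = "sympl_validation_error"
  )
})

test_that("prompt rendering is deterministic and order-sensitive only in the candidate block", {
  cands <- five_candidates()
  p1 <- build_rerank_prompt("calentura", cands, "ctx", NULL, "es")
  expect_identical(p1, build_rerank_prompt("calentura", cands, "ctx", NULL, "es"))
  flipped <- cands[5:1, ]
  flipped$rank <- 1:5
  p2 <- build_rerank_prompt("calentura", flipped, "ctx", NULL, "es")
  expect_false(identical(p1, p2))
  # outside the candidate block the prompts agree line for line
  l1 <- strsplit(p1, "\n")[[1]]
  l2 <- strsplit(p2, "\n")[[1]]
  block <- grepl("^[0-9]+\\. ", l1)
  expect_identical(l1[!block], l2[!block])
  expect_false(identical(l1[block], l2[block]))
})

test_that("the translation prompt quotes the mention and rejects Spanish input", {
  p <- build_translation_prompt("fever", "en")
  expect_true(grepl("fever", p, fixed = TRUE))
  p2 <- build_translation_prompt("night\nsweats", "en")
  expect_true(grepl("night\nsweats", p2, fixed = TRUE))
  expect_error(
    build_translation_prompt("fiebre", "es"),
    class = "sympl_validation_error"
  )
})

test_that("responses resolve surface-first, then code, in rank order", {
  cands <- five_candidates()
  expect_equal(
    parse_rerank_response("Fiebre  Alta", cands)$chosen_code, "C1"
  )
  expect_equal(parse_rerank_response("disnea", cands)$chosen_code, "C4")
  # code answer accepted when no surface matches
  expect_equal(parse_rerank_response("C5", cands)$chosen_code, "C5")
  # duplicate-surface rank order: first match wins
  dup <- cands
  dup$surface[3] <- "fiebre"
  expect_equal(parse_rerank_response("fiebre", dup)$chosen_surface, "fiebre")
  expect_equal(parse_rerank_response("fiebre", dup)$chosen_code, "C1")
})

test_that("out-of-candidate responses trigger the NO_CODE fallback", {
  cands <- five_candidates()
  out <- parse_rerank_response("hallucinated term", cands)
  expect_equal(out$chosen_code, NO_CODE)
  expect_true(out$fallback_triggered)
  empty <- parse_rerank_response("", cands)
  expect_equal(empty$chosen_code, NO_CODE)
  expect_true(empty$fallback_triggered)
})

test_that("parsing never returns a code outside the candidate set union NO_CODE", {
  cands <- five_candidates()
  withr::with_seed(31L, {
    responses <- c(
      cands$surface, cands$code, "",
      replicate(30L, paste(sample(letters, 8L), collapse = ""))
    )
  })
  for (r in responses) {
    code <- parse_rerank_response(r, cands)$chosen_code
    expect_true(code %in% c(cands$code, NO_CODE))
  }
})

test_that("lenient parsing accepts a candidate surface embedded in a longer answer", {
  cands <- five_candidates()
  strictly <- parse_rerank_response("The answer is fiebre alta.", cands)
  expect_equal(strictly$chosen_code, NO_CODE)
  leniently <- parse_rerank_response("The answer is fiebre alta.", cands,
    lenient = TRUE
  )
  expect_equal(leniently$chosen_code, "C1")
})

test_that("the scripted mock replays its script and errors on unknown prompts", {
  client <- mock_client(script = c("hola" = "fiebre"))
  expect_equal(client$complete("hola"), "fiebre")
  expect_error(client$complete("unknown"), class = "sympl_validation_error")
  relaxed <- mock_client(script = c("hola" = "fiebre"), strict = FALSE, default = "?")
  expect_equal(relaxed$complete("unknown"), "?")
})

test_that("the rule-mode mock picks the longest-common-prefix candidate", {
  client <- mock_client(rule = "longest_prefix")
  cands <- tibble::tibble(
    rank = 1:2, surface = c("fiebre alta", "tos"), code = c("C1", "C2"),
    score = c(0.5, 0.4)
  )
  ans <- client$complete("whatever prompt",
    meta = list(mention = "fiebre alt", candidates = cands)
  )
  # independent check of the rule
  lcp <- function(a, b) {
    n <- 0L
    while (n < min(nchar(a), nchar(b)) &&
      substr(a, n + 1L, n + 1L) == substr(b, n + 1L, n + 1L)) {
      n <- n + 1L
    }
    n
  }
  expect_equal(lcp("fiebre alt", "fiebre alta"), 10L)
  expect_equal(lcp("fiebre alt", "tos"), 0L)
  expect_equal(ans, "fiebre alta")
  expect_error(client$complete("prompt"), class = "sympl_validation_error")
})
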