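test_that("read_alias_table parses rows, skips empties, honours dialects", {
  path <- write_fixture_tsv(c(
    "code\tlanguage\tterm\tsemantic_tag\tmainterm",
    "11111009\tes\tfiebre\tfinding\t1",
    "22222003\tes\ttos\tfinding\t0"
  ))
  aliases <- read_alias_table(path)
  expect_equal(nrow(aliases), 2L)
  expect_setequal(aliases$code, c("11111009", "22222003"))
  expect_equal(aliases$is_main, c(TRUE, FALSE))
  expect_equal(attr(aliases, "skipped"), 0L)

  # empty term rows are dropped and counted
  path2 <- write_fixture_tsv(c(
    "code\tlanguage\tterm\tsemantic_tag\tmainterm",
    "11111009\tes\tfiebre\tfinding\t1",
    "22222003\tes\t\tfinding\t0"
  ))
  aliases2 <- read_alias_table(path2)
  expect_equal(nrow(aliases2), 1L)
  expect_equal(attr(aliases2, "skipped"), 1L)

  # permuted columns with a remapped dialect parse identically
  path3 <- write_fixture_tsv(c(
    "termino\tcodigo\tlang\tprincipal",
    "fiebre\t11111009\tes\t1",
    "tos\t22222003\tes\t0"
  ))
  remapped <- read_alias_table(path3, dialect = alias_dialect(
    code = "codigo", term = "termino", language = "lang",
    mainterm = "principal"
  ))
  expect_equal(
    as.data.frame(remapped[order(remapped$code), ]),
    as.data.frame(aliases[order(aliases$code), ])
  )

  expect_error(
    read_alias_table(path3),
    class = "sympl_config_error"
  )
  expect_error(
    read_alias_table(file.path(tempdir(), "does-not-exist.tsv")),
    class = "sympl_io_error"
  )
})

test_that("read_annotations preserves order, maps empty codes to NO_CODE, validates spans", {
  path <- write_fixture_tsv(c(
    "filename\tlabel\tstart_span\tend_span\ttext\tcode",
    "doc1\tSINTOMA\t5\t10\tfever\t386661006",
    "doc1\tSINTOMA\t12\t20\tstrange\t"
  ))
  ann <- read_annotations(path)
  expect_equal(ann$code, c("386661006", NO_CODE))
  expect_equal(ann$start, c(5L, 12L))

  bad <- write_fixture_tsv(c(
    "filename\tlabel\tstart_span\tend_span\ttext\tcode",
    "doc1\tSINTOMA\t10\t5\tfever\t386661006"
  ))
  expect_error(read_annotations(bad), class = "sympl_validation_error")
})

test_that("build_kb unions sources, dedupes on (norm, code), keeps ambiguous surfaces", {
  gaz <- alias_row("fiebre", "C1", is_main = TRUE)
  train_ann <- tibble::tibble(
    doc_id = "d1", label = "SINTOMA", start = 0L, end = 6L,
    text = "fiebre", code = "C1"
  )
  kb <- build_kb(list(gaz), train_ann)
  expect_equal(nrow(kb$aliases), 1L)
  expect_equal(kb$aliases$source, "gazetteer+train")
  expect_true(kb$aliases$is_main)

  # same surface under two codes stays two entries
  kb2 <- build_kb(dplyr::bind_rows(
    alias_row("macrocitose", "397073000"),
    alias_row("macrocitose", "72826005")
  ))
  expect_equal(sum(kb2$aliases$norm == "macrocitose"), 2L)

  # NO_CODE annotations never become aliases
  nc <- tibble::tibble(
    doc_id = "d1", label = "SINTOMA", start = 0L, end = 3L,
    text = "xyz", code = NO_CODE
  )
  kb3 <- build_kb(list(), nc)
  expect_equal(nrow(kb3$aliases), 0L)
  expect_s3_class(kb3, "sympl_kb")
})

test_that("build_kb is idempotent and the KB round-trips through TSV", {
  kb <- tiny_kb()
  again <- build_kb(
    dplyr::select(kb$aliases, -"norm"),
    language = kb$language
  )
  expect_equal(again, kb)

  path <- withr::local_tempfile(fileext = ".tsv")
  write_kb(kb, path)
  expect_equal(read_kb(path), kb)
})

test_that("rare-concept augmentation adds exactly n_new aliases below the threshold", {
  kb <- tiny_kb() # C1 has 2 aliases, C2/C3 one each
  before <- kb_alias_counts(kb)
  aug <- augment_rare_concepts(kb, rarity_threshold = 2L, n_new = 5L, seed = 9L)
  after <- kb_alias_counts(aug)
  merged <- dplyr::left_join(before, after,
    by = "code", suffix = c("_before", "_after")
  )
  expect_equal(
    merged$n_aliases_after,
    merged$n_aliases_before +
      ifelse(merged$n_aliases_before < 2L, 5L, 0L)
  )
  expect_true(all(
    aug$aliases$source[!aug$aliases$norm %in% kb$aliases$norm] == "augmented"
  ))
  # originals preserved
  expect_true(all(kb$aliases$norm %in% aug$aliases$norm))
})

test_that("augmented aliases are single edits of an original alias of the same code", {
  spec <- fixture_spec(n_concepts = 12L, seed = 3L)
  kb <- make_kb(spec)$kb
  aug <- augment_rare_concepts(kb, rarity_threshold = 5L, n_new = 5L, seed = 11L)
  new_rows <- aug$aliases[aug$aliases$source == "augmented", ]
  expect_gt(nrow(new_rows), 0L)
  for (i in seq_len(nrow(new_rows))) {
    originals <- kb$aliases$surface[kb$aliases$code == new_rows$code[[i]]]
    expect_equal(min(edit_distance(new_rows$surface[[i]], originals)), 1L)
  }
  # distinctness within each concept
  expect_equal(anyDuplicated(paste(aug$aliases$norm, aug$aliases$code)), 0L)
})

test_that("augmentation is deterministic under a fixed seed", {
  kb <- make_kb(fixture_spec(n_concepts = 8L, seed = 5L))$kb
  a1 <- augment_rare_concepts(kb, seed = 21L)
  a2 <- augment_rare_concepts(kb, seed = 21L)
  expect_identical(a1, a2)
  path1 <- withr::local_tempfile(fileext = ".tsv")
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_kb(a1, path1)
  write_kb(a2, path2)
  expect_identical(readLines(path1), readLines(path2))
})

test_that("single-character aliases never collapse to empty surfaces", {
  kb <- build_kb(alias_row("x", "C9"))
  aug <- augment_rare_concepts(kb, rarity_threshold = 5L, n_new = 5L, seed = 2L)
  expect_true(all(nchar(aug$aliases$surface) >= 1L))
  expect_equal(nrow(aug$aliases), 6L)
})
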