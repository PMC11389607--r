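#' Column dialects for alias and annotation tables
#'
#' Challenge releases drift in their TSV column names; a dialect maps the
#' canonical field names used internally to the column names found in the
#' file. The defaults follow the gazetteer and annotation layouts used by the
#' Spanish clinical shared-task releases.
#' Unknown extra columns in a file are ignored.
#'
#' @param code,term,language,mainterm Column names in an alias table.
#' @return A named character vector (canonical name -> file column name).
#' @export
alias_dialect <- function(code = "code", term = "term", language = "language",
                          mainterm = "mainterm") {
  c(code = code, term = term, language = language, mainterm = mainterm)
}

#' @rdname alias_dialect
#' @param filename,label,start_span,end_span,text Column names in an
#'   annotation table; `code` is shared with the alias dialect.
#' @export
annotation_dialect <- function(filename = "filename", label = "label",
                               start_span = "start_span", end_span = "end_span",
                               text = "text", code = "code") {
  c(
    filename = filename, label = label, start_span = start_span,
    end_span = end_span, text = text, code = code
  )
}

read_tsv_quiet <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read file: ", path), class = "sympl_io_error")
  }
  readr::read_tsv(path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, na = character()
  )
}

require_columns <- function(df, wanted, path) {
  missing <- setdiff(unname(wanted), names(df))
  if (length(missing) > 0L) {
    abort(
      paste0(
        "missing required column(s) in ", path, ": ",
        paste(missing, collapse = ", ")
      ),
      class = "sympl_config_error"
    )
  }
}

#' Read a concept-alias table (gazetteer, UMLS export, ...)
#'
#' Reads a tab-separated UTF-8 table with a header row and returns one alias
#' per data row. Rows whose code or term is empty after trimming are skipped;
#' the number of skipped rows is attached as attribute `"skipped"`.
#'
#' @param path Path to the TSV file.
#' @param source Provenance recorded on every alias; one of `"gazetteer"`,
#'   `"umls"`, `"train"`.
#' @param dialect Column-name mapping from [alias_dialect()].
#' @return A tibble with columns `surface`, `code`, `language`, `source`,
#'   `is_main`, carrying attribute `skipped` (count of dropped rows).
#' @export
read_alias_table <- function(path, source = "gazetteer",
                             dialect = alias_dialect()) {
  df <- read_tsv_quiet(path)
  require_columns(df, dialect[c("code", "term")], path)
  surface <- str_trim(df[[dialect[["term"]]]])
  code <- str_trim(df[[dialect[["code"]]]])
  language <- if (dialect[["language"]] %in% names(df)) {
    str_trim(df[[dialect[["language"]]]])
  } else {
    rep("es", nrow(df))
  }
  is_main <- if (dialect[["mainterm"]] %in% names(df)) {
    df[[dialect[["mainterm"]]]] %in% c("1", "TRUE", "True", "true", "yes")
  } else {
    rep(FALSE, nrow(df))
  }
  keep <- !is.na(surface) & surface != "" & !is.na(code) & code != ""
  out <- tibble(
    surface = surface[keep], code = code[keep],
    language = language[keep], source = source, is_main = is_main[keep]
  )
  attr(out, "skipped") <- sum(!keep)
  out
}

#' Read a span-annotation table
#'
#' Reads a tab-separated annotation table (document id, entity label,
#' character offsets, mention text, concept code). Offsets are 0-based,
#' end-exclusive, counted in Unicode code points. A missing or empty code is
#' mapped to the [NO_CODE] sentinel, mirroring corpora in which some mentions
#' have no concept in the terminology.
#'
#' @param path Path to the TSV file.
#' @param dialect Column-name mapping from [annotation_dialect()].
#' @return A tibble in file order with columns `doc_id`, `label`, `start`,
#'   `end`, `text`, `code`.
#' @export
read_annotations <- function(path, dialect = annotation_dialect()) {
  df <- read_tsv_quiet(path)
  require_columns(
    df, dialect[c("filename", "label", "start_span", "end_span", "text")], path
  )
  code <- if (dialect[["code"]] %in% names(df)) {
    str_trim(df[[dialect[["code"]]]])
  } else {
    rep("", nrow(df))
  }
  code[is.na(code) | code == ""] <- NO_CODE
  out <- tibble(
    doc_id = df[[dialect[["filename"]]]],
    label = df[[dialect[["label"]]]],
    start = as.integer(df[[dialect[["start_span"]]]]),
    end = as.integer(df[[dialect[["end_span"]]]]),
    text = df[[dialect[["text"]]]],
    code = code
  )
  bad <- which(!is.finite(out$start) | !is.finite(out$end) |
    out$start < 0L | out$start >= out$end)
  if (length(bad) > 0L) {
    abort(
      paste0("invalid span at row ", bad[[1L]], ": start must satisfy 0 <= start < end"),
      class = "sympl_validation_error"
    )
  }
  out
}

source_has <- function(source, what) {
  map_lgl(str_split(source, stringr::fixed("+")), ~ what %in% .x)
}

assert_kb <- function(kb) {
  if (!inherits(kb, "sympl_kb")) {
    abort("expected a knowledge base built by build_kb()",
      class = "sympl_validation_error"
    )
  }
  invisible(kb)
}

new_kb <- function(aliases, language) {
  structure(list(aliases = aliases, language = language), class = "sympl_kb")
}

#' Assemble a linking knowledge base from alias sources
#'
#' Takes any number of alias tables (gazetteer, UMLS synonym exports) plus,
#' optionally, training-set annotations whose (mention text, code) pairs are
#' folded in as aliases with provenance `"train"`. Aliases are deduplicated on
#' the pair (normalized surface, code); when the same pair arrives from
#' several sources the provenances are merged (recorded joined by `"+"`) and
#' the main-term flag is kept if any source set it. Annotations carrying the
#' [NO_CODE] sentinel are excluded: they name no concept.
#'
#' The same surface may legitimately map to several codes; all such rows are
#' kept and [dictionary_lookup()] resolves the ambiguity at query time.
#'
#' @param alias_sets A list of tibbles as returned by [read_alias_table()]
#'   (or a single tibble).
#' @param train_annotations Optional tibble from [read_annotations()].
#' @param language Language tag of the KB (`"es"`, `"fr"`, ... or `"mixed"`).
#' @return An object of class `sympl_kb`: a list with the alias tibble
#'   (`surface`, `code`, `language`, `source`, `is_main`, `norm`) and the KB
#'   language.
#' @export
build_kb <- function(alias_sets, train_annotations = NULL, language = "es") {
  if (is.data.frame(alias_sets)) alias_sets <- list(alias_sets)
  rows <- bind_rows(alias_sets)
  if (!is.null(train_annotations) && nrow(train_annotations) > 0L) {
    tr <- train_annotations |>
      filter(.data$code != NO_CODE) |>
      mutate(
        surface = .data$text, language = !!language,
        source = "train", is_main = FALSE
      ) |>
      select("surface", "code", "language", "source", "is_main")
    rows <- bind_rows(rows, tr)
  }
  if (nrow(rows) == 0L) {
    empty <- tibble(
      surface = character(), code = character(), language = character(),
      source = character(), is_main = logical(), norm = character()
    )
    return(new_kb(empty, language))
  }
  aliases <- rows |>
    mutate(norm = normalize_text(.data$surface)) |>
    filter(.data$norm != "", .data$code != "") |>
    group_by(.data$norm, .data$code) |>
    summarise(
      surface = first(.data$surface),
      language = first(.data$language),
      source = paste(sort(unique(unlist(
        str_split(.data$source, stringr::fixed("+"))
      ))), collapse = "+"),
      is_main = any(.data$is_main),
      .groups = "drop"
    ) |>
    select("surface", "code", "language", "source", "is_main", "norm") |>
    arrange(.data$code, .data$norm)
  new_kb(aliases, language)
}

#' @export
print.sympl_kb <- function(x, ...) {
  cat(
    "<knowledge base> ", nrow(x$aliases), " aliases, ",
    length(unique(x$aliases$code)), " concepts, language: ", x$language,
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Alias counts per concept code
#'
#' @param kb A knowledge base.
#' @return A tibble `code`, `n_aliases`.
#' @export
kb_alias_counts <- function(kb) {
  assert_kb(kb)
  kb$aliases |> count(.data$code, name = "n_aliases")
}

#' Synonym map (code -> surfaces) derived from a knowledge base
#'
#' Used by the NER synonym-replacement augmenter: replacing a mention with
#' another surface of the same code changes the wording but not the label.
#'
#' @param kb A knowledge base.
#' @return A named list mapping each code to its character vector of surfaces.
#' @export
kb_synonym_map <- function(kb) {
  assert_kb(kb)
  split(kb$aliases$surface, kb$aliases$code)
}

#' Persist / restore a knowledge base as a tab-separated file
#'
#' @param kb A knowledge base.
#' @param path Destination / source path.
#' @return `write_kb()` returns `path` invisibly; `read_kb()` returns a
#'   `sympl_kb` equal, field for field, to the one written.
#' @export
write_kb <- function(kb, path) {
  assert_kb(kb)
  kb$aliases |>
    select("surface", "code", "language", "source", "is_main") |>
    mutate(is_main = as.integer(.data$is_main)) |>
    readr::write_tsv(path, progress = FALSE)
  invisible(path)
}

#' @rdname write_kb
#' @param language KB language; `NULL` infers it from the stored aliases
#'   (`"mixed"` when several languages are present).
#' @export
read_kb <- function(path, language = NULL) {
  df <- read_tsv_quiet(path)
  require_columns(
    df, c("surface", "code", "language", "source", "is_main"), path
  )
  aliases <- tibble(
    surface = df$surface, code = df$code, language = df$language,
    source = df$source, is_main = df$is_main %in% c("1", "TRUE")
  )
  if (is.null(language)) {
    langs <- unique(aliases$language)
    language <- if (length(langs) == 1L) langs else "mixed"
  }
  kb <- build_kb(aliases, language = language)
  kb
}
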