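#' Construct a deterministic character n-gram hashing embedder
#'
#' The linking pipeline is written against a pluggable embedding backend: any
#' object with a dimension, an identifier, and an `embed(texts)` operation
#' returning one unit-norm row per input text. Production deployments plug a
#' cross-lingual biomedical sentence encoder in behind this contract; this
#' constructor provides the dependency-free reference backend used for
#' offline testing. Each text is decomposed into character n-grams, the
#' n-grams are hashed into `dim` buckets with a deterministic polynomial
#' rolling hash, counts are accumulated, and the vector is L2-normalized.
#' The empty string maps to a fixed unit basis vector.
#'
#' Surfaces of the same concept that share a character stem share n-grams and
#' therefore land close in cosine; unrelated stems are near-orthogonal (up to
#' occasional hash-bucket collisions).
#'
#' Every call to `$embed` increments an invocation counter readable with
#' [embedder_calls()], which makes short-circuit behaviour of the pipeline
#' observable in tests.
#'
#' @param dim Number of hash buckets (vector dimension), at least 8.
#' @param n Character n-gram order.
#' @return An object of class `sympl_embedder` with fields `id`, `dim`,
#'   `embed` (function: character vector -> numeric matrix).
#' @examples
#' be <- hash_embedder()
#' v <- be$embed(c("fiebre", "fiebres", "tos"))
#' cosine_similarity(v[1, ], v[2, ]) > cosine_similarity(v[1, ], v[3, ])
#' @export
hash_embedder <- function(dim = 256L, n = 3L) {
  stopifnot(dim >= 8L, n >= 1L)
  calls <- new.env(parent = emptyenv())
  calls$n <- 0L
  embed_one <- function(text) {
    v <- numeric(dim)
    if (is.na(text) || nchar(text) == 0L) {
      v[[1L]] <- 1
      return(v)
    }
    codes <- utf8ToInt(text)
    len <- length(codes)
    grams <- if (len < n) {
      list(codes)
    } else {
      lapply(seq_len(len - n + 1L), function(i) codes[i:(i + n - 1L)])
    }
    for (g in grams) {
      h <- 0
      for (c in g) h <- (h * 31 + c) %% dim
      v[[h + 1L]] <- v[[h + 1L]] + 1
    }
    v / sqrt(sum(v^2))
  }
  backend <- list(
    id = paste0("hash-ngram-", n, "-d", dim),
    dim = dim,
    embed = function(texts) {
      stopifnot(is.character(texts))
      calls$n <- calls$n + 1L
      m <- do.call(rbind, lapply(texts, embed_one))
      if (is.null(m)) m <- matrix(numeric(0), nrow = 0L, ncol = dim)
      rownames(m) <- NULL
      m
    },
    .calls = calls
  )
  structure(backend, class = "sympl_embedder")
}

#' Number of embed-batch invocations a backend has served
#'
#' @param backend A backend from [hash_embedder()] (or any backend exposing
#'   the same counter).
#' @return Integer count of `$embed` calls.
#' @export
embedder_calls <- function(backend) {
  backend$.calls$n
}

#' Cosine similarity of two vectors
#'
#' Standard cosine; on unit vectors it reduces to the dot product. A zero
#' vector has no direction and raises an error.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(u, v) {
  stopifnot(length(u) == length(v))
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    abort("cosine similarity is undefined for a zero vector",
      class = "sympl_numeric_error"
    )
  }
  sum(u * v) / (nu * nv)
}

#' Check an embedding backend against the pipeline's contract
#'
#' Runs the conformance suite any backend must satisfy before being plugged
#' into candidate generation: one output row per input text, unit Euclidean
#' norm (within `tol`), determinism for fixed input, and batch-order
#' equivariance (permuting the inputs permutes the rows identically).
#'
#' @param backend The backend to check.
#' @param texts Probe texts.
#' @param tol Norm tolerance.
#' @return `TRUE` invisibly; aborts with a description on violation.
#' @export
check_embedding_backend <- function(backend,
                                    texts = c("fiebre", "tos", "", "dolor abdominal"),
                                    tol = 1e-6) {
  m <- backend$embed(texts)
  if (nrow(m) != length(texts)) {
    abort("backend contract: row count must equal input text count")
  }
  if (ncol(m) != backend$dim) {
    abort("backend contract: column count must equal declared dim")
  }
  norms <- sqrt(rowSums(m^2))
  if (any(abs(norms - 1) > tol)) {
    abort("backend contract: rows must have unit Euclidean norm")
  }
  if (!identical(m, backend$embed(texts))) {
    abort("backend contract: embedding must be deterministic")
  }
  perm <- rev(seq_along(texts))
  if (max(abs(backend$embed(texts[perm]) - m[perm, , drop = FALSE])) > tol) {
    abort("backend contract: embedding must be batch-order equivariant")
  }
  invisible(TRUE)
}
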