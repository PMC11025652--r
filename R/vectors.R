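#' Construct a word-vector table
#'
#' @param vectors numeric matrix, one row per token, with rownames set to the
#'   tokens.
#' @return an object of class `word_vectors` with fields `matrix`, `dim`,
#'   `vocabulary`.
#' @export
word_vectors <- function(vectors) {
  stopifnot(is.matrix(vectors), !is.null(rownames(vectors)))
  if (anyDuplicated(rownames(vectors))) {
    stop("duplicate tokens in vector table", call. = FALSE)
  }
  structure(
    list(matrix = vectors, dim = ncol(vectors), vocabulary = rownames(vectors)),
    class = "word_vectors"
  )
}

#' @export
print.word_vectors <- function(x, ...) {
  cat("<word_vectors>", length(x$vocabulary), "tokens, dim", x$dim, "\n")
  invisible(x)
}

#' Look up one token's vector
#' @param wv a `word_vectors` table.
#' @param token a token.
#' @return numeric vector of length `wv$dim`.
#' @export
get_vector <- function(wv, token) {
  stopifnot(inherits(wv, "word_vectors"))
  if (!token %in% wv$vocabulary) {
    stop("token not in vector vocabulary: ", token, call. = FALSE)
  }
  wv$matrix[token, ]
}

#' Read word vectors in GloVe or fastText plain-text format
#'
#' The GloVe text dialect has one `token v1 ... vD` line per word and no
#' header; the fastText `.vec` dialect is identical except for a leading
#' `"count dim"` header line. Duplicate tokens are resolved first-occurrence
#' wins, with a warning.
#'
#' @param path file path.
#' @param dialect `"glove_text"` or `"fasttext_vec"`.
#' @return a `word_vectors` table.
#' @export
read_vectors <- function(path, dialect = c("glove_text", "fasttext_vec")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (dialect == "fasttext_vec") {
    if (length(lines) < 1L) stop("empty vector file: ", path, call. = FALSE)
    header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
    if (length(header) != 2L || anyNA(suppressWarnings(as.numeric(header)))) {
      stop("fasttext_vec file must begin with a 'count dim' header: ", path,
           call. = FALSE)
    }
    lines <- lines[-1]
  }
  if (length(lines) == 0L) stop("empty vector file: ", path, call. = FALSE)
  parts <- strsplit(trimws(lines), "\\s+")
  dim <- length(parts[[1]]) - 1L
  if (dim < 1L) stop("malformed vector line 1 in ", path, call. = FALSE)
  offset <- if (dialect == "fasttext_vec") 1L else 0L
  bad <- which(vapply(parts, length, 1L) != dim + 1L)
  if (length(bad) > 0L) {
    stop("wrong number of values at line ", bad[1] + offset, " of ", path,
         " (expected dim ", dim, ")", call. = FALSE)
  }
  tokens <- vapply(parts, `[`, "", 1L)
  vals <- vapply(parts, function(p) as.numeric(p[-1]), numeric(dim))
  mat <- if (dim == 1L) matrix(vals, ncol = 1L) else t(vals)
  if (anyNA(mat)) stop("non-numeric vector values in ", path, call. = FALSE)
  if (anyDuplicated(tokens)) {
    warning("duplicate tokens in ", path, "; keeping first occurrence")
    keep <- !duplicated(tokens)
    tokens <- tokens[keep]
    mat <- mat[keep, , drop = FALSE]
  }
  rownames(mat) <- tokens
  word_vectors(mat)
}

#' Write word vectors in GloVe or fastText plain-text format
#'
#' @param wv a `word_vectors` table.
#' @inheritParams read_vectors
#' @return `path`, invisibly.
#' @export
write_vectors <- function(wv, path, dialect = c("glove_text", "fasttext_vec")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(wv, "word_vectors"))
  body <- vapply(seq_along(wv$vocabulary), function(i) {
    paste(wv$vocabulary[i],
          paste(format(wv$matrix[i, ], digits = 17, scientific = FALSE,
                       trim = TRUE), collapse = " "))
  }, "")
  if (dialect == "fasttext_vec") {
    body <- c(paste(length(wv$vocabulary), wv$dim), body)
  }
  writeLines(body, path)
  invisible(path)
}

#' Cosine similarity between two vectors
#'
#' `dot(u, v) / (|u| |v|)`, clamped to `[-1, 1]` against floating-point
#' rounding. The angle is undefined for a zero vector.
#'
#' @param u,v numeric vectors of equal length.
#' @return cosine in `[-1, 1]`.
#' @export
cosine <- function(u, v) {
  if (length(u) != length(v)) {
    stop("vectors differ in dimension", call. = FALSE)
  }
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) {
    stop("cosine undefined for a zero vector", call. = FALSE)
  }
  min(1, max(-1, sum(u * v) / (nu * nv)))
}

#' Default context tokenization
#'
#' Whitespace split, lowercase, surrounding punctuation stripped.
#'
#' @param text a character scalar or a character vector of tokens.
#' @return character vector of tokens.
#' @export
tokenize_context <- function(text) {
  toks <- unlist(strsplit(text, "\\s+"))
  toks <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", tolower(toks))
  toks[nzchar(toks)]
}

#' Contextual cosine similarity (CCS)
#'
#' Cosine between the critical word's vector and the arithmetic mean of the
#' vectors of the in-vocabulary context tokens. Because cosine ignores
#' magnitude, using the sum of the context vectors gives the identical
#' result. Context tokens absent from the vocabulary are skipped; the
#' critical word itself must be in vocabulary.
#'
#' @param critical_word token whose similarity to its context is measured.
#' @param context_tokens character vector of preceding words (already
#'   tokenized; see [tokenize_context()]).
#' @param wv a `word_vectors` table.
#' @param combine `"mean"` or `"sum"` of context vectors (equivalent for the
#'   cosine; both kept for the equivalence check).
#' @return cosine in `[-1, 1]`.
#' @export
ccs <- function(critical_word, context_tokens, wv,
                combine = c("mean", "sum")) {
  combine <- match.arg(combine)
  target <- get_vector(wv, critical_word)
  present <- context_tokens[context_tokens %in% wv$vocabulary]
  if (length(present) == 0L) {
    stop("no context token in vector vocabulary for critical word '",
         critical_word, "'", call. = FALSE)
  }
  ctx <- wv$matrix[present, , drop = FALSE]
  agg <- if (combine == "mean") colMeans(ctx) else colSums(ctx)
  cosine(target, agg)
}

#' Best-completion cosine similarity (BCCS)
#'
#' Cosine between the critical word's vector and the vector of the frame's
#' best (highest-cloze) completion. For the Best condition the critical word
#' is the best completion, so BCCS is 1 by definition.
#'
#' @param critical_word token.
#' @param best_completion the frame's highest-cloze completion token.
#' @param wv a `word_vectors` table.
#' @return cosine in `[-1, 1]`.
#' @export
bccs <- function(critical_word, best_completion, wv) {
  cosine(get_vector(wv, critical_word), get_vector(wv, best_completion))
}

#' Pearson correlation matrix of the predictors
#'
#' @param table data frame of numeric predictor columns (e.g. the predictor
#'   table restricted to its numeric measures).
#' @param columns which columns to correlate; defaults to all numeric ones.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlate_predictors <- function(table, columns = NULL) {
  if (is.null(columns)) {
    columns <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  m <- as.matrix(table[columns])
  if (nrow(m) < 3L) stop("need at least 3 rows to correlate", call. = FALSE)
  const <- columns[apply(m, 2, function(x) stats::sd(x) == 0)]
  if (length(const) > 0L) {
    stop("constant column(s): ", paste(const, collapse = ", "),
         call. = FALSE)
  }
  r <- stats::cor(m)
  diag(r) <- 1
  r
}
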