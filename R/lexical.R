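#' Convert a natural-log probability to surprisal in bits
#'
#' Surprisal is the negative base-2 logarithm of a word's conditional
#' probability in context. Language-model APIs typically return natural-log
#' probabilities, so the conversion is `-log_prob / ln 2`.
#'
#' @param natural_log_prob natural-log probability, `<= 0`.
#' @return surprisal in bits, `>= 0`; 0 iff the probability is exactly 1.
#' @examples
#' surprisal_bits(log(0.5))  # 1 bit
#' @export
surprisal_bits <- function(natural_log_prob) {
  if (any(natural_log_prob > 0)) {
    stop("natural-log probability must be <= 0 (probability <= 1)",
         call. = FALSE)
  }
  -natural_log_prob / log(2)
}

#' Construct a toy table-driven language model
#'
#' A stand-in conditional-probability provider: a categorical distribution
#' over completion tokens per sentence frame. Tokens absent from a frame's
#' table receive a configurable floor probability and the distribution is
#' renormalized, so surprisal is always finite.
#'
#' @param table tibble with columns `frame_id`, `token`, `probability`;
#'   probabilities must be positive and sum to 1 within each frame.
#' @param floor_prob probability assigned to out-of-table completions.
#' @return an object of class `toy_lm` exposing conditional log
#'   probabilities via [lm_log_prob()].
#' @export
toy_lm <- function(table, floor_prob = 1e-8) {
  stopifnot(all(c("frame_id", "token", "probability") %in% names(table)),
            floor_prob > 0, floor_prob < 1)
  if (any(table$probability <= 0)) {
    stop("toy LM probabilities must be positive", call. = FALSE)
  }
  sums <- tapply(table$probability, table$frame_id, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    stop("toy LM distributions must sum to 1 per frame", call. = FALSE)
  }
  structure(list(table = tibble::as_tibble(table), floor_prob = floor_prob),
            class = "toy_lm")
}

#' @export
print.toy_lm <- function(x, ...) {
  cat("<toy_lm>", length(unique(x$table$frame_id)), "frames,",
      nrow(x$table), "completion entries, floor", x$floor_prob, "\n")
  invisible(x)
}

#' Conditional natural-log probability from a provider
#'
#' The provider contract: given a frame (or its context) and a completion
#' token, return the natural log of the conditional probability of the token.
#' For the toy LM, out-of-table tokens receive the floor probability and the
#' frame's distribution is renormalized so it still sums to exactly 1.
#'
#' @param provider a provider object (e.g. from [toy_lm()]).
#' @param frame_id frame identifier.
#' @param token completion token.
#' @return natural-log probability (scalar).
#' @export
lm_log_prob <- function(provider, frame_id, token) {
  UseMethod("lm_log_prob")
}

#' @export
lm_log_prob.toy_lm <- function(provider, frame_id, token) {
  rows <- provider$table[provider$table$frame_id == frame_id, ]
  if (nrow(rows) == 0L) {
    stop("toy LM has no distribution for frame: ", frame_id, call. = FALSE)
  }
  hit <- rows$probability[rows$token == token]
  if (length(hit) == 1L) log(hit) else log(provider$floor_prob)
}

#' Insert floor entries for extra tokens and renormalize exactly
#'
#' Adds the floor probability for each listed token missing from a frame's
#' table and rescales the frame's distribution so it sums to 1 exactly.
#'
#' @param lm a `toy_lm`.
#' @param tokens character vector of completion tokens to guarantee.
#' @return a new `toy_lm` whose per-frame distributions sum to 1.
#' @export
lm_insert_floor <- function(lm, tokens) {
  stopifnot(inherits(lm, "toy_lm"))
  parts <- lapply(split(lm$table, lm$table$frame_id), function(d) {
    missing <- setdiff(tokens, d$token)
    if (length(missing) > 0) {
      d <- dplyr::bind_rows(d, tibble::tibble(
        frame_id = d$frame_id[1], token = missing,
        probability = lm$floor_prob
      ))
    }
    d$probability <- d$probability / sum(d$probability)
    d
  })
  toy_lm(dplyr::bind_rows(parts), floor_prob = lm$floor_prob)
}

#' Vocabulary of a provider
#' @param provider a provider object.
#' @return character vector of tokens the provider covers natively.
#' @export
lm_vocabulary <- function(provider) UseMethod("lm_vocabulary")

#' @export
lm_vocabulary.toy_lm <- function(provider) unique(provider$table$token)

#' Surprisal of a critical word given its sentence frame
#'
#' Applies [surprisal_bits()] to the provider's conditional log probability
#' of the frame's critical word in the given condition.
#'
#' @param provider a conditional-probability provider.
#' @param frames stimulus tibble with `frame_id`, `condition`,
#'   `critical_word`.
#' @param frame_id,condition which item to score.
#' @param require_in_vocab error if the critical word is not natively in the
#'   provider vocabulary (mirrors the whole-token stimulus filter).
#' @return surprisal in bits.
#' @export
item_surprisal <- function(provider, frames, frame_id, condition,
                           require_in_vocab = TRUE) {
  row <- frames[frames$frame_id == frame_id & frames$condition == condition, ]
  if (nrow(row) != 1L) {
    stop("no unique stimulus row for frame ", frame_id, ", condition ",
         condition, call. = FALSE)
  }
  w <- row$critical_word
  if (require_in_vocab && !(w %in% lm_vocabulary(provider))) {
    stop("critical word not in provider vocabulary: ", w, call. = FALSE)
  }
  surprisal_bits(lm_log_prob(provider, frame_id, w))
}

#' Coltheart's N orthographic neighborhood size
#'
#' Counts lexicon entries of identical length that differ from the word at
#' exactly one character position. The word itself is never counted. Word and
#' lexicon are lowercased before comparison.
#'
#' @param word a non-empty token.
#' @param lexicon character vector of tokens.
#' @return nonnegative integer neighbor count.
#' @examples
#' coltheart_n("cat", c("bat", "cot", "cap", "dog"))  # 3
#' @export
coltheart_n <- function(word, lexicon) {
  stopifnot(is.character(word), length(word) == 1L)
  if (nchar(word) == 0L) stop("empty word", call. = FALSE)
  word <- tolower(word)
  lexicon <- unique(tolower(lexicon))
  lexicon <- lexicon[nchar(lexicon) == nchar(word) & lexicon != word]
  if (length(lexicon) == 0L) return(0L)
  wm <- strsplit(word, "")[[1]]
  lm <- strsplit(lexicon, "")
  sum(vapply(lm, function(ch) sum(ch != wm) == 1L, TRUE))
}

#' Serialize / read a toy language model as TSV
#'
#' Plain-text rows `frame_id  token  probability`.
#'
#' @param lm a `toy_lm` object.
#' @param path file path.
#' @return `read_toy_lm` returns a `toy_lm`; `write_toy_lm` returns `path`
#'   invisibly.
#' @export
write_toy_lm <- function(lm, path) {
  stopifnot(inherits(lm, "toy_lm"))
  utils::write.table(lm$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_toy_lm
#' @param floor_prob floor probability for the reconstructed model.
#' @export
read_toy_lm <- function(path, floor_prob = 1e-8) {
  tab <- tibble::as_tibble(utils::read.table(
    path, sep = "\t", header = TRUE,
    colClasses = c("character", "character", "numeric")
  ))
  toy_lm(tab, floor_prob = floor_prob)
}
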