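#' Normalize a cloze response token
#'
#' Responses from the sentence-completion task are lowercased, stripped of
#' surrounding whitespace and punctuation, and truncated to the first
#' whitespace-delimited token of a multi-word response. No spelling
#' correction is applied, so scoring is deterministic and auditable.
#'
#' @param x character vector of raw responses.
#' @return character vector of normalized tokens.
#' @export
normalize_response <- function(x) {
  x <- tolower(trimws(x))
  x <- sub("\\s.*$", "", x)            # first token only
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  x
}

#' Cloze probability of a word for one sentence frame
#'
#' Cloze probability is the proportion of norming participants who produced
#' the given word as the completion of the frame. Unattested words have
#' cloze 0.
#'
#' @param responses character vector of completion responses, one per
#'   respondent (normalized with [normalize_response()] unless
#'   `normalize = FALSE`).
#' @param word the completion token to score.
#' @param normalize apply response normalization before counting?
#' @return a probability in `[0, 1]`.
#' @examples
#' compute_cloze(c(rep("rest", 20), rep("sleep", 10), rep("sun", 5)), "rest")
#' @export
compute_cloze <- function(responses, word, normalize = TRUE) {
  if (length(responses) == 0L) {
    stop("empty cloze response set: at least one respondent required",
         call. = FALSE)
  }
  stopifnot(is.character(word), length(word) == 1L)
  if (normalize) {
    responses <- normalize_response(responses)
    word <- normalize_response(word)
  }
  sum(responses == word) / length(responses)
}

#' Cloze probabilities of every attested completion of a frame
#'
#' @inheritParams compute_cloze
#' @return a tibble with columns `response` and `cloze`, summing to 1.
#' @export
cloze_distribution <- function(responses, normalize = TRUE) {
  if (length(responses) == 0L) {
    stop("empty cloze response set: at least one respondent required",
         call. = FALSE)
  }
  if (normalize) responses <- normalize_response(responses)
  tab <- table(responses)
  tibble::tibble(
    response = names(tab),
    cloze = as.numeric(tab) / length(responses)
  )
}

#' Aggregate plausibility ratings
#'
#' Ratings are on a 1 (very plausible) to 5 (very implausible) scale.
#' Returns the arithmetic mean and the sample standard deviation
#' (n - 1 denominator; 0 for a single rating).
#'
#' @param ratings integer vector of ratings in 1..5.
#' @return a list with elements `mean` and `sd`.
#' @export
aggregate_plausibility <- function(ratings) {
  if (length(ratings) == 0L) {
    stop("empty plausibility rating set", call. = FALSE)
  }
  if (any(ratings < 1 | ratings > 5)) {
    stop("plausibility ratings must lie in 1..5", call. = FALSE)
  }
  list(
    mean = mean(ratings),
    sd = if (length(ratings) > 1L) stats::sd(ratings) else 0
  )
}

#' Apply the stimulus-selection filters
#'
#' A frame survives only if its four critical words appear as whole tokens in
#' every supplied vocabulary (the out-of-vocabulary filter). The retained set
#' is then checked for Related/Unrelated matching on cloze and plausibility:
#' the absolute difference of set-level means must not exceed the tolerance
#' and a Welch two-sample t-test must not reject at the configured p
#' threshold. Both checks are reported; the matching flags describe the
#' retained set rather than removing further frames.
#'
#' @param stimuli tibble with one row per frame x condition and columns
#'   `frame_id`, `condition`, `critical_word`, `cloze`, `plausibility_mean`.
#' @param vocabularies list of character vectors (token sets); a frame is
#'   retained only if all four critical words appear in every set.
#' @param cloze_tol,plaus_tol tolerances on the Related-vs-Unrelated mean
#'   difference (cloze probability units; rating units).
#' @param p_min minimum Welch t-test p-value for the groups to count as
#'   matched.
#' @return a list with `retained` (tibble, subset of input rows),
#'   `exclusions` (tibble `frame_id`, `reason`), and `matching`
#'   (tibble per measure: mean difference, t-test p, matched flag).
#' @export
select_stimuli <- function(stimuli, vocabularies,
                           cloze_tol = 0.01, plaus_tol = 0.2,
                           p_min = 0.2) {
  stopifnot(is.data.frame(stimuli), is.list(vocabularies))
  if (length(vocabularies) > 0 &&
      any(vapply(vocabularies, length, 1L) == 0L)) {
    stop("empty vocabulary supplied", call. = FALSE)
  }
  by_frame <- split(stimuli, stimuli$frame_id)
  bad <- vapply(by_frame, function(d) {
    !setequal(d$condition, CONDITIONS)
  }, TRUE)
  if (any(bad)) {
    stop("frames missing a condition: ",
         paste(names(by_frame)[bad], collapse = ", "), call. = FALSE)
  }

  exclusions <- tibble::tibble(frame_id = character(), reason = character())
  keep <- vapply(by_frame, function(d) {
    for (voc in vocabularies) {
      if (!all(d$critical_word %in% voc)) return(FALSE)
    }
    TRUE
  }, TRUE)
  if (any(!keep)) {
    exclusions <- tibble::tibble(
      frame_id = names(by_frame)[!keep], reason = "oov"
    )
  }
  retained <- dplyr::bind_rows(by_frame[keep])

  matching <- NULL
  if (nrow(retained) > 0) {
    rel <- retained[retained$condition == "Related", ]
    unr <- retained[retained$condition == "Unrelated", ]
    matching <- dplyr::bind_rows(lapply(
      c(cloze = "cloze", plausibility = "plausibility_mean"),
      function(col) {
        a <- rel[[col]]; b <- unr[[col]]
        dm <- abs(mean(a) - mean(b))
        p <- if (length(a) < 2 || length(b) < 2) {
          NA_real_  # too few frames for a group test; mean criterion only
        } else if (stats::sd(a) == 0 && stats::sd(b) == 0) {
          1
        } else {
          stats::t.test(a, b)$p.value
        }
        tol <- if (col == "cloze") cloze_tol else plaus_tol
        tibble::tibble(mean_diff = dm, t_p = p,
                       matched = dm <= tol && (is.na(p) || p > p_min))
      }), .id = "measure")
  }
  list(retained = retained, exclusions = exclusions, matching = matching)
}

#' Check the plausibility structure of the design
#'
#' By design, Implausible completions should be rated clearly implausible
#' (mean above 3.5) and all other conditions clearly plausible (mean below
#' 2). Items violating these bounds are flagged; nothing is removed.
#'
#' @param items tibble with `frame_id`, `condition`, `plausibility_mean`.
#' @return the input with logical column `plausibility_violation`.
#' @export
check_condition_plausibility <- function(items) {
  stopifnot(all(c("condition", "plausibility_mean") %in% names(items)))
  imp <- items$condition == "Implausible"
  items$plausibility_violation <- ifelse(
    imp, items$plausibility_mean <= 3.5, items$plausibility_mean >= 2
  )
  items
}
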