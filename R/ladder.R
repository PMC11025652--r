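model_label <- function(predictors) {
  if (length(predictors) == 0L) "null" else paste(predictors, collapse = " + ")
}

#' Run the four-stage model-comparison ladder
#'
#' Reproduces the staged analysis of single-trial N400 amplitude:
#' \describe{
#'   \item{Stage 1 (single factors)}{each of cloze, plausibility, GloVe CCS,
#'     fastText CCS, language-model surprisal and experimental condition as
#'     the sole predictor of interest, compared to the null model (covariates
#'     and random intercepts only) by null-normalized AIC and
#'     likelihood-ratio test.}
#'   \item{Stage 2 (combined accounts)}{every combination of a predictability
#'     measure (cloze, surprisal) with a contextual-similarity measure
#'     (GloVe CCS, fastText CCS); each combined model is tested against both
#'     of its single-predictor components.}
#'   \item{Stage 3 (plausibility)}{plausibility added to the best single
#'     predictability model (surprisal) and to the two cloze + CCS models.}
#'   \item{Stage 4 (relatedness to best completion)}{GloVe/fastText BCCS
#'     added to the same three base models; optionally re-run on the subset
#'     excluding Best-condition trials, since BCCS is 1 by definition there.}
#' }
#' All fits share covariates and crossed random intercepts and use maximum
#' likelihood. All LRT p-values of one invocation form one
#' Benjamini-Hochberg family by default. Stage winners are the
#' minimum-AIC models, declared "indistinguishable" when the runner-up is
#' within the substantiality threshold; the stage-1 designation ranges over
#' the single-variable models only, since the 4-level condition factor
#' bundles predictability, plausibility and relatedness information (its
#' AIC is still reported).
#'
#' @param data merged trial-amplitude x predictor table (see [fit_lmm()]).
#' @param stages integer subset of 1:4 to run.
#' @param alpha significance level applied to FDR-adjusted p-values.
#' @param delta_threshold AIC substantiality threshold (default 4).
#' @param fdr_family `"global"` (one family per invocation) or
#'   `"per_stage"`.
#' @param best_excluded re-run stage 4 with Best-condition trials excluded?
#' @param standardize passed to [build_spec()].
#' @return an object of class `comparison_report`: list with `models`
#'   (per-model AIC table), `tests` (LRT/FDR table), `winners` (per-stage
#'   winner designation), `alpha`, `n_obs`.
#' @export
run_ladder <- function(data, stages = 1:4, alpha = 0.05,
                       delta_threshold = 4,
                       fdr_family = c("global", "per_stage"),
                       best_excluded = TRUE, standardize = TRUE) {
  fdr_family <- match.arg(fdr_family)
  stages <- sort(unique(as.integer(stages)))
  stopifnot(all(stages %in% 1:4))

  cache <- new.env(parent = emptyenv())
  get_fit <- function(predictors, d) {
    key <- paste0(model_label(predictors), "@", nrow(d))
    if (!is.null(cache[[key]])) return(cache[[key]])
    f <- fit_lmm(build_spec(predictors, standardize = standardize), d)
    cache[[key]] <- f
    f
  }

  models <- list()
  tests <- list()
  add_model <- function(stage, analysis, predictors, fit, null_fit) {
    da <- if (is.null(null_fit)) list(delta = NA_real_, substantial = NA)
          else delta_aic(fit, null_fit)
    models[[length(models) + 1L]] <<- tibble::tibble(
      stage = stage, analysis = analysis,
      model = model_label(predictors),
      aic = fit$aic, log_likelihood = fit$log_likelihood,
      n_params = fit$n_params, delta_aic_null = da$delta,
      substantial = da$substantial, converged = fit$converged
    )
  }
  add_test <- function(stage, analysis, full_label, reduced_label, res,
                       added) {
    tests[[length(tests) + 1L]] <<- tibble::tibble(
      stage = stage, analysis = analysis, model = full_label,
      against = reduced_label, term_added = added,
      chi_sq = res$chi_sq, df = res$df, p_raw = res$p
    )
  }

  null_fit <- get_fit(character(), data)
  add_model(0L, "main", character(), null_fit, null_fit)

  singles <- c("cloze", "plausibility", "glove_ccs", "fasttext_ccs",
               "gpt3_surprisal", "condition")
  if (1L %in% stages) {
    for (p in singles) {
      f <- get_fit(p, data)
      add_model(1L, "main", p, f, null_fit)
      add_test(1L, "main", p, "null", lrt(f, null_fit), p)
    }
  }

  combos <- list(c("cloze", "glove_ccs"), c("cloze", "fasttext_ccs"),
                 c("gpt3_surprisal", "glove_ccs"),
                 c("gpt3_surprisal", "fasttext_ccs"))
  if (2L %in% stages) {
    for (pr in combos) {
      f <- get_fit(pr, data)
      add_model(2L, "main", pr, f, null_fit)
      for (base in pr) {
        fb <- get_fit(base, data)
        add_test(2L, "main", model_label(pr), base, lrt(f, fb),
                 setdiff(pr, base))
      }
    }
  }

  bases <- list("gpt3_surprisal", c("cloze", "glove_ccs"),
                c("cloze", "fasttext_ccs"))
  if (3L %in% stages) {
    for (b in bases) {
      fb <- get_fit(b, data)
      f <- get_fit(c(b, "plausibility"), data)
      add_model(3L, "main", c(b, "plausibility"), f, null_fit)
      add_test(3L, "main", model_label(c(b, "plausibility")),
               model_label(b), lrt(f, fb), "plausibility")
    }
  }

  if (4L %in% stages) {
    run_stage4 <- function(d, analysis) {
      nl <- if (analysis == "main") null_fit else get_fit(character(), d)
      for (b in bases) {
        fb <- get_fit(b, d)
        for (m in c("glove_bccs", "fasttext_bccs")) {
          f <- get_fit(c(b, m), d)
          add_model(4L, analysis, c(b, m), f, nl)
          add_test(4L, analysis, model_label(c(b, m)), model_label(b),
                   lrt(f, fb), m)
        }
      }
    }
    run_stage4(data, "main")
    if (best_excluded) {
      sub <- data[data$condition != "Best", , drop = FALSE]
      run_stage4(sub, "best_excluded")
    }
  }

  models <- dplyr::bind_rows(models)
  tests <- dplyr::bind_rows(tests)
  if (nrow(tests) > 0) {
    if (fdr_family == "global") {
      tests$p_fdr <- fdr_adjust(tests$p_raw)
    } else {
      tests <- dplyr::bind_rows(lapply(
        split(tests, tests$stage),
        function(d) { d$p_fdr <- fdr_adjust(d$p_raw); d }
      ))
    }
    tests$significant <- tests$p_fdr < alpha
  }

  winners <- NULL
  if (nrow(models) > 0) {
    winners <- dplyr::bind_rows(lapply(
      intersect(stages, unique(models$stage)), function(s) {
        m <- models[models$stage == s & models$analysis == "main", ]
        # the 4-level condition factor bundles predictability, plausibility
        # and relatedness into 3 parameters; it is reported but not eligible
        # as the "best single variable" designation
        if (s == 1L) m <- m[m$model != "condition", ]
        m <- m[order(m$aic), ]
        best <- m$model[1]
        indist <- nrow(m) > 1 && (m$aic[2] - m$aic[1]) < delta_threshold
        tibble::tibble(
          stage = s, winner = best,
          runner_up = if (nrow(m) > 1) m$model[2] else NA_character_,
          margin = if (nrow(m) > 1) m$aic[2] - m$aic[1] else NA_real_,
          decisive = !indist,
          designation = if (indist) {
            paste0("indistinguishable: ", best, " vs ", m$model[2])
          } else best
        )
      }))
  }

  structure(list(models = models, tests = tests, winners = winners,
                 alpha = alpha, delta_threshold = delta_threshold,
                 fdr_family = fdr_family, n_obs = nrow(data)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report>", x$n_obs, "observations\n")
  cat("Models (AIC relative to null):\n")
  m <- x$models[order(x$models$stage, x$models$analysis, x$models$aic), ]
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  [stage %d%s] %-50s dAIC %8.1f%s\n", m$stage[i],
                if (m$analysis[i] == "best_excluded") ", Best excl." else "",
                m$model[i], m$delta_aic_null[i],
                if (isTRUE(m$substantial[i])) " *" else ""))
  }
  if (!is.null(x$winners)) {
    cat("Stage winners:\n")
    for (i in seq_len(nrow(x$winners))) {
      cat("  stage", x$winners$stage[i], "->", x$winners$designation[i], "\n")
    }
  }
  invisible(x)
}

#' Per-condition z-scored predictor and amplitude summary
#'
#' Standardizes each variable across observations, averages within
#' experimental condition, and reports the standard error of the condition
#' mean. For comparability with the (negative-going) N400, surprisal and
#' plausibility are sign-flipped, so "up" means a reduced N400 for every
#' variable.
#'
#' @param table data frame with a `condition` column and numeric variables.
#' @param variables which columns to summarize; defaults to all numeric.
#' @param flip variables whose z-scores are multiplied by -1.
#' @return tibble `variable`, `condition`, `mean_z`, `se`, `n`.
#' @export
condition_summary <- function(table, variables = NULL,
                              flip = c("gpt3_surprisal", "plausibility")) {
  stopifnot("condition" %in% names(table))
  if (is.null(variables)) {
    variables <- names(table)[vapply(table, is.numeric, TRUE)]
  }
  out <- lapply(variables, function(v) {
    z <- zscore(table[[v]], v)
    if (v %in% flip) z <- -z
    d <- tibble::tibble(condition = table$condition, z = z)
    s <- dplyr::summarise(
      dplyr::group_by(d, .data$condition),
      mean_z = mean(.data$z),
      se = stats::sd(.data$z) / sqrt(dplyr::n()),
      n = dplyr::n(), .groups = "drop"
    )
    s$variable <- v
    s
  })
  dplyr::bind_rows(out)[, c("variable", "condition", "mean_z", "se", "n")]
}
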