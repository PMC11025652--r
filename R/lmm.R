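ALLOWED_PREDICTORS <- c("cloze", "plausibility", "glove_ccs", "fasttext_ccs",
                        "gpt3_surprisal", "condition", "glove_bccs",
                        "fasttext_bccs")
COVARIATES <- c("frequency", "orthographic_n")
RANDOM_INTERCEPTS <- c("subject", "frame_id", "word", "electrode")

#' Build a mixed-model specification
#'
#' Every model of the comparison ladder shares the same skeleton: the lexical
#' covariates (word frequency, orthographic neighborhood size) as fixed
#' effects and crossed random intercepts for subject, sentence frame,
#' critical word, and electrode. Candidate predictors are added on top. An
#' empty predictor list yields the null specification. Continuous predictors
#' are z-scored before fitting; `condition` is a 4-level factor with Best as
#' the reference level.
#'
#' @param predictors character vector drawn from `cloze`, `plausibility`,
#'   `glove_ccs`, `fasttext_ccs`, `gpt3_surprisal`, `condition`,
#'   `glove_bccs`, `fasttext_bccs`. May be empty (the null model).
#' @param standardize z-score continuous predictors and covariates before
#'   fitting (default TRUE).
#' @return an object of class `model_spec`.
#' @export
build_spec <- function(predictors = character(), standardize = TRUE) {
  predictors <- as.character(predictors)
  unknown <- setdiff(predictors, ALLOWED_PREDICTORS)
  if (length(unknown) > 0) {
    stop("unknown predictor(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(predictors)) {
    stop("duplicate predictor in specification", call. = FALSE)
  }
  fixed <- c(COVARIATES, predictors)
  rand <- paste0("(1 | ", RANDOM_INTERCEPTS, ")")
  formula_str <- paste(
    "amplitude ~", paste(c(fixed, rand), collapse = " + ")
  )
  structure(list(
    predictors = predictors,
    covariates = COVARIATES,
    random_intercepts = RANDOM_INTERCEPTS,
    formula = stats::as.formula(formula_str),
    formula_str = formula_str,
    standardize = standardize
  ), class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$formula_str, "\n")
  invisible(x)
}

# Prepare the modeling frame: factor coding, z-scoring, completeness checks.
prepare_model_data <- function(data, spec) {
  cols <- c("amplitude", spec$covariates, spec$predictors,
            spec$random_intercepts)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop("data lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- data[cols]
  if (anyNA(d)) stop("missing values in modeled columns", call. = FALSE)
  for (g in spec$random_intercepts) {
    d[[g]] <- factor(d[[g]])
    if (nlevels(d[[g]]) < 2L) {
      stop("random factor with < 2 levels: ", g, call. = FALSE)
    }
  }
  if ("condition" %in% names(d)) {
    d$condition <- factor(d$condition, levels = CONDITIONS)
  }
  if (spec$standardize) {
    # covariates are tolerated constant (lmer then drops the column, the
    # same way in every model of a comparison); predictors must vary
    for (v in spec$covariates) {
      if (stats::sd(d[[v]]) > 0) d[[v]] <- zscore(d[[v]], v)
    }
    for (v in setdiff(spec$predictors, "condition")) {
      d[[v]] <- zscore(d[[v]], v)
    }
  }
  d
}

#' Fit a linear mixed-effects model by maximum likelihood
#'
#' Fits the specification with `lme4::lmer` using full maximum likelihood
#' (not REML), so log-likelihoods and AICs are comparable across models that
#' differ in fixed effects. Singular fits (a random-effect variance estimated
#' at zero) are retained -- they are legitimate ML solutions -- but solver
#' non-convergence is flagged.
#'
#' @param spec a `model_spec` from [build_spec()].
#' @param data merged trial-amplitude x predictor table with columns
#'   `amplitude`, `subject`, `frame_id`, `word`, `electrode`, the covariates,
#'   and every predictor named in the spec.
#' @return an object of class `fit_result` with fields `spec`, `fit`,
#'   `log_likelihood`, `n_params`, `aic`, `coefficients`, `n_obs`,
#'   `converged`.
#' @export
fit_lmm <- function(spec, data) {
  stopifnot(inherits(spec, "model_spec"))
  d <- prepare_model_data(data, spec)
  fit <- withCallingHandlers(
    lme4::lmer(spec$formula, data = d, REML = FALSE,
               control = lme4::lmerControl(calc.derivs = FALSE)),
    message = function(m) invokeRestart("muffleMessage")
  )
  ll <- stats::logLik(fit)
  conv <- is.null(fit@optinfo$conv$lme4$messages) ||
    !any(grepl("failed to converge", fit@optinfo$conv$lme4$messages))
  structure(list(
    spec = spec,
    fit = fit,
    log_likelihood = as.numeric(ll),
    n_params = attr(ll, "df"),
    aic = 2 * attr(ll, "df") - 2 * as.numeric(ll),
    coefficients = lme4::fixef(fit),
    n_obs = nrow(d),
    converged = conv
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$spec$formula_str, "\n  logLik", round(x$log_likelihood, 2),
      " k", x$n_params, " AIC", round(x$aic, 2),
      if (!x$converged) " [NON-CONVERGED]" else "", "\n")
  invisible(x)
}

#' Null-normalized AIC difference
#'
#' `fit$aic - null_fit$aic`, with a substantiality flag at `|delta| >= 4`
#' (the conventional threshold for a substantial AIC difference).
#'
#' @param fit,null_fit `fit_result` objects fitted to the same data.
#' @return a list with `delta` and `substantial`.
#' @export
delta_aic <- function(fit, null_fit) {
  stopifnot(inherits(fit, "fit_result"), inherits(null_fit, "fit_result"))
  if (fit$n_obs != null_fit$n_obs) {
    stop("fits use different numbers of observations", call. = FALSE)
  }
  d <- fit$aic - null_fit$aic
  list(delta = d, substantial = abs(d) >= 4)
}

#' Likelihood-ratio test of nested maximum-likelihood fits
#'
#' `chi_sq = 2 (loglik_full - loglik_reduced)`, clamped at zero; degrees of
#' freedom are the difference in parameter counts; the p-value comes from
#' the upper tail of the chi-squared distribution.
#'
#' @param full,reduced `fit_result` objects on identical data; the reduced
#'   model's fixed terms must be a subset of the full model's.
#' @return a list with `chi_sq`, `df`, `p`.
#' @export
lrt <- function(full, reduced) {
  stopifnot(inherits(full, "fit_result"), inherits(reduced, "fit_result"))
  if (full$n_obs != reduced$n_obs) {
    stop("fits use different numbers of observations", call. = FALSE)
  }
  if (!all(reduced$spec$predictors %in% full$spec$predictors)) {
    stop("models are not nested: reduced predictors not a subset",
         call. = FALSE)
  }
  df <- full$n_params - reduced$n_params
  if (df <= 0) {
    if (df < 0) stop("full model has fewer parameters than reduced",
                     call. = FALSE)
    df <- 0L
  }
  chi <- max(0, 2 * (full$log_likelihood - reduced$log_likelihood))
  p <- if (df == 0L) 1 else stats::pchisq(chi, df, lower.tail = FALSE)
  list(chi_sq = chi, df = df, p = p)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values, clamped at 1, returned in the input order.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.finite(p)) || any(p <= 0 | p > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}
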