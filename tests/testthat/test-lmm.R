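test_that("model specifications carry covariates and the full random structure", {
  null_spec <- build_spec()
  expect_match(null_spec$formula_str, "frequency \\+ orthographic_n")
  expect_equal(length(null_spec$predictors), 0)
  spec2 <- build_spec(c("gpt3_surprisal", "glove_ccs"))
  expect_equal(spec2$predictors, c("gpt3_surprisal", "glove_ccs"))
  expect_equal(spec2$random_intercepts, null_spec$random_intercepts)
  expect_error(build_spec("not_a_predictor"), "unknown predictor")
  expect_error(build_spec(c("cloze", "cloze")), "duplicate")
})

test_that("maximum-likelihood fits recover a known slope and satisfy the AIC identity", {
  # zero random-effect variances, known slope: the fixed slope must be
  # recovered within 3 estimated standard errors
  ds <- simulate_dataset(sim_config(n_subjects = 6, n_frames = 12,
                                    sd_subject = 0, sd_frame = 0,
                                    sd_word = 0, sd_electrode = 0,
                                    sd_resid = 2, beta1 = -0.75, seed = 13))
  f <- fit_lmm(build_spec("gpt3_surprisal"), ds$model_data)
  est <- f$coefficients[["gpt3_surprisal"]]
  se <- sqrt(diag(as.matrix(stats::vcov(f$fit))))[["gpt3_surprisal"]]
  expect_lt(abs(est - (-0.75)), 3 * se)
  expect_equal(f$aic, 2 * f$n_params - 2 * f$log_likelihood,
               tolerance = 1e-9)
  expect_true(f$converged)
})

test_that("nesting never decreases the log-likelihood", {
  data <- small_sim()$model_data
  f0 <- fit_lmm(build_spec(), data)
  set.seed(17)
  data$noise_pred <- rnorm(length(unique(data$word)))[
    as.integer(factor(data$word))]
  # a pure-noise predictor cannot lower the maximized likelihood
  spec_noise <- build_spec("cloze")
  d2 <- data
  d2$cloze <- data$noise_pred
  f1 <- fit_lmm(spec_noise, d2)
  expect_gte(f1$log_likelihood, f0$log_likelihood - 1e-6)
})

test_that("missing data and degenerate random factors are rejected", {
  data <- small_sim()$model_data
  d <- data
  d$cloze[1] <- NA
  expect_error(fit_lmm(build_spec("cloze"), d), "missing values")
  d2 <- data[data$subject == data$subject[1], ]
  expect_error(fit_lmm(build_spec(), d2), "subject")
})

test_that("AIC differences against the null carry the substantiality convention", {
  data <- small_sim()$model_data
  f0 <- fit_lmm(build_spec(), data)
  f1 <- fit_lmm(build_spec("gpt3_surprisal"), data)
  self <- delta_aic(f0, f0)
  expect_identical(self$delta, 0)
  expect_false(self$substantial)
  d <- delta_aic(f1, f0)
  expect_equal(d$delta, f1$aic - f0$aic)
  # threshold semantics on synthetic fit results
  fake <- function(aic, n) structure(list(aic = aic, n_obs = n),
                                     class = "fit_result")
  expect_false(delta_aic(fake(103, 10), fake(100, 10))$substantial)
  expect_true(delta_aic(fake(104.5, 10), fake(100, 10))$substantial)
  expect_true(delta_aic(fake(95.5, 10), fake(100, 10))$substantial)
  expect_error(delta_aic(fake(1, 10), fake(1, 20)), "different numbers")
})

test_that("likelihood-ratio tests match the chi-squared tail oracle", {
  fake <- function(ll, k, preds = character()) {
    structure(list(log_likelihood = ll, n_params = k, n_obs = 100,
                   spec = list(predictors = preds)),
              class = "fit_result")
  }
  r <- lrt(fake(-98, 5, "x"), fake(-100, 4))
  expect_equal(r$chi_sq, 4)
  expect_equal(r$df, 1)
  expect_equal(r$p, stats::pchisq(4, 1, lower.tail = FALSE))
  expect_equal(r$p, 0.0455, tolerance = 1e-3)
  r3 <- lrt(fake(-96.095, 7, "x"), fake(-100, 4))
  expect_equal(r3$df, 3)
  expect_equal(r3$p, stats::pchisq(7.81, 3, lower.tail = FALSE),
               tolerance = 1e-3)
  # identical fits: chi-squared 0, p = 1
  same <- lrt(fake(-100, 4), fake(-100, 4))
  expect_equal(same$chi_sq, 0)
  expect_equal(same$p, 1)
  # negative likelihood difference clamps at zero
  clamp <- lrt(fake(-100.001, 5, "x"), fake(-100, 4))
  expect_equal(clamp$chi_sq, 0)
  expect_error(lrt(fake(-98, 5, "x"), fake(-97, 6, c("y", "z"))),
               "not nested")
})

test_that("BH adjustment equals the brute-force min-over-tail definition", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  set.seed(19)
  for (n in 1:12) {
    p <- runif(n)
    expect_equal(fdr_adjust(p), bh_bruteforce(p), tolerance = 1e-15)
  }
  expect_error(fdr_adjust(c(0.5, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("BH adjustment preserves input order and monotonicity", {
  set.seed(23)
  for (i in 1:10) {
    p <- runif(sample(2:12, 1))
    adj <- fdr_adjust(p)
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})
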