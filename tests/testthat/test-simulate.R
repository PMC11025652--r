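test_that("generated frames and vectors encode the intended semantic geometry", {
  cfg <- sim_config(n_subjects = 4, n_frames = 40, seed = 31)
  geo <- gen_frames_and_vectors(cfg)
  expect_equal(nrow(geo$frames), 40 * 4)
  expect_setequal(unique(geo$frames$condition),
                  c("Best", "Related", "Unrelated", "Implausible"))
  # same seed -> identical tables; different seed -> different
  geo2 <- gen_frames_and_vectors(cfg)
  expect_identical(geo$vectors$glove$matrix, geo2$vectors$glove$matrix)
  geo3 <- gen_frames_and_vectors(sim_config(n_frames = 40, seed = 32))
  expect_false(identical(geo$vectors$glove$matrix, geo3$vectors$glove$matrix))
  # BCCS separates Related from Unrelated at many Monte-Carlo SEs
  lm <- gen_toy_lm(cfg, geo)
  cloze <- gen_cloze_responses(lm, 35, 1)
  plaus <- gen_plausibility(cfg, geo$frames, 2)
  pred <- build_predictor_table(geo, lm, cloze, plaus)
  rel <- pred$glove_bccs[pred$condition == "Related"]
  unr <- pred$glove_bccs[pred$condition == "Unrelated"]
  se <- sqrt(var(rel) / length(rel) + var(unr) / length(unr))
  expect_gt(mean(rel) - mean(unr), 5 * se)
  # CCS ordering: Best >= Related > Implausible on average
  ccs_mean <- tapply(pred$glove_ccs, pred$condition, mean)
  expect_gte(ccs_mean[["Best"]], ccs_mean[["Related"]] - 1e-9)
  expect_gt(ccs_mean[["Related"]], ccs_mean[["Implausible"]])
  expect_error(gen_frames_and_vectors(sim_config(embedding_dim = 1)),
               "embedding_dim")
})

test_that("zero geometry noise makes the Related vector equal the Best vector", {
  geo <- gen_frames_and_vectors(
    sim_config(n_frames = 5, noise_related = 0, noise_embedding_set = 0,
               seed = 33))
  b <- geo$frames[geo$frames$condition == "Best", ]
  r <- geo$frames[geo$frames$condition == "Related", ]
  for (i in 1:5) {
    expect_equal(bccs(r$critical_word[i], b$critical_word[i],
                      geo$vectors$glove),
                 1, tolerance = 1e-12)
  }
})

test_that("the toy language model mirrors the cloze profile of the design", {
  cfg <- sim_config(n_frames = 10, seed = 35)
  geo <- gen_frames_and_vectors(cfg)
  lm <- gen_toy_lm(cfg, geo)
  sums <- tapply(lm$table$probability, lm$table$frame_id, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  frames <- geo$frames
  s <- sapply(c("Best", "Related", "Unrelated", "Implausible"), function(cc) {
    item_surprisal(lm, frames, "f001", cc)
  })
  expect_lt(s[["Best"]], s[["Related"]])
  expect_equal(s[["Related"]], s[["Unrelated"]])
  expect_lt(s[["Unrelated"]], s[["Implausible"]])
  expect_error(
    gen_toy_lm(sim_config(lm_probs = c(Best = 0.9, Related = 0.2,
                                       Unrelated = 0.02,
                                       Implausible = 1e-6)), geo),
    "sum above 1")
})

test_that("cloze responses converge to generating probabilities at binomial rate", {
  cfg <- sim_config(n_frames = 3, seed = 37)
  geo <- gen_frames_and_vectors(cfg)
  lm <- gen_toy_lm(cfg, geo)
  resp <- gen_cloze_responses(lm, 10000, 41)
  best_word <- geo$frames$critical_word[geo$frames$condition == "Best" &
                                        geo$frames$frame_id == "f001"]
  est <- compute_cloze(resp$response[resp$frame_id == "f001"], best_word,
                       normalize = FALSE)
  expect_lt(abs(est - 0.5), 3 * sqrt(0.5 * 0.5 / 10000))
  # determinism
  resp2 <- gen_cloze_responses(lm, 10000, 41)
  expect_identical(resp, resp2)
  # degenerate single-completion distribution -> cloze exactly 1
  lm1 <- toy_lm(tibble::tibble(frame_id = "g", token = "only",
                               probability = 1))
  r1 <- gen_cloze_responses(lm1, 12, 1)
  expect_equal(compute_cloze(r1$response, "only"), 1)
})

test_that("plausibility ratings stay on scale and separate conditions", {
  cfg <- sim_config(n_frames = 20, seed = 43)
  geo <- gen_frames_and_vectors(cfg)
  pl <- gen_plausibility(cfg, geo$frames, 45)
  expect_true(all(pl$rating %in% 1:5))
  means <- tapply(pl$rating, pl$condition, mean)
  expect_gt(means[["Implausible"]], 3.5)
  expect_lt(max(means[c("Best", "Related", "Unrelated")]), 2)
  # zero rater noise: every rating equals the rounded condition mean
  cfg0 <- sim_config(n_frames = 3, plaus_sd = 0, seed = 43)
  pl0 <- gen_plausibility(cfg0, gen_frames_and_vectors(cfg0)$frames, 45)
  expect_true(all(pl0$rating[pl0$condition == "Implausible"] == 4))
  expect_true(all(pl0$rating[pl0$condition == "Best"] == 1))
})

test_that("trial amplitudes follow the generative crossed mixed model", {
  # all variances zero and no driver: every amplitude equals the intercept
  cfg0 <- sim_config(n_subjects = 3, n_frames = 4, driver = "none",
                     beta1 = 0, sd_subject = 0, sd_frame = 0, sd_word = 0,
                     sd_electrode = 0, sd_resid = 0, seed = 47)
  ds0 <- simulate_dataset(cfg0)
  expect_true(all(ds0$amplitudes$amplitude == cfg0$beta0))
  # full crossing: subjects x frames x conditions x electrodes
  expect_equal(nrow(ds0$amplitudes), 3 * 4 * 4 * 9)
  # negative surprisal slope orders condition means as the N400 does:
  # Implausible most negative, Best most positive
  ds <- simulate_dataset(sim_config(n_subjects = 12, n_frames = 30,
                                    seed = 49))
  m <- tapply(ds$amplitudes$amplitude, ds$amplitudes$condition, mean)
  expect_lt(m[["Implausible"]], m[["Unrelated"]])
  expect_lt(m[["Unrelated"]], m[["Best"]])
  expect_error(sim_config(sd_resid = -1), "nonnegative")
})

test_that("variance components of simulated amplitudes match the configuration", {
  cfg <- sim_config(n_subjects = 200, n_frames = 40, driver = "none",
                    beta1 = 0, seed = 51)
  ds <- simulate_dataset(cfg)
  gt <- ds$ground_truth
  # realized random-intercept spread matches the configured SDs (moments)
  expect_equal(stats::sd(gt$u_subject), cfg$sd_subject, tolerance = 0.15)
  expect_equal(stats::sd(gt$residual), cfg$sd_resid, tolerance = 0.05)
  # method-of-moments on the amplitudes themselves: total variance within 10%
  total <- cfg$sd_subject^2 + cfg$sd_frame^2 + cfg$sd_word^2 +
    cfg$sd_electrode^2 + cfg$sd_resid^2
  expect_equal(var(ds$amplitudes$amplitude), total, tolerance = 0.1)
})

test_that("simulated datasets are reproducible end to end", {
  cfg <- sim_config(n_subjects = 3, n_frames = 5, waveform = TRUE,
                    artifact_rate = 0.05, seed = 53)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$predictors, b$predictors)
  expect_identical(a$amplitudes, b$amplitudes)
  expect_identical(a$epochs$voltages, b$epochs$voltages)
  expect_identical(a$artifact_truth, b$artifact_truth)
})

test_that("waveform rendering scales amplitudes by the closed-form window factor", {
  cfg <- sim_config(n_subjects = 3, n_frames = 6, waveform = TRUE,
                    sensor_noise_sd = 0, seed = 55)
  ds <- simulate_dataset(cfg)
  k <- component_window_factor(cfg)
  amp <- n400_amplitude(ds$epochs)
  m <- dplyr::inner_join(amp, ds$amplitudes,
                         by = c("subject", "frame_id", "condition",
                                "word", "electrode"),
                         suffix = c("_extracted", "_generating"))
  expect_equal(m$amplitude_extracted, m$amplitude_generating * k,
               tolerance = 1e-12)
  expect_error(sim_config(bump_center = 2000), "outside the epoch")
})

test_that("injected artifacts are recovered by rejection at default thresholds", {
  cfg <- sim_config(n_subjects = 6, n_frames = 10, waveform = TRUE,
                    artifact_rate = 0.1, seed = 57)
  ds <- simulate_dataset(cfg)
  ep <- baseline_correct(rereference(ds$epochs))
  ep <- reject_artifacts(ep, channels = N400_CLUSTER)
  injected <- which(ds$artifact_truth)
  expect_gte(mean(injected %in% which(ep$rejected)), 0.95)
  # clean trials are mostly retained
  expect_lt(mean(ep$rejected[!ds$artifact_truth]), 0.05)
})
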