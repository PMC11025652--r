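#' Simulation configuration
#'
#' All generative parameters of the synthetic dataset: design counts, the
#' embedding geometry, the toy language model's condition probabilities,
#' norming-sample sizes, the generative linear mixed model for single-trial
#' N400 amplitudes, and (optionally) the waveform renderer. Defaults emulate
#' the study design this package models: four completion conditions per
#' sentence frame (Best / Related / Unrelated / Implausible), a best
#' completion with cloze near 0.5, low-cloze Related and Unrelated
#' completions matched on cloze and plausibility, Implausible completions
#' with near-zero probability, and amplitudes generated from crossed random
#' intercepts (subject, frame, word, electrode) plus Gaussian residual
#' noise.
#'
#' @param n_subjects,n_frames design counts (the study-scale design is 125
#'   frames; the default 60 keeps routine runs light).
#' @param electrodes electrode labels of the analysis cluster.
#' @param embedding_dim embedding dimensionality.
#' @param driver which predictor generates the amplitudes: `"surprisal"`,
#'   `"ccs"` (GloVe-set CCS), or `"none"` (null data).
#' @param beta0 fixed intercept (µV).
#' @param beta1 driver slope (µV per SD of the driver; negative = larger
#'   N400 for higher surprisal).
#' @param sd_subject,sd_frame,sd_word,sd_electrode random-intercept SDs (µV).
#' @param sd_resid residual SD (µV).
#' @param lm_probs named completion probabilities per condition.
#' @param n_distractors distractor completions absorbing the remaining
#'   toy-LM probability mass.
#' @param n_context context tokens per frame.
#' @param noise_context,noise_best,noise_related,noise_unrelated,noise_implausible
#'   geometry noise scales (per-dimension SDs relative to the unit topic
#'   direction).
#' @param unrelated_topic_mix weight of the topic direction in the Unrelated
#'   vector (keeps it in the plausible region while far from Best).
#' @param noise_embedding_set independent per-set noise distinguishing the
#'   GloVe-like from the fastText-like table.
#' @param n_cloze_respondents,n_raters norming sample sizes.
#' @param plaus_means named per-condition plausibility means (1-5 scale).
#' @param plaus_sd rater SD of plausibility ratings.
#' @param waveform render single-trial waveforms (epochs) as well?
#' @param srate,window epoch grid (Hz; ms, half-open).
#' @param bump_center,bump_width N400-like Gaussian component center and SD
#'   (ms).
#' @param sensor_noise_sd marginal SD of the additive AR(1) sensor noise
#'   (µV).
#' @param ar_coef AR(1) coefficient of the sensor noise.
#' @param artifact_rate per-trial probability of an injected blink-like
#'   artifact.
#' @param artifact_amplitude artifact peak amplitude (µV).
#' @param mastoids labels of the two mastoid reference channels.
#' @param seed master seed; every generator draws from a named substream of
#'   it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 20, n_frames = 60,
                       electrodes = N400_CLUSTER,
                       embedding_dim = 50,
                       driver = c("surprisal", "ccs", "none"),
                       beta0 = 2, beta1 = -0.75,
                       sd_subject = 1, sd_frame = 0.5, sd_word = 0.5,
                       sd_electrode = 0.25, sd_resid = 5,
                       lm_probs = c(Best = 0.5, Related = 0.02,
                                    Unrelated = 0.02, Implausible = 1e-6),
                       n_distractors = 10,
                       n_context = 6,
                       noise_context = 0.6, noise_best = 0.15,
                       noise_related = 0.25, noise_unrelated = 0.8,
                       noise_implausible = 0.3,
                       unrelated_topic_mix = 0.3,
                       noise_embedding_set = 0.05,
                       n_cloze_respondents = 35, n_raters = 30,
                       plaus_means = c(Best = 1.4, Related = 1.5,
                                       Unrelated = 1.5, Implausible = 4.3),
                       plaus_sd = 0.7,
                       waveform = FALSE,
                       srate = 250, window = c(-100, 900),
                       bump_center = 400, bump_width = 75,
                       sensor_noise_sd = 2, ar_coef = 0.7,
                       artifact_rate = 0, artifact_amplitude = 200,
                       mastoids = c("A1", "A2"),
                       seed = 1L) {
  driver <- match.arg(driver)
  cfg <- as.list(environment())
  sds <- c(sd_subject, sd_frame, sd_word, sd_electrode, sd_resid)
  if (any(sds < 0)) stop("random-effect SDs must be nonnegative",
                         call. = FALSE)
  if (!setequal(names(lm_probs), CONDITIONS)) {
    stop("lm_probs must name the four conditions", call. = FALSE)
  }
  if (any(lm_probs <= 0) || any(lm_probs >= 1)) {
    stop("lm_probs must lie in (0, 1)", call. = FALSE)
  }
  if (sum(lm_probs) > 1) {
    stop("condition probabilities sum above 1", call. = FALSE)
  }
  if (any(plaus_means < 1 | plaus_means > 5)) {
    stop("plausibility means must lie in [1, 5]", call. = FALSE)
  }
  if (embedding_dim < 2) stop("embedding_dim must be >= 2", call. = FALSE)
  if (bump_center < window[1] || bump_center > window[2]) {
    stop("component center lies outside the epoch window", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_subjects, "subjects x", x$n_frames,
      "frames x 4 conditions x", length(x$electrodes), "electrodes;",
      "driver =", x$driver, "; seed =", x$seed, "\n")
  invisible(x)
}

# Sample `n` unique letter-string tokens. A small alphabet and short lengths
# give the synthetic lexicon a nontrivial orthographic neighborhood
# structure (Coltheart's N is mostly nonzero, as for real words).
gen_tokens <- function(n, alphabet = letters[1:8], lengths = 4:5) {
  pool <- character(0)
  for (len in lengths) {
    grid <- do.call(expand.grid, rep(list(alphabet), len))
    pool <- c(pool, do.call(paste0, grid))
  }
  if (n > length(pool)) stop("token pool exhausted", call. = FALSE)
  sample(pool, n)
}

#' Generate sentence frames and word-vector tables
#'
#' Each frame gets a latent unit "topic" direction. Context-word vectors
#' scatter around the topic; the Best completion sits near the topic; the
#' Related completion is the Best vector plus small noise; the Unrelated
#' completion lies in the plausible region (a weak topic component) but far
#' from the Best vector; the Implausible completion points along an
#' independent random direction. Two vector tables (GloVe-like and
#' fastText-like) are produced as independent small-noise realizations of
#' the same latent vectors. Expected orderings:
#' `E[BCCS(Related)] > E[BCCS(Unrelated)]` and
#' `E[CCS(Best)] >= E[CCS(Related)] > E[CCS(Implausible)]`.
#'
#' @param config a `sim_config`.
#' @return list with `frames` (tibble: `frame_id`, `condition`,
#'   `critical_word`, `best_completion`, `context`, `frequency`),
#'   `vectors` (list `glove`, `fasttext` of `word_vectors`), and
#'   `topics` (matrix of latent topic directions, ground truth).
#' @export
gen_frames_and_vectors <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(substream_seed(config$seed, "geometry"), {
    nf <- config$n_frames
    d <- config$embedding_dim
    frame_ids <- sprintf("f%03d", seq_len(nf))
    n_words <- nf * 4
    n_ctx <- nf * config$n_context
    n_dis <- nf * config$n_distractors
    toks <- gen_tokens(n_words + n_ctx + n_dis)
    crit <- matrix(toks[seq_len(n_words)], nrow = nf)
    colnames(crit) <- CONDITIONS
    ctx <- matrix(toks[n_words + seq_len(n_ctx)], nrow = nf)
    dis <- matrix(toks[n_words + n_ctx + seq_len(n_dis)], nrow = nf)

    topics <- matrix(rnorm(nf * d), nf, d)
    topics <- topics / sqrt(rowSums(topics^2))

    latent <- matrix(0, n_words + n_ctx + n_dis, d)
    rownames(latent) <- c(as.vector(crit), as.vector(ctx), as.vector(dis))
    for (f in seq_len(nf)) {
      t_f <- topics[f, ]
      best <- t_f + rnorm(d, 0, config$noise_best / sqrt(d))
      related <- best + rnorm(d, 0, config$noise_related / sqrt(d))
      unrel <- config$unrelated_topic_mix * t_f +
        rnorm(d, 0, config$noise_unrelated / sqrt(d))
      imp_dir <- rnorm(d); imp_dir <- imp_dir / sqrt(sum(imp_dir^2))
      imp <- imp_dir + rnorm(d, 0, config$noise_implausible / sqrt(d))
      latent[crit[f, "Best"], ] <- best
      latent[crit[f, "Related"], ] <- related
      latent[crit[f, "Unrelated"], ] <- unrel
      latent[crit[f, "Implausible"], ] <- imp
      for (j in seq_len(config$n_context)) {
        latent[ctx[f, j], ] <- t_f + rnorm(d, 0, config$noise_context / sqrt(d))
      }
      for (j in seq_len(config$n_distractors)) {
        dd <- rnorm(d); latent[dis[f, j], ] <- dd / sqrt(sum(dd^2))
      }
    }
    make_set <- function() {
      m <- latent + matrix(rnorm(length(latent), 0,
                                 config$noise_embedding_set / sqrt(d)),
                           nrow(latent), d)
      word_vectors(m)
    }
    vectors <- list(glove = make_set(), fasttext = make_set())

    frames <- tibble::tibble(
      frame_id = rep(frame_ids, each = 4),
      condition = rep(CONDITIONS, times = nf),
      critical_word = as.vector(t(crit)),
      best_completion = rep(crit[, "Best"], each = 4),
      context = rep(apply(ctx, 1, paste, collapse = " "), each = 4),
      frequency = runif(n_words, 1.5, 6.5)  # Zipf-style log per-billion
    )
    list(frames = frames, vectors = vectors, topics = topics,
         distractors = dis)
  })
}

#' Generate the toy language model for a frame set
#'
#' Per frame, a categorical distribution assigning the configured condition
#' probabilities to the four critical words and spreading the remaining mass
#' evenly over the frame's distractor completions, summing to 1 exactly.
#'
#' @param config a `sim_config`.
#' @param geometry output of [gen_frames_and_vectors()].
#' @return a `toy_lm`.
#' @export
gen_toy_lm <- function(config, geometry) {
  stopifnot(inherits(config, "sim_config"))
  frames <- geometry$frames
  dis <- geometry$distractors
  rest <- 1 - sum(config$lm_probs)
  rows <- lapply(seq_len(config$n_frames), function(f) {
    fid <- frames$frame_id[(f - 1) * 4 + 1]
    d <- frames[frames$frame_id == fid, ]
    tibble::tibble(
      frame_id = fid,
      token = c(d$critical_word[match(CONDITIONS, d$condition)], dis[f, ]),
      probability = c(unname(config$lm_probs[CONDITIONS]),
                      rep(rest / config$n_distractors, config$n_distractors))
    )
  })
  toy_lm(dplyr::bind_rows(rows))
}

#' Generate cloze-task responses
#'
#' Each respondent's completion of each frame is an independent draw from
#' the frame's toy-LM distribution, so empirical cloze probabilities
#' converge to the generating probabilities with binomial standard error.
#'
#' @param lm a `toy_lm`.
#' @param n_respondents respondents per frame.
#' @param seed substream seed.
#' @return tibble `frame_id`, `respondent_id`, `response`.
#' @export
gen_cloze_responses <- function(lm, n_respondents, seed) {
  stopifnot(inherits(lm, "toy_lm"), n_respondents >= 1)
  with_seed(seed, {
    out <- lapply(split(lm$table, lm$table$frame_id), function(d) {
      tibble::tibble(
        frame_id = d$frame_id[1],
        respondent_id = seq_len(n_respondents),
        response = sample(d$token, n_respondents, replace = TRUE,
                          prob = d$probability)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Generate plausibility ratings
#'
#' Integer 1-5 ratings drawn per rater from a Gaussian centered on the
#' condition's configured mean, rounded and clamped to the scale. With zero
#' rater SD every rating equals the rounded condition mean.
#'
#' @param config a `sim_config`.
#' @param frames frame tibble from [gen_frames_and_vectors()].
#' @param seed substream seed.
#' @return tibble `frame_id`, `condition`, `rater_id`, `rating`.
#' @export
gen_plausibility <- function(config, frames, seed) {
  stopifnot(inherits(config, "sim_config"))
  items <- unique(frames[c("frame_id", "condition")])
  with_seed(seed, {
    n <- config$n_raters
    out <- items[rep(seq_len(nrow(items)), each = n), ]
    out$rater_id <- rep(seq_len(n), times = nrow(items))
    mu <- config$plaus_means[out$condition]
    out$rating <- as.integer(pmin(5, pmax(1, round(rnorm(nrow(out), mu,
                                                         config$plaus_sd)))))
    tibble::as_tibble(out)
  })
}

#' Assemble the per-item stimulus and predictor table
#'
#' Computes, for every frame x condition item: toy-LM surprisal (bits),
#' GloVe/fastText contextual and best-completion cosine similarities,
#' empirical cloze, aggregated plausibility, frequency, and Coltheart's N
#' against the critical-word lexicon.
#'
#' @param geometry output of [gen_frames_and_vectors()].
#' @param lm a `toy_lm`.
#' @param cloze_responses tibble from [gen_cloze_responses()].
#' @param plausibility tibble from [gen_plausibility()].
#' @return predictor tibble, one row per item.
#' @export
build_predictor_table <- function(geometry, lm, cloze_responses,
                                  plausibility) {
  frames <- geometry$frames
  lexicon <- geometry$vectors$glove$vocabulary
  resp <- split(cloze_responses$response, cloze_responses$frame_id)
  plaus <- split(plausibility$rating,
                 paste(plausibility$frame_id, plausibility$condition))
  rows <- lapply(seq_len(nrow(frames)), function(i) {
    r <- frames[i, ]
    ctx <- tokenize_context(r$context)
    pl <- aggregate_plausibility(plaus[[paste(r$frame_id, r$condition)]])
    tibble::tibble(
      frame_id = r$frame_id,
      condition = r$condition,
      word = r$critical_word,
      gpt3_surprisal = surprisal_bits(
        lm_log_prob(lm, r$frame_id, r$critical_word)),
      glove_ccs = ccs(r$critical_word, ctx, geometry$vectors$glove),
      fasttext_ccs = ccs(r$critical_word, ctx, geometry$vectors$fasttext),
      glove_bccs = bccs(r$critical_word, r$best_completion,
                        geometry$vectors$glove),
      fasttext_bccs = bccs(r$critical_word, r$best_completion,
                           geometry$vectors$fasttext),
      cloze = compute_cloze(resp[[r$frame_id]], r$critical_word,
                            normalize = FALSE),
      plausibility = pl$mean,
      plausibility_sd = pl$sd,
      frequency = r$frequency,
      orthographic_n = coltheart_n(r$critical_word, lexicon)
    )
  })
  dplyr::bind_rows(rows)
}

#' Generate single-trial N400 amplitudes from the ground-truth mixed model
#'
#' The generative model mirrors the analysis model: for subject s, frame f,
#' condition c (word w) and electrode e,
#' `amplitude = beta0 + beta1 * z(driver) + u_s + u_f + u_w + u_e + eps`,
#' with independent Gaussian random intercepts and residual, over the full
#' crossed design subjects x frames x conditions x electrodes. The driver is
#' entered in z-units so `beta1` is scale-free.
#'
#' @param config a `sim_config`.
#' @param predictors predictor table from [build_predictor_table()].
#' @param seed substream seed.
#' @return list with `amplitudes` (tibble: `subject`, `frame_id`,
#'   `condition`, `word`, `electrode`, `amplitude`) and `ground_truth`
#'   (realized random intercepts, driver z-values, per-row linear predictor).
#' @export
gen_trial_amplitudes <- function(config, predictors, seed) {
  stopifnot(inherits(config, "sim_config"))
  driver_col <- switch(config$driver,
                       surprisal = "gpt3_surprisal",
                       ccs = "glove_ccs",
                       none = NULL)
  z <- if (is.null(driver_col)) rep(0, nrow(predictors)) else
    zscore(predictors[[driver_col]], driver_col)
  with_seed(seed, {
    subjects <- sprintf("s%02d", seq_len(config$n_subjects))
    electrodes <- config$electrodes
    words <- unique(predictors$word)
    u_s <- stats::setNames(rnorm(length(subjects), 0, config$sd_subject),
                           subjects)
    u_f <- stats::setNames(
      rnorm(config$n_frames, 0, config$sd_frame),
      unique(predictors$frame_id))
    u_w <- stats::setNames(rnorm(length(words), 0, config$sd_word), words)
    u_e <- stats::setNames(rnorm(length(electrodes), 0, config$sd_electrode),
                           electrodes)
    item_idx <- rep(seq_len(nrow(predictors)),
                    times = length(subjects) * length(electrodes))
    grid <- tibble::tibble(
      subject = rep(subjects, each = nrow(predictors) * length(electrodes)),
      frame_id = predictors$frame_id[item_idx],
      condition = predictors$condition[item_idx],
      word = predictors$word[item_idx],
      electrode = rep(rep(electrodes, each = nrow(predictors)),
                      times = length(subjects))
    )
    zz <- z[item_idx]
    mu <- config$beta0 + config$beta1 * zz +
      u_s[grid$subject] + u_f[grid$frame_id] + u_w[grid$word] +
      u_e[grid$electrode]
    eps <- rnorm(nrow(grid), 0, config$sd_resid)
    grid$amplitude <- as.numeric(mu + eps)
    list(
      amplitudes = grid,
      ground_truth = list(
        u_subject = u_s, u_frame = u_f, u_word = u_w, u_electrode = u_e,
        driver_z = z, linear_predictor = as.numeric(mu),
        residual = eps
      )
    )
  })
}

#' Window-mean factor of the N400-like Gaussian component
#'
#' The waveform renderer multiplies each trial's generating amplitude by a
#' unit-peak Gaussian bump `g(t) = exp(-((t - center) / width)^2 / 2)`. The
#' mean of `g` over the analysis-window samples is the exact factor by which
#' extracted window-mean amplitudes are scaled relative to the generating
#' amplitudes; with zero sensor noise the equality is exact.
#'
#' @param config a `sim_config`.
#' @param window analysis window in ms (half-open).
#' @return scalar window-mean factor in (0, 1].
#' @export
component_window_factor <- function(config, window = c(300, 500)) {
  step <- 1000 / config$srate
  t_ms <- seq(config$window[1], config$window[2] - step, by = step)
  idx <- t_ms >= window[1] & t_ms < window[2]
  g <- exp(-((t_ms - config$bump_center) / config$bump_width)^2 / 2)
  mean(g[idx])
}

#' Render single-trial epochs from generating amplitudes
#'
#' One trial per subject x frame x condition; each cluster electrode's trace
#' is that trial-electrode's generating amplitude times a unit-peak Gaussian
#' component centered at `bump_center`, plus AR(1) sensor noise. Mastoid
#' channels carry noise only (so mastoid re-referencing is exercised, not a
#' no-op). Blink-like artifacts -- a 200 ms half-cosine deflection of
#' `artifact_amplitude` µV on all channels -- are injected independently per
#' trial at `artifact_rate`, with ground-truth labels returned.
#'
#' @param config a `sim_config` (with `waveform = TRUE` semantics).
#' @param amplitudes tibble from [gen_trial_amplitudes()].
#' @param seed substream seed.
#' @return list with `epochs` (an `epoch_set`; channels = cluster
#'   electrodes + mastoids) and `artifact_truth` (logical per trial).
#' @export
gen_raw_epochs <- function(config, amplitudes, seed) {
  stopifnot(inherits(config, "sim_config"))
  step <- 1000 / config$srate
  t_ms <- seq(config$window[1], config$window[2] - step, by = step)
  n_samp <- length(t_ms)
  g <- exp(-((t_ms - config$bump_center) / config$bump_width)^2 / 2)

  trials <- unique(amplitudes[c("subject", "frame_id", "condition", "word")])
  amp_wide <- tidyr::pivot_wider(
    amplitudes, names_from = "electrode", values_from = "amplitude"
  )
  amp_wide <- dplyr::left_join(trials, amp_wide,
                               by = c("subject", "frame_id", "condition",
                                      "word"))
  channels <- c(config$electrodes, config$mastoids)
  n_tr <- nrow(trials)
  n_ch <- length(channels)

  with_seed(seed, {
    v <- array(0, dim = c(n_tr, n_ch, n_samp))
    for (j in seq_along(config$electrodes)) {
      a <- amp_wide[[config$electrodes[j]]]
      v[, j, ] <- outer(a, g)
    }
    if (config$sensor_noise_sd > 0) {
      innov_sd <- config$sensor_noise_sd * sqrt(1 - config$ar_coef^2)
      noise <- matrix(rnorm(n_tr * n_ch * n_samp, 0, innov_sd),
                      nrow = n_tr * n_ch, ncol = n_samp)
      noise <- t(apply(noise, 1, function(w) {
        as.numeric(stats::filter(w, config$ar_coef, method = "recursive"))
      }))
      v <- v + array(noise, dim = c(n_tr, n_ch, n_samp))
    }
    artifact <- runif(n_tr) < config$artifact_rate
    if (any(artifact)) {
      dur <- round(200 / step)          # 200 ms blink
      scalp <- seq_along(config$electrodes)  # blinks barely reach mastoids
      for (i in which(artifact)) {
        onset <- sample(seq_len(n_samp - dur), 1)
        bump <- config$artifact_amplitude *
          (1 - cos(2 * pi * seq_len(dur) / dur)) / 2
        span <- onset:(onset + dur - 1)
        v[i, scalp, span] <- v[i, scalp, span] +
          rep(bump, each = length(scalp))
      }
    }
    ep <- epoch_set(v, channels, trials, srate = config$srate,
                    window = config$window)
    list(epochs = ep, artifact_truth = artifact)
  })
}

#' Generate a complete synthetic dataset
#'
#' Runs every generator off named substreams of the master seed and returns
#' the full bundle: frames, embeddings, toy LM, norms, the per-item
#' predictor table, single-trial amplitudes with ground truth, the merged
#' modeling table, and (optionally) rendered epochs.
#'
#' @param config a `sim_config`.
#' @return a list of class `sim_dataset` with elements `config`, `geometry`,
#'   `lm`, `cloze_responses`, `plausibility`, `predictors`, `amplitudes`,
#'   `ground_truth`, `model_data`, and -- when `config$waveform` is TRUE --
#'   `epochs` and `artifact_truth`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  geometry <- gen_frames_and_vectors(config)
  lm <- gen_toy_lm(config, geometry)
  cloze <- gen_cloze_responses(lm, config$n_cloze_respondents,
                               substream_seed(config$seed, "cloze"))
  plaus <- gen_plausibility(config, geometry$frames,
                            substream_seed(config$seed, "plausibility"))
  predictors <- build_predictor_table(geometry, lm, cloze, plaus)
  amp <- gen_trial_amplitudes(config, predictors,
                              substream_seed(config$seed, "amplitudes"))
  model_data <- dplyr::left_join(
    amp$amplitudes,
    predictors[c("frame_id", "condition", "gpt3_surprisal", "glove_ccs",
                 "fasttext_ccs", "glove_bccs", "fasttext_bccs", "cloze",
                 "plausibility", "frequency", "orthographic_n")],
    by = c("frame_id", "condition")
  )
  out <- list(config = config, geometry = geometry, lm = lm,
              cloze_responses = cloze, plausibility = plaus,
              predictors = predictors, amplitudes = amp$amplitudes,
              ground_truth = amp$ground_truth, model_data = model_data)
  if (isTRUE(config$waveform)) {
    ep <- gen_raw_epochs(config, amp$amplitudes,
                         substream_seed(config$seed, "epochs"))
    out$epochs <- ep$epochs
    out$artifact_truth <- ep$artifact_truth
  }
  structure(out, class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("<sim_dataset>", nrow(x$predictors), "items,",
      nrow(x$amplitudes), "trial x electrode amplitudes",
      if (!is.null(x$epochs)) paste0(", ", dim(x$epochs$voltages)[1],
                                     " rendered epochs"),
      "\n")
  invisible(x)
}
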