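#' Simulate a dataset and write it as a file bundle
#'
#' Orchestrates the synthetic-data generators and writes every artifact to
#' `out_dir` in its interchange format: stimulus frames and norms as TSV,
#' word vectors in the GloVe text and fastText `.vec` dialects, the toy
#' language model as TSV, per-item predictors and single-trial amplitudes as
#' TSV, rendered epochs (waveform mode) as a text array container, and a
#' JSON manifest echoing the resolved configuration, the package version,
#' and the row counts of every file.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [sim_config()].
#' @return the `sim_dataset`, invisibly; files on disk as a side effect.
#' @export
run_simulation <- function(out_dir, config = sim_config()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  ds <- simulate_dataset(config)
  p <- function(...) file.path(out_dir, ...)
  write_tsv_table(ds$geometry$frames, p("frames.tsv"))
  write_vectors(ds$geometry$vectors$glove, p("vectors_glove.txt"),
                dialect = "glove_text")
  write_vectors(ds$geometry$vectors$fasttext, p("vectors_fasttext.vec"),
                dialect = "fasttext_vec")
  write_toy_lm(ds$lm, p("toy_lm.tsv"))
  write_tsv_table(ds$cloze_responses, p("cloze_responses.tsv"))
  write_tsv_table(ds$plausibility, p("plausibility_ratings.tsv"))
  write_tsv_table(ds$predictors, p("predictors.tsv"))
  write_tsv_table(ds$amplitudes, p("trial_amplitudes.tsv"))
  files <- c("frames.tsv", "vectors_glove.txt", "vectors_fasttext.vec",
             "toy_lm.tsv", "cloze_responses.tsv", "plausibility_ratings.tsv",
             "predictors.tsv", "trial_amplitudes.tsv")
  if (!is.null(ds$epochs)) {
    write_epochs(ds$epochs, p("epochs"))
    write_tsv_table(tibble::tibble(trial = seq_along(ds$artifact_truth),
                                   artifact = ds$artifact_truth),
                    p("artifact_truth.tsv"))
    files <- c(files, "epochs.json", "epochs_voltages.tsv",
               "artifact_truth.tsv")
  }
  cfg <- unclass(config)
  cfg$electrodes <- as.list(cfg$electrodes)
  manifest <- list(
    tool = "n400pred", version = as.character(utils::packageVersion("n400pred")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = cfg,
    files = files,
    counts = list(
      stimulus_items = nrow(ds$predictors),
      frames = config$n_frames,
      trial_amplitudes = nrow(ds$amplitudes),
      epochs = if (is.null(ds$epochs)) 0L else dim(ds$epochs$voltages)[1]
    )
  )
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(ds)
}

#' Analyze a dataset bundle
#'
#' Loads (or accepts in memory) a simulated bundle, optionally runs the ERP
#' extraction on rendered epochs, and produces the full analysis: predictor
#' correlation matrix, per-condition z-scored summary, the model-comparison
#' ladder, and a human-readable run summary. All outputs are written to
#' `out_dir` with a JSON manifest.
#'
#' @param input a `sim_dataset`, or the path of a bundle directory written
#'   by [run_simulation()].
#' @param out_dir output directory.
#' @param stages ladder stages to run (see [run_ladder()]).
#' @param from_epochs if TRUE and epochs are available, re-derive trial
#'   amplitudes from the waveforms (re-reference, baseline, artifact
#'   rejection, window mean) instead of using the tabulated amplitudes.
#' @param ... further arguments passed to [run_ladder()].
#' @return the `comparison_report`, invisibly.
#' @export
run_analysis <- function(input, out_dir, stages = 1:4,
                         from_epochs = FALSE, ...) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  p <- function(...) file.path(out_dir, ...)

  if (is.character(input)) {
    need <- c("predictors.tsv", "trial_amplitudes.tsv")
    for (f in need) {
      if (!file.exists(file.path(input, f))) {
        stop("missing required input file: ", file.path(input, f),
             call. = FALSE)
      }
    }
    predictors <- read_tsv_table(file.path(input, "predictors.tsv"))
    amplitudes <- read_tsv_table(file.path(input, "trial_amplitudes.tsv"))
    epochs <- if (file.exists(file.path(input, "epochs.json"))) {
      read_epochs(file.path(input, "epochs"))
    }
  } else {
    stopifnot(inherits(input, "sim_dataset"))
    predictors <- input$predictors
    amplitudes <- input$amplitudes
    epochs <- input$epochs
  }

  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, paste0(...))
  }
  note("items: ", nrow(predictors))

  if (from_epochs) {
    if (is.null(epochs)) stop("no epochs available for ERP extraction",
                              call. = FALSE)
    ep <- epochs
    if (all(c("A1", "A2") %in% ep$channel_labels)) {
      ep <- rereference(ep, c("A1", "A2"))
    }
    ep <- baseline_correct(ep)
    ep <- reject_artifacts(ep, channels = intersect(N400_CLUSTER,
                                                    ep$channel_labels))
    note("trials rejected: ", sum(ep$rejected), " of ",
         length(ep$rejected))
    amplitudes <- n400_amplitude(ep)
    ga <- grand_average(ep)
    write_tsv_table(ga, p("grand_average.tsv"))
    dw <- dplyr::bind_rows(lapply(
      setdiff(unique(ga$condition), "Best"),
      function(cc) {
        d <- difference_wave(ga, cc, "Best"); d$condition <- cc; d
      }))
    write_tsv_table(dw, p("difference_waves.tsv"))
  }

  pred_cols <- c("gpt3_surprisal", "glove_ccs", "fasttext_ccs", "glove_bccs",
                 "fasttext_bccs", "cloze", "plausibility")
  corr <- correlate_predictors(predictors, pred_cols)
  write_tsv_table(tibble::as_tibble(corr, rownames = "predictor"),
                  p("predictor_correlations.tsv"))

  data <- dplyr::left_join(
    amplitudes,
    predictors[c("frame_id", "condition", pred_cols, "frequency",
                 "orthographic_n")],
    by = c("frame_id", "condition")
  )
  note("modeled observations: ", nrow(data))

  csum <- condition_summary(
    data[c("condition", "amplitude", pred_cols)],
    variables = c("amplitude", pred_cols)
  )
  write_tsv_table(csum, p("condition_summary.tsv"))

  report <- run_ladder(data, stages = stages, ...)
  write_tsv_table(report$models, p("ladder_models.tsv"))
  write_tsv_table(report$tests, p("ladder_tests.tsv"))
  write_tsv_table(report$winners, p("ladder_winners.tsv"))

  for (i in seq_len(nrow(report$winners))) {
    note("stage ", report$winners$stage[i], " winner: ",
         report$winners$designation[i])
  }
  sig <- report$tests
  note("FDR-significant tests: ", sum(sig$significant), " of ", nrow(sig),
       " at alpha ", report$alpha)
  writeLines(log_lines, p("summary.txt"))

  outputs <- c("predictor_correlations.tsv", "condition_summary.tsv",
               "ladder_models.tsv", "ladder_tests.tsv", "ladder_winners.tsv",
               "summary.txt")
  if (from_epochs) outputs <- c(outputs, "grand_average.tsv",
                                "difference_waves.tsv")
  jsonlite::write_json(
    list(tool = "n400pred",
         version = as.character(utils::packageVersion("n400pred")),
         stages = stages, files = outputs, log = log_lines),
    p("analysis_manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(report)
}
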