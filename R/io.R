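#' Write / read a tab-separated table
#'
#' UTF-8, headered, unquoted TSV -- the interchange format for stimulus,
#' norm, predictor, and amplitude tables.
#'
#' @param x data frame.
#' @param path file path.
#' @return `read_tsv_table` returns a tibble; `write_tsv_table` returns
#'   `path` invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv_table
#' @export
read_tsv_table <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      fileEncoding = "UTF-8"))
}

#' Write an epoch set to disk
#'
#' Portable text container: voltages as a TSV matrix (one row per trial x
#' channel, one column per sample) plus a JSON sidecar carrying the sampling
#' rate, window, channel labels, rejection flags, and trial metadata.
#'
#' @param epochs an `epoch_set`.
#' @param stem path stem; writes `<stem>.json` and `<stem>_voltages.tsv`.
#' @return the stem, invisibly.
#' @export
write_epochs <- function(epochs, stem) {
  stopifnot(inherits(epochs, "epoch_set"))
  dims <- dim(epochs$voltages)
  flat <- matrix(aperm(epochs$voltages, c(2, 1, 3)),
                 nrow = dims[1] * dims[2], ncol = dims[3])
  utils::write.table(flat, paste0(stem, "_voltages.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  side <- list(
    n_trials = dims[1], n_channels = dims[2], n_samples = dims[3],
    srate = epochs$srate, window = epochs$window,
    channel_labels = epochs$channel_labels,
    rejected = epochs$rejected,
    trial_meta = epochs$trial_meta
  )
  jsonlite::write_json(side, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(stem)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(stem) {
  side <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(paste0(stem, "_voltages.tsv"),
                                      sep = "\t", header = FALSE))
  v <- aperm(array(flat, dim = c(side$n_channels, side$n_trials,
                                 side$n_samples)), c(2, 1, 3))
  epoch_set(v, side$channel_labels, tibble::as_tibble(side$trial_meta),
            srate = side$srate, window = side$window,
            rejected = side$rejected)
}
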