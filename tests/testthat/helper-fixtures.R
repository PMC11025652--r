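# Shared in-code fixtures for the test suite.

# A tiny stimulus table: two complete frames with norms.
tiny_stimuli <- function() {
  tibble::tibble(
    frame_id = rep(c("f1", "f2"), each = 4),
    condition = rep(c("Best", "Related", "Unrelated", "Implausible"), 2),
    critical_word = c("rest", "relaxation", "sun", "airlines",
                      "wrong", "incorrect", "lonely", "screened"),
    cloze = c(0.5, 0.02, 0.02, 0, 0.498, 0.023, 0.023, 0),
    plausibility_mean = c(1.4, 1.5, 1.5, 4.3, 1.4, 1.5, 1.5, 4.3)
  )
}

# A small deterministic word-vector table.
tiny_vectors <- function() {
  m <- rbind(
    rest = c(1, 0, 0, 0), relaxation = c(0.9, 0.1, 0, 0),
    sun = c(0, 1, 0, 0), airlines = c(0, 0, 1, 0),
    his = c(0.5, 0.5, 0, 0), vacation = c(1, 1, 0, 0)
  )
  word_vectors(m)
}

# Deterministic constant-trace epochs: value per trial x channel, constant
# over samples.
const_epochs <- function(values, channels, meta = NULL) {
  n_tr <- nrow(values)
  v <- array(0, dim = c(n_tr, length(channels), 250))
  for (i in seq_len(n_tr)) for (j in seq_along(channels)) {
    v[i, j, ] <- values[i, j]
  }
  if (is.null(meta)) {
    meta <- tibble::tibble(subject = "s1", frame_id = sprintf("f%d", 1:n_tr),
                           condition = "Best",
                           critical_word = sprintf("w%d", 1:n_tr))
  }
  epoch_set(v, channels, meta)
}

# Brute-force Benjamini-Hochberg: the min-over-tail definition,
# independent of stats::p.adjust.
bh_bruteforce <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(n)
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(ranked[i:n] * n / (i:n)))
  }
  out <- numeric(n)
  out[o] <- adj
  out
}

# Brute-force Coltheart's N by exhaustive one-substitution scan.
coltheart_bruteforce <- function(word, lexicon) {
  word <- tolower(word); lexicon <- unique(tolower(lexicon))
  count <- 0L
  for (w in lexicon) {
    if (w == word || nchar(w) != nchar(word)) next
    diffs <- 0L
    for (k in seq_len(nchar(word))) {
      if (substr(w, k, k) != substr(word, k, k)) diffs <- diffs + 1L
    }
    if (diffs == 1L) count <- count + 1L
  }
  count
}

# Small default-noise model dataset reused across modeling tests.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_dataset(sim_config(n_subjects = 6, n_frames = 12,
                                            seed = 42))
    }
    cache
  }
})
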