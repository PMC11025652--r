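Package: n400pred
Title: Single-Trial N400 Amplitude Modeling with Surprisal and Semantic
    Similarity Predictors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for linking single-trial N400 event-related potential
    amplitudes to word-level predictors derived from language statistics:
    language-model surprisal (in bits), contextual cosine similarity and
    best-completion cosine similarity from word embeddings, together with
    human cloze and plausibility norms and lexical covariates. Includes
    readers for GloVe and fastText plain-text vector formats, an ERP
    preprocessing pipeline (mastoid re-referencing, baseline correction,
    artifact rejection, 300-500 ms centroparietal amplitude extraction),
    a four-stage crossed-random-effects model-comparison ladder (AIC,
    likelihood-ratio tests, Benjamini-Hochberg correction), and a
    synthetic-data generator that simulates stimuli, embeddings, a toy
    language model, norms, and single-trial EEG with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    lme4,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
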