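---
title: "Modeling single-trial N400 amplitudes with surprisal and semantic similarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling single-trial N400 amplitudes with surprisal and semantic similarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

The N400 is a negative-going event-related potential (ERP) component peaking
roughly 400 ms after a word appears; its amplitude is modulated by how hard
the word is to process semantically. Competing mechanistic accounts attribute
N400 amplitude to (a) *predictive preactivation* — how predictable the word
was in its context, (b) *contextual semantic similarity* — how close the
word's meaning is to the meaning of the words that preceded it, or (c) a
combination of both. These constructs can be operationalized from the
statistics of language: predictability as the **surprisal** (negative
log₂-probability, in bits) a language model assigns the word, and similarity
as the **cosine** between word embeddings — either against the mean of the
context word vectors (*contextual cosine similarity*, CCS) or against the
single most expected completion (*best-completion cosine similarity*, BCCS).

`n400pred` implements the full analysis chain that adjudicates among these
accounts: stimulus norming and selection, predictor computation, single-trial
N400 extraction from EEG epochs, and a staged mixed-effects model comparison.
Because real EEG recordings, commercial language-model APIs, and
multi-gigabyte embedding downloads are impractical as test dependencies, the
package also ships a synthetic-data generator that reproduces the *structure*
of such a study with known ground truth, so every stage is testable
end-to-end.

## The experimental design being emulated

Each sentence frame has four completions:

| Condition | Role | Cloze | Plausibility |
|---|---|---|---|
| Best | highest-cloze completion | ≈ 0.5 | plausible (< 2) |
| Related | low-cloze, semantically related to Best | ≈ 0.02 | plausible |
| Unrelated | low-cloze, unrelated to Best, matched to Related | ≈ 0.02 | plausible |
| Implausible | near-zero probability, implausible | ≈ 0 | implausible (> 3.5) |

*Cloze probability* is the proportion of norming participants who produce a
word when completing the frame; *plausibility* is rated 1 (very plausible) to
5 (very implausible). The study-scale design retains 125 frames × 4
conditions = 500 items, with Related and Unrelated matched on cloze and
plausibility so they differ only in their relation to the Best completion.
`select_stimuli()` applies the two selection rules: every critical word must
appear as a whole token in every model vocabulary (frames failing this are
excluded with reason `"oov"`), and the Related/Unrelated sets must match at
the group level (absolute mean difference within tolerance — defaults 0.01
cloze, 0.2 rating units — *and* a Welch t-test p above 0.2; both are
reported, since a "no overall difference" claim names an outcome rather than
a test).

Decisions the package had to make where convention is silent:

* **Cloze response normalization.** Responses are lowercased, stripped of
  surrounding punctuation, and truncated to the first whitespace-delimited
  token; no spelling correction. This is deterministic and auditable;
  alternatives (e.g., correcting typos) would require a dictionary and a
  judgment call per item.
* **Plausibility dispersion** uses the n−1 (sample) standard deviation.

## Predictors

* `surprisal_bits()` converts a natural-log conditional probability to bits
  (−ln P⁄ln 2). Any conditional-probability provider can stand behind
  `item_surprisal()`; the bundled `toy_lm()` is a table-driven provider with
  a floor probability (default 1e−8) for out-of-table completions so
  surprisal stays finite — the reason the analysis uses cloze *probability*
  rather than cloze surprisal is precisely that zero cloze cannot be
  log-transformed.
* `ccs()` is the cosine between the critical word's vector and the
  arithmetic mean of the in-vocabulary context vectors. Cosine ignores
  vector magnitude, so the mean and the sum of the context vectors give
  identical results (verified to 1e−12 in the tests). Context tokens missing
  from the vocabulary are skipped — the whole-token vocabulary filter
  applies to critical words only.
* `bccs()` is the cosine between the critical word and the frame's Best
  completion; it equals 1 for Best-condition items by definition, which is
  why the final analysis stage is repeated with Best trials excluded.
* `coltheart_n()` counts same-length lexicon words differing at exactly one
  character position (orthographic neighborhood size); `frequency` is a
  log-scaled (Zipf-style) measure supplied as data. Both enter every model
  as covariates, never as predictors of interest.
* `read_vectors()` supports the two plain-text embedding dialects in the
  wild: GloVe text (no header) and fastText `.vec` (a `count dim` header).
  Duplicate tokens keep the first occurrence with a warning; dimensionality
  errors cite the offending line.

## ERP pipeline

Epochs are trials × channels × samples arrays in µV on a half-open
[−100, 900) ms grid at 250 Hz — 250 samples, sample *k* at (−100 + 4*k*) ms.
Half-open windows avoid double-counting boundary samples; the same
convention applies to the baseline ([−100, 0) ms) and the N400 measurement
window ([300, 500) ms). The chain is:

1. `rereference()` — subtract the mean of the left/right mastoid channels;
2. `baseline_correct()` — subtract each trial/channel's pre-onset mean;
3. `reject_artifacts()` — flag trials whose peak-to-peak range on any
   examined channel exceeds 100 µV (blinks, eye movements, amplifier
   saturation) or stays under 0.5 µV (flat channel). The original study
   names the artifact classes but not its thresholds; these defaults are
   ordinary practice for 29-channel sentence-reading EEG.
4. `n400_amplitude()` — the mean voltage 300–500 ms at each of the nine
   centroparietal electrodes (C3, Cz, C4, CP3, CPz, CP4, P3, Pz, P4), one
   row per retained trial × electrode.

The single-trial outcome is kept per electrode rather than averaged across
the cluster because the analysis model includes an electrode random
intercept — averaging would leave that term nothing to do.

## The model-comparison ladder

Every model is a linear mixed-effects regression of single-trial amplitude
with fixed covariates (frequency, orthographic N) and crossed random
intercepts for subject, sentence frame, critical word, and electrode. The
random structure is identical across all models so their likelihoods are
comparable; random slopes are deliberately omitted (a parsimonious structure
avoids convergence and singularity trouble). Fits use **maximum likelihood,
not REML**, because the compared models differ in fixed effects — REML
likelihoods would not be comparable. Continuous predictors are z-scored for
solver stability; condition is treatment-coded with Best as reference. Both
choices are this package's conventions — the analysis they mirror does not
state its own.

The four stages of `run_ladder()`:

1. **Single factors** — cloze, plausibility, GloVe CCS, fastText CCS,
   surprisal, condition; each compared to the null model by ΔAIC and a
   likelihood-ratio test (LRT).
2. **Combined accounts** — each {cloze, surprisal} × {GloVe, fastText} CCS
   pair; each combined model is tested against both components.
3. **Plausibility** — added to the surprisal model and the two cloze + CCS
   models.
4. **Relatedness to best completion** — GloVe/fastText BCCS added to the
   same three bases, then the whole stage re-run excluding Best trials
   (where BCCS ≡ 1).

Conventions: `chi_sq` is clamped at zero; |ΔAIC| ≥ 4 counts as substantial;
when the top two models are closer than that the stage winner is reported as
"indistinguishable" rather than picking one. All LRT p-values of one
invocation form a single Benjamini–Hochberg FDR family by default
(`fdr_family = "per_stage"` is available); which p-values share a family is
underdetermined in the source analysis, so the choice is configurable and
recorded in the report. The stage-1 winner designation ranges over the
single-variable models only: the four-level condition factor bundles
predictability, plausibility, and relatedness into three parameters and is
reported alongside rather than competing for "best single predictor."

## The synthetic generator

`sim_config()` fixes every generative parameter; `simulate_dataset()` runs
the generators off named substreams of one master seed
(`substream_seed()`), so any component regenerates independently and the
full pipeline is bit-reproducible.

* **Embedding geometry.** Each frame has a latent unit *topic* direction.
  Context vectors scatter around the topic; Best sits near the topic;
  Related = Best + small noise; Unrelated keeps a weak (0.3) topic
  component but is otherwise random — in the plausible region yet far from
  Best; Implausible points along an independent direction. This yields the
  orderings the design requires: BCCS(Related) > BCCS(Unrelated) and
  CCS(Best) ≥ CCS(Related) > CCS(Implausible). Two vector tables
  (GloVe-like, fastText-like) are independent small-noise (0.05)
  realizations of the same latent vectors, emulating the near-unity
  inter-embedding correlations of real pretrained sets.
* **Toy language model.** Every frame's completion distribution assigns
  Best 0.5, Related 0.02, Unrelated 0.02, Implausible 10⁻⁶, with the rest
  spread over 10 distractors — the cloze profile of the design (Best ≈ 50%,
  low-cloze ≈ 2%, Implausible ≈ 0%). A consequence worth knowing: toy
  surprisal is *exactly* a function of condition, so the condition factor
  can always match the surprisal model's likelihood and trails it only by
  the AIC penalty on its two extra parameters. Real language models break
  this degeneracy; the toy model does not need to.
* **Norms.** Cloze responses are i.i.d. draws from the toy LM (35
  respondents per frame); plausibility ratings are rounded clamped
  Gaussians (30 raters; means 1.4/1.5/1.5/4.3, rater SD 0.7).
* **Amplitudes.** `amplitude = β₀ + β₁·z(driver) + u_subject + u_frame +
  u_word + u_electrode + ε` over the full subjects × frames × conditions ×
  electrodes crossing. Defaults: β₀ = 2 µV, β₁ = −0.75 µV/SD,
  σ_subject = 1, σ_frame = 0.5, σ_word = 0.5, σ_electrode = 0.25,
  σ_ε = 5 µV. No µV-scale effect sizes are published for this design, so
  these are declared simulation conventions chosen to give realistic
  single-trial signal-to-noise (effects an order of magnitude below trial
  noise). The driver enters in z-units so β₁ is scale-free; with β₁ < 0,
  condition means order Implausible < Unrelated < Best — the classic N400
  pattern.
* **Waveforms.** In waveform mode each trial-electrode trace is the
  generating amplitude times a unit-peak Gaussian bump (center 400 ms, SD
  75 ms) plus AR(1) sensor noise (φ = 0.7, marginal SD 2 µV); mastoids
  carry noise only. The 2 µV default comes from a signal-to-noise budget:
  extraction adds window-mean, baseline-mean and reference noise on top of
  the generative residual already in the amplitudes, and at 2 µV the
  predicted extraction-vs-ground-truth correlation is ≈ 0.95. The
  window-mean of the bump over [300, 500) ms (`component_window_factor()`,
  ≈ 0.768 at defaults) is the exact closed-form factor linking generating
  and extracted amplitudes when noise is zero. Optional blink artifacts — a
  200 ms, 200 µV half-cosine on the scalp channels (not the mastoids, which
  would otherwise subtract them right back out during re-referencing) —
  carry ground-truth labels for testing the rejection stage.

### What the generator does and does not emulate

It reproduces the statistical skeleton the analysis assumes: the crossed
random-effects structure, the condition profile of cloze/plausibility/
similarity, and an N400-like component in noise. It does **not** model
oscillatory EEG, inter-electrode spatial correlation (electrode effects are
intercepts, exactly as in the analysis model), subword tokenization,
per-frame variation in the completion distribution, or words shared across
frames. Passing tests therefore demonstrate that the pipeline measures and
adjudicates correctly when its assumptions hold — not that those assumptions
hold of any particular real dataset.

## Problem sizes

Routine runs and tests use 20 subjects × 60 frames (43,200 trial×electrode
observations) for amplitude-level analyses — large enough that the ladder's
decisions are stable across seeds — and 5 subjects × 24 frames when full
waveforms are rendered (a study-scale epochs array would occupy ~1 GB to no
inferential benefit). Replicated checks (driver recovery, null calibration)
restrict the ladder to the stages they quantify. Study-scale (125-frame)
stimulus generation is used wherever the design count itself is the point.

## Known limitations

* `fit_lmm()` delegates the numerical optimization to `lme4::lmer`;
  singular fits (variance components estimated at zero) are retained as
  legitimate ML solutions, and only solver non-convergence is flagged and
  excluded from comparisons.
* The toy LM's surprisal/condition degeneracy (above) makes stage-1
  comparisons between surprisal and condition uninformative in simulation.
* LRT p-values for variance components would be conservative at boundaries;
  the ladder only ever tests fixed effects, where the χ² reference is
  standard.
* The matching check reports a group-level test; it does not search for a
  maximally matched subset.
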