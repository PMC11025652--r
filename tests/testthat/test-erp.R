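test_that("epoch grid is 250 samples on the half-open [-100, 900) ms window", {
  ep <- const_epochs(matrix(0, 2, 3), c("Cz", "A1", "A2"))
  t <- epoch_times(ep)
  expect_length(t, 250)
  expect_equal(t[1], -100)
  expect_equal(t[2] - t[1], 4)
  expect_equal(t[250], 896)
  expect_error(
    epoch_set(array(0, c(1, 1, 100)), "Cz",
              tibble::tibble(subject = "s1")),
    "inconsistent")
})

test_that("mastoid re-referencing subtracts the mastoid average samplewise", {
  # mastoids at zero: no change
  vals <- rbind(c(3, 0, 0), c(-2, 0, 0))
  ep <- const_epochs(vals, c("Cz", "A1", "A2"))
  expect_equal(rereference(ep)$voltages, ep$voltages)
  # all channels equal to the mastoids: all zeros
  ep2 <- const_epochs(rbind(c(5, 5, 5)), c("Cz", "A1", "A2"))
  expect_true(all(rereference(ep2)$voltages == 0))
  # once mastoids are zeroed, re-referencing is idempotent
  set.seed(2)
  v <- array(rnorm(2 * 3 * 250), c(2, 3, 250))
  ep3 <- epoch_set(v, c("Cz", "A1", "A2"),
                   tibble::tibble(subject = c("s1", "s1")))
  once <- rereference(ep3)
  twice <- rereference(once)
  expect_equal(twice$voltages, once$voltages, tolerance = 1e-12)
  expect_error(rereference(ep3, c("A1", "M2")), "M2")
})

test_that("baseline correction zeroes the pre-onset mean", {
  # constant +7 trace becomes all zeros
  ep <- const_epochs(rbind(c(7, 7, 7)), c("Cz", "A1", "A2"))
  expect_true(all(baseline_correct(ep)$voltages == 0))
  # trace already zero in the baseline is unchanged
  v <- array(0, c(1, 1, 250))
  v[1, 1, 26:250] <- -5
  ep2 <- epoch_set(v, "Cz", tibble::tibble(subject = "s1"))
  expect_equal(baseline_correct(ep2)$voltages, v)
  # random trace: baseline-window mean is 0 within 1e-9
  set.seed(4)
  v3 <- array(rnorm(3 * 2 * 250, 5, 10), c(3, 2, 250))
  ep3 <- epoch_set(v3, c("Cz", "Pz"), tibble::tibble(subject = rep("s1", 3)))
  bc <- baseline_correct(ep3)
  base_idx <- which(epoch_times(ep3) < 0)
  for (i in 1:3) for (j in 1:2) {
    expect_lt(abs(mean(bc$voltages[i, j, base_idx])), 1e-9)
  }
  ep4 <- epoch_set(array(0, c(1, 1, 225)), "Cz",
                   tibble::tibble(subject = "s1"), window = c(0, 900))
  expect_error(baseline_correct(ep4), "baseline")
})

test_that("artifact flags respect thresholds and are monotone", {
  set.seed(6)
  v <- array(rnorm(10 * 2 * 250, 0, 5), c(10, 2, 250))
  v[3, 1, 100:150] <- v[3, 1, 100:150] + 200   # blink-like deflection
  ep <- epoch_set(v, c("Cz", "Pz"), tibble::tibble(subject = rep("s1", 10)))
  r100 <- reject_artifacts(ep, p2p_threshold = 100)
  expect_true(r100$rejected[3])
  clean <- epoch_set(array(rnorm(5 * 1 * 250, 0, 2), c(5, 1, 250)), "Cz",
                     tibble::tibble(subject = rep("s1", 5)))
  expect_equal(sum(reject_artifacts(clean, 100)$rejected), 0)
  # stricter threshold flags a superset
  r50 <- reject_artifacts(ep, p2p_threshold = 50)
  expect_true(all(which(r100$rejected) %in% which(r50$rejected)))
  # flatline detection
  flat <- const_epochs(rbind(c(1, 1)), c("Cz", "Pz"))
  expect_true(reject_artifacts(flat)$rejected[1])
  expect_error(reject_artifacts(ep, p2p_threshold = -1), "positive")
})

test_that("N400 amplitude is the window mean per retained trial and electrode", {
  # -5 µV flat inside 300-500 ms, 0 elsewhere
  v <- array(0, c(2, 2, 250))
  idx <- which(epoch_times(const_epochs(matrix(0, 1, 2), c("Cz", "Pz"))) >= 300 &
               epoch_times(const_epochs(matrix(0, 1, 2), c("Cz", "Pz"))) < 500)
  v[1, , idx] <- -5
  ep <- epoch_set(v, c("Cz", "Pz"),
                  tibble::tibble(subject = c("s1", "s1"),
                                 condition = c("Best", "Best")))
  amp <- n400_amplitude(ep, cluster_labels = c("Cz", "Pz"))
  expect_equal(amp$amplitude, c(-5, -5, 0, 0))
  # rejected trials never appear
  ep$rejected <- c(TRUE, FALSE)
  amp2 <- n400_amplitude(ep, cluster_labels = c("Cz", "Pz"))
  expect_equal(nrow(amp2), 2)
  expect_equal(amp2$amplitude, c(0, 0))
  expect_error(n400_amplitude(ep, cluster_labels = "XX"), "XX")
  # Gaussian bump: amplitude equals the numerical window mean
  t_ms <- epoch_times(ep)
  g <- exp(-((t_ms - 400) / 80)^2 / 2)
  v3 <- array(rep(-3 * g, each = 1), c(1, 1, 250))
  ep3 <- epoch_set(v3, "Cz", tibble::tibble(subject = "s1"))
  expect_equal(n400_amplitude(ep3, "Cz")$amplitude,
               mean(-3 * g[t_ms >= 300 & t_ms < 500]), tolerance = 1e-9)
})

test_that("extraction is linear over superposed epochs", {
  set.seed(8)
  va <- array(rnorm(4 * 1 * 250), c(4, 1, 250))
  vb <- array(rnorm(4 * 1 * 250), c(4, 1, 250))
  meta <- tibble::tibble(subject = rep("s1", 4))
  a <- n400_amplitude(epoch_set(va, "Cz", meta), "Cz")$amplitude
  b <- n400_amplitude(epoch_set(vb, "Cz", meta), "Cz")$amplitude
  ab <- n400_amplitude(epoch_set(va + vb, "Cz", meta), "Cz")$amplitude
  expect_equal(ab, a + b, tolerance = 1e-9)
})

test_that("grand averages and difference waves follow their definitions", {
  set.seed(10)
  v <- array(rnorm(6 * 1 * 250), c(6, 1, 250))
  meta <- tibble::tibble(subject = rep("s1", 6),
                         condition = rep(c("Best", "Unrelated"), each = 3))
  ep <- epoch_set(v, "Cz", meta)
  ga <- grand_average(ep)
  for (cc in c("Best", "Unrelated")) {
    rows <- which(meta$condition == cc)
    oracle <- colMeans(v[rows, 1, ])
    expect_equal(ga$voltage[ga$condition == cc], oracle, tolerance = 1e-12)
  }
  # single trial per condition -> the trial itself
  ep1 <- epoch_set(v[c(1, 4), , , drop = FALSE], "Cz", meta[c(1, 4), ])
  ga1 <- grand_average(ep1)
  expect_equal(ga1$voltage[ga1$condition == "Best"], v[1, 1, ])
  expect_equal(ga1$voltage[ga1$condition == "Unrelated"], v[4, 1, ])
  # difference waves
  dw <- difference_wave(ga, "Unrelated", "Best")
  expect_equal(dw$voltage,
               ga$voltage[ga$condition == "Unrelated"] -
                 ga$voltage[ga$condition == "Best"])
  self_dw <- difference_wave(ga, "Best", "Best")
  expect_true(all(self_dw$voltage == 0))
  anti <- difference_wave(ga, "Best", "Unrelated")
  expect_equal(anti$voltage, -dw$voltage)
  expect_error(difference_wave(ga, "Missing"), "Missing")
})

test_that("epoch sets round-trip through the text container", {
  set.seed(12)
  v <- array(rnorm(3 * 2 * 250), c(3, 2, 250))
  meta <- tibble::tibble(subject = c("s1", "s1", "s2"),
                         condition = c("Best", "Related", "Best"))
  ep <- epoch_set(v, c("Cz", "Pz"), meta, rejected = c(FALSE, TRUE, FALSE))
  stem <- withr::local_tempfile()
  write_epochs(ep, stem)
  back <- read_epochs(stem)
  expect_equal(back$voltages, ep$voltages, tolerance = 1e-12)
  expect_equal(back$channel_labels, ep$channel_labels)
  expect_equal(back$rejected, ep$rejected)
  expect_equal(tibble::as_tibble(back$trial_meta), meta)
})
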