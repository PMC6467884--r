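cfg <- decoder_config()

test_that("band-limiting preserves 17 Hz and attenuates 60 Hz per the Butterworth response", {
  fs <- 250
  t <- seq_len(10 * fs) / fs
  # steady-state gain measured on the second half of the record (clear of
  # the causal filter's transient)
  gain_at <- function(f) {
    rec <- eeg_recording(sin(2 * pi * f * t), fs)
    out <- bandlimit(rec, cfg)$samples
    half <- seq(length(t) %/% 2, length(t))
    sqrt(mean(out[half]^2) / mean(rec$samples[half]^2))
  }
  expect_lt(abs(gain_at(17) - 1), 0.05)
  # closed-form magnitude of the designed digital 4th-order Butterworth
  # (bilinear design: the analog response evaluated at prewarped
  # frequencies tan(pi f / fs))
  h60 <- 1 / sqrt(1 + (tan(pi * 60 / fs) / tan(pi * 30 / fs))^(2 * 4))
  expect_lt(abs(gain_at(60) / h60 - 1), 0.10)
})

test_that("band-limiting maps zero to zero and rejects impossible bands", {
  z <- eeg_recording(numeric(250), 250)
  expect_equal(bandlimit(z, cfg)$samples, numeric(250))
  expect_error(bandlimit(eeg_recording(numeric(50), 50), cfg), "Nyquist")
})

test_that("epoching yields non-overlapping 1-second epochs, truncating partials", {
  rec <- generate_ssvep(ssvep_spec(17, snr = Inf), 10, 250)
  eps <- epochs(rec, cfg)
  expect_length(eps, 10L)
  expect_true(all(vapply(eps, function(e) length(e$samples) == 250L, logical(1))))
  expect_equal(unlist(lapply(eps, `[[`, "samples")), rec$samples)

  rec2 <- eeg_recording(rnorm(2625), 250)   # 10.5 s
  expect_length(epochs(rec2, cfg), 10L)
  expect_length(epochs(eeg_recording(rnorm(250), 250), cfg), 1L)
  expect_error(epochs(eeg_recording(rnorm(100), 250), cfg), "shorter")
})

test_that("Welch power ranks the stimulated bin above the alternative", {
  t <- seq_len(250) / 250
  psd17 <- welch_power(eeg_recording(sin(2 * pi * 17 * t), 250), cfg)
  expect_true(all(psd17$power >= 0))
  expect_true(!is.unsorted(psd17$freqs))
  expect_gt(bbisim:::psd_at(psd17, 17), bbisim:::psd_at(psd17, 15))
  expect_equal(epoch_vote(psd17, cfg), "yes")
  psd15 <- welch_power(eeg_recording(sin(2 * pi * 15 * t), 250), cfg)
  expect_equal(epoch_vote(psd15, cfg), "no")
})

test_that("white noise shows no mean power preference between the target bins", {
  diffs <- vapply(1:1000, function(s) {
    rec <- generate_idle(1, 250, noise_exponent = 0, seed = s)
    psd <- welch_power(epochs(rec, cfg)[[1]], cfg)
    bbisim:::psd_at(psd, 17) - bbisim:::psd_at(psd, 15)
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 2 * stats::sd(diffs) / sqrt(length(diffs)))
})

test_that("a DC-only epoch carries no power at either target bin", {
  psd <- welch_power(eeg_recording(rep(3.7, 250), 250), cfg)
  expect_lt(bbisim:::psd_at(psd, 17), 1e-20)
  expect_lt(bbisim:::psd_at(psd, 15), 1e-20)
})

test_that("an exact power tie abstains", {
  psd <- structure(list(freqs = c(15, 17), power = c(1, 1),
                        epoch_index = 1L), class = "psd_estimate")
  expect_equal(epoch_vote(psd, cfg), "abstain")
})

test_that("cursor moves by one step per vote, clamps at the sides, ignores abstain", {
  expect_equal(cursor_update(0, "yes", cfg), -0.2)
  expect_equal(cursor_update(0, "no", cfg), 0.2)
  expect_equal(cursor_update(-0.95, "yes", cfg), -1)
  expect_equal(cursor_update(0.95, "no", cfg), 1)
  expect_equal(cursor_update(0, "abstain", cfg), 0)
})

test_that("a side hit decides immediately, regardless of later votes", {
  votes <- c(rep("no", 6), rep("yes", 4))       # hits +1 after 5 "no"
  res <- tally_decision(votes, cfg)
  expect_equal(res$decision$value, 0L)
  expect_equal(res$decision$basis, "hit")
})

test_that("without a hit the majority decides; ties fall to the closest side", {
  votes <- c("yes", "no", "yes", "no", "yes", "yes", "no", "yes", "no", "yes")
  res <- tally_decision(votes, cfg)               # 6 yes / 4 no, no hit
  expect_true(all(abs(res$trace) < 1))
  expect_equal(res$decision$value, 1L)
  expect_equal(res$decision$basis, "closest-side")

  # under constant steps an exact vote tie always returns the cursor to
  # centre; centre resolves to the conservative do-not-rotate side
  tie <- c("yes", "no", "yes", "no", "no", "yes", "no", "yes", "no", "yes")
  res2 <- tally_decision(tie, cfg)
  expect_equal(res2$trace[10], 0)
  expect_equal(res2$decision$value, 0L)
  expect_equal(res2$decision$basis, "closest-side")

  # without a hit, the majority side always coincides with the side
  # nearest the cursor's final position
  set.seed(8)
  for (i in 1:20) {
    votes <- sample(c("yes", "no", "abstain"), 10, replace = TRUE,
                    prob = c(0.35, 0.35, 0.3))
    res3 <- tally_decision(votes, cfg)
    if (res3$decision$basis == "hit") next
    last <- res3$trace[10]
    if (last != 0)
      expect_equal(res3$decision$value, as.integer(last < 0))
  }

  expect_error(tally_decision(character(0), cfg), "empty")
})

test_that("noise-free recordings decode correctly with unanimous votes", {
  for (f in c(15, 17)) {
    res <- decode(generate_ssvep(ssvep_spec(f, snr = Inf), 10, 250), cfg)
    want <- if (f == 17) "yes" else "no"
    expect_equal(unname(res$votes), rep(want, 10))
    expect_equal(res$decision$value, as.integer(f == 17))
    expect_equal(res$decision$basis, "hit")
  }
})

test_that("decode equals the stage-by-stage composition and is deterministic", {
  for (s in 1:5) {
    rec <- generate_ssvep(ssvep_spec(17, snr = 0.5, seed = s), 10, 250)
    fast <- decode(rec, cfg)
    eps <- epochs(bandlimit(rec, cfg), cfg)
    slow <- vapply(eps, function(e) epoch_vote(welch_power(e, cfg), cfg),
                   character(1))
    expect_equal(unname(fast$votes), unname(slow))
    expect_identical(fast, decode(rec, cfg))
  }
})

test_that("swapping the target frequencies flips every decision", {
  swapped <- decoder_config(f_yes = 15, f_no = 17)
  for (s in 1:10) {
    rec <- generate_ssvep(ssvep_spec(17, snr = 2, seed = s), 10, 250)
    expect_equal(decode(rec, cfg)$decision$value,
                 1L - decode(rec, swapped)$decision$value)
  }
})

test_that("at SNR 2 the decoder is correct in at least 95 of 100 seeds", {
  hits <- vapply(1:100, function(s) {
    decode(generate_ssvep(ssvep_spec(17, snr = 2, seed = s), 10, 250),
           cfg)$decision$value == 1L
  }, logical(1))
  expect_gte(sum(hits), 95L)
})
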