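#' Decoder configuration
#'
#' Settings of the SSVEP decision pipeline: a 4th-order Butterworth
#' band-limiting filter between 0 and 30 Hz, 1-second epochs, Welch power
#' at the two target frequencies (17 Hz = "Yes"/rotate, 15 Hz =
#' "No"/do-not-rotate), an epoch tally over a 10-second window, and a
#' cursor that moves a fixed fraction of the screen per epoch vote.
#'
#' The "0 Hz" lower band edge is implemented as a low-pass at the upper
#' edge plus mean removal; a true 0 Hz high-pass corner is degenerate.
#'
#' @param filter_order Butterworth order (4).
#' @param band Two-element Hz interval, `c(0, 30)`.
#' @param epoch_len Epoch length in seconds (1).
#' @param window_len Decision window in seconds (10).
#' @param f_yes,f_no Target frequencies in Hz for the "Yes" (rotate) and
#'   "No" (do-not-rotate) LEDs; 17 and 15.
#' @param cursor_step Screen fraction the cursor moves per epoch vote, on
#'   the \[-1, +1\] axis (-1 is the "Yes" side). Default 0.2, i.e. five
#'   consistent epochs reach a side.
#'
#' @return An object of class `"decoder_config"`.
#' @export
decoder_config <- function(filter_order = 4L, band = c(0, 30), epoch_len = 1,
                           window_len = 10, f_yes = 17, f_no = 15,
                           cursor_step = 0.2) {
  stopifnot(length(band) == 2L, band[1] < band[2])
  if (f_yes == f_no) stop("f_yes and f_no must differ")
  if (f_yes <= band[1] || f_yes >= band[2] || f_no <= band[1] || f_no >= band[2])
    stop("both target frequencies must lie inside the analysis band")
  structure(
    list(filter_order = as.integer(filter_order), band = as.numeric(band),
         epoch_len = epoch_len, window_len = window_len,
         f_yes = f_yes, f_no = f_no, cursor_step = cursor_step),
    class = "decoder_config"
  )
}

# Butterworth designs are deterministic in (order, normalized cutoff);
# cache them, as every decode in a simulated session reuses the same one.
.butter_cache <- new.env(parent = emptyenv())
cached_butter <- function(order, w) {
  key <- paste(order, format(w, digits = 15))
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(order, w, type = "low")
    .butter_cache[[key]] <- bf
  }
  bf
}

#' Band-limit a recording
#'
#' Applies the decoder's causal Butterworth low-pass at the upper band edge
#' (drift is handled by mean removal, see [decoder_config()]), attenuating
#' line noise at 60 Hz while preserving the 0–30 Hz analysis band.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [decoder_config()].
#' @return The filtered [eeg_recording()].
#' @export
bandlimit <- function(rec, cfg = decoder_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  hi <- cfg$band[2]
  if (hi >= rec$fs / 2)
    stop(sprintf("band edge %g Hz is at or above the Nyquist rate %g Hz",
                 hi, rec$fs / 2))
  x <- rec$samples - mean(rec$samples)
  bf <- cached_butter(cfg$filter_order, hi / (rec$fs / 2))
  y <- as.numeric(signal::filter(bf, x))
  eeg_recording(y, rec$fs, label = rec$label, start_time = rec$start_time)
}

#' Split a recording into 1-second epochs
#'
#' Non-overlapping consecutive epochs of `cfg$epoch_len` seconds; a
#' trailing partial epoch is discarded.
#'
#' @inheritParams bandlimit
#' @return List of [eeg_recording()] epochs.
#' @export
epochs <- function(rec, cfg = decoder_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  len <- round(cfg$epoch_len * rec$fs)
  if (abs(cfg$epoch_len * rec$fs - len) > 1e-9)
    stop("epoch_len * fs must be an integer number of samples")
  n_ep <- length(rec$samples) %/% len
  if (n_ep < 1L) stop("recording is shorter than one epoch")
  lapply(seq_len(n_ep), function(i) {
    eeg_recording(rec$samples[((i - 1L) * len + 1L):(i * len)], rec$fs,
                  label = rec$label,
                  start_time = rec$start_time + (i - 1L) * cfg$epoch_len)
  })
}

#' Welch power estimate of one epoch
#'
#' Power spectral density of a single epoch using one full-length
#' Hann-windowed segment (the averaged-periodogram estimator degenerates to
#' a single periodogram at this segment length). With 1-second epochs the
#' bin spacing is exactly 1 Hz, so the 15 and 17 Hz targets fall on exact
#' bins at the design sampling rates.
#'
#' @param epoch One [eeg_recording()] of length `epoch_len * fs`.
#' @param cfg A [decoder_config()].
#' @param epoch_index Optional integer tag carried through to the estimate.
#' @return An object of class `"psd_estimate"`: list with `freqs` (Hz),
#'   `power` (µV²/Hz) and `epoch_index`.
#' @export
welch_power <- function(epoch, cfg = decoder_config(), epoch_index = NA_integer_) {
  stopifnot(inherits(epoch, "eeg_recording"))
  x <- epoch$samples
  n <- length(x)
  w <- hann_window(n)
  xw <- (x - mean(x)) * w
  sp <- Mod(stats::fft(xw))^2
  # one-sided PSD normalised by window power (U = sum(w^2)) and fs
  nh <- n %/% 2L
  pxx <- sp[seq_len(nh + 1L)] / (sum(w^2) * epoch$fs)
  pxx[2:(nh + if (n %% 2L == 0L) 0L else 1L)] <-
    2 * pxx[2:(nh + if (n %% 2L == 0L) 0L else 1L)]
  freqs <- seq(0, nh) * epoch$fs / n
  structure(list(freqs = freqs, power = pxx, epoch_index = epoch_index),
            class = "psd_estimate")
}

hann_window <- function(n) {
  0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / n)
}

# Power at the bin nearest `f` (exact at the design rates).
psd_at <- function(psd, f) {
  psd$power[which.min(abs(psd$freqs - f))]
}

#' Vote of one epoch: "yes", "no" or "abstain"
#'
#' Compares the Welch power at the two target bins; the higher power wins.
#' An exact tie records no vote for the epoch (abstain).
#'
#' @param psd A [welch_power()] estimate.
#' @param cfg A [decoder_config()].
#' @return `"yes"`, `"no"` or `"abstain"`.
#' @export
epoch_vote <- function(psd, cfg = decoder_config()) {
  p_yes <- psd_at(psd, cfg$f_yes)
  p_no <- psd_at(psd, cfg$f_no)
  if (p_yes > p_no) "yes" else if (p_no > p_yes) "no" else "abstain"
}

#' Move the feedback cursor by one epoch vote
#'
#' The cursor lives on \[-1, +1\]; a "yes" vote moves it `cursor_step`
#' towards -1 (the "Yes" side), "no" towards +1, abstain leaves it in
#' place. Positions are clamped at the edges; reaching an edge is a hit.
#'
#' @param position Current position in \[-1, 1\].
#' @param vote `"yes"`, `"no"` or `"abstain"`.
#' @param cfg A [decoder_config()].
#' @return Updated position.
#' @export
cursor_update <- function(position, vote, cfg = decoder_config()) {
  stopifnot(abs(position) <= 1)
  delta <- switch(vote, yes = -cfg$cursor_step, no = cfg$cursor_step,
                  abstain = 0, stop("vote must be yes/no/abstain"))
  max(-1, min(1, position + delta))
}

#' A decoded binary decision
#'
#' @param value 0 (do-not-rotate) or 1 (rotate/"Yes").
#' @param basis How the decision was reached: `"hit"` (cursor reached a
#'   side) or `"closest-side"` (window elapsed; side nearest the cursor's
#'   last position, also used to break an exact vote tie).
#' @param role One of `"sender-1"`, `"sender-2"`, `"receiver"`, or `NA`.
#' @param trial,round Optional protocol coordinates.
#' @return An object of class `"bci_decision"`.
#' @export
decision <- function(value, basis = c("hit", "closest-side"), role = NA_character_,
                     trial = NA_integer_, round = NA_integer_) {
  stopifnot(value %in% c(0, 1))
  basis <- match.arg(basis)
  structure(list(value = as.integer(value), basis = basis, role = role,
                 trial = trial, round = round),
            class = "bci_decision")
}

#' @export
print.bci_decision <- function(x, ...) {
  cat(sprintf("<decision> %s (%d) via %s\n",
              if (x$value == 1L) "rotate" else "do-not-rotate",
              x$value, x$basis))
  invisible(x)
}

#' Tally epoch votes into a final decision
#'
#' Replays the cursor over the vote sequence. If the cursor hits a side,
#' that side's decision is final (basis `"hit"`) regardless of later
#' votes. Otherwise the majority of votes decides; an exact tie falls back
#' to the side nearest the cursor's last position (basis
#' `"closest-side"`), with a cursor exactly at centre resolved to
#' do-not-rotate (the conservative action).
#'
#' @param votes Character vector of `"yes"`/`"no"`/`"abstain"`.
#' @param cfg A [decoder_config()].
#' @return A list with `decision` (a [decision()]) and `trace`, the cursor
#'   position after each vote.
#' @export
tally_decision <- function(votes, cfg = decoder_config()) {
  if (length(votes) == 0L) stop("empty vote sequence")
  if (length(votes) > round(cfg$window_len / cfg$epoch_len))
    stop("more votes than the decision window allows")
  pos <- 0
  trace <- numeric(length(votes))
  hit <- NULL
  for (i in seq_along(votes)) {
    pos <- cursor_update(pos, votes[i], cfg)
    trace[i] <- pos
    if (is.null(hit) && abs(pos) >= 1) hit <- if (pos <= -1) 1L else 0L
  }
  if (!is.null(hit)) {
    dec <- decision(hit, basis = "hit")
  } else {
    n_yes <- sum(votes == "yes")
    n_no <- sum(votes == "no")
    if (n_yes != n_no) {
      dec <- decision(as.integer(n_yes > n_no), basis = "closest-side")
    } else {
      dec <- decision(as.integer(trace[length(trace)] < 0), basis = "closest-side")
    }
  }
  list(decision = dec, trace = trace)
}

#' Decode a recording into a rotate / do-not-rotate decision
#'
#' The full pipeline: band-limit, split into 1-second epochs (at most
#' `window_len` of them), estimate Welch power per epoch, vote 17 vs 15 Hz,
#' drive the cursor, and tally. Deterministic for a fixed recording and
#' configuration.
#'
#' @inheritParams bandlimit
#' @return A list with `decision`, `trace` (cursor positions) and `votes`.
#' @export
#' @examples
#' rec <- generate_ssvep(ssvep_spec(17, snr = Inf), duration = 10, fs = 250)
#' decode(rec)$decision
decode <- function(rec, cfg = decoder_config()) {
  filt <- bandlimit(rec, cfg)
  len <- round(cfg$epoch_len * rec$fs)
  n_ep <- length(filt$samples) %/% len
  if (n_ep < 1L) stop("recording is shorter than one epoch")
  n_max <- round(cfg$window_len / cfg$epoch_len)
  if (n_ep > n_max) n_ep <- n_max
  # all epochs at once: one Hann-windowed FFT per column, numerically
  # identical to welch_power() on each epoch in turn
  m <- matrix(filt$samples[seq_len(n_ep * len)], nrow = len)
  m <- sweep(m, 2, colMeans(m)) * hann_window(len)
  sp <- Mod(stats::mvfft(m))^2
  bins <- seq(0, len %/% 2L) * rec$fs / len
  p_yes <- sp[which.min(abs(bins - cfg$f_yes)), ]
  p_no <- sp[which.min(abs(bins - cfg$f_no)), ]
  votes <- ifelse(p_yes > p_no, "yes", ifelse(p_no > p_yes, "no", "abstain"))
  res <- tally_decision(votes, cfg)
  list(decision = res$decision, trace = res$trace, votes = votes)
}
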