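#' Single-channel EEG recording
#'
#' Lightweight container for a single-channel EEG time series, the raw
#' material of the SSVEP decoder. Amplitudes are in microvolts.
#'
#' @param samples Numeric vector of amplitudes in µV. Must be finite.
#' @param fs Sampling rate in Hz (> 0).
#' @param label Channel name; occipital "Oz" by default, where SSVEP
#'   responses are strongest.
#' @param start_time Offset of the first sample in seconds.
#'
#' @return An object of class `"eeg_recording"`: a list with elements
#'   `samples`, `fs`, `label`, `start_time`.
#' @export
#' @examples
#' rec <- eeg_recording(sin(2 * pi * 17 * seq(0, 1, by = 1/250)[-1]), fs = 250)
#' rec
eeg_recording <- function(samples, fs, label = "Oz", start_time = 0) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("EEG samples must be finite")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("sampling rate `fs` must be a single positive number")
  structure(
    list(samples = samples, fs = fs, label = as.character(label),
         start_time = as.numeric(start_time)),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> channel %s: %d samples @ %g Hz (%.3f s)\n",
              x$label, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' @export
length.eeg_recording <- function(x) length(x$samples)

#' SSVEP stimulus specification
#'
#' Parameters of a synthetic steady-state visually evoked potential: a
#' sinusoid at the flicker frequency of the attended LED, embedded in 1/f^α
#' Gaussian background noise. In the experimental design emulated here the
#' "Yes"/rotate LED flickers at 17 Hz and the "No"/do-not-rotate LED at
#' 15 Hz.
#'
#' @param target_freq Flicker frequency in Hz (15 or 17 in the reference
#'   design). Must be positive and below the Nyquist rate of the recording
#'   it is rendered at.
#' @param amplitude Sinusoid amplitude in µV. The decoder only compares
#'   powers, so the absolute scale is arbitrary.
#' @param noise_exponent Spectral slope α of the 1/f^α background; α = 1 is
#'   the physiologically typical "pink" choice, α = 0 gives white noise.
#' @param snr Ratio of sinusoid power to background-noise power within the
#'   0–30 Hz analysis band (the band the decoder sees). `Inf` means a
#'   noise-free recording.
#' @param seed Integer seed; identical seed and spec reproduce the recording
#'   bit for bit.
#'
#' @return An object of class `"ssvep_spec"`.
#' @export
ssvep_spec <- function(target_freq, amplitude = 5, noise_exponent = 1,
                       snr = 4, seed = 1L) {
  if (target_freq <= 0) stop("target_freq must be positive")
  if (snr < 0) stop("snr must be nonnegative")
  structure(
    list(target_freq = target_freq, amplitude = amplitude,
         noise_exponent = noise_exponent, snr = snr, seed = as.integer(seed)),
    class = "ssvep_spec"
  )
}

# 1/f^alpha Gaussian noise synthesized directly in the frequency domain:
# independent complex-Gaussian coefficients scaled by f^(-alpha/2) on a
# Hermitian-symmetric grid (DC killed), then one inverse FFT. Returns the
# zero-mean real series plus its power inside [0, band_hi] Hz (by
# Parseval, from the synthesized coefficients), which callers use to
# rescale to a requested SNR.
pink_noise <- function(n, fs, alpha, band_hi = 30) {
  nh <- n %/% 2L                       # positive-frequency bins 1..nh
  freqs <- seq_len(nh) * fs / n
  scale <- if (alpha == 0) rep(1, nh) else freqs^(-alpha / 2)
  coef <- complex(real = stats::rnorm(nh), imaginary = stats::rnorm(nh)) * scale
  spec <- complex(length.out = n)      # DC = 0
  spec[2:(nh + 1L)] <- coef
  if (n %% 2L == 0L) {
    spec[nh + 1L] <- complex(real = sqrt(2) * Re(coef[nh]))  # real Nyquist bin
    if (nh > 1L) spec[n:(nh + 2L)] <- Conj(coef[-nh])
  } else {
    spec[n:(nh + 2L)] <- Conj(coef)
  }
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  p_band <- sum(Mod(spec[1L + which(freqs <= band_hi)])^2) * 2 / n^2
  if (n %% 2L == 0L && fs / 2 <= band_hi)
    p_band <- p_band - Mod(spec[nh + 1L])^2 / n^2   # Nyquist bin counted once
  list(x = x, band_power = p_band)
}

# Power of `x` restricted to [0, band_hi] Hz, by Parseval over FFT bins.
band_power <- function(x, fs, band_hi = 30) {
  n <- length(x)
  sp <- Mod(stats::fft(x))^2 / n^2
  freqs <- seq(0, n - 1) * fs / n
  keep <- freqs <= band_hi | freqs >= fs - band_hi   # two-sided bins
  sum(sp[keep])
}

#' Generate a synthetic SSVEP recording
#'
#' Renders a target sinusoid at `spec$target_freq` plus seeded 1/f^α
#' background noise, with the noise scaled so that the ratio of sinusoid
#' power to noise power within the 0–30 Hz band equals `spec$snr`.
#'
#' @param spec An [ssvep_spec()].
#' @param duration Duration in seconds; `duration * fs` must be a whole
#'   number of samples.
#' @param fs Sampling rate in Hz. Senders are recorded at 250 Hz in the
#'   reference design, the Receiver at 5000 Hz (later decimated to 500 Hz).
#'
#' @return An [eeg_recording()].
#' @export
#' @examples
#' rec <- generate_ssvep(ssvep_spec(17, snr = 4, seed = 1), duration = 10, fs = 250)
#' length(rec$samples)  # 2500
generate_ssvep <- function(spec, duration, fs) {
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9)
    stop("duration * fs must be a whole number of samples")
  n <- as.integer(round(n))
  if (spec$target_freq >= fs / 2)
    stop(sprintf("target frequency %g Hz is at or above the Nyquist rate %g Hz",
                 spec$target_freq, fs / 2))
  t <- seq_len(n) / fs
  sine <- spec$amplitude * sin(2 * pi * spec$target_freq * t)
  if (is.infinite(spec$snr)) {
    samples <- sine
  } else if (spec$snr == 0) {
    samples <- withr_seed(spec$seed, pink_noise(n, fs, spec$noise_exponent))$x
  } else {
    noise <- withr_seed(spec$seed, pink_noise(n, fs, spec$noise_exponent))
    p_sine <- spec$amplitude^2 / 2
    samples <- sine + noise$x * sqrt((p_sine / spec$snr) / noise$band_power)
  }
  eeg_recording(samples, fs)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Generate idle (no-SSVEP) background EEG
#'
#' Pure 1/f^α background noise with no target sinusoid, emulating the
#' resting occipital signal outside the SSVEP task window. Over many seeds
#' the mean power at 15 Hz and 17 Hz is indistinguishable.
#'
#' @param duration Duration in seconds.
#' @param fs Sampling rate in Hz.
#' @param noise_exponent Spectral slope α; 0 gives white noise.
#' @param seed Integer seed.
#' @param amplitude_rms RMS amplitude in µV of the generated noise.
#'
#' @return An [eeg_recording()].
#' @export
generate_idle <- function(duration, fs, noise_exponent = 1, seed = 1L,
                          amplitude_rms = 5) {
  n <- duration * fs
  if (abs(n - round(n)) > 1e-9)
    stop("duration * fs must be a whole number of samples")
  n <- as.integer(round(n))
  noise <- withr_seed(seed, pink_noise(n, fs, noise_exponent))$x
  noise <- noise / stats::sd(noise) * amplitude_rms
  eeg_recording(noise, fs)
}

#' Downsample an EEG recording
#'
#' Integer decimation with an anti-aliasing low-pass applied first (an
#' 8th-order Butterworth with cutoff at 80% of the new Nyquist rate), so
#' spectral content below the new Nyquist rate — in particular the
#' 15/17 Hz SSVEP bands — is preserved without folding. The Receiver's
#' acquisition in the reference design is decimated from 5000 Hz to 500 Hz
#' before decoding.
#'
#' @param rec An [eeg_recording()].
#' @param target_fs New sampling rate in Hz; `rec$fs` must be an integer
#'   multiple of it.
#'
#' @return An [eeg_recording()] at `target_fs`.
#' @export
downsample <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs > rec$fs)
    stop("target_fs exceeds the recording's sampling rate")
  if (target_fs == rec$fs) return(rec)
  q <- rec$fs / target_fs
  if (abs(q - round(q)) > 1e-9)
    stop("fs must be an integer multiple of target_fs for decimation")
  q <- as.integer(round(q))
  bf <- cached_butter(8L, 0.8 / q)
  y <- as.numeric(signal::filter(bf, rec$samples))
  out <- y[seq(1L, length(y), by = q)]
  eeg_recording(out, target_fs, label = rec$label, start_time = rec$start_time)
}
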