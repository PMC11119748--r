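# Shared fixtures and independent oracles. These deliberately avoid the
# package's own signal-processing path: pitch is measured by autocorrelation,
# spectra by plain FFTs.

SR <- 16000L

# pure or harmonic tone as a waveform
make_tone <- function(freq, dur = 1, sr = SR, amp = 0.8, n_harm = 1L) {
  t <- (seq_len(round(dur * sr)) - 1L) / sr
  x <- Reduce(`+`, lapply(seq_len(n_harm), function(h) {
    sin(2 * pi * h * freq * t) / h
  }))
  waveform(amp * x / max(abs(x)), sr)
}

# autocorrelation pitch tracker with parabolic peak refinement
pitch_autocorr <- function(w, fmin = 60, fmax = 400) {
  x <- w$samples - mean(w$samples)
  sr <- w$sample_rate
  max_lag <- ceiling(sr / fmin)
  n <- length(x)
  nfft <- 2^ceiling(log2(2 * n))
  X <- fft(c(x, numeric(nfft - n)))
  r <- Re(fft(X * Conj(X), inverse = TRUE))[1:(max_lag + 1L)]
  lags <- ceiling(sr / fmax):max_lag
  k <- lags[which.max(r[lags + 1L])]
  # parabolic interpolation around the peak
  if (k > 1 && k < max_lag) {
    y1 <- r[k]; y2 <- r[k + 1L]; y3 <- r[k + 2L]
    denom <- y1 - 2 * y2 + y3
    delta <- if (abs(denom) > 1e-12) 0.5 * (y1 - y3) / denom else 0
    k <- k + delta
  }
  sr / k
}

# spectral flatness: geometric over arithmetic mean of the power spectrum
spectral_flatness <- function(w) {
  p <- Mod(fft(w$samples))^2
  p <- p[2:(length(p) %/% 2)] + 1e-12
  exp(mean(log(p))) / mean(p)
}

# FFT peak location in Hz (zero-padded for sub-bin resolution)
dominant_freq <- function(w, pad = 8L) {
  n <- length(w$samples)
  s <- Mod(fft(c(w$samples, numeric((pad - 1L) * n))))
  half <- seq_len((pad * n) %/% 2L)
  (which.max(s[half]) - 1L) * w$sample_rate / (pad * n)
}

rms_db <- function(x) 20 * log10(sqrt(mean(x^2)))

# eight tone bursts separated by silences; returns the waveform and the true
# silence midpoints (ground truth for the segmentation oracle)
make_burst_recording <- function(sr = SR, burst_s = 0.4, gap_s = 0.3,
                                 freq = 180) {
  nb <- round(burst_s * sr); ng <- round(gap_s * sr)
  t <- (seq_len(nb) - 1L) / sr
  ramp <- pmin(1, pmin(seq_len(nb), rev(seq_len(nb))) / (0.01 * sr))
  burst <- 0.8 * sin(2 * pi * freq * t) * ramp
  x <- numeric(0)
  mids <- numeric(0)
  for (b in 1:8) {
    x <- c(x, burst)
    if (b < 8) {
      mids <- c(mids, (length(x) + ng / 2) / sr)
      x <- c(x, numeric(ng))
    }
  }
  list(wave = waveform(x, sr), silence_mids = mids)
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# non-stationary, speech-like harmonic signal: vibrato + amplitude modulation
speech_like_tone <- function(dur, f0 = 170, sr = SR) {
  t <- (seq_len(round(dur * sr)) - 1L) / sr
  inst <- f0 * (1 + 0.06 * sin(2 * pi * 3 * t))
  phase <- 2 * pi * cumsum(inst) / sr
  x <- Reduce(`+`, lapply(1:5, function(h) sin(h * phase) / h))
  am <- 0.55 + 0.45 * sin(2 * pi * 2.3 * t)
  waveform(0.8 * am * x / max(abs(x)), sr)
}
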