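# Acoustic front end: 24 log-mel filterbank energies on 25 ms frames with a
# 10 ms shift, utterance-level mean normalization. Standard recipe for the
# embedding extractor; no voice-activity detection by default.

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# triangular mel filterbank, nfft/2+1 bins x n_mels
mel_filterbank <- function(n_mels, nfft, sample_rate, f_min = 20,
                           f_max = sample_rate / 2 - 400) {
  mels <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_mels + 2L)
  hz <- mel_to_hz(mels)
  bins <- hz * nfft / sample_rate
  n_bins <- nfft %/% 2L + 1L
  fb <- matrix(0, n_bins, n_mels)
  k <- seq_len(n_bins) - 1L
  for (m in seq_len(n_mels)) {
    lo <- bins[m]; ctr <- bins[m + 1L]; hi <- bins[m + 2L]
    up <- (k - lo) / (ctr - lo)
    down <- (hi - k) / (hi - ctr)
    fb[, m] <- pmax(0, pmin(up, down))
  }
  fb
}

#' Log-mel filterbank features
#'
#' Frames a 16 kHz waveform (25 ms Hamming window, 10 ms shift), computes
#' power spectra and 24 triangular mel filterbank energies, takes logs with a
#' floor, and applies per-utterance mean normalization.
#'
#' @param w a \code{waveform} at 16 kHz, duration at least
#'   \code{min_duration_s}.
#' @param n_mels number of mel filters (default 24).
#' @param frame_length_ms,frame_shift_ms framing parameters in milliseconds.
#' @param mean_norm subtract the per-coefficient mean over frames.
#' @param log_floor absolute floor applied to filterbank power before the
#'   log; pure digital silence sits exactly at this floor.
#' @param floor_rel relative energy floor: filterbank powers are additionally
#'   floored at \code{floor_rel} times the utterance maximum (a ~70 dB
#'   dynamic range by default), so silent frames behave like quiet frames
#'   rather than minus-infinity outliers. Set to 0 to disable.
#' @param min_duration_s minimum accepted duration in seconds.
#' @return numeric matrix (frames x \code{n_mels}) of class
#'   \code{frame_features}.
#' @export
compute_features <- function(w, n_mels = 24L, frame_length_ms = 25,
                             frame_shift_ms = 10, mean_norm = TRUE,
                             log_floor = 1e-10, floor_rel = 1e-7,
                             min_duration_s = 0.5) {
  stopifnot(inherits(w, "waveform"))
  ps_validate(w$sample_rate == 16000L,
              "features require 16 kHz input; resample first")
  ps_validate(wave_duration(w) >= min_duration_s,
              sprintf("input too short: minimum duration is %.2f s",
                      min_duration_s))
  win <- round(frame_length_ms / 1000 * w$sample_rate)   # 400
  hop <- round(frame_shift_ms / 1000 * w$sample_rate)    # 160
  n <- length(w$samples)
  n_frames <- (n - win) %/% hop + 1L

  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, `+`)
  frames <- matrix(w$samples[idx], nrow = win) *
    (0.54 - 0.46 * cos(2 * pi * (seq_len(win) - 1L) / (win - 1L)))  # Hamming

  nfft <- 2^ceiling(log2(win))                           # 512
  padded <- rbind(frames, matrix(0, nfft - win, n_frames))
  spec <- stats::mvfft(padded)[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  power <- Re(spec * Conj(spec))

  fb <- mel_filterbank(n_mels, nfft, w$sample_rate)
  energies <- crossprod(fb, power)                       # n_mels x frames
  floor_val <- max(log_floor, max(energies) * floor_rel)
  logm <- t(log(pmax(energies, floor_val)))              # frames x n_mels
  if (mean_norm) logm <- sweep(logm, 2L, colMeans(logm))
  structure(logm, class = c("frame_features", "matrix", "array"),
            frame_length_ms = frame_length_ms, frame_shift_ms = frame_shift_ms)
}
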