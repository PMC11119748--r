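# Tempo augmentation: waveform-similarity overlap-add (WSOLA) time-scale
# modification. Changes speaking rate while preserving pitch and spectral
# envelope, used to multiply the number of training samples per segment.

#' Tempo-distort a waveform (WSOLA)
#'
#' Time-scale modification by waveform-similarity overlap-add: Hann-windowed
#' synthesis frames advance at a fixed hop while the matching analysis frames
#' advance at \code{alpha} times that hop, each shifted within a tolerance to
#' maximize cross-correlation with the natural continuation of the previous
#' frame. Output duration is approximately \code{duration(w) / alpha};
#' fundamental frequency and spectral envelope are preserved.
#'
#' @param w a \code{waveform}.
#' @param alpha speed multiplier in \code{[0.7, 1.3]}; \code{alpha = 1} is the
#'   identity. Values above 1 speed up (shorter output).
#' @param seed accepted for interface stability; the algorithm is
#'   deterministic and never consumes randomness.
#' @param frame_length synthesis frame length in samples (Hann window).
#' @param tolerance maximum analysis-frame shift in samples.
#' @return a \code{waveform} at the same sampling rate.
#' @export
tempo_distort <- function(w, alpha, seed = 0L, frame_length = 512L,
                          tolerance = 128L) {
  stopifnot(inherits(w, "waveform"))
  ps_validate(is.numeric(alpha) && length(alpha) == 1L && is.finite(alpha) &&
                alpha >= 0.7 && alpha <= 1.3,
              "alpha must be a single value in [0.7, 1.3]")
  if (alpha == 1) return(w)

  x <- w$samples
  n <- length(x)
  N <- as.integer(frame_length)
  Hs <- N %/% 2L                     # synthesis hop; Hann at 50% overlap
  tol <- as.integer(tolerance)
  ps_validate(n >= N + 2L * tol, "input too short for WSOLA frame length")

  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(N) - 1L) / N)  # periodic Hann, COLA
  target_len <- max(N, as.integer(round(n / alpha)))
  n_frames <- (target_len - N) %/% Hs + 1L

  out <- numeric((n_frames - 1L) * Hs + N)
  norm <- numeric(length(out))
  deltas <- seq(-tol, tol)

  prev_pos <- 1L                     # analysis start of previous frame
  delta <- 0L
  for (k in seq_len(n_frames)) {
    pos_a <- as.integer(round((k - 1L) * Hs * alpha)) + 1L
    if (k == 1L) {
      delta <- 0L
    } else {
      # natural continuation of the previously chosen frame
      ref_start <- prev_pos + Hs
      ref <- x[ref_start:(ref_start + N - 1L)]
      lo <- max(1L, pos_a - tol)
      hi <- min(n - N + 1L, pos_a + tol)
      cand_starts <- lo:hi
      idx <- outer(cand_starts, 0L:(N - 1L), `+`)
      scores <- matrix(x[idx], nrow = length(cand_starts)) %*% ref
      delta <- cand_starts[which.max(scores)] - pos_a
    }
    start <- pos_a + delta
    start <- max(1L, min(start, n - N + 1L))
    frame <- x[start:(start + N - 1L)]
    o <- (k - 1L) * Hs
    out[(o + 1L):(o + N)] <- out[(o + 1L):(o + N)] + frame * win
    norm[(o + 1L):(o + N)] <- norm[(o + 1L):(o + N)] + win
    prev_pos <- start
  }
  out <- out / pmax(norm, 1e-3)
  out <- out[seq_len(min(length(out), target_len))]
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak
  waveform(out, w$sample_rate)
}

#' Augment a set of segments by tempo distortion
#'
#' Produces, for every input waveform, the original plus one tempo-distorted
#' copy per factor, each tagged with its source and factor. Augmented copies
#' inherit the source segment's perceptual labels downstream. Output order is
#' deterministic: segments in input order, original first, then factors in the
#' given order.
#'
#' @param segments non-empty list of \code{waveform}s (optionally named).
#' @param factors numeric vector of tempo factors in \code{[0.7, 1.3]}; may be
#'   empty, in which case the originals are returned unchanged.
#' @param seed forwarded to \code{\link{tempo_distort}} (deterministic).
#' @return list of entries \code{list(wave, source, alpha)} of length
#'   \code{length(segments) * (length(factors) + 1)}.
#' @export
augment_set <- function(segments, factors = c(0.9, 1.1), seed = 0L) {
  ps_validate(is.list(segments) && length(segments) > 0L &&
                all(vapply(segments, inherits, logical(1), "waveform")),
              "segments must be a non-empty list of waveforms")
  nm <- names(segments)
  if (is.null(nm)) nm <- sprintf("segment_%02d", seq_along(segments))
  out <- vector("list", length(segments) * (length(factors) + 1L))
  i <- 0L
  for (s in seq_along(segments)) {
    i <- i + 1L
    out[[i]] <- list(wave = segments[[s]], source = nm[s], alpha = 1)
    for (f in factors) {
      i <- i + 1L
      out[[i]] <- list(wave = tempo_distort(segments[[s]], f, seed = seed),
                       source = nm[s], alpha = f)
    }
  }
  out
}
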