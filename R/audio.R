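# Audio pipeline: waveform container, loading/resampling, canonical passage
# text, pause detection and eight-way passage segmentation.

#' Waveform container
#'
#' A validated mono waveform: amplitude samples in [-1, 1] plus a sampling
#' rate. All pipeline stages consume and produce this type.
#'
#' @param samples numeric vector of amplitudes in [-1, 1].
#' @param sample_rate sampling rate in Hz (positive integer).
#' @return object of class \code{waveform}.
#' @export
waveform <- function(samples, sample_rate) {
  ps_validate(is.numeric(samples) && length(samples) > 0L,
              "waveform must contain at least one sample")
  ps_validate(all(is.finite(samples)), "waveform samples must all be finite")
  ps_validate(is.numeric(sample_rate) && length(sample_rate) == 1L &&
                sample_rate > 0 && sample_rate == round(sample_rate),
              "sample_rate must be a positive integer (Hz)")
  ps_validate(max(abs(samples)) <= 1 + 1e-6,
              "waveform samples must lie in [-1, 1]; peak-normalize first")
  structure(list(samples = as.numeric(pmin(1, pmax(-1, samples))),
                 sample_rate = as.integer(sample_rate)),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform> %d samples @ %d Hz (%.3f s), peak %.3f\n",
              length(x$samples), x$sample_rate, wave_duration(x),
              max(abs(x$samples))))
  invisible(x)
}

#' Duration of a waveform in seconds
#' @param w a \code{waveform}.
#' @return duration in seconds.
#' @export
wave_duration <- function(w) length(w$samples) / w$sample_rate

#' Resample a waveform with a polyphase windowed-sinc filter
#'
#' Rational-factor resampling (zero-stuff, low-pass, decimate). Identity when
#' the waveform is already at the target rate, which makes resampling
#' idempotent.
#'
#' @param w a \code{waveform}.
#' @param rate target sampling rate in Hz.
#' @param lobes one-sided length of the sinc kernel in zero crossings;
#'   controls transition-band sharpness.
#' @return resampled \code{waveform} at \code{rate}.
#' @export
resample_waveform <- function(w, rate = 16000L, lobes = 10L) {
  stopifnot(inherits(w, "waveform"))
  rate <- as.integer(rate)
  if (w$sample_rate == rate) return(w)
  g <- ps_gcd(w$sample_rate, rate)
  L <- rate %/% g            # upsampling factor
  M <- w$sample_rate %/% g   # downsampling factor

  n <- length(w$samples)
  up <- numeric(n * L)
  up[seq(1L, by = L, length.out = n)] <- w$samples

  # anti-alias / anti-image low-pass at the tighter of the two Nyquists
  fc <- 1 / (2 * max(L, M))              # cycles per (upsampled) sample
  half <- lobes * max(L, M)
  t <- seq(-half, half)
  h <- 2 * fc * sinc(2 * fc * t) * hann_window(2L * half + 1L)
  h <- h / sum(h) * L                    # unity passband gain after zero-stuffing

  y <- stats::convolve(up, rev(h), type = "open")
  y <- y[(half + 1L):(half + n * L)]     # compensate group delay
  out <- y[seq(1L, n * L, by = M)]
  peak <- max(abs(out))
  if (peak > 1) out <- out / peak        # guard against filter overshoot
  waveform(out, rate)
}

ps_gcd <- function(a, b) if (b == 0L) a else ps_gcd(b, a %% b)
sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Load a passage-reading recording
#'
#' Reads a PCM WAV file (16-bit integer or 32-bit float), collapses stereo to
#' mono by channel averaging, resamples to the pipeline rate, and
#' peak-normalizes the amplitude.
#'
#' @param path path to a WAV file.
#' @param target_rate pipeline sampling rate in Hz; default 16000.
#' @return a mono \code{waveform} at \code{target_rate} with peak amplitude 1.
#' @export
load_recording <- function(path, target_rate = 16000L) {
  raw <- read_wav(path)
  mono <- rowMeans(raw$samples)
  ps_validate(length(mono) > 0L, sprintf("zero-length audio: %s", path))
  peak <- max(abs(mono))
  if (peak > 0) mono <- mono / peak
  w <- waveform(mono, raw$sample_rate)
  w <- resample_waveform(w, target_rate)
  peak <- max(abs(w$samples))
  if (peak > 0) w$samples <- w$samples / peak
  w
}

# -- canonical passage ------------------------------------------------------

# First paragraph of "La chevre de M. Seguin", the standard French clinical
# phonetics reading text. Stored as the eight clinically used spans: the four
# sentence boundaries after sentence 1 plus the three major clause commas of
# sentence 3 give the seven canonical break points.
.passage_spans <- c(
  "Monsieur Seguin n'avait jamais eu de bonheur avec ses chèvres.",
  "Il les perdait toutes de la même façon.",
  "Un beau matin,",
  "elles cassaient leur corde,",
  "s'en allaient dans la montagne,",
  "et là-haut le loup les mangeait.",
  "Ni les caresses de leur maître ni la peur du loup rien ne les retenait.",
  paste("C'était paraît-il des chèvres indépendantes",
        "voulant à tout prix le grand air et la liberté.")
)

#' Canonical passage text
#'
#' The full printed passage of the clinical reading task (first paragraph of
#' "La chevre de M. Seguin"), identical across calls.
#'
#' @return a single string (five sentences).
#' @export
canonical_passage <- function() paste(.passage_spans, collapse = " ")

#' Canonical passage spans
#'
#' The eight text spans delimited by the seven default break points.
#' @return character vector of length 8.
#' @export
canonical_passage_spans <- function() .passage_spans

#' Default text-anchored break specification
#'
#' Seven break points anchored at the canonical passage's natural breaks
#' (sentence boundaries and major clause commas), each mapped at run time to
#' the nearest detected pause. Break positions are expressed as fractions of
#' the spoken passage, approximated by cumulative character counts.
#'
#' @param window_s RMS analysis window for pause detection (seconds).
#' @param threshold_db silence threshold in dBFS (RMS re. full scale).
#' @param min_pause_s minimum pause duration in seconds.
#' @return object of class \code{break_spec}.
#' @export
default_break_spec <- function(window_s = 0.025, threshold_db = -35,
                               min_pause_s = 0.150) {
  lens <- nchar(.passage_spans)
  fracs <- cumsum(lens)[-length(lens)] / sum(lens)
  structure(list(spans = .passage_spans, break_fracs = fracs,
                 window_s = window_s, threshold_db = threshold_db,
                 min_pause_s = min_pause_s),
            class = "break_spec")
}

#' Detect pauses by short-time RMS energy
#'
#' Marks stretches where the RMS energy in consecutive analysis windows stays
#' below a dBFS threshold for at least a minimum duration.
#'
#' @param w a \code{waveform}.
#' @param window_s analysis window in seconds (non-overlapping).
#' @param threshold_db RMS threshold in dBFS.
#' @param min_pause_s minimum pause duration in seconds.
#' @return data.frame with columns \code{start_s}, \code{end_s}, \code{mid_s}.
#' @export
detect_pauses <- function(w, window_s = 0.025, threshold_db = -35,
                          min_pause_s = 0.150) {
  stopifnot(inherits(w, "waveform"))
  win <- max(1L, round(window_s * w$sample_rate))
  n_win <- length(w$samples) %/% win
  ps_validate(n_win >= 1L, "recording shorter than one analysis window")
  x <- w$samples[seq_len(n_win * win)]
  rms <- sqrt(colMeans(matrix(x^2, nrow = win)))
  silent <- 20 * log10(pmax(rms, 1e-12)) < threshold_db

  runs <- rle(silent)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & (runs$lengths * window_s >= min_pause_s)
  if (!any(keep)) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      mid_s = numeric(0)))
  }
  s <- (starts[keep] - 1L) * win / w$sample_rate
  e <- ends[keep] * win / w$sample_rate
  data.frame(start_s = s, end_s = e, mid_s = (s + e) / 2)
}

#' Segment a passage recording
#'
#' Cuts a recording into contiguous segments at explicit cut times or, with
#' the default text-anchored \code{\link{default_break_spec}}, at detected
#' pauses nearest to the passage's seven natural break points — yielding the
#' eight segments of the canonical passage. Segment times are half-open
#' intervals \code{[start_s, end_s)} from recording start.
#'
#' @param w a \code{waveform}.
#' @param breaks either a numeric vector of cut times in seconds (strictly
#'   increasing, inside the recording) or a \code{break_spec}.
#' @param recording_id identifier stored with each segment.
#' @return data.frame of class \code{passage_segments} with columns
#'   \code{recording_id}, \code{index}, \code{start_s}, \code{end_s},
#'   \code{text_span}.
#' @export
segment_passage <- function(w, breaks = default_break_spec(),
                            recording_id = "recording") {
  stopifnot(inherits(w, "waveform"))
  dur <- wave_duration(w)

  if (is.numeric(breaks)) {
    ps_validate(all(breaks > 0 & breaks < dur),
                "cut times must lie strictly inside the recording")
    ps_validate(!is.unsorted(breaks, strictly = TRUE),
                "cut times must be strictly increasing")
    cuts <- as.numeric(breaks)
    bounds <- c(0, cuts, dur)
    spans <- rep(NA_character_, length(cuts) + 1L)
  } else if (inherits(breaks, "break_spec")) {
    pauses <- detect_pauses(w, breaks$window_s, breaks$threshold_db,
                            breaks$min_pause_s)
    # speech region: strip pauses touching the recording edges
    speech_start <- 0
    speech_end <- dur
    if (nrow(pauses) > 0L && pauses$start_s[1L] <= 1e-9) {
      speech_start <- pauses$end_s[1L]
      pauses <- pauses[-1L, , drop = FALSE]
    }
    if (nrow(pauses) > 0L && pauses$end_s[nrow(pauses)] >= dur - 1e-9) {
      speech_end <- pauses$start_s[nrow(pauses)]
      pauses <- pauses[-nrow(pauses), , drop = FALSE]
    }
    n_breaks <- length(breaks$break_fracs)
    targets <- speech_start + breaks$break_fracs * (speech_end - speech_start)
    mids <- pauses$mid_s[pauses$mid_s > speech_start & pauses$mid_s < speech_end]
    if (length(mids) < n_breaks) {
      k <- length(mids) + 1L
      ps_stop(sprintf(
        "segmentation failed: only %d pauses detected; no pause available for text break %d (\"%s\" | \"%s\")",
        length(mids), k, breaks$spans[k], breaks$spans[k + 1L]),
        "ps_segmentation_error")
    }
    cuts <- match_breaks_to_pauses(targets, mids)
    bounds <- c(speech_start, cuts, speech_end)
    spans <- breaks$spans
  } else {
    ps_validate(FALSE, "breaks must be numeric cut times or a break_spec")
  }

  out <- data.frame(
    recording_id = recording_id,
    index = seq_len(length(bounds) - 1L),
    start_s = bounds[-length(bounds)],
    end_s = bounds[-1L],
    text_span = spans,
    stringsAsFactors = FALSE
  )
  class(out) <- c("passage_segments", "data.frame")
  out
}

# Order-preserving assignment of text-break targets to pause midpoints
# minimizing total absolute mismatch (each break to a distinct pause, in
# order). Dynamic program over (break, pause) pairs; with exactly as many
# pauses as breaks this reduces to using all pauses in order.
match_breaks_to_pauses <- function(targets, mids) {
  B <- length(targets); P <- length(mids)
  cost <- matrix(Inf, B + 1L, P + 1L)
  cost[1L, ] <- 0
  take <- matrix(FALSE, B + 1L, P + 1L)
  for (k in seq_len(B)) {
    for (i in k:P) {
      skip <- cost[k + 1L, i]
      use <- cost[k, i] + abs(mids[i] - targets[k])
      if (use <= skip) {
        cost[k + 1L, i + 1L] <- use
        take[k + 1L, i + 1L] <- TRUE
      } else {
        cost[k + 1L, i + 1L] <- skip
      }
    }
  }
  cuts <- numeric(B)
  i <- P + 1L
  for (k in (B + 1L):2L) {
    while (!take[k, i]) i <- i - 1L
    cuts[k - 1L] <- mids[i - 1L]
    i <- i - 1L
  }
  cuts
}

#' Extract the audio of each segment
#'
#' Slices a waveform at segment boundaries (half-open intervals, sample index
#' = floor(time * rate)); concatenating the slices in index order reproduces
#' the spanned region sample-for-sample.
#'
#' @param w the segmented \code{waveform}.
#' @param segments a \code{passage_segments} table from
#'   \code{\link{segment_passage}}.
#' @return named list of \code{waveform}s, one per segment, in index order.
#' @export
segment_audio <- function(w, segments) {
  stopifnot(inherits(w, "waveform"), inherits(segments, "passage_segments"))
  sr <- w$sample_rate
  lapply(seq_len(nrow(segments)), function(i) {
    a <- floor(segments$start_s[i] * sr) + 1L
    b <- floor(segments$end_s[i] * sr)
    ps_validate(b >= a, sprintf("segment %d is empty", i))
    waveform(w$samples[a:b], sr)
  })
}

#' Write a segment table as TSV
#'
#' @param segments a \code{passage_segments} table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(as.data.frame(segments)[, c("recording_id", "index",
                                                 "start_s", "end_s")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
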