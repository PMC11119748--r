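# Minimal RIFF/WAVE reader and writer.
#
# Supports the two encodings produced by clinical recorders and by this
# package itself: 16-bit integer PCM (format tag 1) and 32-bit IEEE float
# (format tag 3), mono or stereo, any sample rate. Chunks other than "fmt "
# and "data" are skipped. No compressed formats.

#' Read a PCM WAV file
#'
#' @param path path to a RIFF/WAVE file (16-bit PCM or 32-bit float).
#' @return list with \code{samples} (numeric matrix, frames x channels, in
#'   [-1, 1]) and \code{sample_rate} (Hz).
#' @export
read_wav <- function(path) {
  ps_input(is.character(path) && length(path) == 1L && file.exists(path),
           sprintf("WAV file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)

  riff <- readChar(con, 4L, useBytes = TRUE)
  ps_input(identical(riff, "RIFF"), sprintf("not a RIFF file: %s", path))
  readBin(con, "integer", 1L, 4L, endian = "little")  # total size, unused
  wave <- readChar(con, 4L, useBytes = TRUE)
  ps_input(identical(wave, "WAVE"), sprintf("not a WAVE file: %s", path))

  fmt <- NULL; data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4L) break
    size <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(size) == 0L) break
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", size)
      fmt <- list(
        tag       = readBin(body[1:2],  "integer", 1L, 2L, endian = "little", signed = FALSE),
        channels  = readBin(body[3:4],  "integer", 1L, 2L, endian = "little", signed = FALSE),
        rate      = readBin(body[5:8],  "integer", 1L, 4L, endian = "little"),
        bits      = readBin(body[15:16], "integer", 1L, 2L, endian = "little", signed = FALSE)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", size)
    } else {
      readBin(con, "raw", size + size %% 2L)  # skip, chunks are word-aligned
    }
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  ps_input(!is.null(fmt), sprintf("corrupt WAV (no fmt chunk): %s", path))
  ps_input(!is.null(data_raw), sprintf("corrupt WAV (no data chunk): %s", path))
  ps_input(fmt$tag %in% c(1L, 3L),
           sprintf("unsupported WAV format tag %d (PCM or IEEE float only)", fmt$tag))

  if (fmt$tag == 1L) {
    ps_input(fmt$bits == 16L, sprintf("unsupported PCM bit depth %d (16-bit only)", fmt$bits))
    x <- readBin(data_raw, "integer", length(data_raw) %/% 2L, 2L,
                 endian = "little", signed = TRUE) / 32768
  } else {
    ps_input(fmt$bits == 32L, sprintf("unsupported float bit depth %d (32-bit only)", fmt$bits))
    x <- readBin(data_raw, "numeric", length(data_raw) %/% 4L, 4L, endian = "little")
  }
  ps_validate(length(x) > 0L, sprintf("zero-length audio: %s", path))
  n_ch <- fmt$channels
  m <- matrix(x, ncol = n_ch, byrow = TRUE)
  list(samples = m, sample_rate = fmt$rate)
}

#' Write a mono or multichannel WAV file
#'
#' @param samples numeric vector or frames x channels matrix in [-1, 1].
#' @param sample_rate sampling rate in Hz.
#' @param path output path.
#' @param bits 16 (integer PCM) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(samples, sample_rate, path, bits = 16L) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1L)
  ps_validate(bits %in% c(16L, 32L), "bits must be 16 or 32")
  n_ch <- ncol(samples)
  interleaved <- as.numeric(t(samples))
  bytes_per <- bits %/% 8L
  data_size <- length(interleaved) * bytes_per
  block_align <- n_ch * bytes_per

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, 4L, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4L, endian = "little")
  writeBin(if (bits == 16L) 1L else 3L, con, 2L, endian = "little")
  writeBin(as.integer(n_ch), con, 2L, endian = "little")
  writeBin(as.integer(sample_rate), con, 4L, endian = "little")
  writeBin(as.integer(sample_rate * block_align), con, 4L, endian = "little")
  writeBin(as.integer(block_align), con, 2L, endian = "little")
  writeBin(as.integer(bits), con, 2L, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4L, endian = "little")
  if (bits == 16L) {
    q <- as.integer(round(pmax(-1, pmin(1, interleaved)) * 32767))
    writeBin(q, con, 2L, endian = "little")
  } else {
    writeBin(interleaved, con, 4L, endian = "little")
  }
  invisible(path)
}
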