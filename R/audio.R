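#' Synthesise audio from an f0 contour
#'
#' Renders a harmonic (pulse-train-like) voice signal whose instantaneous
#' fundamental follows the contour: the phase is the cumulative integral of
#' the sample-interpolated f0, and harmonics `1..n_harmonics` with 1/k
#' amplitudes are summed. Unvoiced frames produce silence (with short
#' cosine on/off ramps to avoid clicks); a low-level noise floor can be
#' added for realism. Deterministic given `seed`.
#'
#' @param contour tibble with `time_s`, `f0_hz`, `voiced`
#' @param fs sampling rate (Hz), default 20 kHz
#' @param n_harmonics requested number of harmonics; harmonics above 0.45*fs
#'   are dropped automatically
#' @param noise_db noise floor relative to unit amplitude (dB); `-Inf` for none
#' @param seed integer seed for the noise
#' @return numeric waveform, `length = round(max(time_s) * fs) + 1`
#' @export
synthesize_audio <- function(contour, fs = 20000, n_harmonics = 10,
                             noise_db = -50, seed = 1L) {
  stopifnot(all(c("time_s", "f0_hz", "voiced") %in% names(contour)))
  if (any(contour$voiced & (is.na(contour$f0_hz) | contour$f0_hz <= 0))) {
    abort("Voiced frames must carry a strictly positive f0.")
  }
  f0max <- suppressWarnings(max(contour$f0_hz, na.rm = TRUE))
  if (!is.finite(f0max)) f0max <- 0
  if (f0max > 0 && fs < 2 * f0max) {
    abort("Sampling rate below twice the maximum fundamental.")
  }
  kmax <- if (f0max > 0) max(1L, floor(0.45 * fs / f0max)) else 1L
  k <- seq_len(min(n_harmonics, kmax))

  n <- round(max(contour$time_s) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  voiced_t <- contour$time_s[contour$voiced]
  f0_t <- contour$f0_hz[contour$voiced]
  x <- numeric(n)
  if (length(voiced_t) >= 2L) {
    f0_s <- approx(voiced_t, f0_t, xout = t, rule = 2)$y
    phase <- 2 * pi * cumsum(f0_s) / fs
    for (kk in k) x <- x + sin(kk * phase) / kk
    x <- x / sum(1 / k) * 0.5
    # voicing mask with 5-ms ramps
    vmask <- approx(contour$time_s, as.numeric(contour$voiced), xout = t,
                    method = "constant", rule = 2)$y
    ramp_n <- max(1L, round(0.005 * fs))
    kern <- rep(1 / ramp_n, ramp_n)
    sm <- as.numeric(stats::filter(c(rep(vmask[1], ramp_n), vmask,
                                     rep(vmask[length(vmask)], ramp_n)),
                                   kern, sides = 2))
    sm <- sm[ramp_n + seq_len(n)]
    sm[is.na(sm)] <- vmask[is.na(sm)]
    x <- x * sm
    x[vmask == 0] <- 0
  }
  if (is.finite(noise_db)) {
    amp <- 10^(noise_db / 20)
    vmask2 <- if (length(voiced_t) >= 2L) {
      approx(contour$time_s, as.numeric(contour$voiced), xout = t,
             method = "constant", rule = 2)$y
    } else {
      rep(0, n)
    }
    x <- x + with_seed(seed, rnorm(n, 0, amp)) * vmask2
  }
  x
}

#' Write a mono PCM-16 WAV file
#'
#' Minimal RIFF/WAVE writer for the package's synthesized audio (16-bit
#' signed PCM, single channel).
#'
#' @param wave numeric vector in `[-1, 1]` (clipped otherwise)
#' @param path output file path
#' @param fs sampling rate (Hz)
#' @return `path`, invisibly
#' @export
write_wav <- function(wave, path, fs = 20000) {
  pcm <- as.integer(round(pmin(pmax(wave, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_bytes <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_bytes), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(c(1L, 1L), con, size = 2, endian = "little")          # PCM, mono
  writeBin(as.integer(fs), con, size = 4, endian = "little")
  writeBin(as.integer(fs * 2L), con, size = 4, endian = "little") # byte rate
  writeBin(c(2L, 16L), con, size = 2, endian = "little")          # align, bits
  writeChar("data", con, eos = NULL)
  writeBin(data_bytes, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a mono PCM-16 WAV file
#'
#' Counterpart to [write_wav()]; handles canonical 16-bit mono RIFF files.
#'
#' @param path WAV file path
#' @return list with `wave` (numeric in `[-1, 1]`) and `fs`
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4)
  if (!identical(riff, "RIFF")) abort("Not a RIFF/WAVE file.")
  invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
  wave_id <- readChar(con, 4)
  if (!identical(wave_id, "WAVE")) abort("Not a RIFF/WAVE file.")
  fs <- NULL
  repeat {
    id <- readChar(con, 4)
    if (length(id) == 0 || nchar(id) < 4) abort("No data chunk found.")
    sz <- readBin(con, integer(), 1, size = 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, integer(), 2, size = 2, endian = "little")
      if (fmt[1] != 1L || fmt[2] != 1L) abort("Only mono PCM is supported.")
      fs <- readBin(con, integer(), 1, size = 4, endian = "little")
      invisible(readBin(con, integer(), 1, size = 4, endian = "little"))
      bits <- readBin(con, integer(), 2, size = 2, endian = "little")[2]
      if (bits != 16L) abort("Only 16-bit PCM is supported.")
      if (sz > 16) invisible(readBin(con, raw(), sz - 16))
    } else if (id == "data") {
      pcm <- readBin(con, integer(), sz / 2, size = 2, signed = TRUE,
                     endian = "little")
      return(list(wave = pcm / 32767, fs = fs))
    } else {
      invisible(readBin(con, raw(), sz))
    }
  }
}
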