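#' Autocorrelation f0 tracking
#'
#' Frame-based fundamental-frequency estimation in the classic
#' autocorrelation family: each Hann-windowed frame's normalized
#' autocorrelation is corrected by the window's own autocorrelation (which
#' removes the window-induced downward bias on the peak), the highest
#' corrected peak in the lag range `[1/f0_max, 1/f0_min]` is located, and
#' the peak lag is refined by local cosine interpolation (exact for a pure
#' tone, sub-sample accurate for voiced speech). A frame is voiced when the
#' corrected peak height reaches `voicing_threshold` and the frame RMS is
#' above an energy floor.
#'
#' @param wave numeric waveform
#' @param fs sampling rate (Hz); must be at least `4 * f0_max`
#' @param f0_min,f0_max search range (Hz)
#' @param hop_ms frame hop (ms)
#' @param window_ms analysis window length (ms)
#' @param voicing_threshold corrected-autocorrelation voicing threshold
#' @param energy_floor RMS below which a frame is unvoiced
#' @param octave_cost per-octave score penalty on longer candidate lags, so
#'   the true period peak beats its subharmonic duplicates
#' @return contour tibble: `time_s`, `f0_hz` (NA when unvoiced), `voiced`
#' @export
track_f0 <- function(wave, fs, f0_min = 75, f0_max = 500, hop_ms = 5,
                     window_ms = 40, voicing_threshold = 0.45,
                     energy_floor = 1e-3, octave_cost = 0.02) {
  if (f0_min >= f0_max) abort("`f0_min` must be below `f0_max`.")
  if (fs < 4 * f0_max) abort("Sampling rate must be at least 4 * f0_max.")
  win_n <- round(window_ms / 1000 * fs)
  if (length(wave) < win_n) abort("Signal shorter than one analysis window.")
  hop_n <- round(hop_ms / 1000 * fs)
  lag_min <- max(2L, floor(fs / f0_max))
  lag_max <- ceiling(fs / f0_min)
  if (lag_max >= win_n) abort("Window too short for `f0_min`; increase `window_ms`.")

  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_n) / (win_n + 1))
  nfft <- 2^ceiling(log2(2 * win_n))
  # window autocorrelation (normalized), for bias correction
  wf <- fft(c(w, rep(0, nfft - win_n)))
  rw <- Re(fft(Mod(wf)^2, inverse = TRUE))[seq_len(lag_max + 2)]
  rw <- rw / rw[1]

  starts <- seq(1L, length(wave) - win_n + 1L, by = hop_n)
  centers <- (starts - 1 + win_n / 2) / fs
  n_frames <- length(starts)
  f0 <- rep(NA_real_, n_frames)
  voiced <- rep(FALSE, n_frames)

  for (i in seq_len(n_frames)) {
    x <- wave[starts[i] + seq_len(win_n) - 1L]
    if (sqrt(mean(x^2)) < energy_floor) next
    x <- (x - mean(x)) * w
    xf <- fft(c(x, rep(0, nfft - win_n)))
    r <- Re(fft(Mod(xf)^2, inverse = TRUE))[seq_len(lag_max + 2)]
    if (r[1] <= 0) next
    rc <- (r / r[1]) / rw # window-corrected normalized autocorrelation
    idx <- (lag_min + 1L):(lag_max + 1L) # 1-based: entry j is lag j-1
    v <- rc[idx]
    # candidate peaks: local maxima above threshold, scored with a small
    # octave cost so the period peak beats its subharmonics
    is_max <- v >= c(-Inf, v[-length(v)]) & v >= c(v[-1], -Inf)
    cand <- idx[is_max & is.finite(v) & v >= voicing_threshold]
    if (length(cand) == 0L) next
    score <- rc[cand] - octave_cost * log2((cand - 1) / lag_min)
    pk <- cand[which.max(score)]
    height <- rc[pk]
    lag <- pk - 1L
    # cosine interpolation around the peak (exact for r(l) ~ A cos(w(l - p)))
    y0 <- rc[pk]; ym <- rc[pk - 1L]; yp <- rc[pk + 1L]
    delta <- 0
    cw <- (yp + ym) / (2 * y0)
    if (is.finite(cw) && abs(cw) < 1 && y0 > 0) {
      om <- acos(cw)
      if (om > 1e-6) {
        u <- atan2((ym - yp) / (2 * sin(om)), y0)
        delta <- -u / om
      }
    } else {
      denom <- ym - 2 * y0 + yp
      if (is.finite(denom) && denom < 0) delta <- 0.5 * (ym - yp) / denom
    }
    delta <- min(max(delta, -1), 1)
    est <- fs / (lag + delta)
    f0[i] <- min(max(est, f0_min), f0_max)
    voiced[i] <- TRUE
  }
  tibble(time_s = centers, f0_hz = f0, voiced = voiced)
}

#' Interpolate across short unvoiced gaps
#'
#' Linear interpolation of f0 across unvoiced stretches no longer than
#' `max_gap_ms`, so that epochs spanning brief consonantal voicing breaks
#' (e.g. the /b/ of "by", the /t/ of "not" in the carrier phrase) can be
#' averaged. Longer gaps stay missing. The original voicing flags are
#' preserved; interpolated frames are marked in a new `filled` column.
#'
#' @param contour tibble with `time_s`, `f0_hz`, `voiced`
#' @param max_gap_ms longest gap to fill (ms)
#' @return the contour with filled `f0_hz` and a logical `filled` column
#' @export
interpolate_unvoiced <- function(contour, max_gap_ms = 100) {
  stopifnot(all(c("time_s", "f0_hz", "voiced") %in% names(contour)))
  out <- contour
  out$filled <- FALSE
  miss <- !out$voiced | is.na(out$f0_hz)
  if (!any(miss) || all(miss)) return(out)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$values)
  for (j in ok) {
    a <- starts[j]; b <- ends[j]
    if (a == 1L || b == nrow(out)) next # edge gaps cannot be interpolated
    gap_ms <- (out$time_s[b + 1L] - out$time_s[a - 1L]) * 1000
    if (gap_ms > max_gap_ms + 1e-9) next
    fill <- approx(
      x = out$time_s[c(a - 1L, b + 1L)],
      y = out$f0_hz[c(a - 1L, b + 1L)],
      xout = out$time_s[a:b]
    )$y
    out$f0_hz[a:b] <- fill
    out$filled[a:b] <- TRUE
  }
  out
}
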