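#' Convert a frequency ratio to cents
#'
#' The cent is the standard logarithmic pitch unit: 1200 cents per octave,
#' 100 cents per equal-tempered semitone. All response measures in the
#' package are expressed in cents relative to a baseline frequency, which
#' makes trials comparable across speakers with different habitual f0.
#'
#' \deqn{\mathrm{cents} = 1200 \log_2(f_2 / f_1)}
#'
#' @param f2 frequency of interest (Hz); vectorised
#' @param f1 reference frequency (Hz); vectorised, recycled
#' @return numeric vector of cents; positive when `f2 > f1`
#' @examples
#' hz_to_cents(220 * 2^(1 / 12), 220) # one semitone = 100 cents
#' hz_to_cents(440, 220)              # one octave  = 1200 cents
#' @export
hz_to_cents <- function(f2, f1) {
  if (!is.numeric(f2) || !is.numeric(f1)) {
    abort("`f2` and `f1` must be numeric.")
  }
  bad2 <- !is.na(f2) & f2 <= 0
  bad1 <- !is.na(f1) & f1 <= 0
  if (any(bad2) || any(bad1)) {
    abort("Frequencies must be strictly positive to convert to cents.")
  }
  1200 * log2(f2 / f1)
}

#' Convert cents back to Hz given a reference
#'
#' Inverse of [hz_to_cents()]: `cents_to_hz(hz_to_cents(f, ref), ref) == f`.
#'
#' @param cents numeric vector of cents
#' @param f1 reference frequency (Hz)
#' @return frequencies in Hz
#' @export
cents_to_hz <- function(cents, f1) {
  if (any(!is.na(f1) & f1 <= 0)) abort("Reference frequency must be > 0.")
  f1 * 2^(cents / 1200)
}
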