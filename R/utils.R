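#' Derive a child RNG seed deterministically
#'
#' Hierarchical seeding: every randomised stage derives its own stream from a
#' single session seed so that subjects, trials and replicates are independent
#' yet fully reproducible. Kept inside 32-bit integer range.
#'
#' @param seed parent integer seed
#' @param index non-negative integer stream index
#' @return an integer seed in `[0, 2^31 - 2]`
#' @export
derive_seed <- function(seed, index = 0L) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- (as.double(seed) %% m)
  for (k in c(as.double(index) + 1, 2654435769)) {
    s <- (s * 48271 + k) %% m
  }
  as.integer(s)
}

# run code under a local RNG seeded deterministically, without touching the
# caller's .Random.seed
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister")
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name))
  }
  invisible(x)
}

# uniform-grid check used by epoching and tracking
contour_hop_ms <- function(contour) {
  dt <- diff(contour$time_s)
  if (length(dt) == 0L) abort("Contour has fewer than 2 frames.")
  if (max(abs(dt - dt[1])) > 1e-9) {
    abort("Contour time grid is not uniform.")
  }
  dt[1] * 1000
}
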