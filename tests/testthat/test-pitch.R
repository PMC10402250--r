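const_contour <- function(f0, dur = 1, hop = 0.005) {
  tibble::tibble(time_s = seq(0, dur, hop), f0_hz = f0, voiced = TRUE)
}

test_that("constant tones are tracked within one cent", {
  for (f in c(110, 220, 330)) {
    w <- synthesize_audio(const_contour(f), fs = 20000, seed = 1)
    trk <- track_f0(w, 20000)
    expect_true(all(trk$voiced))
    expect_true(all(abs(hz_to_cents(trk$f0_hz, f)) < 1))
  }
})

test_that("silence and sub-floor signals are unvoiced", {
  trk <- track_f0(rep(0, 20000), 20000)
  expect_false(any(trk$voiced))
  expect_true(all(is.na(trk$f0_hz)))
  trk2 <- track_f0(rnorm(20000, 0, 1e-5), 20000)
  expect_false(any(trk2$voiced))
})

test_that("a slow glide is tracked within 3 cents of the generating contour", {
  t <- seq(0, 1, 0.005)
  ct <- tibble::tibble(time_s = t, f0_hz = 200 + 40 * t, voiced = TRUE)
  trk <- track_f0(synthesize_audio(ct, seed = 2), 20000)
  gen <- approx(ct$time_s, ct$f0_hz, xout = trk$time_s)$y
  err <- hz_to_cents(trk$f0_hz, gen)
  inner <- seq_along(err) > 2 & seq_along(err) < length(err) - 1
  expect_true(all(abs(err[inner]) < 3))
})

test_that("a 200-cent step is localized within one hop", {
  t <- seq(0, 1, 0.005)
  f0 <- ifelse(t < 0.5, 200, 200 * 2^(200 / 1200))
  ct <- tibble::tibble(time_s = t, f0_hz = f0, voiced = TRUE)
  trk <- track_f0(synthesize_audio(ct, seed = 3), 20000)
  crossed <- trk$time_s[which(trk$f0_hz > 200 * 2^(100 / 1200))[1]]
  expect_lte(abs(crossed - 0.5), 0.005 + 1e-9)
})

test_that("estimates never leave the search range", {
  withr::with_seed(11, {
    w <- rnorm(30000, 0, 0.3) # rough noise can trigger spurious voicing
    trk <- track_f0(w, 20000, f0_min = 75, f0_max = 500)
    est <- trk$f0_hz[trk$voiced]
    if (length(est) > 0) {
      expect_true(all(est >= 75 & est <= 500))
    }
    succeed()
  })
})

test_that("halving the hop leaves constant-tone estimates within a cent", {
  w <- synthesize_audio(const_contour(220), seed = 4)
  t5 <- track_f0(w, 20000, hop_ms = 5)
  t25 <- track_f0(w, 20000, hop_ms = 2.5)
  joined <- dplyr::inner_join(t5, t25, by = "time_s")
  expect_gt(nrow(joined), 100)
  expect_true(all(abs(hz_to_cents(joined$f0_hz.x, joined$f0_hz.y)) < 1))
})

test_that("synthesis round-trip recovers random smooth contours within 3 cents RMS", {
  withr::with_seed(21, {
    for (r in 1:4) {
      t <- seq(0, 1.2, 0.005)
      n <- length(t)
      base <- runif(1, 120, 260)
      cents <- runif(1, -30, 0) * (t - 0.6)
      for (k in seq_len(sample(1:3, 1))) {
        pk <- runif(1, 0.2, 1.0)
        u <- (t - pk) / 0.15
        cents <- cents + ifelse(abs(u) < 1, runif(1, -80, 80) * 0.5 * (1 + cos(pi * u)), 0)
      }
      rho <- exp(-5 / 150) # wander no faster than the analysis window
      j <- as.numeric(stats::filter(rnorm(n, 0, 15 * sqrt(1 - rho^2)), rho,
                                    "recursive", init = rnorm(1, 0, 15)))
      ct <- tibble::tibble(time_s = t, f0_hz = base * 2^((cents + j) / 1200),
                           voiced = TRUE)
      trk <- track_f0(synthesize_audio(ct, seed = r), 20000)
      cmp <- dplyr::inner_join(trk, ct, by = "time_s", suffix = c(".est", ".gen"))
      cmp <- cmp[cmp$voiced.est, ]
      err <- hz_to_cents(cmp$f0_hz.est, cmp$f0_hz.gen)
      expect_lt(sqrt(mean(err^2)), 3)
    }
  })
})

test_that("unvoiced regions of synthesized audio are silent", {
  ct <- const_contour(220)
  ct$voiced[ct$time_s >= 0.4 & ct$time_s < 0.6] <- FALSE
  ct$f0_hz[!ct$voiced] <- NA
  w <- synthesize_audio(ct, seed = 5, noise_db = -Inf)
  t <- (seq_along(w) - 1) / 20000
  expect_true(all(w[t >= 0.42 & t <= 0.58] == 0))
  expect_gt(sqrt(mean(w[t < 0.35]^2)), 0.05)
})

test_that("tracker and synthesizer reject invalid input", {
  expect_error(track_f0(rnorm(100), 20000), "shorter")
  expect_error(track_f0(rnorm(5000), 20000, f0_min = 500, f0_max = 400), "below")
  expect_error(track_f0(rnorm(5000), 1500, f0_max = 500), "4 \\* f0_max")
  bad <- tibble::tibble(time_s = c(0, 0.005), f0_hz = c(-10, 100),
                        voiced = c(TRUE, TRUE))
  expect_error(synthesize_audio(bad), "positive")
  expect_error(synthesize_audio(const_contour(400), fs = 700), "twice")
})

test_that("gap interpolation fills short gaps linearly and leaves long ones", {
  t <- seq(0, 0.5, 0.005)
  ct <- tibble::tibble(time_s = t, f0_hz = 200 + 4 * t, voiced = TRUE)
  gap <- t > 0.2 & t < 0.245 # 40-ms gap
  ct$voiced[gap] <- FALSE
  ct$f0_hz[gap] <- NA
  out <- interpolate_unvoiced(ct, max_gap_ms = 100)
  mid <- out$f0_hz[abs(out$time_s - 0.2225) < 0.0026][1]
  lo <- 200 + 4 * 0.2
  hi <- 200 + 4 * 0.245
  expect_equal(mid, (lo + hi) / 2, tolerance = 0.01)
  expect_true(all(out$filled[gap]))
  expect_equal(out$voiced, ct$voiced) # voicing flags untouched
  # long gap stays missing
  out2 <- interpolate_unvoiced(ct, max_gap_ms = 20)
  expect_true(all(is.na(out2$f0_hz[gap])))
  # identity on all-voiced contours
  full <- tibble::tibble(time_s = t, f0_hz = 200, voiced = TRUE)
  out3 <- interpolate_unvoiced(full)
  expect_equal(out3$f0_hz, full$f0_hz)
  expect_false(any(out3$filled))
})

test_that("WAV files round-trip through write and read", {
  w <- synthesize_audio(const_contour(220, dur = 0.3), seed = 6)
  path <- withr::local_tempfile(fileext = ".wav")
  write_wav(w, path, fs = 20000)
  back <- read_wav(path)
  expect_equal(back$fs, 20000)
  expect_equal(length(back$wave), length(w))
  expect_lt(max(abs(back$wave - w)), 1 / 32000) # quantization only
})
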