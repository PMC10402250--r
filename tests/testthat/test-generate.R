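trial_row <- function(task = "vowel", trial_id = "t1", focus = NA_character_,
                      duration_s = 3) {
  tibble::tibble(trial_id = trial_id, block = 1L, task = task, focus = focus,
                 duration_s = duration_s)
}

event_row <- function(onset_s, cents, trial_id = "t1", event_id = 1L) {
  tibble::tibble(trial_id = trial_id, event_id = event_id, onset_s = onset_s,
                 cents = cents, duration_ms = 200)
}

test_that("a noise-free opposing response dips by exactly its magnitude", {
  sub <- subject_model(
    "control", f0_jitter_cents_sd = 0,
    response_magnitude_mean = tibble::tibble(task = "vowel", focus = NA, mean_cents = 80),
    response_magnitude_sdlog = 0,
    response_peak_latency_mean_ms = c(opposing = 180, following = 180),
    response_peak_latency_sd_ms = 0,
    p_opposing = 1
  )
  g <- generate_trial_f0(trial_row(), event_row(1.0, 200), sub, seed = 1)
  peak_t <- 1.0 + 0.180
  f0_at <- g$contour$f0_hz[abs(g$contour$time_s - peak_t) < 1e-9]
  expect_equal(hz_to_cents(f0_at, sub$baseline_f0_hz), -80, tolerance = 1e-9)
  expect_equal(g$truth$true_resp_dir, "opposing")
  expect_equal(g$truth$true_magnitude_cents, 80)
  # outside the pulse support the contour is flat at baseline
  before <- g$contour$f0_hz[g$contour$time_s < 1.08]
  expect_equal(before, rep(sub$baseline_f0_hz, length(before)))
})

test_that("control events spawn no response pulse", {
  sub <- subject_model("control", f0_jitter_cents_sd = 0)
  g <- generate_trial_f0(trial_row(), event_row(1.0, 0), sub, seed = 2)
  expect_equal(g$contour$f0_hz, rep(sub$baseline_f0_hz, nrow(g$contour)))
  expect_true(is.na(g$truth$true_resp_dir))
})

test_that("opposing fraction converges to p_opposing over many pulses", {
  sub <- subject_model("control", f0_jitter_cents_sd = 0, p_opposing = 0.512)
  ev <- tibble::tibble(trial_id = "t1", event_id = seq_len(10000),
                       onset_s = 1.0, cents = 200, duration_ms = 200)
  g <- generate_trial_f0(trial_row(), ev, sub, seed = 3)
  frac <- mean(g$truth$true_resp_dir == "opposing")
  expect_equal(frac, 0.512, tolerance = 0.01 / 0.512) # +/- 0.01 absolute
})

test_that("sentence contours carry the focus-dependent intonation and gaps", {
  sub <- subject_model("control", f0_jitter_cents_sd = 0,
                       intonation = intonation_model(duration_sdlog = 0))
  tr <- trial_row("sentence", focus = "corrective", duration_s = NA)
  g <- generate_trial_f0(tr, event_row(0.05, 0), sub, seed = 4)
  al <- g$alignment
  expect_equal(al$word[1], "not")
  # voicing breaks: end of "not", start of "by"
  expect_true(all(!g$contour$voiced[g$contour$time_s >= 0.21 &
                                      g$contour$time_s < 0.25]))
  by_start <- al$start_s[al$word == "by"]
  expect_true(all(!g$contour$voiced[g$contour$time_s >= by_start &
                                      g$contour$time_s < by_start + 0.04]))
  # stressed-word mean equals accent height plus local declination
  obj <- al[al$is_stressed, ]
  inw <- g$contour$time_s >= obj$start_s & g$contour$time_s < obj$end_s
  cents <- hz_to_cents(g$contour$f0_hz[inw], sub$baseline_f0_hz)
  decl <- sub$intonation$declination_cents_per_s *
    (g$contour$time_s[inw] - max(al$end_s) / 2)
  expect_equal(mean(cents - decl), 51.07, tolerance = 1e-6)
  g2 <- generate_trial_f0(dplyr::mutate(tr, focus = "new"), event_row(0.05, 0),
                          sub, seed = 4)
  expect_equal(g2$alignment$word[1], "lay")
})

test_that("sessions are reproducible and pathology rates match the target", {
  man <- design_session(session_config("vowel", n_blocks = 1, trials_per_block = 30),
                        seed = 7)
  sub <- subject_model("ataxia")
  s1 <- generate_session(man, sub, seed = 9)
  s2 <- generate_session(man, sub, seed = 9)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$trials$contour, s2$trials$contour)
  # pathology rate across many trials
  big <- design_session(session_config("vowel", n_blocks = 4, trials_per_block = 45),
                        seed = 8)
  sb <- generate_session(big, sub, seed = 10)
  path <- sb$ground_truth %>% dplyr::distinct(trial_id, pathology)
  frac <- mean(path$pathology != "none")
  expect_lt(abs(frac - 0.25), 3 * sqrt(0.25 * 0.75 / nrow(path)))
  expect_gte(mean(path$pathology == "none"), 0.6)
})

test_that("cohorts have the requested structure and determinism", {
  coh <- small_cohort()
  expect_equal(nrow(coh$participants), 6)
  expect_equal(sort(unique(coh$trials$task)), c("sentence", "vowel"))
  expect_equal(nrow(coh$trials), 6 * (18 + 72))
  # per-subject trial counts
  cnt <- coh$trials %>% dplyr::count(participant)
  expect_true(all(cnt$n == 90))
  coh2 <- generate_cohort(
    n_ataxia = 3, n_control = 3,
    vowel_config = session_config("vowel", n_blocks = 1, trials_per_block = 18),
    sentence_config = session_config("sentence", n_blocks = 2, trials_per_block = 36,
                                     min_trials_per_condition = 10),
    seed = 101
  )
  expect_identical(coh$ground_truth, coh2$ground_truth)
})

test_that("simulate_measures reflects its generative cell means", {
  m <- simulate_measures(n_ataxia = 40, n_control = 40, n_trials_per_cell = 60,
                         subject_magnitude_sdlog = 0.02,
                         subject_latency_sd_ms = 2, seed = 5)
  cellmeans <- m %>%
    dplyr::group_by(group, task, focus) %>%
    dplyr::summarise(mean = mean(magnitude_cents), .groups = "drop") %>%
    dplyr::left_join(psr_default_effects()$magnitude,
                     by = c("group", "task", "focus"))
  expect_true(all(abs(cellmeans$mean - cellmeans$mean_cents) /
                    cellmeans$mean_cents < 0.05))
  opp <- m %>%
    dplyr::group_by(resp_dir) %>%
    dplyr::summarise(n = sum(n_trials), lat = mean(latency_ms))
  expect_equal(sum(opp$n[opp$resp_dir == "opposing"]) / sum(opp$n), 0.512,
               tolerance = 0.05)
  expect_gt(opp$lat[opp$resp_dir == "opposing"],
            opp$lat[opp$resp_dir == "following"])
})
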