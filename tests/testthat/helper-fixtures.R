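# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# small reduced-trials cohort with default noise/pathology levels
small_cohort <- function() {
  cached("small_cohort", generate_cohort(
    n_ataxia = 3, n_control = 3,
    vowel_config = session_config("vowel", n_blocks = 1, trials_per_block = 18),
    sentence_config = session_config("sentence", n_blocks = 2, trials_per_block = 36,
                                     min_trials_per_condition = 10),
    seed = 101
  ))
}

small_results <- function() {
  cached("small_results", measure_cohort(small_cohort()))
}

# fully deterministic cohort: no jitter, no latency/magnitude/duration
# scatter, no pathologies
noisefree_cohort <- function() {
  cached("noisefree_cohort", generate_cohort(
    n_ataxia = 1, n_control = 1,
    vowel_config = session_config("vowel", n_blocks = 1, trials_per_block = 12),
    sentence_config = session_config("sentence", n_blocks = 1, trials_per_block = 36,
                                     min_trials_per_condition = 5),
    seed = 202,
    p_pathology = 0,
    subject_magnitude_sdlog = 0,
    subject_latency_sd_ms = 0,
    f0_jitter_cents_sd = 0,
    response_magnitude_sdlog = 0,
    response_peak_latency_sd_ms = 0,
    intonation = intonation_model(duration_sdlog = 0)
  ))
}

# 10+10-subject cohort at reduced trial counts, default noise and pathology
recovery_cohort <- function() {
  cached("recovery_cohort", generate_cohort(
    n_ataxia = 10, n_control = 10,
    vowel_config = session_config("vowel", n_blocks = 1, trials_per_block = 24),
    sentence_config = session_config("sentence", n_blocks = 2, trials_per_block = 36,
                                     min_trials_per_condition = 10),
    seed = 404
  ))
}

# synthetic epoch on the standard grid from a vector of cents
make_epoch <- function(cents, trial_id = "t1", event_id = 1L, pert_cents = 200,
                       task = "vowel", focus = NA_character_,
                       participant = "P01", rel_ms = seq(-50, 400, by = 5)) {
  stopifnot(length(cents) == length(rel_ms))
  out <- tibble::tibble(
    participant = participant, trial_id = trial_id, event_id = event_id,
    task = task, focus = focus, pert_cents = pert_cents,
    baseline_hz = 200, rel_ms = rel_ms, cents = cents
  )
  class(out) <- c("psr_epochs", class(tibble::tibble()))
  out
}

# analytic raised-cosine pulse on a rel-time grid (ms)
pulse_on_grid <- function(rel_ms, peak_ms, amp, width_ms = 200) {
  u <- (rel_ms - peak_ms) / (width_ms / 2)
  ifelse(abs(u) < 1, amp * 0.5 * (1 + cos(pi * u)), 0)
}
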