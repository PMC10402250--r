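#' Session configuration for a perturbation task
#'
#' Describes one recording session of the auditory feedback perturbation
#' paradigm. Two tasks are supported: a sustained vowel (repeated 3-s /a/
#' vocalizations, two mid-vocalization feedback shifts each) and a
#' sentence-production task (carrier phrase "Lay/not your OBJECT by your
#' LOCATION" with new-information vs corrective semantic focus, one shift
#' shortly after voice onset). Feedback shifts are +200, -200 or 0 cents
#' (controls) and last 200 ms.
#'
#' Defaults reproduce the standard design: vowel task 2 blocks x 45 trials
#' (90 vocalizations, two shifts each, 700-900 ms inter-stimulus intervals);
#' sentence task 5 blocks x 50 trials (250 phrases, shift 50 ms after voice
#' onset, at least 30 trials per shift condition per focus).
#'
#' @param task `"vowel"` or `"sentence"`
#' @param n_blocks number of blocks
#' @param trials_per_block trials per block
#' @param vowel_duration_s vocalization length for vowel trials (s)
#' @param perturbations_per_vowel_trial shifts per vowel trial
#' @param isi_range_ms onset-to-onset interval range between the shifts of a
#'   vowel trial, `c(low, high)` in ms
#' @param pert_magnitude_cents set of signed shift magnitudes (cents);
#'   0 denotes control events
#' @param pert_duration_ms shift duration (ms)
#' @param sentence_pert_onset_ms shift onset after voice onset, sentence task (ms)
#' @param min_trials_per_condition required trials per shift condition
#'   (per focus for the sentence task)
#' @param device_delay_ms feedback-loop hardware delay, stored as metadata (ms)
#' @param hop_ms contour frame hop (ms)
#' @return a `psr_session_config` list
#' @export
session_config <- function(task = c("vowel", "sentence"),
                           n_blocks = NULL,
                           trials_per_block = NULL,
                           vowel_duration_s = 3,
                           perturbations_per_vowel_trial = 2,
                           isi_range_ms = c(700, 900),
                           pert_magnitude_cents = c(200, -200, 0),
                           pert_duration_ms = 200,
                           sentence_pert_onset_ms = 50,
                           min_trials_per_condition = 30,
                           device_delay_ms = 12,
                           hop_ms = 5) {
  task <- match.arg(task)
  if (is.null(n_blocks)) n_blocks <- if (task == "vowel") 2L else 5L
  if (is.null(trials_per_block)) trials_per_block <- if (task == "vowel") 45L else 50L
  assert_scalar_number(n_blocks, "n_blocks", positive = TRUE)
  assert_scalar_number(trials_per_block, "trials_per_block", positive = TRUE)
  assert_scalar_number(vowel_duration_s, "vowel_duration_s", positive = TRUE)
  assert_scalar_number(pert_duration_ms, "pert_duration_ms", positive = TRUE)
  assert_scalar_number(hop_ms, "hop_ms", positive = TRUE)
  if (length(isi_range_ms) != 2L || isi_range_ms[1] > isi_range_ms[2] ||
      any(isi_range_ms <= 0)) {
    abort("`isi_range_ms` must be c(low, high) with 0 < low <= high.")
  }
  if (!0 %in% pert_magnitude_cents) {
    abort("`pert_magnitude_cents` must include 0 (control events).")
  }
  structure(
    list(
      task = task,
      n_blocks = as.integer(n_blocks),
      trials_per_block = as.integer(trials_per_block),
      vowel_duration_s = vowel_duration_s,
      perturbations_per_vowel_trial = as.integer(perturbations_per_vowel_trial),
      isi_range_ms = as.numeric(isi_range_ms),
      pert_magnitude_cents = as.numeric(pert_magnitude_cents),
      pert_duration_ms = pert_duration_ms,
      sentence_pert_onset_ms = sentence_pert_onset_ms,
      min_trials_per_condition = as.integer(min_trials_per_condition),
      device_delay_ms = device_delay_ms,
      hop_ms = hop_ms
    ),
    class = "psr_session_config"
  )
}

#' Default generative cell means for the pitch-shift response
#'
#' Mean absolute response magnitudes (cents) per group x task x focus cell and
#' peak-latency means (ms) per response direction used as generator defaults.
#' The magnitude cells follow the group/task/focus structure typical of
#' published perturbation studies in ataxic and healthy speakers: larger
#' responses in sentence production than sustained vowels, larger for
#' corrective than new-information focus, larger in the ataxia group;
#' latencies differ by response direction (following faster than opposing)
#' but not by group.
#'
#' @return a list with elements `magnitude` (tibble: group, task, focus,
#'   mean_cents), `latency` (tibble: resp_dir, mean_ms) and `p_opposing`
#' @export
psr_default_effects <- function() {
  list(
    magnitude = tibble(
      group = c("control", "ataxia", "control", "ataxia", "control", "ataxia"),
      task = c("vowel", "vowel", "sentence", "sentence", "sentence", "sentence"),
      focus = c(NA, NA, "new", "new", "corrective", "corrective"),
      mean_cents = c(34.69, 42.70, 93.12, 115.89, 129.89, 146.98)
    ),
    latency = tibble(
      resp_dir = c("opposing", "following"),
      mean_ms = c(229.37, 195.18)
    ),
    p_opposing = 0.512
  )
}

#' Intonation model for synthetic sentence production
#'
#' Generative description of the phrasal intonation of the carrier phrase
#' "Lay/not your OBJECT by your LOCATION". The stressed OBJECT word carries a
#' pitch-accent plateau whose height, intensity level and vowel duration
#' depend on semantic focus (corrective focus is marked more strongly in f0
#' and intensity but with a *shorter* stressed vowel). A linear declination
#' spans the phrase; voicing breaks of fixed length occur at the /t/ of "not"
#' and the /b/ of "by".
#'
#' @param declination_cents_per_s linear f0 declination slope (cents/s)
#' @param accent_height_cents named vector, pitch-accent height on the stressed
#'   word per focus (cents re speaker baseline)
#' @param accent_intensity_db named vector, intensity level on the stressed
#'   word per focus (dB)
#' @param stressed_vowel_duration_ms named vector, stressed-vowel duration per
#'   focus (ms)
#' @param duration_sdlog trial-level lognormal sdlog of the stressed-vowel
#'   duration (0 for fully deterministic timing)
#' @param base_intensity_db intensity level outside the stressed word (dB)
#' @param gap_ms length of the /t/ and /b/ voicing breaks (ms)
#' @param accent_ramp_ms rise/fall time of the accent plateau, placed just
#'   outside the word so the within-word mean equals the plateau height (ms)
#' @return a `psr_intonation_model` list
#' @export
intonation_model <- function(declination_cents_per_s = -20,
                             accent_height_cents = c(new = 38.65, corrective = 51.07),
                             accent_intensity_db = c(new = 65.31, corrective = 65.79),
                             stressed_vowel_duration_ms = c(new = 248.15, corrective = 235.84),
                             duration_sdlog = 0.05,
                             base_intensity_db = 63,
                             gap_ms = 40,
                             accent_ramp_ms = 30) {
  for (v in list(accent_height_cents, accent_intensity_db, stressed_vowel_duration_ms)) {
    if (!all(c("new", "corrective") %in% names(v))) {
      abort("Focus-dependent parameters need named entries 'new' and 'corrective'.")
    }
  }
  if (any(stressed_vowel_duration_ms <= 0)) abort("Durations must be > 0.")
  structure(
    list(
      declination_cents_per_s = declination_cents_per_s,
      accent_height_cents = accent_height_cents,
      accent_intensity_db = accent_intensity_db,
      stressed_vowel_duration_ms = stressed_vowel_duration_ms,
      duration_sdlog = duration_sdlog,
      base_intensity_db = base_intensity_db,
      gap_ms = gap_ms,
      accent_ramp_ms = accent_ramp_ms
    ),
    class = "psr_intonation_model"
  )
}

#' Generative model of one speaker
#'
#' Bundles everything the trial generator needs to emulate one participant:
#' habitual f0, slow f0 wander, the distribution of reflexive pitch-shift
#' responses (magnitude per task/focus cell, peak latency per response
#' direction, probability of opposing the shift) and the intonation model.
#' Magnitudes are drawn trial-by-trial from a mean-parameterised lognormal;
#' latencies from a normal truncated to the physiologically plausible range.
#'
#' @param group `"ataxia"` or `"control"`
#' @param baseline_f0_hz habitual fundamental frequency (Hz)
#' @param f0_jitter_cents_sd stationary sd of the slow f0 wander (cents)
#' @param jitter_tau_ms correlation time of the f0 wander (ms)
#' @param response_magnitude_mean tibble with columns task, focus, mean_cents
#'   (focus `NA` for the vowel task); defaults to the group's cells from
#'   [psr_default_effects()]
#' @param response_magnitude_sdlog trial-level lognormal sdlog of magnitude
#' @param response_peak_latency_mean_ms named vector per response direction (ms)
#' @param response_peak_latency_sd_ms trial-level latency sd (ms); kept small
#'   because latency scatter smears the averaged peak
#' @param response_width_ms full support width of the raised-cosine response pulse (ms)
#' @param p_opposing probability that a response opposes the shift direction
#' @param intonation an [intonation_model()]
#' @return a `psr_subject_model` list
#' @export
subject_model <- function(group = c("control", "ataxia"),
                          baseline_f0_hz = 200,
                          f0_jitter_cents_sd = 20,
                          jitter_tau_ms = 50,
                          response_magnitude_mean = NULL,
                          response_magnitude_sdlog = 0.35,
                          response_peak_latency_mean_ms = NULL,
                          response_peak_latency_sd_ms = 10,
                          response_width_ms = 200,
                          p_opposing = 0.512,
                          intonation = intonation_model()) {
  group <- match.arg(group)
  if (p_opposing < 0 || p_opposing > 1) abort("`p_opposing` must be in [0, 1].")
  assert_scalar_number(baseline_f0_hz, "baseline_f0_hz", positive = TRUE)
  if (is.null(response_magnitude_mean)) {
    response_magnitude_mean <- psr_default_effects()$magnitude %>%
      filter(.data$group == !!group) %>%
      select("task", "focus", "mean_cents")
  }
  if (any(response_magnitude_mean$mean_cents < 0)) {
    abort("Response magnitudes must be >= 0.")
  }
  if (is.null(response_peak_latency_mean_ms)) {
    lat <- psr_default_effects()$latency
    response_peak_latency_mean_ms <- setNames(lat$mean_ms, lat$resp_dir)
  }
  if (any(response_peak_latency_mean_ms <= 60) ||
      any(response_peak_latency_mean_ms >= 300)) {
    abort("Latency means must lie within (60, 300) ms.")
  }
  structure(
    list(
      group = group,
      baseline_f0_hz = baseline_f0_hz,
      f0_jitter_cents_sd = f0_jitter_cents_sd,
      jitter_tau_ms = jitter_tau_ms,
      response_magnitude_mean = response_magnitude_mean,
      response_magnitude_sdlog = response_magnitude_sdlog,
      response_peak_latency_mean_ms = response_peak_latency_mean_ms,
      response_peak_latency_sd_ms = response_peak_latency_sd_ms,
      response_width_ms = response_width_ms,
      p_opposing = p_opposing,
      intonation = intonation
    ),
    class = "psr_subject_model"
  )
}

# look up a subject's mean magnitude for a task/focus cell
subject_cell_magnitude <- function(subject, task, focus) {
  tab <- subject$response_magnitude_mean
  row <- if (task == "vowel") {
    tab[tab$task == "vowel", ]
  } else {
    tab[tab$task == "sentence" & !is.na(tab$focus) & tab$focus == focus, ]
  }
  if (nrow(row) == 0L) {
    abort(sprintf("No magnitude mean defined for task '%s', focus '%s'.", task, focus))
  }
  row$mean_cents[1]
}
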