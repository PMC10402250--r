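#' Stressed-word prosody for one trial
#'
#' Means of f0 (cents relative to a participant reference, conventionally
#' the session-median f0) and intensity over the stressed word, plus the
#' stressed-vowel duration from the alignment. Used on control (0-cent)
#' sentence trials to verify that the elicitation produced the intended
#' prosodic marking of semantic focus.
#'
#' @param contour tibble `time_s`, `f0_hz`, `voiced` (+ `intensity_db`)
#' @param alignment word alignment as from [sentence_alignment()]
#' @param ref_f0_hz participant reference f0 (Hz)
#' @return one-row tibble: mean_f0_cents, mean_intensity_db, vowel_duration_ms
#' @export
measure_stressed_word <- function(contour, alignment, ref_f0_hz) {
  if (is.null(alignment) || !any(alignment$is_stressed)) {
    abort("Alignment with a stressed word is required.")
  }
  assert_scalar_number(ref_f0_hz, "ref_f0_hz", positive = TRUE)
  obj <- alignment[alignment$is_stressed, ][1, ]
  inw <- contour$time_s >= obj$start_s & contour$time_s < obj$end_s
  f0 <- contour$f0_hz[inw & contour$voiced]
  f0 <- f0[!is.na(f0)]
  if (length(f0) == 0L) abort("No voiced frames inside the stressed word.")
  ints <- if ("intensity_db" %in% names(contour)) {
    mean(contour$intensity_db[inw], na.rm = TRUE)
  } else {
    NA_real_
  }
  tibble(
    mean_f0_cents = mean(hz_to_cents(f0, ref_f0_hz)),
    mean_intensity_db = ints,
    vowel_duration_ms = (obj$vowel_end_s - obj$vowel_start_s) * 1000
  )
}

#' Stressed-word prosody across a cohort's control trials
#'
#' Applies [measure_stressed_word()] to every control (0-cent) sentence
#' trial, referencing each participant's f0 to their session-median f0.
#'
#' @param cohort a `psr_cohort` (or `psr_session` with participant columns)
#' @return tidy tibble: participant, group, trial_id, focus, mean_f0_cents,
#'   mean_intensity_db, vowel_duration_ms
#' @export
prosody_measures <- function(cohort) {
  trials <- cohort$trials %>% filter(.data$task == "sentence")
  if (nrow(trials) == 0L) abort("No sentence trials in the cohort.")
  ctrl_ids <- cohort$events %>%
    group_by(.data$trial_id) %>%
    summarise(all_control = all(.data$cents == 0), .groups = "drop") %>%
    filter(.data$all_control) %>%
    pull("trial_id")
  trials <- trials %>% filter(.data$trial_id %in% ctrl_ids)
  if (nrow(trials) == 0L) abort("No control sentence trials found.")

  ref <- trials %>%
    group_by(.data$participant) %>%
    summarise(
      ref_f0_hz = median(unlist(purrr::map(.data$contour, ~ .x$f0_hz)), na.rm = TRUE),
      .groups = "drop"
    )
  trials %>%
    left_join(ref, by = "participant") %>%
    (\(df) purrr::map_dfr(seq_len(nrow(df)), function(i) {
      m <- measure_stressed_word(df$contour[[i]], df$alignment[[i]], df$ref_f0_hz[i])
      tibble(
        participant = df$participant[i], group = df$group[i],
        trial_id = df$trial_id[i], focus = df$focus[i]
      ) %>% dplyr::bind_cols(m)
    }))()
}
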