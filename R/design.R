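#' Design a perturbation session
#'
#' Builds the trial schedule for one session: block/trial structure, semantic
#' focus assignment (sentence task), and the pseudo-randomized perturbation
#' events. Magnitudes (+200, -200, 0 cents by default) are balanced across
#' events and shuffled; for the sentence task balancing is within focus x
#' magnitude cells so each cell meets `min_trials_per_condition`. Vowel trials
#' receive `perturbations_per_vowel_trial` events whose onset-to-onset
#' intervals are drawn uniformly from `isi_range_ms`; sentence trials receive
#' a single event at `sentence_pert_onset_ms` after voice onset. All onsets
#' are snapped to the contour frame grid (`hop_ms`).
#'
#' @param config a [session_config()]
#' @param seed integer seed; the design is deterministic given the seed
#' @return a `psr_manifest`: list with `config` and tibbles `trials`
#'   (trial_id, block, task, focus, duration_s) and `events`
#'   (trial_id, event_id, onset_s, cents, duration_ms)
#' @examples
#' man <- design_session(session_config("vowel"), seed = 1)
#' nrow(man$trials) # 90
#' @export
design_session <- function(config, seed = 1L) {
  stopifnot(inherits(config, "psr_session_config"))
  n_trials <- config$n_blocks * config$trials_per_block
  hop_s <- config$hop_ms / 1000
  snap <- function(x_s) round(x_s / hop_s) * hop_s

  with_seed(derive_seed(seed, 1L), {
    if (config$task == "vowel") {
      # feasibility: last event + duration + response tail must fit in trial
      first_lo <- 0.4
      first_hi <- 0.7
      max_end <- first_hi + (config$perturbations_per_vowel_trial - 1) *
        config$isi_range_ms[2] / 1000 + (config$pert_duration_ms + 450) / 1000
      if (max_end > config$vowel_duration_s) {
        abort(sprintf(
          "Cannot fit %d perturbations (+ response window) inside a %.2f-s vowel trial.",
          config$perturbations_per_vowel_trial, config$vowel_duration_s
        ))
      }
      trials <- tibble(
        trial_id = sprintf("v%03d", seq_len(n_trials)),
        block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
        task = "vowel",
        focus = NA_character_,
        duration_s = config$vowel_duration_s
      )
      n_events <- n_trials * config$perturbations_per_vowel_trial
      mags <- sample(rep(config$pert_magnitude_cents, length.out = n_events))
      onset1 <- snap(runif(n_trials, first_lo, first_hi))
      events <- purrr::map_dfr(seq_len(n_trials), function(i) {
        k <- config$perturbations_per_vowel_trial
        isis <- runif(max(k - 1, 0), config$isi_range_ms[1], config$isi_range_ms[2]) / 1000
        onsets <- snap(onset1[i] + cumsum(c(0, isis)))
        tibble(
          trial_id = trials$trial_id[i],
          event_id = seq_len(k),
          onset_s = onsets,
          cents = mags[(i - 1) * k + seq_len(k)],
          duration_ms = config$pert_duration_ms
        )
      })
    } else {
      cells <- tidyr::expand_grid(
        focus = c("new", "corrective"),
        cents = config$pert_magnitude_cents
      )
      reps <- ceiling(n_trials / nrow(cells))
      plan <- cells[rep(seq_len(nrow(cells)), reps)[seq_len(n_trials)], ]
      counts <- plan %>% count(.data$focus, .data$cents)
      if (any(counts$n < config$min_trials_per_condition)) {
        abort(sprintf(
          "Design yields fewer than %d trials per perturbation condition per focus.",
          config$min_trials_per_condition
        ))
      }
      plan <- plan[sample.int(n_trials), ]
      trials <- tibble(
        trial_id = sprintf("s%03d", seq_len(n_trials)),
        block = rep(seq_len(config$n_blocks), each = config$trials_per_block),
        task = "sentence",
        focus = plan$focus,
        duration_s = NA_real_ # set at generation (depends on focus durations)
      )
      events <- tibble(
        trial_id = trials$trial_id,
        event_id = 1L,
        onset_s = snap(config$sentence_pert_onset_ms / 1000),
        cents = plan$cents,
        duration_ms = config$pert_duration_ms
      )
    }
    structure(
      list(config = config, trials = trials, events = events, seed = as.integer(seed)),
      class = "psr_manifest"
    )
  })
}

#' @method print psr_manifest
#' @export
print.psr_manifest <- function(x, ...) {
  cat(sprintf(
    "<psr_manifest> %s task: %d trials, %d perturbation events (%d control)\n",
    x$config$task, nrow(x$trials), nrow(x$events), sum(x$events$cents == 0)
  ))
  invisible(x)
}
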