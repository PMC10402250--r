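#' Build per-participant intonation templates
#'
#' Averages each participant's control (0-cent) epochs within a focus
#' condition into an intonation template: the pitch movement the speaker
#' produces at this point of the phrase in the absence of a perturbation.
#' Missing frames are ignored pointwise.
#'
#' @param epochs a `psr_epochs` tibble (sentence task)
#' @param min_control minimum control epochs per participant x focus cell
#' @return tibble: participant, focus, rel_ms, mean_cents, n_control
#' @export
build_templates <- function(epochs, min_control = 5) {
  ctrl <- epochs %>% filter(.data$pert_cents == 0, .data$task == "sentence")
  if (nrow(ctrl) == 0L) abort("No sentence control epochs to build templates from.")
  counts <- ctrl %>%
    distinct(.data$participant, .data$focus, .data$trial_id, .data$event_id) %>%
    count(.data$participant, .data$focus)
  short <- counts %>% filter(.data$n < min_control)
  if (nrow(short) > 0L) {
    abort(sprintf(
      "Too few control epochs (< %d) for: %s.", min_control,
      paste(sprintf("%s/%s (n=%d)", short$participant, short$focus, short$n),
            collapse = ", ")
    ))
  }
  ctrl %>%
    group_by(.data$participant, .data$focus, .data$rel_ms) %>%
    summarise(
      mean_cents = mean(.data$cents, na.rm = TRUE),
      n_control = n_distinct(.data$trial_id, .data$event_id),
      .groups = "drop"
    )
}

#' Subtract intonation templates (difference-wave analysis)
#'
#' Removes the phrasal intonation from each perturbed sentence epoch by
#' subtracting the participant's focus-matched average control contour
#' pointwise; without this step, pitch movement due to intonation is
#' indistinguishable from the perturbation-driven response. The resulting
#' difference waves are re-centered so the baseline-window mean is zero.
#' Vowel-task epochs pass through unchanged (their baseline centering
#' already removes the flat reference).
#'
#' @param epochs a `psr_epochs` tibble
#' @param templates output of [build_templates()]; built internally if `NULL`
#' @param min_control passed to [build_templates()]
#' @param pre_ms baseline extent for re-centering (ms)
#' @return `psr_epochs` tibble with sentence epochs replaced by difference
#'   waves (control sentence epochs are dropped: they define the templates)
#' @export
subtract_templates <- function(epochs, templates = NULL, min_control = 5,
                               pre_ms = 50) {
  sent <- epochs %>% filter(.data$task == "sentence")
  vowel <- epochs %>% filter(.data$task != "sentence")
  if (nrow(sent) == 0L) return(epochs)
  if (is.null(templates)) {
    templates <- build_templates(sent, min_control = min_control)
  }
  pert <- sent %>% filter(.data$pert_cents != 0)
  missing_tpl <- pert %>%
    distinct(.data$participant, .data$focus) %>%
    anti_join(templates %>% distinct(.data$participant, .data$focus),
              by = c("participant", "focus"))
  if (nrow(missing_tpl) > 0L) {
    abort(sprintf(
      "No intonation template for: %s.",
      paste(sprintf("%s/%s", missing_tpl$participant, missing_tpl$focus),
            collapse = ", ")
    ))
  }
  grid_ok <- pert %>%
    left_join(templates, by = c("participant", "focus", "rel_ms"))
  if (any(is.na(grid_ok$mean_cents) & !is.na(grid_ok$cents))) {
    abort("Epoch and template frame grids do not match.")
  }
  diff <- grid_ok %>%
    mutate(cents = .data$cents - .data$mean_cents) %>%
    group_by(.data$trial_id, .data$event_id) %>%
    mutate(cents = .data$cents -
             mean(.data$cents[.data$rel_ms >= -pre_ms & .data$rel_ms < 0],
                  na.rm = TRUE)) %>%
    ungroup() %>%
    select(-"mean_cents", -"n_control")
  out <- bind_rows(vowel, diff)
  class(out) <- c("psr_epochs", class(tibble()))
  out
}
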