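#' Classify the response direction of each perturbed epoch
#'
#' Compares the mean f0 of the 50-ms pre-perturbation window with the mean
#' of the 400-ms post-perturbation window (both on the cent scale of the
#' epoch). The response is *up* when the post-window mean exceeds the
#' pre-window mean; a response whose sign matches the perturbation sign is
#' labelled `following`, one that counters it `opposing`. An exactly zero
#' difference (probability zero under continuous noise, but possible on
#' constructed data) is labelled `none` and excluded from averaging cells.
#'
#' @param epochs a `psr_epochs` tibble; control epochs (pert 0) are not
#'   allowed
#' @param pre_ms,post_ms window extents (ms)
#' @return tibble: one row per epoch with identifiers, `post_minus_pre`
#'   (cents) and `resp_dir` in `{opposing, following, none}`
#' @export
classify_direction <- function(epochs, pre_ms = 50, post_ms = 400) {
  if (any(epochs$pert_cents == 0)) {
    abort("Control epochs (0 cents) have no response direction; remove them first.")
  }
  id_cols <- intersect(
    c("participant", "group", "trial_id", "event_id", "task", "focus", "pert_cents"),
    names(epochs)
  )
  epochs %>%
    group_by(across(dplyr::all_of(id_cols))) %>%
    summarise(
      post_minus_pre =
        mean(.data$cents[.data$rel_ms > 0 & .data$rel_ms <= post_ms], na.rm = TRUE) -
        mean(.data$cents[.data$rel_ms >= -pre_ms & .data$rel_ms < 0], na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      resp_dir = case_when(
        .data$post_minus_pre == 0 ~ "none",
        sign(.data$post_minus_pre) == sign(.data$pert_cents) ~ "following",
        TRUE ~ "opposing"
      )
    )
}

#' Event-related averaging within cells
#'
#' Pointwise averaging of time-locked epochs within each cell — participant
#' x task (x focus) x perturbation direction x response direction — to
#' suppress trial-to-trial noise before peak measurement. Missing frames
#' are ignored per time point; any cell with at least one epoch is averaged.
#'
#' @param epochs a `psr_epochs` tibble (perturbed epochs only)
#' @param directions output of [classify_direction()]; computed internally
#'   when `NULL`. Epochs labelled `none` are dropped.
#' @return `psr_avg` tibble: cell identifiers, `rel_ms`, `mean_cents`,
#'   `n_trials`
#' @export
event_related_average <- function(epochs, directions = NULL) {
  pert <- epochs %>% filter(.data$pert_cents != 0)
  if (nrow(pert) == 0L) abort("No perturbed epochs to average.")
  if (is.null(directions)) directions <- classify_direction(pert)
  dir_key <- intersect(c("trial_id", "event_id"), names(directions))
  pert <- pert %>%
    left_join(directions %>% select(dplyr::all_of(dir_key), "resp_dir"),
              by = dir_key) %>%
    filter(.data$resp_dir %in% c("opposing", "following"))
  cell_cols <- intersect(
    c("participant", "group", "task", "focus", "pert_cents", "resp_dir"),
    names(pert)
  )
  out <- pert %>%
    group_by(across(dplyr::all_of(c(cell_cols, "rel_ms")))) %>%
    summarise(
      mean_cents = mean(.data$cents, na.rm = TRUE),
      n_trials = n_distinct(.data$trial_id, .data$event_id),
      .groups = "drop"
    ) %>%
    group_by(across(dplyr::all_of(cell_cols))) %>%
    mutate(n_trials = max(.data$n_trials)) %>%
    ungroup()
  class(out) <- c("psr_avg", class(tibble()))
  out
}

#' Measure peak magnitude and latency of averaged responses
#'
#' For each averaged cell, searches the post-perturbation window (default
#' the half-open interval (60, 300] ms — the reflex cannot start before
#' ~60 ms and later peaks risk capturing volitional corrections) for the
#' extremum: the maximum for cells classified as upward responses, the
#' minimum for downward. Magnitude is the absolute value at the peak,
#' latency its time point; ties take the earliest frame. Whether a cell is
#' upward follows from its response direction and perturbation sign.
#'
#' @param averages a `psr_avg` tibble from [event_related_average()]
#' @param window search window `c(lo, hi)` in ms, lo exclusive, hi inclusive
#' @return tibble: cell identifiers, `n_trials`, `peak_sign` (`up`/`down`),
#'   `magnitude_cents`, `latency_ms`
#' @export
measure_peaks <- function(averages, window = c(60, 300)) {
  cell_cols <- intersect(
    c("participant", "group", "task", "focus", "pert_cents", "resp_dir"),
    names(averages)
  )
  span <- range(averages$rel_ms)
  if (span[1] > window[1] || span[2] < window[2]) {
    abort("Averaged epochs do not cover the peak-search window.")
  }
  averages %>%
    filter(.data$rel_ms > window[1], .data$rel_ms <= window[2]) %>%
    group_by(across(dplyr::all_of(cell_cols))) %>%
    group_modify(function(df, key) {
      vals <- df$mean_cents
      if (all(is.na(vals))) {
        abort(sprintf("All frames missing in the peak window for a cell (%s).",
                      paste(unlist(key), collapse = "/")))
      }
      up <- if (key$resp_dir == "opposing") key$pert_cents < 0 else key$pert_cents > 0
      target <- if (up) max(vals, na.rm = TRUE) else min(vals, na.rm = TRUE)
      at <- which(vals == target)[1] # earliest frame on ties
      tibble(
        n_trials = df$n_trials[1],
        peak_sign = if (up) "up" else "down",
        magnitude_cents = abs(target),
        latency_ms = df$rel_ms[at]
      )
    }) %>%
    ungroup()
}

#' Potential and realized averaged-response cells
#'
#' Tabulates the averaged-response cell grid: *potential* cells are the full
#' cross-product participant x perturbation direction x response direction
#' (x focus for the sentence task); *realized* cells actually contain at
#' least one epoch; the difference are non-responses (speakers who never,
#' e.g., followed an upward shift in a condition).
#'
#' @param participants character vector of participant ids (or a count)
#' @param measures optional measures tibble (from [measure_peaks()]) used to
#'   count realized cells
#' @param tasks tasks in the design
#' @param directions perturbation directions
#' @param response_directions response directions
#' @param focus_levels focus levels (sentence task only)
#' @return tibble per task (+ total row): potential, realized, non_responses
#' @export
count_cells <- function(participants, measures = NULL,
                        tasks = c("vowel", "sentence"),
                        directions = c(200, -200),
                        response_directions = c("opposing", "following"),
                        focus_levels = c("new", "corrective")) {
  n_p <- if (is.numeric(participants)) participants else length(unique(participants))
  per_task <- tibble(task = tasks) %>%
    mutate(potential = purrr::map_dbl(.data$task, function(tk) {
      base <- n_p * length(directions) * length(response_directions)
      if (tk == "sentence") base * length(focus_levels) else base
    }))
  if (!is.null(measures)) {
    realized <- measures %>%
      distinct(across(dplyr::any_of(
        c("participant", "task", "focus", "pert_cents", "resp_dir")
      ))) %>%
      count(.data$task, name = "realized")
    per_task <- per_task %>%
      left_join(realized, by = "task") %>%
      mutate(realized = dplyr::coalesce(.data$realized, 0L))
  } else {
    per_task$realized <- NA_integer_
  }
  total <- per_task %>%
    summarise(task = "total",
              potential = sum(.data$potential),
              realized = if (all(is.na(.data$realized))) NA_integer_
                         else sum(.data$realized))
  bind_rows(per_task, total) %>%
    mutate(non_responses = .data$potential - .data$realized)
}
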