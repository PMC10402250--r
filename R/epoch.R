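#' Epoch a contour around one perturbation onset
#'
#' Extracts the window from `pre_ms` before to `post_ms` after the
#' perturbation onset (defaults -50..+400 ms, the conventional pitch-shift
#' analysis window) and converts it to the cent scale relative to the
#' baseline mean, the mean f0 over the half-open baseline window
#' `[-pre_ms, 0)`. Onsets are aligned to the nearest contour frame. Voiced
#' and interpolation-filled frames enter the baseline mean; frames still
#' missing yield `NA` cents.
#'
#' @param contour tibble `time_s`, `f0_hz`, `voiced` (and optionally `filled`)
#' @param onset_s perturbation onset (s, contour time base)
#' @param pre_ms,post_ms window extent around the onset (ms)
#' @return tibble: `rel_ms`, `f0_hz`, `cents`, `usable` (voiced or filled),
#'   with attribute `baseline_hz`
#' @export
epoch_trial <- function(contour, onset_s, pre_ms = 50, post_ms = 400) {
  hop <- contour_hop_ms(contour)
  t0 <- contour$time_s[1]
  i_on <- round((onset_s - t0) / (hop / 1000)) + 1L
  n_pre <- round(pre_ms / hop)
  n_post <- round(post_ms / hop)
  lo <- i_on - n_pre
  hi <- i_on + n_post
  if (lo < 1L || hi > nrow(contour)) {
    abort("Contour does not cover the full epoch window around the onset.")
  }
  sl <- contour[lo:hi, ]
  usable <- sl$voiced | (if ("filled" %in% names(sl)) sl$filled else FALSE)
  usable <- usable & !is.na(sl$f0_hz)
  rel_ms <- (seq(lo, hi) - i_on) * hop
  base_idx <- rel_ms >= -pre_ms & rel_ms < 0
  base_vals <- sl$f0_hz[base_idx & usable]
  if (length(base_vals) < 2L) {
    abort("Too few usable baseline frames to reference the epoch.")
  }
  baseline_hz <- mean(base_vals)
  out <- tibble(
    rel_ms = rel_ms,
    f0_hz = ifelse(usable, sl$f0_hz, NA_real_),
    cents = ifelse(usable, hz_to_cents(sl$f0_hz, baseline_hz), NA_real_),
    usable = usable
  )
  attr(out, "baseline_hz") <- baseline_hz
  out
}

#' Apply trial exclusion rules
#'
#' Reproduces the standard screening of perturbation trials before epoching:
#' * `mistimed` — the perturbation arrived at the wrong time: outside the
#'   first word of the phrase (sentence task) or overrunning the
#'   vocalization (vowel task);
#' * `missing_frames` — more than `max_missing` of an epoch window is
#'   unvoiced after gap interpolation (pitch-tracking dropouts);
#' * `insufficient_coverage` — the contour cannot cover an epoch window;
#' * `disfluency` — trials flagged as disfluent/hesitant in the session's
#'   ground truth (the synthetic stand-in for the human screening pass).
#'
#' A trial is excluded if any of its perturbation events fails a rule.
#'
#' @param session a `psr_session` or `psr_cohort`
#' @param max_missing tolerated fraction of missing epoch frames
#' @param max_gap_ms gap-interpolation limit passed to [interpolate_unvoiced()]
#' @param pre_ms,post_ms epoch window (ms)
#' @return list: `kept` (trial tibble), `log` (tibble trial_id, reason)
#' @export
exclude_trials <- function(session, max_missing = 0.2, max_gap_ms = 100,
                           pre_ms = 50, post_ms = 400) {
  trials <- session$trials
  events <- session$events
  truth <- session$ground_truth
  missing_contour <- purrr::map_lgl(trials$contour, is.null)
  if (any(missing_contour)) {
    abort(sprintf("Trial '%s' has no contour.",
                  trials$trial_id[which(missing_contour)[1]]))
  }
  flagged <- unique(truth$trial_id[!is.na(truth$pathology) &
                                     truth$pathology == "disfluency"])

  reasons <- purrr::map_chr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    if (tr$trial_id %in% flagged) return("disfluency")
    ev <- events[events$trial_id == tr$trial_id, ]
    ct <- interpolate_unvoiced(tr$contour[[1]], max_gap_ms = max_gap_ms)
    hop <- contour_hop_ms(ct)
    for (j in seq_len(nrow(ev))) {
      onset <- ev$onset_s[j]
      if (tr$task == "sentence") {
        al <- tr$alignment[[1]]
        w1 <- al[1, ]
        if (onset < w1$start_s || onset >= w1$end_s) return("mistimed")
      } else {
        if (onset + ev$duration_ms[j] / 1000 > tr$duration_s + 1e-9) {
          return("mistimed")
        }
      }
      lo_t <- onset - pre_ms / 1000
      hi_t <- onset + post_ms / 1000
      if (lo_t < ct$time_s[1] - 1e-9 ||
          hi_t > ct$time_s[nrow(ct)] + 1e-9) {
        return("insufficient_coverage")
      }
      in_win <- ct$time_s >= lo_t - 1e-9 & ct$time_s <= hi_t + 1e-9
      usable <- (ct$voiced | ct$filled)[in_win] & !is.na(ct$f0_hz[in_win])
      if (mean(!usable) > max_missing) return("missing_frames")
    }
    NA_character_
  })

  keep <- is.na(reasons)
  list(
    kept = trials[keep, ],
    log = tibble(trial_id = trials$trial_id[!keep], reason = reasons[!keep])
  )
}

#' Epoch all perturbation events of a session or cohort
#'
#' Interpolates short voicing gaps, then extracts one baseline-referenced
#' cent-scale epoch per perturbation event of the supplied (already
#' screened) trials. Returns a long tibble, the central data structure of
#' the downstream analysis.
#'
#' @param trials trial tibble (e.g. `exclude_trials()$kept`) with list-column
#'   `contour` and identifier columns
#' @param events event tibble (`trial_id`, `event_id`, `onset_s`, `cents`)
#' @param max_gap_ms gap-interpolation limit (ms)
#' @param pre_ms,post_ms epoch window (ms)
#' @return `psr_epochs` tibble: participant (if present), group, trial_id,
#'   event_id, task, focus, pert_cents, baseline_hz, rel_ms, cents
#' @export
epoch_events <- function(trials, events, max_gap_ms = 100,
                         pre_ms = 50, post_ms = 400) {
  id_cols <- intersect(c("participant", "group"), names(trials))
  out <- purrr::map_dfr(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    ev <- events[events$trial_id == tr$trial_id, ]
    if (nrow(ev) == 0L) return(NULL)
    ct <- interpolate_unvoiced(tr$contour[[1]], max_gap_ms = max_gap_ms)
    purrr::map_dfr(seq_len(nrow(ev)), function(j) {
      ep <- epoch_trial(ct, ev$onset_s[j], pre_ms = pre_ms, post_ms = post_ms)
      res <- tibble(
        trial_id = tr$trial_id,
        event_id = ev$event_id[j],
        task = tr$task,
        focus = tr$focus,
        pert_cents = ev$cents[j],
        baseline_hz = attr(ep, "baseline_hz"),
        rel_ms = ep$rel_ms,
        cents = ep$cents
      )
      for (col in rev(id_cols)) res[[col]] <- tr[[col]]
      res[, c(id_cols, setdiff(names(res), id_cols))]
    })
  })
  class(out) <- c("psr_epochs", class(out))
  out
}
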