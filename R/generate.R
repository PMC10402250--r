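#' Word alignment for one synthetic carrier phrase
#'
#' Nominal word boundaries for "Lay/not your OBJECT by your LOCATION".
#' New-information focus uses "lay", corrective focus "not" as the first
#' word. The stressed OBJECT word's length follows the focus-dependent
#' stressed-vowel duration (scaled by `dur_mult` for trial-to-trial
#' variation); vowel boundaries within the word are included.
#'
#' @param intonation an [intonation_model()]
#' @param focus `"new"` or `"corrective"`
#' @param dur_mult multiplicative trial-level duration factor
#' @return tibble: word, start_s, end_s, is_stressed, vowel_start_s, vowel_end_s
#' @export
sentence_alignment <- function(intonation, focus, dur_mult = 1) {
  vd <- intonation$stressed_vowel_duration_ms[[focus]] * dur_mult / 1000
  obj_dur <- vd + 0.05 # onset consonant margin before the vowel
  w <- c(if (focus == "corrective") "not" else "lay",
         "your", "OBJECT", "by", "your", "LOCATION")
  durs <- c(0.25, 0.15, obj_dur, 0.20, 0.15, 0.35)
  end <- cumsum(durs)
  start <- end - durs
  tibble(
    word = w,
    start_s = start,
    end_s = end,
    is_stressed = w == "OBJECT",
    vowel_start_s = ifelse(w == "OBJECT", start + 0.05, NA_real_),
    vowel_end_s = ifelse(w == "OBJECT", start + 0.05 + vd, NA_real_)
  )
}

# smooth accent plateau: height h over [a, b], raised-cosine ramps of length
# `ramp` placed outside the interval so the mean over [a, b] equals h exactly
accent_profile <- function(t, a, b, h, ramp) {
  out <- numeric(length(t))
  out[t >= a & t <= b] <- h
  ri <- t > a - ramp & t < a
  out[ri] <- h * 0.5 * (1 + cos(pi * (a - t[ri]) / ramp))
  rf <- t > b & t < b + ramp
  out[rf] <- h * 0.5 * (1 + cos(pi * (t[rf] - b) / ramp))
  out
}

# raised-cosine (Hann) response pulse with peak `amp` at `peak`, full support
# width `width`
hann_pulse <- function(t, peak, amp, width) {
  u <- (t - peak) / (width / 2)
  ifelse(abs(u) < 1, amp * 0.5 * (1 + cos(pi * u)), 0)
}

# AR(1) f0 wander in cents with stationary sd `sd` and correlation time
# `tau_ms`, sampled at `hop_ms`
ar1_jitter <- function(n, sd, tau_ms, hop_ms) {
  if (sd <= 0) return(numeric(n))
  rho <- exp(-hop_ms / tau_ms)
  innov <- rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = rnorm(1, 0, sd)))
}

# mean-parameterised lognormal multiplier: E[exp(s Z - s^2/2)] = 1
lognorm_mult <- function(n, sdlog) exp(rnorm(n, 0, sdlog) - sdlog^2 / 2)

#' Generate the f0 contour for one trial
#'
#' Synthesises a ground-truthed f0 contour on the frame grid:
#' \deqn{f_0(t) = \mathrm{baseline} \cdot
#'   2^{(\mathrm{intonation}(t) + \sum \mathrm{pulses}(t) + \mathrm{jitter}(t))/1200}}
#' Each non-control perturbation event spawns one raised-cosine response
#' pulse whose sign opposes the shift with probability `p_opposing` (else
#' follows it), with lognormal magnitude and truncated-normal peak latency
#' drawn from the subject model. Sentence trials carry the focus-dependent
#' intonation (declination + accent plateau on the stressed word), an
#' intensity track, and 40-ms voicing breaks at the /t/ of "not" and the
#' /b/ of "by"; vowel trials are flat apart from jitter and pulses.
#'
#' @param trial one row of a manifest `trials` tibble
#' @param events the trial's perturbation events (manifest `events` rows)
#' @param subject a [subject_model()]
#' @param seed integer seed for this trial
#' @param hop_ms frame hop (ms)
#' @return list with `contour` (tibble: time_s, f0_hz, voiced, intensity_db),
#'   `alignment` (sentence trials; else `NULL`) and `truth` (tibble: one row
#'   per event with true response direction, magnitude, latency)
#' @export
generate_trial_f0 <- function(trial, events, subject, seed, hop_ms = 5) {
  with_seed(seed, {
    im <- subject$intonation
    sentence <- trial$task == "sentence"
    if (sentence) {
      dur_mult <- lognorm_mult(1, im$duration_sdlog)
      alignment <- sentence_alignment(im, trial$focus, dur_mult)
      duration <- max(alignment$end_s)
    } else {
      alignment <- NULL
      duration <- trial$duration_s
    }
    hop_s <- hop_ms / 1000
    t <- seq(0, duration, by = hop_s)
    n <- length(t)

    # intonation (cents) and intensity (dB)
    if (sentence) {
      decl <- im$declination_cents_per_s * (t - duration / 2)
      obj <- alignment[alignment$is_stressed, ]
      accent <- accent_profile(t, obj$start_s, obj$end_s,
                               im$accent_height_cents[[trial$focus]],
                               im$accent_ramp_ms / 1000)
      intonation <- decl + accent
      level <- im$accent_intensity_db[[trial$focus]] + rnorm(1, 0, 0.5)
      intensity <- im$base_intensity_db +
        accent_profile(t, obj$start_s, obj$end_s,
                       level - im$base_intensity_db, im$accent_ramp_ms / 1000) +
        rnorm(n, 0, 0.5)
    } else {
      intonation <- numeric(n)
      intensity <- im$base_intensity_db + rnorm(n, 0, 0.5)
    }

    # response pulses + per-event ground truth
    pulses <- numeric(n)
    truth <- purrr::map_dfr(seq_len(nrow(events)), function(i) {
      ev <- events[i, ]
      if (ev$cents == 0) {
        return(tibble(
          trial_id = trial$trial_id, event_id = ev$event_id,
          pert_cents = 0, true_resp_dir = NA_character_,
          true_magnitude_cents = NA_real_, true_peak_latency_ms = NA_real_
        ))
      }
      opposing <- runif(1) < subject$p_opposing
      resp_dir <- if (opposing) "opposing" else "following"
      resp_sign <- if (opposing) -sign(ev$cents) else sign(ev$cents)
      mag <- subject_cell_magnitude(subject, trial$task, trial$focus) *
        lognorm_mult(1, subject$response_magnitude_sdlog)
      lat <- rnorm(1, subject$response_peak_latency_mean_ms[[resp_dir]],
                   subject$response_peak_latency_sd_ms)
      lat <- min(max(lat, 90), 285)
      pulses <<- pulses + hann_pulse(t, ev$onset_s + lat / 1000,
                                     resp_sign * mag, subject$response_width_ms / 1000)
      tibble(
        trial_id = trial$trial_id, event_id = ev$event_id,
        pert_cents = ev$cents, true_resp_dir = resp_dir,
        true_magnitude_cents = mag, true_peak_latency_ms = lat
      )
    })

    jitter <- ar1_jitter(n, subject$f0_jitter_cents_sd, subject$jitter_tau_ms, hop_ms)
    f0 <- cents_to_hz(intonation + pulses + jitter, subject$baseline_f0_hz)

    voiced <- rep(TRUE, n)
    if (sentence) {
      gap <- im$gap_ms / 1000
      w1 <- alignment[1, ]
      if (w1$word == "not") voiced[t >= w1$end_s - gap & t < w1$end_s] <- FALSE
      by_w <- alignment[alignment$word == "by", ]
      voiced[t >= by_w$start_s & t < by_w$start_s + gap] <- FALSE
    }
    contour <- tibble(
      time_s = t,
      f0_hz = ifelse(voiced, f0, NA_real_),
      voiced = voiced,
      intensity_db = ifelse(voiced, intensity, NA_real_)
    )
    list(contour = contour, alignment = alignment, truth = truth)
  })
}

#' Generate a full session for one subject
#'
#' Runs [generate_trial_f0()] over every trial of a designed session and
#' injects trial pathologies at the configured rate: mis-timed perturbation
#' pulses (the shift arrives too late — outside the first word for sentences,
#' overrunning the vocalization for vowels), pitch-tracking dropouts (a 150-ms
#' unvoiced stretch inside an epoch window), and disfluencies (flag only,
#' standing in for productions a human rater would reject). Pathological
#' trials are what the downstream exclusion stage must catch.
#'
#' @param manifest a [design_session()] result
#' @param subject a [subject_model()]
#' @param seed integer seed
#' @param p_pathology total pathology rate (default 0.25)
#' @param pathology_mix named probabilities for `mistimed_pulse`,
#'   `tracking_dropout`, `disfluency` given a pathological trial
#' @return a `psr_session`: list with `trials` (manifest columns + list-cols
#'   `contour`, `alignment`), `events` (possibly shifted onsets), and
#'   `ground_truth` (per event, incl. `pathology`)
#' @export
generate_session <- function(manifest, subject, seed = 1L,
                             p_pathology = 0.25,
                             pathology_mix = c(mistimed_pulse = 0.9,
                                               tracking_dropout = 0.05,
                                               disfluency = 0.05)) {
  stopifnot(inherits(manifest, "psr_manifest"))
  cfg <- manifest$config
  trials <- manifest$trials
  events <- manifest$events
  n_tr <- nrow(trials)

  with_seed(derive_seed(seed, 2L), {
    pathology <- rep("none", n_tr)
    is_path <- runif(n_tr) < p_pathology
    pathology[is_path] <- sample(names(pathology_mix), sum(is_path),
                                 replace = TRUE, prob = pathology_mix)
    trial_seeds <- sample.int(2^31 - 2, n_tr)
    shift_s <- runif(n_tr, 0.3, 0.6)

    out <- purrr::map(seq_len(n_tr), function(i) {
      tr <- trials[i, ]
      ev <- events[events$trial_id == tr$trial_id, ]
      if (pathology[i] == "mistimed_pulse") {
        hop_s <- cfg$hop_ms / 1000
        if (cfg$task == "sentence") {
          ev$onset_s <- round((ev$onset_s + shift_s[i]) / hop_s) * hop_s
        } else {
          k <- nrow(ev)
          ev$onset_s[k] <- round((tr$duration_s - 0.1) / hop_s) * hop_s
        }
      }
      g <- generate_trial_f0(tr, ev, subject, trial_seeds[i], hop_ms = cfg$hop_ms)
      if (pathology[i] == "tracking_dropout") {
        on <- ev$onset_s[sample.int(nrow(ev), 1)]
        drop <- g$contour$time_s >= on + 0.1 & g$contour$time_s < on + 0.25
        g$contour$voiced[drop] <- FALSE
        g$contour$f0_hz[drop] <- NA_real_
        g$contour$intensity_db[drop] <- NA_real_
      }
      list(g = g, ev = ev)
    })

    trials$duration_s <- purrr::map_dbl(out, ~ max(.x$g$contour$time_s))
    trials$contour <- purrr::map(out, ~ .x$g$contour)
    trials$alignment <- purrr::map(out, ~ .x$g$alignment)
    events <- purrr::map_dfr(out, "ev")
    ground_truth <- purrr::map_dfr(out, ~ .x$g$truth) %>%
      left_join(tibble(trial_id = trials$trial_id, pathology = pathology),
                by = "trial_id")
    structure(
      list(config = cfg, trials = trials, events = events,
           ground_truth = ground_truth, seed = as.integer(seed)),
      class = "psr_session"
    )
  })
}

#' Generate a synthetic cohort
#'
#' Draws per-subject generative models around the group-level cell means and
#' generates complete vowel and sentence sessions for every subject, together
#' with metadata and a ground-truth table for recovery testing. Subject-level
#' heterogeneity: a single lognormal magnitude multiplier (shared across
#' cells, i.e. a random intercept on the log scale), a normal peak-latency
#' offset shared across response directions, sex-dependent habitual f0.
#'
#' @param n_ataxia,n_control subjects per group
#' @param vowel_config,sentence_config [session_config()]s; `NULL` skips a task
#' @param effects generative cell means, see [psr_default_effects()]
#' @param seed integer master seed
#' @param subject_magnitude_sdlog between-subject lognormal sdlog of magnitude
#' @param subject_latency_sd_ms between-subject sd of the latency offset (ms)
#' @param p_pathology per-trial pathology rate
#' @param ... further arguments passed to [subject_model()]
#' @return a `psr_cohort`: list with `participants` (metadata + `subject`
#'   list-col), `trials`, `events`, `ground_truth` tibbles (all carrying
#'   `participant` and `group`)
#' @export
generate_cohort <- function(n_ataxia = 22, n_control = 29,
                            vowel_config = session_config("vowel"),
                            sentence_config = session_config("sentence"),
                            effects = psr_default_effects(),
                            seed = 1L,
                            subject_magnitude_sdlog = 0.2,
                            subject_latency_sd_ms = 30,
                            p_pathology = 0.25,
                            ...) {
  stopifnot(n_ataxia >= 1, n_control >= 1)
  groups <- c(rep("ataxia", n_ataxia), rep("control", n_control))
  n_sub <- length(groups)
  ids <- sprintf("P%02d", seq_len(n_sub))

  participants <- with_seed(derive_seed(seed, 3L), {
    sex <- sample(c("F", "M"), n_sub, replace = TRUE, prob = c(0.65, 0.35))
    baseline <- ifelse(sex == "F", rnorm(n_sub, 210, 15), rnorm(n_sub, 120, 10))
    mag_mult <- lognorm_mult(n_sub, subject_magnitude_sdlog)
    lat_off <- rnorm(n_sub, 0, subject_latency_sd_ms)
    subjects <- purrr::map(seq_len(n_sub), function(i) {
      mags <- effects$magnitude %>%
        filter(.data$group == groups[i]) %>%
        mutate(mean_cents = .data$mean_cents * mag_mult[i]) %>%
        select("task", "focus", "mean_cents")
      lat <- setNames(effects$latency$mean_ms, effects$latency$resp_dir)
      lat <- pmin(pmax(lat + lat_off[i], 100), 280)
      subject_model(
        group = groups[i], baseline_f0_hz = baseline[i],
        response_magnitude_mean = mags,
        response_peak_latency_mean_ms = lat,
        p_opposing = effects$p_opposing, ...
      )
    })
    tibble(
      participant = ids, group = groups, sex = sex,
      age = sample(24:79, n_sub, replace = TRUE),
      baseline_f0_hz = round(baseline, 1),
      subject = subjects
    )
  })

  configs <- purrr::compact(list(vowel = vowel_config, sentence = sentence_config))
  sessions <- purrr::map(seq_len(n_sub), function(i) {
    purrr::imap(configs, function(cfg, task) {
      s_des <- derive_seed(seed, 100L + i * 10L + match(task, names(configs)))
      man <- design_session(cfg, seed = s_des)
      man$trials$trial_id <- paste0(ids[i], "_", man$trials$trial_id)
      man$events$trial_id <- paste0(ids[i], "_", man$events$trial_id)
      generate_session(man, participants$subject[[i]],
                       seed = derive_seed(s_des, 7L),
                       p_pathology = p_pathology)
    })
  })

  flatten <- function(field) {
    purrr::map_dfr(seq_len(n_sub), function(i) {
      purrr::map_dfr(sessions[[i]], function(s) {
        s[[field]] %>% mutate(participant = ids[i], group = groups[i], .before = 1)
      })
    })
  }
  structure(
    list(
      participants = participants,
      trials = flatten("trials"),
      events = flatten("events"),
      ground_truth = flatten("ground_truth"),
      configs = configs,
      seed = as.integer(seed)
    ),
    class = "psr_cohort"
  )
}

#' @method print psr_cohort
#' @export
print.psr_cohort <- function(x, ...) {
  cat(sprintf(
    "<psr_cohort> %d participants (%d ataxia / %d control), %d trials, %d events\n",
    nrow(x$participants), sum(x$participants$group == "ataxia"),
    sum(x$participants$group == "control"), nrow(x$trials), nrow(x$events)
  ))
  invisible(x)
}

#' Simulate averaged response measures directly
#'
#' Draws cell-level averaged pitch-shift-response measures (one row per
#' participant x task x focus x perturbation direction x response direction)
#' from the same subject/cell hierarchy as the waveform generator, without
#' synthesising contours. Intended for statistical calibration studies
#' (type-I error, power, estimator consistency) where hundreds of replicate
#' cohorts are needed; full-pipeline behaviour is validated separately by
#' parameter recovery on generated contours.
#'
#' @inheritParams generate_cohort
#' @param n_trials_per_cell trials entering each participant x task x focus x
#'   direction cell before the opposing/following split
#' @param trial_magnitude_sdlog trial-level lognormal sdlog of magnitude
#' @param trial_latency_sd_ms trial-level latency sd (ms)
#' @return tibble of measures: participant, group, task, focus, pert_cents,
#'   resp_dir, n_trials, magnitude_cents, latency_ms
#' @export
simulate_measures <- function(n_ataxia = 22, n_control = 29,
                              effects = psr_default_effects(),
                              n_trials_per_cell = 20,
                              trial_magnitude_sdlog = 0.35,
                              trial_latency_sd_ms = 10,
                              subject_magnitude_sdlog = 0.2,
                              subject_latency_sd_ms = 30,
                              seed = 1L) {
  groups <- c(rep("ataxia", n_ataxia), rep("control", n_control))
  n_sub <- length(groups)
  ids <- sprintf("P%02d", seq_len(n_sub))
  with_seed(derive_seed(seed, 4L), {
    mag_mult <- lognorm_mult(n_sub, subject_magnitude_sdlog)
    lat_off <- rnorm(n_sub, 0, subject_latency_sd_ms)
    lat_means <- setNames(effects$latency$mean_ms, effects$latency$resp_dir)
    cells <- effects$magnitude %>% tidyr::expand_grid(pert_cents = c(200, -200))
    purrr::map_dfr(seq_len(n_sub), function(i) {
      sub_cells <- cells %>% filter(.data$group == groups[i])
      purrr::map_dfr(seq_len(nrow(sub_cells)), function(j) {
        cell <- sub_cells[j, ]
        n_opp <- rbinom(1, n_trials_per_cell, effects$p_opposing)
        ns <- c(opposing = n_opp, following = n_trials_per_cell - n_opp)
        purrr::map_dfr(names(ns)[ns > 0], function(dir) {
          nd <- ns[[dir]]
          tibble(
            participant = ids[i], group = groups[i],
            task = cell$task, focus = cell$focus, pert_cents = cell$pert_cents,
            resp_dir = dir, n_trials = nd,
            magnitude_cents = cell$mean_cents * mag_mult[i] *
              lognorm_mult(1, trial_magnitude_sdlog / sqrt(nd)),
            latency_ms = min(max(
              lat_means[[dir]] + lat_off[i] + rnorm(1, 0, trial_latency_sd_ms / sqrt(nd)),
              70), 295)
          )
        })
      })
    })
  })
}
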