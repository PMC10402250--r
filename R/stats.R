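#' Cohen's d from a mixed-model t statistic
#'
#' Effect size for an LMM fixed effect from its t statistic and denominator
#' degrees of freedom:
#' \deqn{d = 2t/\sqrt{\mathrm{df}}}
#'
#' @param t t statistic(s)
#' @param df degrees of freedom (> 0), recycled
#' @return Cohen's d, same sign as `t`
#' @examples
#' cohens_d_from_lmm(2, 47) # 0.583
#' @export
cohens_d_from_lmm <- function(t, df) {
  if (any(!is.na(df) & df <= 0)) abort("`df` must be > 0.")
  2 * t / sqrt(df)
}

# factor-coding shared by the model fits
prepare_measures <- function(measures) {
  m <- as_tibble(measures)
  if ("pert_cents" %in% names(m) && !"pert_dir" %in% names(m)) {
    m$pert_dir <- ifelse(m$pert_cents > 0, "up", "down")
  }
  for (col in intersect(c("group", "task", "pert_dir", "resp_dir"), names(m))) {
    m[[col]] <- factor(m[[col]])
  }
  if ("focus" %in% names(m)) {
    m$focus <- factor(ifelse(is.na(m$focus), "none", m$focus))
  }
  m
}

check_participants <- function(m, min_per_group = 2) {
  np <- m %>% distinct(.data$participant, .data$group) %>% count(.data$group)
  if (n_distinct(m$participant) < 2) {
    abort("At least two participants are required for a random participant intercept.")
  }
  if (any(np$n < min_per_group)) {
    abort(sprintf("Each group needs at least %d participants.", min_per_group))
  }
}

# fit lmer, collect coefficients (Satterthwaite df), anova, LS-means with
# Tukey-adjusted pairwise contrasts, Cohen's d per coefficient. Degenerate
# data (zero residual variance) breaks the Satterthwaite machinery; such
# fits fall back to plain lme4 with residual-df t tests.
fit_psr_lmm <- function(formula, data, outcome, emm_specs) {
  fit <- tryCatch(lmerTest::lmer(formula, data = data), error = function(e) NULL)
  co <- if (!is.null(fit)) {
    tryCatch(summary(fit)$coefficients, error = function(e) NULL)
  }
  if (is.null(co) || !"df" %in% colnames(co)) {
    # zero-residual data: treat participant as a fixed blocking factor
    fml <- stats::update(lme4::nobars(formula), . ~ . + participant)
    fit <- stats::lm(fml, data = data)
    co_all <- summary(fit)$coefficients
    keep <- !grepl("^participant", rownames(co_all))
    df_resid <- stats::df.residual(fit)
    co <- cbind(co_all[keep, c("Estimate", "Std. Error"), drop = FALSE],
                df = df_resid, `t value` = co_all[keep, "t value"],
                `Pr(>|t|)` = co_all[keep, "Pr(>|t|)"])
    an <- as.data.frame(stats::anova(fit))
    an <- an[!rownames(an) %in% c("participant", "Residuals"), , drop = FALSE]
    anova_tbl <- tibble(
      term = rownames(an),
      num_df = an$Df, den_df = df_resid,
      f_value = an$`F value`, p_value = an$`Pr(>F)`
    )
  } else {
    an <- as.data.frame(anova(fit))
    anova_tbl <- tibble(
      term = rownames(an),
      num_df = an$NumDF, den_df = an$DenDF,
      f_value = an$`F value`, p_value = an$`Pr(>F)`
    )
  }
  singular <- if (inherits(fit, "merMod")) lme4::isSingular(fit) else TRUE
  if (singular) {
    warn(paste0("Degenerate or singular random-effect fit for ", outcome,
                "; variance components at the boundary."))
  }
  effects <- tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    df = unname(co[, "df"]),
    statistic = unname(co[, "t value"]),
    p_value = unname(co[, "Pr(>|t|)"])
  ) %>%
    mutate(cohens_d = ifelse(.data$term == "(Intercept)", NA_real_,
                             cohens_d_from_lmm(.data$statistic, .data$df)))
  lsm <- purrr::map(emm_specs, function(sp) {
    emm <- emmeans::emmeans(fit, stats::as.formula(paste("~", sp)))
    list(
      means = as_tibble(as.data.frame(emm)),
      contrasts = as_tibble(as.data.frame(
        emmeans::contrast(emm, method = "pairwise", adjust = "tukey")
      ))
    )
  })
  names(lsm) <- emm_specs
  structure(
    list(outcome = outcome, model = fit, effects = effects, anova = anova_tbl,
         lsmeans = lsm, singular = singular),
    class = "psr_model"
  )
}

#' Fit the response-magnitude mixed model
#'
#' Linear mixed-effects model of absolute pitch-shift-response magnitude
#' with group, task, perturbation direction and response direction as fixed
#' effects and a random participant intercept; least-squares (model-based)
#' cell means and Tukey-adjusted pairwise contrasts per effect; Cohen's
#' d = 2t/sqrt(df) per coefficient.
#'
#' @param measures measures tibble (from [measure_peaks()] joined to group
#'   metadata, or [simulate_measures()])
#' @return a `psr_model`
#' @export
fit_magnitude_model <- function(measures) {
  m <- prepare_measures(measures)
  check_participants(m)
  if (n_distinct(m$task) < 2) abort("Both tasks must be present.")
  fit_psr_lmm(
    magnitude_cents ~ group + task + pert_dir + resp_dir + (1 | participant),
    m, "magnitude_cents",
    emm_specs = c("group", "task", "pert_dir", "resp_dir", "task:group")
  )
}

#' Fit the sentence-focus magnitude model
#'
#' Mixed model of absolute response magnitude on sentence-task measures
#' only, with semantic focus, group and their interaction as fixed effects
#' and a random participant intercept.
#'
#' @param measures measures tibble; only `task == "sentence"` rows are used
#' @return a `psr_model`
#' @export
fit_focus_model <- function(measures) {
  m <- prepare_measures(measures) %>% filter(.data$task == "sentence")
  if (nrow(m) == 0L) abort("No sentence-task measures supplied.")
  m$focus <- droplevels(m$focus)
  check_participants(m)
  fit_psr_lmm(
    magnitude_cents ~ focus * group + (1 | participant),
    m, "magnitude_cents",
    emm_specs = c("focus", "group", "focus:group")
  )
}

#' Fit the peak-latency mixed model
#'
#' Same fixed-effect structure as [fit_magnitude_model()] with peak latency
#' (ms) as the outcome.
#'
#' @param measures measures tibble
#' @return a `psr_model`
#' @export
fit_latency_model <- function(measures) {
  m <- prepare_measures(measures)
  check_participants(m)
  if (n_distinct(m$task) < 2) abort("Both tasks must be present.")
  fit_psr_lmm(
    latency_ms ~ group + task + pert_dir + resp_dir + (1 | participant),
    m, "latency_ms",
    emm_specs = c("group", "task", "pert_dir", "resp_dir")
  )
}

#' Logistic regression on response direction
#'
#' Models the probability of an opposing (vs following) response with
#' group, task, perturbation direction and sentence focus as fixed effects
#' (focus coded `none` for vowel measures). Terms with fewer than two
#' observed levels are dropped automatically. Quasi-separation (fitted
#' probabilities at 0/1) is reported with a warning, not an error.
#'
#' @param measures tibble with `resp_dir` and the design columns
#' @return a `psr_model` with Wald z tests
#' @export
direction_glm <- function(measures) {
  m <- prepare_measures(measures)
  if (!"resp_dir" %in% names(m)) abort("`measures` must contain `resp_dir`.")
  m$opposing <- as.integer(m$resp_dir == "opposing")
  cand <- c("group", "task", "pert_dir", "focus")
  terms <- cand[purrr::map_lgl(cand, function(cl) {
    cl %in% names(m) && n_distinct(m[[cl]]) >= 2
  })]
  if (length(terms) == 0L) abort("No fixed effect with at least two levels.")
  fml <- as.formula(paste("opposing ~", paste(terms, collapse = " + ")))
  fit <- glm(fml, data = m, family = binomial())
  probs <- stats::fitted(fit)
  if (any(probs < 1e-8 | probs > 1 - 1e-8)) {
    warn("Fitted probabilities numerically 0 or 1: possible separation; coefficients may be unstable.")
  }
  co <- summary(fit)$coefficients
  effects <- tibble(
    term = rownames(co),
    estimate = unname(co[, "Estimate"]),
    std_error = unname(co[, "Std. Error"]),
    statistic = unname(co[, "z value"]),
    p_value = unname(co[, "Pr(>|z|)"])
  )
  structure(
    list(outcome = "opposing", model = fit, effects = effects,
         anova = NULL, lsmeans = NULL, singular = FALSE),
    class = "psr_model"
  )
}

#' Mixed models for stressed-word prosody
#'
#' One mixed model per prosodic outcome (mean f0 in cents, mean intensity
#' in dB, stressed-vowel duration in ms) with semantic focus as fixed
#' effect and a random participant intercept, fitted on control-trial
#' prosody measures.
#'
#' @param prosody tibble from [prosody_measures()]
#' @return named list of `psr_model`s (`f0`, `intensity`, `duration`)
#' @export
fit_prosody_models <- function(prosody) {
  m <- as_tibble(prosody)
  m$focus <- factor(m$focus)
  check_participants(
    m %>% mutate(group = if ("group" %in% names(m)) .data$group else "all"),
    min_per_group = 1
  )
  outcomes <- c(f0 = "mean_f0_cents", intensity = "mean_intensity_db",
                duration = "vowel_duration_ms")
  purrr::imap(outcomes, function(col, nm) {
    fit_psr_lmm(
      as.formula(paste(col, "~ focus + (1 | participant)")),
      m, col, emm_specs = "focus"
    )
  })
}

#' @method print psr_model
#' @export
print.psr_model <- function(x, ...) {
  cat(sprintf("<psr_model> outcome: %s%s\n", x$outcome,
              if (isTRUE(x$singular)) " (singular random-effect fit)" else ""))
  print(x$effects, n = Inf)
  invisible(x)
}

#' @rdname tidy-psr
#' @param x a `psr_model`
#' @param ... unused
#' @export
tidy.psr_model <- function(x, ...) x$effects

#' Broom-style accessors for fitted PSR models
#'
#' `tidy()` returns the fixed-effect table (estimate, SE, df, t, p, Cohen's
#' d); `glance()` a one-row model summary.
#'
#' @name tidy-psr
#' @return tibbles
#' @export
glance.psr_model <- function(x, ...) {
  fit <- x$model
  if (inherits(fit, "merMod")) {
    tibble(
      outcome = x$outcome,
      nobs = stats::nobs(fit),
      n_participants = lme4::ngrps(fit)[["participant"]],
      sigma = stats::sigma(fit),
      logLik = as.numeric(stats::logLik(fit)),
      AIC = stats::AIC(fit),
      singular = x$singular
    )
  } else {
    tibble(
      outcome = x$outcome,
      nobs = stats::nobs(fit),
      deviance = stats::deviance(fit),
      AIC = stats::AIC(fit),
      singular = x$singular
    )
  }
}
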