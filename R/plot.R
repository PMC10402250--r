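#' Plot event-related averaged pitch-shift responses
#'
#' Grand-average response waves by perturbation direction (columns) and
#' response direction (line type), coloured by group when present — the
#' conventional display of averaged pitch-shift responses. Participant-level
#' averages are averaged again within display cells.
#'
#' @param object a `psr_avg` tibble from [event_related_average()]
#' @param task which task to display (default: all, facetted)
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.psr_avg <- function(object, task = NULL, ...) {
  df <- object
  if (!is.null(task)) df <- df %>% filter(.data$task == !!task)
  grp <- "group" %in% names(df)
  cell <- c(if (grp) "group", "task", "pert_cents", "resp_dir", "rel_ms")
  df <- df %>%
    group_by(across(dplyr::all_of(cell))) %>%
    summarise(mean_cents = mean(.data$mean_cents, na.rm = TRUE), .groups = "drop") %>%
    mutate(pert_lab = ifelse(.data$pert_cents > 0, "upward shift", "downward shift"))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$rel_ms, .data$mean_cents,
                                        linetype = .data$resp_dir)) +
    ggplot2::annotate("rect", xmin = 0, xmax = 200, ymin = -Inf, ymax = Inf,
                      alpha = 0.12) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_grid(task ~ pert_lab) +
    ggplot2::labs(x = "Time re perturbation onset (ms)",
                  y = "Voice f0 (cents re baseline)",
                  linetype = "Response") +
    ggplot2::theme_minimal()
  if (grp) {
    p <- p + ggplot2::aes(colour = .data$group) + ggplot2::labs(colour = "Group")
  }
  p
}

#' Plot stressed-word prosody by semantic focus
#'
#' Group means with standard-error bars for mean f0, mean intensity and
#' stressed-vowel duration by focus condition.
#'
#' @param prosody tibble from [prosody_measures()]
#' @return a ggplot
#' @export
plot_prosody <- function(prosody) {
  long <- prosody %>%
    tidyr::pivot_longer(
      c("mean_f0_cents", "mean_intensity_db", "vowel_duration_ms"),
      names_to = "measure", values_to = "value"
    ) %>%
    mutate(measure = dplyr::recode(.data$measure,
      mean_f0_cents = "mean f0 (cents)",
      mean_intensity_db = "mean intensity (dB)",
      vowel_duration_ms = "vowel duration (ms)"
    )) %>%
    group_by(.data$focus, .data$measure) %>%
    summarise(
      mean = mean(.data$value, na.rm = TRUE),
      se = sd(.data$value, na.rm = TRUE) / sqrt(sum(!is.na(.data$value))),
      .groups = "drop"
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$focus, .data$mean)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$se,
                                          ymax = .data$mean + .data$se)) +
    ggplot2::facet_wrap(~measure, scales = "free_y") +
    ggplot2::labs(x = "Semantic focus", y = NULL) +
    ggplot2::theme_minimal()
}
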