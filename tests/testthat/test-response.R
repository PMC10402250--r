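rel <- seq(-50, 400, 5)

test_that("direction labels follow the pre/post window comparison", {
  up12 <- make_epoch(ifelse(rel > 0, 12, 0), pert_cents = 200)
  expect_equal(classify_direction(up12)$resp_dir, "following")
  down12 <- make_epoch(ifelse(rel > 0, -12, 0), pert_cents = 200)
  expect_equal(classify_direction(down12)$resp_dir, "opposing")
  # same responses under a downward shift flip the labels
  expect_equal(classify_direction(
    make_epoch(ifelse(rel > 0, 12, 0), pert_cents = -200))$resp_dir, "opposing")
  zero <- make_epoch(rep(0, 91), pert_cents = -200)
  expect_equal(classify_direction(zero)$resp_dir, "none")
  expect_error(classify_direction(make_epoch(rep(0, 91), pert_cents = 0)),
               "Control")
})

test_that("classification is perfect without noise and degrades with it", {
  coh <- noisefree_cohort()
  scr <- exclude_trials(coh)
  eps <- epoch_events(scr$kept, coh$events)
  diffs <- subtract_templates(eps)
  pert <- diffs %>% dplyr::filter(pert_cents != 0)
  cls <- classify_direction(pert)
  truth <- coh$ground_truth %>%
    dplyr::select(trial_id, event_id, true_resp_dir) %>%
    dplyr::filter(!is.na(true_resp_dir))
  j <- dplyr::inner_join(cls, truth, by = c("trial_id", "event_id"))
  expect_gt(nrow(j), 50)
  expect_true(all(j$resp_dir == j$true_resp_dir))
  # with noise, accuracy drops below 1 but stays above chance
  cohn <- small_cohort()
  scrn <- exclude_trials(cohn)
  epsn <- subtract_templates(epoch_events(scrn$kept, cohn$events)) %>%
    dplyr::filter(pert_cents != 0)
  clsn <- classify_direction(epsn)
  truthn <- cohn$ground_truth %>%
    dplyr::filter(!is.na(true_resp_dir)) %>%
    dplyr::select(trial_id, event_id, true_resp_dir)
  jn <- dplyr::inner_join(clsn, truthn, by = c("trial_id", "event_id"))
  acc <- mean(jn$resp_dir == jn$true_resp_dir)
  expect_lt(acc, 1)
  expect_gt(acc, 0.55)
})

test_that("event-related averages behave like means", {
  p <- pulse_on_grid(rel, 180, 40)
  one <- make_epoch(p, trial_id = "t1")
  avg1 <- event_related_average(one, directions = tibble::tibble(
    trial_id = "t1", event_id = 1L, resp_dir = "following"
  ))
  expect_equal(avg1$mean_cents, p)
  expect_equal(unique(avg1$n_trials), 1)
  # k identical copies leave the average unchanged
  copies <- dplyr::bind_rows(lapply(1:4, function(i) {
    make_epoch(p, trial_id = paste0("t", i))
  }))
  dirs <- tibble::tibble(trial_id = paste0("t", 1:4), event_id = 1L,
                         resp_dir = "following")
  avg4 <- event_related_average(copies, directions = dirs)
  expect_equal(avg4$mean_cents, p)
  expect_equal(unique(avg4$n_trials), 4)
  # adding a constant to every epoch shifts the average by that constant
  shifted <- copies %>% dplyr::mutate(cents = cents + 7.5)
  avg_s <- event_related_average(shifted, directions = dirs)
  expect_equal(avg_s$mean_cents, avg4$mean_cents + 7.5)
})

test_that("averaging suppresses noise at the CLT rate", {
  sd <- 25
  withr::with_seed(13, {
    eps <- dplyr::bind_rows(lapply(1:30, function(i) {
      make_epoch(pulse_on_grid(rel, 200, 100) + rnorm(91, 0, sd),
                 trial_id = paste0("t", i))
    }))
  })
  dirs <- tibble::tibble(trial_id = paste0("t", 1:30), event_id = 1L,
                         resp_dir = "following")
  avg <- event_related_average(eps, directions = dirs)
  m <- measure_peaks(avg)
  expect_lt(abs(m$magnitude_cents - 100), 3 * sd / sqrt(30))
})

test_that("peak measurement matches its construction and boundary rules", {
  down <- make_epoch(pulse_on_grid(rel, 180, -40), pert_cents = 200)
  avg <- event_related_average(down, directions = tibble::tibble(
    trial_id = "t1", event_id = 1L, resp_dir = "opposing"
  ))
  m <- measure_peaks(avg)
  expect_equal(m$peak_sign, "down")
  expect_equal(m$magnitude_cents, 40)
  expect_equal(m$latency_ms, 180)
  # a pulse peaking beyond the window is reported at the boundary
  late <- make_epoch(pulse_on_grid(rel, 320, 50), pert_cents = 200)
  avg_l <- event_related_average(late, directions = tibble::tibble(
    trial_id = "t1", event_id = 1L, resp_dir = "following"
  ))
  m_l <- measure_peaks(avg_l)
  expect_equal(m_l$latency_ms, 300)
  expect_equal(m_l$magnitude_cents, pulse_on_grid(300, 320, 50))
  # flat zero: magnitude 0, tie broken at the earliest window frame
  flat <- make_epoch(rep(0, 91), pert_cents = 200)
  avg_f <- event_related_average(flat, directions = tibble::tibble(
    trial_id = "t1", event_id = 1L, resp_dir = "following"
  ))
  m_f <- measure_peaks(avg_f)
  expect_equal(m_f$magnitude_cents, 0)
  expect_equal(m_f$latency_ms, 65)
})

test_that("windowed peak search agrees with a brute-force scan", {
  brute <- function(avg_cell, up) {
    w <- avg_cell[avg_cell$rel_ms > 60 & avg_cell$rel_ms <= 300, ]
    v <- w$mean_cents
    i <- if (up) which(v == max(v))[1] else which(v == min(v))[1]
    c(abs(v[i]), w$rel_ms[i])
  }
  withr::with_seed(17, {
    for (r in 1:200) {
      pert <- sample(c(200, -200), 1)
      dir <- sample(c("opposing", "following"), 1)
      cents <- rnorm(91, 0, 30) +
        pulse_on_grid(rel, runif(1, 60, 350), runif(1, -120, 120))
      ep <- make_epoch(cents, pert_cents = pert)
      avg <- event_related_average(ep, directions = tibble::tibble(
        trial_id = "t1", event_id = 1L, resp_dir = dir
      ))
      m <- measure_peaks(avg)
      up <- if (dir == "opposing") pert < 0 else pert > 0
      bf <- brute(avg, up)
      expect_equal(c(m$magnitude_cents, m$latency_ms), bf)
    }
  })
})

test_that("cell accounting reproduces the potential response grid", {
  tab <- count_cells(51)
  expect_equal(tab$potential[tab$task == "vowel"], 204)
  expect_equal(tab$potential[tab$task == "sentence"], 408)
  expect_equal(tab$potential[tab$task == "total"], 612)
  one <- count_cells(1, tasks = "vowel", directions = 200,
                     response_directions = "opposing")
  expect_equal(one$potential, c(1, 1))
  # realized cells counted from measures
  res <- small_results()
  tab2 <- count_cells(small_cohort()$participants$participant, res$measures)
  realized <- res$measures %>%
    dplyr::distinct(participant, task, focus, pert_cents, resp_dir) %>%
    nrow()
  expect_equal(tab2$realized[tab2$task == "total"], realized)
  expect_true(all(tab2$realized <= tab2$potential))
  expect_equal(tab2$non_responses, tab2$potential - tab2$realized)
})
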