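make_log <- function(...) {
  rows <- list(...)
  tibble::tibble(
    button = vapply(rows, `[[`, character(1), 1),
    t_on = vapply(rows, function(r) as.numeric(r[[2]]), numeric(1)),
    t_off = vapply(rows, function(r) as.numeric(r[[3]]), numeric(1))
  )
}

test_that("log validation merges, clamps and rejects as specified", {
  expect_warning(
    merged <- validate_log(make_log(list("LEFT", 2, 5), list("LEFT", 4, 9))),
    "merged 1"
  )
  expect_equal(nrow(merged), 1L)
  expect_equal(c(merged$t_on, merged$t_off), c(2, 9))

  empty <- validate_log(tibble::tibble(button = character(), t_on = numeric(), t_off = numeric()))
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "trial_duration"), 60)

  expect_error(validate_log(make_log(list("LEFT", 5, 3))), "row\\(s\\) 1")
  expect_error(validate_log(make_log(list("MIDDLE", 1, 2))), "unknown button")
  expect_error(validate_log(make_log(list("LEFT", 1, 2)), trial_duration = -3), "positive")

  expect_warning(
    clamped <- validate_log(make_log(list("RIGHT", -2, 70)), trial_duration = 60),
    "clamped"
  )
  expect_equal(c(clamped$t_on, clamped$t_off), c(0, 60))
})

test_that("timeline resolution implements the transition-overlap rule", {
  log <- make_log(list("LEFT", 0, 10), list("RIGHT", 9.8, 20))
  tl <- resolve_timeline(log, tau_overlap = 0.4, trial_duration = 20)
  expect_equal(tl$label, c("GROUPED_H", "TRANSITION", "GROUPED_V"))
  expect_equal(tl$t_start, c(0, 9.8, 10))
  expect_equal(tl$t_end, c(9.8, 10, 20))
  expect_equal(
    unname(unlist(dominance_times(tl))),
    c(19.8, 0, 0, 0.2)
  )
  expect_equal(count_switches(tl), 1L)
  expect_equal(rivalry_rate(count_switches(tl), 20), 3)

  # a long both-press is the deliberate ungrouped percept
  long <- resolve_timeline(
    make_log(list("LEFT", 0, 10), list("RIGHT", 5, 30)),
    tau_overlap = 0.4, trial_duration = 30
  )
  expect_equal(long$label, c("GROUPED_H", "UNGROUPED", "GROUPED_V"))

  # a short both-press at the trial edge has no flank and stays ungrouped
  edge <- resolve_timeline(
    make_log(list("LEFT", 0, 0.2), list("RIGHT", 0, 0.2)),
    tau_overlap = 0.4, trial_duration = 10
  )
  expect_equal(edge$label, c("UNGROUPED", "UNREPORTED"))

  none <- resolve_timeline(
    tibble::tibble(button = character(), t_on = numeric(), t_off = numeric()),
    trial_duration = 60
  )
  expect_equal(nrow(none), 1L)
  expect_equal(none$label, "UNREPORTED")
  expect_equal(none$t_end, 60)
})

test_that("fuzzed timelines match the 1-ms grid-scan oracle", {
  set.seed(42)
  for (i in 1:300) {
    log <- fuzz_log()
    vl <- suppressWarnings(validate_log(log, trial_duration = 20))
    tl <- resolve_timeline(vl, tau_overlap = 0.4)
    oracle <- grid_scan_oracle(vl, 20, tau_overlap = 0.4)
    expect_equal(tl$label, oracle$label)
    expect_equal(tl$t_start, oracle$t_start, tolerance = 1e-9)
    expect_equal(tl$t_end, oracle$t_end, tolerance = 1e-9)
    # partition conservation
    expect_equal(sum(unlist(dominance_times(tl))), 20, tolerance = 1e-9)
  }
})

test_that("increasing the overlap threshold only moves time from ungrouped to transition", {
  set.seed(7)
  for (i in 1:50) {
    log <- suppressWarnings(validate_log(fuzz_log(), trial_duration = 20))
    taus <- c(0, 0.2, 0.4, 1, 5)
    d <- lapply(taus, function(tau) dominance_times(resolve_timeline(log, tau_overlap = tau)))
    grouped <- vapply(d, `[[`, numeric(1), "t_grouped")
    mixed <- vapply(d, `[[`, numeric(1), "t_mixed")
    trans <- vapply(d, `[[`, numeric(1), "t_transition")
    expect_true(all(abs(grouped - grouped[1]) < 1e-12))
    expect_true(all(abs(mixed - mixed[1]) < 1e-12))
    expect_true(all(diff(trans) >= -1e-12))
  }
  # tau_overlap = 0: no span is shorter than zero
  tl0 <- resolve_timeline(
    make_log(list("LEFT", 0, 10), list("RIGHT", 9.8, 20)),
    tau_overlap = 0, trial_duration = 20
  )
  expect_equal(dominance_times(tl0)$t_transition, 0)
})

test_that("switch counting ignores interludes and respects labels", {
  # H, unreported, H resumes: no switch
  tl <- resolve_timeline(
    make_log(list("LEFT", 0, 5), list("LEFT", 10, 20)),
    trial_duration = 20
  )
  expect_equal(count_switches(tl), 0L)
  # H, unreported, V: one switch regardless of gap length by default
  tl2 <- resolve_timeline(
    make_log(list("LEFT", 0, 5), list("RIGHT", 15, 20)),
    trial_duration = 20
  )
  expect_equal(count_switches(tl2), 1L)
  # but a finite tau_gap refuses to bridge the 10-s unreported span
  expect_equal(count_switches(tl2, tau_gap = 2), 0L)
  # all-mixed trial
  expect_equal(count_switches(resolve_timeline(make_log(), trial_duration = 60)), 0L)
})

test_that("simulated trials with a known alternation count are recovered exactly", {
  # 13 alternations built by construction: 14 exclusive periods
  n_periods <- 14L
  bounds <- seq(0, 60, length.out = n_periods + 1L)
  log <- tibble::tibble(
    button = rep(c("LEFT", "RIGHT"), length.out = n_periods),
    t_on = bounds[-length(bounds)],
    t_off = bounds[-1L]
  )
  tl <- resolve_timeline(log, trial_duration = 60)
  expect_equal(count_switches(tl), 13L)
  expect_equal(rivalry_rate(count_switches(tl), 60), 13)
  expect_equal(mean_epoch(dominance_times(tl)$t_grouped, 13L), 60 / 13)
})

test_that("mean epoch follows the grouped-time over switch-count definition", {
  expect_equal(mean_epoch(48, 12), 4)
  expect_equal(mean_epoch(0, 5), 0)
  expect_true(is.na(mean_epoch(10, 0)))
  expect_error(mean_epoch(-1, 3), "non-negative")
  # rate/epoch consistency on fuzzed logs
  set.seed(11)
  for (i in 1:50) {
    tl <- resolve_timeline(
      suppressWarnings(validate_log(fuzz_log(), trial_duration = 20))
    )
    n <- count_switches(tl)
    if (n > 0) {
      expect_equal(mean_epoch(dominance_times(tl)$t_grouped, n) * n,
        dominance_times(tl)$t_grouped,
        tolerance = 1e-12
      )
    }
  }
})

test_that("the epoch difference has the documented sign convention", {
  # within-hemifield epochs 48 ms longer: difference is negative
  expect_equal(epoch_difference(3.552, 3.6), -0.048)
  expect_equal(epoch_difference(2.5, 2.5), 0)
  # within-hemifield epochs 116 ms shorter: difference is positive
  expect_equal(epoch_difference(2.616, 2.5), 0.116)
  m1 <- tibble::tibble(mean_epoch = 4.1)
  m2 <- tibble::tibble(mean_epoch = 4.0)
  expect_equal(epoch_difference(m1, m2), 0.1)
  expect_true(is.na(epoch_difference(NA_real_, 3)))
})

test_that("per-condition aggregation averages counterbalanced pairs", {
  metrics <- tibble::tibble(
    participant_id = "P1",
    trial_id = 1:3,
    condition_id = c("MO_SE_SH", "MO_SE_SH", "CENTRAL"),
    trial_duration = 60,
    t_grouped = c(40, 44, 50), t_ungrouped = c(5, 3, 0),
    t_mixed = c(15, 13, 10), t_transition = c(0, 0, 0),
    t_both_total = c(5, 3, 0),
    n_switches = c(12, 14, 10), rivalry_rate = c(12, 14, 10),
    mean_epoch = c(40 / 12, 44 / 14, 5)
  )
  agg <- aggregate_by_condition(metrics)
  se <- agg[agg$condition_id == "MO_SE_SH", ]
  expect_equal(se$rivalry_rate, 13)
  expect_equal(se$t_grouped, 42)
  expect_equal(se$n_trials, 2L)
  central <- agg[agg$condition_id == "CENTRAL", ]
  expect_equal(central$rivalry_rate, 10)

  # a requested condition with no trials becomes a missing-data row
  agg2 <- aggregate_by_condition(metrics, conditions = c("MO_SE_SH", "MO_DE_SH"))
  expect_true(is.na(agg2$t_grouped[agg2$condition_id == "MO_DE_SH"]))
  expect_equal(agg2$n_trials[agg2$condition_id == "MO_DE_SH"], 0L)

  # an undefined epoch in one of the two trials does not poison the pair
  metrics$mean_epoch[2] <- NA_real_
  agg3 <- aggregate_by_condition(metrics)
  expect_equal(agg3$mean_epoch[agg3$condition_id == "MO_SE_SH"], 40 / 12)
})
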