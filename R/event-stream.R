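#' Validate and repair a raw button-press interval log
#'
#' A button log records, for one trial, the intervals during which each of
#' the two response buttons was held down (`LEFT` = both discs horizontal,
#' `RIGHT` = both vertical; both pressed = one of each; none = mixed
#' percept). Repairs performed silently would hide recording faults, so each
#' repair (clamping to the trial window, dropping empty intervals, merging
#' overlapping or adjacent same-button intervals) is collected into a
#' `repairs` attribute and reported once as a warning.
#'
#' @param log A data frame with columns `button` (`"LEFT"`/`"RIGHT"`),
#'   `t_on`, `t_off` (seconds); id columns (`participant_id`, `trial_id`,
#'   `condition_id`, `trial_duration`) are carried through if present and
#'   constant.
#' @param trial_duration Trial duration in seconds; defaults to the log's
#'   `trial_duration` column, else 60.
#' @return A `button_log` tibble sorted by `t_on`, with disjoint per-button
#'   intervals, and attributes `trial_duration` and `repairs`.
#' @export
#' @examples
#' validate_log(tibble::tibble(button = "LEFT", t_on = 2, t_off = 5))
validate_log <- function(log, trial_duration = NULL) {
  log <- as_tibble(log)
  needed <- c("button", "t_on", "t_off")
  missing_cols <- setdiff(needed, names(log))
  if (length(missing_cols)) {
    abort(sprintf("log is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  dur <- trial_duration %||%
    (if ("trial_duration" %in% names(log) && nrow(log)) log$trial_duration[[1]] else 60)
  if (!is.numeric(dur) || length(dur) != 1L || !is.finite(dur) || dur <= 0) {
    abort("`trial_duration` must be a single positive number.")
  }
  ids <- lapply(
    intersect(c("participant_id", "trial_id", "condition_id"), names(log)),
    function(nm) unique(log[[nm]])
  )
  names(ids) <- intersect(c("participant_id", "trial_id", "condition_id"), names(log))
  multi <- names(ids)[lengths(ids) > 1L]
  if (length(multi)) {
    abort(sprintf("log mixes several values of %s; pass one trial at a time.", paste(multi, collapse = ", ")))
  }

  bad_button <- which(!log$button %in% c("LEFT", "RIGHT"))
  if (length(bad_button)) {
    abort(sprintf("unknown button in row(s) %s", paste(bad_button, collapse = ", ")))
  }
  bad_order <- which(!is.finite(log$t_on) | !is.finite(log$t_off) | log$t_on >= log$t_off)
  if (length(bad_order)) {
    abort(sprintf("t_on >= t_off (or non-finite time) in row(s) %s", paste(bad_order, collapse = ", ")))
  }

  vc <- validate_core(log$button, log$t_on, log$t_off, dur)
  out <- tibble(
    button = rep(c("LEFT", "RIGHT"), c(length(vc$l_on), length(vc$r_on))),
    t_on = c(vc$l_on, vc$r_on),
    t_off = c(vc$l_off, vc$r_off)
  )
  out <- out[order(out$t_on, out$button), , drop = FALSE]
  repairs <- vc$repairs
  for (nm in names(ids)) out[[nm]] <- ids[[nm]][1L]
  out$trial_duration <- dur
  out <- dplyr::relocate(out, all_of(names(ids)))
  if (length(repairs)) {
    warn(paste0("log repaired: ", paste(repairs, collapse = "; ")))
  }
  attr(out, "trial_duration") <- dur
  attr(out, "repairs") <- repairs
  class(out) <- c("button_log", class(out))
  out
}

# Vector-level validation shared by validate_log() and analyze_logs():
# clamps times into [0, dur], drops empty intervals, merges per-button
# overlaps/adjacencies. Assumes buttons/ordering already checked.
validate_core <- function(button, t_on, t_off, dur) {
  repairs <- character()
  clamped <- which(t_on < 0 | t_off > dur)
  if (length(clamped)) {
    repairs <- c(repairs, sprintf(
      "clamped %d interval(s) to [0, %g] (row %s)",
      length(clamped), dur, paste(clamped, collapse = ", ")
    ))
    t_on <- pmax(t_on, 0)
    t_off <- pmin(t_off, dur)
  }
  keep <- t_off - t_on > 0
  if (any(!keep)) {
    repairs <- c(repairs, sprintf("dropped %d interval(s) empty after clamping", sum(!keep)))
  }
  sel_l <- keep & button == "LEFT"
  sel_r <- keep & button == "RIGHT"
  ml <- merge_intervals(t_on[sel_l], t_off[sel_l])
  mr <- merge_intervals(t_on[sel_r], t_off[sel_r])
  if (ml$n_merged > 0L) {
    repairs <- c(repairs, sprintf("merged %d overlapping/adjacent LEFT interval(s)", ml$n_merged))
  }
  if (mr$n_merged > 0L) {
    repairs <- c(repairs, sprintf("merged %d overlapping/adjacent RIGHT interval(s)", mr$n_merged))
  }
  list(
    l_on = ml$t_on, l_off = ml$t_off, r_on = mr$t_on, r_off = mr$t_off,
    repairs = repairs
  )
}

# Merge sorted-or-not intervals, fusing overlaps and exact adjacencies.
merge_intervals <- function(t_on, t_off) {
  if (length(t_on) == 0L) {
    return(list(t_on = numeric(), t_off = numeric(), n_merged = 0L))
  }
  o <- order(t_on, t_off)
  t_on <- t_on[o]
  t_off <- t_off[o]
  out_on <- t_on[1L]
  out_off <- t_off[1L]
  n_merged <- 0L
  for (i in seq_along(t_on)[-1L]) {
    j <- length(out_on)
    if (t_on[i] <= out_off[j]) {
      out_off[j] <- max(out_off[j], t_off[i])
      n_merged <- n_merged + 1L
    } else {
      out_on <- c(out_on, t_on[i])
      out_off <- c(out_off, t_off[i])
    }
  }
  list(t_on = out_on, t_off = out_off, n_merged = n_merged)
}

# Fast timeline core on plain vectors. Intervals per button must be disjoint
# and inside [0, dur]. Returns list(t_start, t_end, label) where label is a
# character vector over percept_levels.
timeline_core <- function(l_on, l_off, r_on, r_off, dur, tau_overlap) {
  cuts <- sort(unique(c(0, dur, l_on, l_off, r_on, r_off)))
  cuts <- cuts[cuts >= 0 & cuts <= dur]
  mid <- (cuts[-length(cuts)] + cuts[-1L]) / 2
  in_left <- pressed_at(mid, l_on, l_off)
  in_right <- pressed_at(mid, r_on, r_off)
  state <- 1L * in_left + 2L * in_right # 0 none, 1 left, 2 right, 3 both
  r <- rle(state)
  ends <- cuts[cumsum(r$lengths) + 1L]
  starts <- c(0, ends[-length(ends)])
  lab <- c("UNREPORTED", "GROUPED_H", "GROUPED_V", "BOTH")[r$values + 1L]
  both <- which(lab == "BOTH")
  for (i in both) {
    short <- (ends[i] - starts[i]) < tau_overlap
    flanked <- i > 1L && i < length(lab) &&
      lab[i - 1L] %in% c("GROUPED_H", "GROUPED_V") &&
      lab[i + 1L] %in% c("GROUPED_H", "GROUPED_V") &&
      lab[i - 1L] != lab[i + 1L]
    lab[i] <- if (short && flanked) "TRANSITION" else "UNGROUPED"
  }
  list(t_start = starts, t_end = ends, label = lab)
}

# Membership of points in a union of disjoint sorted intervals [on, off).
pressed_at <- function(x, t_on, t_off) {
  if (length(t_on) == 0L) {
    return(rep(FALSE, length(x)))
  }
  bounds <- as.numeric(rbind(t_on, t_off))
  findInterval(x, bounds) %% 2L == 1L
}

#' Resolve a button log into a labelled percept timeline
#'
#' Partitions the trial `[0, trial_duration]` exhaustively into intervals
#' labelled `GROUPED_H` (exclusive left press), `GROUPED_V` (exclusive right
#' press), `UNGROUPED` (sustained both-press), `UNREPORTED` (no press;
#' mixed/piecemeal percept), and `TRANSITION`. A both-pressed span counts as
#' a transition wave -- and is excluded from dominance-epoch accounting --
#' only when it is shorter than `tau_overlap` and immediately flanked by the
#' two different exclusive percepts; this preserves deliberate sustained
#' both-presses (the ungrouped percept) while removing the brief motor
#' overlap that marks a dominance change.
#'
#' @param log A button log (validated with [validate_log()]; unvalidated
#'   data frames are validated on the fly).
#' @param tau_overlap Maximum duration (s) of a both-press span that can be
#'   read as a transition wave. Default 0.4.
#' @param tau_gap Optional strictness knob carried to [count_switches()]:
#'   the longest non-exclusive gap (s) across which a dominance change still
#'   counts as a switch. Default `Inf` (gap length ignored).
#' @param trial_duration Override for the trial duration in seconds.
#' @return A `percept_timeline` tibble with columns `t_start`, `t_end`,
#'   `label`; intervals partition the trial exactly and adjacent intervals
#'   have distinct labels.
#' @export
#' @examples
#' log <- tibble::tibble(
#'   button = c("LEFT", "RIGHT"), t_on = c(0, 9.8), t_off = c(10, 20)
#' )
#' resolve_timeline(log, trial_duration = 20)
resolve_timeline <- function(log, tau_overlap = 0.4, tau_gap = Inf,
                             trial_duration = NULL) {
  check_number(tau_overlap, "tau_overlap", lower = 0)
  if (!(is.numeric(tau_gap) && length(tau_gap) == 1L && !is.na(tau_gap) && tau_gap >= 0)) {
    abort("`tau_gap` must be a single non-negative number (Inf allowed).")
  }
  if (!inherits(log, "button_log")) {
    log <- validate_log(log, trial_duration = trial_duration)
  }
  dur <- trial_duration %||% attr(log, "trial_duration")
  core <- timeline_core(
    log$t_on[log$button == "LEFT"], log$t_off[log$button == "LEFT"],
    log$t_on[log$button == "RIGHT"], log$t_off[log$button == "RIGHT"],
    dur, tau_overlap
  )
  out <- tibble(t_start = core$t_start, t_end = core$t_end, label = core$label)
  for (nm in intersect(c("participant_id", "trial_id", "condition_id"), names(log))) {
    attr(out, nm) <- log[[nm]][1L]
  }
  attr(out, "trial_duration") <- dur
  attr(out, "tau_overlap") <- tau_overlap
  attr(out, "tau_gap") <- tau_gap
  class(out) <- c("percept_timeline", class(out))
  out
}

#' Dominance times of a percept timeline
#'
#' Sums interval lengths by label class: `t_grouped` is the cumulative time
#' of exclusive dominance of the grouped percept (horizontal plus vertical),
#' `t_ungrouped` the sustained both-press time, `t_mixed` the unreported
#' (mixed/piecemeal) time, and `t_transition` the excluded transition-wave
#' time. The four components sum to the trial duration.
#'
#' @param timeline A `percept_timeline`.
#' @return A one-row tibble with `t_grouped`, `t_ungrouped`, `t_mixed`,
#'   `t_transition`.
#' @export
dominance_times <- function(timeline) {
  len <- timeline$t_end - timeline$t_start
  lab <- timeline$label
  tibble(
    t_grouped = sum(len[lab %in% c("GROUPED_H", "GROUPED_V")]),
    t_ungrouped = sum(len[lab == "UNGROUPED"]),
    t_mixed = sum(len[lab == "UNREPORTED"]),
    t_transition = sum(len[lab == "TRANSITION"])
  )
}

#' Count perceptual switches in a timeline
#'
#' A switch is each change of percept in the sequence of exclusive-dominance
#' labels (`GROUPED_H`/`GROUPED_V`) after deleting all non-exclusive
#' intervals; a same-orientation percept resuming after a mixed interlude is
#' not a switch. With a finite `tau_gap`, changes separated by a
#' non-exclusive gap longer than `tau_gap` seconds are not counted.
#'
#' @param timeline A `percept_timeline`.
#' @param tau_gap Longest bridgeable gap (s); default taken from the
#'   timeline attribute (itself `Inf` unless set in [resolve_timeline()]).
#' @return Integer switch count.
#' @export
count_switches <- function(timeline, tau_gap = NULL) {
  tau_gap <- tau_gap %||% attr(timeline, "tau_gap") %||% Inf
  excl <- timeline$label %in% c("GROUPED_H", "GROUPED_V")
  lab <- timeline$label[excl]
  if (length(lab) < 2L) {
    return(0L)
  }
  gaps <- timeline$t_start[excl][-1L] - timeline$t_end[excl][-sum(excl)]
  sum(lab[-1L] != lab[-length(lab)] & gaps <= tau_gap)
}

#' Rivalry rate in switches per minute
#'
#' @param n_switches Switch count for the trial.
#' @param trial_duration Trial duration in seconds (default 60).
#' @return `n_switches * 60 / trial_duration`, the number of perceptual
#'   switches per minute.
#' @export
rivalry_rate <- function(n_switches, trial_duration = 60) {
  if (any(n_switches < 0) || any(trial_duration <= 0)) {
    abort("`n_switches` must be >= 0 and `trial_duration` > 0.")
  }
  n_switches * 60 / trial_duration
}

#' Mean epoch of exclusive grouped dominance
#'
#' The mean duration of one exclusive-dominance period of the grouped
#' percept: cumulative grouped time divided by the switch count. For a 60-s
#' trial this equals the grouped time divided by the per-minute rivalry
#' rate; using the raw switch count keeps the definition valid for other
#' trial durations. Undefined (NA) when no switches occurred.
#'
#' @param t_grouped Cumulative exclusive grouped-dominance time (s).
#' @param n_switches Switch count. Vectorised with `t_grouped`.
#' @return Mean epoch in seconds; `NA` where `n_switches` is 0.
#' @export
#' @examples
#' mean_epoch(48, 12) # 4
mean_epoch <- function(t_grouped, n_switches) {
  if (any(t_grouped < 0, na.rm = TRUE) || any(n_switches < 0, na.rm = TRUE)) {
    abort("`t_grouped` and `n_switches` must be non-negative.")
  }
  ifelse(n_switches == 0, NA_real_, t_grouped / n_switches)
}

#' Between- minus within-hemifield epoch difference
#'
#' The per-participant difference statistic `d_epoch = mean_epoch(MO SE/DH)
#' - mean_epoch(MO SE/SH)`: positive when the between-hemifield epochs are
#' longer. An undefined epoch on either side propagates as `NA`.
#'
#' @param metrics_se_dh,metrics_se_sh Either numeric mean epochs (s) or
#'   one-row metric tables containing a `mean_epoch` column.
#' @return The difference in seconds.
#' @export
#' @examples
#' epoch_difference(3.552, 3.6) # -0.048: within-hemifield epochs longer
epoch_difference <- function(metrics_se_dh, metrics_se_sh) {
  pull_epoch <- function(x) {
    if (is.data.frame(x)) {
      if (!"mean_epoch" %in% names(x)) abort("metric tables must have a `mean_epoch` column.")
      x$mean_epoch
    } else if (is.numeric(x)) {
      x
    } else {
      abort("epoch inputs must be numeric or metric tables.")
    }
  }
  pull_epoch(metrics_se_dh) - pull_epoch(metrics_se_sh)
}

# Metrics for one trial from plain interval vectors; returns a named numeric
# vector. Kept free of tibble overhead for use in cohort-scale loops.
trial_metrics_core <- function(l_on, l_off, r_on, r_off, dur, tau_overlap, tau_gap) {
  tl <- timeline_core(l_on, l_off, r_on, r_off, dur, tau_overlap)
  len <- tl$t_end - tl$t_start
  lab <- tl$label
  t_grouped <- sum(len[lab == "GROUPED_H" | lab == "GROUPED_V"])
  t_ungrouped <- sum(len[lab == "UNGROUPED"])
  t_mixed <- sum(len[lab == "UNREPORTED"])
  t_transition <- sum(len[lab == "TRANSITION"])
  excl <- lab == "GROUPED_H" | lab == "GROUPED_V"
  elab <- lab[excl]
  n_sw <- if (length(elab) < 2L) {
    0L
  } else {
    gaps <- tl$t_start[excl][-1L] - tl$t_end[excl][-length(elab)]
    sum(elab[-1L] != elab[-length(elab)] & gaps <= tau_gap)
  }
  c(
    t_grouped = t_grouped, t_ungrouped = t_ungrouped, t_mixed = t_mixed,
    t_transition = t_transition, t_both_total = t_ungrouped + t_transition,
    n_switches = n_sw, rivalry_rate = n_sw * 60 / dur,
    mean_epoch = if (n_sw == 0L) NA_real_ else t_grouped / n_sw
  )
}

#' Outcome metrics for one trial
#'
#' Combines [dominance_times()], [count_switches()], [rivalry_rate()] and
#' [mean_epoch()] into one row. `t_both_total` (= `t_ungrouped` +
#' `t_transition`) is the raw "both buttons pressed" total, exported for
#' audit because the transition share is excluded from the ungrouped
#' account.
#'
#' @param timeline A `percept_timeline`.
#' @return A one-row tibble of metrics with any id attributes
#'   (`participant_id`, `trial_id`, `condition_id`) restored as columns.
#' @export
trial_metrics <- function(timeline) {
  dur <- attr(timeline, "trial_duration")
  dt <- dominance_times(timeline)
  n_sw <- count_switches(timeline)
  out <- mutate(dt,
    t_both_total = .data$t_ungrouped + .data$t_transition,
    n_switches = n_sw,
    rivalry_rate = rivalry_rate(n_sw, dur),
    mean_epoch = mean_epoch(.data$t_grouped, n_sw),
    trial_duration = dur
  )
  ids <- intersect(c("participant_id", "trial_id", "condition_id"), names(attributes(timeline)))
  if (length(ids)) {
    idtb <- as_tibble(setNames(lapply(ids, function(nm) attr(timeline, nm)), ids))
    out <- dplyr::bind_cols(idtb, out)
  }
  out
}

#' Per-trial metrics for a table of event logs
#'
#' Validates and analyses every `(participant_id, trial_id)` trial found in
#' a flat event-log table (the file schema of [read_event_logs()]).
#'
#' @param logs A data frame with columns `participant_id`, `trial_id`,
#'   `condition_id`, `button`, `t_on`, `t_off`, `trial_duration`.
#' @param tau_overlap,tau_gap Timeline parameters, see [resolve_timeline()].
#' @return A tibble with one row per trial and all [trial_metrics()]
#'   columns.
#' @export
analyze_logs <- function(logs, tau_overlap = 0.4, tau_gap = Inf) {
  logs <- as_tibble(logs)
  needed <- c("participant_id", "trial_id", "condition_id", "button", "t_on", "t_off", "trial_duration")
  missing_cols <- setdiff(needed, names(logs))
  if (length(missing_cols)) {
    abort(sprintf("`logs` is missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  bad_button <- which(!logs$button %in% c("LEFT", "RIGHT"))
  if (length(bad_button)) {
    abort(sprintf("unknown button in row(s) %s", paste(bad_button, collapse = ", ")))
  }
  bad_order <- which(!is.finite(logs$t_on) | !is.finite(logs$t_off) | logs$t_on >= logs$t_off)
  if (length(bad_order)) {
    abort(sprintf("t_on >= t_off (or non-finite time) in row(s) %s", paste(bad_order, collapse = ", ")))
  }
  if (any(!is.finite(logs$trial_duration) | logs$trial_duration <= 0)) {
    abort("`trial_duration` must be positive for every row.")
  }

  key <- paste(logs$participant_id, logs$trial_id, sep = "\r")
  idx <- split(seq_len(nrow(logs)), factor(key, levels = unique(key)))
  n_trials <- length(idx)
  metric_names <- c(
    "t_grouped", "t_ungrouped", "t_mixed", "t_transition",
    "t_both_total", "n_switches", "rivalry_rate", "mean_epoch"
  )
  mm <- matrix(NA_real_, nrow = n_trials, ncol = length(metric_names))
  first <- integer(n_trials)
  durs <- numeric(n_trials)
  all_repairs <- character()
  for (i in seq_len(n_trials)) {
    rows <- idx[[i]]
    first[i] <- rows[1L]
    dur <- logs$trial_duration[rows[1L]]
    durs[i] <- dur
    vc <- validate_core(logs$button[rows], logs$t_on[rows], logs$t_off[rows], dur)
    if (length(vc$repairs)) {
      all_repairs <- c(all_repairs, sprintf(
        "trial (%s, %s): %s", logs$participant_id[rows[1L]], logs$trial_id[rows[1L]],
        paste(vc$repairs, collapse = "; ")
      ))
    }
    mm[i, ] <- trial_metrics_core(
      vc$l_on, vc$l_off, vc$r_on, vc$r_off, dur, tau_overlap, tau_gap
    )
  }
  if (length(all_repairs)) {
    warn(paste0("log repaired: ", paste(all_repairs, collapse = " | ")))
  }
  out <- tibble(
    participant_id = logs$participant_id[first],
    trial_id = logs$trial_id[first],
    condition_id = logs$condition_id[first],
    trial_duration = durs
  )
  colnames(mm) <- metric_names
  dplyr::bind_cols(out, as_tibble(mm))
}

#' Average per-trial metrics over counterbalanced trial pairs
#'
#' Each logical condition is run as two counterbalanced trials; the outcome
#' measures are averaged per condition for each participant. Single-trial
#' conditions (the central control) pass through; a requested condition with
#' no trials yields an `NA` row. `mean_epoch` is averaged over the trials
#' where it is defined and is `NA` only when no trial of the condition had a
#' switch.
#'
#' @param metrics Per-trial metrics from [analyze_logs()].
#' @param conditions Optional character vector of condition ids every
#'   participant must be reported for; missing combinations become `NA`
#'   rows.
#' @return A tibble with one row per participant x condition, the arithmetic
#'   mean of each metric over its trials, and `n_trials`.
#' @export
aggregate_by_condition <- function(metrics, conditions = NULL) {
  metric_cols <- c(
    "t_grouped", "t_ungrouped", "t_mixed", "t_transition",
    "t_both_total", "n_switches", "rivalry_rate", "mean_epoch"
  )
  out <- metrics |>
    group_by(.data$participant_id, .data$condition_id) |>
    summarise(
      across(all_of(setdiff(metric_cols, "mean_epoch")), \(x) mean(x)),
      # a trial without switches has no defined epoch; average over the
      # trials where it exists, undefined only if none had a switch
      mean_epoch = if (all(is.na(.data$mean_epoch))) NA_real_ else mean(.data$mean_epoch, na.rm = TRUE),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  if (!is.null(conditions)) {
    out <- tidyr::complete(
      out,
      participant_id = unique(out$participant_id),
      condition_id = conditions
    )
    out <- filter(out, .data$condition_id %in% conditions)
    out$n_trials[is.na(out$n_trials)] <- 0L
  }
  out
}
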