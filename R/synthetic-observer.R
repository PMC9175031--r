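#' Parameters of a synthetic rivalry observer
#'
#' The observer is a coupled two-zone rivalry renewal process plus a motor
#' layer. Each rivalry zone (one disc position) holds an eye-dominance
#' state whose durations are Gamma distributed; at each zone renewal the
#' zone adopts the other zone's currently dominant eye with probability
#' `eye_coupling`, else the opposite eye, so `eye_coupling = 1` yields fully
#' synchronised eye dominance (perceptual grouping by eye of origin) and
#' `eye_coupling = 0.5` makes the zones independent. Renewals may pass
#' through a mixed (piecemeal) interlude. The motor layer turns latent
#' percepts into button presses with press latency, a brief both-pressed
#' overlap at each dominance change, and occasional report lapses.
#'
#' @param epoch_gamma_shape Shape of the Gamma dominance-duration
#'   distribution (dimensionless, > 0). Default 3, a conventional choice
#'   for rivalry dominance durations.
#' @param epoch_mean Mean zone dominance duration (s). Default 3.2.
#' @param mixed_prob Probability that a renewal passes through a mixed
#'   interlude. Default 0.2.
#' @param mixed_mean Mean mixed-interlude duration (s, exponential).
#'   Default 1.5.
#' @param eye_coupling Probability that a renewing zone adopts the other
#'   zone's dominant eye. Default 0.92.
#' @param press_latency_mean,press_latency_sd Motor latency of each report
#'   boundary (s; normal truncated at 0). Defaults 0.35 and 0.1.
#' @param overlap_mean,overlap_sd Both-pressed overlap at each dominance
#'   change (s; normal truncated at 0). Defaults 0.15 and 0.05.
#' @param lapse_prob Probability that an exclusive dominance period goes
#'   unreported. Default 0.03.
#' @return An `observer_params` list.
#' @export
observer_params <- function(epoch_gamma_shape = 3,
                            epoch_mean = 3.2,
                            mixed_prob = 0.2,
                            mixed_mean = 1.5,
                            eye_coupling = 0.92,
                            press_latency_mean = 0.35,
                            press_latency_sd = 0.1,
                            overlap_mean = 0.15,
                            overlap_sd = 0.05,
                            lapse_prob = 0.03) {
  check_number(epoch_gamma_shape, "epoch_gamma_shape", lower = 1e-9)
  check_number(epoch_mean, "epoch_mean", lower = 1e-9)
  check_number(mixed_prob, "mixed_prob", lower = 0, upper = 1)
  check_number(mixed_mean, "mixed_mean", lower = 1e-9)
  check_number(eye_coupling, "eye_coupling", lower = 0, upper = 1)
  check_number(press_latency_mean, "press_latency_mean", lower = 0)
  check_number(press_latency_sd, "press_latency_sd", lower = 0)
  check_number(overlap_mean, "overlap_mean", lower = 0)
  check_number(overlap_sd, "overlap_sd", lower = 0)
  check_number(lapse_prob, "lapse_prob", lower = 0, upper = 1)
  structure(
    list(
      epoch_gamma_shape = epoch_gamma_shape, epoch_mean = epoch_mean,
      mixed_prob = mixed_prob, mixed_mean = mixed_mean,
      eye_coupling = eye_coupling,
      press_latency_mean = press_latency_mean, press_latency_sd = press_latency_sd,
      overlap_mean = overlap_mean, overlap_sd = overlap_sd,
      lapse_prob = lapse_prob
    ),
    class = "observer_params"
  )
}

resolve_condition_layout <- function(condition, variant = 1L) {
  if (is.character(condition) && length(condition) == 1L) {
    return(condition_layout(condition, variant))
  }
  if (is.data.frame(condition)) {
    needed <- c("condition_id", "eye", "position", "orientation")
    if (!all(needed %in% names(condition))) {
      abort("`condition` must have columns condition_id, eye, position, orientation.")
    }
    if (length(unique(condition$condition_id)) != 1L) {
      abort("`condition` must describe a single trial.")
    }
    return(condition)
  }
  abort("`condition` must be a condition id string or a layout table.")
}

#' Simulate the latent percept process for one trial
#'
#' Runs the coupled two-zone renewal process under a given trial layout and
#' returns the latent percept timeline, labelled `GROUPED_H`/`GROUPED_V`
#' (the two zone percepts share an orientation), `UNGROUPED` (they differ)
#' or `MIXED` (piecemeal interlude). The `CENTRAL` condition degenerates to
#' a single zone whose exclusive percepts carry the `GROUPED_*` labels
#' (classical rivalry maps to the same two buttons).
#'
#' @param params An [observer_params()] list.
#' @param condition A condition id (see [condition_layout()]) or a layout
#'   table for one trial.
#' @param duration Trial duration in seconds. Default 60.
#' @param seed Optional integer seed (caller RNG preserved); `NULL` uses
#'   the current RNG stream.
#' @param variant Counterbalance variant when `condition` is an id.
#' @return A `latent_timeline` tibble (`t_start`, `t_end`, `label`)
#'   partitioning the trial.
#' @export
simulate_latent_process <- function(params, condition, duration = 60,
                                    seed = NULL, variant = 1L) {
  stopifnot(inherits(params, "observer_params"))
  check_number(duration, "duration", lower = 1e-9)
  layout <- resolve_condition_layout(condition, variant)
  with_seed(seed, {
    zones <- unique(layout$position)
    nz <- length(zones)
    # orientation shown in zone z by eye e (1 = left, 2 = right)
    ori <- matrix("", nrow = nz, ncol = 2L, dimnames = list(zones, c("left", "right")))
    for (i in seq_len(nrow(layout))) {
      ori[layout$position[i], layout$eye[i]] <- layout$orientation[i]
    }
    if (any(ori == "")) abort("layout does not cover every zone x eye cell.")

    shape <- params$epoch_gamma_shape
    scale <- params$epoch_mean / shape
    cpl <- params$eye_coupling

    state <- integer(nz) # 1 = left eye dominant, 2 = right eye dominant
    state[1L] <- sample(1:2, 1L)
    if (nz == 2L) {
      state[2L] <- if (runif(1) < cpl) state[1L] else 3L - state[1L]
    }
    nxt <- rgamma(nz, shape = shape, scale = scale)

    chg_t <- vector("list", nz) # per-zone eye-change times
    chg_s <- vector("list", nz)
    for (z in seq_len(nz)) {
      chg_t[[z]] <- 0
      chg_s[[z]] <- state[z]
    }
    mix_on <- numeric()
    mix_off <- numeric()
    while (min(nxt) < duration) {
      j <- which.min(nxt)
      tj <- nxt[j]
      new_eye <- if (nz == 1L) {
        3L - state[1L]
      } else if (runif(1) < cpl) {
        state[3L - j]
      } else {
        3L - state[3L - j]
      }
      if (new_eye != state[j]) {
        state[j] <- new_eye
        chg_t[[j]] <- c(chg_t[[j]], tj)
        chg_s[[j]] <- c(chg_s[[j]], new_eye)
      }
      if (runif(1) < params$mixed_prob) {
        mix_on <- c(mix_on, tj)
        mix_off <- c(mix_off, tj + rexp(1, rate = 1 / params$mixed_mean))
      }
      nxt[j] <- tj + rgamma(1, shape = shape, scale = scale)
    }

    mix <- merge_intervals(pmax(mix_on, 0), pmin(mix_off, duration))
    cuts <- sort(unique(c(
      0, duration, unlist(chg_t), mix$t_on, mix$t_off
    )))
    cuts <- cuts[cuts >= 0 & cuts <= duration]
    mid <- (cuts[-length(cuts)] + cuts[-1L]) / 2
    eye_at <- function(z) chg_s[[z]][findInterval(mid, chg_t[[z]])]
    o1 <- ori[1L, ][eye_at(1L)]
    lab <- if (nz == 2L) {
      o2 <- ori[2L, ][eye_at(2L)]
      ifelse(o1 == o2, paste0("GROUPED_", o1), "UNGROUPED")
    } else {
      paste0("GROUPED_", o1)
    }
    lab[pressed_at(mid, mix$t_on, mix$t_off)] <- "MIXED"
    r <- rle(unname(lab))
    ends <- cuts[cumsum(r$lengths) + 1L]
    out <- tibble(
      t_start = c(0, ends[-length(ends)]),
      t_end = ends,
      label = r$values
    )
    attr(out, "trial_duration") <- duration
    attr(out, "condition_id") <- layout$condition_id[1L]
    class(out) <- c("latent_timeline", class(out))
    out
  })
}

truncnorm0 <- function(n, mean, sd) pmax(0, rnorm(n, mean, sd))

#' Render a latent percept timeline as a button-press log
#'
#' Applies the motor layer: every reported percept period becomes the
#' corresponding press pattern (left button for grouped-horizontal, right
#' for grouped-vertical, both for ungrouped, none for mixed); each report
#' boundary is shifted by a press-latency draw; at each dominance change
#' the newly pressed button precedes the released button by an overlap draw
#' (truncated at 0), producing the brief both-pressed transition span; and
#' exclusive dominance periods lapse unreported with probability
#' `lapse_prob`. With zero latency, overlap and lapse the log reproduces
#' the latent timeline exactly.
#'
#' @param latent A `latent_timeline` from [simulate_latent_process()].
#' @param params An [observer_params()] list.
#' @param seed Optional integer seed; `NULL` uses the current RNG stream.
#' @return A tibble (`button`, `t_on`, `t_off`) with disjoint per-button
#'   intervals and a `trial_duration` attribute.
#' @export
render_button_log <- function(latent, params, seed = NULL) {
  stopifnot(inherits(params, "observer_params"))
  dur <- attr(latent, "trial_duration")
  with_seed(seed, {
    k <- nrow(latent)
    sets <- lapply(latent$label, function(l) {
      switch(l,
        GROUPED_H = "LEFT",
        GROUPED_V = "RIGHT",
        UNGROUPED = c("LEFT", "RIGHT"),
        MIXED = character()
      )
    })
    excl <- latent$label %in% c("GROUPED_H", "GROUPED_V")
    lapses <- runif(k) < params$lapse_prob
    for (i in which(excl & lapses)) sets[[i]] <- character()

    # perturbed run boundaries b'_0..b'_k (b'_k pinned at trial end)
    b <- c(latent$t_start, dur)
    lat <- truncnorm0(k, params$press_latency_mean, params$press_latency_sd)
    bp <- c(b[seq_len(k)] + lat, dur)
    bp <- pmin(cummax(bp), dur)

    # overlap extensions at dominance-change boundaries (run i -> run i+1)
    ext <- numeric(k)
    for (i in seq_len(k - 1L)) {
      a <- sets[[i]]
      nx <- sets[[i + 1L]]
      if (length(a) && length(nx) && !setequal(a, nx) && length(setdiff(a, nx))) {
        ext[i] <- truncnorm0(1L, params$overlap_mean, params$overlap_sd)
      }
    }

    ints <- list(LEFT = list(on = numeric(), off = numeric()),
                 RIGHT = list(on = numeric(), off = numeric()))
    for (i in seq_len(k)) {
      a <- sets[[i]]
      if (!length(a)) next
      nx <- if (i < k) sets[[i + 1L]] else character()
      for (btn in a) {
        off <- bp[i + 1L]
        if (ext[i] > 0 && !(btn %in% nx)) off <- min(dur, off + ext[i])
        ints[[btn]]$on <- c(ints[[btn]]$on, bp[i])
        ints[[btn]]$off <- c(ints[[btn]]$off, off)
      }
    }
    ml <- merge_intervals(ints$LEFT$on, ints$LEFT$off)
    mr <- merge_intervals(ints$RIGHT$on, ints$RIGHT$off)
    kl <- ml$t_off - ml$t_on > 0
    kr <- mr$t_off - mr$t_on > 0
    button <- rep(c("LEFT", "RIGHT"), c(sum(kl), sum(kr)))
    t_on <- c(ml$t_on[kl], mr$t_on[kr])
    t_off <- c(ml$t_off[kl], mr$t_off[kr])
    o <- order(t_on, button)
    out <- tibble(button = button[o], t_on = t_on[o], t_off = t_off[o])
    attr(out, "trial_duration") <- dur
    out
  })
}

#' Simulate one trial end to end
#'
#' @inheritParams simulate_latent_process
#' @param keep_latent Attach the latent timeline as attribute `latent`?
#' @return A button-log tibble as from [render_button_log()].
#' @export
simulate_trial <- function(params, condition, duration = 60, seed = NULL,
                           variant = 1L, keep_latent = FALSE) {
  with_seed(seed, {
    latent <- simulate_latent_process(params, condition, duration, seed = NULL, variant = variant)
    log <- render_button_log(latent, params, seed = NULL)
    if (isTRUE(keep_latent)) attr(log, "latent") <- latent
    log
  })
}

#' Configuration of a simulated two-group cohort
#'
#' Defaults emulate the study conditions: 17 glaucoma and 14 control
#' participants, 9 trials each (8 counterbalanced grouping trials plus a
#' central control) of 60 s. Group differences are injected only through
#' the mean zone dominance duration (`epoch_mean`): glaucoma observers have
#' longer epochs, hence lower rivalry rates; all other observer parameters
#' are shared. The defaults are calibrated so the central-condition rates
#' approximate 13 (glaucoma) and 17 (control) switches/min and the grouped
#' dominance time in same-eye conditions approximates 47-49 s per 60-s
#' trial.
#'
#' @param n_glaucoma,n_control Group sizes (defaults 17 and 14).
#' @param epoch_mean_glaucoma,epoch_mean_control Group means of
#'   `epoch_mean` (s). Defaults 3.7 and 2.9.
#' @param epoch_mean_sd Between-observer SD of `epoch_mean` (s).
#'   Default 0.6.
#' @param age_mean_glaucoma,age_sd_glaucoma,age_mean_control,age_sd_control
#'   Age distributions (years). Defaults 61 +/- 12 and 53 +/- 11.
#' @param base_params Shared [observer_params()]; each observer inherits
#'   these with a group-specific `epoch_mean` draw.
#' @param trial_duration Trial duration (s). Default 60.
#' @param seed Master seed for the hierarchical seed derivation.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_glaucoma = 17, n_control = 14,
                          epoch_mean_glaucoma = 3.7, epoch_mean_control = 2.9,
                          epoch_mean_sd = 0.6,
                          age_mean_glaucoma = 61, age_sd_glaucoma = 12,
                          age_mean_control = 53, age_sd_control = 11,
                          base_params = observer_params(),
                          trial_duration = 60,
                          seed = 1L) {
  check_number(n_glaucoma, "n_glaucoma", lower = 1)
  check_number(n_control, "n_control", lower = 1)
  check_number(epoch_mean_glaucoma, "epoch_mean_glaucoma", lower = 1e-9)
  check_number(epoch_mean_control, "epoch_mean_control", lower = 1e-9)
  check_number(epoch_mean_sd, "epoch_mean_sd", lower = 0)
  check_number(age_mean_glaucoma, "age_mean_glaucoma", lower = 0)
  check_number(age_sd_glaucoma, "age_sd_glaucoma", lower = 0)
  check_number(age_mean_control, "age_mean_control", lower = 0)
  check_number(age_sd_control, "age_sd_control", lower = 0)
  check_number(trial_duration, "trial_duration", lower = 1e-9)
  check_number(seed, "seed")
  stopifnot(inherits(base_params, "observer_params"))
  structure(
    list(
      n_glaucoma = as.integer(n_glaucoma), n_control = as.integer(n_control),
      epoch_mean_glaucoma = epoch_mean_glaucoma,
      epoch_mean_control = epoch_mean_control,
      epoch_mean_sd = epoch_mean_sd,
      age_mean_glaucoma = age_mean_glaucoma, age_sd_glaucoma = age_sd_glaucoma,
      age_mean_control = age_mean_control, age_sd_control = age_sd_control,
      base_params = base_params,
      trial_duration = trial_duration,
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a full cohort of button logs
#'
#' For each participant, draws observer parameters from the group
#' distribution, shuffles the 9-trial catalog, and simulates every trial.
#' Seeds are derived hierarchically (master seed -> participant seeds ->
#' trial seeds), so a fixed master seed reproduces the cohort exactly.
#'
#' @param config A [cohort_config()].
#' @return A `rivalry_cohort` list with elements `logs` (flat event-log
#'   tibble in the file schema), `metadata` (`participant_id`, `group`,
#'   `age`, `seed`) and `params` (per-participant observer parameters).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  catalog <- build_condition_set(include_central = TRUE)
  n_total <- config$n_glaucoma + config$n_control
  groups <- rep(group_levels, c(config$n_glaucoma, config$n_control))
  p_ids <- c(
    sprintf("G%02d", seq_len(config$n_glaucoma)),
    sprintf("C%02d", seq_len(config$n_control))
  )
  p_seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L, n_total))

  logs <- vector("list", n_total)
  meta <- vector("list", n_total)
  ptab <- vector("list", n_total)
  n_trials <- length(unique(catalog$trial))
  for (i in seq_len(n_total)) {
    g <- groups[i]
    res <- with_seed(p_seeds[i], {
      mu0 <- if (g == "glaucoma") config$epoch_mean_glaucoma else config$epoch_mean_control
      epoch_mu <- max(0.8, rnorm(1, mu0, config$epoch_mean_sd))
      age <- round(rnorm(
        1,
        if (g == "glaucoma") config$age_mean_glaucoma else config$age_mean_control,
        if (g == "glaucoma") config$age_sd_glaucoma else config$age_sd_control
      ))
      trial_order <- sample(unique(catalog$trial))
      trial_seeds <- sample.int(.Machine$integer.max - 1L, n_trials)
      list(epoch_mu = epoch_mu, age = age, trial_order = trial_order, trial_seeds = trial_seeds)
    })
    pars <- modifyList(unclass(config$base_params), list(epoch_mean = res$epoch_mu))
    pars <- do.call(observer_params, pars)
    trial_logs <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      layout <- catalog[catalog$trial == res$trial_order[t], , drop = FALSE]
      log <- simulate_trial(pars, layout, duration = config$trial_duration, seed = res$trial_seeds[t])
      trial_logs[[t]] <- list(
        trial_id = rep(t, nrow(log)),
        condition_id = rep(layout$condition_id[1L], nrow(log)),
        button = log$button, t_on = log$t_on, t_off = log$t_off
      )
    }
    logs[[i]] <- tibble(
      participant_id = p_ids[i],
      trial_id = unlist(lapply(trial_logs, `[[`, "trial_id")),
      condition_id = unlist(lapply(trial_logs, `[[`, "condition_id")),
      button = unlist(lapply(trial_logs, `[[`, "button")),
      t_on = unlist(lapply(trial_logs, `[[`, "t_on")),
      t_off = unlist(lapply(trial_logs, `[[`, "t_off")),
      trial_duration = config$trial_duration
    )
    meta[[i]] <- tibble(
      participant_id = p_ids[i], group = g, age = res$age, seed = p_seeds[i]
    )
    ptab[[i]] <- dplyr::bind_cols(
      tibble(participant_id = p_ids[i], group = g),
      as_tibble(unclass(pars))
    )
  }
  out <- list(
    logs = dplyr::relocate(
      bind_rows(logs),
      "participant_id", "trial_id", "condition_id", "button", "t_on", "t_off", "trial_duration"
    ),
    metadata = bind_rows(meta),
    params = bind_rows(ptab)
  )
  class(out) <- "rivalry_cohort"
  out
}

#' @export
print.rivalry_cohort <- function(x, ...) {
  cat(sprintf(
    "<rivalry_cohort> %d participants (%s), %d trials, %d press intervals\n",
    nrow(x$metadata),
    paste(sprintf("%d %s", table(x$metadata$group)[group_levels], group_levels), collapse = ", "),
    dplyr::n_distinct(paste(x$logs$participant_id, x$logs$trial_id)),
    nrow(x$logs)
  ))
  invisible(x)
}

#' Closed-form expected rivalry rate of a synthetic observer
#'
#' For the single-zone (central) condition the latent process is an
#' ordinary renewal process whose cycle is one Gamma dominance duration
#' plus, with probability `mixed_prob`, an exponential mixed interlude.
#' The expected number of switches in a trial of length `t` is
#' `t/m + (s2 - m^2) / (2 m^2)` (renewal-function expansion, with `m` and
#' `s2` the cycle mean and variance), scaled to switches per minute.
#'
#' @param params An [observer_params()] list.
#' @param duration Trial duration in seconds. Default 60.
#' @return Expected rivalry rate (switches/min) including the
#'   finite-trial truncation correction.
#' @export
expected_rivalry_rate <- function(params, duration = 60) {
  stopifnot(inherits(params, "observer_params"))
  mu <- params$epoch_mean
  shape <- params$epoch_gamma_shape
  p <- params$mixed_prob
  m <- params$mixed_mean
  cyc_mean <- mu + p * m
  cyc_var <- mu^2 / shape + (p * 2 * m^2 - (p * m)^2)
  n_expected <- duration / cyc_mean + (cyc_var - cyc_mean^2) / (2 * cyc_mean^2)
  n_expected * 60 / duration
}
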