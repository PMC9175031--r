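#' Run configuration for the analysis pipeline
#'
#' @param tau_overlap Transition-wave threshold (s), see
#'   [resolve_timeline()]. Default 0.4.
#' @param tau_gap Switch-bridging gap limit (s); default `Inf`.
#' @param trial_duration Trial duration (s). Default 60.
#' @param seed Seed recorded in provenance and used by `simulate` stages.
#' @param use_age_covariate Adjust the rivalry-rate group tests for age?
#'   Default `TRUE`.
#' @param pairwise_method Familywise correction for pairwise comparisons:
#'   `"bonferroni"` (default) or `"lsd"`.
#' @param alpha Nominal significance level recorded in reports.
#'   Default 0.05.
#' @param verbose Emit per-stage progress messages to standard error?
#' @return A `run_config` list.
#' @export
run_config <- function(tau_overlap = 0.4, tau_gap = Inf, trial_duration = 60,
                       seed = 1L, use_age_covariate = TRUE,
                       pairwise_method = c("bonferroni", "lsd"),
                       alpha = 0.05, verbose = FALSE) {
  check_number(tau_overlap, "tau_overlap", lower = 0)
  if (!(is.numeric(tau_gap) && length(tau_gap) == 1L && !is.na(tau_gap) && tau_gap >= 0)) {
    abort("`tau_gap` must be a single non-negative number (Inf allowed).")
  }
  check_number(trial_duration, "trial_duration", lower = 1e-9)
  check_number(seed, "seed")
  check_number(alpha, "alpha", lower = 1e-12, upper = 1)
  pairwise_method <- match.arg(pairwise_method)
  structure(
    list(
      tau_overlap = tau_overlap, tau_gap = tau_gap,
      trial_duration = trial_duration, seed = as.integer(seed),
      use_age_covariate = isTRUE(use_age_covariate),
      pairwise_method = pairwise_method, alpha = alpha,
      verbose = isTRUE(verbose)
    ),
    class = "run_config"
  )
}

stage_msg <- function(config, fmt, ...) {
  if (isTRUE(config$verbose)) inform(sprintf(paste0("[rivalryr] ", fmt), ...))
}

run_stage <- function(stage, config, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)), parent = e)
  })
}

summarise_dominance <- function(metrics_by_condition, metadata) {
  metrics_by_condition |>
    left_join(metadata, by = "participant_id") |>
    group_by(.data$group, .data$condition_id) |>
    summarise(
      across(
        all_of(c("t_grouped", "t_ungrouped", "t_mixed")),
        list(mean = \(x) mean(x), sd = \(x) sd(x))
      ),
      n = dplyr::n(), .groups = "drop"
    ) |>
    arrange(match(.data$condition_id, condition_levels), match(.data$group, group_levels))
}

#' Run the complete analysis pipeline on a cohort of button logs
#'
#' Executes validate -> resolve -> per-trial metrics -> per-condition
#' aggregation -> group summaries -> statistical battery, and returns a
#' report bundle holding every table plus a provenance block (configuration
#' hash, seed, package version). The bundle is deterministic given inputs
#' and configuration. A self-consistency audit recomputes the group
#' summaries from the emitted per-participant table and aborts on any
#' mismatch.
#'
#' The statistical battery comprises: 4 (condition) x 2 (group) mixed
#' ANOVAs for grouped, ungrouped and mixed dominance time; a 4 x 2
#' (percept) x 2 (group) ANOVA for the percept effect; rivalry-rate mixed
#' ANOVAs for the two same-eye conditions (2 x 2, age covariate) and with
#' the central condition added (3 x 2); an independent t-test with Cohen's
#' d for the central rate and central exclusive dominance; pairwise
#' condition comparisons of grouped time; and the Mann-Whitney U test on
#' the per-participant epoch differences (between- minus within-hemifield
#' mean epoch). Participants with an undefined mean epoch in either
#' same-eye condition are excluded from the epoch-difference test and
#' counted in `epoch_diff_excluded`.
#'
#' @param logs Flat event-log tibble (schema of [read_event_logs()]).
#' @param metadata Cohort metadata (`participant_id`, `group`, `age`, ...).
#' @param config A [run_config()].
#' @return A `rivalry_report` list; see Details.
#' @export
run_pipeline <- function(logs, metadata, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  metadata <- as_tibble(metadata)
  check_schema(metadata, c("participant_id", "group", "age"), "metadata")

  metrics <- run_stage("metrics", config, {
    stage_msg(config, "resolving %d trials from %d press intervals",
      dplyr::n_distinct(paste(logs$participant_id, logs$trial_id)), nrow(logs))
    analyze_logs(logs, tau_overlap = config$tau_overlap, tau_gap = config$tau_gap)
  })
  unknown <- setdiff(unique(metrics$participant_id), metadata$participant_id)
  if (length(unknown)) {
    abort(sprintf("logs contain participants absent from metadata: %s", paste(unknown, collapse = ", ")))
  }

  by_condition <- run_stage("aggregate", config, {
    out <- aggregate_by_condition(metrics)
    stage_msg(config, "aggregated to %d participant x condition rows", nrow(out))
    out
  })
  joined <- left_join(by_condition, metadata, by = "participant_id")

  dominance_summary <- run_stage("summaries", config, summarise_dominance(by_condition, metadata))
  rate_summary <- run_stage("summaries", config, {
    joined |>
      filter(.data$condition_id %in% c("CENTRAL", "MO_SE_SH", "MO_SE_DH")) |>
      group_by(.data$group, .data$condition_id) |>
      summarise(
        rate_mean = mean(.data$rivalry_rate), rate_sd = sd(.data$rivalry_rate),
        n = dplyr::n(), .groups = "drop"
      ) |>
      arrange(match(.data$condition_id, condition_levels), match(.data$group, group_levels))
  })

  epoch_diff <- run_stage("epochs", config, {
    wide <- joined |>
      filter(.data$condition_id %in% c("MO_SE_SH", "MO_SE_DH")) |>
      select("participant_id", "group", "condition_id", "mean_epoch") |>
      tidyr::pivot_wider(names_from = "condition_id", values_from = "mean_epoch")
    mutate(wide, d_epoch = epoch_difference(.data$MO_SE_DH, .data$MO_SE_SH))
  })
  epoch_diff_complete <- filter(epoch_diff, !is.na(.data$d_epoch))
  epoch_diff_summary <- epoch_diff_complete |>
    group_by(.data$group) |>
    summarise(
      min = min(.data$d_epoch), q1 = quantile(.data$d_epoch, 0.25, names = FALSE),
      median = median(.data$d_epoch), q3 = quantile(.data$d_epoch, 0.75, names = FALSE),
      max = max(.data$d_epoch), mean = mean(.data$d_epoch),
      n = dplyr::n(), .groups = "drop"
    )

  stats <- run_stage("stats", config, {
    grouping4 <- filter(joined, .data$condition_id != "CENTRAL")
    se_rate <- filter(joined, .data$condition_id %in% c("MO_SE_SH", "MO_SE_DH"))
    se_central_rate <- filter(joined, .data$condition_id %in% c("CENTRAL", "MO_SE_SH", "MO_SE_DH"))
    central <- filter(joined, .data$condition_id == "CENTRAL")
    cov <- if (config$use_age_covariate) "age" else NULL
    percept_long <- grouping4 |>
      select("participant_id", "group", "condition_id", "t_grouped", "t_ungrouped") |>
      tidyr::pivot_longer(c("t_grouped", "t_ungrouped"),
        names_to = "percept", values_to = "t_dominance"
      ) |>
      mutate(percept = ifelse(.data$percept == "t_grouped", "grouped", "ungrouped"))
    g <- function(v) central[[v]][central$group == "glaucoma"]
    c_ <- function(v) central[[v]][central$group == "control"]
    list(
      anova_grouped = mixed_anova(grouping4, "t_grouped", "condition_id", "group", "participant_id"),
      anova_ungrouped = mixed_anova(grouping4, "t_ungrouped", "condition_id", "group", "participant_id"),
      anova_mixed = mixed_anova(grouping4, "t_mixed", "condition_id", "group", "participant_id"),
      anova_percept = mixed_anova(
        percept_long, "t_dominance", c("condition_id", "percept"), "group", "participant_id"
      ),
      anova_rate_se = mixed_anova(se_rate, "rivalry_rate", "condition_id", "group",
        "participant_id", covariate = cov
      ),
      anova_rate_se_central = mixed_anova(se_central_rate, "rivalry_rate", "condition_id",
        "group", "participant_id", covariate = cov
      ),
      # reported as control minus glaucoma: positive t/d = control larger
      ttest_central_rate = independent_t(c_("rivalry_rate"), g("rivalry_rate")),
      ttest_central_dominance = independent_t(c_("t_grouped"), g("t_grouped")),
      pairwise_grouped = pairwise_comparisons(
        grouping4, "t_grouped", "condition_id", "participant_id",
        method = config$pairwise_method
      ),
      mwu_epoch_diff = mann_whitney_u(
        epoch_diff_complete$d_epoch[epoch_diff_complete$group == "glaucoma"],
        epoch_diff_complete$d_epoch[epoch_diff_complete$group == "control"]
      )
    )
  })

  # self-consistency audit: summary cells must equal recomputation from the
  # emitted per-participant table
  run_stage("audit", config, {
    again <- summarise_dominance(aggregate_by_condition(metrics), metadata)
    if (!isTRUE(all.equal(as.data.frame(again), as.data.frame(dominance_summary),
      tolerance = 1e-12
    ))) {
      abort("report summaries do not match recomputation from the metrics table.")
    }
  })

  out <- list(
    metrics = metrics,
    by_condition = joined,
    dominance_summary = dominance_summary,
    rate_summary = rate_summary,
    epoch_diff = epoch_diff,
    epoch_diff_summary = epoch_diff_summary,
    epoch_diff_excluded = sum(is.na(epoch_diff$d_epoch)),
    stats = stats,
    provenance = list(
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed,
      version = as.character(packageVersion("rivalryr")),
      n_participants = nrow(metadata),
      n_trials = dplyr::n_distinct(paste(metrics$participant_id, metrics$trial_id))
    ),
    config = config
  )
  class(out) <- "rivalry_report"
  stage_msg(config, "report complete (%d participants, %d trials)",
    out$provenance$n_participants, out$provenance$n_trials)
  out
}

#' @export
print.rivalry_report <- function(x, ...) {
  cat(sprintf(
    "<rivalry_report> %d participants, %d trials (rivalryr %s, seed %d, config %s)\n",
    x$provenance$n_participants, x$provenance$n_trials,
    x$provenance$version, x$provenance$seed, substr(x$provenance$config_hash, 1, 8)
  ))
  cat("\nDominance time by group x condition (s):\n")
  print(as.data.frame(x$dominance_summary), digits = 3)
  cat("\nRivalry rate (switches/min):\n")
  print(as.data.frame(x$rate_summary), digits = 3)
  cat("\nEpoch difference (MO SE/DH - MO SE/SH, s):\n")
  print(as.data.frame(x$epoch_diff_summary), digits = 3)
  invisible(x)
}

#' @export
tidy.rivalry_report <- function(x, ...) x$by_condition

#' @export
glance.rivalry_report <- function(x, ...) {
  tibble(
    n_participants = x$provenance$n_participants,
    n_trials = x$provenance$n_trials,
    epoch_diff_excluded = x$epoch_diff_excluded,
    seed = x$provenance$seed,
    config_hash = x$provenance$config_hash,
    version = x$provenance$version
  )
}

provenance_header <- function(report) {
  p <- report$provenance
  sprintf(
    "# rivalryr %s | seed %d | config %s | participants %d | trials %d",
    p$version, p$seed, p$config_hash, p$n_participants, p$n_trials
  )
}

write_with_provenance <- function(df, path, header) {
  readr::write_lines(header, path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a report bundle to a directory of delimited text files
#'
#' Every table is written as UTF-8 CSV prefixed by a one-line provenance
#' comment (package version, seed, configuration hash). Missing values are
#' serialised as empty cells.
#'
#' @param report A `rivalry_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "rivalry_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- provenance_header(report)
  w <- function(df, name) write_with_provenance(df, file.path(dir, name), hdr)
  w(report$metrics, "metrics.csv")
  w(report$by_condition, "metrics_by_condition.csv")
  w(report$dominance_summary, "dominance_summary.csv")
  w(report$rate_summary, "rate_summary.csv")
  w(report$epoch_diff, "epoch_differences.csv")
  w(report$epoch_diff_summary, "epoch_difference_summary.csv")
  for (nm in names(report$stats)) {
    obj <- report$stats[[nm]]
    tab <- if (inherits(obj, "rivalry_anova")) tidy(obj) else obj
    w(tab, paste0(nm, ".csv"))
  }
  invisible(dir)
}
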