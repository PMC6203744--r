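#' End-to-end group-comparison report for a swim cohort
#'
#' Runs the full analysis chain on a cohort table with trajectories:
#' per-trial metrics, strategy classification, per-day group comparisons
#' (Mann-Whitney, Bonferroni-adjusted within each metric's across-day
#' family), day-5 (last-day) spatial-strategy comparison, and per-group
#' improvement rates. Subject-level values (per-subject means within day)
#' are the units of comparison. The report is deterministic given its
#' inputs.
#'
#' @param cohort tibble with a \code{trajectory} list-column and columns
#'   subject, group, day, trial (e.g. \code{\link{simulate_cohort}}).
#' @param thresholds classifier thresholds, see
#'   \code{\link{strategy_thresholds}}.
#' @return a \code{cohort_report}: list with \code{metrics} (per-trial
#'   table with labels), \code{speed} (overall group comparison),
#'   \code{by_day} (per-day latency/corridor/efficiency comparisons,
#'   Bonferroni within metric), \code{spatial} (per-group per-day spatial
#'   percentages, improvement rates, last-day comparison on per-subject
#'   spatial percent).
#' @export
run_report <- function(cohort, thresholds = strategy_thresholds()) {
  need <- c("subject", "group", "day", "trial", "trajectory")
  if (!all(need %in% names(cohort)))
    stop("cohort must have columns ", paste(need, collapse = ", "), call. = FALSE)
  groups <- sort(unique(cohort$group))
  if (length(groups) != 2)
    stop("report expects exactly two groups", call. = FALSE)
  met <- cohort_metrics(classify_cohort(cohort, thresholds))

  subj_day <- met |>
    dplyr::group_by(.data$group, .data$subject, .data$day) |>
    dplyr::summarise(latency_s = mean(.data$latency_s),
                     mean_speed_mps = mean(.data$mean_speed_mps),
                     corridor_percent = mean(.data$corridor_percent),
                     efficiency_ratio = mean(.data$efficiency_ratio),
                     spatial_percent = spatial_percent(.data$label),
                     .groups = "drop")
  subj_overall <- subj_day |>
    dplyr::group_by(.data$group, .data$subject) |>
    dplyr::summarise(mean_speed_mps = mean(.data$mean_speed_mps),
                     .groups = "drop")
  pick <- function(df, g, col) df[[col]][df$group == g]

  speed_cmp <- mann_whitney_u(pick(subj_overall, groups[1], "mean_speed_mps"),
                              pick(subj_overall, groups[2], "mean_speed_mps"))
  speed_cmp$metric <- "mean_speed_mps"
  speed_cmp$group_means <- paste(
    sprintf("%s=%.3f", groups,
            vapply(groups, function(g)
              mean(pick(subj_overall, g, "mean_speed_mps")), numeric(1))),
    collapse = ";")

  days <- sort(unique(cohort$day))
  by_day <- list()
  for (metric in c("latency_s", "corridor_percent", "efficiency_ratio")) {
    fam <- dplyr::bind_rows(lapply(days, function(d) {
      dd <- subj_day[subj_day$day == d, ]
      row <- mann_whitney_u(pick(dd, groups[1], metric),
                            pick(dd, groups[2], metric))
      row$metric <- metric; row$day <- d
      row
    }))
    by_day[[metric]] <- bonferroni_family(fam)
  }
  by_day <- dplyr::bind_rows(by_day)

  group_day_sp <- met |>
    dplyr::group_by(.data$group, .data$day) |>
    dplyr::summarise(spatial_percent = spatial_percent(.data$label),
                     .groups = "drop")
  improvement <- group_day_sp |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(improvement_rate_percent = improvement_rate(
      .data$spatial_percent[which.min(.data$day)],
      .data$spatial_percent[which.max(.data$day)]), .groups = "drop")
  last_day <- max(days)
  dd <- subj_day[subj_day$day == last_day, ]
  last_cmp <- mann_whitney_u(pick(dd, groups[1], "spatial_percent"),
                             pick(dd, groups[2], "spatial_percent"))
  last_cmp$metric <- "spatial_percent"; last_cmp$day <- last_day

  structure(list(groups = groups, metrics = met, subject_day = subj_day,
                 speed = speed_cmp, by_day = by_day,
                 spatial = list(by_group_day = group_day_sp,
                                improvement = improvement,
                                last_day_comparison = last_cmp)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report: groups %s, %d trials>\n",
              paste(x$groups, collapse = " vs "), nrow(x$metrics)))
  cat("swim speed: ", x$speed$group_means,
      sprintf(" (U = %g, p = %.4g)\n", x$speed$statistic, x$speed$p_value))
  print(x$spatial$improvement)
  invisible(x)
}

#' Write a report to CSV tables
#'
#' Writes the per-trial metric table and the comparison tables as plain
#' CSVs with fixed numeric formatting; identical reports produce
#' byte-identical files.
#'
#' @param report a \code{cohort_report}.
#' @param dir output directory (created if needed).
#' @return vector of written paths, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "cohort_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fmt <- function(df) {
    df <- as.data.frame(df)
    df$trajectory <- NULL
    for (j in seq_along(df))
      if (is.numeric(df[[j]])) df[[j]] <- sprintf("%.8g", df[[j]])
    df
  }
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(fmt(df), p, sep = ",", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    paths <<- c(paths, p)
  }
  wr(report$metrics, "trial_metrics.csv")
  wr(report$subject_day, "subject_day.csv")
  wr(report$speed, "speed_comparison.csv")
  wr(report$by_day, "by_day_comparisons.csv")
  wr(report$spatial$by_group_day, "spatial_percent_by_day.csv")
  wr(report$spatial$improvement, "improvement_rates.csv")
  wr(report$spatial$last_day_comparison, "last_day_spatial_comparison.csv")
  invisible(paths)
}
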